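#' Aligned read set
#'
#' A light container for coordinate-sorted single-end aligned reads: a
#' data.frame with columns `contig`, `pos` (1-based leftmost reference
#' position), `strand` (`"+"`/`"-"`), `seq` (reference-oriented bases, as in
#' SAM), `qual` (phred+33 string) and `mapq`, carrying the sample id as an
#' attribute. Reads are stored reference-oriented; routines that care about
#' molecule ends (damage counting, simulation) re-orient per read.
#'
#' @param reads data.frame with the columns above.
#' @param sample_id character scalar.
#' @return An object of class `aln_reads` (also a data.frame).
#' @export
aln_reads <- function(reads, sample_id = "sample") {
  need <- c("contig", "pos", "strand", "seq", "qual", "mapq")
  missing_cols <- setdiff(need, names(reads))
  if (length(missing_cols)) {
    stop("aln_reads: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  reads <- as.data.frame(reads)[, need]
  if (nrow(reads)) {
    if (any(reads$pos < 1L)) stop("aln_reads: positions must be >= 1")
    if (any(nchar(reads$seq) != nchar(reads$qual))) {
      stop("aln_reads: sequence and quality lengths differ")
    }
    if (!all(reads$strand %in% c("+", "-"))) {
      stop("aln_reads: strand must be '+' or '-'")
    }
  }
  reads$pos <- as.integer(reads$pos)
  reads$mapq <- as.integer(reads$mapq)
  rownames(reads) <- NULL
  structure(reads, class = c("aln_reads", "data.frame"), sample_id = sample_id)
}

#' @export
print.aln_reads <- function(x, ...) {
  cat(sprintf("<aln_reads> sample '%s': %d reads on %d contig(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$contig))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

read_lengths <- function(rs) nchar(rs$seq)

## TRUE when reads are coordinate-sorted within each contig.
is_coord_sorted <- function(rs) {
  if (nrow(rs) < 2L) return(TRUE)
  all(unlist(lapply(split(rs$pos, rs$contig), function(p) !is.unsorted(p))))
}

## Subset preserving class/attributes.
reads_subset <- function(rs, keep) {
  aln_reads(as.data.frame(rs)[keep, , drop = FALSE],
            sample_id = attr(rs, "sample_id"))
}

#' Pile up read bases at single-base reference positions
#'
#' Internal workhorse shared by consensus building, haplogroup status calls,
#' pseudohaploid genotyping and contamination estimation. Returns one row per
#' (read, site) overlap with the read base, its phred quality, and the offset
#' of the site from the molecule's 5' end (strand-aware), after optional
#' end-trimming and mapping-quality filtering.
#'
#' @param rs an [aln_reads] object.
#' @param contig contig name to pile up on.
#' @param positions integer vector of 1-based reference positions.
#' @param min_mapq,min_bq quality filters.
#' @param end_trim disregard bases within this many positions of either read
#'   end (damage avoidance).
#' @return data.frame with columns `site` (index into `positions`), `pos`,
#'   `base`, `bq`, `read`, `off5`, `len`, `strand`.
#' @keywords internal
pileup_bases <- function(rs, contig, positions, min_mapq = 0L, min_bq = 0L,
                         end_trim = 0L) {
  empty <- data.frame(site = integer(0), pos = integer(0),
                      base = character(0), bq = integer(0), read = integer(0),
                      off5 = integer(0), len = integer(0), strand = character(0))
  on_contig <- which(rs$contig == contig & rs$mapq >= min_mapq)
  if (!length(on_contig) || !length(positions)) return(empty)
  sub <- as.data.frame(rs)[on_contig, ]
  lens <- nchar(sub$seq)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = positions, width = 1L),
    IRanges::IRanges(start = sub$pos, width = lens)
  )
  if (!length(hits)) return(empty)
  si <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  off <- positions[si] - sub$pos[ri] + 1L       # reference-orientation offset
  len <- lens[ri]
  base <- substr(sub$seq[ri], off, off)
  bq <- utf8ToInt(paste(substr(sub$qual[ri], off, off), collapse = "")) - 33L
  if (!length(bq)) bq <- integer(0)
  off5 <- ifelse(sub$strand[ri] == "+", off, len - off + 1L)
  keep <- bq >= min_bq & off5 > end_trim & (len - off5 + 1L) > end_trim
  data.frame(site = si, pos = positions[si], base = base, bq = bq,
             read = on_contig[ri], off5 = off5, len = len,
             strand = sub$strand[ri])[keep, , drop = FALSE]
}
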