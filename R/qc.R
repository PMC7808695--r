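## Read-level screening statistics: quality/length filtering, duplicate
## collapse, deamination damage profiles, endogenous content and depth of
## coverage, and the screening decision.

#' Filter aligned reads on mapping quality and length
#'
#' Both thresholds are inclusive: a read with MAPQ exactly `min_mapq` or
#' length exactly `min_len` is kept. Read order is preserved; an empty result
#' is allowed.
#'
#' @param rs an [aln_reads] object.
#' @param min_mapq minimum mapping quality (default 30).
#' @param min_len minimum read length in bp (default 30).
#' @return The filtered [aln_reads].
#' @export
filter_reads <- function(rs, min_mapq = 30L, min_len = 30L) {
  reads_subset(rs, rs$mapq >= min_mapq & read_lengths(rs) >= min_len)
}

#' Collapse PCR/optical duplicates
#'
#' Reads sharing (contig, 5' alignment position, strand, length) are
#' considered duplicates of one molecule; the copy with the highest summed
#' base quality is kept, ties broken by lexicographically smallest sequence.
#' The 5' position of a reverse-strand read is its rightmost reference
#' coordinate. Input must be coordinate-sorted.
#'
#' @param rs an [aln_reads] object, coordinate-sorted.
#' @return A list: `reads` (deduplicated [aln_reads], original order) and
#'   `n_removed`.
#' @export
collapse_duplicates <- function(rs) {
  if (!is_coord_sorted(rs)) {
    stop("collapse_duplicates: input must be coordinate-sorted")
  }
  n <- nrow(rs)
  if (n == 0L) return(list(reads = rs, n_removed = 0L))
  len <- read_lengths(rs)
  p5 <- ifelse(rs$strand == "+", rs$pos, rs$pos + len - 1L)
  key <- paste(rs$contig, p5, rs$strand, len, sep = "\r")
  score <- qual_sums(rs$qual)
  ord <- order(key, -score, rs$seq)
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  list(reads = reads_subset(rs, keep), n_removed = n - length(keep))
}

#' Post-mortem deamination damage profile
#'
#' Per-position C-to-T mismatch frequency from the 5' end of each molecule
#' and G-to-A from the 3' end, against the reference. Reverse-strand reads
#' are re-oriented to molecule coordinates before counting, so "5'" always
#' means the sequenced molecule's 5' terminus. Positions with zero
#' opportunities (no reference C at that 5' offset, or no G at the 3'
#' offset) report `NA`, not 0.
#'
#' @param rs an [aln_reads] object.
#' @param ref named character vector of contig sequences (must cover every
#'   read span).
#' @param window number of positions profiled from each end (default 25).
#' @return An object of class `damage_profile`: `window`, `ct5`, `ga3`
#'   (frequencies, `NA` when unobservable), and `counts` (data.frame of
#'   per-position opportunity and mismatch counts).
#' @export
damage_profile <- function(rs, ref, window = 25L) {
  bad <- setdiff(unique(rs$contig), names(ref))
  if (length(bad)) {
    stop("damage_profile: reference missing contig(s): ",
         paste(bad, collapse = ", "))
  }
  len <- read_lengths(rs)
  ref_slice <- substring(ref[rs$contig], rs$pos, rs$pos + len - 1L)
  minus <- rs$strand == "-"
  read_m <- rs$seq
  read_m[minus] <- revcomp(read_m[minus])
  ref_m <- ref_slice
  ref_m[minus] <- revcomp(ref_m[minus])
  opp5 <- mis5 <- opp3 <- mis3 <- integer(window)
  for (p in seq_len(window)) {
    rb <- substr(ref_m, p, p)
    db <- substr(read_m, p, p)
    opp5[p] <- sum(rb == "C")
    mis5[p] <- sum(rb == "C" & db == "T")
    q <- len - p + 1L
    rb3 <- substr(ref_m, q, q)
    db3 <- substr(read_m, q, q)
    ok <- len >= p
    opp3[p] <- sum(ok & rb3 == "G")
    mis3[p] <- sum(ok & rb3 == "G" & db3 == "A")
  }
  ct5 <- ifelse(opp5 > 0, mis5 / opp5, NA_real_)
  ga3 <- ifelse(opp3 > 0, mis3 / opp3, NA_real_)
  structure(list(window = window, ct5 = ct5, ga3 = ga3,
                 counts = data.frame(position = seq_len(window), opp5 = opp5,
                                     mis5 = mis5, opp3 = opp3, mis3 = mis3)),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("<damage_profile> window %d; 5' C-T at position 1: %s\n",
              x$window,
              ifelse(is.na(x$ct5[1]), "NA",
                     sprintf("%.1f%%", 100 * x$ct5[1]))))
  invisible(x)
}

#' Per-sample sequencing QC summary
#'
#' Endogenous content is the percentage of raw reads that survived mapping
#' and filtering; depth of coverage is total aligned bases divided by
#' compartment length, reported separately for the nuclear genome and the
#' mitochondrion.
#'
#' @param n_reads_raw total raw (pre-mapping) read count; must be > 0.
#' @param rs post-filter [aln_reads].
#' @param compartment_lengths named contig lengths (> 0).
#' @param mt_contig name of the mitochondrial contig (default `"MT"`).
#' @param n_duplicates_removed optional count from [collapse_duplicates()].
#' @return An object of class `sample_qc` with fields `endogenous_pct`,
#'   `doc_nuclear`, `doc_mt`, `mean_fragment_bp`, `n_reads_raw`,
#'   `n_reads_postfilter`, `n_duplicates_removed`.
#' @export
sample_qc <- function(n_reads_raw, rs, compartment_lengths, mt_contig = "MT",
                      n_duplicates_removed = NA_integer_) {
  if (n_reads_raw <= 0) stop("sample_qc: raw read count must be > 0")
  if (any(compartment_lengths <= 0)) {
    stop("sample_qc: compartment lengths must be > 0")
  }
  len <- read_lengths(rs)
  is_mt <- rs$contig == mt_contig
  nuc_len <- sum(compartment_lengths[setdiff(names(compartment_lengths),
                                             mt_contig)])
  mt_len <- compartment_lengths[[mt_contig]]
  structure(list(
    endogenous_pct = 100 * nrow(rs) / n_reads_raw,
    doc_nuclear = sum(len[!is_mt]) / nuc_len,
    doc_mt = sum(len[is_mt]) / mt_len,
    mean_fragment_bp = if (nrow(rs)) mean(len) else NA_real_,
    n_reads_raw = n_reads_raw,
    n_reads_postfilter = nrow(rs),
    n_duplicates_removed = n_duplicates_removed
  ), class = "sample_qc")
}

#' @export
print.sample_qc <- function(x, ...) {
  cat(sprintf(
    "<sample_qc> Endo%% %.2f | DoC %.3f | MT DoC %.1f | mean fragment %.1f bp\n",
    x$endogenous_pct, x$doc_nuclear, x$doc_mt, x$mean_fragment_bp))
  invisible(x)
}

#' Screening decision for deeper sequencing
#'
#' A sample passes screening when its endogenous content is at least
#' `min_endo_pct` percent AND its position-1 5' C-to-T damage is at least
#' `min_ct5_pct` percent (both boundaries inclusive — the complement of the
#' exclusion rule "endogenous < 0.5% and < 10% C-T damage"). A missing
#' position-1 damage estimate fails with an explanatory reason.
#'
#' @param qc a [sample_qc] (or anything with `$endogenous_pct`).
#' @param dp a [damage_profile] (or anything with `$ct5`).
#' @param min_endo_pct,min_ct5_pct thresholds in percent.
#' @return A list: `decision` (`"pass"`/`"fail"`) and `reasons` (character,
#'   empty on pass).
#' @export
screen_sample <- function(qc, dp, min_endo_pct = 0.5, min_ct5_pct = 10) {
  reasons <- character(0)
  ct5_1 <- dp$ct5[1]
  if (is.na(ct5_1)) {
    reasons <- c(reasons, "insufficient damage opportunities")
  } else if (100 * ct5_1 < min_ct5_pct) {
    reasons <- c(reasons, sprintf("5' C-T damage %.1f%% < %.1f%%",
                                  100 * ct5_1, min_ct5_pct))
  }
  if (qc$endogenous_pct < min_endo_pct) {
    reasons <- c(reasons, sprintf("endogenous content %.2f%% < %.2f%%",
                                  qc$endogenous_pct, min_endo_pct))
  }
  list(decision = if (length(reasons)) "fail" else "pass", reasons = reasons)
}
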