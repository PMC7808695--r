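## Readers and writers for the interchange formats: SAM (reads), FASTA
## (reference), VCF + labels TSV (SNP panel), Newick + TSV (haplogroup
## definitions), 3-column ASCII tables (calibration curves).

#' Write an aligned read set as coordinate-sorted single-end SAM
#'
#' @param rs an [aln_reads] object.
#' @param ref_lengths named integer vector of contig lengths (header `@SQ`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(rs, ref_lengths, path) {
  if (!is_coord_sorted(rs)) stop("write_sam: reads must be coordinate-sorted")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)),
           sprintf("@RG\tID:%s\tSM:%s", attr(rs, "sample_id"),
                   attr(rs, "sample_id")))
  body <- character(0)
  if (nrow(rs)) {
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                    paste0(attr(rs, "sample_id"), ".", seq_len(nrow(rs))),
                    ifelse(rs$strand == "-", 16L, 0L),
                    rs$contig, rs$pos, rs$mapq, nchar(rs$seq), rs$seq, rs$qual)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a single-end SAM file into an aligned read set
#'
#' The file is converted to BAM with Rsamtools and scanned. Unmapped records
#' and records whose CIGAR is not a single pure match (`<n>M`) are tallied and
#' skipped: gapped or clipped alignments are outside this package's read
#' model.
#'
#' @param path SAM (or BAM) file path.
#' @param sample_id sample name; defaults to the file stem.
#' @return An [aln_reads] object with attribute `skipped` = c(unmapped,
#'   non_pure_match).
#' @export
read_sam <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("read_sam: no such file: ", path)
  sample_id <- sample_id %||% sub("\\.(sam|bam)$", "", basename(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  }
  b <- Rsamtools::scanBam(
    Rsamtools::BamFile(bam),
    param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "strand", "pos", "mapq", "cigar", "seq", "qual")
    )
  )[[1]]
  unmapped <- bitwAnd(b$flag, 4L) > 0L | is.na(b$pos)
  pure <- !unmapped & grepl("^[0-9]+M$", b$cigar)
  skipped <- c(unmapped = sum(unmapped), non_pure_match = sum(!unmapped & !pure))
  keep <- which(pure)
  rs <- aln_reads(data.frame(
    contig = as.character(b$rname)[keep],
    pos = b$pos[keep],
    strand = ifelse(as.character(b$strand)[keep] == "-", "-", "+"),
    seq = as.character(b$seq)[keep],
    qual = as.character(b$qual)[keep],
    mapq = b$mapq[keep]
  ), sample_id = sample_id)
  attr(rs, "skipped") <- skipped
  rs
}

#' Write / read a reference genome as FASTA
#'
#' Thin wrappers over Biostrings keeping the package-internal representation
#' (a named character vector of contig sequences).
#'
#' @param ref named character vector of contig sequences.
#' @param path file path.
#' @return `write_fasta()` returns `path`; `read_fasta()` the named vector.
#' @export
write_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a SNP site panel as VCF plus a population-label TSV
#'
#' @param panel a [site_panel] object.
#' @param vcf_path,labels_path output paths.
#' @return `vcf_path`, invisibly.
#' @export
write_panel_vcf <- function(panel, vcf_path, labels_path = NULL) {
  sites <- panel$sites
  geno <- panel$geno                      # individuals x sites dosage
  gt <- matrix("./.", nrow = ncol(geno), ncol = nrow(geno))
  codes <- c("0/0", "0/1", "1/1")
  ok <- !is.na(t(geno))
  gt[ok] <- codes[t(geno)[ok] + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(sites$contig)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"),
    apply(cbind(sites$contig, sites$pos, paste0("snp", seq_len(nrow(sites))),
                sites$ref, sites$alt, ".", "PASS", ".", "GT", gt),
          1, paste, collapse = "\t")
  )
  writeLines(lines, vcf_path)
  if (!is.null(labels_path)) {
    write.table(panel$labels, labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(vcf_path)
}

#' Read a biallelic SNP panel from VCF (+ optional labels TSV)
#'
#' Multi-allelic records, non-SNP alleles, and (by default) transition sites
#' are dropped, with the counts reported in the `dropped` attribute. Ancient
#' population genomics restricts to transversions because post-mortem
#' deamination creates artifactual transitions.
#'
#' @param path VCF path (plain or gzipped).
#' @param labels_path optional TSV with columns `individual`, `population`
#'   (extra columns kept). Every genotyped individual must be present.
#' @param transversions_only drop transition sites (default TRUE).
#' @return A [site_panel] object.
#' @export
read_panel_vcf <- function(path, labels_path = NULL, transversions_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v)
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT) &
    fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES
  tv <- is_transversion(fix$REF, fix$ALT)
  keep <- if (transversions_only) snp & tv else snp
  dropped <- c(non_biallelic_snp = sum(!snp),
               transitions = if (transversions_only) sum(snp & !tv) else 0L)
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]
  dosage <- matrix(NA_integer_, nrow = ncol(gt_raw), ncol = nrow(gt_raw),
                   dimnames = list(colnames(gt_raw), NULL))
  clean <- gsub("\\|", "/", t(gt_raw))
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- read.table(labels_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    miss <- setdiff(rownames(dosage), labels$individual)
    if (length(miss)) {
      stop("read_panel_vcf: label file missing individual(s): ",
           paste(miss, collapse = ", "))
    }
  }
  panel <- site_panel(
    sites = data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                       ref = fix$REF, alt = fix$ALT,
                       is_transversion = is_transversion(fix$REF, fix$ALT)),
    geno = dosage, labels = labels
  )
  attr(panel, "dropped") <- dropped
  panel
}

#' Read a radiocarbon calibration curve table
#'
#' Accepts the standard IntCal distribution layout: comment lines starting
#' with `#`, then at least three columns (cal BP, conventional 14C age BP,
#' curve sigma), comma- or whitespace-separated.
#'
#' @param path curve file path.
#' @param name curve label.
#' @return A [cal_curve] object.
#' @export
read_calcurve <- function(path, name = basename(path)) {
  first <- readLines(path, n = 50)
  first <- first[!grepl("^\\s*#", first)][1]
  sep <- if (grepl(",", first)) "," else ""
  tab <- read.table(path, comment.char = "#", sep = sep, header = FALSE,
                    strip.white = TRUE)
  cal_curve(cal_bp = tab[[1]], mu = tab[[2]], sigma = tab[[3]], name = name)
}

#' Write haplogroup definitions (Newick tree + variants TSV)
#'
#' @param defs a [haplo_defs] object.
#' @param tree_path,variants_path output paths.
#' @return `tree_path`, invisibly.
#' @export
write_haplo_defs <- function(defs, tree_path, variants_path) {
  ape::write.tree(defs$tree, file = tree_path)
  write.table(defs$variants, variants_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(tree_path)
}

#' @rdname write_haplo_defs
#' @param contig contig the variants live on (stored on the object).
#' @export
read_haplo_defs <- function(tree_path, variants_path, contig = "MT") {
  tree <- ape::read.tree(tree_path)
  variants <- read.table(variants_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  haplo_defs(tree, variants, contig = contig)
}
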