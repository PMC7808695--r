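## Pseudohaploid genotyping, identity-by-state distances, and classical
## multidimensional scaling.

#' Pseudohaploid genotype calls at panel sites
#'
#' At each panel site one high-quality read base is sampled uniformly among
#' passing bases that match the site's ref or alt allele (bases matching
#' neither are excluded before sampling); sites with no passing ref/alt base
#' are missing. This avoids diploid genotype calling at low coverage: every
#' individual contributes exactly one allele per covered site.
#'
#' @param rs an [aln_reads] object.
#' @param panel a [site_panel] (its `sites` table is used).
#' @param min_mapq,min_bq quality filters (defaults 30 / 30).
#' @param seed integer seed making the allele sampling reproducible.
#' @return An object of class `pseudohaploid`: integer vector (`0` ref, `1`
#'   alt, `NA` missing) with attributes `n_covered` and `sample_id`.
#' @export
pseudohaploid_call <- function(rs, panel, min_mapq = 30L, min_bq = 30L,
                               seed = 1L) {
  sites <- panel$sites
  calls <- rep(NA_integer_, nrow(sites))
  with_seed(seed, {
    for (ctg in unique(sites$contig)) {
      idx <- which(sites$contig == ctg)
      pb <- pileup_bases(rs, ctg, sites$pos[idx], min_mapq = min_mapq,
                         min_bq = min_bq)
      if (!nrow(pb)) next
      is_ref <- pb$base == sites$ref[idx][pb$site]
      is_alt <- pb$base == sites$alt[idx][pb$site]
      pb <- pb[is_ref | is_alt, , drop = FALSE]
      al <- as.integer(is_alt[is_ref | is_alt])
      if (!nrow(pb)) next
      ## Uniform sampling among passing alleles per site.
      ord <- sample.int(nrow(pb))
      first <- ord[!duplicated(pb$site[ord])]
      calls[idx[pb$site[first]]] <- al[first]
    }
  })
  structure(calls, n_covered = sum(!is.na(calls)),
            sample_id = attr(rs, "sample_id"), class = "pseudohaploid")
}

#' Covered-SNP count and percentage of the panel
#'
#' @param n_covered number of covered panel sites (or a `pseudohaploid`
#'   object).
#' @param panel_size total panel size M (> 0).
#' @return list with `n_covered`, `percent` (rounded to 1 decimal).
#' @export
coverage_report <- function(n_covered, panel_size) {
  if (panel_size <= 0) stop("coverage_report: panel size must be > 0")
  if (inherits(n_covered, "pseudohaploid")) {
    n_covered <- attr(n_covered, "n_covered")
  }
  list(n_covered = n_covered,
       percent = round(100 * n_covered / panel_size, 1))
}

#' Haploidize diploid panel genotypes
#'
#' Draws one allele per site per individual (heterozygotes by a fair coin)
#' so identity-by-state comparisons with pseudohaploid ancient samples are
#' made on a uniform ploidy; mixing diploid and haploid callsets biases IBS.
#'
#' @param geno individuals x sites dosage matrix (0/1/2/NA).
#' @param seed integer seed.
#' @return Matrix of 0/1/NA haploid calls, same dimnames.
#' @export
haploidize <- function(geno, seed = 1L) {
  with_seed(seed, {
    out <- geno
    out[geno == 2L] <- 1L
    het <- which(geno == 1L)
    out[het] <- rbinom(length(het), 1L, 0.5)
    out
  })
}

#' Pairwise identity-by-state sharing and distances
#'
#' For each pair of individuals, `p_ibs` is the fraction of overlapping
#' non-missing sites carrying the identical allele; the genetic distance is
#' `1 - p_ibs`. Pairs with fewer than `min_overlap` shared sites are flagged
#' and their distance set missing.
#'
#' @param calls individuals x sites matrix of haploid 0/1/NA calls (rownames
#'   = individual ids).
#' @param min_overlap minimum shared non-missing sites per pair (default
#'   500).
#' @return An object of class `ibs_matrix`: `p_ibs`, `overlap`, `distance`
#'   (all n x n), and `flagged` (logical matrix).
#' @export
ibs_matrix <- function(calls, min_overlap = 500L) {
  if (nrow(calls) < 2L) stop("ibs_matrix: need at least 2 individuals")
  a1 <- (calls == 1L) & !is.na(calls)
  a0 <- (calls == 0L) & !is.na(calls)
  mode(a1) <- "numeric"; mode(a0) <- "numeric"
  shared_same <- tcrossprod(a1) + tcrossprod(a0)
  overlap <- tcrossprod(a1 + a0)
  p_ibs <- ifelse(overlap > 0, shared_same / overlap, NA_real_)
  distance <- 1 - p_ibs
  flagged <- overlap < min_overlap
  diag(distance) <- 0
  distance[flagged & !diag(nrow(calls))] <- NA_real_
  structure(list(p_ibs = p_ibs, overlap = overlap, distance = distance,
                 flagged = flagged), class = "ibs_matrix")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix and takes the top eigenpairs
#' (`stats::cmdscale`), with a deterministic sign convention: the first
#' nonzero loading of each axis is made positive. Individuals with any
#' missing distance are dropped first and reported.
#'
#' @param d an [ibs_matrix] or a symmetric distance matrix.
#' @param n_dims number of dimensions (default 2).
#' @return list with `points` (individuals x n_dims), `eig` (all
#'   eigenvalues), `dropped` (ids removed for missing distances).
#' @export
classical_mds <- function(d, n_dims = 2L) {
  D <- if (inherits(d, "ibs_matrix")) d$distance else d
  if (!isSymmetric(unname(D))) stop("classical_mds: distance matrix must be symmetric")
  dropped <- character(0)
  while (anyNA(D) && nrow(D) > 2L) {
    worst <- which.max(rowSums(is.na(D)))
    dropped <- c(dropped, rownames(D)[worst] %||% as.character(worst))
    D <- D[-worst, -worst, drop = FALSE]
  }
  if (anyNA(D)) stop("classical_mds: too many missing distances")
  fit <- cmdscale(D, k = n_dims, eig = TRUE)
  pts <- fit$points
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  list(points = pts, eig = fit$eig, dropped = dropped)
}
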