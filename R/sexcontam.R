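## Genetic sex from X/Y read counts, mitochondrial consensus and
## mixture-likelihood contamination, and male X method-of-moments
## contamination.

#' Genetic sex from the Y read ratio
#'
#' `Ry = nY / (nX + nY)` with a normal-approximation 95% confidence interval
#' `Ry +/- 1.96 sqrt(Ry(1-Ry)/(nX+nY))`. The sample is called XY when the
#' whole interval sits above `xy_threshold`, XX when it sits below
#' `xx_threshold`, and inconclusive otherwise.
#'
#' @param nX,nY read counts mapped to X and Y after filtering.
#' @param xy_threshold,xx_threshold assignment thresholds on Ry (defaults
#'   0.075 and 0.016, the published criteria of the shotgun sex-typing
#'   method).
#' @return An object of class `sex_call`: `nX`, `nY`, `ry`, `ci_low`,
#'   `ci_high`, `assignment`.
#' @export
ry_sex <- function(nX, nY, xy_threshold = 0.075, xx_threshold = 0.016) {
  n <- nX + nY
  if (n <= 0) stop("ry_sex: no sex-chromosome reads (nX + nY = 0)")
  ry <- nY / n
  half <- 1.96 * sqrt(ry * (1 - ry) / n)
  ci <- c(max(0, ry - half), min(1, ry + half))
  assignment <- if (ci[1] > xy_threshold) "XY"
  else if (ci[2] < xx_threshold) "XX"
  else "inconclusive"
  structure(list(nX = nX, nY = nY, ry = ry, ci_low = ci[1], ci_high = ci[2],
                 assignment = assignment), class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("<sex_call> %s, Ry %.3f (%.3f-%.3f) from %d reads\n",
              x$assignment, x$ry, x$ci_low, x$ci_high, x$nX + x$nY))
  invisible(x)
}

#' Majority-rule mitochondrial consensus
#'
#' Per-site majority base over reads, after disregarding `end_trim` bases
#' from each read end (deamination damage concentrates at the termini).
#' Sites with depth below `min_depth` and ties emit `N`.
#'
#' @param rs an [aln_reads] object.
#' @param mt_length length of the mitochondrial contig.
#' @param mt_contig contig name (default `"MT"`).
#' @param min_depth minimum depth for a call (default 3).
#' @param end_trim bases ignored at each read end (default 7).
#' @return A consensus sequence string of length `mt_length` (N = no call).
#' @export
mt_consensus <- function(rs, mt_length, mt_contig = "MT", min_depth = 3L,
                         end_trim = 7L) {
  sub <- as.data.frame(rs)[rs$contig == mt_contig, , drop = FALSE]
  counts <- matrix(0L, nrow = 4, ncol = mt_length, dimnames = list(DNA_BASES))
  if (nrow(sub)) {
    lens <- nchar(sub$seq)
    use <- lens > 2L * end_trim
    sub <- sub[use, , drop = FALSE]
    lens <- lens[use]
    if (nrow(sub)) {
      trimmed <- substr(sub$seq, end_trim + 1L, lens - end_trim)
      tlens <- lens - 2L * end_trim
      pos <- unlist(lapply(seq_len(nrow(sub)), function(i) {
        sub$pos[i] + end_trim + seq_len(tlens[i]) - 1L
      }))
      base <- unlist(strsplit(trimmed, "", fixed = TRUE))
      code <- match(base, DNA_BASES)
      ok <- !is.na(code) & pos >= 1L & pos <= mt_length
      idx <- (pos[ok] - 1L) * 4L + code[ok]
      tab <- tabulate(idx, nbins = 4L * mt_length)
      counts <- matrix(tab, nrow = 4, dimnames = list(DNA_BASES))
    }
  }
  depth <- colSums(counts)
  top <- apply(counts, 2, max)
  winner <- DNA_BASES[apply(counts, 2, which.max)]
  tie <- colSums(counts == rep(top, each = 4)) > 1L
  winner[depth < min_depth | tie | top == 0L] <- "N"
  paste(winner, collapse = "")
}

#' Mitochondrial contamination by two-component mixture likelihood
#'
#' Models each read as coming from the sample's own consensus with
#' probability `1 - c` or from a modern contaminant haplotype (averaged over
#' a candidate panel) with probability `c`. Per-read likelihoods use only
#' sites where some panel haplotype disagrees with the consensus
#' (discriminating sites), with a symmetric per-base error `epsilon`:
#' matches contribute `1 - epsilon`, mismatches `epsilon / 3`. Read termini
#' are trimmed so residual deamination cannot masquerade as contaminant
#' alleles. The estimate is the grid maximiser of the mixture log-likelihood
#' over `c in {0, 0.001, ..., 1}` and the 95% CI is the profile-likelihood
#' region (log-likelihood within 1.92 of the maximum).
#'
#' @param rs an [aln_reads] with mitochondrial reads.
#' @param consensus consensus string from [mt_consensus()].
#' @param contaminant_panel character vector of candidate contaminant
#'   mitochondrial haplotypes (full-length strings).
#' @param error_rate per-base error; `NULL` (default) estimates it from
#'   non-discriminating sites, with deamination-type mismatches excluded.
#' @param mt_contig contig name.
#' @param end_trim bases ignored at each read end (default 7).
#' @param grid_step grid resolution for `c` (default 0.001).
#' @return An object of class `contam_estimate` (`method = "mt_mixture"`).
#' @export
mt_contamination <- function(rs, consensus, contaminant_panel,
                             error_rate = NULL, mt_contig = "MT",
                             end_trim = 7L, grid_step = 0.001) {
  if (!length(contaminant_panel)) {
    stop("mt_contamination: contaminant panel is empty")
  }
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  hap_mat <- do.call(rbind, strsplit(contaminant_panel, "", fixed = TRUE))
  callable <- cons != "N"
  disc <- which(callable &
                  colSums(hap_mat != rep(cons, each = nrow(hap_mat))) > 0)
  if (!length(disc)) stop("mt_contamination: unidentifiable (no discriminating sites)")
  pb <- pileup_bases(rs, mt_contig, disc, end_trim = end_trim)
  pb <- pb[pb$base %in% DNA_BASES, , drop = FALSE]
  if (!nrow(pb)) {
    stop("mt_contamination: unidentifiable (no reads cover discriminating sites)")
  }
  ## Error rate from non-discriminating callable sites, ignoring C-T/G-A
  ## mismatch types (deamination leakage).
  eps <- error_rate
  if (is.null(eps)) {
    nd <- which(callable)
    nd <- setdiff(nd, disc)
    if (length(nd) > 2000L) {
      nd <- nd[unique(round(seq(1, length(nd), length.out = 2000L)))]
    }
    pe <- pileup_bases(rs, mt_contig, nd, end_trim = end_trim)
    pe <- pe[pe$base %in% DNA_BASES, , drop = FALSE]
    if (nrow(pe)) {
      cb <- cons[pe$pos]
      mism <- pe$base != cb
      deam_like <- (cb == "C" & pe$base == "T") | (cb == "G" & pe$base == "A")
      eps <- sum(mism & !deam_like) / max(1L, sum(!deam_like))
    }
    eps <- max(eps %||% 0, 1e-4)
  }
  eps <- min(max(eps, 1e-6), 0.25)
  cons_b <- cons[pb$pos]
  match_cons <- pb$base == cons_b
  reads <- unique(pb$read)
  n_sites_r <- tabulate(match(pb$read, reads), length(reads))
  m_cons_r <- rowsum(as.numeric(!match_cons), match(pb$read, reads))[, 1]
  ## log L(read | consensus) and per-haplotype, then panel mean.
  logLA <- (n_sites_r - m_cons_r) * log1p(-eps) + m_cons_r * log(eps / 3)
  logLH <- matrix(NA_real_, nrow = length(reads), ncol = nrow(hap_mat))
  for (h in seq_len(nrow(hap_mat))) {
    hb <- hap_mat[h, pb$pos]
    m_h <- rowsum(as.numeric(pb$base != hb), match(pb$read, reads))[, 1]
    logLH[, h] <- (n_sites_r - m_h) * log1p(-eps) + m_h * log(eps / 3)
  }
  mx <- apply(logLH, 1, max)
  logLB <- mx + log(rowMeans(exp(logLH - mx)))
  cgrid <- seq(0, 1, by = grid_step)
  base <- pmax(logLA, logLB)
  a <- exp(logLA - base)
  b <- exp(logLB - base)
  ll <- vapply(cgrid, function(cc) sum(base + log((1 - cc) * a + cc * b)),
               numeric(1))
  best <- which.max(ll)
  inside <- ll >= ll[best] - qchisq(0.95, 1) / 2
  structure(list(
    method = "mt_mixture",
    estimate = cgrid[best],
    ci_low = min(cgrid[inside]),
    ci_high = max(cgrid[inside]),
    n_informative = length(reads),
    error_rate = eps,
    loglik = ll[best]
  ), class = "contam_estimate")
}

#' @export
print.contam_estimate <- function(x, ...) {
  cat(sprintf("<contam_estimate> %s: %.2f%% (95%% CI %.2f-%.2f%%), n = %d\n",
              x$method, 100 * x$estimate, 100 * x$ci_low, 100 * x$ci_high,
              x$n_informative))
  invisible(x)
}

#' Male X-chromosome contamination by method of moments
#'
#' A male carries one X, so any site where his reads show both panel alleles
#' indicates contamination (or error). The estimator contrasts the aggregate
#' minor-allele read fraction at known polymorphic sites (`m_poly`) with the
#' per-allele mismatch rate at monomorphic control sites (`m_mono`), scaled
#' by the expected allele difference between the sample and a random
#' contaminant, `mean(2 f (1 - f))`:
#' `c_hat = (m_poly - m_mono) / mean(2 f (1 - f))`, clamped to `[0, 1]`.
#' Only sites with at least two passing reads are informative (a single read
#' can never show a minor allele). The 95% CI is a site-level bootstrap.
#'
#' @param rs an [aln_reads] for a male sample.
#' @param x_sites data.frame with `pos`, `ref`, `alt`, `f` (population
#'   alt-allele frequency; `f = 0` rows are monomorphic controls).
#' @param min_mapq,min_bq quality filters (defaults 30 / 20).
#' @param x_contig contig name (default `"X"`).
#' @param min_sites minimum informative polymorphic sites (default 50).
#' @param n_boot bootstrap resamples (default 200).
#' @return An object of class `contam_estimate` (`method = "x_moments"`).
#' @export
x_contamination <- function(rs, x_sites, min_mapq = 30L, min_bq = 20L,
                            x_contig = "X", min_sites = 50L, n_boot = 200L) {
  poly <- x_sites[x_sites$f > 0 & x_sites$f < 1, , drop = FALSE]
  mono <- x_sites[x_sites$f == 0, , drop = FALSE]
  if (!nrow(poly)) stop("x_contamination: insufficient sites (no polymorphic sites)")
  pp <- pileup_bases(rs, x_contig, poly$pos, min_mapq = min_mapq,
                     min_bq = min_bq)
  site_counts <- function(pb, tab) {
    nr <- vapply(seq_len(nrow(tab)), function(i) {
      sum(pb$site == i & pb$base == tab$ref[i])
    }, numeric(1))
    na <- vapply(seq_len(nrow(tab)), function(i) {
      sum(pb$site == i & pb$base == tab$alt[i])
    }, numeric(1))
    cbind(n_ref = nr, n_alt = na)
  }
  cnt <- site_counts(pp, poly)
  tot <- rowSums(cnt)
  informative <- which(tot >= 2)
  if (length(informative) < min_sites) {
    stop("x_contamination: insufficient sites (", length(informative),
         " informative polymorphic sites, need ", min_sites, ")")
  }
  minor <- pmin(cnt[, 1], cnt[, 2])[informative]
  tot_i <- tot[informative]
  ## Per-allele error from monomorphic controls (any non-ref base / 3).
  m_mono <- 0
  mono_mis <- mono_tot <- numeric(0)
  if (nrow(mono)) {
    pm <- pileup_bases(rs, x_contig, mono$pos, min_mapq = min_mapq,
                       min_bq = min_bq)
    pm <- pm[pm$base %in% DNA_BASES, , drop = FALSE]
    if (nrow(pm)) {
      mono_mis <- as.numeric(pm$base != mono$ref[pm$site])
      mono_tot <- rep(1, nrow(pm))
      m_mono <- sum(mono_mis) / sum(mono_tot) / 3
    }
  }
  denom <- mean(2 * poly$f[informative] * (1 - poly$f[informative]))
  est <- clamp((sum(minor) / sum(tot_i) - m_mono) / denom, 0, 1)
  boots <- vapply(seq_len(n_boot), function(b) {
    ii <- sample.int(length(informative), replace = TRUE)
    mp <- sum(minor[ii]) / sum(tot_i[ii])
    mm <- if (length(mono_mis)) {
      jj <- sample.int(length(mono_mis), replace = TRUE)
      sum(mono_mis[jj]) / sum(mono_tot[jj]) / 3
    } else 0
    dn <- mean(2 * poly$f[informative][ii] * (1 - poly$f[informative][ii]))
    clamp((mp - mm) / dn, 0, 1)
  }, numeric(1))
  ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
  structure(list(
    method = "x_moments",
    estimate = est,
    ci_low = min(ci[1], est),
    ci_high = max(ci[2], est),
    n_informative = length(informative)
  ), class = "contam_estimate")
}
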