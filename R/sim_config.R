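#' Simulation configuration
#'
#' Assembles and validates every knob of the synthetic-data generator. The
#' defaults emulate the statistical structure of a small ancient skeletal
#' assemblage sequenced by shotgun screening: very short fragments (means in
#' the 39-45.5 bp range), strong 5' C-to-T deamination (19-30% at the first
#' position), low endogenous content (0.1-14.7%), sub-3% human contamination,
#' and a reference panel of K ancestral source populations plus admixed
#' ancient individuals with known ancestry fractions.
#'
#' @param seed integer root seed; all per-sample streams derive from it.
#' @param genome named lengths (bp) of the four synthetic compartments
#'   `auto`, `X`, `Y`, `MT`.
#' @param n_source_pops number of ancestral source populations (K_true).
#' @param fst_per_pop per-population drift parameters in `[0, 1)`
#'   (Balding-Nichols F values).
#' @param n_panel_per_pop diploid reference individuals simulated per
#'   population.
#' @param n_snps autosomal biallelic transversion SNPs in the panel.
#' @param admixed_specs data.frame with column `sample` plus one `q_<pop>`
#'   column per source population: the true ancestry vector of each ancient
#'   individual (rows sum to 1).
#' @param read_specs data.frame with one row per ancient sample: columns
#'   `sample`, `sex` ("XX"/"XY"), `endogenous` (fraction of raw reads that
#'   map), `coverage_x` (target autosomal depth), `mean_fragment_bp`,
#'   `deamination_rate_5p` (position-1 C-to-T rate), `deamination_decay`
#'   (per-position geometric multiplier), `seq_error_rate`,
#'   `contamination_fraction`, `dup_rate` (injected PCR-duplicate fraction).
#' @param mt_copy_number mitochondrial copy number relative to one autosome
#'   copy; sets the MT depth excess over the nuclear genome.
#' @param contaminant_divergence substitutions per bp separating the (modern,
#'   undamaged, female) contaminant haplotype from the reference.
#' @param fragment_cv coefficient of variation of the lognormal fragment
#'   length distribution.
#' @param n_x_poly,n_x_mono X-chromosome sites with known population allele
#'   frequency (polymorphic) and flanking monomorphic control sites, used by
#'   the male X contamination estimator.
#' @param haplo_tips_mt,haplo_tips_y leaf haplogroups on the synthetic
#'   mitochondrial / Y haplogroup trees.
#' @param vars_per_branch defining variants per tree branch.
#' @param isotope_specs data.frame with one row per sample: `sample`,
#'   `delta13c`, `delta15n` (collagen values, permil), `cal_age_calbp` (true
#'   calendar age) and `c14_sigma` (lab measurement error, years), driving
#'   the radiocarbon simulation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(auto = 100000L, X = 30000L, Y = 12000L,
                                  MT = 8000L),
                       n_source_pops = 3L,
                       fst_per_pop = rep(0.1, n_source_pops),
                       n_panel_per_pop = 20L,
                       n_snps = 5000L,
                       admixed_specs = NULL,
                       read_specs = NULL,
                       mt_copy_number = 100,
                       contaminant_divergence = 0.01,
                       fragment_cv = 0.25,
                       n_x_poly = 150L,
                       n_x_mono = 150L,
                       haplo_tips_mt = 6L,
                       haplo_tips_y = 6L,
                       vars_per_branch = 3L,
                       isotope_specs = NULL) {
  if (is.null(read_specs)) read_specs <- default_read_specs()
  if (is.null(isotope_specs)) {
    isotope_specs <- default_isotope_specs(read_specs$sample)
  }
  if (is.null(admixed_specs)) {
    admixed_specs <- default_admixed_specs(read_specs$sample, n_source_pops)
  }
  cfg <- list(seed = as.integer(seed), genome = genome,
              n_source_pops = as.integer(n_source_pops),
              fst_per_pop = fst_per_pop,
              n_panel_per_pop = as.integer(n_panel_per_pop),
              n_snps = as.integer(n_snps), admixed_specs = admixed_specs,
              read_specs = read_specs, mt_copy_number = mt_copy_number,
              contaminant_divergence = contaminant_divergence,
              fragment_cv = fragment_cv,
              n_x_poly = as.integer(n_x_poly), n_x_mono = as.integer(n_x_mono),
              haplo_tips_mt = as.integer(haplo_tips_mt),
              haplo_tips_y = as.integer(haplo_tips_y),
              vars_per_branch = as.integer(vars_per_branch),
              isotope_specs = isotope_specs)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

## Study-like default cohort: one well-preserved petrous-bone-like sample,
## two marginal samples that pass screening, and two that fail it (one on
## endogenous content, one on damage).
default_read_specs <- function() {
  data.frame(
    sample = c("anc1", "anc2", "anc3", "anc4", "anc5"),
    sex = c("XX", "XY", "XY", "XX", "XY"),
    endogenous = c(0.006, 0.147, 0.009, 0.001, 0.026),
    coverage_x = c(0.25, 1.0, 0.25, 0.05, 0.08),
    mean_fragment_bp = c(45.5, 39, 40.1, 42, 43),
    deamination_rate_5p = c(0.251, 0.298, 0.189, 0.25, 0.04),
    deamination_decay = rep(0.55, 5),
    seq_error_rate = rep(5e-4, 5),
    contamination_fraction = c(0.0023, 0.0073, 0.0009, 0.01, 0.01),
    dup_rate = rep(0.05, 5),
    stringsAsFactors = FALSE
  )
}

## Adult collagen values in the limited-marine-signal range typical of
## coastal Neolithic Denmark; children carry a lactation-elevated delta15N.
default_isotope_specs <- function(samples) {
  n <- length(samples)
  data.frame(
    sample = samples,
    delta13c = rep(c(-20.8, -19.3, -19.4, -19.7, -19.2), length.out = n),
    delta15n = rep(c(8.3, 11.5, 12.4, 9.4, 8.7), length.out = n),
    cal_age_calbp = rep(c(4450, 4250, 4500, 4400, 4300), length.out = n),
    c14_sigma = rep(c(31, 34, 36, 29, 26), length.out = n),
    stringsAsFactors = FALSE
  )
}

## Ancients carry a substantial "steppe-like" component (last source pop),
## mirroring admixed 3rd-millennium Europeans over a farmer/forager substrate.
default_admixed_specs <- function(samples, k) {
  q <- matrix(1 / k, nrow = length(samples), ncol = k)
  if (k >= 2) {
    base <- rep(0.15 / (k - 1), k)
    base[k] <- 0.45
    base[1] <- 1 - sum(base[-1])
    for (i in seq_along(samples)) {
      qi <- base + c(0.05, -0.05, rep(0, k - 2)) * ((i %% 3) - 1)
      q[i, ] <- qi / sum(qi)
    }
  }
  out <- data.frame(sample = samples, q, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("q_pop", seq_len(k))
  out
}

validate_sim_config <- function(cfg) {
  chk_frac <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("sim_config: field '", field, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!all(c("auto", "X", "Y", "MT") %in% names(cfg$genome))) {
    stop("sim_config: field 'genome' needs lengths for auto, X, Y, MT")
  }
  if (any(cfg$genome <= 0)) stop("sim_config: field 'genome' lengths must be > 0")
  if (cfg$n_snps < 1L) stop("sim_config: field 'n_snps' must be >= 1")
  if (cfg$n_source_pops < 1L) {
    stop("sim_config: field 'n_source_pops' must be >= 1")
  }
  if (length(cfg$fst_per_pop) != cfg$n_source_pops ||
      any(!is.finite(cfg$fst_per_pop)) || any(cfg$fst_per_pop < 0) ||
      any(cfg$fst_per_pop >= 1)) {
    stop("sim_config: field 'fst_per_pop' must be ", cfg$n_source_pops,
         " drift values in [0, 1)", call. = FALSE)
  }
  rs <- cfg$read_specs
  chk_frac(rs$endogenous, "endogenous")
  chk_frac(rs$deamination_rate_5p, "deamination_rate_5p")
  chk_frac(rs$contamination_fraction, "contamination_fraction")
  chk_frac(rs$seq_error_rate, "seq_error_rate")
  chk_frac(rs$dup_rate, "dup_rate")
  if (any(rs$deamination_decay <= 0 | rs$deamination_decay >= 1)) {
    stop("sim_config: field 'deamination_decay' must lie in (0, 1)")
  }
  if (any(rs$coverage_x <= 0)) {
    stop("sim_config: field 'coverage_x' must be > 0")
  }
  if (any(!rs$sex %in% c("XX", "XY"))) {
    stop("sim_config: field 'sex' must be 'XX' or 'XY'")
  }
  if (any(rs$mean_fragment_bp < 30)) {
    stop("sim_config: field 'mean_fragment_bp' must be >= the 30 bp read minimum")
  }
  qm <- as.matrix(cfg$admixed_specs[, -1, drop = FALSE])
  if (ncol(qm) != cfg$n_source_pops) {
    stop("sim_config: field 'admixed_specs' must have one q column per source population")
  }
  if (any(abs(rowSums(qm) - 1) > 1e-8) || any(qm < 0)) {
    stop("sim_config: field 'admixed_specs' rows must be ancestry fractions summing to 1")
  }
  if (!all(rs$sample %in% cfg$admixed_specs$sample)) {
    stop("sim_config: every read_specs sample needs a row in 'admixed_specs'")
  }
  invisible(cfg)
}
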