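## Shotgun read simulation for ancient samples: short lognormal fragments,
## strand-symmetric 5' C->T / 3' G->A deamination with geometric positional
## decay, sequencing error, an undamaged divergent contaminant, sex-dependent
## X/Y representation, elevated mitochondrial copy number, and injected PCR
## duplicates. All truth is recorded.

## Per-compartment sampling weights: expected read share is proportional to
## compartment length x copy number per cell.
compartment_weights <- function(cfg, sex, contaminant = FALSE) {
  g <- cfg$genome
  x_copies <- if (contaminant || sex == "XX") 2 else 1
  y_copies <- if (contaminant || sex == "XX") 0 else 1
  c(auto = 2 * g[["auto"]], X = x_copies * g[["X"]], Y = y_copies * g[["Y"]],
    MT = cfg$mt_copy_number * g[["MT"]])
}

## Contaminant haplotype: the reference with one transversion substitution
## per 1/divergence bp on average (transversions, so damage cannot mimic the
## contaminant alleles). Shared across all samples (a single modern source).
simulate_contaminant <- function(cfg, ref) {
  with_seed(derive_seed(cfg$seed, "contaminant"), {
    out <- ref
    for (ctg in names(ref)) {
      L <- nchar(ref[[ctg]])
      n_sub <- max(1L, round(L * cfg$contaminant_divergence))
      pos <- sort(sample.int(L, n_sub))
      old <- substring(ref[[ctg]], pos, pos)
      new <- vapply(old, function(b) sample(TRANSVERSION_PARTNERS[[b]], 1),
                    character(1), USE.NAMES = FALSE)
      out[[ctg]] <- apply_variants(ref[[ctg]], pos, new)
    }
    out
  })
}

## 5' C->T at rate delta * decay^(p-1), mirrored 3' G->A, in molecule
## orientation.
apply_deamination <- function(seqs, lens, delta, decay) {
  if (delta <= 0 || !length(seqs)) return(seqs)
  max_p <- min(max(lens), ceiling(log(1e-6 / delta) / log(decay)) + 1L)
  for (p in seq_len(max_p)) {
    rate <- delta * decay^(p - 1)
    sel <- which(lens >= p & substr(seqs, p, p) == "C" &
                   runif(length(seqs)) < rate)
    if (length(sel)) {
      s <- seqs[sel]; substr(s, p, p) <- "T"; seqs[sel] <- s
    }
    p3 <- lens - p + 1L
    sel <- which(lens >= p & substr(seqs, p3, p3) == "G" &
                   runif(length(seqs)) < rate)
    if (length(sel)) {
      s <- seqs[sel]
      substr(s, p3[sel], p3[sel]) <- "A"
      seqs[sel] <- s
    }
  }
  seqs
}

## Fragment lengths: lognormal truncated to [30, 150] bp (shorter molecules
## never survive adapter trimming upstream), with meanlog calibrated so the
## truncated mean equals the configured mean.
sample_fragment_lengths <- function(n, target_mean, cv, min_len = 30L,
                                    max_len = 150L) {
  sdlog <- sqrt(log(1 + cv^2))
  trunc_mean <- function(mu) {
    num <- exp(mu + sdlog^2 / 2) *
      pnorm((mu + sdlog^2 - log(min_len)) / sdlog)
    num / (1 - plnorm(min_len, mu, sdlog))
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - target_mean,
                       interval = c(log(min_len) - 2, log(target_mean) + 1),
                       tol = 1e-10)$root
  lens <- rlnorm(n, mu, sdlog)
  while (any(bad <- lens < min_len)) {
    lens[bad] <- rlnorm(sum(bad), mu, sdlog)
  }
  as.integer(pmin(round(lens), max_len))
}

## Uniform substitution errors at per-base rate e.
apply_seq_error <- function(seqs, lens, e) {
  if (e <= 0 || !length(seqs)) return(seqs)
  n_err <- rbinom(length(seqs), lens, e)
  for (i in which(n_err > 0L)) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample.int(lens[i], n_err[i])
    s[at] <- vapply(s[at], function(b) sample(setdiff(DNA_BASES, b), 1),
                    character(1))
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

## Inject alternate alleles into reference-oriented read sequences at
## (site pos, read) overlap pairs flagged by `use_alt`.
inject_alleles <- function(seqs, read_idx, offsets, alt, use_alt) {
  todo <- which(use_alt)
  while (length(todo)) {
    first <- todo[!duplicated(read_idx[todo])]
    s <- seqs[read_idx[first]]
    substr(s, offsets[first], offsets[first]) <- alt[first]
    seqs[read_idx[first]] <- s
    todo <- setdiff(todo, first)
  }
  seqs
}

#' Simulate aligned shotgun reads for every configured ancient sample
#'
#' Reads are emitted already aligned (mapping is out of scope): each mapped
#' read is a fragment drawn from one of the four compartments with
#' probability proportional to length x copy number, carrying the sample's
#' alleles at panel SNPs (one allele per read, drawn from the diploid
#' dosage), its mitochondrial / Y haplogroup variants, deamination damage,
#' and sequencing error. Contaminant reads come from a single undamaged
#' divergent female haplotype. The raw (pre-mapping) read total is recorded
#' so endogenous content can be recomputed downstream.
#'
#' @param cfg a [sim_config].
#' @param panel output of [simulate_panel()] (the list with `panel` and
#'   `truth`).
#' @param ref reference genome (generated from `cfg` if NULL).
#' @param mt_defs,y_defs haplogroup definitions (generated if NULL).
#' @return A list with `reads` (named list of [aln_reads]), `truth` (one row
#'   per sample: sex, realised contamination, deamination parameters, true
#'   haplogroups, raw/mapped/duplicate counts) and `details` (per-sample true
#'   haplotype strings).
#' @export
simulate_reads <- function(cfg, panel, ref = NULL, mt_defs = NULL,
                           y_defs = NULL) {
  validate_sim_config(cfg)
  ref <- ref %||% simulate_reference(cfg)
  mt_defs <- mt_defs %||% simulate_haplo_defs(cfg, ref, "MT")
  y_defs <- y_defs %||% simulate_haplo_defs(cfg, ref, "Y")
  contaminant <- simulate_contaminant(cfg, ref)
  x_sites <- panel$panel$x_sites
  sites <- panel$panel$sites
  out_reads <- list()
  truth_rows <- list()
  details <- list()
  for (i in seq_len(nrow(cfg$read_specs))) {
    spec <- cfg$read_specs[i, ]
    sim <- with_seed(derive_seed(cfg$seed, paste0("reads_", spec$sample)), {
      simulate_sample_reads(cfg, spec, panel, ref, contaminant, mt_defs,
                            y_defs, x_sites, sites)
    })
    out_reads[[spec$sample]] <- sim$reads
    truth_rows[[spec$sample]] <- sim$truth
    details[[spec$sample]] <- sim$details
  }
  list(reads = out_reads, truth = do.call(rbind, truth_rows),
       details = details)
}

simulate_sample_reads <- function(cfg, spec, panel, ref, contaminant,
                                  mt_defs, y_defs, x_sites, sites) {
  if (spec$coverage_x <= 0) stop("simulate_reads: coverage must be > 0")
  if (!spec$sex %in% c("XX", "XY")) {
    stop("simulate_reads: sex must be 'XX' or 'XY'")
  }
  sample_id <- spec$sample
  ## True uniparental haplogroups and haplotypes.
  mt_hg <- sample(mt_defs$tree$tip.label, 1)
  mt_vars <- mt_defs$variants[path_variant_idx(mt_defs, mt_hg), ]
  mt_hap <- apply_variants(ref[["MT"]], mt_vars$pos, mt_vars$der)
  y_hg <- NA_character_
  y_hap <- ref[["Y"]]
  if (spec$sex == "XY") {
    y_hg <- sample(y_defs$tree$tip.label, 1)
    y_vars <- y_defs$variants[path_variant_idx(y_defs, y_hg), ]
    y_hap <- apply_variants(ref[["Y"]], y_vars$pos, y_vars$der)
  }
  ## Male X haplotype carries the sample's fixed alleles at the known sites.
  x_hap <- ref[["X"]]
  if (spec$sex == "XY" && !is.null(x_sites)) {
    xa <- panel$truth$x_alleles[sample_id, ]
    carry <- which(xa == 1L & x_sites$f > 0)
    x_hap <- apply_variants(x_hap, x_sites$pos[carry], x_sites$alt[carry])
  }
  endo_src <- list(auto = ref[["auto"]], X = x_hap, Y = y_hap, MT = mt_hap)
  cont_src <- contaminant
  ## Read counts: coverage_x fixes the autosomal depth; the raw (pre-mapping)
  ## total follows from the configured endogenous fraction, counting the
  ## to-be-injected PCR duplicates as raw reads too.
  w_endo <- compartment_weights(cfg, spec$sex, contaminant = FALSE)
  w_cont <- compartment_weights(cfg, spec$sex, contaminant = TRUE)
  n_target <- round(spec$coverage_x * cfg$genome[["auto"]] /
                      spec$mean_fragment_bp * sum(w_endo) / w_endo[["auto"]])
  n_raw <- max(n_target, round(n_target * (1 + spec$dup_rate) /
                                 max(spec$endogenous, 1e-6)))
  n_tot <- rbinom(1L, n_raw, spec$endogenous)
  if (n_tot == 0L) n_tot <- 1L
  n_dup <- round(n_tot * spec$dup_rate / (1 + spec$dup_rate))
  n_map <- n_tot - n_dup
  is_cont <- runif(n_map) < spec$contamination_fraction
  comp <- character(n_map)
  comp[!is_cont] <- sample(names(w_endo), sum(!is_cont), replace = TRUE,
                           prob = w_endo)
  if (any(is_cont)) {
    comp[is_cont] <- sample(names(w_cont), sum(is_cont), replace = TRUE,
                            prob = w_cont)
  }
  ## Lognormal fragment lengths (family choice documented in the vignette).
  lens <- sample_fragment_lengths(n_map, spec$mean_fragment_bp,
                                  cfg$fragment_cv)
  L_comp <- cfg$genome[comp]
  lens <- pmin(lens, L_comp)
  pos <- as.integer(floor(runif(n_map) * (L_comp - lens + 1)) + 1L)
  strand <- sample(c("+", "-"), n_map, replace = TRUE)
  src <- ifelse(is_cont, "cont", "endo")
  seqs <- character(n_map)
  for (s in c("endo", "cont")) {
    for (ctg in unique(comp[src == s])) {
      sel <- which(src == s & comp == ctg)
      hap <- if (s == "endo") endo_src[[ctg]] else cont_src[[ctg]]
      seqs[sel] <- substring(hap, pos[sel], pos[sel] + lens[sel] - 1L)
    }
  }
  ## Endogenous autosomal reads carry one allele per covered panel SNP,
  ## drawn from the sample's diploid dosage.
  dos <- panel$panel$geno[sample_id, ]
  auto_endo <- which(src == "endo" & comp == "auto")
  if (length(auto_endo) && nrow(sites)) {
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos, width = 1L),
      IRanges::IRanges(pos[auto_endo], width = lens[auto_endo])
    )
    if (length(hits)) {
      si <- S4Vectors::queryHits(hits)
      ri <- auto_endo[S4Vectors::subjectHits(hits)]
      use_alt <- runif(length(si)) < dos[si] / 2
      seqs <- inject_alleles(seqs, ri, sites$pos[si] - pos[ri] + 1L,
                             sites$alt[si], use_alt)
    }
  }
  ## Contaminant X reads draw population alleles at the known X sites.
  cont_x <- which(src == "cont" & comp == "X")
  if (length(cont_x) && !is.null(x_sites)) {
    poly <- which(x_sites$f > 0)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(x_sites$pos[poly], width = 1L),
      IRanges::IRanges(pos[cont_x], width = lens[cont_x])
    )
    if (length(hits)) {
      si <- poly[S4Vectors::queryHits(hits)]
      ri <- cont_x[S4Vectors::subjectHits(hits)]
      use_alt <- runif(length(si)) < x_sites$f[si]
      ## The contaminant haplotype may carry a divergence substitution at
      ## such a site; reset non-alt draws to the panel ref allele.
      seqs <- inject_alleles(seqs, ri, x_sites$pos[si] - pos[ri] + 1L,
                             ifelse(use_alt, x_sites$alt[si], x_sites$ref[si]),
                             rep(TRUE, length(si)))
    }
  }
  ## Damage (endogenous only) and sequencing error, in molecule orientation.
  minus <- strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  endo <- which(src == "endo")
  seqs[endo] <- apply_deamination(seqs[endo], lens[endo],
                                  spec$deamination_rate_5p,
                                  spec$deamination_decay)
  seqs <- apply_seq_error(seqs, lens, spec$seq_error_rate)
  seqs[minus] <- revcomp(seqs[minus])
  ## Base qualities (mostly high with a low-quality tail) and mapping
  ## qualities (a small fraction below the usual MAPQ 30 cut).
  qpool <- sample(c(37L, 33L, 12L), sum(lens), replace = TRUE,
                  prob = c(0.8, 0.12, 0.08))
  quals <- split_string(intToUtf8(qpool + 33L), lens)
  ## Emitted reads are confident alignments; sub-threshold alignments belong
  ## to the discarded remainder of the raw total.
  mapq <- sample(c(37L, 33L), n_map, replace = TRUE, prob = c(0.9, 0.1))
  df <- data.frame(contig = comp, pos = pos, strand = strand, seq = seqs,
                   qual = quals, mapq = mapq, stringsAsFactors = FALSE)
  ## Injected PCR duplicates: identical coordinates and sequence.
  if (n_dup > 0L) {
    df <- rbind(df, df[sample.int(n_map, n_dup, replace = TRUE), ])
  }
  df <- df[order(match(df$contig, names(cfg$genome)), df$pos), ]
  q <- as.matrix(cfg$admixed_specs[cfg$admixed_specs$sample == sample_id,
                                   -1, drop = FALSE])
  list(
    reads = aln_reads(df, sample_id = sample_id),
    truth = data.frame(
      sample = sample_id, sex = spec$sex,
      endogenous = spec$endogenous,
      contamination = spec$contamination_fraction,
      contamination_realised = mean(is_cont),
      deamination_rate_5p = spec$deamination_rate_5p,
      deamination_decay = spec$deamination_decay,
      mean_fragment_bp = spec$mean_fragment_bp,
      mt_haplogroup = mt_hg, y_haplogroup = y_hg,
      n_reads_raw = n_raw, n_reads_mapped = n_map + n_dup,
      n_duplicates_injected = n_dup,
      stringsAsFactors = FALSE
    ),
    details = list(mt_haplotype = mt_hap, y_haplotype = y_hap,
                   x_haplotype = x_hap, true_q = q[1, ])
  )
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper generating, from one config, everything the pipeline
#' consumes: reference, SNP panel (+truth), mitochondrial and Y haplogroup
#' definitions, contaminant haplotype, and aligned reads for every sample.
#'
#' @param cfg a [sim_config].
#' @return A list: `ref`, `panel`, `panel_truth`, `mt_defs`, `y_defs`,
#'   `reads`, `read_truth`, `details`.
#' @export
simulate_dataset <- function(cfg) {
  ref <- simulate_reference(cfg)
  pan <- simulate_panel(cfg, ref)
  mt_defs <- simulate_haplo_defs(cfg, ref, "MT")
  y_defs <- simulate_haplo_defs(cfg, ref, "Y")
  rd <- simulate_reads(cfg, pan, ref, mt_defs, y_defs)
  list(ref = ref, panel = pan$panel, panel_truth = pan$truth,
       mt_defs = mt_defs, y_defs = y_defs, reads = rd$reads,
       read_truth = rd$truth, details = rd$details)
}

#' Simulate a radiocarbon calibration curve
#'
#' The curve maps calendar age (cal BP) to conventional radiocarbon age: the
#' identity mapping plus an optional smooth random wiggle of standard
#' deviation `wiggle_sd` years, with constant curve uncertainty. With
#' `wiggle_sd = 0` the curve is exactly the identity, for closed-form checks.
#'
#' @param seed integer seed for the wiggle.
#' @param span_calbp two-element range of the cal BP grid.
#' @param wiggle_sd standard deviation (yr) of the wiggle; 0 for none,
#'   negative is an error.
#' @param step grid step in years.
#' @param sigma_curve constant curve sigma in years (> 0).
#' @return A [cal_curve].
#' @export
simulate_calcurve <- function(seed = 1L, span_calbp = c(0, 10000),
                              wiggle_sd = 20, step = 1, sigma_curve = 15) {
  if (length(span_calbp) != 2L || diff(span_calbp) <= 0) {
    stop("simulate_calcurve: span must be a positive range")
  }
  if (wiggle_sd < 0) stop("simulate_calcurve: wiggle_sd must be >= 0")
  if (sigma_curve <= 0) stop("simulate_calcurve: sigma_curve must be > 0")
  grid <- seq(span_calbp[1], span_calbp[2], by = step)
  wiggle <- 0
  if (wiggle_sd > 0) {
    wiggle <- with_seed(seed, {
      raw <- rnorm(length(grid))
      k <- max(3L, min(length(grid), round(50 / step)))
      sm <- stats::filter(raw, rep(1 / k, k), circular = TRUE)
      as.numeric(sm) / stats::sd(sm) * wiggle_sd
    })
  }
  cal_curve(cal_bp = grid, mu = grid + wiggle,
            sigma = rep(sigma_curve, length(grid)),
            name = sprintf("synthetic(seed=%d)", as.integer(seed)))
}
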