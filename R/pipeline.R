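## End-to-end pipeline driver: reads every input from files, runs the stage
## order QC -> screening -> sex/contamination -> haplogroups -> genotyping ->
## IBS/MDS -> admixture -> calibration, and assembles a reproducible report.
## Stages after screening run only for samples that pass it.

#' Simulate radiocarbon measurements against a known curve
#'
#' Each sample's conventional age is drawn around the curve value at its true
#' calendar age, shifted by the diet-proportional marine reservoir offset
#' implied by its collagen delta13C.
#'
#' @param cfg a [sim_config] (uses `isotope_specs`).
#' @param curve a [cal_curve].
#' @param diet a [diet_model].
#' @return data.frame: `sample`, `cal_age_true_calbp`, `delta13c`,
#'   `delta15n`, `alpha_true`, `uncal_bp`, `sigma`.
#' @export
simulate_radiocarbon <- function(cfg, curve, diet = diet_model()) {
  iso <- cfg$isotope_specs
  with_seed(derive_seed(cfg$seed, "radiocarbon"), {
    mu <- approx(curve$cal_bp, curve$mu, xout = iso$cal_age_calbp)$y
    alpha <- marine_fraction(iso$delta13c, diet)
    m <- round(rnorm(nrow(iso), mu + alpha * diet$reservoir_full_marine,
                     iso$c14_sigma))
    data.frame(sample = iso$sample, cal_age_true_calbp = iso$cal_age_calbp,
               delta13c = iso$delta13c, delta15n = iso$delta15n,
               alpha_true = alpha, uncal_bp = m, sigma = iso$c14_sigma,
               stringsAsFactors = FALSE)
  })
}

#' Write a simulated dataset to disk in the interchange formats
#'
#' SAM per sample, FASTA reference, VCF + labels for the panel, Newick + TSV
#' haplogroup definitions, contaminant mitochondrial haplotype FASTA, X-site
#' and raw-read-count tables, radiocarbon/isotope table, calibration curve,
#' and the documented truth TSV.
#'
#' @param sim output of [simulate_dataset()].
#' @param cfg the [sim_config] that produced it.
#' @param dir output directory (created).
#' @param curve optional [cal_curve]; a synthetic curve is generated when
#'   NULL.
#' @return Invisibly, the named list of paths (a ready [pipeline_config]
#'   input).
#' @export
write_dataset <- function(sim, cfg, dir, curve = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  ref_lengths <- stats::setNames(nchar(sim$ref), names(sim$ref))
  sam <- character(0)
  for (s in names(sim$reads)) {
    sam[s] <- p(paste0(s, ".sam"))
    write_sam(sim$reads[[s]], ref_lengths, sam[s])
  }
  write_fasta(sim$ref, p("reference.fa"))
  write_panel_vcf(sim$panel, p("panel.vcf"), p("panel_labels.tsv"))
  write_haplo_defs(sim$mt_defs, p("mt_tree.nwk"), p("mt_variants.tsv"))
  write_haplo_defs(sim$y_defs, p("y_tree.nwk"), p("y_variants.tsv"))
  contaminant <- simulate_contaminant(cfg, sim$ref)
  write_fasta(c(contaminant_mt = contaminant[["MT"]]), p("contaminant_mt.fa"))
  write.table(sim$panel$x_sites, p("x_sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$read_truth[, c("sample", "n_reads_raw")], p("raw_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  curve <- curve %||% simulate_calcurve(seed = cfg$seed,
                                        span_calbp = c(3000, 6000))
  write.table(data.frame(cal_bp = curve$cal_bp, mu = curve$mu,
                         sigma = curve$sigma),
              p("calcurve.14c"), sep = ",", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  dates <- simulate_radiocarbon(cfg, curve)
  write.table(dates, p("dates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$read_truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(sam = sam, reference = p("reference.fa"),
                 panel_vcf = p("panel.vcf"),
                 panel_labels = p("panel_labels.tsv"),
                 mt_tree = p("mt_tree.nwk"), mt_variants = p("mt_variants.tsv"),
                 y_tree = p("y_tree.nwk"), y_variants = p("y_variants.tsv"),
                 contaminant_mt = p("contaminant_mt.fa"),
                 x_sites = p("x_sites.tsv"), raw_counts = p("raw_counts.tsv"),
                 curve = p("calcurve.14c"), dates = p("dates.tsv")))
}

PIPELINE_THRESHOLD_DEFAULTS <- list(
  min_mapq = 30, min_len = 30, geno_min_bq = 30, xcontam_min_bq = 20,
  mt_min_depth = 3, mt_end_trim = 7, screen_endo = 0.5, screen_ct5 = 10,
  x_doc_min = 0.5, mt_doc_min = 5
)

#' Pipeline configuration
#'
#' @param paths named list of input paths as produced by [write_dataset()]:
#'   `sam` (named vector, one per sample), `reference`, `panel_vcf`,
#'   `panel_labels`, `mt_tree`, `mt_variants`, `y_tree`, `y_variants`,
#'   `contaminant_mt`, `x_sites`, `raw_counts`, `curve`, `dates`.
#' @param thresholds named list overriding any of the defaults
#'   `r paste(names(PIPELINE_THRESHOLD_DEFAULTS), collapse = ", ")`; unknown
#'   keys are rejected.
#' @param seed integer seed driving every stochastic stage.
#' @param k_values admixture K values to fit (default 2:6).
#' @param n_replicates admixture replicates per K (default 10).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths, thresholds = list(), seed = 1L,
                            k_values = 2:6, n_replicates = 10L) {
  unknown <- setdiff(names(thresholds), names(PIPELINE_THRESHOLD_DEFAULTS))
  if (length(unknown)) {
    stop("pipeline_config: unknown threshold key(s): ",
         paste(unknown, collapse = ", "))
  }
  th <- utils::modifyList(PIPELINE_THRESHOLD_DEFAULTS, thresholds)
  need <- c("sam", "reference", "panel_vcf", "panel_labels", "mt_tree",
            "mt_variants", "y_tree", "y_variants", "contaminant_mt",
            "x_sites", "raw_counts", "curve", "dates")
  miss <- setdiff(need, names(paths))
  if (length(miss)) {
    stop("pipeline_config: missing path(s): ", paste(miss, collapse = ", "))
  }
  structure(list(paths = paths, thresholds = th, seed = as.integer(seed),
                 k_values = k_values, n_replicates = as.integer(n_replicates)),
            class = "pipeline_config")
}

## Small stable hash of the configuration (md5 of its deparse) so every
## report can state what produced it.
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(status, name, expr) {
  res <- tryCatch(list(value = expr, status = "ok", message = ""),
                  error = function(e) list(value = NULL, status = "error",
                                           message = conditionMessage(e)))
  status[[name]] <- list(status = res$status, message = res$message)
  list(value = res$value, status = status)
}

#' Run the full analysis pipeline
#'
#' Stage order: read filtering and duplicate collapse, QC statistics and
#' damage profiles, the screening decision, then — for passing samples only —
#' genetic sex, mitochondrial consensus + contamination (when the MT depth
#' exceeds `mt_doc_min`), male X contamination (when the X depth exceeds
#' `x_doc_min`), mitochondrial haplogroup scoring and Y parsimony placement,
#' pseudohaploid genotyping and coverage, cohort IBS/MDS against the
#' haploidized panel, unsupervised admixture across `k_values` with replicate
#' mode alignment, and radiocarbon calibration with reservoir correction.
#' Stage failures are recorded per stage and leave the rest of the report
#' intact.
#'
#' @param cfg a [pipeline_config].
#' @return A list of class `pipeline_report`: `qc`, `sex`, `contamination`,
#'   `haplogroups`, `coverage`, `mds`, `admixture`, `chronology`, `stages`
#'   (status per stage), `seed`, `config_hash`.
#' @export
run_pipeline <- function(cfg) {
  th <- cfg$thresholds
  status <- list()
  ref <- read_fasta(cfg$paths$reference)
  comp_len <- stats::setNames(nchar(ref), names(ref))
  panel <- read_panel_vcf(cfg$paths$panel_vcf, cfg$paths$panel_labels)
  mt_defs <- read_haplo_defs(cfg$paths$mt_tree, cfg$paths$mt_variants, "MT")
  y_defs <- read_haplo_defs(cfg$paths$y_tree, cfg$paths$y_variants, "Y")
  cont_mt <- read_fasta(cfg$paths$contaminant_mt)
  x_sites <- read.table(cfg$paths$x_sites, header = TRUE, sep = "\t")
  raw_counts <- read.table(cfg$paths$raw_counts, header = TRUE, sep = "\t")
  samples <- names(cfg$paths$sam)
  qc_rows <- list(); damage <- list(); reads <- list()
  for (s in samples) {
    rs <- read_sam(cfg$paths$sam[[s]], sample_id = s)
    filtered <- filter_reads(rs, min_mapq = th$min_mapq, min_len = th$min_len)
    dd <- collapse_duplicates(filtered)
    reads[[s]] <- dd$reads
    n_raw <- raw_counts$n_reads_raw[match(s, raw_counts$sample)]
    ## Endogenous content counts all confidently mapped reads (pre-dedup, as
    ## mapping software reports); damage and downstream calls use the
    ## duplicate-collapsed set.
    qc <- sample_qc(n_raw, filtered, comp_len,
                    n_duplicates_removed = dd$n_removed)
    dp <- damage_profile(dd$reads, ref)
    damage[[s]] <- dp
    dec <- screen_sample(qc, dp, min_endo_pct = th$screen_endo,
                         min_ct5_pct = th$screen_ct5)
    qc_rows[[s]] <- data.frame(
      sample = s, endo_pct = qc$endogenous_pct, doc = qc$doc_nuclear,
      mt_doc = qc$doc_mt, mean_fragment_bp = qc$mean_fragment_bp,
      ct5_pct = 100 * dp$ct5[1], n_duplicates_removed = dd$n_removed,
      screen = dec$decision,
      screen_reasons = paste(dec$reasons, collapse = "; "),
      stringsAsFactors = FALSE
    )
  }
  qc_tab <- do.call(rbind, qc_rows)
  rownames(qc_tab) <- NULL
  passing <- qc_tab$sample[qc_tab$screen == "pass"]

  sex_rows <- list(); contam_rows <- list(); haplo_rows <- list()
  cov_rows <- list(); calls <- list()
  for (s in passing) {
    rs <- reads[[s]]
    st <- run_stage(status, paste0("sex:", s), {
      ry_sex(sum(rs$contig == "X"), sum(rs$contig == "Y"))
    })
    status <- st$status
    sx <- st$value
    if (!is.null(sx)) {
      sex_rows[[s]] <- data.frame(sample = s, nX = sx$nX, nY = sx$nY,
                                  ry = sx$ry, ci_low = sx$ci_low,
                                  ci_high = sx$ci_high,
                                  assignment = sx$assignment)
    }
    mt_doc <- qc_tab$mt_doc[qc_tab$sample == s]
    cons <- NULL
    if (mt_doc > th$mt_doc_min) {
      st <- run_stage(status, paste0("mt_contam:", s), {
        cons <- mt_consensus(rs, comp_len[["MT"]],
                             min_depth = th$mt_min_depth,
                             end_trim = th$mt_end_trim)
        mt_contamination(rs, cons, unname(cont_mt),
                         end_trim = th$mt_end_trim)
      })
      status <- st$status
      if (!is.null(st$value)) {
        ce <- st$value
        contam_rows[[paste0(s, "_mt")]] <- data.frame(
          sample = s, method = ce$method, estimate = ce$estimate,
          ci_low = ce$ci_low, ci_high = ce$ci_high,
          n_informative = ce$n_informative)
      }
    }
    x_doc <- sum(read_lengths(rs)[rs$contig == "X"]) / comp_len[["X"]]
    if (!is.null(sx) && sx$assignment == "XY" && x_doc > th$x_doc_min) {
      st <- run_stage(status, paste0("x_contam:", s), {
        with_seed(derive_seed(cfg$seed, paste0("xboot_", s)), {
          x_contamination(rs, x_sites, min_mapq = th$min_mapq,
                          min_bq = th$xcontam_min_bq)
        })
      })
      status <- st$status
      if (!is.null(st$value)) {
        ce <- st$value
        contam_rows[[paste0(s, "_x")]] <- data.frame(
          sample = s, method = ce$method, estimate = ce$estimate,
          ci_low = ce$ci_low, ci_high = ce$ci_high,
          n_informative = ce$n_informative)
      }
    }
    ## Haplogroups: mtDNA from the consensus when available, else from read
    ## statuses; Y by parsimony placement for males.
    st <- run_stage(status, paste0("mt_haplo:", s), {
      if (!is.null(cons)) {
        mt_haplogroup_from_consensus(cons, mt_defs)[1, ]
      } else {
        sts <- snp_status(rs, mt_defs, min_bq = th$geno_min_bq,
                          damage_mask = FALSE)
        assign_mt_haplogroup(sts$pos[sts$status == "derived"],
                             sts$pos[sts$status != "missing"], mt_defs)[1, ]
      }
    })
    status <- st$status
    if (!is.null(st$value)) {
      haplo_rows[[paste0(s, "_mt")]] <- data.frame(
        sample = s, locus = "mtDNA", haplogroup = st$value$haplogroup,
        score = st$value$score)
    }
    if (!is.null(sx) && sx$assignment == "XY") {
      st <- run_stage(status, paste0("y_haplo:", s), {
        place_on_tree(snp_status(rs, y_defs, min_bq = th$geno_min_bq,
                                 damage_mask = TRUE), y_defs)
      })
      status <- st$status
      if (!is.null(st$value)) {
        haplo_rows[[paste0(s, "_y")]] <- data.frame(
          sample = s, locus = "Y", haplogroup = st$value$haplogroup,
          score = st$value$score)
      }
    }
    st <- run_stage(status, paste0("genotype:", s), {
      pseudohaploid_call(rs, panel, min_mapq = th$min_mapq,
                         min_bq = th$geno_min_bq,
                         seed = derive_seed(cfg$seed, paste0("geno_", s)))
    })
    status <- st$status
    if (!is.null(st$value)) {
      calls[[s]] <- st$value
      cr <- coverage_report(st$value, nrow(panel$sites))
      cov_rows[[s]] <- data.frame(sample = s, n_covered = cr$n_covered,
                                  percent = cr$percent)
    }
  }

  ## Cohort analyses: IBS/MDS and admixture over ancients + haploidized panel.
  mds <- NULL; admix <- NULL
  if (length(calls)) {
    st <- run_stage(status, "ibs_mds", {
      hap_panel <- haploidize(panel$geno, seed = derive_seed(cfg$seed, "hap"))
      anc <- do.call(rbind, lapply(calls, as.integer))
      rownames(anc) <- names(calls)
      all_calls <- rbind(hap_panel, anc)
      ib <- ibs_matrix(all_calls)
      list(ibs = ib, mds = classical_mds(ib))
    })
    status <- st$status
    mds <- st$value
    st <- run_stage(status, "admixture", {
      anc <- do.call(rbind, lapply(calls, as.integer))
      rownames(anc) <- names(calls)
      G <- rbind(panel$geno, anc)
      ploidy <- c(rep(2L, nrow(panel$geno)), rep(1L, nrow(anc)))
      fits_by_k <- lapply(cfg$k_values, function(k) {
        fits <- lapply(seq_len(cfg$n_replicates), function(r) {
          admixture_fit(G, k, ploidy = ploidy,
                        seed = derive_seed(cfg$seed,
                                           paste0("admix_", k, "_", r)))
        })
        align_modes(fits)
      })
      names(fits_by_k) <- paste0("K", cfg$k_values)
      fits_by_k
    })
    status <- st$status
    admix <- st$value
  }

  ## Chronology: calibrate raw and reservoir-corrected dates.
  st <- run_stage(status, "chronology", {
    curve <- read_calcurve(cfg$paths$curve)
    dates <- read.table(cfg$paths$dates, header = TRUE, sep = "\t")
    diet <- diet_model()
    rows <- lapply(seq_len(nrow(dates)), function(i) {
      d <- radiocarbon_date(dates$uncal_bp[i], dates$sigma[i],
                            sample_id = dates$sample[i])
      cal <- calibrate(d, curve)
      alpha <- marine_fraction(dates$delta13c[i], diet)
      cal_rc <- calibrate(reservoir_correct(d, alpha, diet), curve)
      fmt <- function(x) paste(sprintf("%d-%d", x$hpd_bce$bce_old,
                                       x$hpd_bce$bce_young), collapse = "; ")
      data.frame(sample = dates$sample[i], uncal_bp = dates$uncal_bp[i],
                 sigma = dates$sigma[i], delta13c = dates$delta13c[i],
                 alpha = alpha, cal_bce_954 = fmt(cal),
                 cal_bce_rescorr_954 = fmt(cal_rc),
                 median_cal_bp = cal$median_cal_bp,
                 median_cal_bp_rescorr = cal_rc$median_cal_bp)
    })
    do.call(rbind, rows)
  })
  status <- st$status

  structure(list(
    qc = qc_tab,
    sex = if (length(sex_rows)) do.call(rbind, sex_rows),
    contamination = if (length(contam_rows)) do.call(rbind, contam_rows),
    haplogroups = if (length(haplo_rows)) do.call(rbind, haplo_rows),
    coverage = if (length(cov_rows)) do.call(rbind, cov_rows),
    mds = mds, admixture = admix, chronology = st$value,
    damage = damage, stages = status, seed = cfg$seed,
    config_hash = config_hash(cfg)
  ), class = "pipeline_report")
}

#' Write a pipeline report as deterministic TSV tables
#'
#' Every table carries the configuration hash and seed in a comment header;
#' re-running with an identical configuration yields byte-identical files.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# config_hash: %s seed: %d", report$config_hash,
                 report$seed)
  paths <- character(0)
  emit <- function(tab, name) {
    if (is.null(tab)) return()
    path <- file.path(dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    write.table(format(tab, digits = 10, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
    close(con)
    paths <<- c(paths, path)
  }
  emit(report$qc, "qc")
  emit(report$sex, "sex")
  emit(report$contamination, "contamination")
  emit(report$haplogroups, "haplogroups")
  emit(report$coverage, "coverage")
  emit(report$chronology, "chronology")
  if (!is.null(report$mds)) {
    pts <- as.data.frame(report$mds$mds$points)
    names(pts) <- paste0("dim", seq_len(ncol(pts)))
    pts <- cbind(individual = rownames(report$mds$mds$points), pts)
    emit(pts, "mds")
  }
  if (!is.null(report$admixture)) {
    for (kname in names(report$admixture)) {
      q <- as.data.frame(report$admixture[[kname]]$representative$Q)
      names(q) <- paste0("Q", seq_len(ncol(q)))
      q <- cbind(individual = rownames(q), q)
      emit(q, paste0("admixture_", kname))
    }
  }
  stat <- data.frame(
    stage = names(report$stages),
    status = vapply(report$stages, function(x) x$status, character(1)),
    message = vapply(report$stages, function(x) x$message, character(1))
  )
  emit(stat, "stages")
  invisible(paths)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d sample(s), %d passing screening; hash %s\n",
              nrow(x$qc), sum(x$qc$screen == "pass"), x$config_hash))
  invisible(x)
}
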