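## Synthetic reference genome, SNP panel and haplogroup definitions.

#' Simulate the reference genome (one contig per compartment)
#'
#' @param cfg a [sim_config].
#' @return Named character vector with contigs `auto`, `X`, `Y`, `MT`.
#' @export
simulate_reference <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "reference"), {
    stats::setNames(
      vapply(cfg$genome, function(L) random_dna(L), character(1)),
      names(cfg$genome)
    )
  })
}

#' Simulate a biallelic transversion SNP panel with known truth
#'
#' Allele frequencies follow the Balding-Nichols model: each site has an
#' ancestral frequency `p ~ U(0.05, 0.95)`; population k draws its frequency
#' from `Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`, so the per-population
#' frequency has mean `p` and variance `F_k p (1-p)`. Panel individuals are
#' diploid binomial draws from their population's frequencies; admixed
#' (ancient) individuals draw from the Q-weighted mixture frequency.
#'
#' @param cfg a [sim_config].
#' @param ref reference genome from [simulate_reference()] (generated if
#'   NULL).
#' @return A list with elements `panel` (a [site_panel] holding panel and
#'   admixed individuals' dosages, labels, and X contamination sites) and
#'   `truth` (ancestral frequencies `p_anc`, per-population frequency matrix
#'   `F` (K x sites), true ancestry matrix `Q`, and per-sample X alleles).
#' @export
simulate_panel <- function(cfg, ref = NULL) {
  validate_sim_config(cfg)
  ref <- ref %||% simulate_reference(cfg)
  K <- cfg$n_source_pops
  with_seed(derive_seed(cfg$seed, "panel"), {
    L <- nchar(ref[["auto"]])
    pos <- sort(sample.int(L, cfg$n_snps))
    ref_al <- substring(ref[["auto"]], pos, pos)
    alt_al <- vapply(ref_al, function(b) sample(TRANSVERSION_PARTNERS[[b]], 1),
                     character(1), USE.NAMES = FALSE)
    p_anc <- runif(cfg$n_snps, 0.05, 0.95)
    F_true <- matrix(NA_real_, nrow = K, ncol = cfg$n_snps,
                     dimnames = list(paste0("pop", seq_len(K)), NULL))
    for (k in seq_len(K)) {
      f <- cfg$fst_per_pop[k]
      F_true[k, ] <- if (f == 0) p_anc else {
        rbeta(cfg$n_snps, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      }
    }
    n_pan <- cfg$n_panel_per_pop
    pan_ids <- paste0(rep(rownames(F_true), each = n_pan), "_",
                      rep(seq_len(n_pan), K))
    pan_geno <- matrix(NA_integer_, nrow = K * n_pan, ncol = cfg$n_snps,
                       dimnames = list(pan_ids, NULL))
    for (k in seq_len(K)) {
      rows <- (k - 1L) * n_pan + seq_len(n_pan)
      pan_geno[rows, ] <- matrix(
        rbinom(n_pan * cfg$n_snps, 2L, rep(F_true[k, ], each = n_pan)),
        nrow = n_pan
      )
    }
    qm <- as.matrix(cfg$admixed_specs[, -1, drop = FALSE])
    rownames(qm) <- cfg$admixed_specs$sample
    adm_geno <- matrix(NA_integer_, nrow = nrow(qm), ncol = cfg$n_snps,
                       dimnames = list(rownames(qm), NULL))
    for (i in seq_len(nrow(qm))) {
      p_mix <- as.numeric(qm[i, ] %*% F_true)
      adm_geno[i, ] <- rbinom(cfg$n_snps, 2L, p_mix)
    }
    geno <- rbind(pan_geno, adm_geno)
    labels <- data.frame(
      individual = rownames(geno),
      population = c(rep(rownames(F_true), each = n_pan), rep("ancient", nrow(qm))),
      stringsAsFactors = FALSE
    )
    ## X sites for the male contamination estimator: polymorphic sites with a
    ## known population frequency plus monomorphic error-control sites.
    Lx <- nchar(ref[["X"]])
    xpos <- sort(sample.int(Lx, cfg$n_x_poly + cfg$n_x_mono))
    xref <- substring(ref[["X"]], xpos, xpos)
    xalt <- vapply(xref, function(b) sample(TRANSVERSION_PARTNERS[[b]], 1),
                   character(1), USE.NAMES = FALSE)
    xf <- rep(0, length(xpos))
    xf[sample.int(length(xpos), cfg$n_x_poly)] <- runif(cfg$n_x_poly, 0.1, 0.9)
    x_sites <- data.frame(pos = xpos, ref = xref, alt = xalt, f = xf)
    ## Fixed endogenous X alleles for each (male) ancient sample.
    x_alleles <- matrix(
      rbinom(nrow(qm) * length(xpos), 1L, rep(xf, each = nrow(qm))),
      nrow = nrow(qm), dimnames = list(rownames(qm), NULL)
    )
    sites <- data.frame(contig = "auto", pos = pos, ref = ref_al, alt = alt_al,
                        is_transversion = TRUE, stringsAsFactors = FALSE)
    list(
      panel = site_panel(sites, geno, labels, x_sites = x_sites),
      truth = list(p_anc = p_anc, F = F_true, Q = rbind(
        `rownames<-`(diag(K)[rep(seq_len(K), each = n_pan), , drop = FALSE],
                     pan_ids),
        qm
      ), x_alleles = x_alleles)
    )
  })
}

#' Simulate a haplogroup definition tree with branch-defining variants
#'
#' Builds a random rooted tree whose tips are leaf haplogroups and whose
#' internal nodes are basal haplogroups, then assigns each branch a set of
#' defining variants at unique positions on the target contig. With
#' `transversions_only = TRUE` (the default) derived alleles are transversion
#' partners of the reference base, so deamination damage cannot mimic a
#' defining variant.
#'
#' @param cfg a [sim_config].
#' @param ref reference genome.
#' @param contig `"MT"` or `"Y"`.
#' @param transversions_only restrict derived alleles to transversions.
#' @return A [haplo_defs] object.
#' @export
simulate_haplo_defs <- function(cfg, ref, contig = c("MT", "Y"),
                                transversions_only = TRUE) {
  contig <- match.arg(contig)
  n_tips <- if (contig == "MT") cfg$haplo_tips_mt else cfg$haplo_tips_y
  with_seed(derive_seed(cfg$seed, paste0("haplodefs_", contig)), {
    tree <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
    prefix <- if (contig == "MT") "mt" else "y"
    tree$tip.label <- paste0(prefix, LETTERS[seq_len(n_tips)])
    tree$node.label <- paste0(prefix, "N", seq_len(tree$Nnode))
    n_branch <- nrow(tree$edge)
    L <- nchar(ref[[contig]])
    pos_pool <- sample.int(L, n_branch * cfg$vars_per_branch)
    labels <- c(tree$tip.label, tree$node.label)
    vars <- vector("list", n_branch)
    for (b in seq_len(n_branch)) {
      child <- labels[tree$edge[b, 2]]
      pos <- pos_pool[(b - 1L) * cfg$vars_per_branch + seq_len(cfg$vars_per_branch)]
      anc <- substring(ref[[contig]], pos, pos)
      der <- vapply(seq_along(pos), function(i) {
        cand <- if (transversions_only) TRANSVERSION_PARTNERS[[anc[i]]] else
          setdiff(DNA_BASES, anc[i])
        sample(cand, 1)
      }, character(1))
      vars[[b]] <- data.frame(branch = child, pos = pos, anc = anc, der = der,
                              stringsAsFactors = FALSE)
    }
    haplo_defs(tree, do.call(rbind, vars), contig = contig)
  })
}
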