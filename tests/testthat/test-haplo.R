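test_that("variant status distinguishes missing, conflict, derived and damage-masked", {
  vars <- data.frame(branch = c("b1", "b1", "b2", "b2"),
                     pos = c(10L, 20L, 30L, 40L),
                     anc = c("A", "A", "C", "A"),
                     der = c("C", "T", "T", "T"))
  ## reads covering: pos 10 (two reads disagreeing), pos 20 (derived), 30/40
  ## uncovered / covered.
  rs <- make_reads("MT", pos = c(8L, 8L, 18L),
                   strand = "+",
                   seq = c("AACAA", "AAAAA", "AATAA"))
  st <- snp_status(rs, vars, min_bq = 0, min_mapq = 0, damage_mask = FALSE,
                   contig = "MT")
  expect_equal(st$status, c("conflict", "derived", "missing", "missing"))
  masked <- snp_status(rs, vars, min_bq = 0, min_mapq = 0, damage_mask = TRUE,
                       contig = "MT")
  ## A->T defining variants are untouched; C->T variants are masked
  expect_equal(masked$status[3], "missing")
  expect_equal(masked$status[2], "derived")
})

test_that("haplogroup scoring is exact for a fully observed leaf and empty otherwise", {
  sim <- default_dataset()
  defs <- sim$mt_defs
  leaf <- defs$tree$tip.label[1]
  path_pos <- defs$variants$pos[paleogen:::path_variant_idx(defs, leaf)]
  full <- assign_mt_haplogroup(path_pos, defs$variants$pos, defs)
  expect_equal(full$haplogroup[1], leaf)
  expect_equal(full$score[1], 1.0)
  none <- assign_mt_haplogroup(integer(0), defs$variants$pos, defs)
  expect_equal(none$haplogroup, paleogen:::haplo_root(defs))
  expect_true(is.na(none$score))
})

test_that("every leaf haplogroup is recovered from its own full-coverage consensus", {
  sim <- default_dataset()
  for (defs in list(sim$mt_defs, sim$y_defs)) {
    ref <- sim$ref[[defs$contig]]
    for (leaf in defs$tree$tip.label) {
      v <- defs$variants[paleogen:::path_variant_idx(defs, leaf), ]
      hap <- paleogen:::apply_variants(ref, v$pos, v$der)
      call <- mt_haplogroup_from_consensus(hap, defs)
      expect_equal(call$haplogroup[1], leaf)
      expect_equal(call$score[1], 1.0)
    }
  }
})

test_that("parsimony placement finds the leaf, allows basal calls, needs data", {
  sim <- default_dataset()
  defs <- sim$y_defs
  leaf <- defs$tree$tip.label[2]
  vars <- defs$variants
  on_path <- paleogen:::path_variant_idx(defs, leaf)
  st <- vars
  st$status <- "ancestral"
  st$status[on_path] <- "derived"
  call <- place_on_tree(st, defs)
  expect_equal(call$haplogroup, leaf)
  expect_equal(call$n_conflicts, 0L)

  ## support only on a shared internal branch -> that internal node
  internal <- setdiff(unique(vars$branch), defs$tree$tip.label)
  deep <- internal[which.min(vapply(internal, function(h) {
    length(paleogen:::haplo_path(defs, h))
  }, numeric(1)))]
  st2 <- vars
  st2$status <- "missing"
  st2$status[vars$branch == deep] <- "derived"
  call2 <- place_on_tree(st2, defs)
  expect_equal(call2$haplogroup, deep)

  st3 <- vars
  st3$status <- "missing"
  expect_error(place_on_tree(st3, defs), "no informative sites")
})

test_that("placement is invariant to permutation of the variant list", {
  sim <- default_dataset()
  rs <- sim$reads$anc2
  st <- snp_status(rs, sim$y_defs)
  a <- place_on_tree(st, sim$y_defs)
  set.seed(1)
  b <- place_on_tree(st[sample.int(nrow(st)), ], sim$y_defs)
  expect_equal(a$haplogroup, b$haplogroup)
  expect_equal(a$score, b$score)
})

test_that("deamination does not move placements on transversion-defined trees", {
  cfg_hot <- one_sample_cfg(seed = 61, sex = "XY",
                            deamination_rate_5p = 0.30,
                            genome = c(auto = 2000L, X = 2000L, Y = 20000L,
                                       MT = 2000L), coverage_x = 6,
                            mt_copy_number = 2)
  sim <- simulate_dataset(cfg_hot)
  truth <- sim$read_truth$y_haplogroup[1]
  st <- snp_status(sim$reads$s1, sim$y_defs, damage_mask = TRUE)
  call <- place_on_tree(st, sim$y_defs)
  expect_equal(call$haplogroup, truth)
})

test_that("low-coverage placements land on the true clade or an ancestor of it", {
  n_samp <- 10
  specs <- data.frame(
    sample = paste0("m", seq_len(n_samp)), sex = "XY", endogenous = 0.9,
    coverage_x = 0.5, mean_fragment_bp = 42, deamination_rate_5p = 0.25,
    deamination_decay = 0.55, seq_error_rate = 5e-4,
    contamination_fraction = 0, dup_rate = 0
  )
  cfg <- sim_config(seed = 62,
                    genome = c(auto = 2000L, X = 2000L, Y = 30000L,
                               MT = 2000L),
                    n_snps = 20L, mt_copy_number = 2,
                    read_specs = specs,
                    admixed_specs = data.frame(sample = specs$sample,
                                               q_pop1 = 1, q_pop2 = 0,
                                               q_pop3 = 0))
  sim <- simulate_dataset(cfg)
  ok <- vapply(specs$sample, function(s) {
    truth <- sim$read_truth$y_haplogroup[sim$read_truth$sample == s]
    call <- place_on_tree(snp_status(sim$reads[[s]], sim$y_defs), sim$y_defs)
    ## correct clade: called node lies on the root-to-truth path (or is truth)
    call$haplogroup %in% c(paleogen:::haplo_path(sim$y_defs, truth),
                           paleogen:::haplo_root(sim$y_defs))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("haplogroup definitions validate their tree and variants", {
  tr <- ape::read.tree(text = "((A,B)N2,C)N1;")
  vars <- data.frame(branch = "A", pos = c(5L, 5L), anc = "A", der = "C")
  expect_error(haplo_defs(tr, vars), "duplicated positions")
  vars2 <- data.frame(branch = "Z", pos = 5L, anc = "A", der = "C")
  expect_error(haplo_defs(tr, vars2), "unknown branch")
})
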