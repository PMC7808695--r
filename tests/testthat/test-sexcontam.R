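test_that("Ry sex caller reproduces the closed-form ratio, CI and assignment", {
  xx <- ry_sex(10000, 0)
  expect_equal(xx$ry, 0)
  expect_equal(xx$assignment, "XX")

  xy <- ry_sex(5000, 5000)
  expect_equal(xy$ry, 0.5)
  expect_equal(xy$assignment, "XY")

  g5 <- ry_sex(91900, 8100)
  expect_equal(g5$ry, 0.081)
  expect_equal(g5$ci_low, 0.081 - 1.96 * sqrt(0.081 * 0.919 / 1e5),
               tolerance = 1e-12)
  expect_equal(round(c(g5$ci_low, g5$ci_high), 4), c(0.0793, 0.0827))
  expect_equal(g5$assignment, "XY")

  expect_error(ry_sex(0, 0), "nX \\+ nY")
})

test_that("Ry confidence width shrinks monotonically with read count", {
  widths <- vapply(c(100, 1000, 10000, 100000), function(n) {
    s <- ry_sex(round(0.92 * n), round(0.08 * n))
    s$ci_high - s$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("consensus calls majority bases, N under min depth or ties", {
  reads <- make_reads("MT", pos = rep(1L, 4), strand = "+",
                      seq = c("ACGTACGTACGTACGTAAAA", "ACGTACGTACGTACGTAAAA",
                              "ACGTACGTACGTACGTAAAA", "ACGTACGTACGTTCGTAAAA"))
  cons <- mt_consensus(reads, mt_length = 20, min_depth = 3, end_trim = 0)
  expect_equal(substr(cons, 13, 13), "A")    # 3 vs 1 majority
  cons2 <- mt_consensus(reads[1:2, ] |> as.data.frame() |>
                          aln_reads(sample_id = "x"),
                        mt_length = 20, min_depth = 3, end_trim = 0)
  expect_equal(cons2, strrep("N", 20))       # depth 2 < 3
  tie <- make_reads("MT", pos = c(1L, 1L), strand = "+",
                    seq = c("AAA", "TAA"))
  cons3 <- mt_consensus(tie, mt_length = 3, min_depth = 1, end_trim = 0)
  expect_equal(substr(cons3, 1, 1), "N")
})

test_that("end trimming drops the damage-bearing termini from the consensus", {
  reads <- make_reads("MT", pos = 1L, strand = "+", seq = strrep("A", 20))
  cons <- mt_consensus(reads, mt_length = 20, min_depth = 1, end_trim = 7)
  expect_equal(cons, paste0(strrep("N", 7), strrep("A", 6), strrep("N", 7)))
})

test_that("simulated high-depth consensus is nearly identical to the true haplotype", {
  sim <- default_dataset()
  rs <- collapse_duplicates(filter_reads(sim$reads$anc2))$reads
  cons <- mt_consensus(rs, nchar(sim$ref[["MT"]]))
  truth <- sim$details$anc2$mt_haplotype
  cb <- strsplit(cons, "")[[1]]
  tb <- strsplit(truth, "")[[1]]
  called <- cb != "N"
  expect_gt(mean(called), 0.95)
  expect_gte(mean(cb[called] == tb[called]), 0.999)
})

test_that("contamination is zero when reads exactly match the consensus", {
  hap <- strrep("ACGTGGTTCA", 50)          # 500 bp
  reads <- make_reads("MT", pos = seq(1, 451, by = 3), strand = "+",
                      seq = substring(hap, seq(1, 451, by = 3),
                                      seq(1, 451, by = 3) + 49))
  contaminant <- paleogen:::apply_variants(hap, c(100, 200, 300, 400),
                                           c("C", "T", "A", "A"))
  est <- mt_contamination(reads, hap, contaminant, error_rate = 0.001,
                          end_trim = 0)
  expect_equal(est$estimate, 0)
  expect_equal(est$ci_low, 0)
})

test_that("contamination is unidentifiable without discriminating sites", {
  hap <- strrep("ACGT", 100)
  reads <- make_reads("MT", pos = 1L, strand = "+", seq = substr(hap, 1, 50))
  expect_error(mt_contamination(reads, hap, hap, error_rate = 0.001),
               "unidentifiable")
})

test_that("mixture estimate recovers a large simulated contamination fraction", {
  cfg <- one_sample_cfg(seed = 51, contamination_fraction = 0.2,
                        mt_copy_number = 150,
                        genome = c(auto = 2000L, X = 2000L, Y = 1000L,
                                   MT = 5000L), n_snps = 20L)
  sim <- simulate_dataset(cfg)
  rs <- collapse_duplicates(filter_reads(sim$reads$s1))$reads
  cons <- mt_consensus(rs, 5000)
  contaminant <- paleogen:::simulate_contaminant(cfg, sim$ref)
  est <- mt_contamination(rs, cons, contaminant[["MT"]])
  truth <- sim$read_truth$contamination_realised[1]
  expect_lt(abs(est$estimate - truth), 0.05)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
})

test_that("male X contamination is zero for clean single-source data", {
  cfg <- one_sample_cfg(seed = 52, sex = "XY", contamination_fraction = 0,
                        seq_error_rate = 0, deamination_rate_5p = 0,
                        coverage_x = 12,
                        genome = c(auto = 2000L, X = 30000L, Y = 2000L,
                                   MT = 1000L),
                        mt_copy_number = 2, n_x_poly = 150, n_x_mono = 150)
  sim <- simulate_dataset(cfg)
  set.seed(1)
  est <- x_contamination(sim$reads$s1, sim$panel$x_sites)
  expect_equal(est$estimate, 0)
})

test_that("male X contamination recovers a simulated 2.5% with a covering CI", {
  cfg <- one_sample_cfg(seed = 53, sex = "XY", contamination_fraction = 0.025,
                        coverage_x = 12,
                        genome = c(auto = 2000L, X = 40000L, Y = 2000L,
                                   MT = 1000L),
                        mt_copy_number = 2, n_x_poly = 200, n_x_mono = 200)
  sim <- simulate_dataset(cfg)
  set.seed(2)
  est <- x_contamination(sim$reads$s1, sim$panel$x_sites)
  expect_lt(abs(est$estimate - 0.025), 0.02)
  expect_true(est$ci_low <= 0.035 && est$ci_high >= 0.012)
})

test_that("X estimator demands polymorphic sites and enough of them", {
  cfg <- one_sample_cfg(seed = 54, sex = "XY", coverage_x = 2,
                        genome = c(auto = 2000L, X = 10000L, Y = 2000L,
                                   MT = 1000L), mt_copy_number = 2)
  sim <- simulate_dataset(cfg)
  mono_only <- data.frame(pos = c(10L, 20L), ref = c("A", "C"),
                          alt = c("C", "A"), f = c(0, 0))
  expect_error(x_contamination(sim$reads$s1, mono_only), "insufficient sites")
  few_poly <- data.frame(pos = c(10L, 20L), ref = c("A", "C"),
                         alt = c("C", "A"), f = c(0.5, 0.3))
  expect_error(x_contamination(sim$reads$s1, few_poly), "insufficient sites")
})
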