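test_that("read filtering keeps exactly the reads meeting both inclusive thresholds", {
  rs <- make_reads("auto", pos = c(1, 10, 20, 30),
                   strand = c("+", "+", "-", "+"),
                   seq = c(strrep("A", 30), strrep("A", 29), strrep("A", 50),
                           strrep("A", 35)),
                   mapq = c(30L, 37L, 29L, 31L))
  kept <- filter_reads(rs)
  expect_equal(nrow(kept), 2L)           # MAPQ 29 out, length 29 out
  expect_equal(kept$pos, c(1L, 30L))     # order preserved, boundaries kept
})

test_that("filtering a mixed simulated set matches an exhaustive per-read check", {
  sim <- default_dataset()
  rs <- sim$reads$anc3
  kept <- filter_reads(rs, min_mapq = 30, min_len = 40)
  manual <- vapply(seq_len(nrow(rs)), function(i) {
    rs$mapq[i] >= 30 && nchar(rs$seq[i]) >= 40
  }, logical(1))
  expect_equal(nrow(kept), sum(manual))
  expect_equal(kept$pos, rs$pos[manual])
})

test_that("duplicate collapse keeps one read per key, preferring quality then sequence", {
  two <- make_reads("auto", pos = c(5, 5), strand = c("+", "+"),
                    seq = c("ACGTACGTAC", "ACGTACGTAC"),
                    qual = c("FFFFFFFFFF", "!!!!!!!!!!"))
  out <- collapse_duplicates(two)
  expect_equal(out$n_removed, 1L)
  expect_equal(out$reads$qual, "FFFFFFFFFF")

  strands <- make_reads("auto", pos = c(5, 5), strand = c("+", "-"),
                        seq = c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(collapse_duplicates(strands)$n_removed, 0L)

  tie <- make_reads("auto", pos = c(5, 5), strand = c("+", "+"),
                    seq = c("TTTTTTTTTT", "AAAAAAAAAA"))
  expect_equal(collapse_duplicates(tie)$reads$seq, "AAAAAAAAAA")
})

test_that("collapse removes exactly the injected duplicates at low coverage", {
  cfg <- one_sample_cfg(seed = 41, dup_rate = 0.2, coverage_x = 0.05,
                        genome = c(auto = 200000L, X = 5000L, Y = 2000L,
                                   MT = 5000L), mt_copy_number = 2)
  sim <- simulate_dataset(cfg)
  out <- collapse_duplicates(sim$reads$s1)
  expect_equal(out$n_removed,
               sim$read_truth$n_duplicates_injected[1])
})

test_that("collapse requires coordinate-sorted input and is idempotent after filtering", {
  unsorted <- make_reads("auto", pos = c(10, 5), strand = c("+", "+"),
                         seq = c("ACGTACGTAC", "ACGTACGTAC"))
  expect_error(collapse_duplicates(unsorted), "sorted")
  sim <- default_dataset()
  once <- collapse_duplicates(filter_reads(sim$reads$anc1))
  twice <- collapse_duplicates(once$reads)
  expect_equal(twice$n_removed, 0L)
  expect_identical(as.data.frame(twice$reads), as.data.frame(once$reads))
})

test_that("damage profile counts a single constructed mismatch correctly", {
  ref <- c(auto = "CCCCAAAAGG")
  rs <- make_reads("auto", pos = 1, strand = "+", seq = "TCCCAAAAGG")
  dp <- damage_profile(rs, ref, window = 10)
  expect_equal(dp$ct5[1], 1)
  expect_equal(dp$ct5[2], 0)
  expect_equal(dp$ga3[1], 0)   # 3' G present, read matches
  ## zero opportunities reported as missing, not zero
  rs2 <- make_reads("auto", pos = 5, strand = "+", seq = "AAAA")
  dp2 <- damage_profile(rs2, ref, window = 4)
  expect_true(all(is.na(dp2$ct5)))
})

test_that("damage estimates follow the configured geometric decay", {
  cfg <- one_sample_cfg(seed = 42, deamination_rate_5p = 0.25,
                        deamination_decay = 0.5, coverage_x = 3,
                        genome = c(auto = 100000L, X = 5000L, Y = 2000L,
                                   MT = 5000L), mt_copy_number = 2)
  sim <- simulate_dataset(cfg)
  dp <- damage_profile(sim$reads$s1, sim$ref)
  for (p in 1:4) {
    expected <- 0.25 * 0.5^(p - 1)
    se <- sqrt(expected * (1 - expected) / dp$counts$opp5[p])
    expect_lt(abs(dp$ct5[p] - expected), 3 * se + 1e-3)
    expect_lt(abs(dp$ga3[p] - expected), 3 * se + 1e-3)
  }
})

test_that("sample QC computes endogenous content and depth of coverage", {
  one <- make_reads("auto", pos = 1, strand = "+", seq = strrep("A", 50))
  qc <- sample_qc(100, one, c(auto = 100, MT = 10))
  expect_equal(qc$endogenous_pct, 1)
  expect_equal(qc$doc_nuclear, 0.5)
  expect_equal(qc$doc_mt, 0)
  empty <- filter_reads(one, min_mapq = 99)
  expect_equal(sample_qc(100, empty, c(auto = 100, MT = 10))$endogenous_pct, 0)
  expect_error(sample_qc(0, one, c(auto = 100, MT = 10)), "raw")
})

test_that("simulated endogenous content and depth match the generator truth", {
  sim <- default_dataset()
  tr <- sim$read_truth[sim$read_truth$sample == "anc2", ]
  filtered <- filter_reads(sim$reads$anc2)
  qc <- sample_qc(tr$n_reads_raw, filtered,
                  setNames(nchar(sim$ref), names(sim$ref)))
  se <- 100 * sqrt(0.147 * (1 - 0.147) / tr$n_reads_raw)
  expect_lt(abs(qc$endogenous_pct - 14.7), 3 * se)
  ## autosomal depth close to the configured coverage
  auto_doc <- sum(nchar(filtered$seq[filtered$contig == "auto"])) /
    nchar(sim$ref[["auto"]])
  expect_lt(abs(auto_doc - 1.0), 0.15)
})

test_that("screening keeps well-preserved samples and rejects the rest", {
  qc <- function(e) list(endogenous_pct = e)
  dp <- function(ct) list(ct5 = ct)
  expect_equal(screen_sample(qc(14.7), dp(0.298))$decision, "pass")
  expect_equal(screen_sample(qc(0.1), dp(0.30))$decision, "fail")
  expect_equal(screen_sample(qc(0.5), dp(0.10))$decision, "pass")  # inclusive
  miss <- screen_sample(qc(5), dp(NA_real_))
  expect_equal(miss$decision, "fail")
  expect_match(miss$reasons, "insufficient damage opportunities")
})
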