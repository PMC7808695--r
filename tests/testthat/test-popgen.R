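test_that("pseudohaploid calls sample uniformly among passing ref/alt bases", {
  panel <- site_panel(
    sites = data.frame(contig = "auto", pos = seq_len(10000L),
                       ref = "A", alt = "C", is_transversion = TRUE),
    geno = NULL
  )
  ## every site covered by 3 ref reads and 1 alt read (length-1 reads)
  n <- 10000L
  rs <- make_reads("auto",
                   pos = rep(seq_len(n), each = 4),
                   strand = "+",
                   seq = rep(c("A", "A", "A", "C"), n))
  calls <- pseudohaploid_call(rs, panel, min_mapq = 0, min_bq = 0, seed = 5)
  expect_equal(attr(calls, "n_covered"), n)
  frac_alt <- mean(calls == 1L)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(frac_alt - 0.25), 3 * se)
})

test_that("pseudohaploid calls handle single reads and off-panel bases", {
  panel <- site_panel(
    sites = data.frame(contig = "auto", pos = c(5L, 10L), ref = c("A", "C"),
                       alt = c("C", "G"), is_transversion = TRUE),
    geno = NULL
  )
  rs <- make_reads("auto", pos = c(5L, 10L), strand = "+", seq = c("A", "T"))
  calls <- pseudohaploid_call(rs, panel, min_mapq = 0, min_bq = 0, seed = 1)
  expect_equal(as.integer(calls), c(0L, NA_integer_))
  expect_equal(attr(calls, "n_covered"), 1L)
})

test_that("coverage percentages reproduce published panel arithmetic", {
  M <- 12731663
  expect_equal(coverage_report(101541, M)$percent, 0.8)
  expect_equal(coverage_report(8928427, M)$percent, 70.1)
  expect_equal(coverage_report(298837, M)$percent, 2.3)
  expect_equal(coverage_report(0, M)$percent, 0)
  expect_error(coverage_report(10, 0), "panel size")
})

test_that("IBS matrix equals a naive double-loop recomputation exactly", {
  cfg <- sim_config(seed = 71, n_snps = 5000, n_panel_per_pop = 6)
  pan <- simulate_panel(cfg)
  hap <- haploidize(pan$panel$geno[1:20, ], seed = 3)
  hap[sample.int(length(hap), 5000)] <- NA   # missingness
  ib <- ibs_matrix(hap, min_overlap = 10)
  for (i in 1:19) {
    for (j in (i + 1):20) {
      ok <- !is.na(hap[i, ]) & !is.na(hap[j, ])
      p <- sum(hap[i, ok] == hap[j, ok]) / sum(ok)
      expect_identical(unname(ib$p_ibs[i, j]), p)
      expect_identical(unname(ib$distance[j, i]), 1 - p)
    }
  }
})

test_that("IBS endpoints: identical vectors at 0, complementary at 1, no overlap flagged", {
  g <- rbind(a = c(0L, 1L, 0L, 1L), b = c(0L, 1L, 0L, 1L),
             c = c(1L, 0L, 1L, 0L), d = c(NA, NA, NA, NA))
  ib <- ibs_matrix(g, min_overlap = 1)
  expect_equal(ib$distance["a", "b"], 0)
  expect_equal(ib$distance["a", "c"], 1)
  expect_true(is.na(ib$distance["a", "d"]))
  expect_true(ib$flagged["a", "d"])
  expect_equal(diag(ib$distance), c(a = 0, b = 0, c = 0, d = 0))
})

test_that("classical MDS reproduces planted plane geometry to 1e-9", {
  set.seed(8)
  pts <- cbind(runif(15, -3, 3), runif(15, -2, 2))
  D <- as.matrix(dist(pts))
  fit <- classical_mds(D, n_dims = 2)
  D2 <- as.matrix(dist(fit$points))
  expect_lt(max(abs(D2 - D)), 1e-9)
})

test_that("equilateral triangle and duplicated points behave as geometry dictates", {
  D <- matrix(1, 3, 3) - diag(3)
  fit <- classical_mds(D)
  d <- as.matrix(dist(fit$points))
  expect_lt(max(abs(d[upper.tri(d)] - 1)), 1e-9)
  expect_equal(fit$eig[1:2], c(0.5, 0.5), tolerance = 1e-9)

  D4 <- rbind(cbind(D, D[, 1]), c(D[1, ], 0))   # point 4 duplicates point 1
  fit4 <- classical_mds(D4)
  expect_lt(max(abs(fit4$points[1, ] - fit4$points[4, ])), 1e-9)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(classical_mds(bad), "symmetric")
})

test_that("MDS sign convention makes results deterministic", {
  D <- as.matrix(dist(cbind(c(0, 1, 3, 7), c(2, 8, 1, 4))))
  a <- classical_mds(D)
  b <- classical_mds(D)
  expect_identical(a, b)
  expect_true(all(a$points[1, ] >= 0 | abs(a$points[1, ]) < 1e-12))
})

test_that("haploidization maps dosages to legal haploid calls", {
  g <- matrix(c(0L, 1L, 2L, NA), 2, 2)
  h <- haploidize(g, seed = 4)
  expect_equal(h[!is.na(g) & g == 0L], 0L)
  expect_equal(h[!is.na(g) & g == 2L], 1L)
  expect_true(h[2, 1] %in% c(0L, 1L))
  expect_true(is.na(h[2, 2]))
  expect_identical(haploidize(g, seed = 4), h)
})
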