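test_that("H and N are the diagonal and total sums of the count matrix", {
  C <- matrix(c(31, 0, 0, 23), 2, 2, byrow = TRUE)
  expect_equal(compute_H(C), 54)
  expect_equal(compute_N(C), 54)
  expect_equal(compute_H(matrix(0, 2, 2)), 0)
  C2 <- matrix(c(2, 1, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(compute_H(C2), 6)
  expect_equal(compute_N(C2), 10)
  expect_error(compute_H(matrix(1, 3, 3)))
})

test_that("analytic posterior is the conjugate Beta(H+a, N-H+b)", {
  p <- posterior_theta(54, 54)
  expect_equal(p$a, 54.5)
  expect_equal(p$b, 0.5)
  expect_equal(p$mean, 54.5 / 55)
  # no data: posterior equals the prior
  p0 <- posterior_theta(0, 0)
  expect_equal(p0$mean, 0.5)
  expect_equal(p0$a, 0.5)
  # symmetry at H = N/2
  expect_equal(posterior_theta(5, 10)$mean, 0.5)
  expect_error(posterior_theta(5, 3), "H <= N")
})

test_that("unnormalized beta-binomial posterior matches the Beta density", {
  # prior x binomial likelihood, normalized by adaptive numeric
  # integration, must reproduce the conjugate Beta density pointwise
  for (case in list(c(5, 10), c(1, 7), c(12, 30))) {
    H <- case[1]; N <- case[2]
    un <- function(t) t^(0.5 - 1) * (1 - t)^(0.5 - 1) *
      choose(N, H) * t^H * (1 - t)^(N - H)
    Z <- integrate(un, 0, 1, rel.tol = 1e-10)$value
    grid <- seq(1e-4, 1 - 1e-4, length.out = 1e4)
    db <- dbeta(grid, H + 0.5, N - H + 0.5)
    expect_lt(max(abs(un(grid) / Z - db) / pmax(db, 1)), 1e-6)
  }
})

test_that("HDI is the narrowest interval", {
  # monotone increasing density: interval ends at 1
  h <- hdi(posterior_theta(54, 54))
  expect_equal(unname(h["high"]), 1)
  expect_equal(unname(h["low"]), qbeta(0.05, 54.5, 0.5))
  # symmetric posterior: interval symmetric about 1/2
  h2 <- hdi(posterior_theta(10, 20))
  expect_equal(unname(h2["low"] + h2["high"]), 1, tolerance = 1e-4)
  # sample mode approximates the analytic narrowest interval
  set.seed(99)
  draws <- rbeta(10000, 3.5, 0.5)
  hs <- hdi(draws)
  ha <- kmerphase:::.hdi_beta(3.5, 0.5, 0.95)
  expect_lt(max(abs(hs - ha)), 0.02)
})

test_that("classification thresholds are strict and mirror-symmetric", {
  expect_equal(classify_result(0.99, 0.95, 1.0), "type1")
  expect_equal(classify_result(0.01, 0.0, 0.05), "type2")
  expect_equal(classify_result(0.80, 0.45, 0.99), "undetermined")
  expect_equal(classify_result(0.5, 0.2, 0.8), "undetermined")
})

test_that("three unanimous reads is the smallest valid type-1 call", {
  calls <- vapply(0:6, function(n) {
    p <- posterior_theta(n, n)
    h <- hdi(p)
    classify_result(p$mean, h["low"], h["high"])
  }, character(1))
  expect_equal(min(which(calls == "type1")) - 1, 3)
  expect_equal(calls[3], "undetermined")  # N = 2 fails on the HDI bound
})

test_that("posterior mean is monotone in H and hdi_low in unanimous N", {
  means <- vapply(0:20, function(h) posterior_theta(h, 20)$mean, numeric(1))
  expect_true(all(diff(means) > 0))
  lows <- vapply(1:20, function(n) hdi(posterior_theta(n, n))["low"],
                 numeric(1))
  expect_true(all(diff(lows) > 0))
})

test_that("results for (H, N) and (N-H, N) are mirror images", {
  for (case in list(c(3, 10), c(0, 4), c(7, 7))) {
    H <- case[1]; N <- case[2]
    p1 <- posterior_theta(H, N); p2 <- posterior_theta(N - H, N)
    expect_equal(p1$mean, 1 - p2$mean)
    h1 <- hdi(p1); h2 <- hdi(p2)
    expect_equal(unname(h1["low"]), unname(1 - h2["high"]), tolerance = 1e-6)
    c1 <- classify_result(p1$mean, h1["low"], h1["high"])
    c2 <- classify_result(p2$mean, h2["low"], h2["high"])
    flip <- c(type1 = "type2", type2 = "type1",
              undetermined = "undetermined")
    expect_equal(unname(flip[c1]), c2)
  }
})

test_that("MCMC sampling agrees with the analytic posterior", {
  for (case in list(c(5, 10), c(54, 54), c(2, 3))) {
    H <- case[1]; N <- case[2]
    pa <- posterior_theta(H, N)
    pm <- posterior_theta(H, N, method = "mcmc", draws = 1000, chains = 4,
                          seed = 17)
    expect_lt(abs(pa$mean - pm$mean), 0.01)
    expect_lt(max(abs(hdi(pa) - hdi(pm))), 0.02)
    # seeded determinism
    pm2 <- posterior_theta(H, N, method = "mcmc", draws = 1000, chains = 4,
                           seed = 17)
    expect_identical(pm$samples, pm2$samples)
  }
})

test_that("results table round-trips through the TSV writer", {
  pairs <- data.frame(gene_id = "g", lo = 0L, hi = 1L)
  snps <- data.frame(snp_index = 0:1, snp_id = c("s1", "s2"),
                     chrom = "chrT", pos = c(99L, 199L),
                     hap0_base = c("A", "C"), hap1_base = c("G", "T"))
  tab <- phase_count_table(pairs, snps)
  tab <- update_phase_counts(c(0, 2), tab)
  tab <- update_phase_counts(c(0, 2), tab)
  tab <- update_phase_counts(c(0, 2), tab)
  res <- phase_posteriors(tab)
  expect_equal(res$H, 3)
  expect_equal(res$N, 3)
  expect_equal(res$classification, "type1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, f)
  back <- read.delim(f)
  expect_equal(back$snp1_pos, 100)  # written 1-based
  expect_equal(back$H, res$H)
  expect_equal(back$theta_mean, res$theta_mean, tolerance = 1e-6)
  expect_equal(back$classification, res$classification)
  # empty result set: header-only file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(res[0, ], f2)
  expect_length(readLines(f2), 1)
  expect_equal(nrow(read.delim(f2)), 0)
})
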