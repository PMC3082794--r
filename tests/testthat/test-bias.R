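# Begg adjusted rank correlation and Egger regression asymmetry tests.

test_that("Begg statistic is Kendall tau between deviates and variances", {
  # deviates increase perfectly with variance -> tau = 1
  s <- effect_studies(sprintf("s%d", 1:6),
                      c(0.0, 0.5, 1.1, 1.8, 2.6, 3.5),
                      sqrt(c(0.2, 0.4, 0.7, 1.1, 1.6, 2.2)))
  b <- begg_test(s)
  expect_equal(b$statistic, 1)
  expect_lt(b$p, 0.05)
  # relabeling ids changes nothing
  s2 <- s; s2$study_id <- rev(s$study_id)
  expect_equal(begg_test(s2)$statistic, b$statistic)
  expect_error(begg_test(s[1:2, ]), "at least 3")
})

test_that("exact permutation p matches brute-force enumeration at k=5", {
  s <- effect_studies(sprintf("s%d", 1:5), c(1, 2, 3, 4, 5),
                      c(1, 2, 3, 4, 5))
  got <- begg_test(s, exact = TRUE)
  expect_equal(got$p_method, "exact")

  # oracle: recompute the deviates and enumerate all 120 orderings
  v <- s$se^2
  w <- 1 / v
  est <- sum(w * s$effect) / sum(w)
  t_i <- (s$effect - est) / sqrt(v - 1 / sum(w))
  s_obs <- kendall_s_oracle(t_i, v)
  hits <- 0L
  for (p in perms_oracle(5)) {
    if (abs(kendall_s_oracle(t_i, v[p])) >= abs(s_obs)) hits <- hits + 1L
  }
  expect_equal(got$p, hits / 120)
})

test_that("exact enumeration path agrees with the tie-free recursion", {
  set.seed(13)
  s <- effect_studies(sprintf("s%d", 1:6), rnorm(6), runif(6, 0.2, 1))
  p_rec <- begg_test(s, exact = TRUE)$p
  # force the enumeration path through the internal helper
  v <- s$se^2
  w <- 1 / v
  est <- sum(w * s$effect) / sum(w)
  t_i <- (s$effect - est) / sqrt(v - 1 / sum(w))
  expect_equal(crcbias:::kendall_exact_enum(t_i, v), p_rec)
})

test_that("normal approximation tracks the exact p on small samples", {
  set.seed(17)
  for (i in 1:30) {
    s <- effect_studies(sprintf("s%d", 1:8), rnorm(8), runif(8, 0.1, 1))
    pe <- begg_test(s, exact = TRUE)$p
    pn <- begg_test(s, exact = FALSE)$p
    expect_lt(abs(pe - pn), 0.05)
  }
})

test_that("Egger regression recovers closed-form OLS", {
  # standardized effects (1, 2, 4) at precisions (1, 2, 3):
  # slope = 3/2, intercept = 7/3 - 3 = -2/3 by the normal equations
  s <- effect_studies(c("a", "b", "c"),
                      effect = c(1, 2, 4) / c(1, 2, 3) * 1,
                      se = 1 / c(1, 2, 3))
  e <- egger_test(s)
  expect_equal(e$statistic, -2 / 3, tolerance = 1e-10)
  expect_equal(e$slope, 3 / 2, tolerance = 1e-10)

  # generated exactly as theta/se = 2 * (1/se): line through the origin
  se <- c(0.2, 0.4, 0.8, 1.5)
  s0 <- effect_studies(sprintf("s%d", 1:4), effect = 2 + 0 * se, se = se)
  e0 <- egger_test(s0)
  expect_equal(e0$statistic, 0, tolerance = 1e-10)
  expect_equal(e0$p, 1)

  expect_error(egger_test(effect_studies(c("a", "b", "c"), 1:3,
                                         rep(0.5, 3))),
               "precision constant")
})

test_that("Egger intercept is invariant to duplication, flips with sign", {
  set.seed(19)
  s <- effect_studies(sprintf("s%d", 1:10), rnorm(10, 0.3),
                      runif(10, 0.1, 0.8))
  e1 <- egger_test(s)
  dup <- effect_studies(sprintf("d%d", 1:20), rep(s$effect, 2),
                        rep(s$se, 2))
  e2 <- egger_test(dup)
  expect_equal(e2$statistic, e1$statistic, tolerance = 1e-10)
  expect_gt(abs(e2$t), abs(e1$t))

  neg <- effect_studies(s$study_id, -s$effect, s$se)
  expect_equal(egger_test(neg)$statistic, -e1$statistic, tolerance = 1e-10)
  expect_equal(begg_test(neg)$statistic, -begg_test(s)$statistic)
})

test_that("both tests hold their size under a no-bias simulation", {
  set.seed(23)
  n_rep <- 1000
  rej <- matrix(FALSE, n_rep, 2)
  for (i in 1:n_rep) {
    sim <- simulate_meta(15, effect = 0.2, tau2 = 0)
    rej[i, 1] <- begg_test(sim$published)$p < 0.10
    rej[i, 2] <- egger_test(sim$published)$p < 0.10
  }
  mc <- 3 * sqrt(0.1 * 0.9 / n_rep)  # ~0.028
  expect_lt(abs(mean(rej[, 1]) - 0.10), mc)
  expect_lt(abs(mean(rej[, 2]) - 0.10), mc)
})

test_that("funnel data exports one row per study with symmetric bounds", {
  one <- effect_studies("solo", 0.4, 0.2)
  f1 <- funnel_data(one)
  expect_equal(nrow(f1$data), 1)
  expect_equal(f1$bounds$lower[1], f1$bounds$upper[1])  # meet at se = 0

  set.seed(29)
  k <- 34
  s <- simulate_meta(k, effect = 0.5, seed = 7)$published
  f <- funnel_data(s)
  expect_equal(nrow(f$data), k)
  expect_true(all(f$bounds$upper - f$center >= 0))
  expect_equal(f$bounds$upper - f$center, f$center - f$bounds$lower)

  # exactly mirrored set: equal counts either side of the center line
  m <- effect_studies(sprintf("s%d", 1:6), c(-3, -2, -1, 1, 2, 3),
                      rep(0.5, 6))
  fm <- funnel_data(m)
  expect_equal(sum(fm$data$effect > fm$center),
               sum(fm$data$effect < fm$center))
})
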