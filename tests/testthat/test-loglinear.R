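# Log-linear capture-recapture fitting, information criteria, interval
# estimation, model selection and completeness.

test_that("eight hierarchical models are enumerated canonically", {
  specs <- crc_models()
  expect_length(specs, 8)
  labels <- vapply(specs, `[[`, character(1), "label")
  expect_equal(anyDuplicated(labels), 0L)
  expect_equal(labels[1], "A B C")
  expect_equal(labels[8], "A B C AB AC BC")
  nint <- vapply(specs, function(s) length(s$interactions), integer(1))
  expect_equal(sort(nint), c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L))
})

test_that("an exactly independent table is fitted without error", {
  # all 8 cells of the underlying 2x2x2 equal 10; we observe 7 of them
  tab <- capture_table(10, 10, 10, 10, 10, 10, 10)
  fit <- crc_fit(tab)
  expect_lt(fit$g2, 1e-10)
  expect_equal(fit$x_hat, 10, tolerance = 1e-6)
  expect_equal(fit$n_est, 80, tolerance = 1e-6)
  expect_true(fit$identifiable)
})

test_that("likelihood equations hold: fitted margins match observed", {
  tab <- hbv_review_table()
  d <- crcbias:::cell_design()
  for (spec in crc_models()) {
    fit <- crc_fit(tab, spec, ci = FALSE)
    mu <- fit$fitted
    y <- as.numeric(tab$cells)
    for (f in c("A", "B", "C")) {
      idx <- d[[f]] == 1
      expect_equal(sum(mu[idx]), sum(y[idx]), tolerance = 1e-6)
    }
    for (term in spec$interactions) {
      fs <- strsplit(term, "")[[1]]
      idx <- d[[fs[1]]] == 1 & d[[fs[2]]] == 1
      expect_equal(sum(mu[idx]), sum(y[idx]), tolerance = 1e-6)
    }
  }
})

test_that("saturated model reproduces any strictly positive table", {
  set.seed(11)
  sat <- crc_models()[[8]]
  for (i in 1:10) {
    tab <- random_capture_table()
    fit <- crc_fit(tab, sat, ci = FALSE)
    expect_lt(fit$g2, 1e-8)
    expect_equal(unname(fit$fitted), as.numeric(tab$cells),
                 tolerance = 1e-6)
  }
})

test_that("independence fit agrees with an IPF oracle", {
  set.seed(99)
  for (i in 1:50) {
    tab <- random_capture_table()
    fit <- crc_fit(tab, ci = FALSE)
    mu_ipf <- ipf_independence(as.numeric(tab$cells))
    expect_equal(unname(fit$fitted), mu_ipf, tolerance = 1e-6)
  }
})

test_that("independence X estimate is invariant to source relabeling", {
  set.seed(5)
  tab <- random_capture_table()
  x0 <- crc_fit(tab, ci = FALSE)$x_hat
  cl <- tab$cells
  # swap sources A and C: a<->c, ab<->bc, ac fixed, abc fixed
  tab2 <- capture_table(cl["c"], cl["b"], cl["a"], cl["bc"], cl["ac"],
                        cl["ab"], cl["abc"])
  expect_equal(crc_fit(tab2, ci = FALSE)$x_hat, x0, tolerance = 1e-8)
})

test_that("chi-square tails and information criteria follow their forms", {
  expect_equal(chi2_pvalue(3.10, 3), pchisq(3.10, 3, lower.tail = FALSE))
  fit <- crc_fit(hbv_review_table(), ci = FALSE)
  expect_equal(round(chi2_pvalue(fit$g2, fit$df), 4), 0.3767)
  expect_equal(chi2_pvalue(0, 3), 1.0)
  expect_equal(chi2_pvalue(0, 0), 1.0)
  expect_error(chi2_pvalue(-1, 3), "nonnegative")

  expect_equal(crc_aic(3.10, 3), -2.90)
  expect_equal(crc_aic(1.84, 2), -2.16)
  expect_equal(crc_aic(0, 0), 0)
  expect_equal(crc_bic(5.5, 0, 34), 5.5)
  expect_equal(crc_bic(3.10, 3, 34), 3.10 - 3 * log(34 / (2 * pi)))
})

test_that("divergent fits are flagged rather than reported numerically", {
  tab <- hbv_review_table()
  fits <- crc_fit_all(tab)
  flags <- vapply(fits, `[[`, logical(1), "identifiable")
  labels <- vapply(fits, function(f) f$model$label, character(1))
  expect_equal(labels[!flags], c("A B C AB BC", "A B C AB AC BC"))
  for (f in fits[!flags]) {
    expect_identical(f$x_hat, Inf)
    expect_identical(f$n_est, Inf)
    expect_error(crc_completeness(tab, f), "non-identifiable")
  }
})

test_that("profile interval brackets the estimate and tightens with level", {
  tab <- hbv_review_table()
  fit <- crc_fit(tab)
  expect_true(fit$ci_x["lower"] <= fit$x_hat)
  expect_true(fit$ci_x["upper"] >= fit$x_hat)

  ind <- capture_table(10, 10, 10, 10, 10, 10, 10)
  wide <- confidence_interval_x(ind, level = 0.95)
  narrow <- confidence_interval_x(ind, level = 0.05)
  expect_lt(diff(narrow), diff(wide))
  expect_true(narrow["lower"] <= 10 && 10 <= narrow["upper"])

  delta <- confidence_interval_x(tab, method = "delta")
  f0 <- crc_fit(tab, ci = FALSE)
  expect_true(delta["lower"] <= f0$x_hat && f0$x_hat <= delta["upper"])

  sat <- crc_models()[[8]]
  expect_error(confidence_interval_x(tab, sat), "non-identifiable")
})

test_that("model selection minimizes the criterion with stable ties", {
  tab <- hbv_review_table()
  fits <- crc_fit_all(tab)
  expect_equal(crc_select(fits, "aic")$model$label, "A B C")
  expect_equal(crc_select(fits, "bic")$model$label, "A B C")

  single <- structure(fits[3], class = "crc_fit_list")
  expect_equal(crc_select(single)$model$label, fits[[3]]$model$label)

  # artificial tie: equal criterion, different interaction counts
  mk <- function(label, nint, aic) {
    structure(list(model = list(label = label,
                                interactions = rep("AB", nint)),
                   aic = aic, bic = aic, identifiable = TRUE),
              class = "crc_fit")
  }
  tied <- structure(list(mk("two", 2, -1), mk("one", 1, -1)),
                    class = "crc_fit_list")
  expect_equal(crc_select(tied)$model$label, "one")

  none <- structure(list(structure(list(identifiable = FALSE),
                                   class = "crc_fit")),
                    class = "crc_fit_list")
  expect_error(crc_select(none), "no identifiable")
})

test_that("completeness transforms counts by the estimated total", {
  tab <- capture_table(2, 2, 2, 1, 1, 1, 1)
  # degenerate fit with nothing missing: everything is complete
  fit0 <- structure(list(n_est = tab$n_obs, x_hat = 0,
                         ci_x = c(lower = 0, upper = 0),
                         identifiable = TRUE),
                    class = "crc_fit")
  comp <- crc_completeness(tab, fit0)
  expect_equal(comp$completeness[comp$source == "All three sources"], 100)
  expect_true(all(comp$completeness > 0 & comp$completeness <= 100))
  expect_true(all(comp$ci_lower <= comp$completeness + 1e-9))
})
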