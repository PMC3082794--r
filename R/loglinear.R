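# Three-source log-linear capture-recapture: fit hierarchical Poisson
# models to the 7 observed cells, extrapolate the unobserved
# caught-by-no-source cell X, and report N = n_obs + X.

# Design rows in cell order a, b, c, ab, ac, bc, abc; the eighth,
# unobserved row is (0, 0, 0).
cell_design <- function() {
  data.frame(
    A = c(1, 0, 0, 1, 1, 0, 1),
    B = c(0, 1, 0, 1, 0, 1, 1),
    C = c(0, 0, 1, 0, 1, 1, 1)
  )
}

#' Enumerate the eight hierarchical three-source log-linear models
#'
#' Main effects for the three sources are always present; the models
#' differ in which of the pairwise source-dependence terms AB, AC, BC
#' they include (all subsets, from none to all three). Three-way
#' interaction is not estimable with one unobserved cell.
#'
#' @return A list of 8 model specs, each with `interactions` (subset of
#'   `"AB"`, `"AC"`, `"BC"`) and a canonical `label` such as `"A B C AC"`,
#'   ordered from no interaction to all three pairwise terms.
#' @examples
#' sapply(crc_models(), `[[`, "label")
#' @export
crc_models <- function() {
  sets <- list(character(0), "AB", "AC", "BC",
               c("AB", "AC"), c("AB", "BC"), c("AC", "BC"),
               c("AB", "AC", "BC"))
  lapply(sets, function(s) {
    structure(list(interactions = s,
                   label = paste(c("A", "B", "C", s), collapse = " ")),
              class = "crc_model_spec")
  })
}

model_formula <- function(spec) {
  terms <- c("A", "B", "C",
             vapply(spec$interactions, function(t) {
               paste(strsplit(t, "")[[1]], collapse = ":")
             }, character(1)))
  as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

#' Upper-tail chi-square p-value for a deviance statistic
#'
#' @param g2 Likelihood-ratio statistic, `>= 0`.
#' @param df Degrees of freedom, `>= 0`. At `df = 0` a saturated model
#'   with `g2 = 0` is reported as `p = 1`.
#' @return The upper-tail probability.
#' @export
chi2_pvalue <- function(g2, df) {
  if (g2 < 0 || df < 0) stop("g2 and df must be nonnegative")
  if (df == 0) return(if (g2 <= .Machine$double.eps^0.5) 1.0 else 0.0)
  pchisq(g2, df, lower.tail = FALSE)
}

#' Akaike information criterion on the deviance scale
#'
#' `AIC = G^2 - 2 * df`: among models fitted to the same cells, smaller
#' is better; the subtraction rewards parsimony through the residual
#' degrees of freedom.
#'
#' @param g2 Deviance statistic.
#' @param df Residual degrees of freedom.
#' @export
crc_aic <- function(g2, df) g2 - 2 * df

#' Bayesian information criterion on the deviance scale
#'
#' `BIC = G^2 - ln(n_obs / 2*pi) * df`, with `n_obs` the number of
#' observed studies.
#'
#' @param g2 Deviance statistic.
#' @param df Residual degrees of freedom.
#' @param n_obs Observed sample size.
#' @export
crc_bic <- function(g2, df, n_obs) {
  stopifnot(n_obs >= 1)
  g2 - log(n_obs / (2 * pi)) * df
}

# Deviance of the model fitted to all 8 cells with the unobserved cell
# frozen at x (possibly non-integer). Used by the profile CI.
profile_deviance <- function(table, spec, x) {
  d <- rbind(cell_design(), c(0, 0, 0))
  d$y <- c(as.numeric(table$cells), x)
  fit <- suppressWarnings(glm(model_formula(spec), family = poisson(),
                              data = d,
                              control = list(maxit = 100, epsilon = 1e-12)))
  fit$deviance
}

#' Profile-likelihood confidence interval for the unobserved cell
#'
#' Profiles the Poisson likelihood over the frozen value of the
#' caught-by-no-source cell: the interval is the set of x whose
#' profile deviance lies within the chi-square(1) quantile of the
#' minimum. A log-normal delta-method interval (normal interval for the
#' intercept, exponentiated) is available as an alternative.
#'
#' @param table A `capture_table`.
#' @param model A spec from [crc_models()].
#' @param level Confidence level.
#' @param method `"profile"` (default) or `"delta"`.
#' @return `c(lower, upper)` for X; lower bounded below by 0.
#' @export
confidence_interval_x <- function(table, model = crc_models()[[1]],
                                  level = 0.95,
                                  method = c("profile", "delta")) {
  method <- match.arg(method)
  fit <- crc_fit(table, model, ci = FALSE)
  if (!fit$identifiable) stop("CI undefined for a non-identifiable fit")
  x_hat <- fit$x_hat
  if (method == "delta") {
    z <- qnorm(1 - (1 - level) / 2)
    lo <- exp(log(x_hat) - z * fit$se_log_x)
    hi <- exp(log(x_hat) + z * fit$se_log_x)
    return(c(lower = max(0, lo), upper = hi))
  }
  crit <- qchisq(level, 1)
  d0 <- profile_deviance(table, model, x_hat)
  f <- function(x) profile_deviance(table, model, x) - d0 - crit
  # lower bound
  lo <- if (f(0) <= 0) 0 else
    uniroot(f, c(1e-9, x_hat), tol = 1e-7)$root
  # upper bound: expand until the deviance crosses the cutoff
  hi_cap <- max(10 * x_hat + 10, 1000 * table$n_obs)
  up <- x_hat * 2 + 1
  while (f(up) < 0 && up < hi_cap) up <- up * 2
  hi <- if (f(up) < 0) Inf else uniroot(f, c(x_hat, up), tol = 1e-7)$root
  c(lower = lo, upper = hi)
}

#' Fit one log-linear model to a three-source capture table
#'
#' A Poisson regression of the seven observed cell counts on source
#' indicator main effects plus the spec's pairwise interaction
#' indicators (iteratively reweighted least squares via [stats::glm()]).
#' The estimated unobserved cell is the model's prediction for the
#' all-absent pattern, `exp(intercept)`; the estimated total study
#' population is `n_obs + x_hat`.
#'
#' Fits whose extrapolated cell diverges — `x_hat > 1000 * n_obs`, or a
#' non-finite intercept standard error — are flagged non-identifiable
#' and report `x_hat` and `n_est` as `Inf`. This occurs, e.g., for
#' models whose sufficient statistics involve an empty overlap cell.
#'
#' @param table A `capture_table`.
#' @param model A spec from [crc_models()] (default: independence).
#' @param ci_level Confidence level for the X interval.
#' @param ci_method `"profile"` or `"delta"`; see
#'   [confidence_interval_x()].
#' @param ci Compute the interval (skipped internally when not needed).
#' @return A `crc_fit`: model, `df`, `g2`, `p`, `x_hat`, `n_est`,
#'   `ci_x`, `aic`, `bic`, `identifiable`, `converged`.
#' @examples
#' tab <- hbv_review_table()
#' crc_fit(tab)  # independence model: G2 = 3.10 on 3 df, X ~ 5.2
#' @export
crc_fit <- function(table, model = crc_models()[[1]], ci_level = 0.95,
                    ci_method = "profile", ci = TRUE) {
  stopifnot(inherits(table, "capture_table"), table$n_obs > 0)
  d <- cell_design()
  d$y <- as.numeric(table$cells)
  g <- suppressWarnings(glm(model_formula(model), family = poisson(),
                            data = d,
                            control = list(maxit = 100, epsilon = 1e-12)))
  g2 <- g$deviance
  df <- g$df.residual
  x_hat <- unname(exp(coef(g)[1]))
  se0 <- suppressWarnings(sqrt(diag(vcov(g)))[1])
  identifiable <- is.finite(se0) && is.finite(x_hat) &&
    x_hat <= 1000 * table$n_obs
  fit <- structure(
    list(model = model, df = df, g2 = g2,
         p = chi2_pvalue(max(0, g2), df),
         x_hat = if (identifiable) x_hat else Inf,
         n_est = if (identifiable) table$n_obs + x_hat else Inf,
         ci_x = c(lower = NA_real_, upper = NA_real_),
         aic = crc_aic(g2, df),
         bic = crc_bic(g2, df, table$n_obs),
         identifiable = identifiable,
         converged = g$converged,
         se_log_x = unname(se0),
         fitted = setNames(unname(g$fitted.values), CELL_NAMES),
         n_obs = table$n_obs),
    class = "crc_fit"
  )
  if (ci && identifiable)
    fit$ci_x <- confidence_interval_x(table, model, level = ci_level,
                                      method = ci_method)
  fit
}

#' @export
print.crc_fit <- function(x, ...) {
  cat("Log-linear capture-recapture fit: ", x$model$label, "\n", sep = "")
  cat(sprintf("  G2 = %.2f on %d df (p = %.4f)\n", x$g2, x$df, x$p))
  if (x$identifiable) {
    cat(sprintf("  X = %.2f missing studies (95%% CI %.1f-%.1f); N = %.1f\n",
                x$x_hat, x$ci_x[1], x$ci_x[2], x$n_est))
  } else {
    cat("  X and N diverge (non-identifiable fit)\n")
  }
  cat(sprintf("  AIC = %.2f, BIC = %.2f\n", x$aic, x$bic))
  invisible(x)
}

#' Fit all eight log-linear models
#'
#' @inheritParams crc_fit
#' @return A `crc_fit_list` of 8 fits in the canonical order of
#'   [crc_models()]. Per-fit identifiability/convergence flags are
#'   carried through; the batch never aborts.
#' @examples
#' fits <- crc_fit_all(hbv_review_table())
#' fits
#' @export
crc_fit_all <- function(table, ci_level = 0.95, ci_method = "profile") {
  fits <- lapply(crc_models(), function(m)
    crc_fit(table, m, ci_level = ci_level, ci_method = ci_method))
  structure(fits, class = "crc_fit_list")
}

#' Tabulate a list of fits
#'
#' @param fits A `crc_fit_list`.
#' @param digits Decimals for G2/AIC/BIC display columns.
#' @return A data frame with one row per model: label, df, g2, p, n_est
#'   and x_hat (rounded to whole studies, `Inf` when non-identifiable),
#'   CI bounds, aic, bic, identifiable.
#' @export
crc_fit_table <- function(fits, digits = 2) {
  stopifnot(inherits(fits, "crc_fit_list"))
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      model = f$model$label, df = f$df,
      g2 = round_half_up(f$g2, digits),
      p = round_half_up(f$p, 4),
      n_est = if (f$identifiable) round_half_up(f$n_est) else Inf,
      x_hat = if (f$identifiable) round_half_up(f$x_hat) else Inf,
      ci_lower = round_half_up(f$ci_x[1], 1),
      ci_upper = round_half_up(f$ci_x[2], 1),
      aic = round_half_up(f$aic, digits),
      bic = round_half_up(f$bic, digits),
      identifiable = f$identifiable,
      row.names = NULL
    )
  }))
}

#' @export
print.crc_fit_list <- function(x, ...) {
  cat("Log-linear models fitted to three sources\n")
  df <- crc_fit_table(x)
  df$identifiable <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}

#' Select the best-fitting identifiable model
#'
#' The identifiable fit with the smallest information criterion wins;
#' ties are broken toward fewer interaction terms, then canonical order.
#'
#' @param fits A `crc_fit_list`.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @return The selected `crc_fit`.
#' @export
crc_select <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  ok <- Filter(function(f) f$identifiable, fits)
  if (!length(ok)) stop("no identifiable fits to select from")
  crit <- vapply(ok, `[[`, numeric(1), criterion)
  nterm <- vapply(ok, function(f) length(f$model$interactions), integer(1))
  ord <- order(crit, nterm, seq_along(ok))
  ok[[ord[1]]]
}

#' Search completeness given a selected model
#'
#' Completeness of a source is the share of the estimated total study
#' population it retrieved: `100 * observed / N_hat`. `N_hat` is taken
#' at whole-study resolution (rounded to the nearest integer), matching
#' how an estimated study count is reported. Interval bounds transform
#' the X interval monotonically:
#' `lower = 100 * count / (n_obs + x_upper)` and vice versa.
#'
#' @param table A `capture_table`.
#' @param fit An identifiable `crc_fit` (e.g. from [crc_select()]).
#' @return A `crc_completeness` data frame: one row per source plus an
#'   overall row, with observed count, estimated total, completeness
#'   percent and CI bounds.
#' @examples
#' tab <- hbv_review_table()
#' crc_completeness(tab, crc_select(crc_fit_all(tab)))
#' @export
crc_completeness <- function(table, fit) {
  stopifnot(inherits(table, "capture_table"), inherits(fit, "crc_fit"))
  if (!fit$identifiable)
    stop("completeness undefined for a non-identifiable fit")
  n_hat <- round_half_up(fit$n_est)
  counts <- c(table$margins, all = table$n_obs)
  labels <- c(table$sources, "All three sources")
  pct <- 100 * counts / n_hat
  lo <- 100 * counts / (table$n_obs + fit$ci_x["upper"])
  hi <- 100 * counts / (table$n_obs + fit$ci_x["lower"])
  out <- data.frame(
    source = labels,
    observed = as.integer(counts),
    estimated = rep(n_hat, 4),
    completeness = round_half_up(pct, 1),
    ci_lower = round_half_up(lo, 1),
    ci_upper = round_half_up(hi, 1),
    row.names = NULL
  )
  class(out) <- c("crc_completeness", "data.frame")
  out
}
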