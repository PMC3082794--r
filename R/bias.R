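# Small-study / publication-bias diagnostics: funnel-plot data export,
# the Begg adjusted rank correlation test, and the Egger regression
# asymmetry test.

#' Funnel-plot data
#'
#' Per-study rows (effect vs standard error) plus the pseudo-confidence
#' funnel: `pooled +/- z * se` evaluated over the observed SE range.
#' Asymmetry of the scatter about the pooled line suggests — but does
#' not prove — selective publication.
#'
#' @param studies An `effect_studies` data frame.
#' @param pooled Center line; defaults to the fixed-effect pooled
#'   estimate (a single study is its own center).
#' @param level Pseudo-CI level for the funnel bounds.
#' @return A `funnel_data` list: `data` (study rows), `center`, and
#'   `bounds` (se grid with lower/upper funnel lines meeting at se = 0).
#' @export
funnel_data <- function(studies, pooled = NULL, level = 0.95) {
  if (nrow(studies) < 1) stop("need at least 1 study")
  if (is.null(pooled)) {
    pooled <- if (nrow(studies) >= 2)
      pool_effects(studies, model = "fixed")$est_fixed
    else studies$effect[1]
  }
  z <- qnorm(1 - (1 - level) / 2)
  se_grid <- seq(0, max(studies$se), length.out = 50)
  structure(
    list(data = data.frame(study_id = studies$study_id,
                           effect = studies$effect, se = studies$se),
         center = pooled,
         bounds = data.frame(se = se_grid,
                             lower = pooled - z * se_grid,
                             upper = pooled + z * se_grid),
         level = level),
    class = "funnel_data"
  )
}

# --- Kendall S machinery -------------------------------------------------

# S = #concordant - #discordant pairs (ties contribute 0).
kendall_s <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(x[(i + 1):n] - x[i]) * sign(y[(i + 1):n] - y[i]))
  }
  s
}

# Tie-corrected variance of S under the null (Kendall 1970), with the
# two cross-product tie terms.
kendall_s_var <- function(x, y) {
  n <- length(x)
  tx <- table(x); ty <- table(y)
  t1 <- function(t) sum(t * (t - 1) * (2 * t + 5))
  t2 <- function(t) sum(t * (t - 1) * (t - 2))
  t3 <- function(t) sum(t * (t - 1))
  v <- (n * (n - 1) * (2 * n + 5) - t1(tx) - t1(ty)) / 18
  if (n > 2)
    v <- v + t2(tx) * t2(ty) / (9 * n * (n - 1) * (n - 2))
  v <- v + t3(tx) * t3(ty) / (2 * n * (n - 1))
  v
}

# Null distribution of S for tie-free data: the inversion-count
# generating function prod_{i=1..n} (1 + z + ... + z^(i-1)) gives the
# number of permutations with each inversion count; S = M - 2*inv with
# M = n(n-1)/2. Identical to enumerating all n! orderings.
kendall_s_counts <- function(n) {
  counts <- 1
  for (i in 2:n) counts <- convolve_counts(counts, i)
  m <- n * (n - 1) / 2
  list(s = m - 2 * (0:m), counts = counts)
}

convolve_counts <- function(counts, i) {
  out <- numeric(length(counts) + i - 1)
  for (j in 0:(i - 1)) {
    idx <- seq_along(counts) + j
    out[idx] <- out[idx] + counts
  }
  out
}

# All permutations of 1..n (n small), as an n!-row matrix.
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Exact permutation p-value P(|S| >= |s_obs|) by full enumeration
# (handles ties; n <= 8 kept cheap).
kendall_exact_enum <- function(x, y) {
  n <- length(x)
  s_obs <- kendall_s(x, y)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  pr <- which(upper.tri(sx), arr.ind = TRUE)
  sxv <- sx[pr]
  perms <- all_perms(n)
  hits <- 0L
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    s <- sum(sxv * sy[cbind(p[pr[, 1]], p[pr[, 2]])])
    if (abs(s) >= abs(s_obs) - 1e-9) hits <- hits + 1L
  }
  hits / nrow(perms)
}

#' Begg adjusted rank correlation test
#'
#' Correlates variance-standardized effect deviates with study
#' variances. The deviates are `t_i = (theta_i - theta_F) /
#' sqrt(v_i - v_F)`, where `theta_F` is the fixed-effect pooled estimate
#' and `v_F` its variance (the subtraction removes the correlation
#' induced by pooling). The test statistic is Kendall's tau-b between
#' `t_i` and `v_i`; a positive association means imprecise studies
#' report systematically larger effects.
#'
#' @param studies An `effect_studies` data frame, `k >= 3`.
#' @param exact Use the exact permutation distribution of Kendall's S
#'   (tie-free data of any supported size via the inversion-count
#'   recursion; tied data by full enumeration for `k <= 8`). Falls back
#'   to the normal approximation with a warning when not available.
#'   Requires `k <= 10`.
#' @return A `bias_test`: `statistic` (tau-b), `s` (Kendall S), `p`
#'   (two-sided), `method`, `p_method`.
#' @details The normal approximation uses the tie-corrected null
#'   variance of S and a continuity correction. If any `v_i <= v_F`
#'   numerically, the offending denominator is floored at 1e-12 with a
#'   warning so degenerate fixtures stay defined.
#' @export
begg_test <- function(studies, exact = FALSE) {
  k <- nrow(studies)
  if (k < 3) stop("need at least 3 studies")
  y <- studies$effect
  v <- studies$se^2
  w <- 1 / v
  est_f <- sum(w * y) / sum(w)
  v_f <- 1 / sum(w)
  d <- v - v_f
  if (any(d <= 0)) {
    warning("some v_i <= var(pooled); flooring variance correction at 1e-12")
    d <- pmax(d, 1e-12)
  }
  t_i <- (y - est_f) / sqrt(d)
  tau <- suppressWarnings(cor(t_i, v, method = "kendall"))
  s <- kendall_s(t_i, v)
  p_method <- "normal"
  p <- NA_real_
  if (exact) {
    if (k > 10) {
      warning("exact permutation p only supported for k <= 10; ",
              "using normal approximation")
    } else if (anyDuplicated(t_i) == 0 && anyDuplicated(v) == 0) {
      dist <- kendall_s_counts(k)
      p <- sum(dist$counts[abs(dist$s) >= abs(s) - 1e-9]) / sum(dist$counts)
      p_method <- "exact"
    } else if (k <= 8) {
      p <- kendall_exact_enum(t_i, v)
      p_method <- "exact"
    } else {
      warning("ties present and k > 8; using normal approximation")
    }
  }
  if (is.na(p)) {
    vs <- kendall_s_var(t_i, v)
    z <- if (s == 0) 0 else (abs(s) - 1) / sqrt(vs)
    p <- 2 * pnorm(-abs(z))
    p <- min(1, p)
  }
  structure(
    list(method = "begg", statistic = tau, s = s, p = p,
         p_method = p_method, k = k),
    class = "bias_test"
  )
}

#' Egger regression asymmetry test
#'
#' Ordinary least squares of the standardized effect
#' `theta_i / se_i` on precision `1 / se_i`, with intercept. Under no
#' small-study asymmetry the line passes through the origin; the
#' two-sided t test on the intercept (k - 2 df) is the test.
#'
#' @param studies An `effect_studies` data frame, `k >= 3` with
#'   non-constant standard errors.
#' @param weighted Weight the standardized regression by `1/se^2`
#'   (variant; classic unweighted form is the default).
#' @return A `bias_test`: `statistic` (intercept), `se`, `t`, `p`
#'   (two-sided), `slope` (the precision coefficient, an estimate of the
#'   underlying effect).
#' @export
egger_test <- function(studies, weighted = FALSE) {
  k <- nrow(studies)
  if (k < 3) stop("need at least 3 studies")
  x <- 1 / studies$se
  y <- studies$effect / studies$se
  if (max(x) - min(x) < 1e-12)
    stop("precision constant, intercept not estimable (collinear with slope)")
  fit <- if (weighted) lm(y ~ x, weights = 1 / studies$se^2) else lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients
  b0 <- sm[1, 1]; se0 <- sm[1, 2]; tval <- sm[1, 3]
  if (se0 < 1e-12) {
    # residuals are numerically zero: the line is exact, so the
    # intercept is either exactly zero (no asymmetry) or exactly nonzero
    tval <- if (abs(b0) < 1e-8) 0 else sign(b0) * Inf
  }
  p <- 2 * pt(-abs(tval), df = k - 2)
  structure(
    list(method = "egger", statistic = b0, se = se0, t = tval, p = p,
         slope = sm[2, 1], k = k, weighted = weighted),
    class = "bias_test"
  )
}

#' @export
print.bias_test <- function(x, ...) {
  if (x$method == "begg") {
    cat(sprintf("Begg rank correlation test: tau = %.3f, p = %.4f (%s)\n",
                x$statistic, x$p, x$p_method))
  } else {
    cat(sprintf(
      "Egger regression asymmetry test: intercept = %.3f (SE %.3f), t = %.2f, p = %.4f\n",
      x$statistic, x$se, x$t, x$p))
  }
  invisible(x)
}
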