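# Duval-Tweedie nonparametric trim-and-fill: estimate the number of
# suppressed studies from funnel asymmetry, impute their mirror images,
# and re-pool.

#' Rank-based estimators of the suppressed-study count
#'
#' Given deviations of study effects from a chosen center, ranks their
#' absolute values and evaluates one of the Duval-Tweedie estimators of
#' the number of studies missing from the deficient side. `L0` uses the
#' Wilcoxon-type rank sum `T` of the excess (positive) side:
#' `L0 = (4T - k(k+1)) / (2k - 1)`. `R0` is one less than the length of
#' the run of largest absolute ranks that all lie on the excess side.
#'
#' @param deviations Effects minus the center; positive values are the
#'   excess side.
#' @param estimator `"L0"` (default) or `"R0"`.
#' @return A nonnegative integer (L0 rounded to the nearest integer,
#'   floored at 0).
#' @examples
#' estimate_k0(c(-3, -2, -1, 0, 1, 2, 3, 4, 5))  # 2
#' @export
estimate_k0 <- function(deviations, estimator = c("L0", "R0")) {
  estimator <- match.arg(estimator)
  k <- length(deviations)
  r <- rank(abs(deviations))
  if (estimator == "L0") {
    t_pos <- sum(r[deviations > 0])
    l0 <- (4 * t_pos - k * (k + 1)) / (2 * k - 1)
    return(max(0L, as.integer(round_half_up(l0))))
  }
  ord <- order(r, decreasing = TRUE)
  run <- 0L
  for (i in ord) {
    if (deviations[i] > 0) run <- run + 1L else break
  }
  max(0L, run - 1L)
}

#' Duval-Tweedie trim-and-fill
#'
#' Iteratively (i) pools the studies remaining after trimming the `k0`
#' most extreme effects on the excess side (fixed-effect pooling during
#' trimming), (ii) re-centers all deviations at that pooled estimate,
#' and (iii) re-estimates `k0`, until `k0` stabilizes (max 50 rounds).
#' The `k0` trimmed studies are then "filled" by reflecting them about
#' the final center (`2 * center - effect`, keeping each study's
#' original standard error) and the full set is re-pooled.
#'
#' @param studies An `effect_studies` data frame, `k >= 3`.
#' @param side Which side studies are suspected missing from: `"left"`,
#'   `"right"`, or `"auto"` (the side opposite the sign of the Egger
#'   intercept; a zero intercept falls back to left).
#' @param estimator Passed to [estimate_k0()].
#' @param pool_model Pooling model for the adjusted estimate
#'   (`"random"` default; trimming always centers on fixed-effect
#'   pools).
#' @param maxit Iteration cap.
#' @return A `trim_fill_result`: `k0`, `side`, `estimator`, `filled`
#'   (imputed studies), `pooled_original`, `pooled_adjusted`,
#'   `iterations`, `stabilized`.
#' @export
trim_and_fill <- function(studies, side = c("auto", "left", "right"),
                          estimator = c("L0", "R0"),
                          pool_model = c("random", "fixed"), maxit = 50) {
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  pool_model <- match.arg(pool_model)
  k <- nrow(studies)
  if (k < 3) stop("need at least 3 studies")
  if (side == "auto") {
    b0 <- tryCatch(egger_test(studies)$statistic, error = function(e) 0)
    side <- if (b0 < 0) "right" else "left"
  }
  # orient so the excess side is positive (missing side negative)
  flip <- side == "right"
  y <- if (flip) -studies$effect else studies$effect
  se <- studies$se
  ord <- order(y)   # ascending; largest y are the excess extremes
  k0 <- 0L
  it <- 0L
  stabilized <- FALSE
  center <- NA_real_
  repeat {
    it <- it + 1L
    keep <- ord[seq_len(k - k0)]
    center <- if (length(keep) >= 2) {
      w <- 1 / se[keep]^2
      sum(w * y[keep]) / sum(w)
    } else y[keep]
    k0_new <- estimate_k0(y - center, estimator)
    k0_new <- min(k0_new, k - 2L)  # keep >=2 studies to center on
    if (k0_new == k0) { stabilized <- TRUE; break }
    k0 <- k0_new
    if (it >= maxit) break
  }
  if (!stabilized)
    warning("trim-and-fill iteration did not stabilize; returning last state")
  filled <- NULL
  if (k0 > 0) {
    trim_idx <- ord[(k - k0 + 1):k]
    f_eff <- 2 * center - y[trim_idx]
    if (flip) f_eff <- -f_eff
    filled <- effect_studies(paste0("fill_", seq_len(k0)),
                             f_eff, se[trim_idx])
  }
  pooled_original <- pool_effects(studies, model = pool_model)
  pooled_adjusted <- if (k0 > 0) {
    aug <- rbind(studies[, c("study_id", "effect", "se")],
                 filled[, c("study_id", "effect", "se")])
    pool_effects(aug, model = pool_model)
  } else pooled_original
  structure(
    list(k0 = k0, side = side, estimator = estimator,
         center = if (flip) -center else center,
         filled = filled,
         pooled_original = pooled_original,
         pooled_adjusted = pooled_adjusted,
         iterations = it, stabilized = stabilized),
    class = "trim_fill_result"
  )
}

#' @export
print.trim_fill_result <- function(x, ...) {
  cat(sprintf(
    "Trim-and-fill (%s, %s side): %d stud%s imputed in %d iteration%s\n",
    x$estimator, x$side, x$k0, if (x$k0 == 1) "y" else "ies",
    x$iterations, if (x$iterations == 1) "" else "s"))
  cat(sprintf("  Pooled (original): %.4f (SE %.4f)\n",
              x$pooled_original$est, x$pooled_original$se))
  cat(sprintf("  Pooled (adjusted): %.4f (SE %.4f)\n",
              x$pooled_adjusted$est, x$pooled_adjusted$se))
  invisible(x)
}
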