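# Effect-size handling and pooling: proportion transforms, inverse-
# variance fixed-effect and DerSimonian-Laird random-effects pooling,
# and the Q / I^2 / tau^2 heterogeneity summaries.

#' Assemble per-study effect data
#'
#' @param study_id Study identifiers (unique).
#' @param effect Effect estimates on the analysis scale.
#' @param se Standard errors, strictly positive.
#' @return A data frame of class `effect_studies`.
#' @export
effect_studies <- function(study_id, effect, se) {
  study_id <- as.character(study_id)
  if (anyDuplicated(study_id)) stop("duplicate study_id")
  if (any(!is.finite(effect)) || any(!is.finite(se)))
    stop("effect and se must be finite")
  if (any(se <= 0)) stop("se must be > 0")
  out <- data.frame(study_id = study_id, effect = effect, se = se,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_studies", "data.frame")
  out
}

#' Transform event counts to an effect estimate and standard error
#'
#' @param events,total Nonnegative integers, `events <= total`,
#'   `total > 0`.
#' @param scale `"raw"` (proportion with binomial SE), `"logit"`
#'   (log-odds, 0.5 added to both cells at the 0/total boundaries), or
#'   `"ft"` (Freeman-Tukey double-arcsine, variance `1/(4n+2)`).
#' @return `c(effect, se)`.
#' @details On the raw scale a boundary proportion (0 or `total` events)
#'   has zero estimated variance and is rejected: pooling weights would
#'   be infinite. Use `"logit"` or `"ft"`, which remain finite there.
#' @examples
#' transform_proportion(5, 10, "raw")    # 0.5, sqrt(0.025)
#' transform_proportion(0, 10, "logit")  # finite via continuity correction
#' @export
transform_proportion <- function(events, total, scale = c("raw", "logit", "ft")) {
  scale <- match.arg(scale)
  if (total <= 0) stop("total must be positive")
  if (events < 0 || events > total) stop("need 0 <= events <= total")
  if (scale == "raw") {
    p <- events / total
    if (events == 0 || events == total)
      stop("raw-scale se is zero at a boundary proportion; ",
           "use scale = \"logit\" or \"ft\"")
    return(c(effect = p, se = sqrt(p * (1 - p) / total)))
  }
  if (scale == "logit") {
    e <- events; n <- total
    if (e == 0 || e == n) { e <- e + 0.5; n <- n + 1 }
    return(c(effect = log(e / (n - e)), se = sqrt(1 / e + 1 / (n - e))))
  }
  # Freeman-Tukey double arcsine
  eff <- 0.5 * (asin(sqrt(events / (total + 1))) +
                  asin(sqrt((events + 1) / (total + 1))))
  c(effect = eff, se = sqrt(1 / (4 * total + 2)))
}

#' Pool study effects with heterogeneity summaries
#'
#' Inverse-variance fixed-effect pooling, Cochran's
#' `Q = sum w_i (theta_i - theta_F)^2`, the DerSimonian-Laird
#' moment estimator `tau^2 = max(0, (Q - df) / C)` with
#' `C = sum w - sum w^2 / sum w`, `I^2 = max(0, 100 (Q - df) / Q)`, and
#' random-effects pooling with weights `1 / (v_i + tau^2)`. The Q test
#' is flagged at the conventional 10% level for heterogeneity.
#'
#' @param studies An `effect_studies` data frame (or any data frame with
#'   `effect` and `se`), at least 2 rows.
#' @param model Which pooled estimate to surface as `$est` / `$se`:
#'   `"random"` (default) or `"fixed"`. Both are always computed.
#' @return A `meta_result`.
#' @examples
#' s <- effect_studies(c("s1", "s2"), c(0, 2), c(1, 1))
#' pool_effects(s)   # Q = 2, tau2 = 1
#' @export
pool_effects <- function(studies, model = c("random", "fixed")) {
  model <- match.arg(model)
  if (nrow(studies) < 2) stop("need at least 2 studies to pool")
  y <- studies$effect
  v <- studies$se^2
  w <- 1 / v
  est_f <- sum(w * y) / sum(w)
  se_f <- sqrt(1 / sum(w))
  k <- length(y)
  df <- k - 1
  q <- sum(w * (y - est_f)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / cc)
  i2 <- max(0, 100 * (q - df) / q)
  if (q == 0) i2 <- 0
  wr <- 1 / (v + tau2)
  est_r <- sum(wr * y) / sum(wr)
  se_r <- sqrt(1 / sum(wr))
  p_q <- pchisq(q, df, lower.tail = FALSE)
  structure(
    list(k = k, model = model,
         est = if (model == "random") est_r else est_f,
         se = if (model == "random") se_r else se_f,
         est_fixed = est_f, se_fixed = se_f,
         est_random = est_r, se_random = se_r,
         q = q, df = df, p_q = p_q,
         q_significant = p_q < 0.10,
         i2 = i2, tau2 = tau2),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Pooled effect (%s-effects): %.4f (SE %.4f), k = %d\n",
              x$model, x$est, x$se, x$k))
  cat(sprintf("Heterogeneity: Q = %.2f on %d df (p = %.4f%s), I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$df, x$p_q,
              if (x$q_significant) ", significant at 10%" else "",
              x$i2, x$tau2))
  invisible(x)
}

#' Forest-plot-ready study rows
#'
#' @param studies An `effect_studies` data frame.
#' @param pooled Optional `meta_result` supplying weights; defaults to
#'   pooling `studies`.
#' @param level Confidence level for per-study intervals.
#' @return A data frame with per-study estimate, CI and percent weight
#'   (random-effects weights).
#' @export
forest_rows <- function(studies, pooled = NULL, level = 0.95) {
  if (is.null(pooled)) pooled <- pool_effects(studies)
  z <- qnorm(1 - (1 - level) / 2)
  w <- 1 / (studies$se^2 + pooled$tau2)
  data.frame(
    study_id = studies$study_id,
    effect = studies$effect,
    ci_lower = studies$effect - z * studies$se,
    ci_upper = studies$effect + z * studies$se,
    weight_pct = 100 * w / sum(w)
  )
}
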