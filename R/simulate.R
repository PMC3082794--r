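# Synthetic-data generators: multi-source capture processes with
# controllable pairwise source dependence, and meta-analyses with
# selective-publication suppression.

# Probabilities of the 8 capture patterns under a log-linear model with
# main effects on the logit of each marginal capture probability and
# pairwise log odds-ratio dependence terms.
capture_pattern_probs <- function(p, dependence = c(AB = 0, AC = 0, BC = 0)) {
  stopifnot(length(p) == 3, all(p > 0), all(p < 1))
  dep <- c(AB = 0, AC = 0, BC = 0)
  dep[names(dependence)] <- dependence
  g <- expand.grid(A = 0:1, B = 0:1, C = 0:1)
  eta <- g$A * qlogis(p[1]) + g$B * qlogis(p[2]) + g$C * qlogis(p[3]) +
    g$A * g$B * dep["AB"] + g$A * g$C * dep["AC"] + g$B * g$C * dep["BC"]
  w <- exp(eta)
  data.frame(g, prob = w / sum(w))
}

#' Simulate a three-source capture process
#'
#' Each of `n_true` studies draws a capture pattern from the log-linear
#' probability model with per-source (marginal, at independence) capture
#' probabilities `p` and pairwise log odds-ratio `dependence` terms.
#' Studies drawing the all-absent pattern are unobserved: they are
#' counted but excluded from the returned table. At
#' `dependence = 0` the three sources capture independently.
#'
#' @param n_true True number of studies, `>= 1`.
#' @param p Length-3 vector of capture probabilities in (0, 1).
#' @param dependence Named numeric with any of `AB`, `AC`, `BC`
#'   (log odds ratios; default all 0).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `capture_table` with attributes `n_missed` (studies drawn
#'   into the unobserved cell), `n_true`, and `pattern_probs`.
#' @examples
#' tab <- simulate_capture(5000, c(0.4, 0.5, 0.2), seed = 1)
#' attr(tab, "n_missed")
#' @export
simulate_capture <- function(n_true, p = c(0.5, 0.5, 0.5),
                             dependence = c(AB = 0, AC = 0, BC = 0),
                             seed = NULL) {
  stopifnot(n_true >= 1)
  pp <- capture_pattern_probs(p, dependence)
  obs_mass <- sum(pp$prob[pp$A + pp$B + pp$C > 0])
  if (obs_mass <= 0) stop("no probability mass on observable patterns")
  draws <- with_seed(seed, as.vector(rmultinom(1, n_true, pp$prob)))
  pat <- paste0(pp$A, pp$B, pp$C)
  cnt <- setNames(draws, pat)
  tab <- capture_table(cnt["100"], cnt["010"], cnt["001"], cnt["110"],
                       cnt["101"], cnt["011"], cnt["111"])
  attr(tab, "n_missed") <- unname(cnt["000"])
  attr(tab, "n_true") <- n_true
  attr(tab, "pattern_probs") <- pp
  tab
}

#' Simulate a meta-analysis with selective publication
#'
#' Generates `k` studies with effects
#' `theta_i = effect + b_i + e_i`, where `b_i ~ N(0, tau2)` is the
#' between-study deviation and `e_i ~ N(0, se_i^2)` the within-study
#' error; standard errors are drawn uniformly on `se_range`. A selection
#' function mapping `(effect, se)` to a publication probability is then
#' applied; both the published and the suppressed studies are returned
#' so simulation oracles can see the truth.
#'
#' @param k Number of studies before selection, `>= 2`.
#' @param effect True common effect.
#' @param tau2 Between-study variance, `>= 0`.
#' @param se_range Range of the uniform standard-error distribution.
#' @param selection `NULL` (publish everything) or
#'   `function(effect, se)` returning publication probabilities.
#' @param seed Optional integer seed.
#' @return A list with `published` and `suppressed` `effect_studies`.
#' @examples
#' sim <- simulate_meta(20, effect = 0.3, seed = 1)
#' nrow(sim$published)  # 20: no selection
#' @export
simulate_meta <- function(k, effect = 0, tau2 = 0, se_range = c(0.05, 0.5),
                          selection = NULL, seed = NULL) {
  stopifnot(k >= 2, tau2 >= 0, length(se_range) == 2, all(se_range > 0))
  with_seed(seed, {
    se <- runif(k, se_range[1], se_range[2])
    y <- effect + rnorm(k, 0, sqrt(tau2)) + rnorm(k, 0, se)
    keep <- if (is.null(selection)) rep(TRUE, k) else {
      pr <- pmin(1, pmax(0, selection(y, se)))
      as.logical(rbinom(k, 1, pr))
    }
    if (sum(keep) < 2)
      stop("fewer than 2 published studies; increase k or relax selection")
    ids <- sprintf("study_%03d", seq_len(k))
    list(published = effect_studies(ids[keep], y[keep], se[keep]),
         suppressed = if (any(!keep))
           effect_studies(ids[!keep], y[!keep], se[!keep])
         else effect_studies(character(0), numeric(0), numeric(0)))
  })
}
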