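# Independent oracles and small generators shared across tests.

# Iterative proportional fitting for the independence (main-effects)
# log-linear model on the 7 observed cells: cyclically rescale the
# fitted cells so each source's captured/not-captured split matches the
# data. Deliberately independent of the glm-based fitting path.
ipf_independence <- function(cells, tol = 1e-12, maxit = 5000) {
  d <- data.frame(
    A = c(1, 0, 0, 1, 1, 0, 1),
    B = c(0, 1, 0, 1, 0, 1, 1),
    C = c(0, 0, 1, 0, 1, 1, 1)
  )
  mu <- rep(sum(cells) / 7, 7)
  for (it in seq_len(maxit)) {
    old <- mu
    for (f in c("A", "B", "C")) {
      idx <- d[[f]] == 1
      mu[idx] <- mu[idx] * sum(cells[idx]) / sum(mu[idx])
      mu[!idx] <- mu[!idx] * sum(cells[!idx]) / sum(mu[!idx])
    }
    if (max(abs(mu - old)) < tol) break
  }
  mu
}

# Random strictly-positive capture table.
random_capture_table <- function() {
  n <- sample(1:30, 7, replace = TRUE)
  capture_table(n[1], n[2], n[3], n[4], n[5], n[6], n[7])
}

# Random per-study records with at least one source flag set.
random_records <- function(n) {
  repeat {
    flags <- matrix(runif(3 * n) < 0.5, n, 3)
    none <- !rowSums(flags)
    flags[none, sample(3, sum(none), replace = TRUE)] <- TRUE
    # fix rows individually (matrix indexing above sets columns bluntly)
    for (i in which(!apply(flags, 1, any)))
      flags[i, sample(3, 1)] <- TRUE
    if (all(apply(flags, 1, any))) break
  }
  data.frame(study_id = sprintf("s%03d", seq_len(n)),
             source_a = flags[, 1], source_b = flags[, 2],
             source_c = flags[, 3])
}

# All permutations of 1..n, written independently of the package's
# internal generator (simple insertion recursion).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- perms_oracle(n - 1)
  out <- list()
  for (p in smaller) for (pos in 0:(n - 1)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# Kendall S by explicit double loop (oracle form).
kendall_s_oracle <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  s
}
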