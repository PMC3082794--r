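# Multi-source retrieval data: the 7-cell capture structure of a
# three-source search (A = electronic databases, B = reference lists,
# C = gray literature / personal contact).

CELL_PATTERNS <- c("100", "010", "001", "110", "101", "011", "111")
CELL_NAMES <- c("a", "b", "c", "ab", "ac", "bc", "abc")

#' Construct a three-source capture table from its seven cells
#'
#' The seven cells partition the studies retrieved by at least one of three
#' search sources: `n_a`, `n_b`, `n_c` found by exactly one source,
#' `n_ab`, `n_ac`, `n_bc` by exactly two, and `n_abc` by all three. The
#' eighth cell of the underlying 2x2x2 table — studies captured by no
#' source — is unobservable and is what the log-linear machinery in
#' [crc_fit()] estimates.
#'
#' @param n_a,n_b,n_c Counts of studies found by exactly one source.
#' @param n_ab,n_ac,n_bc Counts found by exactly two sources.
#' @param n_abc Count found by all three sources.
#' @param sources Character vector of length 3 naming the sources.
#' @return A `capture_table`: cells, total observed `n_obs`, and per-source
#'   margins `m_a`, `m_b`, `m_c`.
#' @examples
#' capture_table(7, 9, 1, 12, 0, 3, 2)
#' @seealso [build_capture_table()], [overlap_summary()], [crc_fit_all()]
#' @export
capture_table <- function(n_a, n_b, n_c, n_ab, n_ac, n_bc, n_abc,
                          sources = c("A", "B", "C")) {
  cells <- c(a = n_a, b = n_b, c = n_c, ab = n_ab, ac = n_ac, bc = n_bc,
             abc = n_abc)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be nonnegative integers")
  if (length(sources) != 3L)
    stop("exactly three source labels required")
  cells <- as.integer(cells)
  names(cells) <- CELL_NAMES
  margins <- c(
    a = cells["a"] + cells["ab"] + cells["ac"] + cells["abc"],
    b = cells["b"] + cells["ab"] + cells["bc"] + cells["abc"],
    c = cells["c"] + cells["ac"] + cells["bc"] + cells["abc"]
  )
  names(margins) <- c("a", "b", "c")
  structure(
    list(cells = cells, n_obs = sum(cells), margins = margins,
         sources = sources),
    class = "capture_table"
  )
}

#' @export
print.capture_table <- function(x, ...) {
  cat("Three-source capture table (", x$n_obs, " studies observed)\n", sep = "")
  df <- data.frame(pattern = CELL_PATTERNS, cell = toupper(CELL_NAMES),
                   count = unname(x$cells))
  print(df, row.names = FALSE)
  cat("Margins: ", paste(sprintf("%s=%d", x$sources, x$margins),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build a capture table from per-study source indicators
#'
#' @param records A data frame with columns `study_id`, `source_a`,
#'   `source_b`, `source_c`; the source columns logical (or 0/1).
#' @param sources Source labels passed to [capture_table()].
#' @return A `capture_table`.
#' @details Every study must have been retrieved by at least one source
#'   (a study captured by no source cannot appear in the data), and
#'   `study_id` must be unique.
#' @examples
#' recs <- data.frame(study_id = c("s1", "s2", "s3"),
#'                    source_a = c(TRUE, TRUE, FALSE),
#'                    source_b = c(FALSE, TRUE, TRUE),
#'                    source_c = c(FALSE, FALSE, FALSE))
#' build_capture_table(recs)
#' @export
build_capture_table <- function(records, sources = c("A", "B", "C")) {
  if (is.null(records) || nrow(records) == 0L)
    stop("no records")
  need <- c("study_id", "source_a", "source_b", "source_c")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  id <- as.character(records$study_id)
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate study_id: ", paste(unique(dup), collapse = ", "))
  a <- as.logical(records$source_a)
  b <- as.logical(records$source_b)
  c_ <- as.logical(records$source_c)
  if (anyNA(a) || anyNA(b) || anyNA(c_))
    stop("source indicators must be logical or 0/1")
  none <- !(a | b | c_)
  if (any(none))
    stop("record(s) captured by no source: ",
         paste(id[none], collapse = ", "))
  pat <- paste0(as.integer(a), as.integer(b), as.integer(c_))
  counts <- vapply(CELL_PATTERNS, function(p) sum(pat == p), integer(1))
  capture_table(counts[1], counts[2], counts[3], counts[4], counts[5],
                counts[6], counts[7], sources = sources)
}

#' Summarize source overlap
#'
#' Counts and integer percents of studies retrieved by at least two
#' sources and by all three.
#'
#' @param table A `capture_table`.
#' @return A list with `count_ge2`, `pct_ge2`, `count_all3`, `pct_all3`
#'   (percents rounded half away from zero to the nearest integer).
#' @examples
#' overlap_summary(hbv_review_table())  # 17 of 34 (50%), 2 of 34 (6%)
#' @export
overlap_summary <- function(table) {
  stopifnot(inherits(table, "capture_table"))
  ge2 <- sum(table$cells[c("ab", "ac", "bc", "abc")])
  all3 <- unname(table$cells["abc"])
  structure(
    list(count_ge2 = ge2,
         pct_ge2 = round_half_up(100 * ge2 / table$n_obs),
         count_all3 = all3,
         pct_all3 = round_half_up(100 * all3 / table$n_obs),
         n_obs = table$n_obs),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(
    "%d of %d studies (%d%%) found by >=2 sources; %d (%d%%) by all three\n",
    x$count_ge2, x$n_obs, x$pct_ge2, x$count_all3, x$pct_all3))
  invisible(x)
}

#' Two-sample (Petersen) capture-recapture estimate
#'
#' The classical two-list estimator of an unknown population size:
#' `N = n1 * n2 / m`, where `m` studies appear on both lists. The Chapman
#' variant `(n1+1)(n2+1)/(m+1) - 1` is nearly unbiased and remains defined
#' when the lists do not overlap.
#'
#' @param n1,n2 List sizes (>= 1).
#' @param m Overlap, `0 <= m <= min(n1, n2)`.
#' @param chapman Use the Chapman small-sample variant.
#' @param level Confidence level for the normal-approximation interval.
#' @return A list with `n_hat`, `se`, `ci` (lower/upper, floored at the
#'   number of distinct studies observed), and `method`.
#' @examples
#' petersen_estimate(10, 12, 4)            # 30
#' petersen_estimate(10, 12, 4, chapman = TRUE)  # 29.6
#' @export
petersen_estimate <- function(n1, n2, m, chapman = FALSE, level = 0.95) {
  stopifnot(n1 >= 1, n2 >= 1, m >= 0, m <= min(n1, n2))
  if (m == 0 && !chapman)
    stop("estimate undefined (no overlap); consider chapman = TRUE")
  if (chapman) {
    n_hat <- (n1 + 1) * (n2 + 1) / (m + 1) - 1
    v <- (n1 + 1) * (n2 + 1) * (n1 - m) * (n2 - m) / ((m + 1)^2 * (m + 2))
  } else {
    n_hat <- n1 * n2 / m
    v <- n1 * n2 * (n1 - m) * (n2 - m) / m^3
  }
  z <- qnorm(1 - (1 - level) / 2)
  obs <- n1 + n2 - m
  ci <- c(max(obs, n_hat - z * sqrt(v)), n_hat + z * sqrt(v))
  names(ci) <- c("lower", "upper")
  list(n_hat = n_hat, se = sqrt(v), ci = ci,
       method = if (chapman) "chapman" else "petersen")
}
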