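#' Per-participant sleep-quartile means of PEDB
#'
#' Partitions a participant's temporally ordered events into four
#' contiguous blocks ([quartile_indices()] rule) and averages the PEDB
#' values within each block.
#'
#' @param series A [pedb_series()] (N >= 4 events) or numeric vector.
#' @return Object of class `quartile_summary`: a one-row data frame with
#'   columns `participant_id`, `q1`-`q4`, `n_events`.
#' @examples
#' quartile_means(1:8)[, c("q1", "q2", "q3", "q4")]
#' @export
quartile_means <- function(series) {
  values <- if (inherits(series, "pedb_series")) series$pedb else series
  pid <- if (inherits(series, "pedb_series")) {
    attr(series, "participant_id")
  } else {
    "unknown"
  }
  n <- length(values)
  if (n < 4) {
    stop("participant has fewer than 4 retained events; excluded from ",
         "quartile analyses", call. = FALSE)
  }
  qb <- quartile_bounds(n)
  qm <- vapply(1:4, function(q) mean(values[qb$start[q]:qb$end[q]]),
               numeric(1))
  out <- data.frame(participant_id = pid, q1 = qm[1], q2 = qm[2],
                    q3 = qm[3], q4 = qm[4], n_events = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("quartile_summary", "data.frame")
  out
}

test_result <- function(test_name, statistic, p_value, n, comparison,
                        degenerate = FALSE) {
  data.frame(test = test_name, comparison = comparison,
             statistic = statistic, p_value = p_value, n = n,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Within-group quartile comparison (Wilcoxon signed-rank)
#'
#' Paired two-sided Wilcoxon signed-rank test of per-participant quartile
#' means between two sleep quartiles — the within-group check for an
#' overnight change in post-event deep breathing.  The exact distribution
#' is used for n <= 25 pairs (no ties/zeros), the normal approximation with
#' continuity correction otherwise.
#'
#' @param summaries Data frame of stacked [quartile_means()] rows (>= 5
#'   participants).
#' @param qa,qb Quartile indices 1-4 to compare (default 1 vs 4, the
#'   headline start-vs-end-of-night comparison).
#' @return A one-row test-result data frame (`test`, `comparison`,
#'   `statistic`, `p_value`, `n`, `degenerate`).
#' @export
within_group_quartile_test <- function(summaries, qa = 1, qb = 4) {
  stopifnot(all(c(paste0("q", qa), paste0("q", qb)) %in% names(summaries)))
  a <- summaries[[paste0("q", qa)]]
  b <- summaries[[paste0("q", qb)]]
  n <- length(a)
  if (n < 5) {
    stop("need at least 5 participants with both quartiles defined",
         call. = FALSE)
  }
  lab <- sprintf("Q%d-vs-Q%d", qa, qb)
  d <- b - a
  if (all(d == 0)) {
    return(test_result("wilcoxon_signed_rank", NA_real_, 1, n, lab,
                       degenerate = TRUE))
  }
  use_exact <- n <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(b, a, paired = TRUE, exact = use_exact,
                       correct = TRUE))
  test_result("wilcoxon_signed_rank", unname(wt$statistic), wt$p.value, n,
              lab)
}

#' Between-group comparison (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U (rank-sum) test between two groups'
#' per-participant summaries of one quartile.
#'
#' @param group_a,group_b Numeric vectors of per-participant quartile means
#'   (>= 5 each).
#' @param comparison Label stored on the result.
#' @return A one-row test-result data frame.
#' @export
between_group_test <- function(group_a, group_b,
                               comparison = "groupA-vs-groupB") {
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 5 || nb < 5) {
    stop("need at least 5 participants per group", call. = FALSE)
  }
  if (length(unique(c(group_a, group_b))) == 1L) {
    return(test_result("mann_whitney_u", NA_real_, 1, na + nb, comparison,
                       degenerate = TRUE))
  }
  no_ties <- !any(duplicated(c(group_a, group_b)))
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = no_ties && na + nb <= 50))
  test_result("mann_whitney_u", unname(wt$statistic), wt$p.value, na + nb,
              comparison)
}

#' Per-subject Spearman correlation of event duration and PEDB
#'
#' For each participant, the Spearman rank correlation between respiratory
#' event durations and the corresponding PEDB values; summarized per group
#' as the median and interquartile range of the per-subject coefficients.
#' Subjects with constant durations or constant PEDB (undefined ranks) are
#' flagged and excluded from the summary.
#'
#' @param series_list List of [pedb_series()] (each with >= 3 events).
#' @param group_label Label stored on the summary.
#' @return Object of class `correlation_summary`: list with `rho`
#'   (named per-subject coefficients, NA when undefined), `median_rho`,
#'   `iqr` (`c(lo, hi)`), `n_flagged`, `group_label`.
#' @export
event_duration_correlation <- function(series_list, group_label = "group") {
  rho <- vapply(series_list, function(s) {
    stopifnot(inherits(s, "pedb_series"))
    if (nrow(s) < 3) return(NA_real_)
    if (stats::sd(s$duration_s) == 0 || stats::sd(s$pedb) == 0) {
      return(NA_real_)
    }
    stats::cor(s$duration_s, s$pedb, method = "spearman")
  }, numeric(1))
  names(rho) <- vapply(series_list, attr, character(1), "participant_id")
  ok <- rho[!is.na(rho)]
  structure(list(rho = rho,
                 median_rho = if (length(ok)) stats::median(ok) else NA_real_,
                 iqr = if (length(ok)) {
                   stats::quantile(ok, c(0.25, 0.75), names = FALSE)
                 } else {
                   c(NA_real_, NA_real_)
                 },
                 n_flagged = sum(is.na(rho)), group_label = group_label),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    "<correlation_summary> %s: median rho %.4g (IQR %.4g to %.4g), %d subjects (%d flagged)\n",
    x$group_label, x$median_rho, x$iqr[1], x$iqr[2], length(x$rho),
    x$n_flagged))
  invisible(x)
}
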