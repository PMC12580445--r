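#' Least-squares polynomial regression on a curve
#'
#' Fits a polynomial of the given degree in the normalized position
#' variable by ordinary least squares and evaluates it on the full grid.
#' Used to smooth group characteristic curves and to compare candidate
#' degrees.
#'
#' @param grid Numeric positions (typically in `[0, 1]`).
#' @param values Curve values at `grid`.
#' @param degree Polynomial degree 1-3; needs more points than `degree`.
#' @return Object of class `polynomial_fit`: list with `degree`,
#'   `coefficients` (ascending powers), `fitted_values` on `grid`,
#'   `rmse_train` and an `rmse_test` slot filled by
#'   [select_polynomial_degree()].
#' @examples
#' x <- normalized_positions(11)
#' fit <- fit_polynomial_regression(x, 2 * x^2 - x + 0.5, degree = 2)
#' round(fit$coefficients, 10)
#' @export
fit_polynomial_regression <- function(grid, values, degree) {
  stopifnot(length(grid) == length(values))
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3", call. = FALSE)
  if (length(grid) <= degree) {
    stop("underdetermined fit: need more than `degree` points", call. = FALSE)
  }
  fit <- stats::lm(values ~ stats::poly(grid, degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  structure(list(degree = degree, coefficients = coefs,
                 fitted_values = unname(stats::fitted(fit)),
                 rmse_train = rmse(values, stats::fitted(fit)),
                 rmse_test = NA_real_),
            class = "polynomial_fit")
}

eval_polynomial <- function(coefficients, x) {
  drop(outer(x, seq_along(coefficients) - 1, `^`) %*% coefficients)
}

#' Root mean square error
#'
#' `sqrt(mean((fitted - true)^2))` over equal-length vectors.
#'
#' @param true_values,fitted_values Numeric vectors of equal length >= 1.
#' @return Single nonnegative number in the units of the inputs.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(true_values, fitted_values) {
  if (length(true_values) != length(fitted_values) ||
      length(true_values) < 1) {
    stop("inputs must be equal-length vectors of length >= 1", call. = FALSE)
  }
  sqrt(mean((fitted_values - true_values)^2))
}

#' Split curve points into train and test sets
#'
#' Random 80/20 (by default) holdout over the curve's points.  The two
#' endpoints are always kept in the training set so that test-set
#' prediction never requires polynomial extrapolation beyond the observed
#' grid.
#'
#' @param grid,values The curve (>= 5 points).
#' @param test_fraction Fraction of points held out (default 0.2).
#' @param seed RNG seed; the split is deterministic for a fixed seed.
#' @return List with data frames `train` and `test` (columns `grid`,
#'   `values`) and the integer `test_idx`.
#' @export
split_train_test <- function(grid, values, test_fraction = 0.2, seed = NULL) {
  n <- length(grid)
  stopifnot(length(values) == n)
  if (n < 5) stop("need at least 5 points to hold out a test set", call. = FALSE)
  stopifnot(test_fraction > 0, test_fraction < 1)
  n_test <- max(1L, round(test_fraction * n))
  interior <- 2:(n - 1)
  if (n_test > length(interior)) {
    stop("test_fraction too large: endpoints must stay in the training set",
         call. = FALSE)
  }
  test_idx <- with_seed(seed, sort(sample(interior, n_test)))
  list(train = data.frame(grid = grid[-test_idx], values = values[-test_idx]),
       test = data.frame(grid = grid[test_idx], values = values[test_idx]),
       test_idx = test_idx)
}

#' Select the polynomial regression degree by held-out RMSE
#'
#' Fits each candidate degree on the training portion of the curve and
#' evaluates RMSE on the held-out points.  The degree with the smallest
#' test RMSE wins; ties (within `1e-12`) go to the lower degree, encoding
#' a preference for smoother fits.  Optionally averages test RMSE over
#' repeated random splits for stability.
#'
#' @param grid,values The curve to model (typically a group characteristic
#'   curve).
#' @param degrees Candidate degrees (subset of 1:3, default all).
#' @param test_fraction Held-out fraction per split (default 0.2).
#' @param seed RNG seed for the split(s).
#' @param n_repeats Number of random splits (default 1, matching a single
#'   holdout; larger values report mean test RMSE across splits).
#' @return Object of class `model_selection`: list with `table` (data
#'   frame `degree`, `rmse_train`, `rmse_test`), `selected_degree`,
#'   `fits` (per-degree `polynomial_fit`s refit on all points), and
#'   `rationale`.
#' @export
select_polynomial_degree <- function(grid, values, degrees = 1:3,
                                     test_fraction = 0.2, seed = NULL,
                                     n_repeats = 1) {
  stopifnot(all(degrees %in% 1:3), length(degrees) >= 1, n_repeats >= 1)
  degrees <- sort(unique(degrees))
  if (length(grid) <= max(degrees) + 1) {
    stop("not enough points for the largest candidate degree", call. = FALSE)
  }
  seeds <- if (n_repeats == 1) list(seed) else
    as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n_repeats)))
  tr_mat <- matrix(NA_real_, n_repeats, length(degrees))
  te_mat <- matrix(NA_real_, n_repeats, length(degrees))
  for (r in seq_len(n_repeats)) {
    sp <- split_train_test(grid, values, test_fraction, seed = seeds[[r]])
    for (d in seq_along(degrees)) {
      fit <- fit_polynomial_regression(sp$train$grid, sp$train$values,
                                       degrees[d])
      tr_mat[r, d] <- fit$rmse_train
      te_mat[r, d] <- rmse(sp$test$values,
                           eval_polynomial(fit$coefficients, sp$test$grid))
    }
  }
  tab <- data.frame(degree = degrees,
                    rmse_train = colMeans(tr_mat),
                    rmse_test = colMeans(te_mat))
  best <- min(tab$rmse_test)
  selected <- min(tab$degree[tab$rmse_test <= best + 1e-12])
  fits <- lapply(degrees, function(d) {
    f <- fit_polynomial_regression(grid, values, d)
    f$rmse_test <- tab$rmse_test[tab$degree == d]
    f
  })
  names(fits) <- paste0("degree_", degrees)
  structure(list(table = tab, selected_degree = selected, fits = fits,
                 rationale = sprintf(
                   "degree %d has the minimum held-out RMSE (%.4g); ties go to the lower degree for smoothness",
                   selected, best)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection>\n")
  print(x$table, row.names = FALSE)
  cat("selected degree:", x$selected_degree, "\n")
  invisible(x)
}
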