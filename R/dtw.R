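#' Dynamic time warping distance between two sequences
#'
#' Computes the accumulated-cost matrix of the classic DTW recursion
#' `D(i, j) = cost(x_i, y_j) + min(D(i-1, j), D(i, j-1), D(i-1, j-1))`
#' with `D(1, 1) = cost(x_1, y_1)` and first row/column accumulating along
#' their only predecessor.  The distance is `D(L, R)`: the minimum total
#' cost over monotone alignment paths that connect the first and last
#' indices of both sequences.  No warping window and no path-length
#' normalization are applied.
#'
#' @param x,y Numeric sequences of lengths L, R >= 1 (lengths may differ).
#' @param local_cost `"absolute"` (default, `|x_i - y_j|`) or `"squared"`
#'   (`(x_i - y_j)^2`).
#' @return Object of class `dtw_result`: list with `cost_matrix` (L x R
#'   accumulated costs), `distance`, `L`, `R`, `local_cost`.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 3))$distance  # 1
#' @export
dtw_distance <- function(x, y, local_cost = c("absolute", "squared")) {
  local_cost <- match.arg(local_cost)
  if (length(x) < 1 || length(y) < 1) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  stopifnot(is.numeric(x), is.numeric(y))
  L <- length(x)
  R <- length(y)
  cost <- abs(outer(x, y, `-`))
  if (local_cost == "squared") cost <- cost^2
  D <- matrix(0, L, R)
  D[, 1] <- cumsum(cost[, 1])
  D[1, ] <- cumsum(cost[1, ])
  if (L > 1 && R > 1) {
    for (i in 2:L) {
      for (j in 2:R) {
        D[i, j] <- cost[i, j] + min(D[i - 1L, j], D[i, j - 1L],
                                    D[i - 1L, j - 1L])
      }
    }
  }
  structure(list(cost_matrix = D, distance = D[L, R], L = L, R = R,
                 local_cost = local_cost),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> %d x %d, %s local cost: distance %.6g\n",
              x$L, x$R, x$local_cost, x$distance))
  invisible(x)
}

#' Per-quartile DTW distances between two curves
#'
#' Splits each curve into four contiguous index blocks (near-equal sizes,
#' remainders to the later quartiles; the same rule as
#' [quartile_indices()]) and computes the DTW distance between
#' corresponding quartile segments.  Lengths of the two curves may differ.
#'
#' @param curve_a,curve_b `characteristic_curve`s, `standardized_curve`s
#'   or numeric vectors with at least 4 points each.
#' @param local_cost Passed to [dtw_distance()].
#' @return Data frame with columns `quartile` (1-4) and `distance`.
#' @export
quartile_dtw <- function(curve_a, curve_b,
                         local_cost = c("absolute", "squared")) {
  local_cost <- match.arg(local_cost)
  a <- curve_values(curve_a)
  b <- curve_values(curve_b)
  if (length(a) < 4 || length(b) < 4) {
    stop("curves must have at least 4 points to be split into quartiles",
         call. = FALSE)
  }
  qa <- quartile_bounds(length(a))
  qb <- quartile_bounds(length(b))
  dist <- vapply(1:4, function(q) {
    dtw_distance(a[qa$start[q]:qa$end[q]], b[qb$start[q]:qb$end[q]],
                 local_cost = local_cost)$distance
  }, numeric(1))
  data.frame(quartile = 1:4, distance = dist)
}

# Accept the containers the pipeline produces as well as raw numerics.
curve_values <- function(x) {
  if (inherits(x, "characteristic_curve")) return(x$mean_values)
  if (inherits(x, "standardized_curve")) return(x$values)
  if (inherits(x, "pedb_series")) return(x$pedb)
  stopifnot(is.numeric(x))
  x
}
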