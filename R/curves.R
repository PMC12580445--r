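#' Normalized event positions
#'
#' Maps event indices `1..N` onto the unit interval: `x_i = (i - 1) /
#' (N - 1)`, so the first and last respiratory events of every participant
#' land on 0 and 1 and series of different lengths become comparable.
#'
#' @param n Number of events (>= 2; a one-event series cannot be rescaled).
#' @return Numeric vector of `n` equally spaced positions in `[0, 1]`.
#' @examples
#' normalized_positions(5)
#' @export
normalized_positions <- function(n) {
  stop_if_not_scalar_number(n, "n")
  if (n < 2) {
    stop("need at least 2 events to define normalized positions", call. = FALSE)
  }
  (seq_len(n) - 1) / (n - 1)
}

# C1 quadratic spline through (x, y), initial slope from the parabola
# through the first three points.  With that start the recursion
# z[i+1] = 2*secant[i] - z[i] reproduces any globally quadratic series
# exactly, and the spline interpolates every knot by construction.
quad_spline_eval <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  sl <- diff(y) / h
  z <- numeric(n)
  z[1] <- if (n == 2) sl[1] else sl[1] - h[1] * (sl[2] - sl[1]) / (h[1] + h[2])
  for (i in seq_len(n - 1)) z[i + 1] <- 2 * sl[i] - z[i]
  j <- findInterval(xout, x, rightmost.closed = TRUE)
  j[j < 1L] <- 1L
  j[j > n - 1L] <- n - 1L
  d <- xout - x[j]
  y[j] + z[j] * d + (z[j + 1] - z[j]) / (2 * h[j]) * d^2
}

#' Standardize a PEDB series to a common length by exact interpolation
#'
#' Fits a piecewise-polynomial interpolant `P(x)` through the series on its
#' normalized positions — linear for `degree = 1`, a C1 quadratic spline
#' for `degree = 2` — and evaluates it at `M` uniformly spaced points in
#' `[0, 1]`.  The interpolant reproduces the original values exactly at the
#' original positions, so standardization never distorts observed data;
#' only lengths change.  Downsampling (`M < N`) is refused because it would
#' break that exactness.
#'
#' @param series A [pedb_series()] (N >= 2 events) or a numeric vector of
#'   PEDB values.
#' @param m Target common length `M >= N` (typically the maximum event
#'   count in the participant's group, see [group_max_length()]).
#' @param degree Interpolation degree, 1 (default; most stable) or 2.
#' @return Object of class `standardized_curve`: list with `participant_id`,
#'   `grid` (the M normalized positions), `values`, `source_n`,
#'   `interp_degree`.
#' @examples
#' interpolate_series(c(1, 3), m = 3)$values  # 1 2 3
#' @export
interpolate_series <- function(series, m, degree = 1) {
  values <- if (inherits(series, "pedb_series")) series$pedb else series
  pid <- if (inherits(series, "pedb_series")) {
    attr(series, "participant_id")
  } else {
    "unknown"
  }
  n <- length(values)
  if (n < 2) {
    stop("series must contain at least 2 events to be standardized",
         call. = FALSE)
  }
  if (!degree %in% c(1, 2)) {
    stop("interpolation degree must be 1 or 2", call. = FALSE)
  }
  stop_if_not_scalar_number(m, "m")
  if (m < n) {
    stop("M must be >= N: downsampling would violate interpolation ",
         "exactness", call. = FALSE)
  }
  x <- normalized_positions(n)
  xout <- normalized_positions(m)
  vals <- if (degree == 1) {
    stats::approx(x, values, xout = xout)$y
  } else {
    quad_spline_eval(x, values, xout)
  }
  structure(list(participant_id = pid, grid = xout, values = vals,
                 source_n = n, interp_degree = degree),
            class = "standardized_curve")
}

#' Common standardization length of a group
#'
#' The common grid length for a group is the maximum retained-event count
#' over its members, so no participant's series is ever downsampled.
#'
#' @param series_list List of [pedb_series()] (or numeric vectors).
#' @return Integer `M`.
#' @export
group_max_length <- function(series_list) {
  lens <- vapply(series_list, function(s) {
    if (inherits(s, "pedb_series")) nrow(s) else length(s)
  }, integer(1))
  max(lens)
}

#' Group characteristic PEDB curve (pointwise mean)
#'
#' The characteristic curve of a group is the pointwise arithmetic mean of
#' its members' standardized curves, all sharing the same grid.
#'
#' @param curves List of `standardized_curve`s with identical grids.
#' @param group_label Label stored on the result.
#' @return Object of class `characteristic_curve`: list with `grid`,
#'   `mean_values`, `ci_low`, `ci_high` (NA until a bootstrap band is
#'   added), `k` (group size), `m` (grid length), `group_label`.
#' @seealso [bootstrap_confidence_band()]
#' @export
group_characteristic_curve <- function(curves, group_label = "group") {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "standardized_curve")))
  m <- length(curves[[1]]$grid)
  if (!all(vapply(curves, function(cv) length(cv$grid) == m, logical(1)))) {
    stop("all curves must share the same grid length M", call. = FALSE)
  }
  vals <- do.call(rbind, lapply(curves, `[[`, "values"))
  structure(list(grid = curves[[1]]$grid, mean_values = colMeans(vals),
                 ci_low = rep(NA_real_, m), ci_high = rep(NA_real_, m),
                 k = length(curves), m = m, group_label = group_label),
            class = "characteristic_curve")
}

#' @export
print.characteristic_curve <- function(x, ...) {
  cat(sprintf("<characteristic_curve> %s: K = %d participants, M = %d points\n",
              x$group_label, x$k, x$m))
  cat(sprintf("  mean PEDB %.3g-%.3g%s\n", min(x$mean_values),
              max(x$mean_values),
              if (all(is.na(x$ci_low))) " (no confidence band)" else
                sprintf(", band level %s", attr(x, "level"))))
  invisible(x)
}

#' Bootstrap confidence band for a group characteristic curve
#'
#' Resamples participants (whole standardized curves, the natural block
#' unit given within-participant dependence) with replacement `n_boot`
#' times, computes each replicate's mean curve, and takes pointwise
#' percentile intervals at the requested level.  The band is clipped to
#' contain the observed mean curve, so `ci_low <= mean <= ci_high` holds
#' pointwise by construction.
#'
#' @param curves List of `standardized_curve`s on a common grid (K >= 1;
#'   K = 1 yields a zero-width band with a warning).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Band level in (0, 1) (default 0.95).
#' @param seed RNG seed for the resampling (deterministic when fixed).
#' @param group_label Label stored on the result.
#' @return A `characteristic_curve` with `ci_low`/`ci_high` filled in and
#'   the level stored as an attribute.
#' @export
bootstrap_confidence_band <- function(curves, n_boot = 1000, level = 0.95,
                                      seed = NULL, group_label = "group") {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  cc <- group_characteristic_curve(curves, group_label = group_label)
  k <- cc$k
  if (k == 1) {
    warning("bootstrap band over a single participant is zero-width")
    cc$ci_low <- cc$mean_values
    cc$ci_high <- cc$mean_values
    attr(cc, "level") <- level
    return(cc)
  }
  vals <- do.call(rbind, lapply(curves, `[[`, "values"))
  bm <- with_seed(seed, {
    idx <- sample.int(k, k * n_boot, replace = TRUE)
    rowsum(vals[idx, , drop = FALSE], rep(seq_len(n_boot), each = k)) / k
  })
  alpha <- (1 - level) / 2
  qs <- apply(bm, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  cc$ci_low <- pmin(qs[1, ], cc$mean_values)
  cc$ci_high <- pmax(qs[2, ], cc$mean_values)
  attr(cc, "level") <- level
  cc
}

#' Plot characteristic PEDB curves
#'
#' One line per group over the normalized respiratory event index, with
#' ribbons for the bootstrap confidence bands where present.
#'
#' @param ... Named `characteristic_curve` objects (names override their
#'   `group_label`s) or a single (optionally named) list of them.
#' @return A ggplot object.
#' @export
plot_characteristic_curve <- function(...) {
  curves <- list(...)
  if (length(curves) == 1 && is.list(curves[[1]]) &&
      !inherits(curves[[1]], "characteristic_curve")) {
    curves <- curves[[1]]
  }
  if (is.null(names(curves))) names(curves) <- rep("", length(curves))
  df <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cc <- curves[[i]]
    lab <- if (nzchar(names(curves)[i])) names(curves)[i] else cc$group_label
    data.frame(grid = cc$grid, mean = cc$mean_values, ci_low = cc$ci_low,
               ci_high = cc$ci_high, group = lab, stringsAsFactors = FALSE)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$mean,
                                        colour = .data$group,
                                        fill = .data$group))
  if (!all(is.na(df$ci_low))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.2, colour = NA)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Normalized respiratory event index",
                  y = "PEDB (flow units)", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
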