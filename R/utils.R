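# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  `seed = NULL` runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Contiguous quartile blocks of 1..n: base size n %/% 4, the n %% 4
# remainder indices assigned to the LAST quartiles, so quartile q covers
# idx_start[q]..idx_end[q].  Shared by quartile_dtw() and quartile_means().
quartile_bounds <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 4)
  base <- n %/% 4L
  rem <- n %% 4L
  sizes <- rep.int(base, 4L) + c(rep.int(0L, 4L - rem), rep.int(1L, rem))
  ends <- cumsum(sizes)
  data.frame(quartile = 1:4, start = c(1L, ends[-4L] + 1L), end = ends)
}

#' Contiguous quartile index blocks
#'
#' Splits indices `1..n` into four contiguous blocks of near-equal size;
#' when `n` is not divisible by 4 the extra indices go to the later
#' quartiles.  This single rule defines "sleep quartiles" everywhere in the
#' package (quartile means, quartile DTW).
#'
#' @param n Number of ordered items (events or curve points); must be >= 4.
#' @return A data frame with columns `quartile`, `start`, `end` (inclusive
#'   1-based index bounds).
#' @examples
#' quartile_indices(10)
#' @export
quartile_indices <- function(n) quartile_bounds(n)

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
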