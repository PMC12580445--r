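# Shared fixtures and independent oracles, built in code at test time.

# Pure sine airflow: amplitude `amp`, breathing frequency `freq_hz`.
make_sine <- function(freq_hz, dur_s, fs, amp = 1) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq_hz * t)
}

# --- Brute-force DTW oracle: exhaustive monotone alignment paths --------

# All monotone paths from (1,1) to (L,R) with steps (1,0), (0,1), (1,1),
# as a list of two-column index matrices.
enumerate_paths <- function(L, R) {
  res <- list()
  walk <- function(i, j, path) {
    if (i == L && j == R) {
      res[[length(res) + 1L]] <<- path
      return(invisible())
    }
    if (i < L) walk(i + 1L, j, rbind(path, c(i + 1L, j)))
    if (j < R) walk(i, j + 1L, rbind(path, c(i, j + 1L)))
    if (i < L && j < R) walk(i + 1L, j + 1L, rbind(path, c(i + 1L, j + 1L)))
  }
  walk(1L, 1L, matrix(c(1L, 1L), 1L))
  res
}

# Minimum path cost by direct enumeration (absolute local cost).
brute_dtw <- function(x, y, paths = NULL) {
  if (is.null(paths)) paths <- enumerate_paths(length(x), length(y))
  cost <- abs(outer(x, y, `-`))
  min(vapply(paths, function(p) sum(cost[p]), numeric(1)))
}

# Path indicator matrix: one row per monotone path, one column per cell of
# the L x R cost matrix (column-major).  `costs %*% t(path_matrix)` then
# gives every path's total cost for a batch of cost matrices at once.
path_matrix <- function(L, R) {
  paths <- enumerate_paths(L, R)
  A <- matrix(0, length(paths), L * R)
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    A[k, (p[, 2] - 1L) * L + p[, 1]] <- 1
  }
  A
}

# All sequences of length `len` over the given values, one per row.
all_seqs <- function(len, values = 0:2) {
  as.matrix(expand.grid(rep(list(values), len), KEEP.OUT.ATTRS = FALSE))
}

# --- Exhaustive matching oracle -----------------------------------------

# Optimal one-to-one matching within a single stratum: maximizes the pair
# count, then minimizes the total age difference, by enumeration over all
# injective case -> control assignments (small strata only).
stratum_optimum <- function(case_ages, ctrl_ages, max_age_diff = 10) {
  nc <- length(case_ages)
  best <- list(count = -1L, total = Inf)
  assign_next <- function(i, used, count, total) {
    if (i > nc) {
      if (count > best$count ||
          (count == best$count && total < best$total)) {
        best <<- list(count = count, total = total)
      }
      return(invisible())
    }
    assign_next(i + 1L, used, count, total)  # leave case i unmatched
    for (j in seq_along(ctrl_ages)) {
      if (used[j]) next
      d <- abs(case_ages[i] - ctrl_ages[j])
      if (d > max_age_diff) next
      used[j] <- TRUE
      assign_next(i + 1L, used, count + 1L, total + d)
      used[j] <- FALSE
    }
  }
  assign_next(1L, rep(FALSE, length(ctrl_ages)), 0L, 0)
  best
}

# Random participant table with a handful of strata.
random_participants <- function(n, prefix, seed) {
  withr::with_seed(seed, data.frame(
    id = sprintf("%s%03d", prefix, seq_len(n)),
    age = sample(45:80, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    race = sample(c("white", "black"), n, replace = TRUE, prob = c(0.8, 0.2)),
    bmi = round(runif(n, 20, 40), 1),
    ahi = round(runif(n, 6, 60), 1),
    stringsAsFactors = FALSE))
}
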