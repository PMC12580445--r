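test_that("quartile means follow the contiguous-block rule", {
  expect_equal(unlist(quartile_means(1:4)[, paste0("q", 1:4)],
                      use.names = FALSE), c(1, 2, 3, 4))
  expect_equal(unlist(quartile_means(1:8)[, paste0("q", 1:4)],
                      use.names = FALSE), c(1.5, 3.5, 5.5, 7.5))
  expect_equal(unlist(quartile_means(rep(2.2, 9))[, paste0("q", 1:4)],
                      use.names = FALSE), rep(2.2, 4))
  expect_error(quartile_means(1:3), "fewer than 4")
})

test_that("quartile blocks cover every event exactly once", {
  for (n in c(4, 5, 6, 7, 8, 13, 101)) {
    qb <- quartile_indices(n)
    idx <- unlist(lapply(1:4, function(q) qb$start[q]:qb$end[q]))
    expect_equal(sort(idx), 1:n)
    expect_false(any(duplicated(idx)))
    sizes <- qb$end - qb$start + 1
    expect_true(max(sizes) - min(sizes) <= 1)
    expect_true(all(diff(sizes) >= 0))     # remainders go to later quartiles
  }
})

test_that("identical quartiles give a degenerate signed-rank p of 1", {
  qs <- do.call(rbind, lapply(1:8, function(i) quartile_means(rep(i, 8))))
  tr <- within_group_quartile_test(qs, 1, 4)
  expect_equal(tr$p_value, 1)
  expect_true(tr$degenerate)
})

test_that("14 uniformly positive shifts give the exact all-signs p-value", {
  withr::with_seed(2, {
    qs <- do.call(rbind, lapply(1:14, function(i) {
      base <- runif(1, 1, 2)
      quartile_means(c(rep(base, 6), rep(base + runif(1, 0.3, 0.6), 2)))
    }))
  })
  tr <- within_group_quartile_test(qs, 1, 4)
  expect_equal(tr$p_value, 2 / 2^14, tolerance = 1e-12)
  expect_lt(tr$p_value, 0.05)
  expect_error(within_group_quartile_test(qs[1:4, ], 1, 4), "at least 5")
})

test_that("Mann-Whitney handles identity, separation and small groups", {
  a <- c(1.1, 1.9, 2.4, 3.2, 4.0, 4.7, 5.1, 6.3, 7.2, 8.4, 8.9, 9.5, 10.1, 11.3)
  tr_same <- between_group_test(a, a)
  expect_gt(tr_same$p_value, 0.99)

  b <- a + 100                       # complete separation, no overlap
  tr_sep <- between_group_test(a, b)
  expect_equal(tr_sep$statistic, 0)
  expect_equal(tr_sep$p_value, 2 / choose(28, 14), tolerance = 1e-12)

  tr_deg <- between_group_test(rep(1, 5), rep(1, 5))
  expect_equal(tr_deg$p_value, 1)
  expect_true(tr_deg$degenerate)

  expect_error(between_group_test(1:3, 1:6), "at least 5")
})

test_that("per-subject Spearman correlation hits the monotone extremes", {
  mk <- function(vals, durs, id) {
    pedb_series(vals, onset_s = seq_along(vals) * 60,
                duration_s = durs, stage = rep("NREM", length(vals)),
                participant_id = id)
  }
  up <- mk(c(1, 2, 3, 4), c(11, 12, 13, 14), "up")
  down <- mk(c(4, 3, 2, 1), c(11, 12, 13, 14), "down")
  flat <- mk(c(1, 2, 3, 4), c(12, 12, 12, 12), "flat")
  cs <- event_duration_correlation(list(up, down, flat))
  expect_equal(unname(cs$rho["up"]), 1)
  expect_equal(unname(cs$rho["down"]), -1)
  expect_true(is.na(cs$rho["flat"]))
  expect_equal(cs$n_flagged, 1)
})

test_that("independent durations give a group median rho near zero", {
  withr::with_seed(30, {
    series <- lapply(1:50, function(i) {
      n <- 30
      pedb_series(runif(n, 1, 2), onset_s = seq_len(n) * 90,
                  duration_s = runif(n, 11, 35),
                  stage = rep("NREM", n),
                  participant_id = sprintf("s%02d", i))
    })
  })
  cs <- event_duration_correlation(series)
  expect_lt(abs(cs$median_rho), 0.1)
})

test_that("rank tests are invariant to a change of flow units", {
  withr::with_seed(17, {
    qs <- do.call(rbind, lapply(1:10, function(i) quartile_means(runif(12, 1, 3))))
  })
  # signed-rank: unchanged under affine rescaling (units are arbitrary)
  tr1 <- within_group_quartile_test(qs, 1, 4)
  qs_scaled <- qs
  for (q in paste0("q", 1:4)) qs_scaled[[q]] <- 7.3 * qs_scaled[[q]] + 2
  tr2 <- within_group_quartile_test(qs_scaled, 1, 4)
  expect_equal(tr1$p_value, tr2$p_value, tolerance = 1e-12)

  # Mann-Whitney: unchanged under any strictly monotone transform
  withr::with_seed(18, {
    a <- runif(8, 1, 2)
    b <- runif(8, 1.2, 2.2)
  })
  p_raw <- between_group_test(a, b)$p_value
  p_exp <- between_group_test(exp(2 * a), exp(2 * b))$p_value
  expect_equal(p_raw, p_exp, tolerance = 1e-12)
})
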