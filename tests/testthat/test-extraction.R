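test_that("a pure sine is segmented into full breaths with exact p2p", {
  fs <- 100
  x <- make_sine(0.25, 60, fs)           # 15 cycles in 60 s
  br <- detect_breaths(x, fs)
  expect_equal(nrow(br), 15)
  expect_true(all(abs(br$p2p - 2) < 1e-6))
  expect_true(all(br$end_s > br$start_s))
  expect_true(all(diff(br$start_s) > 0))
})

test_that("degenerate signals yield no breaths", {
  expect_equal(nrow(detect_breaths(rep(0, 1000), 10)), 0)
  expect_equal(nrow(detect_breaths(rep(3.7, 1000), 10)), 0)  # constant offset
})

test_that("one full sine cycle is exactly one breath", {
  fs <- 50
  br <- detect_breaths(make_sine(0.25, 4, fs), fs)
  expect_equal(nrow(br), 1)
})

test_that("a detection window restricts segmentation", {
  fs <- 50
  x <- make_sine(0.25, 60, fs)
  br <- detect_breaths(x, fs, window = c(20, 40))
  expect_equal(nrow(br), 5)
  expect_true(all(br$start_s >= 20 - 1 / fs))
  expect_true(all(br$end_s <= 40 + 1 / fs))
})

test_that("post-event triplet selection honors the next event", {
  breaths <- data.frame(start_s = seq(0, 36, by = 4),
                        end_s = seq(4, 40, by = 4),
                        p2p = c(1, 1, 3, 2.5, 2, 1, 1, 1, 1, 1))
  ev <- list(onset_s = 0, duration_s = 8)
  tri <- post_event_breaths(breaths, ev)                # plenty of breaths
  expect_equal(tri$n_breaths_used, 3)
  expect_equal(tri$amplitudes, c(3, 2.5, 2))

  tri2 <- post_event_breaths(breaths, ev, next_onset_s = 17)  # 2 fit
  expect_equal(tri2$n_breaths_used, 2)
  expect_equal(tri2$amplitudes, c(3, 2.5))

  expect_null(post_event_breaths(breaths, ev, next_onset_s = 8))
})

test_that("PEDB is the mean of the available amplitudes", {
  expect_equal(compute_pedb(list(amplitudes = c(3, 2, 1),
                                 n_breaths_used = 3L)), 2)
  expect_equal(compute_pedb(list(amplitudes = c(4, 2),
                                 n_breaths_used = 2L)), 3)
  expect_equal(compute_pedb(list(amplitudes = rep(0.7, 3),
                                 n_breaths_used = 3L)), 0.7)
  expect_error(compute_pedb(NULL), "at least one")
})

test_that("extraction reproduces generator ground truth on clean records", {
  rec <- simulate_record(sim_config(duration_h = 2, target_ahi = 20,
                                    trend_slope = 0.45, noise_sd = 0,
                                    seed = 21))
  s <- extract_record(rec, participant_id = "p")
  truth <- truth_pedb_series(rec)
  expect_equal(nrow(s), nrow(truth))
  expect_true(all(abs(s$pedb - truth$pedb) / truth$pedb <= 0.01))
})

test_that("stage filters partition the full series", {
  rec <- simulate_record(sim_config(duration_h = 3, target_ahi = 20,
                                    rem_fraction = 0.25, seed = 13))
  tst <- extract_record(rec, "TST")
  nrem <- extract_record(rec, "NREM")
  rem <- extract_record(rec, "REM")
  expect_equal(nrow(nrem) + nrow(rem), nrow(tst))
  expect_true(all(rem$stage == "REM"))
  expect_true(all(nrem$stage == "NREM"))
})

test_that("REM filter on an all-NREM record yields an empty series", {
  rec <- simulate_record(sim_config(duration_h = 1, rem_fraction = 0,
                                    seed = 2))
  rem <- extract_record(rec, "REM")
  expect_s3_class(rem, "pedb_series")
  expect_equal(nrow(rem), 0)
})

test_that("PEDB scales with the signal and ignores constant offsets", {
  rec <- simulate_record(sim_config(duration_h = 1, target_ahi = 15,
                                    noise_sd = 0, seed = 31))
  base <- build_pedb_series(rec$airflow, rec$fs, rec$events)
  scaled <- build_pedb_series(3 * rec$airflow, rec$fs, rec$events)
  shifted <- build_pedb_series(rec$airflow + 5, rec$fs, rec$events)
  expect_equal(scaled$pedb, 3 * base$pedb, tolerance = 1e-12)
  expect_equal(shifted$pedb, base$pedb, tolerance = 1e-9)
})

test_that("malformed event tables are rejected", {
  rec <- simulate_record(sim_config(duration_h = 1, seed = 3))
  ev <- rec$events
  expect_error(build_pedb_series(rec$airflow, rec$fs, ev[c(2, 1), ]),
               "sorted")
  ev2 <- ev
  ev2$duration_s[1] <- ev2$onset_s[2] - ev2$onset_s[1] + 5
  expect_error(build_pedb_series(rec$airflow, rec$fs, ev2), "overlap")
})
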