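test_that("realized event count stays within 20% of the AHI target", {
  for (seed in 1:3) {
    rec <- simulate_record(sim_config(duration_h = 6, target_ahi = 20,
                                      seed = seed), signal = FALSE)
    expect_gte(nrow(rec$events), 96)
    expect_lte(nrow(rec$events), 144)
  }
})

test_that("realized AHI tracks the target across seeds and severities", {
  for (ahi in c(12, 40)) {
    realized <- vapply(1:10, function(seed) {
      rec <- simulate_record(sim_config(duration_h = 4, target_ahi = ahi,
                                        seed = seed), signal = FALSE)
      nrow(rec$events) / 4
    }, numeric(1))
    expect_true(all(abs(realized - ahi) / ahi <= 0.2))
  }
})

test_that("identical seeds reproduce records bit for bit", {
  cfg <- sim_config(duration_h = 1, target_ahi = 15, seed = 42)
  r1 <- simulate_record(cfg)
  r2 <- simulate_record(cfg)
  expect_identical(r1$airflow, r2$airflow)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$truth_pedb, r2$truth_pedb)
})

test_that("no trend, no noise, no jitter gives constant ground truth", {
  rec <- simulate_record(sim_config(duration_h = 2, trend_slope = 0,
                                    noise_sd = 0, jitter_sd = 0, seed = 5),
                         signal = FALSE)
  expect_equal(rec$truth_pedb, rep(1.5, length(rec$truth_pedb)))
})

test_that("a positive trend makes ground-truth PEDB nondecreasing", {
  rec <- simulate_record(sim_config(duration_h = 4, trend_slope = 0.6,
                                    jitter_sd = 0, noise_sd = 0, seed = 8),
                         signal = FALSE)
  expect_true(all(diff(rec$truth_pedb) >= 0))
})

test_that("events are sorted, non-overlapping, long enough and spaced", {
  for (seed in c(2, 17)) {
    cfg <- sim_config(duration_h = 6, target_ahi = 45, seed = seed)
    rec <- simulate_record(cfg, signal = FALSE)
    ev <- rec$events
    expect_true(all(diff(ev$onset_s) > 0))
    expect_true(all(ev$duration_s > 10))
    ends <- ev$onset_s + ev$duration_s
    gaps <- ev$onset_s[-1] - ends[-nrow(ev)]
    expect_true(all(gaps >= cfg$min_gap_breaths * rec$breath_s))
    expect_length(rec$truth_pedb, nrow(ev))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(target_ahi = 5), "target_ahi")
  expect_error(sim_config(event_dur_mean_s = 9), "event_dur_mean_s")
  expect_error(sim_config(overshoot_gain = 0.8), "overshoot_gain")
  expect_error(sim_config(rem_fraction = 1.2), "rem_fraction")
  expect_error(sim_config(duration_h = 0), "duration_h")
})

test_that("cohort simulation yields matched-size, reproducible groups", {
  cc <- sim_config(duration_h = 2, trend_slope = 0.45, seed = 1)
  ca <- sim_config(duration_h = 2, trend_slope = 0, seed = 1)
  coh1 <- simulate_cohort(14, cc, ca, seed = 7, signal = FALSE)
  coh2 <- simulate_cohort(14, cc, ca, seed = 7, signal = FALSE)
  expect_identical(coh1$participants, coh2$participants)
  expect_identical(coh1$records[["C001"]]$truth_pedb,
                   coh2$records[["C001"]]$truth_pedb)
  expect_equal(sum(coh1$participants$asthma == "control"), 14)
  expect_equal(sum(coh1$participants$asthma == "asthma"), 14)
})

test_that("only the trending group gains overshoot across the night", {
  cc <- sim_config(duration_h = 6, target_ahi = 30, trend_slope = 0.45,
                   seed = 1)
  ca <- sim_config(duration_h = 6, target_ahi = 30, trend_slope = 0, seed = 1)
  coh <- simulate_cohort(6, cc, ca, seed = 3, signal = FALSE)
  quarter_gain <- function(rec) {
    tp <- rec$truth_pedb
    n <- length(tp)
    qb <- quartile_indices(n)
    mean(tp[qb$start[4]:qb$end[4]]) - mean(tp[qb$start[1]:qb$end[1]])
  }
  ctrl_ids <- coh$participants$id[coh$participants$asthma == "control"]
  asth_ids <- coh$participants$id[coh$participants$asthma == "asthma"]
  gain_ctrl <- vapply(coh$records[ctrl_ids], quarter_gain, numeric(1))
  gain_asth <- vapply(coh$records[asth_ids], quarter_gain, numeric(1))
  expect_true(all(gain_ctrl > 0.2))          # 0.75 * slope = 0.34 expected
  expect_true(all(abs(gain_asth) < 0.1))     # jitter only
})
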