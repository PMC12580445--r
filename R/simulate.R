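#' Simulation configuration for a synthetic overnight airflow record
#'
#' Bundles and validates every knob of the synthetic polysomnography
#' generator.  The defaults describe a plausible obstructive sleep apnea
#' night: 6 h of sleep, breathing at 15 breaths/min, respiratory events
#' lasting 22 s on average (as reported for large OSA cohorts), and a
#' post-event overshoot 1.5 times the tidal amplitude.
#'
#' @param duration_h Recording duration in hours (> 0).
#' @param fs Sampling rate of the airflow signal in Hz (> 0).
#' @param breath_rate Breathing rate in breaths per minute (> 0).
#' @param tidal_amp Baseline peak-to-peak airflow amplitude (arbitrary flow
#'   units; thermistor airflow is uncalibrated, so units are relative).
#' @param target_ahi Target apnea-hypopnea index in events per hour of
#'   sleep; must exceed 5, the OSA inclusion threshold.
#' @param event_dur_mean_s,event_dur_sd_s Mean and SD of event duration in
#'   seconds; events always last more than 10 s (scoring definition), so
#'   draws are truncated from below.
#' @param apnea_fraction Fraction of events realized as apneas (airflow
#'   suppressed to < 10 % of baseline); the rest are hypopneas (> 30 %
#'   reduction).
#' @param overshoot_gain Amplitude of the three post-event deep breaths
#'   relative to `tidal_amp` at the start of the night (>= 1).
#' @param trend_slope Linear change of the overshoot gain from the start to
#'   the end of the night, in gain units: 0 gives a flat, "asthma-like"
#'   night; positive values give the "control-like" overnight increase.
#' @param trend_quad Optional quadratic term of the overshoot-gain trend in
#'   normalized time (default 0); lets curvature be injected so that
#'   degree-2 regression behaviour can be exercised.
#' @param rem_fraction Fraction of sleep epochs labeled REM, in `[0, 1]`;
#'   REM is placed as contiguous blocks in the second half of the night.
#' @param noise_sd SD of additive Gaussian sensor noise on the airflow
#'   signal (flow units; >= 0).
#' @param jitter_sd SD of the multiplicative per-breath amplitude jitter
#'   (dimensionless; >= 0).  Applied to every breath, including the
#'   post-event deep breaths, so ground-truth PEDB values inherit it.
#' @param min_gap_breaths Refractory gap, in breaths, required between the
#'   end of one event and the onset of the next (default 4, so the three
#'   post-event breaths are never consumed by the following event; set
#'   below 3 to exercise triplet truncation).
#' @param seed Integer RNG seed; identical configurations with identical
#'   seeds reproduce records bit for bit.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_record()], [simulate_cohort()]
#' @examples
#' cfg <- sim_config(duration_h = 2, target_ahi = 20, seed = 1)
#' cfg
#' @export
sim_config <- function(duration_h = 6, fs = 10, breath_rate = 15,
                       tidal_amp = 1, target_ahi = 20,
                       event_dur_mean_s = 22, event_dur_sd_s = 5,
                       apnea_fraction = 0.5, overshoot_gain = 1.5,
                       trend_slope = 0, trend_quad = 0, rem_fraction = 0.2,
                       noise_sd = 0.02, jitter_sd = 0.05,
                       min_gap_breaths = 4, seed = 1L) {
  cfg <- list(duration_h = duration_h, fs = fs, breath_rate = breath_rate,
              tidal_amp = tidal_amp, target_ahi = target_ahi,
              event_dur_mean_s = event_dur_mean_s,
              event_dur_sd_s = event_dur_sd_s,
              apnea_fraction = apnea_fraction,
              overshoot_gain = overshoot_gain, trend_slope = trend_slope,
              trend_quad = trend_quad, rem_fraction = rem_fraction,
              noise_sd = noise_sd, jitter_sd = jitter_sd,
              min_gap_breaths = min_gap_breaths, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  chk(cfg$duration_h > 0, "duration_h must be > 0")
  chk(cfg$fs > 0, "fs must be > 0")
  chk(cfg$breath_rate > 0, "breath_rate must be > 0")
  chk(cfg$tidal_amp > 0, "tidal_amp must be > 0")
  chk(cfg$target_ahi > 5, "target_ahi must be > 5 (OSA inclusion threshold)")
  chk(cfg$event_dur_mean_s > 10, "event_dur_mean_s must be > 10 s")
  chk(cfg$event_dur_sd_s >= 0, "event_dur_sd_s must be >= 0")
  chk(cfg$apnea_fraction >= 0 && cfg$apnea_fraction <= 1,
      "apnea_fraction must be in [0, 1]")
  chk(cfg$overshoot_gain >= 1, "overshoot_gain must be >= 1")
  chk(cfg$rem_fraction >= 0 && cfg$rem_fraction <= 1,
      "rem_fraction must be in [0, 1]")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$jitter_sd >= 0, "jitter_sd must be >= 0")
  chk(cfg$min_gap_breaths >= 0, "min_gap_breaths must be >= 0")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %.3g h at %g Hz, %g breaths/min, tidal amp %g\n",
              x$duration_h, x$fs, x$breath_rate, x$tidal_amp))
  cat(sprintf("  target AHI %g, event duration %g (SD %g) s, apnea fraction %g\n",
              x$target_ahi, x$event_dur_mean_s, x$event_dur_sd_s,
              x$apnea_fraction))
  cat(sprintf("  overshoot gain %g, trend slope %g, trend quad %g\n",
              x$overshoot_gain, x$trend_slope, x$trend_quad))
  cat(sprintf("  REM fraction %g, noise SD %g, jitter SD %g, seed %d\n",
              x$rem_fraction, x$noise_sd, x$jitter_sd, x$seed))
  invisible(x)
}

# Core event/breath layout.  Must run inside with_seed().  Works entirely in
# breath units: events and post-event breaths are aligned to breath
# boundaries, so every annotated interval covers whole breaths and the
# ground-truth amplitudes are unambiguous.
#
# Events are placed one per equal time slot with uniform jitter inside the
# window that keeps the event, its refractory gap and the slot boundary
# compatible.  This yields a homogeneous event density with the realized
# count pinned to round(target_ahi * duration_h).
simulate_layout <- function(cfg) {
  tb <- 60 / cfg$breath_rate                      # breath period, s
  total_s <- cfg$duration_h * 3600
  n_breaths <- floor(total_s / tb)
  n_ev <- max(1L, round(cfg$target_ahi * cfg$duration_h))
  slot_b <- n_breaths / n_ev
  gap_b <- max(0L, as.integer(cfg$min_gap_breaths))
  min_dur_b <- ceiling((10 + 1e-9) / tb)          # duration must exceed 10 s

  dur_b <- pmax(min_dur_b,
                round(stats::rnorm(n_ev, cfg$event_dur_mean_s,
                                   cfg$event_dur_sd_s) / tb))
  max_dur_b <- floor(slot_b) - gap_b - 1L
  if (max_dur_b < min_dur_b) {
    stop("target_ahi too high for breath_rate/min_gap_breaths: ",
         "events cannot fit without overlapping", call. = FALSE)
  }
  dur_b <- pmin(dur_b, max_dur_b)

  slot_lo <- ceiling((seq_len(n_ev) - 1) * slot_b)          # 0-based breath idx
  slot_hi <- floor(seq_len(n_ev) * slot_b) - dur_b - gap_b
  slot_hi <- pmax(slot_hi, slot_lo)
  start_b <- slot_lo + floor(stats::runif(n_ev) * (slot_hi - slot_lo + 1))
  start_b <- pmin(start_b, slot_hi)

  onset_s <- start_b * tb
  duration_s <- dur_b * tb
  type <- ifelse(stats::runif(n_ev) < cfg$apnea_fraction, "apnea", "hypopnea")

  # Sleep stages per 30-s epoch; REM as contiguous blocks preferentially in
  # the second half of the night.
  epoch_s <- 30
  n_ep <- max(1L, ceiling(total_s / epoch_s))
  stages <- rep("NREM", n_ep)
  n_rem <- round(cfg$rem_fraction * n_ep)
  if (n_rem >= n_ep) {
    stages[] <- "REM"
  } else if (n_rem > 0) {
    sizes <- c(floor(n_rem * 0.25), floor(n_rem * 0.35))
    sizes <- c(sizes, n_rem - sum(sizes))
    starts <- pmax(1L, floor(n_ep * c(0.50, 0.70, 0.88)))
    for (b in seq_along(sizes)) {
      if (sizes[b] <= 0) next
      idx <- starts[b] + seq_len(sizes[b]) - 1L
      stages[idx[idx <= n_ep]] <- "REM"
    }
  }
  ev_stage <- stages[pmin(n_ep, floor(onset_s / epoch_s) + 1L)]

  # Per-breath amplitudes: tidal baseline with multiplicative jitter,
  # suppressed during events, overshooting for the first breaths after each
  # event offset.  The overshoot gain follows the configured overnight trend
  # evaluated at the event onset in normalized time.
  amp <- cfg$tidal_amp * (1 + stats::rnorm(n_breaths, 0, cfg$jitter_sd))
  xt <- onset_s / total_s
  gain <- cfg$overshoot_gain + cfg$trend_slope * xt + cfg$trend_quad * xt^2
  next_onset_b <- c(start_b[-1L], n_breaths)
  truth <- numeric(n_ev)
  n_truth <- integer(n_ev)
  for (i in seq_len(n_ev)) {
    ev_idx <- (start_b[i] + 1L):(start_b[i] + dur_b[i])
    supp <- if (type[i] == "apnea") 0.05 else 0.5
    amp[ev_idx] <- amp[ev_idx] * supp
    end_b <- start_b[i] + dur_b[i]
    n_avail <- min(3L, next_onset_b[i] - end_b)
    if (n_avail >= 1L) {
      ob_idx <- (end_b + 1L):(end_b + n_avail)
      ob_amp <- cfg$tidal_amp * gain[i] *
        (1 + stats::rnorm(n_avail, 0, cfg$jitter_sd))
      amp[ob_idx] <- ob_amp
      truth[i] <- mean(ob_amp)
      n_truth[i] <- n_avail
    } else {
      truth[i] <- NA_real_
      n_truth[i] <- 0L
    }
  }

  list(breath_s = tb, n_breaths = n_breaths, amp = amp,
       events = data.frame(onset_s = onset_s, duration_s = duration_s,
                           type = type, stage = ev_stage,
                           stringsAsFactors = FALSE),
       truth_pedb = truth, truth_n_breaths = n_truth,
       stages = stages, epoch_s = epoch_s, total_s = total_s)
}

#' Simulate one synthetic overnight airflow record
#'
#' Generates tidal breathing as one sinusoidal flow cycle per breath
#' (inspiration positive), suppresses breath amplitude during annotated
#' apneas (to 5 % of baseline) and hypopneas (to 50 %), and injects three
#' overshooting deep breaths immediately after each event whose amplitude
#' follows the configured overnight trend.  The per-event mean overshoot
#' amplitudes are recorded as `truth_pedb`, the extraction ground truth.
#'
#' Events are aligned to breath boundaries, never overlap, always last more
#' than 10 s, and are separated by at least `min_gap_breaths` breaths.  The
#' realized event count equals `round(target_ahi * duration_h)`.
#'
#' @param config A [sim_config()].
#' @param signal If `FALSE`, skip synthesizing the sampled airflow vector
#'   and return only events, stages and ground truth (fast path for
#'   statistical simulation studies that operate on PEDB series directly).
#' @return An object of class `psg_record`: a list with `airflow` (numeric
#'   vector or `NULL`), `fs`, `events` (data frame `onset_s`, `duration_s`,
#'   `type`, `stage`), `truth_pedb`, `truth_n_breaths`, `stages` (per
#'   30-s epoch), `epoch_s`, `breath_s` and `config`.
#' @examples
#' rec <- simulate_record(sim_config(duration_h = 1, target_ahi = 15, seed = 7))
#' rec
#' nrow(rec$events)
#' @export
simulate_record <- function(config, signal = TRUE) {
  config <- validate_sim_config(config)
  with_seed(config$seed, {
    lay <- simulate_layout(config)
    airflow <- NULL
    if (signal) {
      n <- floor(lay$total_s * config$fs)
      t <- (seq_len(n) - 1) / config$fs
      bi <- pmin(floor(t / lay$breath_s), lay$n_breaths - 1)
      phase <- t / lay$breath_s - bi
      airflow <- 0.5 * lay$amp[bi + 1] * sin(2 * pi * phase)
      if (config$noise_sd > 0) {
        airflow <- airflow + stats::rnorm(n, 0, config$noise_sd)
      }
    }
    structure(list(airflow = airflow, fs = config$fs, events = lay$events,
                   truth_pedb = lay$truth_pedb,
                   truth_n_breaths = lay$truth_n_breaths,
                   stages = lay$stages, epoch_s = lay$epoch_s,
                   breath_s = lay$breath_s, config = config),
              class = "psg_record")
  })
}

#' @export
print.psg_record <- function(x, ...) {
  cat("<psg_record>\n")
  dur_h <- x$config$duration_h
  cat(sprintf("  %.3g h, %d events (realized AHI %.1f), %s airflow\n",
              dur_h, nrow(x$events), nrow(x$events) / dur_h,
              if (is.null(x$airflow)) "no" else
                sprintf("%d samples of", length(x$airflow))))
  cat(sprintf("  stages: %d epochs, %.0f%% REM\n", length(x$stages),
              100 * mean(x$stages == "REM")))
  invisible(x)
}

#' Ground-truth PEDB series of a synthetic record
#'
#' Converts the generator's per-event mean overshoot amplitudes into a
#' [pedb_series()] without touching the airflow signal — the reference
#' against which signal-based extraction is validated, and a fast input for
#' simulation studies of the downstream statistics.
#'
#' @param record A `psg_record` from [simulate_record()].
#' @param participant_id Identifier stored on the series.
#' @return A `pedb_series` object (events with zero recoverable post-event
#'   breaths, possible when the refractory gap is disabled, are dropped).
#' @export
truth_pedb_series <- function(record, participant_id = "truth") {
  stopifnot(inherits(record, "psg_record"))
  keep <- record$truth_n_breaths > 0L
  pedb_series(values = record$truth_pedb[keep],
              onset_s = record$events$onset_s[keep],
              duration_s = record$events$duration_s[keep],
              stage = record$events$stage[keep],
              n_breaths_used = record$truth_n_breaths[keep],
              participant_id = participant_id)
}

#' Simulate a matched synthetic case-control cohort
#'
#' Draws `n_per_group` control-like and asthma-like participants.  Each
#' participant gets an independent record whose generator seed is derived
#' deterministically from `seed`.  Asthma-group metadata is drawn from
#' `metadata_spec`; each control is a demographic near-clone of one asthma
#' participant (same sex, race and BMI category, age within 5 years), so
#' exact one-to-one matching is feasible by construction.
#'
#' @param n_per_group Participants per group (>= 1).
#' @param config_control,config_asthma [sim_config()]s for the two groups
#'   (their `seed` fields are overwritten by derived sub-seeds).
#' @param metadata_spec List of distribution parameters: `age_mean`,
#'   `age_sd`, `male_frac`, `race_probs` (named numeric), `bmi_mean`,
#'   `bmi_sd`.
#' @param seed Master RNG seed.
#' @param signal Passed to [simulate_record()]; `FALSE` skips airflow
#'   synthesis.
#' @return A list with `participants` (data frame `id`, `age`, `sex`,
#'   `race`, `bmi`, `ahi`, `asthma`) and `records` (list of `psg_record`
#'   keyed by participant id).
#' @examples
#' coh <- simulate_cohort(2, sim_config(duration_h = 1, seed = 1),
#'                        sim_config(duration_h = 1, seed = 2),
#'                        seed = 42, signal = FALSE)
#' coh$participants
#' @export
simulate_cohort <- function(n_per_group, config_control, config_asthma,
                            metadata_spec = list(), seed = 1L,
                            signal = TRUE) {
  stopifnot(n_per_group >= 1)
  config_control <- validate_sim_config(config_control)
  config_asthma <- validate_sim_config(config_asthma)
  spec <- utils::modifyList(
    list(age_mean = 62, age_sd = 11, male_frac = 0.31,
         race_probs = c(white = 0.88, black = 0.12),
         bmi_mean = 30.7, bmi_sd = 6.2),
    metadata_spec)

  with_seed(seed, {
    n <- n_per_group
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    age_a <- round(pmin(90, pmax(40, stats::rnorm(n, spec$age_mean, spec$age_sd))))
    sex_a <- ifelse(stats::runif(n) < spec$male_frac, "male", "female")
    race_a <- sample(names(spec$race_probs), n, replace = TRUE,
                     prob = spec$race_probs)
    bmi_a <- round(pmin(48, pmax(17, stats::rnorm(n, spec$bmi_mean, spec$bmi_sd))), 1)
    age_c <- round(pmin(90, pmax(40, age_a + stats::runif(n, -5, 5))))
    # control BMI perturbed within the asthma participant's BMI category
    bmi_c <- vapply(bmi_a, function(b) {
      lim <- switch(bmi_category(b),
                    underweight = c(17, 18.4), normal = c(18.5, 24.9),
                    overweight = c(25, 29.9), obese = c(30, 48))
      round(min(lim[2], max(lim[1], b + stats::runif(1, -1.5, 1.5))), 1)
    }, numeric(1))

    make_group <- function(cfg, ids, ages, sexes, races, bmis, label, seeds) {
      recs <- vector("list", n)
      ahi <- numeric(n)
      for (i in seq_len(n)) {
        cfg_i <- cfg
        cfg_i$seed <- as.integer(seeds[i])
        recs[[i]] <- simulate_record(cfg_i, signal = signal)
        ahi[i] <- nrow(recs[[i]]$events) / cfg$duration_h
      }
      names(recs) <- ids
      list(meta = data.frame(id = ids, age = ages, sex = sexes, race = races,
                             bmi = bmis, ahi = round(ahi, 1), asthma = label,
                             stringsAsFactors = FALSE),
           recs = recs)
    }

    asth <- make_group(config_asthma, sprintf("A%03d", seq_len(n)),
                       age_a, sex_a, race_a, bmi_a, "asthma",
                       sub_seeds[seq_len(n)])
    ctrl <- make_group(config_control, sprintf("C%03d", seq_len(n)),
                       age_c, sex_a, race_a, bmi_c, "control",
                       sub_seeds[n + seq_len(n)])

    list(participants = rbind(ctrl$meta, asth$meta),
         records = c(ctrl$recs, asth$recs))
  })
}
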