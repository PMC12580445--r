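# pedbkit

Quantify post-event deep breathing (PEDB) — the ventilatory overshoot that
follows obstructive apneas and hypopneas — from overnight airflow
recordings, and compare its overnight trajectory between participant
groups.

## The scientific problem

In obstructive sleep apnea (OSA), pharyngeal collapses (apneas: airflow
drops below 10 % of baseline; hypopneas: reductions of more than 30 %;
both lasting over 10 s) usually terminate with an arousal and a burst of
deep inspirations.  Deep inspirations act as bronchodilators in healthy
lungs, but in asthma they can lose that effect or even provoke
bronchoconstriction.  Whether and how the amplitude of these post-event
deep breaths changes across the night — and whether it differs between
OSA patients with and without asthma — is therefore physiologically
informative.  pedbkit packages that analysis for anyone with an airflow
channel (EDF or CSV) and event annotations (NSRR-style XML or CSV), and
ships a synthetic polysomnography generator so that the entire pipeline
is testable without access-controlled clinical data.

## The statistic and the pipeline

For event *i* of a participant, the PEDB value averages the peak-to-peak
amplitudes of the first three post-event breaths:

PEDB_i = (A_i + B_i + C_i) / 3,  A/B/C = max F(i,j) − min F(i,j)

where F(i,j) is the airflow of the j-th breath after event *i* (fewer
than three recoverable breaths are averaged over what exists).  The
per-participant series PEDB_1..PEDB_N (N = number of events) is mapped
onto normalized positions x_i = (i−1)/(N−1) and standardized to the group
maximum length M by exact piecewise-polynomial interpolation (linear by
default, quadratic-spline optional): P(x_i) = PEDB_i at every original
point, evaluated at x'_j = (j−1)/(M−1).  The group characteristic curve
is the pointwise mean over its K participants, with a percentile
bootstrap band from resampling participants (1000 replicates by
default).  Polynomial regressions of degree 1–3 smooth the curve, the
degree chosen by 80/20 train/test RMSE, RMSE = sqrt(mean((ŷ_j − y_j)²)).
Curves are compared by dynamic time warping,

D(i,j) = |x_i − y_j| + min(D(i−1,j), D(i,j−1), D(i−1,j−1)),  DTW = D(L,R),

overall and per sleep quartile, and quartile statistics use the Wilcoxon
signed-rank test (within group), the Mann–Whitney U test (between
groups) and per-subject Spearman correlations of event duration against
PEDB.

## Worked example

```r
library(pedbkit)

# a control-like synthetic night: 6 h, AHI 40, overshoot gain rising
# from 1.5x to 1.95x tidal amplitude across the night
rec <- simulate_record(sim_config(duration_h = 6, target_ahi = 40,
                                  trend_slope = 0.45, seed = 1))
rec
#> <psg_record>
#>   6 h, 240 events (realized AHI 40.0), 216000 samples of airflow
#>   stages: 720 epochs, 20% REM

series <- extract_record(rec, participant_id = "demo")
head(as.data.frame(series), 3)
#>   event_index onset_s duration_s stage n_breaths_used  pedb
#> 1           1      40         20  NREM              3 1.514
#> 2           2     100         24  NREM              3 1.482
#> 3           3     228         16  NREM              3 1.475

round(quartile_means(series)[, c("q1", "q2", "q3", "q4")], 3)
#>      q1   q2    q3   q4
#> 1 1.583 1.69 1.798 1.91
```

The extracted PEDB values sit around 1.5 flow units at the start of the
night (tidal amplitude 1, overshoot gain 1.5) and the quartile means
climb toward 1.9 — the injected +30 % overnight trend.  Across a cohort
of 14 such participants, the within-group comparison of the first versus
the fourth quartile:

```r
coh <- simulate_cohort(14, sim_config(duration_h = 6, target_ahi = 40,
                                      trend_slope = 0.45, seed = 1),
                       sim_config(duration_h = 6, target_ahi = 40,
                                  trend_slope = 0, seed = 2),
                       seed = 99, signal = FALSE)
ctrl_ids <- coh$participants$id[coh$participants$asthma == "control"]
qs <- do.call(rbind, lapply(ctrl_ids, function(id)
  quartile_means(truth_pedb_series(coh$records[[id]], id))))
within_group_quartile_test(qs, 1, 4)
#>                   test comparison statistic      p_value  n degenerate
#> 1 wilcoxon_signed_rank   Q1-vs-Q4       105 0.0001220703 14      FALSE
```

Every participant's fourth-quartile mean exceeds the first, so the
two-sided exact signed-rank p-value reaches its minimum for n = 14,
2/2^14 ≈ 1.2e-4.  `run_pipeline()` chains all of this — extraction,
standardization, bootstrap bands, model selection, DTW and the test
battery — and writes CSV/JSON tables plus a manifest that makes reruns
bit-identical.  A thin command-line wrapper lives in
`inst/cli/pedbkit.R` (`simulate` and `run` subcommands).

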