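test_that("OSA severity brackets are half-open as defined", {
  expect_equal(classify_osa_severity(12), "mild")
  expect_equal(classify_osa_severity(15), "mild")
  expect_equal(classify_osa_severity(15.01), "moderate")
  expect_equal(classify_osa_severity(30), "moderate")
  expect_equal(classify_osa_severity(31), "severe")
  expect_error(classify_osa_severity(4), "AHI")
  expect_error(classify_osa_severity(5), "AHI")
})

test_that("severity classification is a partition of AHI > 5", {
  withr::with_seed(1, {
    ahi <- runif(500, 5.001, 120)
    sev <- classify_osa_severity(ahi)
    expect_true(all(sev %in% c("mild", "moderate", "severe")))
    expect_identical(sev == "mild", ahi <= 15)
    expect_identical(sev == "severe", ahi > 30)
  })
})

test_that("BMI categories resolve boundaries uniquely", {
  expect_equal(bmi_category(17), "underweight")
  expect_equal(bmi_category(18.5), "normal")
  expect_equal(bmi_category(25), "overweight")  # half-open boundary
  expect_equal(bmi_category(29.9), "overweight")
  expect_equal(bmi_category(30.9), "obese")
  expect_error(bmi_category(0), "positive")
  expect_error(bmi_category(-3), "positive")
})

test_that("a forced match pairs and a broken stratum does not", {
  case <- data.frame(id = "A1", age = 60, sex = "female", race = "white",
                     bmi = 31, ahi = 40, stringsAsFactors = FALSE)
  ctrl <- data.frame(id = "C1", age = 63, sex = "female", race = "white",
                     bmi = 32, ahi = 35, stringsAsFactors = FALSE)
  pairs <- match_controls(case, ctrl)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$age_diff, 3)

  ctrl_male <- ctrl
  ctrl_male$sex <- "male"
  expect_equal(nrow(match_controls(case, ctrl_male)), 0)
  expect_equal(attr(match_controls(case, ctrl_male), "unmatched"), "A1")

  ctrl_old <- ctrl
  ctrl_old$age <- 71
  expect_equal(nrow(match_controls(case, ctrl_old)), 0)
})

test_that("greedy matching equals exhaustive optimum on a feasible instance", {
  # Two strata; in each, controls sit close to distinct case ages so the
  # optimal assignment is unambiguous and small enough to enumerate.
  cases <- data.frame(
    id = sprintf("A%02d", 1:10),
    age = c(50, 70, 52, 68, 60, 50, 70, 55, 65, 60),
    sex = rep(c("female", "male"), each = 5),
    race = "white",
    bmi = rep(c(26, 32), each = 5),
    ahi = 40, stringsAsFactors = FALSE)
  withr::with_seed(4, {
    pool <- do.call(rbind, lapply(1:3, function(k) {
      p <- cases
      p$id <- sprintf("C%02d", seq_len(nrow(p)) + (k - 1) * 10)
      p$age <- p$age + sample(c(-2, -1, 1, 2), nrow(p), replace = TRUE)
      p
    }))
  })
  pairs <- match_controls(cases, pool)
  expect_equal(nrow(pairs), 10)
  expect_length(attr(pairs, "unmatched"), 0)

  # oracle per stratum: maximize count, then minimize total age difference
  strat <- function(df) paste(df$sex, df$race, bmi_category(df$bmi),
                              classify_osa_severity(df$ahi))
  total <- 0
  count <- 0
  for (s in unique(strat(cases))) {
    opt <- stratum_optimum(cases$age[strat(cases) == s],
                           pool$age[strat(pool) == s])
    count <- count + opt$count
    total <- total + opt$total
  }
  expect_equal(nrow(pairs), count)
  expect_equal(sum(pairs$age_diff), total)
})

test_that("matching never violates stratum or age constraints", {
  for (seed in 1:5) {
    cases <- random_participants(12, "A", seed)
    pool <- random_participants(30, "C", seed + 100)
    pairs <- match_controls(cases, pool)
    for (r in seq_len(nrow(pairs))) {
      ca <- cases[cases$id == pairs$case_id[r], ]
      co <- pool[pool$id == pairs$control_id[r], ]
      expect_lte(abs(ca$age - co$age), 10)
      expect_equal(ca$sex, co$sex)
      expect_equal(ca$race, co$race)
      expect_equal(bmi_category(ca$bmi), bmi_category(co$bmi))
      expect_equal(classify_osa_severity(ca$ahi),
                   classify_osa_severity(co$ahi))
    }
    expect_false(any(duplicated(pairs$control_id)))
    expect_false(any(duplicated(pairs$case_id)))
  }
})

test_that("identical groups show no demographic differences", {
  g <- random_participants(10, "P", 3)
  s <- cohort_summary(g, g)
  expect_true(all(abs(s$p_value - 1) < 1e-9))
  expect_equal(s$statistic[s$variable == "age"], 0)
})

test_that("disjoint age ranges are detected, t statistic matches by hand", {
  ga <- random_participants(10, "A", 5)
  gb <- random_participants(10, "B", 6)
  ga$age <- 40:49
  gb$age <- 70:79
  s <- cohort_summary(ga, gb, continuous = "age", categorical = character())
  expect_lt(s$p_value, 0.05)
  # Welch t computed from first principles
  t_hand <- (mean(ga$age) - mean(gb$age)) /
    sqrt(var(ga$age) / 10 + var(gb$age) / 10)
  expect_equal(s$statistic, t_hand, tolerance = 1e-12)
})

test_that("Fisher's exact p for a 5/0 vs 0/5 split matches enumeration", {
  ga <- data.frame(age = rnorm(5, 60), bmi = 30, ahi = 20,
                   sex = rep("male", 5), race = "white")
  gb <- data.frame(age = rnorm(5, 60), bmi = 30, ahi = 20,
                   sex = rep("female", 5), race = "white")
  s <- cohort_summary(ga, gb, continuous = character(), categorical = "sex")
  # hypergeometric: both one-sided tables have probability 1/C(10,5) = 1/252
  expect_equal(s$p_value, 2 / 252, tolerance = 1e-12)
})
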