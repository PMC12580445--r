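#' Classify obstructive sleep apnea severity from the AHI
#'
#' Standard severity bands on the apnea-hypopnea index: mild for
#' `5 < AHI <= 15`, moderate for `15 < AHI <= 30`, severe for `AHI > 30`.
#' An AHI of 5 or below does not meet the OSA inclusion criterion and is an
#' error rather than a category.
#'
#' @param ahi Apnea-hypopnea index in events per hour (vectorized).
#' @return Character vector in `c("mild", "moderate", "severe")`.
#' @examples
#' classify_osa_severity(c(12, 15, 30, 31))
#' @export
classify_osa_severity <- function(ahi) {
  stopifnot(is.numeric(ahi))
  if (any(!is.finite(ahi)) || any(ahi <= 5)) {
    stop("AHI must be > 5 for OSA inclusion (AHI <= 5 is not OSA)",
         call. = FALSE)
  }
  ifelse(ahi <= 15, "mild", ifelse(ahi <= 30, "moderate", "severe"))
}

#' Classify body mass index
#'
#' Standard obesity classes with half-open boundaries so each BMI maps to
#' exactly one category: underweight `< 18.5`, normal `[18.5, 25)`,
#' overweight `[25, 30)`, obese `>= 30`.
#'
#' @param bmi Body mass index in kg/m^2 (vectorized, must be positive).
#' @return Character vector in `c("underweight", "normal", "overweight",
#'   "obese")`.
#' @examples
#' bmi_category(c(17, 18.5, 25, 30.9))
#' @export
bmi_category <- function(bmi) {
  stopifnot(is.numeric(bmi))
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("BMI must be a positive number", call. = FALSE)
  }
  ifelse(bmi < 18.5, "underweight",
         ifelse(bmi < 25, "normal",
                ifelse(bmi < 30, "overweight", "obese")))
}

matching_stratum <- function(p) {
  paste(p$sex, p$race, bmi_category(p$bmi), classify_osa_severity(p$ahi),
        sep = "|")
}

#' Match each case to one control
#'
#' One-to-one matched-pair selection: a case and its control must share
#' sex, race, BMI category and OSA severity category exactly, and differ in
#' age by at most `max_age_diff` years.  Within these constraints pairs are
#' assigned greedily by smallest absolute age difference, with ties broken
#' by case id then control id, so the result is deterministic.
#'
#' @param cases,pool Data frames of participants with columns `id`, `age`,
#'   `sex`, `race`, `bmi`, `ahi`; `pool` must be disjoint from `cases`.
#' @param max_age_diff Maximum allowed absolute age difference in years
#'   (default 10).
#' @return A data frame with columns `case_id`, `control_id`, `age_diff`.
#'   Unmatched case ids are attached as `attr(, "unmatched")`.
#' @examples
#' cases <- data.frame(id = "A1", age = 60, sex = "female", race = "white",
#'                     bmi = 31, ahi = 40)
#' pool <- data.frame(id = c("C1", "C2"), age = c(63, 75), sex = "female",
#'                    race = "white", bmi = c(32, 30.5), ahi = c(35, 44))
#' match_controls(cases, pool)
#' @export
match_controls <- function(cases, pool, max_age_diff = 10) {
  need <- c("id", "age", "sex", "race", "bmi", "ahi")
  stopifnot(all(need %in% names(cases)), all(need %in% names(pool)))
  if (any(pool$id %in% cases$id)) {
    stop("`pool` must be disjoint from `cases`", call. = FALSE)
  }
  if (nrow(pool) == 0L || nrow(cases) == 0L) {
    out <- data.frame(case_id = character(), control_id = character(),
                      age_diff = numeric(), stringsAsFactors = FALSE)
    attr(out, "unmatched") <- as.character(cases$id)
    return(out)
  }
  cs <- matching_stratum(cases)
  ps <- matching_stratum(pool)
  cand <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    j <- which(ps == cs[i] & abs(pool$age - cases$age[i]) <= max_age_diff)
    if (length(j) == 0L) return(NULL)
    data.frame(case_id = as.character(cases$id[i]),
               control_id = as.character(pool$id[j]),
               age_diff = abs(pool$age[j] - cases$age[i]),
               stringsAsFactors = FALSE)
  }))
  pairs <- data.frame(case_id = character(), control_id = character(),
                      age_diff = numeric(), stringsAsFactors = FALSE)
  if (!is.null(cand)) {
    cand <- cand[order(cand$age_diff, cand$case_id, cand$control_id), ]
    used_case <- character()
    used_ctrl <- character()
    for (r in seq_len(nrow(cand))) {
      if (cand$case_id[r] %in% used_case) next
      if (cand$control_id[r] %in% used_ctrl) next
      pairs <- rbind(pairs, cand[r, ])
      used_case <- c(used_case, cand$case_id[r])
      used_ctrl <- c(used_ctrl, cand$control_id[r])
    }
    rownames(pairs) <- NULL
  }
  attr(pairs, "unmatched") <-
    setdiff(as.character(cases$id), pairs$case_id)
  pairs
}

#' Descriptive comparison of two participant groups
#'
#' Mean (SD) and a two-sided t-test for continuous variables; level counts
#' and Fisher's exact test for categorical variables — the conventional
#' "Table 1" of a matched case-control study.
#'
#' @param group_a,group_b Data frames of participants (both nonempty; at
#'   least 2 rows each for the t-tests to have a defined variance).
#' @param continuous,categorical Column names to summarize.
#' @return A data frame with one row per variable: `variable`, `type`,
#'   `summary_a`, `summary_b`, `statistic` (t statistic or NA for Fisher),
#'   `p_value`.
#' @export
cohort_summary <- function(group_a, group_b,
                           continuous = c("age", "bmi", "ahi"),
                           categorical = c("sex", "race")) {
  stopifnot(nrow(group_a) >= 1, nrow(group_b) >= 1)
  rows <- list()
  for (v in continuous) {
    if (nrow(group_a) < 2 || nrow(group_b) < 2) {
      stop("t-test needs at least 2 participants per group (variance ",
           "undefined for n < 2)", call. = FALSE)
    }
    a <- group_a[[v]]
    b <- group_b[[v]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(a, b)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous",
      summary_a = sprintf("%.1f (%.1f)", mean(a), stats::sd(a)),
      summary_b = sprintf("%.1f (%.1f)", mean(b), stats::sd(b)),
      statistic = unname(tt$statistic), p_value = tt$p.value,
      stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    lev <- sort(unique(c(group_a[[v]], group_b[[v]])))
    ca <- table(factor(group_a[[v]], levels = lev))
    cb <- table(factor(group_b[[v]], levels = lev))
    p <- if (length(lev) < 2) 1 else
      stats::fisher.test(rbind(as.integer(ca), as.integer(cb)))$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical",
      summary_a = paste(sprintf("%s=%d", lev, as.integer(ca)), collapse = ", "),
      summary_b = paste(sprintf("%s=%d", lev, as.integer(cb)), collapse = ", "),
      statistic = NA_real_, p_value = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
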