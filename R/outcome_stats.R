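#' Outcome registry
#'
#' Maps analysis outcome names to ledger columns and to the missing-data rule
#' family they follow: `lipid` (lab panel; baseline carried to the 3-month
#' visit when absent, post-final panel required), `clinical` (clinic
#' measurements; same rule), or `questionnaire` (item carried forward from
#' the most recent prior visit, with the entire-questionnaire exclusion
#' rule).
#'
#' @return data.frame with columns `outcome`, `column`, `kind`.
#' @export
outcome_registry <- function() {
  data.frame(
    outcome = c("ldl", "hdl", "total_chol", "triglycerides", "systolic_bp",
                "diastolic_bp", "weight", "diet", "activity", "anxiety",
                "stages_of_change", "med_beliefs"),
    column = c("ldl", "hdl", "total_chol", "triglycerides", "systolic_bp",
               "diastolic_bp", "weight", "diet_score", "activity_category",
               "anxiety_score", "stages_of_change", "med_beliefs_likert"),
    kind = c("lipid", "lipid", "lipid", "lipid", "clinical", "clinical",
             "clinical", "questionnaire", "questionnaire", "questionnaire",
             "questionnaire", "questionnaire"),
    stringsAsFactors = FALSE
  )
}

ledger_wide_values <- function(ledger, column) {
  v <- ledger$visits
  val <- ifelse(v$attended, v[[column]], NA)
  out <- data.frame(participant_id = unique(v$participant_id),
                    stringsAsFactors = FALSE)
  for (k in 1:3) {
    out[[paste0("v", k)]] <-
      val[v$visit == k][match(out$participant_id,
                              v$participant_id[v$visit == k])]
  }
  out$arm <- ledger$participants$arm[match(out$participant_id,
                                           ledger$participants$participant_id)]
  out
}

#' Build an analysis dataset under the trial's carry-forward rules
#'
#' Applies the study's missing-data rules for one outcome and returns the
#' per-participant 3-month value, 6-month value and their difference, each
#' value flagged `observed` or `carried_forward`, with excluded participants
#' carrying an explicit reason. Rules:
#'
#' * Lipids and clinic measurements: a missing 3-month value is imputed from
#'   baseline (`mode = "imputation"`); participants without a measurement
#'   after the final visit are excluded. `mode = "no_imputation"` disables
#'   the baseline fill, requiring observed values at both follow-up visits
#'   (the report's second LDL row).
#' * Questionnaires: a missing response at the 3-month (6-month) visit is
#'   carried forward from the most recent prior visit; a participant whose
#'   questionnaire is entirely missing at the final visit as well as at the
#'   baseline or 3-month visit is excluded for that questionnaire. `mode`
#'   does not apply.
#'
#' A value absent from every visit is never fabricated.
#'
#' @param ledger a `trial_ledger`.
#' @param outcome an outcome name from [outcome_registry()].
#' @param mode `"imputation"` (default) or `"no_imputation"`.
#' @return data.frame of class `analysis_dataset`: `participant_id`, `arm`,
#'   `value_3mo`, `value_6mo`, `delta`, `prov_3mo`, `prov_6mo`, `included`,
#'   `reason`.
#' @export
apply_carry_forward <- function(ledger, outcome,
                                mode = c("imputation", "no_imputation")) {
  mode <- match.arg(mode)
  reg <- outcome_registry()
  assert_that(outcome %in% reg$outcome,
              sprintf("unknown outcome '%s'; see outcome_registry()", outcome),
              "grstrial_config_error")
  kind <- reg$kind[reg$outcome == outcome]
  wide <- ledger_wide_values(ledger, reg$column[reg$outcome == outcome])

  n <- nrow(wide)
  value_3mo <- value_6mo <- rep(NA_real_, n)
  prov_3mo <- prov_6mo <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    v1 <- wide$v1[i]; v2 <- wide$v2[i]; v3 <- wide$v3[i]
    if (kind %in% c("lipid", "clinical")) {
      if (!is.na(v2)) {
        value_3mo[i] <- v2; prov_3mo[i] <- "observed"
      } else if (mode == "imputation" && !is.na(v1)) {
        value_3mo[i] <- v1; prov_3mo[i] <- "carried_forward"
      }
      if (!is.na(v3)) {
        value_6mo[i] <- v3; prov_6mo[i] <- "observed"
      }
      if (is.na(value_6mo[i])) {
        reason[i] <- "no measurement after the final visit"
      } else if (is.na(value_3mo[i])) {
        reason[i] <- if (mode == "no_imputation" && !is.na(v1))
          "no observed 3-month measurement (imputation disabled)"
        else "no 3-month measurement"
      }
    } else { # questionnaire
      if (is.na(v3) && (is.na(v1) || is.na(v2))) {
        reason[i] <- "questionnaire missing at final visit and at baseline or 3-month visit"
      } else {
        if (!is.na(v2)) {
          value_3mo[i] <- v2; prov_3mo[i] <- "observed"
        } else if (!is.na(v1)) {
          value_3mo[i] <- v1; prov_3mo[i] <- "carried_forward"
        }
        if (!is.na(v3)) {
          value_6mo[i] <- v3; prov_6mo[i] <- "observed"
        } else if (!is.na(value_3mo[i])) {
          value_6mo[i] <- value_3mo[i]; prov_6mo[i] <- "carried_forward"
        }
        if (is.na(value_3mo[i])) reason[i] <- "no 3-month response"
        else if (is.na(value_6mo[i])) reason[i] <- "no final-visit response"
      }
    }
  }
  included <- is.na(reason)
  out <- data.frame(participant_id = wide$participant_id, arm = wide$arm,
                    value_3mo = value_3mo, value_6mo = value_6mo,
                    delta = ifelse(included, value_6mo - value_3mo, NA_real_),
                    prov_3mo = prov_3mo, prov_6mo = prov_6mo,
                    included = included, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("analysis_dataset", "data.frame")
  out
}

# Rank-sum statistic U = #{(i,j): x_i > y_j} + ties/2, with tie-corrected
# normal moments on the combined midranks.
ranksum_stat <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  N <- m + n
  ties <- table(r)
  sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  list(U = U, mu = m * n / 2, sigma = sqrt(sigma2), tied = any(ties > 1))
}

#' Hodges-Lehmann two-sample shift estimate with rank-sum inference
#'
#' Estimates the location shift between two samples as the median of all
#' `m * n` pairwise differences `x_i - y_j` (midpoint of the two central
#' values when `m * n` is even), with a confidence interval obtained by
#' inverting the Wilcoxon-Mann-Whitney rank-sum distribution and a two-sided
#' rank-sum p-value. The exact null distribution is used whenever
#' `m * n <= exact_limit` and there are no ties; otherwise the normal
#' approximation with midranks and tie-corrected variance is used (no
#' continuity correction; see the methods vignette for the calibration
#' rationale).
#'
#' @param x,y numeric vectors (each length >= 2 after removing `NA`).
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @param exact_limit largest `m * n` for which the exact distribution is
#'   enumerated (default 10,000).
#' @param outcome optional outcome label used in error messages.
#' @return Object of class `shift_estimate`: `n_x`, `n_y`, `hl_difference`,
#'   `ci_low`, `ci_high`, `p_value`, `method`.
#' @export
hodges_lehmann_shift <- function(x, y, alpha = 0.05, exact_limit = 10000,
                                 outcome = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  lbl <- if (is.null(outcome)) "" else sprintf(" for outcome '%s'", outcome)
  if (length(x) < 2 || length(y) < 2) {
    stop_grstrial(sprintf("need >= 2 non-missing values per arm%s (got %d and %d)",
                          lbl, length(x), length(y)),
                  "grstrial_analysis_error")
  }
  m <- length(x); n <- length(y); mn <- m * n
  diffs <- sort(as.numeric(outer(x, y, "-")))
  hl <- median(diffs)

  st <- ranksum_stat(x, y)
  exact <- !st$tied && mn <= exact_limit
  if (exact) {
    U <- st$U
    p <- 2 * min(pwilcox(U, m, n), 1 - pwilcox(U - 1, m, n))
    p <- min(p, 1)
    k <- qwilcox(alpha / 2, m, n)
    if (k == 0) k <- 1
    ci <- c(diffs[k], diffs[mn - k + 1])
    method <- "exact rank-sum inversion"
  } else {
    z <- (st$U - st$mu) / st$sigma
    p <- 2 * pnorm(-abs(z))
    k <- floor(st$mu - qnorm(1 - alpha / 2) * st$sigma)
    k <- max(min(k, mn %/% 2), 0)
    ci <- c(diffs[k + 1], diffs[mn - k])
    method <- "normal approximation, tie-corrected"
  }
  structure(list(n_x = m, n_y = n, hl_difference = hl,
                 ci_low = ci[1], ci_high = ci[2], p_value = p,
                 method = method),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("Hodges-Lehmann shift: %.3g (95%% CI %.3g, %.3g), p = %.3g [%s]\n",
              x$hl_difference, x$ci_low, x$ci_high, x$p_value, x$method))
  invisible(x)
}

arm_summary <- function(ds, arm) {
  d <- ds[ds$included & ds$arm == arm, ]
  c(n = nrow(d),
    m3 = mean(d$value_3mo), s3 = sd(d$value_3mo),
    m6 = mean(d$value_6mo), s6 = sd(d$value_6mo),
    md = mean(d$delta), sdd = sd(d$delta))
}

#' Default report configuration
#'
#' The default report mirrors the trial's outcome table: ten
#' Hodges-Lehmann rows (LDL-C under the imputation and no-imputation rules,
#' HDL-C, systolic and diastolic BP, weight, diet score, physical activity
#' category, anxiety, stages of change) plus four medication-proportion
#' comparisons (statin and antihypertensive use at the 3- and 6-month
#' visits, two-sided Fisher exact test).
#'
#' @param alpha two-sided level for CIs and tests.
#' @param exact_limit see [hodges_lehmann_shift()].
#' @return list used by [analyze_outcomes()] and [subgroup_analysis()].
#' @export
report_config <- function(alpha = 0.05, exact_limit = 10000) {
  list(
    outcomes = list(
      list(outcome = "ldl", mode = "imputation"),
      list(outcome = "ldl", mode = "no_imputation"),
      list(outcome = "hdl", mode = "imputation"),
      list(outcome = "systolic_bp", mode = "imputation"),
      list(outcome = "diastolic_bp", mode = "imputation"),
      list(outcome = "weight", mode = "imputation"),
      list(outcome = "diet", mode = "imputation"),
      list(outcome = "activity", mode = "imputation"),
      list(outcome = "anxiety", mode = "imputation"),
      list(outcome = "stages_of_change", mode = "imputation")
    ),
    medications = list(
      list(column = "on_statin", visit = 2),
      list(column = "on_statin", visit = 3),
      list(column = "on_antihypertensive", visit = 2),
      list(column = "on_antihypertensive", visit = 3)
    ),
    subgroup_outcomes = list(high_grs = c("ldl", "weight", "activity"),
                             positive_med_attitude = "ldl"),
    subgroup_percentile = 0.5,
    alpha = alpha,
    exact_limit = exact_limit,
    arms = c("GRS", "SOC")
  )
}

shift_row <- function(ledger, outcome, mode, config) {
  ds <- apply_carry_forward(ledger, outcome, mode)
  a1 <- config$arms[1]; a2 <- config$arms[2]
  for (a in c(a1, a2)) {
    if (sum(ds$included & ds$arm == a) == 0) {
      stop_grstrial(sprintf("arm %s empty after exclusions for outcome '%s'",
                            a, outcome),
                    "grstrial_analysis_error")
    }
  }
  hl <- hodges_lehmann_shift(ds$delta[ds$included & ds$arm == a1],
                             ds$delta[ds$included & ds$arm == a2],
                             alpha = config$alpha,
                             exact_limit = config$exact_limit,
                             outcome = outcome)
  s1 <- arm_summary(ds, a1); s2 <- arm_summary(ds, a2)
  data.frame(
    outcome = outcome, mode = mode, type = "shift",
    n_grs = s1[["n"]], n_soc = s2[["n"]],
    grs_3mo_mean = s1[["m3"]], grs_3mo_sd = s1[["s3"]],
    grs_6mo_mean = s1[["m6"]], grs_6mo_sd = s1[["s6"]],
    grs_delta_mean = s1[["md"]], grs_delta_sd = s1[["sdd"]],
    soc_3mo_mean = s2[["m3"]], soc_3mo_sd = s2[["s3"]],
    soc_6mo_mean = s2[["m6"]], soc_6mo_sd = s2[["s6"]],
    soc_delta_mean = s2[["md"]], soc_delta_sd = s2[["sdd"]],
    hl_difference = hl$hl_difference, ci_low = hl$ci_low,
    ci_high = hl$ci_high, p_value = hl$p_value,
    prop_grs = NA_real_, prop_soc = NA_real_,
    method = hl$method, error = NA_character_,
    stringsAsFactors = FALSE
  )
}

medication_row <- function(ledger, column, visit, config) {
  v <- ledger$visits
  arm <- ledger$participants$arm[match(v$participant_id,
                                       ledger$participants$participant_id)]
  keep <- v$visit == visit & v$attended & !is.na(v[[column]])
  use <- as.logical(v[[column]][keep])
  a <- factor(arm[keep], levels = config$arms)
  tab <- table(a, factor(use, levels = c(FALSE, TRUE)))
  assert_that(all(rowSums(tab) > 0),
              sprintf("no usable %s data at visit %d in one arm", column, visit),
              "grstrial_analysis_error")
  ft <- fisher.test(tab, alternative = "two.sided")
  data.frame(
    outcome = sprintf("%s_visit%d", sub("^on_", "", column), visit),
    mode = "observed", type = "proportion",
    n_grs = sum(a == config$arms[1]), n_soc = sum(a == config$arms[2]),
    grs_3mo_mean = NA_real_, grs_3mo_sd = NA_real_, grs_6mo_mean = NA_real_,
    grs_6mo_sd = NA_real_, grs_delta_mean = NA_real_, grs_delta_sd = NA_real_,
    soc_3mo_mean = NA_real_, soc_3mo_sd = NA_real_, soc_6mo_mean = NA_real_,
    soc_6mo_sd = NA_real_, soc_delta_mean = NA_real_, soc_delta_sd = NA_real_,
    hl_difference = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = ft$p.value,
    prop_grs = mean(use[a == config$arms[1]]),
    prop_soc = mean(use[a == config$arms[2]]),
    method = "Fisher exact", error = NA_character_,
    stringsAsFactors = FALSE
  )
}

na_row <- function(outcome, mode, type, msg) {
  r <- shiftless_template()
  r$outcome <- outcome; r$mode <- mode; r$type <- type; r$error <- msg
  r
}

shiftless_template <- function() {
  data.frame(outcome = NA_character_, mode = NA_character_,
             type = NA_character_, n_grs = NA_integer_, n_soc = NA_integer_,
             grs_3mo_mean = NA_real_, grs_3mo_sd = NA_real_,
             grs_6mo_mean = NA_real_, grs_6mo_sd = NA_real_,
             grs_delta_mean = NA_real_, grs_delta_sd = NA_real_,
             soc_3mo_mean = NA_real_, soc_3mo_sd = NA_real_,
             soc_6mo_mean = NA_real_, soc_6mo_sd = NA_real_,
             soc_delta_mean = NA_real_, soc_delta_sd = NA_real_,
             hl_difference = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             p_value = NA_real_, prop_grs = NA_real_, prop_soc = NA_real_,
             method = NA_character_, error = NA_character_,
             stringsAsFactors = FALSE)
}

#' Full between-arm outcome report
#'
#' Produces the trial's outcome table: one Hodges-Lehmann shift row per
#' configured outcome (GRS minus standard-of-care difference of 3-to-6-month
#' changes, with rank-sum CI and p-value and per-arm mean +/- SD summaries)
#' and one Fisher-exact row per medication-use comparison. A failure in one
#' outcome is contained: the row carries the error message and the rest of
#' the table is produced. No multiplicity adjustment is applied; the number
#' of comparisons is attached as attribute `n_comparisons`.
#'
#' @param ledger a `trial_ledger`.
#' @param config see [report_config()].
#' @return data.frame of class `trial_report`.
#' @export
analyze_outcomes <- function(ledger, config = report_config()) {
  rows <- lapply(config$outcomes, function(oc) {
    tryCatch(shift_row(ledger, oc$outcome, oc$mode, config),
             grstrial_error = function(e)
               na_row(oc$outcome, oc$mode, "shift", conditionMessage(e)))
  })
  med <- lapply(config$medications, function(mc) {
    tryCatch(medication_row(ledger, mc$column, mc$visit, config),
             grstrial_error = function(e)
               na_row(sprintf("%s_visit%d", sub("^on_", "", mc$column),
                              mc$visit),
                      "observed", "proportion", conditionMessage(e)))
  })
  out <- do.call(rbind, c(rows, med))
  rownames(out) <- NULL
  attr(out, "n_comparisons") <- nrow(out)
  class(out) <- c("trial_report", "data.frame")
  out
}

subset_ledger <- function(ledger, keep_ids) {
  p <- ledger$participants[ledger$participants$participant_id %in% keep_ids, ]
  v <- ledger$visits[ledger$visits$participant_id %in% keep_ids, ]
  rownames(p) <- rownames(v) <- NULL
  structure(list(participants = p, visits = v), class = "trial_ledger")
}

#' Pre-specified subgroup analyses
#'
#' Two subgroups were pre-specified:
#'
#' * `"high_grs"`: participants of the GRS arm whose score percentile exceeds
#'   the reference median (`> 0.5`), compared against the FULL
#'   standard-of-care arm (the control sample sizes are unchanged).
#' * `"positive_med_attitude"`: participants of BOTH arms whose baseline
#'   beliefs-about-medicines Likert aggregate lies strictly above the
#'   within-study median.
#'
#' @param ledger a `trial_ledger` whose participant table carries
#'   `grs_percentile` (for `high_grs`) and whose baseline visit carries
#'   `med_beliefs_likert` (for the attitude split).
#' @param subgroup `"high_grs"` or `"positive_med_attitude"`.
#' @param config see [report_config()]; `config$subgroup_outcomes` selects
#'   the outcomes analyzed per subgroup.
#' @return data.frame of class `trial_report` (shift rows only), with the
#'   subgroup recorded in attribute `subgroup`.
#' @export
subgroup_analysis <- function(ledger,
                              subgroup = c("high_grs", "positive_med_attitude"),
                              config = report_config()) {
  subgroup <- match.arg(subgroup)
  p <- ledger$participants
  if (subgroup == "high_grs") {
    assert_that("grs_percentile" %in% names(p),
                "ledger participants lack grs_percentile",
                "grstrial_validation_error")
    keep_grs <- p$participant_id[p$arm == config$arms[1] &
                                   p$grs_percentile > config$subgroup_percentile]
    if (length(keep_grs) == 0) {
      stop_grstrial("high-GRS subgroup is empty (no GRS-arm percentile > 0.5)",
                    "grstrial_analysis_error")
    }
    keep <- c(keep_grs, p$participant_id[p$arm == config$arms[2]])
  } else {
    base <- ledger$visits[ledger$visits$visit == 1, ]
    agg <- base$med_beliefs_likert[match(p$participant_id,
                                         base$participant_id)]
    assert_that(any(!is.na(agg)),
                "no baseline beliefs-about-medicines aggregates in ledger",
                "grstrial_validation_error")
    med <- median(agg, na.rm = TRUE)
    if (isTRUE(max(agg, na.rm = TRUE) == min(agg, na.rm = TRUE))) {
      stop_grstrial("degenerate attitude split: all Likert aggregates equal",
                    "grstrial_analysis_error")
    }
    keep <- p$participant_id[!is.na(agg) & agg > med]
    if (length(keep) == 0) {
      stop_grstrial("positive-attitude subgroup is empty",
                    "grstrial_analysis_error")
    }
  }
  sub <- subset_ledger(ledger, keep)
  oc_names <- config$subgroup_outcomes[[subgroup]]
  rows <- lapply(oc_names, function(oc) {
    tryCatch(shift_row(sub, oc, "imputation", config),
             grstrial_error = function(e)
               na_row(oc, "imputation", "shift", conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "subgroup") <- subgroup
  class(out) <- c("trial_report", "data.frame")
  out
}

#' @export
print.trial_report <- function(x, digits = 3, ...) {
  sg <- attr(x, "subgroup")
  cat(sprintf("Trial outcome report (%d rows%s)\n", nrow(x),
              if (is.null(sg)) "" else paste0(", subgroup: ", sg)))
  cols <- c("outcome", "mode", "n_grs", "n_soc", "hl_difference",
            "ci_low", "ci_high", "prop_grs", "prop_soc", "p_value")
  print.data.frame(x[, cols], digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write a trial report to CSV and JSON
#'
#' @param report a `trial_report`.
#' @param path_csv,path_json output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) write.csv(report, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(report, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
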