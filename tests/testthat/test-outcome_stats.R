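test_that("lipid carry-forward fills visit 2 from baseline, mode-dependently", {
  led <- mini_ledger(list(P1 = c(150, NA, 120),   # v2 missing -> carried
                          P2 = c(160, 150, 140),  # fully observed
                          P3 = c(155, 150, NA),   # no post-final panel
                          P4 = c(150, NA, 130)),
                     column = "ldl")
  ds <- apply_carry_forward(led, "ldl", mode = "imputation")
  expect_equal(ds$value_3mo[ds$participant_id == "P1"], 150)
  expect_equal(ds$prov_3mo[ds$participant_id == "P1"], "carried_forward")
  expect_equal(ds$delta[ds$participant_id == "P1"], -30)
  expect_true(ds$included[ds$participant_id == "P2"])
  expect_false(ds$included[ds$participant_id == "P3"])
  expect_match(ds$reason[ds$participant_id == "P3"], "final visit")

  # no-imputation mode drops the carried participants, keeping the observed
  ds2 <- apply_carry_forward(led, "ldl", mode = "no_imputation")
  expect_false(ds2$included[ds2$participant_id == "P1"])
  expect_true(ds2$included[ds2$participant_id == "P2"])
  expect_equal(sum(ds$included) - sum(ds2$included), 2)
})

test_that("questionnaire rule carries forward and excludes as stated", {
  led <- mini_ledger(list(P1 = c(3.0, NA, NA),    # missing v2 and v3 -> excluded
                          P2 = c(3.0, 3.5, NA),   # carried v2 -> v3
                          P3 = c(NA, 3.0, 3.5),   # baseline missing, v3 present
                          P4 = c(3.0, NA, 3.5)),  # v2 carried from baseline
                     column = "diet_score")
  ds <- apply_carry_forward(led, "diet")
  expect_false(ds$included[ds$participant_id == "P1"])
  expect_match(ds$reason[ds$participant_id == "P1"], "missing at final visit")
  expect_true(ds$included[ds$participant_id == "P2"])
  expect_equal(ds$value_6mo[ds$participant_id == "P2"], 3.5)
  expect_equal(ds$prov_6mo[ds$participant_id == "P2"], "carried_forward")
  expect_equal(ds$delta[ds$participant_id == "P2"], 0)
  expect_true(ds$included[ds$participant_id == "P3"])
  expect_equal(ds$delta[ds$participant_id == "P4"], 0.5)
  expect_equal(ds$prov_3mo[ds$participant_id == "P4"], "carried_forward")

  # provenance partitions every analyzed value
  anal <- ds[ds$included, ]
  expect_true(all(anal$prov_3mo %in% c("observed", "carried_forward")))
  expect_true(all(anal$prov_6mo %in% c("observed", "carried_forward")))
  # never fabricates: P1 keeps NA values at both follow-ups
  expect_true(all(is.na(ds[!ds$included & ds$participant_id == "P1",
                           c("value_6mo", "delta")])))
})

test_that("hodges_lehmann_shift matches its forced small example", {
  est <- hodges_lehmann_shift(c(1, 2), c(0, 1))
  expect_equal(est$hl_difference, 1)  # pairwise diffs {1, 0, 2, 1}

  est2 <- hodges_lehmann_shift(1:10, 1:10)
  expect_equal(est2$hl_difference, 0)
  expect_gt(est2$p_value, 0.9)
})

test_that("estimator equals the brute-force all-pairs oracle, with ties", {
  set.seed(77)
  for (rep in 1:200) {
    m <- sample(2:30, 1); n <- sample(2:30, 1)
    pool <- if (rep %% 2) sample(-5:5, m + n, TRUE)  # heavy ties
            else rnorm(m + n)
    x <- pool[seq_len(m)]; y <- pool[m + seq_len(n)]
    est <- hodges_lehmann_shift(x, y)
    expect_identical(est$hl_difference, hl_oracle(x, y))
  }
})

test_that("shift estimator is translation-equivariant and antisymmetric", {
  set.seed(15)
  x <- rnorm(12); y <- rnorm(17)
  e0 <- hodges_lehmann_shift(x, y)
  ec <- hodges_lehmann_shift(x + 3.25, y)
  expect_equal(ec$hl_difference, e0$hl_difference + 3.25)
  expect_equal(ec$ci_low, e0$ci_low + 3.25)
  # p for testing shift c against c is invariant
  expect_equal(hodges_lehmann_shift(x + 3.25, y + 3.25)$p_value, e0$p_value)

  swap <- hodges_lehmann_shift(y, x)
  expect_equal(swap$hl_difference, -e0$hl_difference)
  expect_equal(swap$p_value, e0$p_value)
  expect_equal(swap$ci_low, -e0$ci_high)
})

test_that("rank-sum inference agrees with the base-R reference on no-tie data", {
  set.seed(33)
  for (rep in 1:25) {
    x <- rnorm(sample(5:20, 1)); y <- rnorm(sample(5:20, 1), 0.4)
    est <- hodges_lehmann_shift(x, y)
    wt <- wilcox.test(x, y, conf.int = TRUE, exact = TRUE)
    expect_equal(est$p_value, wt$p.value)
    expect_equal(est$hl_difference, unname(wt$estimate))
    expect_equal(c(est$ci_low, est$ci_high), as.numeric(wt$conf.int),
                 tolerance = 1e-12)
  }
})

test_that("analysis errors are raised and contained", {
  expect_error(hodges_lehmann_shift(c(1), c(1, 2), outcome = "ldl"),
               class = "grstrial_analysis_error")
  expect_error(apply_carry_forward(
    mini_ledger(list(P1 = c(1, 1, 1), P2 = c(1, 1, 1))), "bogus"),
    class = "grstrial_config_error")
})

test_that("constructed separation is recovered exactly by the report", {
  # every GRS participant's LDL drops 20, SOC unchanged, no noise
  vals <- list()
  for (i in 1:10) {
    drop <- if (i %% 2 == 1) -20 else 0   # odd ids will be GRS
    vals[[sprintf("P%02d", i)]] <- c(150 + i, 150 + i, 150 + i + drop)
  }
  led <- mini_ledger(vals, column = "ldl",
                     arms = rep(c("GRS", "SOC"), 5))
  est <- hodges_lehmann_shift(
    apply_carry_forward(led, "ldl")$delta[led$participants$arm == "GRS"],
    apply_carry_forward(led, "ldl")$delta[led$participants$arm == "SOC"])
  expect_equal(est$hl_difference, -20)
})

test_that("default report has the full outcome-table shape", {
  sim <- simulate_trial(seed = 2024)
  rep <- analyze_outcomes(sim$ledger)
  expect_equal(nrow(rep), 14)  # 10 shift rows + 4 medication comparisons
  expect_equal(sum(rep$type == "shift"), 10)
  expect_equal(sum(rep$type == "proportion"), 4)
  expect_equal(rep$outcome[1:2], c("ldl", "ldl"))
  expect_equal(rep$mode[1:2], c("imputation", "no_imputation"))
  expect_true(all(is.na(rep$error)))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  shift <- rep[rep$type == "shift", ]
  expect_true(all(shift$ci_low <= shift$hl_difference + 1e-12 &
                    shift$hl_difference <= shift$ci_high + 1e-12))
  expect_equal(attr(rep, "n_comparisons"), 14)
  # the no-imputation LDL row analyzes no more participants than the imputed
  expect_lte(rep$n_grs[2], rep$n_grs[1])
  expect_lte(rep$n_soc[2], rep$n_soc[1])
})

test_that("a failed outcome does not abort the rest of the table", {
  sim <- simulate_trial(trial_sim_config(n_participants = 16), seed = 5)
  # destroy all LDL data
  sim$ledger$visits$ldl <- NA
  rep <- analyze_outcomes(sim$ledger)
  expect_equal(nrow(rep), 14)
  expect_true(all(!is.na(rep$error[rep$outcome == "ldl"])))
  expect_true(any(is.na(rep$error)))
})

test_that("high-GRS subgroup keeps the full comparator arm", {
  sim <- simulate_trial(seed = 404)
  full <- analyze_outcomes(sim$ledger)
  sg <- subgroup_analysis(sim$ledger, "high_grs")
  expect_equal(nrow(sg), 3)
  expect_equal(sg$outcome, c("ldl", "weight", "activity"))
  # SOC n unchanged relative to the full analysis of the same outcome
  expect_equal(sg$n_soc[sg$outcome == "weight"],
               full$n_soc[full$outcome == "weight"])
  expect_lt(sg$n_grs[sg$outcome == "weight"],
            full$n_grs[full$outcome == "weight"])

  # empty subgroup errors
  led2 <- sim$ledger
  led2$participants$grs_percentile <- 0.1
  expect_error(subgroup_analysis(led2, "high_grs"),
               class = "grstrial_analysis_error")
})

test_that("attitude subgroup splits on the within-study median and flags ties", {
  sim <- simulate_trial(seed = 505)
  sg <- subgroup_analysis(sim$ledger, "positive_med_attitude")
  expect_equal(sg$outcome, "ldl")
  base <- sim$ledger$visits[sim$ledger$visits$visit == 1, ]
  med <- median(base$med_beliefs_likert, na.rm = TRUE)
  keep <- base$participant_id[!is.na(base$med_beliefs_likert) &
                                base$med_beliefs_likert > med]
  ds <- apply_carry_forward(sim$ledger, "ldl")
  expected_n <- sum(ds$included & ds$participant_id %in% keep)
  expect_equal(sg$n_grs + sg$n_soc, expected_n)

  led2 <- sim$ledger
  led2$visits$med_beliefs_likert[led2$visits$visit == 1] <- 3
  expect_error(subgroup_analysis(led2, "positive_med_attitude"),
               class = "grstrial_analysis_error")
})
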