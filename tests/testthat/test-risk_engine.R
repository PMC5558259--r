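profile_row <- function(age = 55, sex = "female", total_chol = 200,
                        hdl_chol = 50, systolic_bp = 125, bp_treated = FALSE,
                        smoker = FALSE, diabetes = FALSE) {
  data.frame(age = age, sex = sex, total_chol = total_chol,
             hdl_chol = hdl_chol, systolic_bp = systolic_bp,
             bp_treated = bp_treated, smoker = smoker, diabetes = diabetes,
             stringsAsFactors = FALSE)
}

test_that("10-year engine reproduces the published worked example", {
  # 61-year-old woman, TC 180, HDL 47, SBP 124 untreated, smoker,
  # non-diabetic: published 10-year general-CVD risk 10.48%.
  p <- profile_row(age = 61, sex = "female", total_chol = 180, hdl_chol = 47,
                   systolic_bp = 124, smoker = TRUE)
  expect_equal(framingham_10yr(p), 0.1048, tolerance = 1e-3)
})

fram_risk_for_test <- function(p) framingham_10yr(p)

test_that("all-mean linear predictor returns 1 - baseline survival", {
  tab <- load_coeff_table("cvd10")
  for (sx in c("female", "male")) {
    st <- tab$sex[[sx]]
    # solve for an age that puts LP exactly at the published mean, holding
    # the other covariates at round values
    other <- sum(vapply(st$terms, function(t) {
      if (t$name == "age") return(0)
      x <- switch(t$name, total_chol = 200, hdl_chol = 50, systolic_bp = 125,
                  smoker = 0, diabetes = 0)
      if (!is.null(t$when) && t$when == "bp_treated") return(0)
      if (identical(t$transform, "log")) t$beta * log(x) else t$beta * x
    }, numeric(1)))
    b_age <- st$terms[[1]]$beta
    age <- exp((st$mean_lp - other) / b_age)
    p <- profile_row(age = age, sex = sx, total_chol = 200, hdl_chol = 50,
                     systolic_bp = 125)
    expect_equal(suppressWarnings(fram_risk_for_test(p)),
                 1 - st$baseline_survival, tolerance = 1e-10)
  }
})

test_that("risk is monotone in each covariate in the coefficient's direction", {
  base <- profile_row(sex = "male")
  r0 <- framingham_10yr(base)
  expect_gt(framingham_10yr(profile_row(sex = "male", systolic_bp = 145)), r0)
  expect_gt(framingham_10yr(profile_row(sex = "male", total_chol = 240)), r0)
  expect_lt(framingham_10yr(profile_row(sex = "male", hdl_chol = 70)), r0)
  expect_gt(framingham_10yr(profile_row(sex = "male", smoker = TRUE)), r0)
  expect_gt(framingham_10yr(profile_row(sex = "male", diabetes = TRUE)), r0)
  # sex dispatch uses the other coefficient row
  expect_false(isTRUE(all.equal(r0, framingham_10yr(profile_row(sex = "female")))))
  # 30-year horizon exceeds 10-year for the same profile and is monotone
  expect_gt(framingham_30yr(base), r0)
  expect_gt(framingham_30yr(profile_row(sex = "male", systolic_bp = 145)),
            framingham_30yr(base))
})

test_that("out-of-range covariates warn but still compute", {
  p <- profile_row(age = 95)
  expect_warning(r <- framingham_10yr(p), "supported range")
  expect_true(r > 0 && r < 1)
})

test_that("rr regression is null-calibrated when z is independent of events", {
  set.seed(101)
  n <- 20000
  cohort <- data.frame(event = rbinom(n, 1, 0.08), z = rnorm(n),
                       age = runif(n, 45, 64),
                       sex = sample(c("male", "female"), n, TRUE))
  fit <- fit_rr_regression(cohort)
  expect_gt(fit$ci_high, 1)
  expect_lt(fit$ci_low, 1)
  expect_equal(fit$rr_per_sd, 1, tolerance = 0.05)
  expect_equal(exp(log(fit$rr_per_sd)), fit$rr_per_sd)
  expect_true(fit$ci_low <= fit$rr_per_sd && fit$rr_per_sd <= fit$ci_high)
})

test_that("rr regression recovers an injected per-SD effect", {
  # single large cohort from the generator with truth 1.3
  cfg <- reference_sim_config(n = 50000, true_rr_per_sd = 1.3,
                              weights = synthetic_weights(19, seed = 1))
  ref <- simulate_reference_cohort(cfg, seed = 123)
  fit <- fit_rr_regression(ref$data)
  expect_equal(fit$rr_per_sd, 1.3, tolerance = 0.025)
})

test_that("rr regression refuses degenerate cohorts", {
  cohort <- data.frame(event = 0, z = rnorm(50), age = 50, sex = "male")
  expect_error(fit_rr_regression(cohort), class = "grstrial_fit_error")
})

test_that("update_risk multiplies, caps and is monotone in z", {
  u <- update_risk(0.10, 1.18, z = 1)
  expect_equal(u$updated_10yr, 0.118)
  expect_false(u$capped)

  u0 <- update_risk(0.25, 1.18, z = 0)
  expect_equal(u0$updated_10yr, 0.25)
  expect_equal(u0$genetic_rr, 1)

  # hand evaluation: 0.9 * 1.18^3 = 1.478... -> capped at 1
  u3 <- update_risk(0.9, 1.18, z = 3, cap = 1.0)
  expect_equal(u3$genetic_rr, 1.18^3)
  expect_equal(u3$updated_10yr, 1.0)
  expect_true(u3$capped)

  zs <- seq(-3, 3, by = 0.5)
  ups <- update_risk(rep(0.1, length(zs)), 1.18, zs)$updated_10yr
  expect_true(all(diff(ups) >= 0))

  expect_error(update_risk(1.2, 1.18, 0), class = "grstrial_validation_error")
})
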