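#' Load a Framingham-style coefficient table
#'
#' The risk engine is coefficient-table-driven: a JSON file supplies, per sex,
#' a list of terms (covariate name, transform `log` or `identity`, beta, and
#' an optional `when` condition `bp_treated`/`bp_untreated`), the baseline
#' survival over the table's horizon, and the mean linear predictor of the
#' derivation cohort. Risk is the Cox form `1 - S0 ^ exp(LP - mean_lp)`.
#'
#' Two tables are bundled: `"cvd10"`, the published sex-specific 10-year
#' general-cardiovascular-disease equation (its published female worked
#' example reproduces to 4 decimals), and `"cvd30"`, a clearly flagged
#' synthetic 30-year extrapolation of the same betas under a constant-hazard
#' assumption, used only for the 30-year eligibility branch.
#'
#' @param table `"cvd10"`, `"cvd30"`, or a path to a JSON file of the same
#'   shape.
#' @return list of class `fram_table`.
#' @export
load_coeff_table <- function(table = "cvd10") {
  path <- switch(table,
    cvd10 = system.file("extdata", "framingham_cvd10.json",
                        package = "grstrial", mustWork = TRUE),
    cvd30 = system.file("extdata", "framingham_cvd30_synthetic.json",
                        package = "grstrial", mustWork = TRUE),
    table)
  assert_that(file.exists(path), sprintf("coefficient table not found: %s", path),
              "grstrial_io_error")
  tab <- jsonlite::read_json(path, simplifyVector = FALSE)
  assert_that(all(c("female", "male") %in% names(tab$sex)),
              "coefficient table needs female and male entries",
              "grstrial_format_error")
  class(tab) <- "fram_table"
  tab
}

validate_risk_profile <- function(profile) {
  needed <- c("age", "sex", "total_chol", "hdl_chol", "systolic_bp",
              "bp_treated", "smoker", "diabetes")
  assert_that(all(needed %in% names(profile)),
              sprintf("risk profile needs columns: %s",
                      paste(needed, collapse = ", ")),
              "grstrial_validation_error")
  assert_that(all(profile$sex %in% c("male", "female")),
              "sex must be 'male' or 'female'", "grstrial_validation_error")
  assert_that(all(profile$age >= 20 & profile$age <= 100),
              "age must lie in [20, 100]", "grstrial_validation_error")
  assert_that(all(profile$total_chol > 0) && all(profile$hdl_chol > 0) &&
                all(profile$systolic_bp > 0),
              "lipids and blood pressure must be positive",
              "grstrial_validation_error")
  invisible(profile)
}

fram_linear_predictor <- function(profile, sex_tab) {
  lp <- numeric(nrow(profile))
  for (term in sex_tab$terms) {
    x <- profile[[term$name]]
    assert_that(!is.null(x), sprintf("profile lacks covariate '%s'", term$name),
                "grstrial_validation_error")
    x <- as.numeric(x)
    if (identical(term$transform, "log")) x <- log(x)
    keep <- rep(TRUE, nrow(profile))
    if (!is.null(term$when)) {
      keep <- if (term$when == "bp_treated") as.logical(profile$bp_treated)
              else !as.logical(profile$bp_treated)
    }
    lp <- lp + ifelse(keep, term$beta * x, 0)
  }
  lp
}

fram_risk <- function(profile, coeffs) {
  profile <- as.data.frame(profile)
  validate_risk_profile(profile)
  ranges <- coeffs$supported_ranges
  if (!is.null(ranges)) {
    for (nm in names(ranges)) {
      r <- unlist(ranges[[nm]])
      out <- profile[[nm]] < r[1] | profile[[nm]] > r[2]
      if (any(out)) {
        warning(sprintf("%d value(s) of %s outside the table's supported range [%g, %g]; risk computed anyway",
                        sum(out), nm, r[1], r[2]), call. = FALSE)
      }
    }
  }
  risk <- numeric(nrow(profile))
  for (sx in c("female", "male")) {
    idx <- profile$sex == sx
    if (!any(idx)) next
    st <- coeffs$sex[[sx]]
    lp <- fram_linear_predictor(profile[idx, , drop = FALSE], st)
    risk[idx] <- 1 - st$baseline_survival ^ exp(lp - st$mean_lp)
  }
  pmin(pmax(risk, 0), 1)
}

#' Framingham 10-year risk
#'
#' Computes the 10-year probability of a first cardiovascular event from the
#' classic risk-factor profile using a sex-specific Cox-form coefficient
#' table (`1 - S0 ^ exp(LP - mean_lp)`), clamped to `[0, 1]`. A pure function
#' of its inputs; covariates outside the table's supported range trigger a
#' warning but are still evaluated.
#'
#' @param profile data.frame with columns `age` (years), `sex`
#'   (`"male"`/`"female"`), `total_chol`, `hdl_chol` (mg/dl), `systolic_bp`
#'   (mmHg), `bp_treated`, `smoker`, `diabetes` (logical).
#' @param coeffs a `fram_table`, by default the bundled 10-year table.
#' @return numeric vector of probabilities.
#' @export
framingham_10yr <- function(profile, coeffs = load_coeff_table("cvd10")) {
  fram_risk(profile, coeffs)
}

#' Framingham 30-year risk
#'
#' Same engine as [framingham_10yr()] with the 30-year coefficient table
#' (default: the bundled synthetic constant-hazard extrapolation; see
#' [load_coeff_table()]). Used for the trial's 30-year eligibility branch.
#'
#' @inheritParams framingham_10yr
#' @return numeric vector of probabilities.
#' @export
framingham_30yr <- function(profile, coeffs = load_coeff_table("cvd30")) {
  fram_risk(profile, coeffs)
}

# HC0 sandwich covariance for a glm: bread = model-based vcov,
# meat = crossprod of per-observation score contributions.
glm_sandwich_vcov <- function(fit) {
  X <- stats::model.matrix(fit)
  wres <- stats::residuals(fit, type = "working") * stats::weights(fit, type = "working")
  ef <- X * wres
  br <- vcov(fit)  # dispersion fixed at 1 for the binomial/poisson fits used here
  br %*% crossprod(ef) %*% br
}

#' Fit the adjusted relative-risk regression of incident events on GRS
#'
#' Fits a log-link model for the event probability with the GRS z-score, age,
#' and sex as covariates, so the exponentiated z coefficient is the relative
#' risk per 1 SD of genetic score. The primary fit is log-link binomial
#' (log-binomial); when it fails to converge the engine falls back to a
#' modified Poisson fit. Confidence intervals use robust (HC0 sandwich)
#' standard errors at 95%.
#'
#' @param cohort data.frame with columns `event` (0/1 or logical), `z`
#'   (GRS z-score), `age` (years), `sex` (`"male"`/`"female"` or 0/1).
#' @return Object of class `rr_fit`: `beta_per_sd`, `se_beta`, `rr_per_sd`,
#'   `ci_low`, `ci_high` (RR scale), `model_family`, `n`, `n_events`.
#' @export
fit_rr_regression <- function(cohort) {
  cohort <- as.data.frame(cohort)
  assert_that(all(c("event", "z", "age", "sex") %in% names(cohort)),
              "cohort needs columns event, z, age, sex",
              "grstrial_validation_error")
  cohort$event <- as.integer(as.logical(cohort$event))
  if (!is.numeric(cohort$sex)) {
    cohort$sex_male <- as.integer(cohort$sex == "male")
  } else {
    cohort$sex_male <- as.integer(cohort$sex)
  }
  assert_that(all(is.finite(cohort$z)), "z must be finite",
              "grstrial_validation_error")
  n_ev <- sum(cohort$event)
  assert_that(n_ev >= 1 && n_ev < nrow(cohort),
              "need at least one event and one non-event",
              "grstrial_fit_error")

  form <- event ~ z + age + sex_male
  start <- c(log(max(mean(cohort$event), 1e-6)), 0, 0, 0)
  fit <- tryCatch(
    suppressWarnings(glm(form, data = cohort, family = binomial(link = "log"),
                         start = start)),
    error = function(e) NULL)
  family_used <- "log-binomial"
  if (is.null(fit) || !fit$converged) {
    fit <- tryCatch(
      suppressWarnings(glm(form, data = cohort, family = poisson(link = "log"))),
      error = function(e) NULL)
    family_used <- "modified-poisson"
  }
  if (is.null(fit) || !fit$converged) {
    stop_grstrial(
      sprintf("relative-risk regression failed to converge (n = %d, events = %d)",
              nrow(cohort), n_ev),
      "grstrial_fit_error")
  }
  vc <- glm_sandwich_vcov(fit)
  beta <- unname(coef(fit)["z"])
  se <- sqrt(vc["z", "z"])
  zcrit <- qnorm(0.975)
  out <- list(beta_per_sd = beta, se_beta = se, rr_per_sd = exp(beta),
              ci_low = exp(beta - zcrit * se), ci_high = exp(beta + zcrit * se),
              model_family = family_used, n = nrow(cohort), n_events = n_ev)
  class(out) <- "rr_fit"
  out
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf("Relative risk per 1 SD of GRS: %.3f (95%% CI %.3f, %.3f)\n",
              x$rr_per_sd, x$ci_low, x$ci_high))
  cat(sprintf("  %s fit, n = %d, events = %d\n", x$model_family, x$n, x$n_events))
  invisible(x)
}

#' Genetically updated 10-year risk
#'
#' Multiplies the baseline Framingham 10-year risk by the individual's
#' estimated genetic relative risk `exp(beta_per_sd * z)` and caps the
#' product at `cap` (default 1, since a multiplicative update can exceed a
#' probability's range).
#'
#' @param base_10yr baseline 10-year risk(s) in `[0, 1]`.
#' @param fit an `rr_fit`, or a single relative risk per SD (e.g. `1.18`).
#' @param z GRS z-score(s).
#' @param cap maximum allowed updated risk, in `(0, 1]`.
#' @return data.frame of class `updated_risk` with columns `base_10yr`,
#'   `genetic_rr`, `updated_10yr`, `capped`.
#' @export
update_risk <- function(base_10yr, fit, z, cap = 1.0) {
  assert_that(all(base_10yr >= 0 & base_10yr <= 1),
              "base_10yr must lie in [0, 1]", "grstrial_validation_error")
  assert_that(length(cap) == 1 && cap > 0 && cap <= 1,
              "cap must lie in (0, 1]", "grstrial_validation_error")
  beta <- if (inherits(fit, "rr_fit")) fit$beta_per_sd else log(as.numeric(fit))
  grr <- exp(beta * z)
  raw <- base_10yr * grr
  out <- data.frame(base_10yr = base_10yr, genetic_rr = grr,
                    updated_10yr = pmin(raw, cap), capped = raw > cap)
  class(out) <- c("updated_risk", "data.frame")
  out
}
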