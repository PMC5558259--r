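#' Configuration of the synthetic reference cohort
#'
#' Describes the population the score is normalized against: genotypes in
#' Hardy-Weinberg equilibrium at the score loci, and a binary 10-year
#' incident-CHD indicator whose probability is log-linear in the GRS z-score
#' (the "truth" the relative-risk regression should recover), with additive
#' log-scale age and sex terms.
#'
#' Defaults encode the analysis's stated world: cohort size 8,734, relative
#' risk 1.18 per SD of score. Allele frequencies default to a uniform draw
#' in `[0.1, 0.9]` fixed by the simulation seed (no published frequencies
#' are reproduced); the baseline 10-year event rate at `z = 0` defaults to
#' 0.08, a typical incident-CHD rate for a middle-aged cohort.
#'
#' @param n cohort size.
#' @param weights a `snp_weights` table.
#' @param allele_freqs optional named vector of effect-allele frequencies in
#'   `(0, 1)`; `NULL` draws them uniformly in `[0.1, 0.9]` at simulation
#'   time, deterministically from the seed.
#' @param true_rr_per_sd relative risk per 1 SD of score encoded in the event
#'   model.
#' @param base_event_rate 10-year event probability at `z = 0` for an
#'   average-aged female.
#' @param age_range uniform age range (years).
#' @param sex_ratio probability of male sex.
#' @param beta_age log-risk increment per year of age (centered).
#' @param beta_male log-risk increment for male sex.
#' @return list of class `reference_sim_config`.
#' @export
reference_sim_config <- function(n = 8734,
                                 weights = grs_default_weights(),
                                 allele_freqs = NULL,
                                 true_rr_per_sd = 1.18,
                                 base_event_rate = 0.08,
                                 age_range = c(45, 64),
                                 sex_ratio = 0.5,
                                 beta_age = 0.04,
                                 beta_male = log(2)) {
  assert_that(n >= 2, "reference cohort needs n >= 2", "grstrial_config_error")
  assert_that(true_rr_per_sd > 0, "true_rr_per_sd must be positive",
              "grstrial_config_error")
  assert_that(base_event_rate > 0 && base_event_rate < 1,
              "base_event_rate must lie in (0, 1)", "grstrial_config_error")
  if (!is.null(allele_freqs)) {
    assert_that(all(allele_freqs > 0 & allele_freqs < 1),
                "allele_freqs must lie in (0, 1)", "grstrial_config_error")
  }
  structure(list(n = n, weights = weights, allele_freqs = allele_freqs,
                 true_rr_per_sd = true_rr_per_sd,
                 base_event_rate = base_event_rate, age_range = age_range,
                 sex_ratio = sex_ratio, beta_age = beta_age,
                 beta_male = beta_male),
            class = "reference_sim_config")
}

resolve_allele_freqs <- function(config, seed) {
  if (!is.null(config$allele_freqs)) {
    f <- config$allele_freqs
    assert_that(all(config$weights$rsid %in% names(f)),
                "allele_freqs must name every weight-table rsid",
                "grstrial_config_error")
    return(f[config$weights$rsid])
  }
  with_private_seed(derive_seed(seed, "allele_freqs"),
                    setNames(runif(nrow(config$weights), 0.1, 0.9),
                             config$weights$rsid))
}

simulate_hwe_genotypes <- function(n, freqs, id_prefix = "S") {
  g <- vapply(freqs, function(p) rbinom(n, 2L, p), numeric(n))
  if (n == 1) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(freqs)))
  rownames(g) <- sprintf("%s%04d", id_prefix, seq_len(n))
  g
}

#' Simulate the reference cohort
#'
#' Draws Hardy-Weinberg genotypes at the score loci, computes raw scores and
#' self-normalized z-scores via the scoring module, and samples incident
#' events from `p = min(base_event_rate * true_rr_per_sd^z *
#' exp(beta_age * (age - mean age) + beta_male * male), 1)`. Configurations
#' whose maximum event probability exceeds 1 are rejected before any event is
#' sampled. Deterministic given `(config, seed)`.
#'
#' @param config a `reference_sim_config`.
#' @param seed integer seed.
#' @return list of class `reference_cohort`: `genotypes` (matrix), `data`
#'   (data.frame with `sample_id`, `age`, `sex`, `raw_score`, `allele_count`,
#'   `z`, `event`), `reference` (a `grs_reference`), `allele_freqs`,
#'   `config`.
#' @export
simulate_reference_cohort <- function(config = reference_sim_config(), seed) {
  freqs <- resolve_allele_freqs(config, seed)
  with_private_seed(derive_seed(seed, "reference_cohort"), {
    g <- simulate_hwe_genotypes(config$n, freqs, id_prefix = "REF")
    scores <- compute_raw_grs(g, config$weights)
    ref <- fit_reference(scores$raw_score)
    scores <- normalize_grs(scores, ref)
    age <- runif(config$n, config$age_range[1], config$age_range[2])
    male <- rbinom(config$n, 1L, config$sex_ratio)
    logp <- log(config$base_event_rate) +
      scores$z_score * log(config$true_rr_per_sd) +
      config$beta_age * (age - mean(config$age_range)) +
      config$beta_male * male
    p <- exp(logp)
    if (max(p) > 1) {
      stop_grstrial(sprintf("event probability exceeds 1 (max %.3f) for this configuration; reduce base_event_rate or effect sizes",
                            max(p)),
                    "grstrial_config_error")
    }
    event <- rbinom(config$n, 1L, p)
    dat <- data.frame(sample_id = scores$sample_id, age = age,
                      sex = ifelse(male == 1, "male", "female"),
                      raw_score = scores$raw_score,
                      allele_count = scores$allele_count,
                      z = scores$z_score, percentile = scores$percentile,
                      event = event, stringsAsFactors = FALSE)
    structure(list(genotypes = g, data = dat, reference = ref,
                   allele_freqs = freqs, config = config),
              class = "reference_cohort")
  })
}

default_outcome_params <- function() {
  # mean/sd: baseline scale; delta_sd: SD of the 3-to-6-month change;
  # drift: common per-interval trend; scales follow the trial's printed
  # baseline and change summaries.
  p <- list(
    ldl            = list(mean = 140, sd = 38, delta_sd = 28, drift = -8,
                          kind = "lipid"),
    hdl            = list(mean = 54,  sd = 17, delta_sd = 9,  drift = 0,
                          kind = "lipid"),
    total_chol     = list(mean = 220, sd = 42, delta_sd = 30, drift = -8,
                          kind = "lipid"),
    triglycerides  = list(mean = 150, sd = 90, delta_sd = 60, drift = 0,
                          kind = "lipid"),
    systolic_bp    = list(mean = 129, sd = 18, delta_sd = 13, drift = 0,
                          kind = "clinical"),
    diastolic_bp   = list(mean = 79,  sd = 10, delta_sd = 10, drift = 0,
                          kind = "clinical"),
    weight         = list(mean = 85,  sd = 19, delta_sd = 3.5, drift = 0,
                          kind = "clinical"),
    diet           = list(mean = 3.3, sd = 0.7, delta_sd = 0.8, drift = 0,
                          kind = "questionnaire", range = c(0, 5)),
    activity       = list(mean = 3.6, sd = 1.4, delta_sd = 1.0, drift = 0,
                          kind = "questionnaire", range = c(1, 6),
                          integer = TRUE),
    anxiety        = list(mean = 1.7, sd = 0.4, delta_sd = 0.5, drift = 0,
                          kind = "questionnaire", range = c(1, 4)),
    stages_of_change = list(mean = 4.0, sd = 0.9, delta_sd = 0.8, drift = 0,
                          kind = "questionnaire", range = c(1, 5)),
    med_beliefs    = list(mean = 3.5, sd = 0.8, delta_sd = 0.4, drift = 0,
                          kind = "questionnaire", range = c(1, 5))
  )
  p
}

#' Configuration of the synthetic two-arm trial
#'
#' Describes a three-visit (baseline, 3-month, 6-month) two-arm trial of the
#' stated size: 94 participants randomized in permuted blocks of 8,
#' attendance matching the reported retention (82% at the 3-month visit, 69%
#' at the final visit, monotone dropout), outcome trajectories with
#' between-visit noise SDs on the scale of the reported change summaries,
#' and item-level missingness at attended visits. Arm effects default to
#' zero (a null trial); `arm_effects` shifts the 3-to-6-month change of the
#' GRS arm, and `high_grs_interaction` confines an extra shift to GRS-arm
#' participants above the median score percentile.
#'
#' @param n_participants trial size.
#' @param arm_effects named numeric vector of GRS-arm mean shifts applied to
#'   the 3-to-6-month change (names from [outcome_registry()]).
#' @param high_grs_interaction named numeric vector, extra shift confined to
#'   above-median-percentile GRS-arm participants.
#' @param retention marginal attendance probabilities
#'   `c(visit2 = , visit3 = )` with `visit3 <= visit2`.
#' @param missingness per-kind item-missing probability at attended visits
#'   (`lipid`, `clinical`, `questionnaire`). Defaults are calibrated so the
#'   simulated per-outcome analysis sample sizes land on the scale of the
#'   trial's printed ones: clinic measurements are never item-missing
#'   (the reported BP/weight ns equal the completer counts), lipid panels
#'   are missing ~8% of the time, questionnaires ~35%.
#' @param outcome_params per-outcome list (mean, sd, delta_sd, drift, range);
#'   entries override the defaults.
#' @param weights,allele_freqs score loci, as in [reference_sim_config()].
#' @param block_size randomization block size.
#' @param arm_dropout_or odds multiplier on GRS-arm dropout (1 = none; the
#'   sensitivity knob for arm-differential attrition).
#' @return list of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_participants = 94,
                             arm_effects = numeric(0),
                             high_grs_interaction = numeric(0),
                             retention = c(visit2 = 0.82, visit3 = 0.69),
                             missingness = c(lipid = 0.08, clinical = 0,
                                             questionnaire = 0.35),
                             outcome_params = list(),
                             weights = grs_default_weights(),
                             allele_freqs = NULL,
                             block_size = 8,
                             arm_dropout_or = 1) {
  assert_that(n_participants >= 4, "trial needs at least 4 participants",
              "grstrial_config_error")
  assert_that(all(retention >= 0 & retention <= 1) &&
                retention["visit3"] <= retention["visit2"],
              "retention probabilities must lie in [0, 1] with visit3 <= visit2",
              "grstrial_config_error")
  assert_that(all(missingness >= 0 & missingness <= 1),
              "missingness probabilities must lie in [0, 1]",
              "grstrial_config_error")
  params <- default_outcome_params()
  for (nm in names(outcome_params)) {
    assert_that(nm %in% names(params),
                sprintf("unknown outcome '%s' in outcome_params", nm),
                "grstrial_config_error")
    params[[nm]] <- modifyList(params[[nm]], outcome_params[[nm]])
  }
  for (p in params) assert_that(p$sd > 0 && p$delta_sd > 0,
                                "outcome SDs must be positive",
                                "grstrial_config_error")
  bad <- setdiff(names(arm_effects), names(params))
  assert_that(length(bad) == 0,
              sprintf("arm_effects names unknown: %s", paste(bad, collapse = ", ")),
              "grstrial_config_error")
  structure(list(n_participants = n_participants, arm_effects = arm_effects,
                 high_grs_interaction = high_grs_interaction,
                 retention = retention, missingness = missingness,
                 outcome_params = params, weights = weights,
                 allele_freqs = allele_freqs, block_size = block_size,
                 arm_dropout_or = arm_dropout_or),
            class = "trial_sim_config")
}

clamp_outcome <- function(x, p) {
  if (!is.null(p$range)) x <- pmin(pmax(x, p$range[1]), p$range[2])
  if (isTRUE(p$integer)) x <- round(x)
  x
}

sample_eligible_covariates <- function(n) {
  # Table-1-like screening population; rejection-sample until Framingham
  # eligibility (6% 10-yr inclusive OR >20% 30-yr) holds by construction.
  c10 <- load_coeff_table("cvd10")
  c30 <- load_coeff_table("cvd30")
  draw <- function(k) {
    data.frame(
      age = pmin(pmax(rnorm(k, 57, 9), 35), 80),
      sex = ifelse(rbinom(k, 1, 0.57) == 1, "male", "female"),
      total_chol = pmax(rnorm(k, 220, 42), 110),
      hdl_chol = pmax(rnorm(k, 53, 17), 22),
      systolic_bp = pmax(rnorm(k, 129, 18), 92),
      bp_treated = rbinom(k, 1, 0.30) == 1,
      smoker = rbinom(k, 1, 0.15) == 1,
      diabetes = rbinom(k, 1, 0.06) == 1,
      weight = pmax(rnorm(k, 85, 19), 45),
      ethnicity = sample(c("White", "South-Asian", "Hispanic/Latino"),
                         k, replace = TRUE, prob = c(0.80, 0.08, 0.12)),
      stringsAsFactors = FALSE)
  }
  out <- NULL
  for (round in 1:200) {
    cand <- draw(2 * n)
    r10 <- suppressWarnings(framingham_10yr(cand, c10))
    r30 <- suppressWarnings(framingham_30yr(cand, c30))
    elig <- check_eligibility(r10, r30, cand$ethnicity)$eligible
    cand$risk_10yr <- r10
    cand$risk_30yr <- r30
    out <- rbind(out, cand[elig, ])
    if (nrow(out) >= n) return(out[seq_len(n), ])
  }
  stop_grstrial("could not sample enough eligible covariate profiles",
                "grstrial_config_error")
}

#' Simulate a full two-arm trial
#'
#' Generates genotypes, scores (normalized against `ref`), eligible
#' covariates, permuted-block arm assignments, three visits of outcome
#' measurements with monotone dropout and item missingness, and assembles
#' the trial ledger. The outcome model is `visit2 = baseline + drift +
#' noise` and `visit3 = visit2 + drift + arm effect (+ high-GRS interaction)
#' + noise`, with the between-visit noise SD equal to the configured
#' `delta_sd`, so injected arm effects translate directly into the
#' 3-to-6-month change analyzed downstream. Deterministic given
#' `(config, seed)`.
#'
#' @param config a `trial_sim_config`.
#' @param ref a `grs_reference` for percentile lookup, or `NULL` to use the
#'   analytic Hardy-Weinberg reference implied by the allele frequencies
#'   (mean `sum(2 w p)`, SD `sqrt(sum(2 w^2 p (1 - p)))`, normal
#'   percentiles).
#' @param rr_fit optional `rr_fit` used to attach updated risks to the
#'   participant table (skipped when `NULL`).
#' @param seed integer seed.
#' @return list of class `trial_simulation`: `ledger` (a `trial_ledger`),
#'   `assignments`, `genotypes`, `participants`, `allele_freqs`, `config`.
#' @export
simulate_trial <- function(config = trial_sim_config(), ref = NULL,
                           rr_fit = NULL, seed) {
  freqs <- resolve_allele_freqs(config, seed)
  if (is.null(ref)) {
    w <- config$weights$weight
    ref <- structure(list(mean_raw = sum(2 * w * freqs),
                          sd_raw = sqrt(sum(2 * w^2 * freqs * (1 - freqs))),
                          n_ref = Inf, sorted_scores = NULL),
                     class = "grs_reference")
  }
  n <- config$n_participants
  with_private_seed(derive_seed(seed, "trial"), {
    g <- simulate_hwe_genotypes(n, freqs, id_prefix = "PT")
    scores <- normalize_grs(compute_raw_grs(g, config$weights), ref)
    cov <- sample_eligible_covariates(n)
    cov$participant_id <- rownames(g)

    assign <- permuted_block_randomize(cov$participant_id,
                                       block_size = config$block_size,
                                       seed = derive_seed(seed, "blocks"))
    arm <- assign$arm
    high <- scores$percentile > 0.5

    # Monotone dropout: completer / 3-month-only / baseline-only.
    p3 <- unname(config$retention["visit3"])
    p2 <- unname(config$retention["visit2"])
    if (config$arm_dropout_or != 1) {
      odds <- function(p) p / (1 - p)
      adj <- function(p, or) {
        o <- odds(p) / or
        o / (1 + o)
      }
      p3i <- ifelse(arm == "GRS", adj(p3, config$arm_dropout_or), p3)
      p2i <- pmax(ifelse(arm == "GRS", adj(p2, config$arm_dropout_or), p2), p3i)
    } else {
      p3i <- rep(p3, n); p2i <- rep(p2, n)
    }
    u <- runif(n)
    attends3 <- u < p3i
    attends2 <- u < p2i   # completers are a subset of 3-month attendees

    params <- config$outcome_params
    visits <- NULL
    values <- list()
    for (nm in names(params)) {
      p <- params[[nm]]
      eff <- unname(config$arm_effects[nm])
      if (length(eff) == 0 || is.na(eff)) eff <- 0
      ieff <- unname(config$high_grs_interaction[nm])
      if (length(ieff) == 0 || is.na(ieff)) ieff <- 0
      base <- if (nm == "weight") cov$weight else rnorm(n, p$mean, p$sd)
      v2 <- base + p$drift + rnorm(n, 0, p$delta_sd)
      v3 <- v2 + p$drift + (arm == "GRS") * eff +
        (arm == "GRS" & high) * ieff + rnorm(n, 0, p$delta_sd)
      values[[nm]] <- lapply(list(base, v2, v3),
                             function(x) clamp_outcome(x, p))
    }

    # Medication flags with persistence across visits.
    statin <- matrix(FALSE, n, 3)
    antihtn <- matrix(FALSE, n, 3)
    statin[, 1] <- runif(n) < 0.12
    antihtn[, 1] <- cov$bp_treated
    for (k in 2:3) {
      statin[, k] <- ifelse(statin[, k - 1], runif(n) < 0.92,
                            runif(n) < 0.12)
      antihtn[, k] <- ifelse(antihtn[, k - 1], runif(n) < 0.95,
                             runif(n) < 0.06)
    }

    reg <- outcome_registry()
    rows <- vector("list", 3L)
    for (k in 1:3) {
      attended <- if (k == 1) rep(TRUE, n) else if (k == 2) attends2 else attends3
      vr <- data.frame(participant_id = cov$participant_id, visit = k,
                       attended = attended, stringsAsFactors = FALSE)
      for (nm in names(params)) {
        col <- reg$column[reg$outcome == nm]
        val <- values[[nm]][[k]]
        pm <- unname(config$missingness[params[[nm]]$kind])
        # med_beliefs is administered at baseline only
        if (nm == "med_beliefs" && k > 1) {
          val[] <- NA
        } else {
          drop_item <- runif(n) < pm
          val[drop_item] <- NA
        }
        val[!attended] <- NA
        vr[[col]] <- val
      }
      vr$on_statin <- ifelse(attended, statin[, k], NA)
      vr$on_antihypertensive <- ifelse(attended, antihtn[, k], NA)
      rows[[k]] <- vr
    }
    visit_records <- do.call(rbind, rows)

    ptab <- data.frame(participant_id = cov$participant_id,
                       age = cov$age, sex = cov$sex,
                       ethnicity = cov$ethnicity,
                       risk_10yr = cov$risk_10yr, risk_30yr = cov$risk_30yr,
                       grs_raw = scores$raw_score,
                       grs_allele_count = scores$allele_count,
                       grs_z = scores$z_score,
                       grs_percentile = scores$percentile,
                       stringsAsFactors = FALSE)
    if (!is.null(rr_fit)) {
      ur <- update_risk(ptab$risk_10yr, rr_fit, ptab$grs_z)
      ptab$genetic_rr <- ur$genetic_rr
      ptab$updated_10yr <- ur$updated_10yr
    }
    ledger <- assemble_ledger(assign, visit_records, ptab)
    structure(list(ledger = ledger, assignments = assign, genotypes = g,
                   participants = ledger$participants,
                   allele_freqs = freqs, config = config),
              class = "trial_simulation")
  })
}

#' Write a deterministic fixture suite
#'
#' Writes a small, fully deterministic bundle of plain-text fixtures: the
#' bundled weight table, a 10-sample genotype TSV and an equivalent VCF, a
#' reference-distribution summary JSON, a 94-participant simulated trial
#' (visits, participants, assignments CSVs), and a MANIFEST with MD5
#' checksums. Same seed, byte-identical files.
#'
#' @param out_dir writable directory (created if absent).
#' @param seed integer seed.
#' @return invisibly, a named vector of file paths.
#' @export
make_fixture_suite <- function(out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  weights <- grs_default_weights()
  paths <- c(weights = file.path(out_dir, "weights.tsv"),
             genotypes_tsv = file.path(out_dir, "genotypes.tsv"),
             genotypes_vcf = file.path(out_dir, "genotypes.vcf"),
             reference = file.path(out_dir, "reference.json"),
             visits = file.path(out_dir, "trial_visits.csv"),
             participants = file.path(out_dir, "trial_participants.csv"),
             assignments = file.path(out_dir, "trial_assignments.csv"),
             manifest = file.path(out_dir, "MANIFEST.md"))

  file.copy(system.file("extdata", "grs19_weights.tsv", package = "grstrial"),
            paths["weights"], overwrite = TRUE)

  freqs <- with_private_seed(derive_seed(seed, "allele_freqs"),
                             setNames(runif(nrow(weights), 0.1, 0.9),
                                      weights$rsid))
  g <- with_private_seed(derive_seed(seed, "fixture_genotypes"),
                         simulate_hwe_genotypes(10, freqs, id_prefix = "FX"))
  gt_df <- data.frame(sample_id = rownames(g), g, check.names = FALSE,
                      stringsAsFactors = FALSE)
  write.table(gt_df, paths["genotypes_tsv"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fixture_vcf(g, weights, paths["genotypes_vcf"])

  w <- weights$weight
  ref <- list(mean_raw = sum(2 * w * freqs),
              sd_raw = sqrt(sum(2 * w^2 * freqs * (1 - freqs))),
              n_ref = 8734)
  jsonlite::write_json(ref, paths["reference"], auto_unbox = TRUE, digits = NA)

  sim <- simulate_trial(trial_sim_config(allele_freqs = freqs), seed = seed)
  num_round <- function(df) {
    for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- round(df[[nm]], 6)
    df
  }
  write.csv(num_round(sim$ledger$visits), paths["visits"], row.names = FALSE)
  write.csv(num_round(sim$participants), paths["participants"], row.names = FALSE)
  write.csv(sim$assignments, paths["assignments"], row.names = FALSE)

  sums <- md5sum(unname(paths[names(paths) != "manifest"]))
  manifest <- c("# Fixture suite", "",
                sprintf("Generated with seed %d. Expected MD5 checksums:", seed),
                "",
                sprintf("- `%s`: `%s`", basename(names(sums)), unname(sums)))
  writeLines(manifest, paths["manifest"])
  invisible(paths)
}

# Minimal VCF writer for the fixture suite: one biallelic record per score
# SNP, REF = other allele, ALT = effect allele, GT encodes the dosage.
write_fixture_vcf <- function(g, weights, path) {
  samples <- rownames(g)
  header <- c("##fileformat=VCFv4.2",
              "##source=grstrial_fixture",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gt_string <- function(d) c("0/0", "0/1", "1/1")[d + 1]
  body <- vapply(seq_len(nrow(weights)), function(i) {
    rs <- weights$rsid[i]
    paste(c("1", as.character(1000 + i), rs, weights$other_allele[i],
            weights$effect_allele[i], ".", "PASS", ".", "GT",
            gt_string(g[, rs])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}
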