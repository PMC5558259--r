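#' Default eligibility thresholds and allowed ethnicities
#'
#' The trial enrolled participants with at least a 6% 10-year risk (inclusive
#' boundary) OR more than a 20% 30-year risk (strict boundary), restricted to
#' the race/ethnic groups for which the score's risk alleles were validated,
#' and free of a list of exclusions (prior atherosclerotic disease, active
#' statin therapy, prior genetic testing, limiting conditions, short
#' anticipated survival).
#'
#' @return list with `risk_10yr_min`, `risk_30yr_min`, `allowed_ethnicities`,
#'   `known_exclusions`.
#' @export
eligibility_defaults <- function() {
  list(
    risk_10yr_min = 0.06,
    risk_30yr_min = 0.20,
    allowed_ethnicities = c("White", "South-Asian", "Hispanic/Latino"),
    known_exclusions = c(
      "prior MI", "angina", "CABG", "PCI", "stroke",
      "peripheral arterial disease", "active statin therapy",
      "prior genetic testing", "limiting condition", "survival <1 year")
  )
}

#' Screen trial eligibility
#'
#' A profile is eligible iff (`risk_10yr >= 6%` OR `risk_30yr > 20%`) AND its
#' ethnicity is in the allowed set AND it carries no exclusion flags. The
#' 10-year boundary is inclusive and the 30-year boundary strict, following
#' the enrollment wording. Risks must be computed without genetic
#' information.
#'
#' @param risk_10yr,risk_30yr probabilities in `[0, 1]` (vectors).
#' @param ethnicity character vector.
#' @param exclusions a character vector (one participant) or a list of
#'   character vectors of exclusion flags; empty means none.
#' @param rules threshold/allowed-set configuration, see
#'   [eligibility_defaults()].
#' @return data.frame with columns `eligible` (logical) and `reasons`
#'   (list column enumerating every failed criterion).
#' @export
check_eligibility <- function(risk_10yr, risk_30yr, ethnicity,
                              exclusions = list(),
                              rules = eligibility_defaults()) {
  n <- length(risk_10yr)
  assert_that(length(risk_30yr) == n && length(ethnicity) == n,
              "risk and ethnicity vectors must have equal length",
              "grstrial_validation_error")
  assert_that(all(risk_10yr >= 0 & risk_10yr <= 1) &&
                all(risk_30yr >= 0 & risk_30yr <= 1),
              "risks must lie in [0, 1]", "grstrial_validation_error")
  if (is.character(exclusions)) exclusions <- list(exclusions)
  if (length(exclusions) == 0) exclusions <- rep(list(character(0)), n)
  assert_that(length(exclusions) == n,
              "exclusions must be a list with one entry per participant",
              "grstrial_validation_error")

  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character(0)
    if (!(risk_10yr[i] >= rules$risk_10yr_min ||
          risk_30yr[i] > rules$risk_30yr_min)) {
      r <- c(r, sprintf("risk below threshold (10-yr %.1f%% < %.0f%% and 30-yr %.1f%% <= %.0f%%)",
                        100 * risk_10yr[i], 100 * rules$risk_10yr_min,
                        100 * risk_30yr[i], 100 * rules$risk_30yr_min))
    }
    if (!(ethnicity[i] %in% rules$allowed_ethnicities)) {
      r <- c(r, sprintf("ethnicity '%s' not in allowed set", ethnicity[i]))
    }
    if (length(exclusions[[i]])) {
      r <- c(r, exclusions[[i]])
    }
    reasons[[i]] <- r
  }
  data.frame(eligible = lengths(reasons) == 0,
             reasons = I(reasons))
}

#' Permuted-block randomization
#'
#' Allocates participants to two arms in fixed-size blocks, each block an
#' independent uniform permutation of `block_size / 2` copies of each arm, so
#' imbalance during accrual never exceeds `block_size / 2`. A trailing
#' incomplete block uses the leading entries of one more full permuted block.
#' Deterministic given `seed`; the RNG state of the caller is untouched.
#'
#' @param ids ordered vector of participant ids (enrollment order).
#' @param block_size even integer >= 2 (trial default 8).
#' @param seed integer seed.
#' @param arms length-2 character vector of arm labels.
#' @return data.frame of class `trial_assignments`: `participant_id`, `arm`,
#'   `sequence_index`, `block_index`.
#' @export
permuted_block_randomize <- function(ids, block_size = 8, seed,
                                     arms = c("GRS", "SOC")) {
  assert_that(length(block_size) == 1 && block_size >= 2 &&
                block_size %% 2 == 0,
              "block_size must be an even integer >= 2",
              "grstrial_config_error")
  assert_that(length(arms) == 2 && !anyDuplicated(arms),
              "exactly two distinct arm labels required",
              "grstrial_config_error")
  assert_that(!anyDuplicated(ids), "participant ids must be unique",
              "grstrial_validation_error")
  n <- length(ids)
  n_blocks <- ceiling(n / block_size)
  alloc <- with_private_seed(derive_seed(seed, "randomization"), {
    unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(arms, each = block_size / 2))
    }))
  })[seq_len(n)]
  out <- data.frame(participant_id = ids, arm = alloc,
                    sequence_index = seq_len(n),
                    block_index = (seq_len(n) - 1) %/% block_size + 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_assignments", "data.frame")
  out
}

visit_value_columns <- function() {
  c("ldl", "hdl", "total_chol", "triglycerides", "systolic_bp",
    "diastolic_bp", "weight", "on_statin", "on_antihypertensive",
    "diet_score", "activity_category", "anxiety_score", "stages_of_change",
    "med_beliefs_likert")
}

validate_visit_records <- function(vr) {
  assert_that(all(c("participant_id", "visit", "attended") %in% names(vr)),
              "visit records need participant_id, visit, attended",
              "grstrial_validation_error")
  assert_that(all(vr$visit %in% 1:3), "visit must be 1, 2 or 3",
              "grstrial_validation_error")
  if ("diet_score" %in% names(vr)) {
    assert_that(all(is.na(vr$diet_score) |
                      (vr$diet_score >= 0 & vr$diet_score <= 5)),
                "diet_score must lie in [0, 5]", "grstrial_validation_error")
  }
  if ("activity_category" %in% names(vr)) {
    assert_that(all(is.na(vr$activity_category) |
                      vr$activity_category %in% 1:6),
                "activity_category must be an integer 1-6",
                "grstrial_validation_error")
  }
  invisible(vr)
}

#' Assemble the three-visit trial ledger
#'
#' Joins arm assignments, participant-level covariates and visit records into
#' a complete participant-by-visit grid (3 slots per participant; slots with
#' no record are marked unattended with all measurements missing).
#'
#' @param assignments a `trial_assignments` data.frame.
#' @param visit_records data.frame of visit measurements (columns
#'   `participant_id`, `visit`, `attended`, plus any of
#'   `r paste(visit_value_columns(), collapse = ", ")`).
#' @param participants optional data.frame of participant-level fields
#'   (`participant_id` plus e.g. `grs_z`, `grs_percentile`).
#' @return Object of class `trial_ledger`: list with `participants` (one row
#'   per participant, including `arm`) and `visits` (the complete grid).
#' @export
assemble_ledger <- function(assignments, visit_records, participants = NULL) {
  validate_visit_records(visit_records)
  orphan <- setdiff(visit_records$participant_id, assignments$participant_id)
  assert_that(length(orphan) == 0,
              sprintf("visit records for unknown participant(s): %s",
                      paste(orphan, collapse = ", ")),
              "grstrial_linkage_error")
  assert_that(!anyDuplicated(paste(visit_records$participant_id,
                                   visit_records$visit)),
              "duplicate (participant, visit) records",
              "grstrial_validation_error")

  grid <- expand.grid(participant_id = assignments$participant_id,
                      visit = 1:3, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(match(grid$participant_id, assignments$participant_id),
                     grid$visit), ]
  for (col in setdiff(visit_value_columns(), names(visit_records))) {
    visit_records[[col]] <- NA
  }
  key_g <- paste(grid$participant_id, grid$visit)
  key_v <- paste(visit_records$participant_id, visit_records$visit)
  idx <- match(key_g, key_v)
  visits <- cbind(grid,
                  visit_records[idx, c("attended", visit_value_columns()),
                                drop = FALSE])
  visits$attended[is.na(visits$attended)] <- FALSE
  rownames(visits) <- NULL

  ptab <- data.frame(participant_id = assignments$participant_id,
                     arm = assignments$arm, stringsAsFactors = FALSE)
  if (!is.null(participants)) {
    assert_that("participant_id" %in% names(participants),
                "participants table needs participant_id",
                "grstrial_validation_error")
    # the assignment's arm is authoritative; drop any duplicate columns
    participants <- participants[, c("participant_id",
                                     setdiff(names(participants),
                                             names(ptab))), drop = FALSE]
    ptab <- merge(ptab, participants, by = "participant_id", sort = FALSE)
    ptab <- ptab[match(assignments$participant_id, ptab$participant_id), ]
  }
  rownames(ptab) <- NULL
  structure(list(participants = ptab, visits = visits),
            class = "trial_ledger")
}

#' Attrition summary of a trial ledger
#'
#' @param ledger a `trial_ledger`.
#' @return data.frame of attendance counts and fractions by arm and visit.
#' @export
attrition_summary <- function(ledger) {
  v <- merge(ledger$visits, ledger$participants[, c("participant_id", "arm")],
             by = "participant_id")
  agg <- aggregate(attended ~ arm + visit, data = v, FUN = sum)
  ntab <- table(ledger$participants$arm)
  agg$n <- as.integer(ntab[agg$arm])
  agg$fraction <- agg$attended / agg$n
  agg[order(agg$visit, agg$arm), ]
}

#' @export
print.trial_ledger <- function(x, ...) {
  cat(sprintf("Trial ledger: %d participants (%s), %d visit slots\n",
              nrow(x$participants),
              paste(sprintf("%s n=%d", names(table(x$participants$arm)),
                            table(x$participants$arm)), collapse = ", "),
              nrow(x$visits)))
  invisible(x)
}
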