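#' Load a SNP weight table
#'
#' Reads the tab-separated table defining the loci of the genetic risk score:
#' one row per SNP with its rsid, effect allele (the allele whose dosage is
#' multiplied by the weight), other allele, per-allele log odds ratio weight,
#' and an optional `proxy_for` rsid when the genotyped SNP stands in for an
#' unavailable index SNP. Lines starting with `#` are comments.
#'
#' @param path path to a TSV file with header columns `rsid`, `effect_allele`,
#'   `other_allele`, `weight`, `proxy_for`.
#' @return A `data.frame` of class `snp_weights`.
#' @seealso [grs_default_weights()] for the bundled 19-SNP coronary artery
#'   disease table.
#' @export
load_weight_table <- function(path) {
  assert_that(file.exists(path), sprintf("weight table not found: %s", path),
              "grstrial_io_error")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  needed <- c("rsid", "effect_allele", "other_allele", "weight", "proxy_for")
  assert_that(all(needed %in% names(tab)),
              sprintf("weight table must have columns: %s",
                      paste(needed, collapse = ", ")),
              "grstrial_format_error")
  tab <- tab[, needed]
  tab$weight <- suppressWarnings(as.numeric(tab$weight))
  tab$proxy_for[is.na(tab$proxy_for)] <- ""
  if (nrow(tab) == 0L) {
    class(tab) <- c("snp_weights", "data.frame")
    return(tab)
  }
  assert_that(!anyDuplicated(tab$rsid),
              sprintf("duplicate rsid in weight table: %s",
                      paste(unique(tab$rsid[duplicated(tab$rsid)]), collapse = ", ")),
              "grstrial_format_error")
  assert_that(all(is.finite(tab$weight)),
              "weight table has missing or non-finite weights",
              "grstrial_format_error")
  assert_that(all(tab$effect_allele != tab$other_allele),
              "effect_allele must differ from other_allele",
              "grstrial_format_error")
  rownames(tab) <- NULL
  class(tab) <- c("snp_weights", "data.frame")
  tab
}

#' Bundled 19-SNP coronary artery disease weight table
#'
#' The default score uses 19 SNPs associated with coronary artery disease
#' independent of traditional risk factors, six of them proxies for
#' unavailable index SNPs. The source study does not print the numeric
#' log odds ratio weights or the alleles, so the bundled values are
#' SYNTHETIC PLACEHOLDERS of realistic magnitude (log-OR about 0.05-0.25):
#' the locus list and proxy structure are real, the numbers are not published
#' effect sizes. Supply your own table via [load_weight_table()] for any
#' substantive use.
#'
#' @return A `snp_weights` data.frame with 19 rows.
#' @export
grs_default_weights <- function() {
  load_weight_table(system.file("extdata", "grs19_weights.tsv",
                                package = "grstrial", mustWork = TRUE))
}

#' Read a sample-by-SNP genotype dosage matrix from TSV
#'
#' Rows are samples, columns are rsids; cells are counts of the effect allele
#' in `{0, 1, 2}` or `NA`. The first column must be `sample_id`.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with sample ids as rownames, rsids as colnames.
#' @export
read_genotype_tsv <- function(path) {
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  assert_that(names(tab)[1] == "sample_id",
              "genotype TSV must have sample_id as its first column",
              "grstrial_format_error")
  g <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- tab$sample_id
  validate_dosages(g)
  g
}

validate_dosages <- function(g) {
  ok <- is.na(g) | g %in% c(0, 1, 2)
  assert_that(all(ok), "dosages must be 0, 1, 2 or NA",
              "grstrial_validation_error")
  assert_that(!is.null(rownames(g)) && !is.null(colnames(g)),
              "genotype matrix needs sample rownames and rsid colnames",
              "grstrial_validation_error")
  invisible(g)
}

#' Compute the raw weighted genetic risk score
#'
#' For each sample, `raw_score` is the weighted sum of effect-allele dosages
#' over the weight table, and `allele_count` is the unweighted sum (the
#' "number of high-risk alleles"). Dosages always count effect alleles;
#' orientation against VCF REF/ALT is resolved upstream by
#' [read_genotypes_vcf()].
#'
#' Missing dosages are an error under `missing_policy = "error"`. Under
#' `"mean_impute"` a missing dosage at locus *i* is replaced by
#' `2 * allele_freqs[i]` (the Hardy-Weinberg expectation) in `raw_score`,
#' and `n_missing_imputed` is incremented; `allele_count` sums observed
#' dosages only, so it stays an integer.
#'
#' @param genotypes numeric matrix (samples x rsids, values 0/1/2/NA) as from
#'   [read_genotype_tsv()] or [read_genotypes_vcf()].
#' @param weights a `snp_weights` table.
#' @param missing_policy `"error"` or `"mean_impute"`.
#' @param allele_freqs named vector of reference effect-allele frequencies,
#'   required by `"mean_impute"` for any locus with gaps.
#' @return A `data.frame` of class `grs_result` with columns `sample_id`,
#'   `raw_score`, `allele_count`, `n_missing_imputed` (plus `z_score` and
#'   `percentile` after [normalize_grs()]).
#' @export
compute_raw_grs <- function(genotypes, weights,
                            missing_policy = c("error", "mean_impute"),
                            allele_freqs = NULL) {
  missing_policy <- match.arg(missing_policy)
  assert_that(inherits(weights, "snp_weights"),
              "weights must come from load_weight_table()",
              "grstrial_validation_error")
  assert_that(nrow(weights) > 0L, "weight table is empty; nothing to score",
              "grstrial_validation_error")
  validate_dosages(genotypes)

  absent <- setdiff(weights$rsid, colnames(genotypes))
  if (length(absent)) {
    if (missing_policy == "error") {
      stop_grstrial(sprintf("genotypes missing score SNPs: %s",
                            paste(absent, collapse = ", ")),
                    "grstrial_missing_data_error")
    }
    pad <- matrix(NA_real_, nrow(genotypes), length(absent),
                  dimnames = list(rownames(genotypes), absent))
    genotypes <- cbind(genotypes, pad)
  }
  g <- genotypes[, weights$rsid, drop = FALSE]
  miss <- is.na(g)
  if (any(miss)) {
    if (missing_policy == "error") {
      stop_grstrial("missing dosages under missing_policy = 'error'",
                    "grstrial_missing_data_error")
    }
    assert_that(!is.null(allele_freqs) &&
                  all(weights$rsid[colSums(miss) > 0] %in% names(allele_freqs)),
                "mean_impute needs allele_freqs for every locus with gaps",
                "grstrial_validation_error")
    f <- allele_freqs[weights$rsid]
    assert_that(all(f[colSums(miss) > 0] > 0 & f[colSums(miss) > 0] < 1,
                    na.rm = TRUE),
                "allele_freqs must lie in (0, 1)", "grstrial_validation_error")
  }
  g_imp <- g
  if (any(miss)) {
    fill <- matrix(rep(2 * allele_freqs[weights$rsid], each = nrow(g)),
                   nrow = nrow(g))
    g_imp[miss] <- fill[miss]
  }
  res <- data.frame(
    sample_id = rownames(g),
    raw_score = as.numeric(g_imp %*% weights$weight),
    allele_count = as.integer(rowSums(g, na.rm = TRUE)),
    n_missing_imputed = as.integer(rowSums(miss)),
    stringsAsFactors = FALSE
  )
  class(res) <- c("grs_result", "data.frame")
  res
}

#' Fit a reference distribution from raw scores
#'
#' Summarizes a reference cohort's raw scores into the mean/SD used for
#' z-scoring (sample SD, n - 1 denominator) and keeps the sorted empirical
#' distribution for percentile lookup.
#'
#' @param scores numeric vector of raw scores (length >= 2, finite,
#'   non-constant).
#' @return An object of class `grs_reference`: list with `mean_raw`, `sd_raw`,
#'   `n_ref`, `sorted_scores`.
#' @export
fit_reference <- function(scores) {
  scores <- as.numeric(scores)
  assert_that(length(scores) >= 2 && all(is.finite(scores)),
              "need at least 2 finite reference scores",
              "grstrial_degenerate_reference_error")
  s <- sd(scores)
  assert_that(s > 0, "reference scores are constant (zero variance)",
              "grstrial_degenerate_reference_error")
  structure(list(mean_raw = mean(scores), sd_raw = s,
                 n_ref = length(scores), sorted_scores = sort(scores)),
            class = "grs_reference")
}

#' Normalize raw scores against a reference distribution
#'
#' Fills `z_score = (raw - mean_raw) / sd_raw` and `percentile`, the fraction
#' of reference scores strictly below the raw score (in `[0, 1]`). When the
#' reference carries no empirical distribution, the percentile falls back to
#' the normal approximation `pnorm(z)`.
#'
#' @param result a `grs_result` from [compute_raw_grs()].
#' @param ref a `grs_reference` from [fit_reference()] (or a list with
#'   `mean_raw`, `sd_raw`, `n_ref` and optionally `sorted_scores`).
#' @return `result` with `z_score` and `percentile` columns filled.
#' @export
normalize_grs <- function(result, ref) {
  assert_that(is.list(ref) && is.numeric(ref$sd_raw) && ref$sd_raw > 0,
              "invalid reference distribution", "grstrial_validation_error")
  result$z_score <- (result$raw_score - ref$mean_raw) / ref$sd_raw
  if (!is.null(ref$sorted_scores)) {
    below <- findInterval(result$raw_score, ref$sorted_scores,
                          left.open = TRUE)
    result$percentile <- below / length(ref$sorted_scores)
  } else {
    result$percentile <- pnorm(result$z_score)
  }
  class(result) <- c("grs_result", "data.frame")
  result
}

#' @export
print.grs_reference <- function(x, ...) {
  cat(sprintf("GRS reference distribution: n = %d, mean = %.4f, sd = %.4f\n",
              x$n_ref, x$mean_raw, x$sd_raw))
  invisible(x)
}
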