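test_that("bundled default table parses to the 19-locus score with 6 proxies", {
  w <- grs_default_weights()
  expect_s3_class(w, "snp_weights")
  expect_equal(nrow(w), 19L)
  expect_equal(sum(nzchar(w$proxy_for)), 6L)
  expect_true(all(is.finite(w$weight)))
  expect_false(anyDuplicated(w$rsid) > 0)
})

test_that("weight table validation catches format errors", {
  w <- synthetic_weights(3)
  # header-only file is a valid empty table, but scoring refuses it
  empty <- write_weight_tsv(w[0, ])
  tab <- load_weight_table(empty)
  expect_equal(nrow(tab), 0L)
  g <- random_genotypes(2, w)
  expect_error(compute_raw_grs(g, tab), class = "grstrial_validation_error")

  dup <- write_weight_tsv(rbind(w, w[1, ]))
  expect_error(load_weight_table(dup), class = "grstrial_format_error")

  bad <- w; bad$weight[2] <- NA
  expect_error(load_weight_table(write_weight_tsv(bad)),
               class = "grstrial_format_error")
})

test_that("raw score and allele count follow forced arithmetic", {
  w <- synthetic_weights(2, weights = c(0.1, 0.2))
  g <- matrix(c(2, 1), nrow = 1, dimnames = list("S1", w$rsid))
  res <- compute_raw_grs(g, w)
  expect_equal(res$raw_score, 0.4)
  expect_equal(res$allele_count, 3L)

  g0 <- matrix(0, nrow = 1, ncol = 2, dimnames = list("S1", w$rsid))
  res0 <- compute_raw_grs(g0, w)
  expect_equal(res0$raw_score, 0)
  expect_equal(res0$allele_count, 0L)
})

test_that("scores match a brute-force per-sample loop oracle", {
  w <- synthetic_weights(19, seed = 9)
  g <- random_genotypes(10, w, seed = 10)
  res <- compute_raw_grs(g, w)
  for (i in 1:10) {
    raw <- 0; cnt <- 0
    for (j in seq_len(19)) {
      raw <- raw + w$weight[j] * g[i, w$rsid[j]]
      cnt <- cnt + g[i, w$rsid[j]]
    }
    expect_equal(res$raw_score[i], raw)
    expect_equal(res$allele_count[i], as.integer(cnt))
  }
})

test_that("missing-dosage policies behave as contracted", {
  w <- synthetic_weights(4, seed = 3)
  g <- random_genotypes(6, w, seed = 4, missing_rate = 0.3)
  expect_error(compute_raw_grs(g, w), class = "grstrial_missing_data_error")

  freqs <- setNames(rep(0.5, 4), w$rsid)
  res <- compute_raw_grs(g, w, missing_policy = "mean_impute",
                         allele_freqs = freqs)
  expect_equal(res$n_missing_imputed, as.integer(rowSums(is.na(g))))
  # imputed dosage is 2 * freq = 1 at every gap
  g_filled <- g; g_filled[is.na(g)] <- 1
  expect_equal(res$raw_score, as.numeric(g_filled %*% w$weight))
  # allele_count stays the integer sum of observed dosages
  expect_equal(res$allele_count, as.integer(rowSums(g, na.rm = TRUE)))
})

test_that("fit_reference gives sample moments and rejects degenerate input", {
  ref <- fit_reference(c(1, 3))
  expect_equal(ref$mean_raw, 2)
  expect_equal(ref$sd_raw, sqrt(2))
  expect_error(fit_reference(c(5)), class = "grstrial_degenerate_reference_error")
  expect_error(fit_reference(rep(2, 10)),
               class = "grstrial_degenerate_reference_error")

  # two-pass streaming oracle on a large sample
  set.seed(5)
  x <- rnorm(8734, 1.7, 0.4)
  ref2 <- fit_reference(x)
  m <- sum(x) / length(x)
  s2 <- sum((x - m)^2) / (length(x) - 1)
  expect_equal(ref2$mean_raw, m)
  expect_equal(ref2$sd_raw, sqrt(s2))
})

test_that("normalization centers, scales and bounds percentiles", {
  ref <- fit_reference(c(0, 1, 2, 3, 4))
  res <- data.frame(sample_id = c("a", "b", "c"),
                    raw_score = c(ref$mean_raw, ref$mean_raw + ref$sd_raw, -1),
                    allele_count = 0L, n_missing_imputed = 0L)
  class(res) <- c("grs_result", "data.frame")
  out <- normalize_grs(res, ref)
  expect_equal(out$z_score[1], 0)
  expect_equal(out$z_score[2], 1)
  expect_equal(out$percentile[3], 0)  # below every reference score
  expect_equal(out$percentile[1], 2 / 5)  # strictly-below convention
})

test_that("reference cohort self-normalizes to mean 0, sd 1", {
  w <- synthetic_weights(19, seed = 2)
  g <- random_genotypes(500, w, seed = 20)
  res <- compute_raw_grs(g, w)
  ref <- fit_reference(res$raw_score)
  out <- normalize_grs(res, ref)
  expect_equal(mean(out$z_score), 0, tolerance = 1e-10)
  expect_equal(sd(out$z_score), 1, tolerance = 1e-10)
})

test_that("scoring is linear under concatenation and invariant to column order", {
  w <- synthetic_weights(8, seed = 6)
  g1 <- random_genotypes(7, w, seed = 7)
  g2 <- random_genotypes(5, w, seed = 8)
  rownames(g2) <- paste0("T", seq_len(nrow(g2)))
  both <- compute_raw_grs(rbind(g1, g2), w)
  sep <- rbind(compute_raw_grs(g1, w), compute_raw_grs(g2, w))
  expect_equal(both$raw_score, sep$raw_score)
  expect_equal(both$allele_count, sep$allele_count)

  perm <- g1[, sample(colnames(g1)), drop = FALSE]
  expect_equal(compute_raw_grs(perm, w)$raw_score,
               compute_raw_grs(g1, w)$raw_score)

  # unit weights collapse the weighted score onto the allele count
  w1 <- w; w1$weight <- rep(1, nrow(w1))
  res1 <- compute_raw_grs(g1, w1)
  expect_equal(res1$raw_score, as.numeric(res1$allele_count))
})
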