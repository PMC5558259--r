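# Shared fixture builders. Everything is generated in code; seeds are fixed
# per call site so tests are deterministic.

synthetic_weights <- function(k = 5, weights = NULL, seed = 42) {
  set.seed(seed)
  alleles <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  tab <- data.frame(
    rsid = sprintf("rs%05d", seq_len(k)),
    effect_allele = vapply(seq_len(k), function(i) alleles[[(i - 1) %% 4 + 1]][1], ""),
    other_allele = vapply(seq_len(k), function(i) alleles[[(i - 1) %% 4 + 1]][2], ""),
    weight = weights %||% round(runif(k, 0.05, 0.25), 3),
    proxy_for = "",
    stringsAsFactors = FALSE
  )
  class(tab) <- c("snp_weights", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_genotypes <- function(n, weights, freqs = NULL, seed = 1,
                             missing_rate = 0) {
  set.seed(seed)
  k <- nrow(weights)
  freqs <- freqs %||% runif(k, 0.2, 0.8)
  g <- vapply(freqs, function(p) rbinom(n, 2, p), numeric(n))
  if (n == 1) g <- matrix(g, nrow = 1)
  dimnames(g) <- list(sprintf("S%03d", seq_len(n)), weights$rsid)
  if (missing_rate > 0) g[runif(length(g)) < missing_rate] <- NA
  g
}

write_weight_tsv <- function(tab, path = tempfile(fileext = ".tsv")) {
  writeLines(paste(c("rsid", "effect_allele", "other_allele", "weight",
                     "proxy_for"), collapse = "\t"), path)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE, na = "")
  path
}

# Hand-built three-visit ledger: a list of per-participant visit value
# vectors (NA = missing, NULL visit = not attended) for one outcome column.
mini_ledger <- function(values, column = "ldl", arms = NULL) {
  ids <- names(values)
  arms <- arms %||% rep(c("GRS", "SOC"), length.out = length(ids))
  assign <- data.frame(participant_id = ids, arm = arms,
                       sequence_index = seq_along(ids),
                       block_index = 1L, stringsAsFactors = FALSE)
  class(assign) <- c("trial_assignments", "data.frame")
  rows <- do.call(rbind, lapply(ids, function(id) {
    v <- values[[id]]
    df <- data.frame(participant_id = id, visit = 1:3, attended = TRUE,
                     stringsAsFactors = FALSE)
    df[[column]] <- v
    df
  }))
  assemble_ledger(assign, rows)
}

# Independent brute-force oracle for the two-sample shift estimator:
# explicit double loop over all pairwise differences, midpoint of the two
# central order statistics when the count is even.
hl_oracle <- function(x, y) {
  d <- numeric(0)
  for (xi in x) for (yj in y) d <- c(d, xi - yj)
  d <- sort(d)
  l <- length(d)
  if (l %% 2 == 1) d[(l + 1) / 2] else mean(d[l / 2 + 0:1])
}
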