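`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a private RNG state
#'
#' Saves and restores `.Random.seed` so that seeded package code neither
#' depends on nor disturbs the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_private_seed <- function(seed, expr) {
  seed <- as.integer(seed)  # force before snapshotting the caller's RNG state
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for a named subsystem stream, kept below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) %% 65011 + 1) * 32749 + h) %% 2147483587L
}

stop_grstrial <- function(msg, class) {
  stop(structure(class = c(class, "grstrial_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "grstrial_validation_error") {
  if (!isTRUE(ok)) stop_grstrial(msg, class)
  invisible(TRUE)
}
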