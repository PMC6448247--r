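# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# t-based 95% CI around a mean; n == 1 yields NA bounds (flagged undefined).
meanCI <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) {
    return(list(mean = m, lower = NA_real_, upper = NA_real_,
                defined = FALSE, n = n))
  }
  se <- stats::sd(x) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1L)
  list(mean = m, lower = m - tq * se, upper = m + tq * se,
       defined = TRUE, n = n)
}

stopIfNotProportion <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

# Deterministic short hash of a configuration list (provenance headers).
configHash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}
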