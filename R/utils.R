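# internal helpers

# Run code under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Squared Pearson correlation with the degenerate-input convention r2 = 0
# (constant observed or predicted vector carries no explainable variance).
squaredCorrelation <- function(y, yhat) {
  if (length(y) < 2L || !all(is.finite(yhat))) return(0)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) return(0)
  stats::cor(y, yhat)^2
}

# Coefficient of determination 1 - RSS/TSS (can be negative for bad fits).
rSquared <- function(y, yhat) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  1 - sum((y - yhat)^2) / tss
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
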