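# Independent oracle implementations used for dual-route checks. These are
# deliberately written through different primitives (solve/lm/R's own
# expression evaluator) than the package code paths they verify.

# OLS through the normal equations
olsOracle <- function(X, y) {
  Xa <- cbind(1, X)
  drop(solve(crossprod(Xa), crossprod(Xa, y)))
}

# leave-one-out cross-validated r2 by literal n refits
looOracle <- function(X, y) {
  n <- length(y)
  preds <- vapply(seq_len(n), function(i) {
    cf <- olsOracle(X[-i, , drop = FALSE], y[-i])
    cf[1] + sum(cf[-1] * X[i, ])
  }, 0)
  1 - sum((y - preds)^2) / sum((y - mean(y))^2)
}

# validation statistics via lm()
r2ExtOracle <- function(y, yhat, ybar) 1 - sum((y - yhat)^2) / sum((y - ybar)^2)

rm2Oracle <- function(y, yhat) {
  r2 <- summary(lm(yhat ~ y))$r.squared
  r0d <- 1 - deviance(lm(yhat ~ 0 + y)) / sum((yhat - mean(yhat))^2)
  r0r <- 1 - deviance(lm(y ~ 0 + yhat)) / sum((y - mean(y))^2)
  d <- r2 * (1 - sqrt(max(r2 - r0d, 0)))
  r <- r2 * (1 - sqrt(max(r2 - r0r, 0)))
  c(direct = d, reversed = r, overall = (d + r) / 2)
}

# evaluate an infix expression string with R's own parser/evaluator
evalOracle <- function(text, bindings) {
  env <- list2env(as.list(bindings))
  env$inv <- function(x) 1 / x
  eval(str2lang(text), envir = env)
}

# random bindings keeping the published equation's denominators away from 0
safeBindings <- function() {
  list(TEIZP = runif(1, 1.2, 2), NFA = runif(1, 0.2, 0.8),
       MECN = runif(1, 0.5, 5), MRCH = runif(1, 1.3, 2),
       MCIHN = runif(1, 0.1, 0.5), ZXS = runif(1, 0.5, 1.2))
}

# tiny aligned molecule at given coordinates
makeMol <- function(id, xyz, element = rep("C", nrow(xyz)), ...)
  alignedMolecule(id, element, xyz, ...)

# a FieldMatrix wrapping an arbitrary numeric matrix (1 field, unit grid)
rawFieldMatrix <- function(X) {
  grid <- new("FieldGrid", origin = c(0, 0, 0), spacing = 1,
              counts = c(ncol(X), 1L, 1L), margin = 0)
  colnames(X) <- paste0("S.", seq_len(ncol(X)))
  new("FieldMatrix", values = X, field = rep("S", ncol(X)),
      pointIndex = seq_len(ncol(X)), active = rep(TRUE, ncol(X)),
      grid = grid)
}
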