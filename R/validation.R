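# External and internal (chance-correlation) validation statistics.

#' External predictive r-squared
#'
#' r2_ext = 1 - sum((y - yhat)^2) / sum((y - ybarTrain)^2): squared
#' prediction error on the held-out set referenced to the training-set
#' activity mean. May be negative for a model worse than the training mean;
#' values above 0.5 are conventionally read as robust external prediction.
#'
#' @param yTest observed held-out activities (n >= 2).
#' @param yhatTest predicted held-out activities.
#' @param ybarTrain mean training-set activity.
#' @return numeric(1).
#' @export
r2Ext <- function(yTest, yhatTest, ybarTrain) {
  if (length(yTest) != length(yhatTest) || length(yTest) < 2L)
    stopf("yTest and yhatTest must have equal length >= 2")
  den <- sum((yTest - ybarTrain)^2)
  if (den <= 0)
    stopf("all test activities equal the training mean; r2_ext undefined")
  1 - sum((yTest - yhatTest)^2) / den
}

# through-origin r2 of a on b (model a = k*b)
.r2ThroughOrigin <- function(a, b) {
  k <- sum(a * b) / sum(b * b)
  1 - sum((a - k * b)^2) / sum((a - mean(a))^2)
}

#' rm-squared validation metrics
#'
#' rm2 = r2 * (1 - sqrt(r2 - r0^2)) where r2 is the squared Pearson
#' correlation of predictions and observations and r0^2 the squared
#' correlation of the least-squares fit through the origin (direct variant:
#' predictions regressed on observations; reversed: observations on
#' predictions). The overall value averages the two. A negative radicand
#' (through-origin fit slightly better than the free fit) is clamped to 0,
#' where rm2 reduces to r2.
#'
#' @param y observed activities (n >= 3, non-constant).
#' @param yhat predicted activities (non-constant).
#' @return named numeric: \code{direct}, \code{reversed}, \code{overall},
#'   plus \code{r2}, \code{r02_direct}, \code{r02_reversed} as attributes of
#'   the computation in \code{attr(, "details")}.
#' @export
rm2 <- function(y, yhat) {
  if (length(y) < 3L) stopf("need at least 3 points")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stopf("constant observed or predicted vector")
  r2 <- stats::cor(y, yhat)^2
  r02d <- .r2ThroughOrigin(yhat, y)
  r02r <- .r2ThroughOrigin(y, yhat)
  direct <- r2 * (1 - sqrt(max(r2 - r02d, 0)))
  reversed <- r2 * (1 - sqrt(max(r2 - r02r, 0)))
  out <- c(direct = direct, reversed = reversed,
           overall = (direct + reversed) / 2)
  attr(out, "details") <- c(r2 = r2, r02_direct = r02d, r02_reversed = r02r)
  out
}

# pull an r2 out of whatever a fit function returns
.extractR2 <- function(fit) {
  if (is.numeric(fit) && length(fit) == 1L) return(as.numeric(fit))
  if (is(fit, "LinearQsarModel")) return(fit@stats$r2)
  if (is(fit, "PlsQsarModel")) return(fit@r2)
  if (is.list(fit) && !is.null(fit$r2)) return(fit$r2)
  stopf("cannot extract an r2 from the fit function's return value")
}

#' Y-randomization (response scrambling) validation
#'
#' Permutes the activity vector \code{nIter} times (seeded), refits with
#' the supplied fit function and collects the scrambled-model r2 values.
#' The summary statistic is r2_p = r2 * sqrt(r2 - mean(r2_r)) with the
#' radicand clamped at 0; values above 0.5 indicate the original model is
#' unlikely to be a chance correlation. Iterations whose refit fails are
#' recorded and excluded with a warning.
#'
#' @param fitFn function(X, y) returning an object with an r2 (a
#'   LinearQsarModel, PlsQsarModel, a list with \code{$r2}, or a bare
#'   number). Must be deterministic given its data.
#' @param X descriptor data passed through to \code{fitFn}.
#' @param y activity vector.
#' @param nIter number of scrambles, default 20.
#' @param seed integer seed for the permutations.
#' @return list with \code{r2_p}, \code{r2}, \code{r2_r_list} and
#'   \code{n_effective}.
#' @export
yRandomization <- function(fitFn, X, y, nIter = 20L, seed = 1L) {
  if (nIter < 1L) stopf("nIter must be >= 1")
  r2 <- .extractR2(fitFn(X, y))
  perms <- withSeed(seed, replicate(nIter, sample.int(length(y)),
                                    simplify = FALSE))
  r2r <- vapply(perms, function(p)
    tryCatch(.extractR2(fitFn(X, y[p])), error = function(e) NA_real_), 0)
  failed <- sum(is.na(r2r))
  if (failed)
    warnf("%d scrambled refit(s) failed and were excluded", failed)
  ok <- r2r[!is.na(r2r)]
  r2p <- r2 * sqrt(max(r2 - mean(ok), 0))
  list(r2_p = r2p, r2 = r2, r2_r_list = r2r, n_effective = length(ok))
}

#' Assemble a full validation report
#'
#' External statistics (r2_ext, r2, rm2 family) for held-out predictions,
#' plus optional Y-randomization internals when a fit function and training
#' data are supplied.
#'
#' @param yTest,yhatTest,ybarTrain external-validation inputs.
#' @param fitFn,XTrain,yTrain,nIter,seed Y-randomization inputs (optional).
#' @return a \linkS4class{ValidationReport}.
#' @export
validationReport <- function(yTest, yhatTest, ybarTrain,
                             fitFn = NULL, XTrain = NULL, yTrain = NULL,
                             nIter = 20L, seed = 1L) {
  rext <- r2Ext(yTest, yhatTest, ybarTrain)
  rm <- rm2(yTest, yhatTest)
  det <- attr(rm, "details")
  if (!is.null(fitFn)) {
    yr <- yRandomization(fitFn, XTrain, yTrain, nIter = nIter, seed = seed)
    r2p <- yr$r2_p; r2rList <- yr$r2_r_list
  } else {
    r2p <- NA_real_; r2rList <- numeric()
  }
  new("ValidationReport",
      r2Ext = rext, r2 = unname(det[["r2"]]),
      r02 = c(direct = unname(det[["r02_direct"]]),
              reversed = unname(det[["r02_reversed"]])),
      rm2 = c(direct = unname(rm[["direct"]]),
              reversed = unname(rm[["reversed"]]),
              overall = unname(rm[["overall"]])),
      r2p = r2p, r2rList = r2rList,
      meta = list(published = c(r2_ext = 0.65, rm2 = 0.64, r2_p = 0.61),
                  n_iter = nIter, seed = seed))
}
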