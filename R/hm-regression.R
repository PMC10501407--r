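#' Ordinary least squares with leave-one-out cross-validation
#'
#' Fits y = b0 + X b by OLS and reports the diagnostics used by the heuristic
#' descriptor search: r2, leave-one-out cross-validated r2 (computed through
#' the hat-matrix identity e_i/(1 - h_ii), equivalent to n refits), the
#' residual variance s2 = RSS/(n - k - 1), raw RSS, the overall F statistic
#' and per-coefficient t values.
#'
#' @param X numeric matrix (n x k) with descriptor column names.
#' @param y numeric activity vector, length n.
#' @param provenance character tag stored on the model.
#' @return a \linkS4class{LinearQsarModel}.
#' @export
fitMlr <- function(X, y, provenance = "fitMlr") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stopf("length(y) (%d) != nrow(X) (%d)", length(y), n)
  if (n <= k + 1L) stopf("need n > k + 1 (n = %d, k = %d)", n, k)
  Xa <- cbind("(Intercept)" = 1, X)
  qrx <- qr(Xa)
  if (qrx$rank < ncol(Xa)) {
    dep <- colnames(Xa)[qrx$pivot[(qrx$rank + 1L):ncol(Xa)]]
    stopf("rank-deficient design; dependent column(s): %s",
          paste(dep, collapse = ", "))
  }
  cf <- qr.coef(qrx, y)
  fit <- drop(Xa %*% cf)
  res <- y - fit
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 0 else 1 - rss / tss
  # LOO via hat diagonal
  Q <- qr.Q(qrx)
  h <- rowSums(Q^2)
  looRes <- res / pmax(1 - h, .Machine$double.eps)
  press <- sum(looRes^2)
  r2cv <- if (tss == 0) 0 else 1 - press / tss
  dfres <- n - k - 1L
  s2 <- rss / dfres
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(XtXinv), 0) * s2)
  tv <- cf / se
  fval <- if (r2 >= 1) Inf else (r2 / k) / ((1 - r2) / dfres)
  new("LinearQsarModel",
      intercept = unname(cf[1L]),
      coefficients = cf[-1L],
      stats = list(r2 = r2, r2_cv = r2cv, s2 = s2, rss = rss,
                   f_value = fval, t_values = tv[-1L], n = n,
                   recomputed = TRUE),
      provenance = provenance)
}

#' Collinearity/constancy prefilter for descriptor tables
#'
#' Drops constant columns and columns containing missing values, then
#' enforces the pairwise-collinearity cap: for any descriptor pair with
#' |r| >= \code{collinearityCap} the member less correlated with the activity
#' is dropped (ties broken by keeping the lexicographically smaller name).
#' Implemented as a greedy sweep in decreasing order of |cor(x, y)|, which
#' guarantees every surviving pair satisfies |r| < cap. Dropped names and
#' reasons are attached as \code{attr(result, "dropped")} and messaged.
#'
#' @param table a DescriptorTable.
#' @param y activity vector aligned with the table rows.
#' @param collinearityCap pairwise absolute-correlation cap, default 0.80.
#' @return a filtered \linkS4class{DescriptorTable}.
#' @export
prefilterDescriptors <- function(table, y, collinearityCap = 0.80) {
  m <- descriptorMatrix(table)
  if (length(y) != nrow(m)) stopf("length(y) != number of compounds")
  dropped <- data.frame(name = character(), reason = character(),
                        stringsAsFactors = FALSE)
  hasNA <- colSums(is.na(m)) > 0
  if (any(hasNA))
    dropped <- rbind(dropped, data.frame(name = colnames(m)[hasNA],
                                         reason = "missing values"))
  m <- m[, !hasNA, drop = FALSE]
  sds <- apply(m, 2L, stats::sd)
  isConst <- sds == 0
  if (any(isConst))
    dropped <- rbind(dropped, data.frame(name = colnames(m)[isConst],
                                         reason = "constant"))
  m <- m[, !isConst, drop = FALSE]
  if (!ncol(m)) stopf("all descriptor columns dropped by prefilter")
  ry <- abs(suppressWarnings(stats::cor(m, y)))[, 1L]
  ry[is.na(ry)] <- 0
  ord <- order(-ry, colnames(m))   # strongest y-correlation first, names break ties
  keep <- character()
  for (j in ord) {
    nm <- colnames(m)[j]
    if (length(keep)) {
      r <- suppressWarnings(stats::cor(m[, keep, drop = FALSE], m[, j]))
      if (any(abs(r) >= collinearityCap, na.rm = TRUE)) {
        clash <- keep[which(abs(r) >= collinearityCap)[1L]]
        dropped <- rbind(dropped, data.frame(
          name = nm, reason = sprintf("|r| >= %.2f with %s", collinearityCap, clash)))
        next
      }
    }
    keep <- c(keep, nm)
  }
  keep <- colnames(m)[sort(match(keep, colnames(m)))]  # preserve input order
  if (!length(keep)) stopf("all descriptor columns dropped by prefilter")
  if (nrow(dropped))
    message("prefilter dropped ", nrow(dropped), " descriptor(s)")
  out <- new("DescriptorTable", values = m[, keep, drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Heuristic forward descriptor selection
#'
#' Greedy forward search over a (prefiltered) descriptor table: at each
#' subset size the descriptor giving the largest r2 gain is added, subject to
#' the pairwise collinearity cap against the already-selected set. The trace
#' records r2, LOO r2_cv and s2 at every size up to \code{kMax}; the
#' recommended size is the last k whose r2 gain was at least
#' \code{stopDelta} (further additions are judged to have little influence).
#' Equal-gain ties pick the lexicographically smaller descriptor name.
#'
#' @param table a DescriptorTable (run \code{\link{prefilterDescriptors}}
#'   first to enforce the cap globally).
#' @param y activity vector.
#' @param kMax largest subset size to explore (must be < n - 2).
#' @param stopDelta minimum r2 gain counted as a real improvement,
#'   default 0.02.
#' @param collinearityCap admissibility cap during selection, default 0.80.
#' @return a \linkS4class{SelectionTrace}.
#' @export
heuristicSelect <- function(table, y, kMax = 8L, stopDelta = 0.02,
                            collinearityCap = 0.80) {
  m <- descriptorMatrix(table)
  n <- nrow(m); p <- ncol(m)
  kMax <- min(as.integer(kMax), p)
  if (kMax >= n - 2L) stopf("kMax must be < n - 2 (n = %d)", n)
  ymean <- mean(y); yc <- y - ymean
  tss <- sum(yc^2)
  if (tss == 0) stopf("activity vector is constant")
  # orthonormal basis of [1, X_selected], grown one column at a time
  Q <- matrix(1 / sqrt(n), n, 1L)
  resY <- yc                      # y residualized on the intercept
  selected <- character()
  r2 <- 0
  steps <- data.frame(k = integer(), added = character(), r2 = numeric(),
                      r2_cv = numeric(), s2 = numeric(),
                      stringsAsFactors = FALSE)
  subsets <- list()
  admissible <- rep(TRUE, p); names(admissible) <- colnames(m)
  for (k in seq_len(kMax)) {
    cand <- which(admissible & !(colnames(m) %in% selected))
    if (!length(cand)) break
    C <- m[, cand, drop = FALSE]
    Rc <- C - Q %*% crossprod(Q, C)                 # residualized candidates
    rcn <- sqrt(colSums(Rc^2))
    ryn <- sqrt(sum(resY^2))
    pr <- crossprod(Rc, resY)[, 1L] / (rcn * ryn)   # partial correlation
    pr[!is.finite(pr)] <- 0
    gain <- (1 - r2) * pr^2
    best <- which(gain == max(gain))
    if (length(best) > 1L)                          # deterministic tie-break
      best <- best[order(colnames(C)[best])[1L]] else best <- best[1L]
    nm <- colnames(C)[best]
    selected <- c(selected, nm)
    # update basis and residual
    qnew <- Rc[, best] / rcn[best]
    Q <- cbind(Q, qnew)
    resY <- resY - qnew * sum(qnew * resY)
    r2 <- 1 - sum(resY^2) / tss
    # enforce the collinearity cap for future candidates
    rWithNew <- suppressWarnings(stats::cor(m, m[, nm]))[, 1L]
    admissible <- admissible & (abs(rWithNew) < collinearityCap | is.na(rWithNew))
    fit <- fitMlr(m[, selected, drop = FALSE], y,
                  provenance = sprintf("forward step %d", k))
    steps <- rbind(steps, data.frame(
      k = k, added = nm, r2 = fit@stats$r2, r2_cv = fit@stats$r2_cv,
      s2 = fit@stats$s2, stringsAsFactors = FALSE))
    subsets[[k]] <- selected
  }
  gains <- c(steps$r2[1L], diff(steps$r2))
  rec <- if (any(gains >= stopDelta)) max(which(gains >= stopDelta)) else 1L
  new("SelectionTrace", steps = steps, subsets = subsets,
      recommended = as.integer(rec))
}

#' The published six-descriptor linear model
#'
#' Returns the published heuristic-method model verbatim: intercept -24.280
#' and the six descriptor coefficients (NFA 0.29798, MRCH 0.44403, MECN
#' 5.6298, TEIZP -0.57965, ZXS 3.6953, MCIHN -3.8370). The stats slot carries
#' the published diagnostics (r2 = 0.6682, r2_cv = 0.5669, s2 = 0.0199) and
#' Table t values as metadata (\code{recomputed = FALSE}): they were obtained
#' on the original commercial descriptor matrix and are not recomputed here.
#'
#' @return a \linkS4class{LinearQsarModel}.
#' @export
referenceHmModel <- function() {
  reg <- descriptorRegistry()
  cf <- stats::setNames(reg$coefficient, reg$name)
  new("LinearQsarModel",
      intercept = -24.280,
      coefficients = cf,
      stats = list(r2 = 0.6682, r2_cv = 0.5669, s2 = 0.0199,
                   t_values = stats::setNames(reg$t_value, reg$name),
                   n = 26L, recomputed = FALSE),
      provenance = "published six-descriptor model")
}

#' Evaluate a linear QSAR model on a named descriptor vector
#'
#' Name-keyed evaluation: the order of the supplied values is irrelevant,
#' every model term must be supplied, extra names are ignored with a warning.
#'
#' @param model a LinearQsarModel.
#' @param x named numeric vector, or a matrix/DescriptorTable with descriptor
#'   columns (one prediction per row).
#' @return predicted activity (numeric vector).
#' @export
evaluateLinear <- function(model, x) {
  if (is(x, "DescriptorTable")) x <- descriptorMatrix(x)
  need <- names(model@coefficients)
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    miss <- setdiff(need, colnames(x))
    if (length(miss)) stopf("missing descriptor(s): %s", paste(miss, collapse = ", "))
    extra <- setdiff(colnames(x), need)
    if (length(extra)) warnf("ignoring extra descriptor(s): %s",
                             paste(extra, collapse = ", "))
    drop(model@intercept + x[, need, drop = FALSE] %*% model@coefficients[need])
  } else {
    miss <- setdiff(need, names(x))
    if (length(miss)) stopf("missing descriptor(s): %s", paste(miss, collapse = ", "))
    extra <- setdiff(names(x), need)
    if (length(extra)) warnf("ignoring extra descriptor(s): %s",
                             paste(extra, collapse = ", "))
    unname(model@intercept + sum(model@coefficients[need] * x[need]))
  }
}

#' @describeIn evaluateLinear predict method.
#' @param object a LinearQsarModel.
#' @param newdata named vector, matrix or DescriptorTable.
#' @param ... ignored.
#' @export
setMethod("predict", "LinearQsarModel", function(object, newdata, ...)
  evaluateLinear(object, newdata))

#' Serialize a linear model to structured text
#'
#' Human-readable key/value text with full (17 significant digit) precision;
#' \code{readLinearModel} round-trips exactly.
#'
#' @param model a LinearQsarModel.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeLinearModel <- function(model, path) {
  num <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c("# gbmQSAR linear model",
             paste0("provenance: ", model@provenance),
             paste0("intercept: ", num(model@intercept)))
  for (nm in names(model@coefficients))
    lines <- c(lines, paste0("coef ", nm, ": ", num(model@coefficients[[nm]])))
  for (nm in c("r2", "r2_cv", "s2", "rss", "f_value")) {
    v <- model@stats[[nm]]
    if (!is.null(v)) lines <- c(lines, paste0("stat ", nm, ": ", num(v)))
  }
  tv <- model@stats$t_values
  for (nm in names(tv))
    lines <- c(lines, paste0("tvalue ", nm, ": ", num(tv[[nm]])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeLinearModel
#' @param path path written by \code{writeLinearModel}.
#' @export
readLinearModel <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  kv <- regmatches(lines, regexec("^([^:]+): (.*)$", lines))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  getnum <- function(pat) {
    i <- grep(pat, keys)
    stats::setNames(as.numeric(vals[i]), sub(pat, "", keys[i]))
  }
  cf <- getnum("^coef ")
  st <- as.list(getnum("^stat "))
  tv <- getnum("^tvalue ")
  if (length(tv)) st$t_values <- tv
  st$recomputed <- FALSE
  new("LinearQsarModel",
      intercept = as.numeric(vals[keys == "intercept"]),
      coefficients = cf, stats = st,
      provenance = vals[keys == "provenance"])
}
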