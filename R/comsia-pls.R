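# PLS1 by NIPALS-style latent-variable extraction, with LOO Q2 and the
# CoMSIA reporting conventions (ONC, SEE, F, field contribution fractions).

# Core PLS1 on centered data. Returns regression coefficient vectors for
# every component count 1..ncomp (columns of B).
.pls1 <- function(Xc, yc, ncomp) {
  p <- ncol(Xc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); qv <- numeric(ncomp)
  Xr <- Xc; yr <- yc
  used <- 0L
  for (c in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xr %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- crossprod(Xr, t)[, 1L] / tt
    qs <- sum(yr * t) / tt
    Xr <- Xr - tcrossprod(t, pvec)
    yr <- yr - qs * t
    W[, c] <- w; P[, c] <- pvec; qv[c] <- qs
    used <- c
  }
  if (used == 0L) stopf("PLS found no informative component")
  B <- matrix(0, p, ncomp)
  for (c in seq_len(used)) {
    Wc <- W[, 1:c, drop = FALSE]
    R <- Wc %*% solve(crossprod(P[, 1:c, drop = FALSE], Wc),
                      diag(1, c))
    B[, c] <- R %*% qv[1:c]
  }
  if (used < ncomp) for (c in (used + 1L):ncomp) B[, c] <- B[, used]
  list(B = B, used = used)
}

#' Fit the CoMSIA PLS model with LOO component selection
#'
#' For each candidate component count c = 1..\code{maxComponents} the
#' leave-one-out cross-validated r2 (Q2) is computed by n refits; the
#' optimal number of components (ONC) maximizes Q2, taking the smallest c on
#' ties. The model is then refit on all data at ONC and reported with its
#' non-CV r2, SEE = sqrt(RSS/(n - c - 1)), F = (r2/c)/((1 - r2)/(n - c - 1))
#' and per-field contribution fractions (normalized sums of
#' |coefficient| x column standard deviation over each field block).
#'
#' @param matrix a \linkS4class{FieldMatrix}.
#' @param y activity vector aligned with the matrix rows.
#' @param maxComponents largest component count tried (capped at n - 2).
#' @param ncomp optional fixed component count: skips the ONC search and
#'   fits (and cross-validates) at exactly this count.
#' @return a \linkS4class{PlsQsarModel}.
#' @export
fitPls <- function(matrix, y, maxComponents = 10L, ncomp = NULL) {
  stopifnot(is(matrix, "FieldMatrix"))
  X <- matrix@values[, matrix@active, drop = FALSE]
  n <- nrow(X)
  if (n < 4L) stopf("need at least 4 compounds, got %d", n)
  if (stats::sd(y) == 0) stopf("activity vector is constant")
  if (!is.null(ncomp)) maxComponents <- as.integer(ncomp)
  maxComponents <- min(as.integer(maxComponents), n - 2L)
  ym <- mean(y); xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  tss <- sum(yc^2)
  # LOO PRESS per component count
  press <- numeric(maxComponents)
  for (i in seq_len(n)) {
    Xi <- Xc[-i, , drop = FALSE]; yi <- yc[-i]
    xmI <- colMeans(Xi); ymI <- mean(yi)
    fit <- .pls1(sweep(Xi, 2L, xmI), yi - ymI, maxComponents)
    pred <- drop((Xc[i, ] - xmI) %*% fit$B) + ymI
    press <- press + (yc[i] - pred)^2
  }
  q2 <- 1 - press / tss
  onc <- if (!is.null(ncomp)) maxComponents
         else which.max(q2)              # smallest index on ties (which.max)
  fit <- .pls1(Xc, yc, onc)
  beta <- fit$B[, onc]
  fitted <- drop(Xc %*% beta) + ym
  rss <- sum((y - fitted)^2)
  r2 <- 1 - rss / tss
  dfres <- n - onc - 1L
  see <- sqrt(rss / dfres)
  fval <- if (r2 >= 1) Inf else (r2 / onc) / ((1 - r2) / dfres)
  sds <- apply(X, 2L, stats::sd)
  contrib <- abs(beta) * sds
  fieldOf <- matrix@field[matrix@active]
  fr <- vapply(.FIELD_LABELS, function(f) sum(contrib[fieldOf == f]), 0)
  fr <- fr / sum(fr)
  names(beta) <- colnames(X)
  new("PlsQsarModel",
      ncomp = as.integer(onc), coefficients = beta,
      intercept = ym - sum(xm * beta),
      q2 = q2[onc], q2History = q2, r2 = r2, see = see, fValue = fval,
      fractions = fr,
      columnField = fieldOf,
      columnIndex = which(matrix@active),
      xMeans = xm, yMean = ym,
      meta = list(columnSd = sds, grid = matrix@grid,
                  published = list(q2_abstract = 0.628, q2_table = 0.682,
                                   onc = 1, r2 = 0.928, see = 0.160,
                                   f = 12.194,
                                   fractions = c(S = 0.193, E = 0.194,
                                                 H = 0.331, D = 0.279,
                                                 A = 0.218))))
}

#' @describeIn fitPls predict from a FieldMatrix (or a bare matrix whose
#'   columns match the model's active columns).
#' @param object a PlsQsarModel.
#' @param newdata FieldMatrix or numeric matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "PlsQsarModel", function(object, newdata, ...) {
  X <- if (is(newdata, "FieldMatrix"))
    newdata@values[, object@columnIndex, drop = FALSE]
  else as.matrix(newdata)
  if (ncol(X) != length(object@coefficients))
    stopf("newdata has %d columns; model expects %d", ncol(X),
          length(object@coefficients))
  drop(X %*% object@coefficients) + object@intercept
})

#' Favored/disfavored contour point sets
#'
#' For each field, grid points whose coefficient x column-standard-deviation
#' product lies strictly above the \code{upperPct} percentile of that
#' field's active columns are favored, strictly below the \code{lowerPct}
#' percentile disfavored. Fields with fewer than 2 active columns yield
#' empty contours with a warning.
#'
#' @param model a \linkS4class{PlsQsarModel}.
#' @param grid the \linkS4class{FieldGrid} (defaults to the fit-time grid).
#' @param upperPct,lowerPct percentile thresholds, defaults 80 and 20.
#' @return a \linkS4class{ContourSet}.
#' @export
contourMaps <- function(model, grid = model@meta$grid, upperPct = 80,
                        lowerPct = 20) {
  prodAll <- model@coefficients * model@meta$columnSd
  out <- list()
  for (f in .FIELD_LABELS) {
    sel <- model@columnField == f
    if (sum(sel) < 2L) {
      warnf("field %s has < 2 active columns; empty contours", f)
      out[[f]] <- list(favored = integer(), disfavored = integer(),
                       thresholds = c(lower = NA_real_, upper = NA_real_))
      next
    }
    pr <- prodAll[sel]
    pts <- ((model@columnIndex[sel] - 1L) %% prod(grid@counts)) + 1L
    thr <- stats::quantile(pr, c(lowerPct, upperPct) / 100, names = FALSE)
    out[[f]] <- list(favored = pts[pr > thr[2L]],
                     disfavored = pts[pr < thr[1L]],
                     thresholds = c(lower = thr[1L], upper = thr[2L]))
  }
  new("ContourSet", contours = out, grid = grid)
}

#' Export contour sets as OpenDX scalar grids
#'
#' Writes one file per field and sign (\code{<field>_favored.dx},
#' \code{<field>_disfavored.dx}) containing the coefficient x standard
#' deviation product on the selected points and 0 elsewhere.
#'
#' @param contours a \linkS4class{ContourSet}.
#' @param model the fitted \linkS4class{PlsQsarModel}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
exportContours <- function(contours, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- contours@grid
  nPts <- prod(grid@counts)
  prodAll <- model@coefficients * model@meta$columnSd
  paths <- character()
  for (f in names(contours@contours)) {
    ct <- contours@contours[[f]]
    sel <- model@columnField == f
    pts <- ((model@columnIndex[sel] - 1L) %% nPts) + 1L
    vals <- stats::setNames(prodAll[sel], pts)
    for (side in c("favored", "disfavored")) {
      g <- numeric(nPts)
      g[ct[[side]]] <- vals[as.character(ct[[side]])]
      p <- file.path(dir, paste0(f, "_", side, ".dx"))
      writeOpenDx(g, grid, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
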