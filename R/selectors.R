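# Baseline wavelength selectors: successive projections algorithm (SPA),
# competitive adaptive reweighted sampling (CARS), and regression
# coefficients with non-maximum suppression (RC).

#' @noRd
selected_bands <- function(method, bands) {
  structure(list(method = method, bands = sort(unique(as.integer(bands))),
                 n = length(unique(bands))),
            class = "selected_bands")
}

#' @export
print.selected_bands <- function(x, ...) {
  cat(sprintf("<selected_bands> %s: %d bands: %s\n", x$method, x$n,
              paste(x$bands, collapse = ", ")))
  invisible(x)
}

#' Successive projections algorithm
#'
#' Forward selection minimising collinearity: from each starting
#' wavelength a candidate chain is built by repeatedly picking the column
#' with the largest norm after orthogonal projection onto the complement
#' of the chain so far (Gram-Schmidt). Every (start, chain length)
#' candidate subset is scored by the k-fold cross-validated RMSE of a
#' least-squares model, and the best subset wins.
#'
#' @param X samples x features matrix (column-centred internally).
#' @param y response vector.
#' @param max_vars largest subset size considered.
#' @param folds cross-validation folds for subset scoring.
#' @param starts candidate starting columns (default: all).
#' @return `selected_bands` (method `"SPA"`).
#' @export
spa_select <- function(X, y, max_vars = 10, folds = 5, starts = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(max_vars < min(n, p))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (is.null(starts)) starts <- seq_len(p)
  nz <- colSums(Xc^2) > 1e-12
  starts <- starts[nz[starts]]
  chains <- lapply(starts, function(s) spa_chain(Xc, s, max_vars))
  fold <- cv_folds(n, min(folds, n))
  best <- NULL; best_rmse <- Inf
  for (chain in chains) {
    for (m in seq_along(chain)) {
      sub <- chain[seq_len(m)]
      rmse <- mlr_cv_rmse(X[, sub, drop = FALSE], y, fold)
      if (is.finite(rmse) && rmse < best_rmse) {
        best_rmse <- rmse; best <- sub
      }
    }
  }
  if (is.null(best)) stop("SPA found no usable subset")
  selected_bands("SPA", best)
}

# One projection chain: successively add the column with the largest
# residual norm after projecting out the span of the selected columns.
#' @noRd
spa_chain <- function(Xc, start, max_vars) {
  p <- ncol(Xc)
  sel <- start
  R <- Xc
  for (step in seq_len(max_vars - 1L)) {
    v <- R[, sel[length(sel)]]
    nv <- sum(v^2)
    if (nv < 1e-12) break
    R <- R - outer(v, as.numeric(crossprod(R, v)) / nv)[, , drop = FALSE]
    norms <- colSums(R^2)
    norms[sel] <- -Inf
    cand <- which.max(norms)
    if (norms[cand] < 1e-12) break
    sel <- c(sel, cand)
  }
  sel
}

#' @noRd
mlr_cv_rmse <- function(Xs, y, fold) {
  errs <- 0; n <- length(y)
  for (f in unique(fold)) {
    tr <- fold != f
    df <- data.frame(y = y[tr], Xs[tr, , drop = FALSE])
    m <- tryCatch(lm(y ~ ., data = df), error = function(e) NULL)
    if (is.null(m)) return(Inf)
    nd <- data.frame(Xs[!tr, , drop = FALSE])
    names(nd) <- names(df)[-1L]
    pr <- suppressWarnings(predict(m, nd))
    if (any(!is.finite(pr))) return(Inf)
    errs <- errs + sum((pr - y[!tr])^2)
  }
  sqrt(errs / n)
}

#' Competitive adaptive reweighted sampling
#'
#' Each Monte-Carlo iteration fits a PLS model on a random row sample of
#' the currently retained wavelengths; an exponentially decreasing forced
#' retention ratio prunes the wavelength set, with survivors drawn by
#' adaptive reweighted sampling proportional to the absolute PLS
#' regression coefficients. The subset with the smallest k-fold RMSECV
#' over all iterations is returned.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param n_mc Monte-Carlo iterations (default 50).
#' @param row_frac row sampling fraction per iteration (default 0.8).
#' @param ncomp PLS components used inside the loop.
#' @param folds folds for the RMSECV scoring.
#' @return `selected_bands` (method `"CARS"`) with the retention-ratio
#'   `schedule` and per-iteration `rmsecv` as attributes.
#' @export
cars_select <- function(X, y, n_mc = 50, row_frac = 0.8, ncomp = 10,
                        folds = 5) {
  X <- ensure_colnames(as.matrix(X))
  n <- nrow(X); p <- ncol(X)
  stopifnot(n_mc >= 2L)
  # exponentially decreasing enforced retention: from all p wavelengths at
  # the first iteration down to 2 at the last
  a <- (p / 2)^(1 / (n_mc - 1))
  schedule <- pmax(2L, pmin(p, round(p * a^(-(seq_len(n_mc) - 1L)))))
  retained <- seq_len(p)
  best <- retained; best_rmse <- Inf
  rmsecv <- rep(NA_real_, n_mc)
  for (it in seq_len(n_mc)) {
    rows <- sample.int(n, max(4L, round(row_frac * n)))
    nc <- min(ncomp, length(retained), length(rows) - 2L)
    if (nc < 1L) break
    m <- mixOmics::pls(X[rows, retained, drop = FALSE], y[rows],
                       ncomp = nc, mode = "regression")
    w <- abs(predict(m, X[rows, retained, drop = FALSE])$B.hat[, 1L, nc])
    n_keep <- min(schedule[it], length(retained))
    if (!any(w > 0)) w <- rep(1, length(w))
    retained <- if (n_keep >= length(retained)) retained else
      sort(retained[sample.int(length(retained), n_keep, prob = w)])
    rmsecv[it] <- pls_cv_rmse(X[, retained, drop = FALSE], y,
                              min(ncomp, length(retained)), folds)
    if (is.finite(rmsecv[it]) && rmsecv[it] < best_rmse) {
      best_rmse <- rmsecv[it]; best <- retained
    }
  }
  out <- selected_bands("CARS", best)
  attr(out, "schedule") <- schedule
  attr(out, "rmsecv") <- rmsecv
  out
}

#' @noRd
pls_cv_rmse <- function(Xs, y, ncomp, folds) {
  Xs <- ensure_colnames(as.matrix(Xs))
  n <- nrow(Xs)
  fold <- cv_folds(n, min(folds, n))
  ncomp <- min(ncomp, ncol(Xs))
  errs <- 0
  for (f in unique(fold)) {
    tr <- fold != f
    nc <- min(ncomp, sum(tr) - 2L)
    if (nc < 1L) return(Inf)
    m <- tryCatch(mixOmics::pls(Xs[tr, , drop = FALSE], y[tr], ncomp = nc,
                                mode = "regression"),
                  error = function(e) NULL)
    if (is.null(m)) return(Inf)
    pr <- predict(m, Xs[!tr, , drop = FALSE])$predict[, 1L, nc]
    errs <- errs + sum((pr - y[!tr])^2)
  }
  sqrt(errs / n)
}

#' Regression-coefficient wavelength selection
#'
#' Ranks wavelengths by the absolute regression coefficients of a PLSR
#' model (LV count chosen by RMSECV) and keeps local maxima under
#' non-maximum suppression: a band survives when its |coefficient| is the
#' largest within +/- `nms_window` bands and at least `threshold_frac` of
#' the global maximum.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param nms_window suppression half-width in bands (default 5).
#' @param threshold_frac minimum |coefficient| as a fraction of the global
#'   maximum (default 0.2).
#' @param max_lv passed to [plsr_fit()].
#' @return `selected_bands` (method `"RC"`) with the coefficient vector as
#'   attribute `"coefficients"`.
#' @export
rc_select <- function(X, y, nms_window = 5, threshold_frac = 0.2,
                      max_lv = 15) {
  m <- plsr_fit(X, y, max_lv = max_lv)
  b <- abs(m$coefficients)
  keep <- nms_local_maxima(b, nms_window, threshold_frac * max(b))
  out <- selected_bands("RC", keep)
  attr(out, "coefficients") <- m$coefficients
  out
}

#' @noRd
nms_local_maxima <- function(v, window, threshold) {
  p <- length(v)
  keep <- logical(p)
  for (i in seq_len(p)) {
    lo <- max(1L, i - window); hi <- min(p, i + window)
    win <- v[lo:hi]
    # ties broken toward the lowest band index
    keep[i] <- v[i] >= threshold && v[i] == max(win) &&
      i == lo + which.max(win) - 1L
  }
  which(keep)
}
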