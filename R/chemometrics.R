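# Chemometric toolchain: SPXY sample-set partitioning, PLSR with RMSECV
# latent-variable selection, grid-searched SVR, and the five-fold
# calibration / cross-validation / prediction evaluation protocol.

#' SPXY calibration / prediction split
#'
#' Sample-set partitioning based on joint x-y distances: pairwise
#' Euclidean distances on the predictors and on the response are each
#' normalised by their maximum and summed; the two most distant samples
#' seed the calibration set and samples are then added greedily by largest
#' minimum distance to the already-selected set, until the calibration
#' share is reached. Maximises the spread of both sets. Deterministic.
#'
#' @param X samples x features matrix (e.g. mean spectra).
#' @param y response vector.
#' @param ratio calibration share (default 2/3, a 2:1 split).
#' @return list of class `dataset_split` with sorted `calibration` and
#'   `prediction` index vectors and the `ratio`.
#' @export
spxy_split <- function(X, y, ratio = 2 / 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3L, length(y) == n)
  dx <- as.matrix(dist(X))
  dy <- abs(outer(y, y, "-"))
  if (max(dx) == 0 && max(dy) == 0)
    stop("all samples identical: SPXY split is degenerate")
  d <- (if (max(dx) > 0) dx / max(dx) else dx) +
       (if (max(dy) > 0) dy / max(dy) else dy)
  n_cal <- round(ratio * n)
  seed_pair <- which(d == max(d), arr.ind = TRUE)[1L, ]
  sel <- as.integer(seed_pair)
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    mind <- apply(d[rest, sel, drop = FALSE], 1L, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  structure(list(calibration = sort(sel),
                 prediction = sort(setdiff(seq_len(n), sel)),
                 ratio = ratio),
            class = "dataset_split")
}

#' @noRd
ensure_colnames <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' @noRd
cv_folds <- function(n, k) sample(rep(seq_len(k), length.out = n))

#' Fit a PLSR model, choosing the latent-variable count by RMSECV
#'
#' The root-mean-square error of cross-validation is estimated by k-fold
#' cross-validation with `repeats` repeats for every LV count up to
#' `max_lv`; the count minimising RMSECV is kept and the model refitted on
#' all rows.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param max_lv largest LV count considered (capped at
#'   `min(n - 2, n_features)`).
#' @param folds,repeats cross-validation layout (5-fold, 2 repeats).
#' @return object of class `plsr_model`: the fitted model, `lv`, the
#'   `rmsecv` curve, and the regression `coefficients` at `lv`.
#' @export
plsr_fit <- function(X, y, max_lv = 15, folds = 5, repeats = 2) {
  X <- ensure_colnames(as.matrix(X))
  n <- nrow(X)
  keep <- which(apply(X, 2L, var) > 0)
  if (length(keep) < 1L) stop("no non-constant predictor columns")
  max_lv <- min(max_lv, n - 2L, length(keep))
  if (max_lv < 1L) stop("too few samples/features for PLSR")
  Xk <- X[, keep, drop = FALSE]
  sse <- numeric(max_lv)
  for (r in seq_len(repeats)) {
    fold <- cv_folds(n, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (sum(tr) <= max_lv) next
      m <- mixOmics::pls(Xk[tr, , drop = FALSE], y[tr], ncomp = max_lv,
                         mode = "regression")
      p <- predict(m, Xk[!tr, , drop = FALSE])$predict[, 1L, , drop = FALSE]
      for (lv in seq_len(max_lv))
        sse[lv] <- sse[lv] + sum((p[, 1L, lv] - y[!tr])^2)
    }
  }
  rmsecv <- sqrt(sse / (repeats * n))
  lv <- which.min(rmsecv)
  m <- mixOmics::pls(Xk, y, ncomp = lv, mode = "regression")
  bh <- predict(m, Xk)$B.hat[, 1L, lv]
  coefs <- numeric(ncol(X)); coefs[keep] <- bh
  structure(list(model = m, lv = lv, rmsecv = rmsecv, keep = keep,
                 coefficients = coefs, colnames = colnames(X)),
            class = "plsr_model")
}

#' @param object a `plsr_model`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @rdname plsr_fit
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$colnames
  nk <- newdata[, object$keep, drop = FALSE]
  as.numeric(predict(object$model, nk)$predict[, 1L, object$lv])
}

#' Fit an SVR model with grid-searched hyperparameters
#'
#' Hyperparameters minimising k-fold cross-validated MSE over the grid are
#' selected and the model refitted on all rows. The default grid is
#' cost in \{0.1, 1, 10, 100\} and epsilon in \{0.01, 0.1, 1\}; for the
#' RBF kernel, gamma spans \{0.1, 1, 10\} times the scale heuristic
#' `1 / (n_features * var(X))`.
#'
#' @param X samples x features matrix.
#' @param y response vector.
#' @param kernel `"linear"` or `"rbf"`.
#' @param grid optional data.frame of candidate hyperparameters (columns
#'   `cost`, `epsilon` and, for RBF, `gamma`).
#' @param folds cross-validation folds.
#' @return object of class `svr_model`: the e1071 fit, the chosen `params`
#'   and the full `cv` table.
#' @export
svr_fit <- function(X, y, kernel = c("linear", "rbf"), grid = NULL,
                    folds = 5) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(grid)) {
    grid <- expand.grid(cost = c(0.1, 1, 10, 100),
                        epsilon = c(0.01, 0.1, 1))
    if (kernel == "rbf") {
      g0 <- 1 / (ncol(X) * max(var(as.vector(X)), .Machine$double.eps))
      grid <- merge(grid, data.frame(gamma = g0 * c(0.1, 1, 10)))
    }
  }
  if (!nrow(grid)) stop("empty hyperparameter grid")
  fold <- cv_folds(n, min(folds, n))
  e1071_kernel <- if (kernel == "rbf") "radial" else "linear"
  fit1 <- function(tr, row) {
    args <- list(x = X[tr, , drop = FALSE], y = y[tr],
                 type = "eps-regression", kernel = e1071_kernel,
                 cost = row$cost, epsilon = row$epsilon, scale = FALSE)
    if (kernel == "rbf") args$gamma <- row$gamma
    do.call(e1071::svm, args)
  }
  grid$cv_mse <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- 0
    for (f in unique(fold)) {
      tr <- fold != f
      m <- tryCatch(fit1(tr, grid[i, ]), error = function(e) NULL)
      if (is.null(m)) return(Inf)     # e.g. no support vectors survive
      p <- as.numeric(predict(m, X[!tr, , drop = FALSE]))
      errs <- errs + sum((p - y[!tr])^2)
    }
    errs / n
  }, 0)
  if (!any(is.finite(grid$cv_mse)))
    stop("no hyperparameter combination produced a valid SVR fit")
  bi <- which.min(grid$cv_mse)
  best <- grid[bi, ]
  structure(list(model = fit1(rep(TRUE, n), best), params = best,
                 cv = grid, kernel = kernel),
            class = "svr_model")
}

#' @param object an `svr_model`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @rdname svr_fit
#' @export
predict.svr_model <- function(object, newdata, ...) {
  as.numeric(predict(object$model, as.matrix(newdata)))
}

#' Model specification for the evaluation protocol
#'
#' @param method `"plsr"`, `"svr-linear"` or `"svr-rbf"`, or supply your
#'   own `fit(X, y)` / `predict(model, X)` pair.
#' @param ... passed to [plsr_fit()] / [svr_fit()].
#' @param fit,predict custom functions (used when `method = "custom"`).
#' @return list with `fit`, `predict` and `name`.
#' @export
model_spec <- function(method = c("plsr", "svr-linear", "svr-rbf",
                                  "custom"), ..., fit = NULL,
                       predict = NULL) {
  method <- match.arg(method)
  dots <- list(...)
  switch(method,
    plsr = list(name = "plsr",
                fit = function(X, y) do.call(plsr_fit, c(list(X, y), dots)),
                predict = function(m, X) predict(m, X)),
    "svr-linear" = list(name = "svr-linear",
                fit = function(X, y)
                  do.call(svr_fit, c(list(X, y, kernel = "linear"), dots)),
                predict = function(m, X) predict(m, X)),
    "svr-rbf" = list(name = "svr-rbf",
                fit = function(X, y)
                  do.call(svr_fit, c(list(X, y, kernel = "rbf"), dots)),
                predict = function(m, X) predict(m, X)),
    custom = list(name = "custom", fit = fit, predict = predict))
}

#' Five-fold evaluation protocol
#'
#' The calibration set is split into `k` random segments. For each fold
#' the model is fitted on the other segments and evaluated on (a) the
#' training segments themselves (Rc2, MSEc), (b) the held-out segment
#' (Rcv2, MSEcv) and (c) the full prediction set (Rp2, MSEp). All six
#' metrics are averaged over the folds.
#'
#' @param X_cal,y_cal calibration set.
#' @param X_pred,y_pred prediction (test) set.
#' @param spec a [model_spec()].
#' @param k number of folds.
#' @return object of class `model_metrics`: the six averaged metrics plus
#'   the per-fold records in `$folds`.
#' @export
crossval_protocol <- function(X_cal, y_cal, X_pred, y_pred, spec, k = 5) {
  X_cal <- as.matrix(X_cal); X_pred <- as.matrix(X_pred)
  n <- nrow(X_cal)
  stopifnot(n >= k)
  fold <- cv_folds(n, k)
  recs <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    m <- spec$fit(X_cal[tr, , drop = FALSE], y_cal[tr])
    pt <- spec$predict(m, X_cal[tr, , drop = FALSE])
    pv <- spec$predict(m, X_cal[!tr, , drop = FALSE])
    pp <- spec$predict(m, X_pred)
    data.frame(Rc2 = r_squared(y_cal[tr], pt), MSEc = mse(y_cal[tr], pt),
               Rcv2 = r_squared(y_cal[!tr], pv),
               MSEcv = mse(y_cal[!tr], pv),
               Rp2 = r_squared(y_pred, pp), MSEp = mse(y_pred, pp))
  })
  folds_df <- do.call(rbind, recs)
  out <- as.list(colMeans(folds_df))
  out$folds <- folds_df
  out$model <- spec$name
  class(out) <- "model_metrics"
  out
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("<model_metrics> %s: Rc2 %.4f MSEc %.4f | Rcv2 %.4f MSEcv %.4f | Rp2 %.4f MSEp %.4f\n",
              x$model, x$Rc2, x$MSEc, x$Rcv2, x$MSEcv, x$Rp2, x$MSEp))
  invisible(x)
}
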