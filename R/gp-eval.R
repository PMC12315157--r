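# Program evaluation and SVR fitness.

#' Evaluate a program tree on one or more samples
#'
#' Spectra-based trees evaluate on a samples x bands matrix in one
#' vectorised pass (SF values are per-sample vectors). Image-based trees
#' evaluate per hyperspectral cube; pass a list of cubes to get one
#' feature row per cube.
#'
#' @param tree a GP tree.
#' @param input for the spectra structure: a numeric matrix (samples x
#'   bands) or a single spectrum vector; for the image structure: an
#'   [hsi_cube] or a list of them.
#' @param fset the matching [gp_function_set()].
#' @return numeric matrix, samples x n_features.
#' @export
gp_evaluate <- function(tree, input, fset) {
  if (fset$structure == "spectra") {
    if (is.null(dim(input))) input <- matrix(input, nrow = 1L)
    out <- eval_node(tree, input, fset)
    if (is.null(dim(out))) out <- matrix(out, ncol = 1L)
    return(out)
  }
  cubes <- if (inherits(input, "hsi_cube")) list(input) else input
  rows <- lapply(cubes, function(cb) eval_node(tree, cb, fset))
  do.call(rbind, rows)
}

#' @noRd
eval_node <- function(node, input, fset) {
  if (node$kind == "term") return(node$value)
  if (node$kind == "input") return(input)
  args <- lapply(node$children, eval_node, input = input, fset = fset)
  fset$prims[[node$name]]$fun(args, NULL)
}

#' Feature standardisation
#'
#' Column-wise z-scoring `(x - mean) / sd` with statistics taken from a
#' fitting matrix; zero-variance columns map to 0.
#'
#' @param fit numeric matrix the statistics are estimated from.
#' @return object of class `feature_standardiser` with `$mean`, `$sd` and
#'   `$degenerate` (logical, zero-variance columns).
#' @export
feature_standardiser <- function(fit) {
  mu <- colMeans(fit)
  s <- apply(fit, 2L, sd)
  structure(list(mean = mu, sd = s, degenerate = !is.finite(s) | s == 0),
            class = "feature_standardiser")
}

#' @param std a `feature_standardiser`.
#' @param X matrix to transform.
#' @rdname feature_standardiser
#' @export
standardise_features <- function(std, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = length(std$mean))
  Z <- sweep(X, 2L, std$mean, "-")
  s <- ifelse(std$degenerate, 1, std$sd)
  Z <- sweep(Z, 2L, s, "/")
  Z[, std$degenerate] <- 0
  Z
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; may be negative when
#' the model underperforms the mean predictor.
#'
#' @param y observed values.
#' @param yhat predictions.
#' @return scalar R-squared.
#' @export
r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sst
}

#' Mean squared error
#' @param y observed values.
#' @param yhat predictions.
#' @return scalar MSE.
#' @export
mse <- function(y, yhat) mean((y - yhat)^2)

#' @noRd
fitness_sentinel <- function(fitness_fn) {
  if (fitness_fn == "R2") -Inf else Inf
}

#' @noRd
fitness_better <- function(a, b, fitness_fn) {
  if (fitness_fn == "R2") a > b else a < b
}

#' Fitness of a program tree
#'
#' Features are extracted for all calibration samples, standardised across
#' the combined extracted feature vectors, and a linear-kernel SVR (fixed
#' cost and epsilon) is fitted on the training portion of a fixed 70:30
#' split. Fitness is the R-squared (maximised) or MSE (minimised) of the
#' model on the held-out evaluation portion. Evaluation failures and
#' non-finite features receive the worst-possible sentinel (-Inf / +Inf).
#'
#' @param tree a GP tree.
#' @param input calibration inputs (matrix of spectra, or list of cubes).
#' @param y calibration targets.
#' @param train_idx indices of the training portion (the rest evaluate).
#' @param fset the matching [gp_function_set()].
#' @param fitness_fn `"R2"` or `"MSE"`.
#' @param svr_cost,svr_epsilon linear SVR hyperparameters.
#' @return list with `fitness` and `n_features`.
#' @export
gp_fitness <- function(tree, input, y, train_idx, fset,
                       fitness_fn = c("R2", "MSE"),
                       svr_cost = 1, svr_epsilon = 0.1) {
  fitness_fn <- match.arg(fitness_fn)
  bad <- list(fitness = fitness_sentinel(fitness_fn), n_features = NA_integer_)
  feats <- tryCatch(gp_evaluate(tree, input, fset),
                    error = function(e) NULL)
  if (is.null(feats) || !all(is.finite(feats))) return(bad)
  std <- feature_standardiser(feats)
  Z <- standardise_features(std, feats)
  eval_idx <- setdiff(seq_len(nrow(Z)), train_idx)
  fit <- tryCatch(
    e1071::svm(x = Z[train_idx, , drop = FALSE], y = y[train_idx],
               type = "eps-regression", kernel = "linear",
               cost = svr_cost, epsilon = svr_epsilon, scale = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  pred <- as.numeric(predict(fit, Z[eval_idx, , drop = FALSE]))
  val <- if (fitness_fn == "R2") r_squared(y[eval_idx], pred)
         else mse(y[eval_idx], pred)
  if (!is.finite(val)) return(bad)
  list(fitness = val, n_features = ncol(Z))
}
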