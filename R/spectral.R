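# Spectrum-level operations: ROI mean spectra, SNV, Savitzky-Golay
# smoothing, and variable-width spectral interval selection.

#' Mean reflectance spectrum over the ROI
#'
#' @param cube an [hsi_cube].
#' @return A `reflectance_spectrum`: list with `values` (length-B) and
#'   `wavelengths_nm`.
#' @export
mean_spectrum <- function(cube) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (!any(cube$roi_mask)) stop("empty ROI: no pixels to average")
  d <- dim(cube$reflectance)
  flat <- matrix(cube$reflectance, d[1L] * d[2L], d[3L])
  vals <- colMeans(flat[as.vector(cube$roi_mask), , drop = FALSE])
  structure(list(values = vals, wavelengths_nm = cube$wavelengths_nm),
            class = "reflectance_spectrum")
}

#' Standard normal variate transform
#'
#' Centres a spectrum and scales it to unit sample standard deviation
#' (n - 1 denominator), correcting additive and multiplicative
#' illumination effects per spectrum.
#'
#' @param x numeric vector.
#' @return numeric vector with mean 0 and sd 1.
#' @export
snv <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("SNV undefined for a constant spectrum")
  (x - mean(x)) / s
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; reproduces polynomials up to
#' degree `polyorder` exactly.
#'
#' @param x numeric vector.
#' @param window odd filter length (default 9).
#' @param polyorder polynomial degree, `< window` (default 2).
#' @return smoothed vector, same length as `x`.
#' @export
savitzky_golay <- function(x, window = 9, polyorder = 2) {
  if (window %% 2 == 0) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be < window")
  if (window > length(x)) stop("`window` longer than the spectrum")
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
}

#' Spectral interval selection
#'
#' Aggregates a window of `width` adjacent bands centred at band `center`
#' into a single scalar spectral feature. Windows overhanging the spectrum
#' edge are truncated: the statistic is computed over the surviving bands
#' only (mean weights renormalised to sum to one).
#'
#' @param values numeric spectrum (length B).
#' @param center 1-based centre band index.
#' @param width odd window width, one of 1, 3, 5, 7, 9, 11.
#' @param mode `"mean"` or `"median"`.
#' @return scalar feature.
#' @export
spectra_interval_select <- function(values, center, width = 1,
                                    mode = c("mean", "median")) {
  mode <- match.arg(mode)
  idx <- interval_indices(length(values), center, width)
  if (mode == "mean") mean(values[idx]) else median(values[idx])
}

#' @noRd
interval_indices <- function(n, center, width) {
  if (!(width %in% c(1, 3, 5, 7, 9, 11)))
    stop("`width` must be one of 1,3,5,7,9,11")
  center <- as.integer(center)
  if (center < 1L || center > n)
    stop("`center` band index out of range [1, ", n, "]")
  h <- (width - 1L) / 2L
  max(1L, center - h):min(n, center + h)
}

#' Read / write a spectrum table
#'
#' CSV with one row per sample; columns are wavelengths in nm (plus an
#' optional leading `sample_id`).
#'
#' @param X samples x bands matrix; `wavelengths_nm` its band centres.
#' @param path file path.
#' @return `read_spectra_csv`: list with `X` (matrix, rownames = sample
#'   ids when present) and `wavelengths_nm`.
#' @export
write_spectra_csv <- function(X, wavelengths_nm, path) {
  df <- as.data.frame(X)
  names(df) <- format(wavelengths_nm, trim = TRUE)
  df <- cbind(sample_id = if (is.null(rownames(X))) seq_len(nrow(X)) else
                rownames(X), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ids <- NULL
  if (names(df)[1L] == "sample_id") { ids <- df[[1L]]; df <- df[-1L] }
  X <- as.matrix(df)
  if (!is.null(ids)) rownames(X) <- ids
  list(X = X, wavelengths_nm = as.numeric(names(df)))
}
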