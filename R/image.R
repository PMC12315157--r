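# Grayscale-image operations: hyperspectral-to-grayscale interval
# selection, the filtering / normalisation function set, and spectral
# aggregation. All 2-D filters use symmetric (reflect) border padding and
# are computed over the full rectangle; downstream features read only ROI
# pixels, so convolution stays well-defined near mask holes.

VALID_WIDTHS <- c(1, 3, 5, 7, 9, 11)
VALID_KERNELS <- c(3, 5, 7, 9, 11)
GABOR_THETAS <- (0:7) * pi / 4
GABOR_FREQS <- pi * 2^(-(1 + 0.5 * (0:3)))

#' Grayscale image with ROI mask
#'
#' @param values numeric rows x cols matrix.
#' @param roi_mask logical matrix of the same shape (default all-TRUE).
#' @return object of class `gsi`.
#' @export
gsi <- function(values, roi_mask = NULL) {
  values <- as.matrix(values)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(values), ncol(values))
  if (!all(dim(roi_mask) == dim(values)))
    stop("mask shape must equal image shape")
  if (!all(is.finite(values[roi_mask])))
    stop("non-finite values inside the ROI")
  structure(list(values = values, roi_mask = roi_mask), class = "gsi")
}

#' Select a grayscale image from a wavelength interval
#'
#' Aggregates a window of `width` adjacent bands centred at `center` into
#' one image, per pixel. Windows overhanging the spectral range are
#' truncated and the averaging weights renormalised to sum to one over the
#' surviving bands. The ROI mask is inherited from the cube.
#'
#' @param cube an [hsi_cube].
#' @param center 1-based centre band index.
#' @param width odd window width in 1, 3, 5, 7, 9, 11.
#' @param mode `"mean"`, `"median"` or `"gaussian"`.
#' @param sigma Gaussian width over band offsets, in (0, 5]; required for
#'   `mode = "gaussian"`.
#' @return a [gsi].
#' @export
image_interval_select <- function(cube, center, width = 1,
                                  mode = c("mean", "median", "gaussian"),
                                  sigma = NULL) {
  stopifnot(inherits(cube, "hsi_cube"))
  mode <- match.arg(mode)
  d <- dim(cube$reflectance)
  idx <- interval_indices(d[3L], center, width)
  slab <- cube$reflectance[, , idx, drop = FALSE]
  flat <- matrix(slab, d[1L] * d[2L], length(idx))
  vals <- switch(mode,
    mean = rowMeans(flat),
    median = if (length(idx) == 1L) flat[, 1L] else
      apply(flat, 1L, median),
    gaussian = {
      if (is.null(sigma)) stop("`sigma` required for gaussian mode")
      if (sigma <= 0 || sigma > 5) stop("`sigma` must be in (0, 5]")
      w <- exp(-((idx - center)^2) / (2 * sigma^2))
      w <- w / sum(w)                       # renormalise over surviving bands
      as.numeric(flat %*% w)
    })
  gsi(matrix(vals, d[1L], d[2L]), cube$roi_mask)
}

#' Apply an image filter or normalisation
#'
#' The grayscale function set: Gaussian smoothing, derivative-of-Gaussian
#' gradient magnitude, median / max / min rank filters, Gabor filters at
#' fixed 7x7 or 9x9 kernel size, and min-max scaling of ROI values to
#' `[0, 1]` (a constant ROI maps to all zeros). The ROI mask passes through
#' unchanged.
#'
#' @param image a [gsi].
#' @param kind one of `"gaussian"`, `"dog"`, `"median"`, `"max"`, `"min"`,
#'   `"gabor7"`, `"gabor9"`, `"minmax"`.
#' @param k odd kernel size in 3, 5, 7, 9, 11 (gaussian/median/max/min).
#' @param sigma Gaussian width in (0, 5] (gaussian/dog).
#' @param f,theta Gabor spatial frequency (radians/pixel, one of
#'   `pi * 2^-(1 + 0.5 v)`, v = 0..3) and orientation (multiple of pi/4).
#' @return a [gsi] of the same shape.
#' @export
apply_filter <- function(image, kind, k = NULL, sigma = NULL,
                         f = NULL, theta = NULL) {
  stopifnot(inherits(image, "gsi"))
  x <- image$values
  out <- switch(kind,
    gaussian = {
      check_kernel(k); check_sigma(sigma)
      correlate2(x, gaussian_kernel(k, sigma))
    },
    dog = {
      check_sigma(sigma)
      dog_magnitude(x, sigma)
    },
    median = { check_kernel(k); rank_filter(x, k, "median") },
    max = { check_kernel(k); rank_filter(x, k, "max") },
    min = { check_kernel(k); rank_filter(x, k, "min") },
    gabor7 = correlate2(x, gabor_kernel(7L, check_gabor(f, theta)$f,
                                        check_gabor(f, theta)$theta)),
    gabor9 = correlate2(x, gabor_kernel(9L, check_gabor(f, theta)$f,
                                        check_gabor(f, theta)$theta)),
    minmax = {
      v <- x[image$roi_mask]
      rng <- range(v)
      if (diff(rng) == 0) x * 0 else (x - rng[1L]) / diff(rng)
    },
    stop("unknown filter kind: ", kind))
  gsi(out, image$roi_mask)
}

#' Mean intensity over the ROI of a grayscale image
#'
#' @param image a [gsi].
#' @return scalar spectral feature.
#' @export
spectral_aggregate <- function(image) {
  stopifnot(inherits(image, "gsi"))
  if (!any(image$roi_mask)) stop("empty ROI: nothing to aggregate")
  mean(image$values[image$roi_mask])
}

# ---- kernels ---------------------------------------------------------------

#' @noRd
gaussian_kernel <- function(k, sigma) {
  h <- (k - 1) / 2
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

#' Real Gabor kernel
#'
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(f x' + psi)` with
#' `x' = x cos(theta) + y sin(theta)`. The envelope width, aspect ratio and
#' phase offset are fixed (sigma = 2, gamma = 0.3, psi = 1); orientation and
#' frequency are the evolvable parameters.
#'
#' @param size odd kernel side (7 or 9 in the function set).
#' @param f spatial frequency in radians per pixel.
#' @param theta orientation in radians.
#' @param sigma,gamma,psi fixed envelope parameters.
#' @return size x size numeric matrix.
#' @export
gabor_kernel <- function(size, f, theta, sigma = 2, gamma = 0.3, psi = 1) {
  h <- (size - 1) / 2
  xs <- matrix(rep(-h:h, each = size), size, size)   # column offsets
  ys <- matrix(rep(-h:h, times = size), size, size)  # row offsets
  xp <- xs * cos(theta) + ys * sin(theta)
  yp <- -xs * sin(theta) + ys * cos(theta)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(f * xp + psi)
}

#' @noRd
dog_magnitude <- function(x, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  u <- -h:h
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  dg <- -(u / sigma^2) * exp(-u^2 / (2 * sigma^2))
  kx <- outer(g, dg)    # d/dcol
  ky <- outer(dg, g)    # d/drow
  gx <- correlate2(x, kx)
  gy <- correlate2(x, ky)
  sqrt(gx^2 + gy^2)
}

# ---- spatial machinery -----------------------------------------------------

#' @noRd
pad_symmetric <- function(x, hr, hc) {
  n <- nrow(x); m <- ncol(x)
  ri <- c(rev(seq_len(min(hr, n))), seq_len(n),
          rev(seq_len(n))[seq_len(min(hr, n))])
  ci <- c(rev(seq_len(min(hc, m))), seq_len(m),
          rev(seq_len(m))[seq_len(min(hc, m))])
  x[ri, ci, drop = FALSE]
}

# Direct cross-correlation (OpenCV filter2D semantics) with symmetric
# border padding; kernel sides are <= 11 so the shift-and-add loop is cheap.
#' @noRd
correlate2 <- function(x, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  p <- pad_symmetric(x, hr, hc)
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (kern[i, j] == 0) next
      out <- out + kern[i, j] * p[(i):(i + n - 1L), (j):(j + m - 1L)]
    }
  }
  out
}

#' @noRd
rank_filter <- function(x, k, stat) {
  h <- (k - 1L) %/% 2L
  p <- pad_symmetric(x, h, h)
  n <- nrow(x); m <- ncol(x)
  if (stat == "min" || stat == "max") {
    acc <- NULL
    f <- if (stat == "min") pmin else pmax
    for (i in 0:(k - 1L)) {
      for (j in 0:(k - 1L)) {
        w <- p[(i + 1L):(i + n), (j + 1L):(j + m)]
        acc <- if (is.null(acc)) w else f(acc, w)
      }
    }
    acc
  } else {
    cols <- matrix(0, n * m, k * k)
    idx <- 1L
    for (i in 0:(k - 1L)) {
      for (j in 0:(k - 1L)) {
        cols[, idx] <- p[(i + 1L):(i + n), (j + 1L):(j + m)]
        idx <- idx + 1L
      }
    }
    matrix(apply(cols, 1L, median), n, m)
  }
}

# ---- parameter checks ------------------------------------------------------

#' @noRd
check_kernel <- function(k) {
  if (is.null(k) || !(k %in% VALID_KERNELS))
    stop("kernel size must be one of 3,5,7,9,11")
  invisible(k)
}

#' @noRd
check_sigma <- function(sigma) {
  if (is.null(sigma) || sigma <= 0 || sigma > 5)
    stop("sigma must be in (0, 5]")
  invisible(sigma)
}

#' @noRd
check_gabor <- function(f, theta) {
  if (is.null(f) || min(abs(f - GABOR_FREQS)) > 1e-8)
    stop("Gabor frequency must be pi * 2^-(1 + 0.5 v), v in 0..3")
  if (is.null(theta) || min(abs(theta - GABOR_THETAS)) > 1e-8)
    stop("Gabor orientation must be a multiple of pi/4 in [0, 7 pi/4]")
  list(f = f, theta = theta)
}
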