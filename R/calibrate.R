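# Reflectance calibration: white-reference overexposure correction,
# raw-count to reflectance rescaling, shell segmentation, quadrat gridding.

#' Reference spectra record
#'
#' Holds the per-band white and dark reference counts needed to calibrate a
#' raw cube, plus a seed white spectrum from a non-overexposed acquisition
#' used to reconstruct saturated white-reference entries.
#'
#' @param white_raw length-B white-reference counts (possibly saturated).
#' @param dark length-B dark-reference counts.
#' @param seed_white length-B counts from a non-overexposed acquisition.
#' @param sensor_max scalar sensor saturation value (counts).
#' @return An object of class `reference_spectra`.
#' @export
reference_spectra <- function(white_raw, dark, seed_white, sensor_max) {
  b <- length(white_raw)
  if (length(dark) != b || length(seed_white) != b)
    stop("white_raw, dark and seed_white must have equal length")
  if (!is.numeric(sensor_max) || sensor_max <= 0)
    stop("sensor_max must be a positive scalar")
  structure(list(white_raw = as.numeric(white_raw),
                 dark = as.numeric(dark),
                 seed_white = as.numeric(seed_white),
                 sensor_max = as.numeric(sensor_max)[1L],
                 fit_params = NULL),
            class = "reference_spectra")
}

#' Correct overexposed white-reference entries
#'
#' White-reference bands whose raw counts exceed the sensor maximum are
#' saturated and carry no information. They are replaced by a power-law
#' transform `a * seed^b + c` of a seed white spectrum, with `(a, b, c)`
#' fitted by unconstrained least squares on the non-overexposed bands
#' (initialised at the linear solution with `b = 1`). Non-overexposed
#' entries pass through unchanged.
#'
#' @param ref a [reference_spectra] record.
#' @return `ref` with `$white_corrected` (length-B counts) and
#'   `$fit_params` (named `a`, `b`, `c`) filled in.
#' @export
correct_white_reference <- function(ref) {
  stopifnot(inherits(ref, "reference_spectra"))
  over <- ref$white_raw > ref$sensor_max
  if (all(over))
    stop("all white-reference entries are overexposed: correction unfittable")
  if (!any(over)) {
    ref$white_corrected <- ref$white_raw
    ref$fit_params <- c(a = 1, b = 1, c = 0)
    return(ref)
  }
  ok <- which(!over)
  if (length(ok) < 3L)
    stop("need at least 3 non-overexposed entries to fit the correction")
  xs <- ref$seed_white[ok]
  ys <- ref$white_raw[ok]
  init <- coef(lm(ys ~ xs))            # b = 1 linearisation
  par0 <- c(a = unname(init[2L]), b = 1, c = unname(init[1L]))
  sse <- function(p) {
    pred <- p[1L] * xs^p[2L] + p[3L]
    if (any(!is.finite(pred))) return(.Machine$double.xmax)
    sum((pred - ys)^2)
  }
  fit <- optim(par0, sse, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  p <- fit$par
  out <- ref$white_raw
  out[over] <- p[1L] * ref$seed_white[over]^p[2L] + p[3L]
  ref$white_corrected <- out
  ref$fit_params <- c(a = unname(p[1L]), b = unname(p[2L]), c = unname(p[3L]))
  ref
}

#' Calibrate raw counts to reflectance
#'
#' Standard flat-field calibration: per pixel and band,
#' `Rc = (RR - RD) / (RW - RD)` with `RR` the raw counts, `RW` the white
#' reference and `RD` the dark reference.
#'
#' @param raw rows x cols x bands array of raw counts.
#' @param white length-B white-reference counts.
#' @param dark length-B dark-reference counts.
#' @param wavelengths_nm band centres in nm.
#' @param roi_mask,meta passed to [hsi_cube()].
#' @return An [hsi_cube] of reflectance.
#' @export
calibrate_reflectance <- function(raw, white, dark, wavelengths_nm,
                                  roi_mask = NULL, meta = list()) {
  d <- dim(raw)
  if (length(d) != 3L) stop("`raw` must be rows x cols x bands")
  if (length(white) != d[3L] || length(dark) != d[3L])
    stop("reference spectra must have one entry per band")
  denom <- white - dark
  if (any(denom == 0))
    stop("degenerate band(s): white == dark at band ",
         paste(which(denom == 0), collapse = ", "))
  if (any(denom < 0))
    stop("white reference below dark reference at band ",
         paste(which(denom < 0), collapse = ", "))
  refl <- sweep(sweep(raw, 3L, dark, "-"), 3L, denom, "/")
  hsi_cube(refl, wavelengths_nm, roi_mask = roi_mask, meta = meta)
}

#' Segment bright specular objects out of the ROI
#'
#' Shells and other specular highlights have a high reflectance where
#' sediment is dark; pixels exceeding a threshold at the band nearest
#' `threshold_wavelength_nm` (873 nm by default) are removed from the ROI
#' mask, and the surviving mask is then eroded by a disc to trim mixed
#' boundary pixels.
#'
#' @param cube an [hsi_cube].
#' @param threshold_wavelength_nm wavelength used for thresholding (nm).
#' @param threshold reflectance cutoff; `NULL` (default) uses Otsu's
#'   threshold computed on ROI pixels of that band.
#' @param erosion_radius disc radius in pixels (0 = no erosion).
#' @return The cube with its `roi_mask` updated; attribute `"empty_roi"` is
#'   TRUE when no pixel survives.
#' @export
segment_bright_objects <- function(cube, threshold_wavelength_nm = 873,
                                   threshold = NULL, erosion_radius = 1) {
  stopifnot(inherits(cube, "hsi_cube"))
  wl <- cube$wavelengths_nm
  if (threshold_wavelength_nm < min(wl) || threshold_wavelength_nm > max(wl))
    stop("threshold wavelength outside the cube's spectral range")
  b <- band_nearest(wl, threshold_wavelength_nm)
  img <- cube$reflectance[, , b]
  if (is.null(threshold)) {
    v <- img[cube$roi_mask]
    threshold <- otsu_threshold(v)
  }
  mask <- cube$roi_mask & !(img > threshold)
  if (erosion_radius >= 1 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(erosion_radius) + 1L,
                                shape = "disc")
    mask <- EBImage::erode(EBImage::Image(mask * 1), brush) > 0.5
    mask <- matrix(as.logical(mask), nrow(cube$roi_mask), ncol(cube$roi_mask))
  }
  cube$roi_mask <- mask
  attr(cube, "empty_roi") <- !any(mask)
  cube
}

#' @noRd
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)), range = rng,
                levels = 256L)
}

#' Divide a quadrat cube into a grid of subregion cubes
#'
#' Splits the spatial extent into `rows` x `cols` cells (5 x 5 by default,
#' the field sampling layout); remainder pixels go to the last row/column.
#' Each cell inherits its crop of the ROI mask.
#'
#' @param cube an [hsi_cube].
#' @param rows,cols grid shape.
#' @return List of `rows * cols` sub-cubes in row-major order; each carries
#'   attributes `cell_row` and `cell_col`.
#' @export
grid_quadrat <- function(cube, rows = 5, cols = 5) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$reflectance)
  if (d[1L] < rows || d[2L] < cols)
    stop("quadrat (", d[1L], "x", d[2L], ") smaller than the ",
         rows, "x", cols, " grid")
  rb <- grid_breaks(d[1L], rows)
  cb <- grid_breaks(d[2L], cols)
  out <- vector("list", rows * cols)
  k <- 1L
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      ri <- rb[[i]]; ci <- cb[[j]]
      sub <- hsi_cube(cube$reflectance[ri, ci, , drop = FALSE],
                      cube$wavelengths_nm,
                      roi_mask = cube$roi_mask[ri, ci, drop = FALSE],
                      meta = cube$meta)
      attr(sub, "cell_row") <- i
      attr(sub, "cell_col") <- j
      out[[k]] <- sub
      k <- k + 1L
    }
  }
  out
}

#' @noRd
grid_breaks <- function(n, k) {
  base <- n %/% k
  starts <- (seq_len(k) - 1L) * base + 1L
  ends <- starts + base - 1L
  ends[k] <- n                       # remainder to the last cell
  Map(function(s, e) s:e, starts, ends)
}

#' Reference-cell positions within the sampling grid
#'
#' The field protocol takes ground-truth cores at the four corners and the
#' direct centre of each 5 x 5 quadrat grid.
#'
#' @param rows,cols grid shape.
#' @return data.frame with columns `row`, `col` (corners then centre).
#' @export
reference_cell_indices <- function(rows = 5, cols = 5) {
  data.frame(row = c(1, 1, rows, rows, (rows + 1) %/% 2),
             col = c(1, cols, 1, cols, (cols + 1) %/% 2))
}
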