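#' Hyperspectral cube container
#'
#' An `hsi_cube` bundles a rows x cols x bands reflectance array with its
#' wavelength axis, a boolean region-of-interest mask (TRUE = analysable
#' pixel) and a free-form acquisition record.
#'
#' @param reflectance numeric 3-D array, rows x cols x bands.
#' @param wavelengths_nm strictly increasing numeric vector, one entry per
#'   band, in nanometres.
#' @param roi_mask logical rows x cols matrix; defaults to all-TRUE.
#' @param meta named list of acquisition metadata (exposure, timestamps, ...).
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(reflectance, wavelengths_nm, roi_mask = NULL, meta = list()) {
  if (length(dim(reflectance)) != 3L)
    stop("`reflectance` must be a 3-D array (rows x cols x bands)")
  d <- dim(reflectance)
  if (length(wavelengths_nm) != d[3L])
    stop("band count (", d[3L], ") != length(wavelengths_nm) (",
         length(wavelengths_nm), ")")
  if (any(diff(wavelengths_nm) <= 0))
    stop("`wavelengths_nm` must be strictly increasing")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, d[1L], d[2L])
  roi_mask <- matrix(as.logical(roi_mask), d[1L], d[2L])
  if (!all(dim(roi_mask) == d[1:2]))
    stop("`roi_mask` shape must equal the spatial shape of `reflectance`")
  if (!all(is.finite(reflectance)))
    stop("`reflectance` must be finite")
  structure(list(reflectance = reflectance,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 roi_mask = roi_mask,
                 meta = meta),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.2f-%.2f nm), %d ROI pixels\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              sum(x$roi_mask)))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$reflectance)

#' Index of the band nearest a target wavelength
#'
#' @param wavelengths_nm numeric vector of band centres (nm), or an
#'   `hsi_cube`.
#' @param nm target wavelength in nm.
#' @return 1-based band index.
#' @export
band_nearest <- function(wavelengths_nm, nm) {
  if (inherits(wavelengths_nm, "hsi_cube"))
    wavelengths_nm <- wavelengths_nm$wavelengths_nm
  which.min(abs(wavelengths_nm - nm))
}
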