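# Synthetic hyperspectral scenes with known ground truth: a smooth
# sediment-like base spectrum with planted Gaussian absorption features
# whose depths encode the target attribute, multiplicative spatial
# texture, bright specular "shell" blobs, per-sample illumination drift
# and per-pixel noise. Used to validate every pipeline stage without
# field data.

#' Synthetic scene specification
#'
#' @param bands number of spectral bands.
#' @param wl_range wavelength range in nm (matching a 204-band VNIR
#'   camera by default).
#' @param image_size spatial size (rows, cols) of each sample cube.
#' @param planted_bands data.frame with columns `center_nm`, `width_nm`
#'   (Gaussian sd) and `depth_per_unit` (reflectance dip per unit of the
#'   attribute). Defaults: absorption features at 675 and 940 nm.
#' @param attribute_range range the attribute is drawn from (defaults to
#'   a 0.5-2.1 organic-matter-like range).
#' @param texture_amplitude,texture_length multiplicative texture field:
#'   Gaussian-smoothed white noise with this sd and correlation length
#'   (pixels). `texture_coupling` scales the amplitude with the attribute.
#' @param shell_count,shell_reflectance number and brightness of specular
#'   blobs inserted bright at all bands.
#' @param illumination_range per-sample multiplicative illumination drift
#'   (uniform draw).
#' @param noise_sd per-pixel, per-band Gaussian noise sd. The default
#'   depth-to-noise ratio at mid-range attribute is 5.
#' @return list of class `scene_spec`.
#' @export
synthetic_scene_spec <- function(bands = 204,
                                 wl_range = c(397.32, 1003.58),
                                 image_size = c(24, 24),
                                 planted_bands = NULL,
                                 attribute_range = c(0.5, 2.1),
                                 texture_amplitude = 0.03,
                                 texture_length = 3,
                                 texture_coupling = 0,
                                 shell_count = 2,
                                 shell_reflectance = 0.9,
                                 illumination_range = c(0.95, 1.05),
                                 noise_sd = 0.01) {
  if (is.null(planted_bands)) {
    planted_bands <- data.frame(center_nm = c(675, 940),
                                width_nm = c(15, 20),
                                depth_per_unit = c(0.04, 0.04))
  }
  wl <- seq(wl_range[1L], wl_range[2L], length.out = bands)
  stopifnot(all(planted_bands$center_nm > wl_range[1L]),
            all(planted_bands$center_nm < wl_range[2L]),
            noise_sd >= 0)
  structure(list(bands = bands, wavelengths_nm = wl,
                 image_size = image_size, planted_bands = planted_bands,
                 attribute_range = attribute_range,
                 texture_amplitude = texture_amplitude,
                 texture_length = texture_length,
                 texture_coupling = texture_coupling,
                 shell_count = shell_count,
                 shell_reflectance = shell_reflectance,
                 illumination_range = illumination_range,
                 noise_sd = noise_sd),
            class = "scene_spec")
}

#' Smooth sediment-like base reflectance spectrum
#'
#' Low-order polynomial rising through the VNIR range, resembling wet
#' sediment reflectance.
#'
#' @param wavelengths_nm wavelengths in nm.
#' @return reflectance vector.
#' @export
base_reflectance <- function(wavelengths_nm) {
  s <- (wavelengths_nm - 400) / 600
  0.08 + 0.32 * s - 0.10 * s^2
}

#' Generate one synthetic sample cube
#'
#' Per-pixel spectrum: base spectrum times an illumination scalar, minus
#' planted Gaussian absorption dips with depth proportional to the
#' attribute `y`, modulated by a multiplicative texture field, plus
#' Gaussian noise; bright shell blobs overwrite their pixels at all
#' bands. The ROI mask excludes nothing (shell segmentation is exercised
#' downstream).
#'
#' @param spec a [synthetic_scene_spec()].
#' @param y attribute value of the sample.
#' @return an [hsi_cube] with `meta$y = y` and `meta$shell_mask`.
#' @export
make_sample <- function(spec, y) {
  nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
  B <- spec$bands
  wl <- spec$wavelengths_nm
  spectrum <- base_reflectance(wl)
  for (i in seq_len(nrow(spec$planted_bands))) {
    pb <- spec$planted_bands[i, ]
    spectrum <- spectrum - y * pb$depth_per_unit *
      exp(-((wl - pb$center_nm)^2) / (2 * pb$width_nm^2))
  }
  illum <- runif(1L, spec$illumination_range[1L],
                 spec$illumination_range[2L])
  amp <- spec$texture_amplitude * (1 + spec$texture_coupling * y)
  tex <- if (amp > 0) {
    smooth_noise(nr, nc, spec$texture_length) * amp
  } else matrix(0, nr, nc)
  field <- 1 + tex
  cube <- array(0, dim = c(nr, nc, B))
  for (b in seq_len(B)) {
    cube[, , b] <- spectrum[b] * illum * field +
      if (spec$noise_sd > 0) matrix(rnorm(nr * nc, sd = spec$noise_sd),
                                    nr, nc) else 0
  }
  shell <- matrix(FALSE, nr, nc)
  if (spec$shell_count > 0) {
    for (s in seq_len(spec$shell_count)) {
      cr <- sample.int(nr, 1L); cc <- sample.int(nc, 1L)
      rad <- sample(2:3, 1L)
      rows <- matrix(rep(seq_len(nr), nc), nr, nc)
      cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
      shell <- shell | ((rows - cr)^2 + (cols - cc)^2 <= rad^2)
    }
    for (b in seq_len(B)) {
      sl <- cube[, , b]
      sl[shell] <- spec$shell_reflectance +
        rnorm(sum(shell), sd = spec$noise_sd)
      cube[, , b] <- sl
    }
  }
  cube[cube < 0] <- 0
  hsi_cube(cube, wl, meta = list(y = y, illumination = illum,
                                 shell_mask = shell))
}

#' @noRd
smooth_noise <- function(nr, nc, corr_length) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_length > 0) {
    k <- min(11L, 2L * ceiling(corr_length) + 1L)
    z <- correlate2(z, gaussian_kernel(k, corr_length))
  }
  s <- sd(as.vector(z))
  if (s > 0) z / s else z
}

#' Generate a synthetic dataset
#'
#' Draws `n` attribute values uniformly over the spec's range, builds one
#' cube per sample, and produces the same manifest the field-data path
#' consumes (`sample_id`, `cube`, `quadrat`, `cell_row`, `cell_col`,
#' `porosity`, `organic_matter`). The attribute plays the role of organic
#' matter; a loosely correlated porosity column is included for interface
#' completeness. When `dir` is given, cubes are written as ENVI pairs and
#' the manifest as `manifest.csv`.
#'
#' @param spec a [synthetic_scene_spec()].
#' @param n number of samples (>= 3).
#' @param dir optional output directory.
#' @return list of class `synthetic_dataset`: `samples` (list of cubes),
#'   `y`, `manifest`, `spec`.
#' @export
make_dataset <- function(spec, n, dir = NULL) {
  stopifnot(n >= 3L)
  y <- runif(n, spec$attribute_range[1L], spec$attribute_range[2L])
  samples <- lapply(y, function(yy) make_sample(spec, yy))
  cells <- reference_cell_indices()
  ci <- ((seq_len(n) - 1L) %% nrow(cells)) + 1L
  ar <- spec$attribute_range
  manifest <- data.frame(
    sample_id = sprintf("synth%03d", seq_len(n)),
    cube = NA_character_,
    quadrat = ((seq_len(n) - 1L) %/% nrow(cells)) + 1L,
    cell_row = cells$row[ci],
    cell_col = cells$col[ci],
    porosity = 27 + 27 * (y - ar[1L]) / diff(ar) + rnorm(n, sd = 2),
    organic_matter = y)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      base <- file.path(dir, manifest$sample_id[i])
      write_envi_cube(samples[[i]], base)
      manifest$cube[i] <- paste0(base, ".hdr")
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(samples = samples, y = y, manifest = manifest,
                 spec = spec),
            class = "synthetic_dataset")
}

#' Mean spectra matrix of a dataset
#'
#' Convenience: per-sample ROI mean spectrum, optionally after bright-
#' shell segmentation and per-pixel SNV + Savitzky-Golay preprocessing
#' (the full pipeline order: segment, pretreat, average).
#'
#' @param samples list of [hsi_cube].
#' @param preprocess apply SNV then Savitzky-Golay per pixel?
#' @param segment_shells remove bright specular pixels from the ROI
#'   first (falls back to the full ROI if segmentation empties it)?
#' @param sg_window,sg_polyorder smoothing parameters.
#' @return samples x bands matrix.
#' @export
dataset_mean_spectra <- function(samples, preprocess = FALSE,
                                 segment_shells = FALSE,
                                 sg_window = 9, sg_polyorder = 2) {
  rows <- lapply(samples, function(cb) {
    if (segment_shells) {
      seg <- segment_bright_objects(cb)
      if (!attr(seg, "empty_roi")) cb <- seg
    }
    if (preprocess) cb <- preprocess_cube(cb, sg_window, sg_polyorder)
    mean_spectrum(cb)$values
  })
  do.call(rbind, rows)
}

#' Per-pixel SNV + Savitzky-Golay preprocessing of a cube
#'
#' @param cube an [hsi_cube].
#' @param sg_window,sg_polyorder smoothing parameters.
#' @return the preprocessed cube.
#' @export
preprocess_cube <- function(cube, sg_window = 9, sg_polyorder = 2) {
  d <- dim(cube$reflectance)
  flat <- matrix(cube$reflectance, d[1L] * d[2L], d[3L])
  mu <- rowMeans(flat)
  s <- apply(flat, 1L, sd)
  s[s == 0] <- 1
  flat <- (flat - mu) / s
  flat <- t(apply(flat, 1L, savitzky_golay, window = sg_window,
                  polyorder = sg_polyorder))
  cube$reflectance <- array(flat, dim = d)
  cube
}
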