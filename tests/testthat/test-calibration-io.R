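test_that("ENVI cubes round-trip through write/read in all interleaves", {
  set.seed(1)
  cube <- random_cube(8, 8, 10)
  for (il in c("bsq", "bil", "bip")) {
    base <- file.path(tempdir(), paste0("rt_", il))
    write_envi_cube(cube, base, interleave = il)
    back <- read_envi_cube(paste0(base, ".hdr"))
    expect_equal(back$reflectance, cube$reflectance, tolerance = 1e-6)
    expect_equal(back$wavelengths_nm, cube$wavelengths_nm,
                 tolerance = 1e-6)
    expect_true(all(back$roi_mask))
  }
})

test_that("a 204-band VNIR header parses with its first wavelength intact", {
  wl <- seq(397.32, 1003.58, length.out = 204)
  cube <- hsi_cube(array(0.5, dim = c(2, 2, 204)), wl)
  base <- file.path(tempdir(), "vnir")
  write_envi_cube(cube, base)
  back <- read_envi_cube(paste0(base, ".hdr"))
  expect_equal(back$wavelengths_nm[1], 397.32, tolerance = 1e-4)
  expect_length(back$wavelengths_nm, 204)
})

test_that("contradictory headers and truncated raw files are rejected", {
  cube <- random_cube(4, 4, 6)
  base <- file.path(tempdir(), "bad")
  write_envi_cube(cube, base)
  hdr <- readLines(paste0(base, ".hdr"))
  writeLines(sub("bands = 6", "bands = 8", hdr), paste0(base, ".hdr"))
  expect_error(read_envi_cube(paste0(base, ".hdr")), "contradictory|size")
  # band count consistent with wavelengths but raw too small
  base2 <- file.path(tempdir(), "bad2")
  write_envi_cube(cube, base2)
  raw <- readBin(paste0(base2, ".raw"), "raw",
                 n = file.info(paste0(base2, ".raw"))$size)
  writeBin(raw[seq_len(length(raw) - 64)], paste0(base2, ".raw"))
  expect_error(read_envi_cube(paste0(base2, ".hdr")), "size")
})

test_that("masks round-trip through PNG and text forms", {
  m <- matrix(c(TRUE, FALSE), 6, 4)
  for (ext in c(".png", ".txt")) {
    p <- file.path(tempdir(), paste0("mask", ext))
    write_roi_mask(m, p)
    expect_identical(read_roi_mask(p), m)
  }
})

test_that("white reference passes through untouched when nothing saturates", {
  set.seed(2)
  ref <- reference_spectra(white_raw = runif(20, 100, 900),
                           dark = rep(5, 20),
                           seed_white = runif(20, 100, 900),
                           sensor_max = 1000)
  out <- correct_white_reference(ref)
  expect_identical(out$white_corrected, ref$white_raw)
  expect_equal(unname(out$fit_params), c(1, 1, 0))
  # idempotence
  again <- correct_white_reference(out)
  expect_identical(again$white_corrected, out$white_corrected)
})

test_that("overexposure fit recovers a known affine transform", {
  set.seed(3)
  seed_white <- seq(50, 800, length.out = 40)
  true_white <- 2 * seed_white + 5          # a=2, b=1, c=5
  sensor_max <- 1200
  observed <- pmin(true_white, 2000)        # entries above 1200 are bogus
  observed[true_white > sensor_max] <- 2000
  ref <- reference_spectra(observed, rep(0, 40), seed_white, sensor_max)
  out <- correct_white_reference(ref)
  expect_equal(unname(out$fit_params["a"]), 2, tolerance = 1e-3)
  expect_equal(unname(out$fit_params["b"]), 1, tolerance = 1e-3)
  expect_equal(unname(out$fit_params["c"]), 5, tolerance = 0.05)
  over <- observed > sensor_max
  expect_equal(out$white_corrected[over], true_white[over],
               tolerance = 1e-2)
  expect_identical(out$white_corrected[!over], observed[!over])
})

test_that("white correction falls back to the seed curve when they agree", {
  seed_white <- seq(100, 500, length.out = 30)
  white <- seed_white
  white[25:30] <- 9999                       # saturated tail
  ref <- reference_spectra(white, rep(0, 30), seed_white, 600)
  out <- correct_white_reference(ref)
  expect_equal(out$white_corrected[25:30], seed_white[25:30],
               tolerance = 1e-4)
})

test_that("fully overexposed white references are unfittable", {
  ref <- reference_spectra(rep(2000, 10), rep(0, 10), 1:10, 100)
  expect_error(correct_white_reference(ref), "overexposed")
})

test_that("reflectance calibration follows (RR - RD) / (RW - RD)", {
  wl <- c(500, 600, 700)
  white <- c(90, 80, 100); dark <- c(10, 20, 40)
  raw_white <- array(rep(white, each = 4), dim = c(2, 2, 3))
  expect_equal(unique(as.vector(
    calibrate_reflectance(raw_white, white, dark, wl)$reflectance)), 1)
  raw_dark <- array(rep(dark, each = 4), dim = c(2, 2, 3))
  expect_equal(unique(as.vector(
    calibrate_reflectance(raw_dark, white, dark, wl)$reflectance)), 0)
  raw <- array(50, dim = c(1, 1, 3))
  got <- calibrate_reflectance(raw, c(90, 90, 90), c(10, 10, 10), wl)
  expect_equal(as.vector(got$reflectance), rep(0.5, 3))
  expect_error(calibrate_reflectance(raw, c(90, 10, 90), c(10, 10, 10), wl),
               "degenerate")
})

test_that("calibration is affine per band (closed form)", {
  set.seed(4)
  wl <- seq(400, 900, length.out = 6)
  white <- runif(6, 200, 900); dark <- runif(6, 0, 50)
  alpha <- array(runif(5 * 4 * 6), dim = c(5, 4, 6))
  raw <- sweep(sweep(alpha, 3, white - dark, "*"), 3, dark, "+")
  got <- calibrate_reflectance(raw, white, dark, wl)
  expect_equal(got$reflectance, alpha, tolerance = 1e-12)
})

test_that("bright-object segmentation removes blocks and erodes the rim", {
  wl <- seq(800, 950, length.out = 4)
  arr <- array(0.2, dim = c(10, 10, 4))
  b873 <- band_nearest(wl, 873)
  arr[4:6, 4:6, b873] <- 0.9                  # bright 3x3 shell block
  cube <- hsi_cube(arr, wl)

  no_change <- segment_bright_objects(cube, threshold = 0.95,
                                      erosion_radius = 0)
  expect_identical(no_change$roi_mask, cube$roi_mask)

  seg <- segment_bright_objects(cube, threshold = 0.5, erosion_radius = 1)
  # oracle: threshold, then keep pixels whose clipped 3x3 neighbourhood
  # survives entirely
  thr <- matrix(TRUE, 10, 10); thr[4:6, 4:6] <- FALSE
  expected <- matrix(FALSE, 10, 10)
  for (r in 1:10) for (c in 1:10) {
    nb <- thr[max(1, r - 1):min(10, r + 1), max(1, c - 1):min(10, c + 1)]
    expected[r, c] <- all(nb)
  }
  expect_identical(seg$roi_mask, expected)
  expect_false(attr(seg, "empty_roi"))

  empty <- segment_bright_objects(cube, threshold = min(arr) - 1)
  expect_true(attr(empty, "empty_roi"))
  expect_false(any(empty$roi_mask))
})

test_that("larger erosion radii never grow the ROI", {
  set.seed(5)
  cube <- random_cube(16, 16, 3, wl = c(800, 873, 950))
  prev <- NULL
  for (r in 0:3) {
    seg <- segment_bright_objects(cube, threshold = 0.8,
                                  erosion_radius = r)
    if (!is.null(prev)) expect_true(all(prev | !seg$roi_mask))
    prev <- seg$roi_mask
  }
})

test_that("quadrat gridding partitions pixels exactly", {
  cube <- make_test_cube(10, 10, 3, wl = c(500, 600, 700))
  cells <- grid_quadrat(cube, 5, 5)
  expect_length(cells, 25)
  expect_true(all(vapply(cells, function(cc) all(dim(cc)[1:2] == 2), TRUE)))

  # ragged case: disjoint cover with remainder in the last row/col
  cube2 <- random_cube(23, 17, 2, wl = c(500, 600))
  cells2 <- grid_quadrat(cube2, 5, 5)
  npix <- vapply(cells2, function(cc) prod(dim(cc)[1:2]), 0)
  expect_equal(sum(npix), 23 * 17)
  total <- Reduce(`+`, lapply(cells2, function(cc) sum(cc$reflectance)))
  expect_equal(total, sum(cube2$reflectance), tolerance = 1e-9)

  expect_error(grid_quadrat(random_cube(4, 10, 2, wl = c(1, 2)), 5, 5),
               "smaller")
})

test_that("reference cells are the four corners and the centre", {
  cells <- reference_cell_indices(5, 5)
  expect_equal(cells$row, c(1, 1, 5, 5, 3))
  expect_equal(cells$col, c(1, 5, 1, 5, 3))
})
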