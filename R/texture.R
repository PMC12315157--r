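# Grey-level co-occurrence matrices and the five Haralick-style
# descriptors (homogeneity, entropy, contrast, correlation, energy), plus
# first-order histogram statistics.

GLCM_ANGLES <- (0:3) * pi / 4
GLCM_DISTANCES <- 1:5
GLCM_FEATURES <- c("homogeneity", "entropy", "contrast", "correlation",
                   "energy")
HIST_STATS <- c("mean", "sd", "skewness", "kurtosis")

#' Grey-level co-occurrence matrix
#'
#' Quantises the image to `levels` grey levels by min-max binning over ROI
#' pixels, then counts co-occurrences of level pairs separated by the pixel
#' offset implied by distance `d` and angle `angle`. Both pixels of a pair
#' must lie inside the ROI. Accumulation is symmetric (each pair counted in
#' both orders), so `angle` and `angle + pi` give identical matrices, which
#' is why only four angles are needed.
#'
#' @param image a [gsi].
#' @param d pixel distance, 1..5.
#' @param angle one of 0, pi/4, pi/2, 3*pi/4.
#' @param levels number of grey levels (default 32).
#' @return object of class `glcm_matrix`: `p` (levels x levels probability
#'   matrix summing to 1), plus `levels`, `d`, `angle`.
#' @export
glcm <- function(image, d, angle, levels = 32) {
  stopifnot(inherits(image, "gsi"))
  if (!(d %in% GLCM_DISTANCES)) stop("`d` must be in 1..5")
  ai <- which(abs(angle - GLCM_ANGLES) < 1e-8)
  if (!length(ai)) stop("`angle` must be one of {0,1,2,3} * pi/4")
  q <- quantize_roi(image, levels)
  off <- switch(ai, c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
  n <- nrow(q); m <- ncol(q)
  r0 <- max(1L, 1L - off[1L]):min(n, n - off[1L])
  c0 <- max(1L, 1L - off[2L]):min(m, m - off[2L])
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + off[1L], c0 + off[2L], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("ROI contains no valid pixel pair at this offset")
  ia <- a[keep]; ib <- b[keep]
  counts <- matrix(tabulate(ia * levels + ib + 1L, nbins = levels^2),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)                      # symmetrise
  structure(list(p = counts / sum(counts), levels = levels,
                 d = d, angle = angle),
            class = "glcm_matrix")
}

#' @noRd
quantize_roi <- function(image, levels) {
  x <- image$values
  v <- x[image$roi_mask]
  rng <- range(v)
  q <- if (diff(rng) == 0) {
    matrix(0L, nrow(x), ncol(x))
  } else {
    pmin(as.integer(floor((x - rng[1L]) / diff(rng) * levels)),
         levels - 1L) |> matrix(nrow(x), ncol(x))
  }
  q[!image$roi_mask] <- NA_integer_
  q
}

#' Haralick-style GLCM descriptor
#'
#' With `p(i, j)` the co-occurrence probability at (0-based) grey levels
#' `i`, `j`:
#' homogeneity `sum p / (1 + (i - j)^2)`; entropy `-sum p log2 p`
#' (0 log 0 := 0); contrast `sum p (i - j)^2`; correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)` with the marginal
#' moments of `p` (0 when either marginal sd is 0); energy
#' `sqrt(sum p^2)`, the square root of the angular second moment.
#'
#' @param m a [glcm] matrix.
#' @param name one of `"homogeneity"`, `"entropy"`, `"contrast"`,
#'   `"correlation"`, `"energy"`.
#' @return scalar feature value.
#' @export
glcm_feature <- function(m, name = GLCM_FEATURES) {
  stopifnot(inherits(m, "glcm_matrix"))
  name <- match.arg(name)
  p <- m$p
  L <- m$levels
  i <- matrix(rep(0:(L - 1L), times = L), L, L)   # row level
  j <- matrix(rep(0:(L - 1L), each = L), L, L)    # col level
  switch(name,
    homogeneity = sum(p / (1 + (i - j)^2)),
    entropy = { nz <- p > 0; -sum(p[nz] * log2(p[nz])) },
    contrast = sum(p * (i - j)^2),
    energy = sqrt(sum(p^2)),
    correlation = {
      mu_i <- sum(i * p); mu_j <- sum(j * p)
      s_i <- sqrt(sum(p * (i - mu_i)^2))
      s_j <- sqrt(sum(p * (j - mu_j)^2))
      if (s_i * s_j == 0) 0 else
        sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
    })
}

#' First-order histogram statistic over the ROI
#'
#' Moment statistics of the ROI pixel intensities: mean, sample standard
#' deviation, skewness `m3 / m2^(3/2)` and kurtosis `m4 / m2^2 - 3`
#' (excess; set `excess = FALSE` for the raw fourth standardised moment).
#'
#' @param image a [gsi].
#' @param stat one of `"mean"`, `"sd"`, `"skewness"`, `"kurtosis"`.
#' @param excess report excess kurtosis (normal -> 0)?
#' @return scalar feature value.
#' @export
histogram_feature <- function(image, stat = HIST_STATS, excess = TRUE) {
  stopifnot(inherits(image, "gsi"))
  stat <- match.arg(stat)
  v <- image$values[image$roi_mask]
  n <- length(v)
  if (stat == "mean") return(mean(v))
  if (n < 2L) stop("need >= 2 ROI pixels for sd")
  if (stat == "sd") return(sd(v))
  if (n < 3L || sd(v) == 0)
    stop("skewness/kurtosis degenerate: need >= 3 ROI pixels with spread")
  if (stat == "skewness") return(e1071::skewness(v, type = 1))
  k <- e1071::kurtosis(v, type = 1)
  if (excess) k else k + 3
}
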