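# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results with plain loops and
# textbook formulas, never through the package's own vectorised paths.

# deterministic small cube: value = r/10 + c/100 + b  (distinct per band)
make_test_cube <- function(nr = 6, nc = 6, nb = 5,
                           wl = seq(400, 800, length.out = nb)) {
  arr <- array(0, dim = c(nr, nc, nb))
  for (b in seq_len(nb)) {
    arr[, , b] <- outer(seq_len(nr) / 10, seq_len(nc) / 100, "+") + b
  }
  hsi_cube(arr, wl)
}

random_cube <- function(nr, nc, nb, wl = seq(400, 1000, length.out = nb)) {
  hsi_cube(array(runif(nr * nc * nb), dim = c(nr, nc, nb)), wl)
}

# GLCM by exhaustive pair counting with explicit loops
oracle_glcm <- function(values, mask, d, angle_index, levels) {
  v <- values[mask]
  rng <- range(v)
  q <- if (diff(rng) == 0) matrix(0L, nrow(values), ncol(values)) else
    matrix(pmin(as.integer(floor((values - rng[1]) / diff(rng) * levels)),
                levels - 1L), nrow(values), ncol(values))
  off <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))[[angle_index]]
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(values))) {
    for (c in seq_len(ncol(values))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nrow(values) || c2 < 1 || c2 > ncol(values)) next
      if (!mask[r, c] || !mask[r2, c2]) next
      a <- q[r, c] + 1L; b <- q[r2, c2] + 1L
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) == 0) stop("no valid pairs")
  counts / sum(counts)
}

# the five descriptors straight from their defining sums
oracle_glcm_features <- function(p) {
  L <- nrow(p)
  h <- ent <- con <- asm <- 0
  mu_i <- mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    pij <- p[i, j]
    h <- h + pij / (1 + ((i - 1) - (j - 1))^2)
    if (pij > 0) ent <- ent - pij * log2(pij)
    con <- con + pij * ((i - 1) - (j - 1))^2
    asm <- asm + pij^2
    mu_i <- mu_i + (i - 1) * pij
    mu_j <- mu_j + (j - 1) * pij
  }
  s_i <- s_j <- 0
  for (i in 1:L) for (j in 1:L) {
    s_i <- s_i + p[i, j] * ((i - 1) - mu_i)^2
    s_j <- s_j + p[i, j] * ((j - 1) - mu_j)^2
  }
  s_i <- sqrt(s_i); s_j <- sqrt(s_j)
  corr <- 0
  if (s_i * s_j > 0) {
    for (i in 1:L) for (j in 1:L)
      corr <- corr + ((i - 1) - mu_i) * ((j - 1) - mu_j) * p[i, j]
    corr <- corr / (s_i * s_j)
  }
  c(homogeneity = h, entropy = ent, contrast = con, correlation = corr,
    energy = sqrt(asm))
}

# textbook central moments
oracle_moments <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  c(mean = m, sd = sqrt(sum((v - m)^2) / (n - 1)),
    skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# manual typed-tree construction helpers
node_term <- function(type, value)
  list(kind = "term", name = type, type = type, value = value,
       children = NULL)
node_input <- function(type)
  list(kind = "input", name = paste0("input_", tolower(type)), type = type,
       value = NULL, children = NULL)
node_prim <- function(name, fset, ...) {
  p <- fset$prims[[name]]
  list(kind = "prim", name = name, type = p$ret, value = NULL,
       children = list(...))
}

# minimal spectra tree: to_fv(s_int_mean(input, lambda, w))
minimal_spectra_tree <- function(fset, lambda = 5, w = 3) {
  node_prim("to_fv", fset,
            node_prim("s_int_mean", fset, node_input("SPECTRA"),
                      node_term("LAMBDA", lambda), node_term("W", w)))
}

# small planted-band dataset shared by recovery-style tests
recovery_dataset <- function(n = 60, image_size = c(12, 12),
                             noise_sd = 0.01) {
  spec <- synthetic_scene_spec(image_size = image_size,
                               noise_sd = noise_sd)
  # calibrated reflectance with shells removed, no SNV: per-spectrum
  # standardisation would spread the dip-depth signal across all bands and
  # void the localisation question the recovery experiments ask
  ds <- make_dataset(spec, n)
  X <- dataset_mean_spectra(ds$samples, segment_shells = TRUE)
  planted <- vapply(ds$spec$planted_bands$center_nm,
                    function(nm) band_nearest(ds$spec$wavelengths_nm, nm),
                    0L)
  list(X = X, y = ds$y, planted = planted, ds = ds)
}

hits_planted <- function(bands, planted, tol = 3) {
  any(vapply(bands, function(b) any(abs(b - planted) <= tol), TRUE))
}
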