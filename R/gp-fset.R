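# Strongly typed GP: the function and terminal sets.
#
# Node types: HSI (hyperspectral cube), GSI (grayscale image), SPECTRA
# (reflectance spectrum), SF (scalar spectral feature), FV (feature
# vector), plus the evolvable parameter terminal types LAMBDA, W, SIGMA,
# K, THETA, F, THETAG, D. Feature-concatenation primitives (root2/3/4 and
# the single-feature conversion to_fv) are root-only: they may not nest,
# mirroring the single concatenation layer of the program structures.

GP_PARAM_TYPES <- c("LAMBDA", "W", "SIGMA", "K", "THETA", "F", "THETAG", "D")

#' @noRd
gp_prim <- function(name, ret, args, fun, input_consuming = FALSE) {
  list(name = name, ret = ret, args = args, fun = fun,
       input_consuming = input_consuming)
}

#' Build the typed function set for one program structure
#'
#' The spectra-based structure operates on a preprocessed mean reflectance
#' spectrum: interval selection (mean/median), SF arithmetic, feature
#' conversion and concatenation roots. The image-based structure operates
#' on a hyperspectral cube and adds image interval selection
#' (mean/median/Gaussian), the grayscale filter bank, spectral
#' pretreatment (SNV, Savitzky-Golay), spectral aggregation, mean-spectrum
#' extraction, and the GLCM and histogram texture features.
#'
#' @param structure `"spectra"` or `"image"`.
#' @param n_bands number of spectral bands (range of the lambda terminal).
#' @param image_features include the GLCM/histogram feature-vector
#'   primitives? Disabling them leaves the image structure expressing only
#'   spectral features (it can then reproduce any spectra-based tree).
#' @param glcm_levels grey-level count used by the GLCM primitives.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters used by the
#'   pretreatment primitive.
#' @return object of class `gp_fset`.
#' @export
gp_function_set <- function(structure = c("spectra", "image"), n_bands,
                            image_features = TRUE, glcm_levels = 32,
                            sg_window = 9, sg_polyorder = 2) {
  structure <- match.arg(structure)
  prims <- list()
  add <- function(p) prims[[p$name]] <<- p

  # -- spectral interval selection (both structures) ------------------------
  add(gp_prim("s_int_mean", "SF", c("SPECTRA", "LAMBDA", "W"),
              function(a, ctx) {
                idx <- interval_indices(ncol(a[[1L]]), a[[2L]], a[[3L]])
                rowMeans(a[[1L]][, idx, drop = FALSE])
              }, input_consuming = structure == "spectra"))
  add(gp_prim("s_int_median", "SF", c("SPECTRA", "LAMBDA", "W"),
              function(a, ctx) {
                idx <- interval_indices(ncol(a[[1L]]), a[[2L]], a[[3L]])
                m <- a[[1L]][, idx, drop = FALSE]
                if (ncol(m) == 1L) m[, 1L] else apply(m, 1L, median)
              }, input_consuming = structure == "spectra"))

  # -- SF arithmetic (protected division) -----------------------------------
  add(gp_prim("sf_add", "SF", c("SF", "SF"),
              function(a, ctx) a[[1L]] + a[[2L]]))
  add(gp_prim("sf_sub", "SF", c("SF", "SF"),
              function(a, ctx) a[[1L]] - a[[2L]]))
  add(gp_prim("sf_mul", "SF", c("SF", "SF"),
              function(a, ctx) a[[1L]] * a[[2L]]))
  add(gp_prim("sf_div", "SF", c("SF", "SF"),
              function(a, ctx) ifelse(abs(a[[2L]]) < 1e-9, 0,
                                      a[[1L]] / a[[2L]])))

  # -- conversion and concatenation roots -----------------------------------
  add(gp_prim("to_fv", "FV", "SF",
              function(a, ctx) matrix(a[[1L]], ncol = 1L)))
  add(gp_prim("root2", "FV", c("FV", "FV"),
              function(a, ctx) do.call(cbind, a)))
  add(gp_prim("root3", "FV", c("FV", "FV", "FV"),
              function(a, ctx) do.call(cbind, a)))
  add(gp_prim("root4", "FV", c("FV", "FV", "FV", "FV"),
              function(a, ctx) do.call(cbind, a)))

  if (structure == "image") {
    # -- hyperspectral-to-grayscale interval selection ----------------------
    add(gp_prim("i_int_mean", "GSI", c("HSI", "LAMBDA", "W"),
                function(a, ctx)
                  image_interval_select(a[[1L]], a[[2L]], a[[3L]], "mean"),
                input_consuming = TRUE))
    add(gp_prim("i_int_median", "GSI", c("HSI", "LAMBDA", "W"),
                function(a, ctx)
                  image_interval_select(a[[1L]], a[[2L]], a[[3L]], "median"),
                input_consuming = TRUE))
    add(gp_prim("i_int_gaussian", "GSI", c("HSI", "LAMBDA", "W", "SIGMA"),
                function(a, ctx)
                  image_interval_select(a[[1L]], a[[2L]], a[[3L]],
                                        "gaussian", sigma = a[[4L]]),
                input_consuming = TRUE))
    # -- grayscale filtering / normalisation --------------------------------
    add(gp_prim("f_gaussian", "GSI", c("GSI", "K", "SIGMA"),
                function(a, ctx)
                  apply_filter(a[[1L]], "gaussian", k = a[[2L]],
                               sigma = a[[3L]])))
    add(gp_prim("f_dog", "GSI", c("GSI", "SIGMA"),
                function(a, ctx)
                  apply_filter(a[[1L]], "dog", sigma = a[[2L]])))
    add(gp_prim("f_median", "GSI", c("GSI", "K"),
                function(a, ctx)
                  apply_filter(a[[1L]], "median", k = a[[2L]])))
    add(gp_prim("f_max", "GSI", c("GSI", "K"),
                function(a, ctx)
                  apply_filter(a[[1L]], "max", k = a[[2L]])))
    add(gp_prim("f_min", "GSI", c("GSI", "K"),
                function(a, ctx)
                  apply_filter(a[[1L]], "min", k = a[[2L]])))
    add(gp_prim("f_gabor7", "GSI", c("GSI", "F", "THETA"),
                function(a, ctx)
                  apply_filter(a[[1L]], "gabor7", f = a[[2L]],
                               theta = a[[3L]])))
    add(gp_prim("f_gabor9", "GSI", c("GSI", "F", "THETA"),
                function(a, ctx)
                  apply_filter(a[[1L]], "gabor9", f = a[[2L]],
                               theta = a[[3L]])))
    add(gp_prim("f_minmax", "GSI", "GSI",
                function(a, ctx) apply_filter(a[[1L]], "minmax")))
    # -- spectral pretreatment and extraction -------------------------------
    add(gp_prim("snv_op", "SPECTRA", "SPECTRA",
                function(a, ctx) t(apply(a[[1L]], 1L, snv))))
    add(gp_prim("sg_op", "SPECTRA", "SPECTRA",
                function(a, ctx)
                  t(apply(a[[1L]], 1L, savitzky_golay,
                          window = sg_window, polyorder = sg_polyorder))))
    add(gp_prim("mean_spectra", "SPECTRA", "HSI",
                function(a, ctx) matrix(mean_spectrum(a[[1L]])$values,
                                        nrow = 1L),
                input_consuming = TRUE))
    add(gp_prim("spec_agg", "SF", "GSI",
                function(a, ctx) spectral_aggregate(a[[1L]])))
    if (image_features) {
      for (feat in GLCM_FEATURES) {
        local({
          fname <- feat
          add(gp_prim(paste0("glcm_", fname), "FV", c("GSI", "D", "THETAG"),
                      function(a, ctx)
                        matrix(glcm_feature(glcm(a[[1L]], a[[2L]], a[[3L]],
                                                 levels = glcm_levels),
                                            fname), 1L, 1L)))
        })
      }
      for (st in HIST_STATS) {
        local({
          sname <- st
          add(gp_prim(paste0("hist_", sname), "FV", "GSI",
                      function(a, ctx)
                        matrix(histogram_feature(a[[1L]], sname), 1L, 1L)))
        })
      }
    }
  }

  input_type <- if (structure == "spectra") "SPECTRA" else "HSI"
  fset <- structure(list(structure = structure, n_bands = n_bands,
                         prims = prims, input_type = input_type,
                         glcm_levels = glcm_levels),
                    class = "gp_fset")
  fset$roots <- c("to_fv", "root2", "root3", "root4")
  fset$by_ret <- split(names(prims), vapply(prims, `[[`, "", "ret"))
  # interior FV producers exclude the root-only concatenation primitives
  fset$by_ret$FV <- setdiff(fset$by_ret$FV, c("root2", "root3", "root4"))
  fset$min_depth <- gp_min_depths(fset)
  fset$max_reach <- gp_max_reach(fset)
  # shallowest complete program (root primitive + its argument chains)
  fset$min_root_depth <- min(vapply(fset$roots, function(nm)
    1L + as.integer(max(fset$min_depth[fset$prims[[nm]]$args])), 0L))
  fset
}

#' Sample a terminal value of a given type
#'
#' Parameter terminals and their ranges: lambda (band index, 1..n_bands),
#' w in \{1,3,5,7,9,11\}, sigma in (0,5], k in \{3,5,7,9,11\}, theta in
#' \{0..7\} pi/4, f = pi 2^-(1+0.5v) for v in 0..3, theta_g in \{0..3\}
#' pi/4, d in 1..5.
#'
#' @param type terminal type name.
#' @param fset a [gp_function_set()].
#' @return a terminal node.
#' @export
gp_sample_terminal <- function(type, fset) {
  value <- switch(type,
    LAMBDA = sample.int(fset$n_bands, 1L),
    W = sample(VALID_WIDTHS, 1L),
    SIGMA = runif(1L, .Machine$double.eps, 5),
    K = sample(VALID_KERNELS, 1L),
    THETA = sample(GABOR_THETAS, 1L),
    F = sample(GABOR_FREQS, 1L),
    THETAG = sample(GLCM_ANGLES, 1L),
    D = sample(GLCM_DISTANCES, 1L),
    stop("no terminal of type ", type))
  list(kind = "term", name = type, type = type, value = value,
       children = NULL)
}

#' @noRd
gp_input_node <- function(fset) {
  list(kind = "input", name = paste0("input_", tolower(fset$input_type)),
       type = fset$input_type, value = NULL, children = NULL)
}

#' @noRd
is_terminal_type <- function(type, fset) {
  type %in% GP_PARAM_TYPES || type == fset$input_type
}

# Minimum number of levels needed to complete a subtree of each type
# (terminals count one level), computed by fixpoint over the primitive set.
#' @noRd
gp_min_depths <- function(fset) {
  types <- unique(c(vapply(fset$prims, `[[`, "", "ret"), GP_PARAM_TYPES,
                    fset$input_type, "FV"))
  md <- stats::setNames(rep(Inf, length(types)), types)
  md[GP_PARAM_TYPES[GP_PARAM_TYPES %in% types]] <- 1
  md[fset$input_type] <- 1
  repeat {
    changed <- FALSE
    for (p in fset$prims) {
      need <- 1 + max(md[p$args])
      if (need < md[p$ret]) { md[p$ret] <- need; changed <- TRUE }
    }
    if (!changed) break
  }
  md
}

# Maximum depth a subtree of each type can reach (Inf when a type has a
# self-recursive producer, e.g. GSI filters or SF arithmetic).
#' @noRd
gp_max_reach <- function(fset) {
  mr <- fset$min_depth
  for (iter in seq_len(length(fset$prims) + 2L)) {
    for (p in fset$prims) {
      reach <- 1 + max(mr[p$args])
      if (reach > mr[p$ret]) mr[p$ret] <- reach
    }
  }
  # anything still growing after the fixpoint bound is unbounded
  for (p in fset$prims) {
    if (1 + max(mr[p$args]) > mr[p$ret]) mr[p$ret] <- Inf
  }
  mr
}
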