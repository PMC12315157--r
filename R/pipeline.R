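# Pipeline orchestration: preprocessing runs, repeated evolution runs,
# the method-comparison report, and whole-quadrat prediction maps. These
# functions are the programmatic interface behind the command-line
# wrapper in inst/cli/hsigp.R.

#' Preprocess a directory of quadrat cubes
#'
#' For every ENVI header in `raw_dir`: read the cube (reflectance; if
#' `white.csv` / `dark.csv` spectra are present in `raw_dir` the cube is
#' treated as raw counts and calibrated first), segment bright shell
#' pixels out of the ROI, grid the quadrat into `rows` x `cols` cells and
#' write each cell as an ENVI pair plus mask under `out_dir`, with a
#' `manifest.csv` listing every cell.
#'
#' @param raw_dir input directory.
#' @param out_dir output directory (created).
#' @param rows,cols grid shape (5 x 5 default).
#' @param segment_shells remove bright pixels before gridding?
#' @param erosion_radius passed to [segment_bright_objects()].
#' @return the manifest data.frame (one row per cell), invisibly written
#'   to `out_dir/manifest.csv`.
#' @export
cmd_preprocess <- function(raw_dir, out_dir, rows = 5, cols = 5,
                           segment_shells = TRUE, erosion_radius = 1) {
  headers <- sort(list.files(raw_dir, pattern = "\\.hdr$",
                             full.names = TRUE))
  if (!length(headers)) stop("no ENVI headers found in ", raw_dir)
  white <- dark <- NULL
  wp <- file.path(raw_dir, "white.csv"); dp <- file.path(raw_dir, "dark.csv")
  if (file.exists(wp) && file.exists(dp)) {
    white <- as.numeric(read.csv(wp)[[1L]])
    dark <- as.numeric(read.csv(dp)[[1L]])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rowsList <- list()
  for (h in headers) {
    qname <- sub("\\.hdr$", "", basename(h))
    cube <- read_envi_cube(h)
    if (!is.null(white)) {
      cube <- calibrate_reflectance(cube$reflectance, white, dark,
                                    cube$wavelengths_nm,
                                    roi_mask = cube$roi_mask,
                                    meta = cube$meta)
    }
    if (segment_shells)
      cube <- segment_bright_objects(cube, erosion_radius = erosion_radius)
    cells <- grid_quadrat(cube, rows, cols)
    for (cell in cells) {
      cr <- attr(cell, "cell_row"); cc <- attr(cell, "cell_col")
      base <- file.path(out_dir, sprintf("%s_r%dc%d", qname, cr, cc))
      write_envi_cube(cell, base)
      write_roi_mask(cell$roi_mask, paste0(base, "_mask.txt"))
      rowsList[[length(rowsList) + 1L]] <-
        data.frame(quadrat = qname, cell_row = cr, cell_col = cc,
                   cube = paste0(base, ".hdr"),
                   mask = paste0(base, "_mask.txt"),
                   n_roi = sum(cell$roi_mask))
    }
  }
  manifest <- do.call(rbind, rowsList)
  write.csv(manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  manifest
}

#' Run repeated seeded evolution
#'
#' Executes `runs` independent evolutionary runs (seeds `base_seed + 0 ..
#' runs - 1`), collecting the best individual and fitness trace of each,
#' and the per-band selection-frequency table aggregated over the top 10
#' individuals of every run.
#'
#' @param input calibration spectra matrix or list of cubes.
#' @param y calibration targets.
#' @param config a [gp_config()] (its `seed` is overridden per run).
#' @param runs number of repetitions.
#' @param base_seed seed of the first run.
#' @param out_dir optional directory for trace/tree/frequency artefacts.
#' @return list of class `evolve_report`: `results` (per-run
#'   `gp_result`), `summary` (per-run best fitness and feature count),
#'   `frequency` (per-band selection counts), `seeds`.
#' @export
cmd_evolve <- function(input, y, config = gp_config(), runs = 1,
                       base_seed = 1, out_dir = NULL) {
  seeds <- base_seed + seq_len(runs) - 1L
  results <- vector("list", runs)
  top_trees <- list()
  for (r in seq_len(runs)) {
    cfg <- config
    cfg$seed <- seeds[r]
    results[[r]] <- gp_evolve(input, y, cfg)
    top_trees <- c(top_trees, gp_top_individuals(results[[r]], 10L))
  }
  n_bands <- if (config$structure == "spectra") ncol(input) else
    length(input[[1L]]$wavelengths_nm)
  freq <- wavelength_frequency(top_trees, n_bands)
  summary <- data.frame(
    run = seq_len(runs), seed = seeds,
    best_fitness = vapply(results, function(r) r$best$fitness, 0),
    n_features = vapply(results, function(r) r$best$n_features, 0L))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_len(runs)) {
      write.csv(results[[r]]$trace,
                file.path(out_dir, sprintf("trace_run%02d.csv", r)),
                row.names = FALSE)
      writeLines(tree_to_string(results[[r]]$best$tree),
                 file.path(out_dir, sprintf("best_tree_run%02d.txt", r)))
    }
    write.csv(freq, file.path(out_dir, "wavelength_frequency.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "runs.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seeds = seeds, config = config[setdiff(names(config), "seed")]),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  }
  structure(list(results = results, summary = summary, frequency = freq,
                 seeds = seeds),
            class = "evolve_report")
}

#' Compare wavelength-selection methods
#'
#' Builds the six-metric evaluation table: for each selector (full
#' spectrum, SPA, CARS, RC, and optionally evolved GP trees) and each
#' regression model, runs the five-fold [crossval_protocol()] and records
#' the number of selected wavelengths (`n`).
#'
#' @param X_cal,y_cal calibration set (mean spectra and targets).
#' @param X_pred,y_pred prediction set.
#' @param methods subset of `c("full", "spa", "cars", "rc")`.
#' @param models subset of `c("plsr", "svr-linear", "svr-rbf")`.
#' @param gp_results optional list of `gp_result` runs; each contributes
#'   rows using its best tree's extracted features (the median over runs
#'   is the headline aggregation for GP rows).
#' @param max_lv,spa_max_vars,cars_n_mc selector parameters.
#' @return data.frame with columns `method`, `model`, `n`, `Rc2`, `MSEc`,
#'   `Rcv2`, `MSEcv`, `Rp2`, `MSEp`.
#' @export
cmd_compare <- function(X_cal, y_cal, X_pred, y_pred,
                        methods = c("full", "spa", "cars", "rc"),
                        models = c("plsr", "svr-linear"),
                        gp_results = NULL, max_lv = 15,
                        spa_max_vars = 10, cars_n_mc = 50) {
  sets <- list()
  for (m in methods) {
    sets[[m]] <- switch(m,
      full = seq_len(ncol(X_cal)),
      spa = spa_select(X_cal, y_cal, max_vars = spa_max_vars)$bands,
      cars = cars_select(X_cal, y_cal, n_mc = cars_n_mc)$bands,
      rc = rc_select(X_cal, y_cal, max_lv = max_lv)$bands,
      stop("unknown method: ", m))
  }
  out <- list()
  eval_block <- function(method, n_sel, Xc, Xp) {
    for (mod in models) {
      spec <- if (mod == "plsr") model_spec(mod, max_lv = max_lv) else
        model_spec(mod)
      met <- crossval_protocol(Xc, y_cal, Xp, y_pred, spec)
      out[[length(out) + 1L]] <<-
        data.frame(method = method, model = mod, n = n_sel,
                   Rc2 = met$Rc2, MSEc = met$MSEc, Rcv2 = met$Rcv2,
                   MSEcv = met$MSEcv, Rp2 = met$Rp2, MSEp = met$MSEp)
    }
  }
  for (m in names(sets)) {
    idx <- sets[[m]]
    eval_block(m, length(idx), X_cal[, idx, drop = FALSE],
               X_pred[, idx, drop = FALSE])
  }
  if (!is.null(gp_results)) {
    gp_rows <- list()
    for (r in gp_results) {
      Fc <- gp_evaluate(r$best$tree, X_cal, r$fset)
      Fp <- gp_evaluate(r$best$tree, X_pred, r$fset)
      std <- feature_standardiser(Fc)
      n_sel <- nrow(selected_wavelengths(r$best$tree))
      for (mod in models) {
        spec <- if (mod == "plsr")
          model_spec(mod, max_lv = min(max_lv, ncol(Fc))) else
          model_spec(mod)
        met <- crossval_protocol(standardise_features(std, Fc), y_cal,
                                 standardise_features(std, Fp), y_pred,
                                 spec)
        gp_rows[[length(gp_rows) + 1L]] <-
          data.frame(method = "gp", model = mod, n = n_sel,
                     Rc2 = met$Rc2, MSEc = met$MSEc, Rcv2 = met$Rcv2,
                     MSEcv = met$MSEcv, Rp2 = met$Rp2, MSEp = met$MSEp)
      }
    }
    gdf <- do.call(rbind, gp_rows)
    # median across runs, the robust aggregation for stochastic GP runs
    for (mod in unique(gdf$model)) {
      sub <- gdf[gdf$model == mod, ]
      out[[length(out) + 1L]] <-
        data.frame(method = "gp", model = mod, n = median(sub$n),
                   Rc2 = median(sub$Rc2), MSEc = median(sub$MSEc),
                   Rcv2 = median(sub$Rcv2), MSEcv = median(sub$MSEcv),
                   Rp2 = median(sub$Rp2), MSEp = median(sub$MSEp))
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Predict an attribute across all quadrat cells
#'
#' Applies an evolved tree plus a final linear SVR (fitted on the labelled
#' training cells) to every grid cell, producing the whole-quadrat
#' prediction map.
#'
#' @param result a `gp_result` (its best tree is used).
#' @param cell_spectra matrix of mean spectra, one row per grid cell
#'   (spectra structure), or list of cell cubes (image structure).
#' @param cell_info data.frame with one row per cell (e.g. `quadrat`,
#'   `cell_row`, `cell_col`).
#' @param train_rows indices of cells with ground truth.
#' @param y_train their attribute values.
#' @return `cell_info` with `prediction` and `is_training` columns.
#' @export
cmd_predict_map <- function(result, cell_spectra, cell_info, train_rows,
                            y_train) {
  feats <- gp_evaluate(result$best$tree, cell_spectra, result$fset)
  std <- feature_standardiser(feats[train_rows, , drop = FALSE])
  Z <- standardise_features(std, feats)
  fit <- e1071::svm(x = Z[train_rows, , drop = FALSE], y = y_train,
                    type = "eps-regression", kernel = "linear",
                    cost = result$config$svr_cost,
                    epsilon = result$config$svr_epsilon, scale = FALSE)
  cell_info$prediction <- as.numeric(predict(fit, Z))
  cell_info$is_training <- seq_len(nrow(cell_info)) %in% train_rows
  cell_info
}
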