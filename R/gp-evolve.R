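# The evolutionary loop and run-level reporting.

#' Evolution configuration
#'
#' Defaults follow common GP practice for this problem family: population
#' 2048 for 50 generations, tournament size 4, crossover rate 0.8,
#' mutation rate 0.2, elitism rate 0.01; initial depth 3-6 (spectra) or
#' 4-7 (image) and maximum depth 8 or 9. Scale `population` and
#' `generations` down for desk-size experiments.
#'
#' @param structure `"spectra"` or `"image"`.
#' @param population,generations evolutionary budget.
#' @param crossover_rate,mutation_rate,elitism_rate operator rates.
#' @param tournament_size tournament size k.
#' @param init_depth integer (min, max) initial tree depth; default 3-6
#'   for the spectra structure, 4-7 for the image structure.
#' @param max_depth depth cap; default 8 (spectra) or 9 (image).
#' @param fitness_fn `"R2"` (maximised) or `"MSE"` (minimised), both
#'   measured on the held-out evaluation portion.
#' @param split_ratio training share of the calibration set (drawn once
#'   per run and shared by all individuals).
#' @param svr_cost,svr_epsilon linear SVR hyperparameters used during
#'   fitness evaluation.
#' @param glcm_levels grey levels for GLCM primitives.
#' @param seed optional RNG seed for a reproducible run.
#' @return list of class `gp_config`.
#' @export
gp_config <- function(structure = c("spectra", "image"), population = 2048,
                      generations = 50, crossover_rate = 0.8,
                      mutation_rate = 0.2, elitism_rate = 0.01,
                      tournament_size = 4, init_depth = NULL,
                      max_depth = NULL, fitness_fn = c("R2", "MSE"),
                      split_ratio = 0.7, svr_cost = 1, svr_epsilon = 0.1,
                      glcm_levels = 32, seed = NULL) {
  structure <- match.arg(structure)
  fitness_fn <- match.arg(fitness_fn)
  if (is.null(init_depth))
    init_depth <- if (structure == "spectra") c(3L, 6L) else c(4L, 7L)
  if (is.null(max_depth))
    max_depth <- if (structure == "spectra") 8L else 9L
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_rate >= 0, elitism_rate <= 1,
            all(init_depth > 0), max_depth >= init_depth[2L])
  out <- list(structure = structure, population = population,
              generations = generations, crossover_rate = crossover_rate,
              mutation_rate = mutation_rate, elitism_rate = elitism_rate,
              tournament_size = tournament_size, init_depth = init_depth,
              max_depth = max_depth, fitness_fn = fitness_fn,
              split_ratio = split_ratio, svr_cost = svr_cost,
              svr_epsilon = svr_epsilon, glcm_levels = glcm_levels,
              seed = seed)
  class(out) <- "gp_config"
  out
}

#' Evolve a feature-extraction tree
#'
#' Generational loop: evaluate, copy the top `elitism_rate` share
#' unchanged, and fill the remainder with tournament-selected parents that
#' undergo crossover (with probability `crossover_rate`) or reproduction,
#' followed by mutation (with probability `mutation_rate`). The 70:30
#' fitness split of the calibration samples is drawn once at the start of
#' the run. Returns the fittest individual of the final generation.
#'
#' @param input calibration inputs: samples x bands spectra matrix
#'   (spectra structure) or list of [hsi_cube] (image structure).
#' @param y calibration targets (one per sample).
#' @param config a [gp_config()].
#' @return list of class `gp_result`: `best` (individual with `$tree`,
#'   `$fitness`, `$n_features`), `trace` (per-generation best/mean
#'   fitness), `population` (final), `train_idx`, `fset`, `config`.
#' @export
gp_evolve <- function(input, y, config = gp_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- if (config$structure == "spectra") nrow(input) else length(input)
  stopifnot(n == length(y), n >= 3L)
  n_bands <- if (config$structure == "spectra") ncol(input) else
    length(input[[1L]]$wavelengths_nm)
  fset <- gp_function_set(config$structure, n_bands,
                          glcm_levels = config$glcm_levels)
  train_idx <- sort(sample.int(n, round(config$split_ratio * n)))

  score <- function(tree) {
    f <- gp_fitness(tree, input, y, train_idx, fset, config$fitness_fn,
                    config$svr_cost, config$svr_epsilon)
    list(tree = tree, fitness = f$fitness, n_features = f$n_features)
  }
  pop <- lapply(gp_init_population(config$population, fset,
                                   config$init_depth), score)
  n_elite <- max(1L, ceiling(config$elitism_rate * config$population))
  trace <- data.frame(generation = integer(), best = numeric(),
                      mean = numeric())
  rank_pop <- function(p) {
    fit <- vapply(p, `[[`, 0, "fitness")
    order(fit, decreasing = config$fitness_fn == "R2")
  }
  record <- function(gen, p) {
    fit <- vapply(p, `[[`, 0, "fitness")
    ok <- is.finite(fit)
    rbind(trace, data.frame(generation = gen,
                            best = fit[rank_pop(p)[1L]],
                            mean = if (any(ok)) mean(fit[ok]) else NA_real_))
  }
  trace <- record(0L, pop)
  for (gen in seq_len(config$generations)) {
    ord <- rank_pop(pop)
    nxt <- pop[ord[seq_len(n_elite)]]
    while (length(nxt) < config$population) {
      p1 <- gp_tournament(pop, config$tournament_size, config$fitness_fn)
      p2 <- gp_tournament(pop, config$tournament_size, config$fitness_fn)
      if (runif(1L) < config$crossover_rate) {
        kids <- gp_crossover(p1$tree, p2$tree, fset, config$max_depth)
        c1 <- score(kids[[1L]]); c2 <- score(kids[[2L]])
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (length(nxt) >= config$population) break
        if (runif(1L) < config$mutation_rate) {
          child <- score(gp_mutate(child$tree, fset, config$max_depth))
        }
        nxt[[length(nxt) + 1L]] <- child
      }
    }
    pop <- nxt
    trace <- record(gen, pop)
  }
  ord <- rank_pop(pop)
  best <- pop[[ord[1L]]]
  res <- list(best = best, trace = trace, population = pop,
              train_idx = train_idx, fset = fset, config = config)
  class(res) <- "gp_result"
  res
}

#' @export
print.gp_result <- function(x, ...) {
  cat(sprintf("<gp_result> %s structure, %d generations, pop %d\n",
              x$config$structure, x$config$generations,
              x$config$population))
  cat(sprintf("best %s fitness: %.4f (%d features)\n", x$config$fitness_fn,
              x$best$fitness, x$best$n_features))
  cat("best tree:", tree_to_string(x$best$tree), "\n")
  invisible(x)
}

INTERVAL_PRIMS <- c("s_int_mean", "s_int_median", "i_int_mean",
                    "i_int_median", "i_int_gaussian")

#' Wavelength intervals selected by evolved trees
#'
#' Enumerates every interval-selection node in the given tree(s) and
#' aggregates counts per unique (centre band, width) pair.
#'
#' @param trees a GP tree, an individual, a `gp_result`, or a list of
#'   trees/individuals (e.g. the top 10 of a population).
#' @param wavelengths_nm optional band centres to report `center_nm`.
#' @return data.frame with `center_band`, `width`, `count` (and
#'   `center_nm` when wavelengths are supplied), sorted by count.
#' @export
selected_wavelengths <- function(trees, wavelengths_nm = NULL) {
  trees <- as_tree_list(trees)
  pairs <- list()
  walk <- function(node) {
    if (is_leaf(node)) return(invisible())
    if (node$name %in% INTERVAL_PRIMS) {
      lam <- node$children[[2L]]$value
      w <- node$children[[3L]]$value
      pairs[[length(pairs) + 1L]] <<- c(lam, w)
    }
    for (ch in node$children) walk(ch)
  }
  for (tr in trees) walk(tr)
  if (!length(pairs)) {
    out <- data.frame(center_band = integer(), width = integer(),
                      count = integer())
  } else {
    m <- do.call(rbind, pairs)
    key <- paste(m[, 1L], m[, 2L])
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " "))
    out <- data.frame(center_band = as.integer(parts[, 1L]),
                      width = as.integer(parts[, 2L]),
                      count = as.integer(tab))
    out <- out[order(-out$count, out$center_band), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(wavelengths_nm) && nrow(out))
    out$center_nm <- wavelengths_nm[out$center_band]
  out
}

#' Per-band selection frequency
#'
#' Counts, for every band, how many selected intervals cover it across the
#' given trees (the selection-frequency profile over the spectrum).
#'
#' @param trees as in [selected_wavelengths()].
#' @param n_bands total number of bands.
#' @param wavelengths_nm optional band centres (nm).
#' @return data.frame with `band`, `count` (and `nm`).
#' @export
wavelength_frequency <- function(trees, n_bands, wavelengths_nm = NULL) {
  sel <- selected_wavelengths(trees)
  counts <- integer(n_bands)
  for (i in seq_len(nrow(sel))) {
    idx <- interval_indices(n_bands, sel$center_band[i], sel$width[i])
    counts[idx] <- counts[idx] + sel$count[i]
  }
  out <- data.frame(band = seq_len(n_bands), count = counts)
  if (!is.null(wavelengths_nm)) out$nm <- wavelengths_nm
  out
}

#' @noRd
as_tree_list <- function(trees) {
  if (inherits(trees, "gp_result")) return(list(trees$best$tree))
  if (is.list(trees) && !is.null(trees$kind)) return(list(trees))   # a node
  if (is.list(trees) && !is.null(trees$tree)) return(list(trees$tree))
  lapply(trees, function(t) {
    if (!is.null(t$tree)) t$tree else t
  })
}

#' Top individuals of a finished run
#'
#' @param result a `gp_result`.
#' @param n how many individuals.
#' @return list of individuals, best first.
#' @export
gp_top_individuals <- function(result, n = 10) {
  fit <- vapply(result$population, `[[`, 0, "fitness")
  ord <- order(fit, decreasing = result$config$fitness_fn == "R2")
  result$population[ord[seq_len(min(n, length(ord)))]]
}
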