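test_that("generated trees are type-correct and depth-legal", {
  set.seed(18)
  fs <- gp_function_set("spectra", 204)
  fi <- gp_function_set("image", 204)
  for (i in 1:300) {
    m <- if (i %% 2) "full" else "grow"
    ts <- gp_generate(fs, m, c(3, 6))
    expect_true(isTRUE(gp_typecheck(ts, fs, max_depth = 8)))
    expect_gte(tree_depth(ts), 3)
    ti <- gp_generate(fi, m, c(4, 7))
    expect_true(isTRUE(gp_typecheck(ti, fi, max_depth = 9)))
    expect_gte(tree_depth(ti), 4)
  }
})

test_that("the minimal spectra program is a bare interval selection", {
  set.seed(19)
  fs <- gp_function_set("spectra", 50)
  tr <- gp_generate(fs, "full", target = 3)
  expect_equal(tree_depth(tr), 3)
  expect_equal(tr$name, "to_fv")
  expect_match(tr$children[[1]]$name, "^s_int_")
  expect_equal(tr$children[[1]]$children[[1]]$kind, "input")
})

test_that("image trees always transition from HSI before extracting", {
  set.seed(20)
  fi <- gp_function_set("image", 30)
  for (i in 1:100) {
    tr <- gp_generate(fi, "grow", c(4, 7))
    s <- tree_to_string(tr)
    expect_match(s, "i_int_|mean_spectra")   # an HSI-consuming transition
    expect_match(s, "input_hsi")
  }
})

test_that("tree evaluation composes the module operations faithfully", {
  fs <- gp_function_set("spectra", 10)
  X <- matrix(seq(0.1, 2, length.out = 20), 2, 10)

  tr <- node_prim("root2", fs,
                  minimal_spectra_tree(fs, 3, 3),
                  minimal_spectra_tree(fs, 8, 1))
  got <- gp_evaluate(tr, X, fs)
  expect_equal(dim(got), c(2, 2))
  for (s in 1:2) {
    expect_equal(got[s, 1],
                 spectra_interval_select(X[s, ], 3, 3, "mean"))
    expect_equal(got[s, 2], X[s, 8])
  }

  # self-difference collapses to zero
  diff_tree <- node_prim("to_fv", fs,
    node_prim("sf_sub", fs,
              node_prim("s_int_mean", fs, node_input("SPECTRA"),
                        node_term("LAMBDA", 4), node_term("W", 3)),
              node_prim("s_int_mean", fs, node_input("SPECTRA"),
                        node_term("LAMBDA", 4), node_term("W", 3))))
  expect_equal(as.vector(gp_evaluate(diff_tree, X, fs)), c(0, 0))

  # protected division returns 0 on a vanishing denominator
  div_tree <- node_prim("to_fv", fs,
    node_prim("sf_div", fs,
              node_prim("s_int_mean", fs, node_input("SPECTRA"),
                        node_term("LAMBDA", 2), node_term("W", 1)),
              node_prim("sf_sub", fs,
                        node_prim("s_int_mean", fs, node_input("SPECTRA"),
                                  node_term("LAMBDA", 5), node_term("W", 1)),
                        node_prim("s_int_mean", fs, node_input("SPECTRA"),
                                  node_term("LAMBDA", 5), node_term("W", 1)))))
  expect_equal(as.vector(gp_evaluate(div_tree, X, fs)), c(0, 0))
})

test_that("a hand-built image tree equals manual composition on a cube", {
  set.seed(21)
  cube <- random_cube(8, 8, 12)
  fi <- gp_function_set("image", 12)
  tr <- node_prim("root2", fi,
    node_prim("to_fv", fi,
      node_prim("spec_agg", fi,
        node_prim("f_median", fi,
          node_prim("i_int_mean", fi, node_input("HSI"),
                    node_term("LAMBDA", 5), node_term("W", 3)),
          node_term("K", 3)))),
    node_prim("glcm_contrast", fi,
      node_prim("i_int_mean", fi, node_input("HSI"),
                node_term("LAMBDA", 5), node_term("W", 3)),
      node_term("D", 1), node_term("THETAG", 0)))
  expect_true(isTRUE(gp_typecheck(tr, fi, max_depth = 9)))
  got <- gp_evaluate(tr, cube, fi)

  img <- image_interval_select(cube, 5, 3, "mean")
  manual1 <- spectral_aggregate(apply_filter(img, "median", k = 3))
  manual2 <- glcm_feature(glcm(img, 1, 0, levels = 32), "contrast")
  expect_equal(as.vector(got), c(manual1, manual2), tolerance = 1e-12)
})

test_that("image structure without image features matches spectra structure", {
  set.seed(22)
  cube <- random_cube(6, 6, 15)
  fs <- gp_function_set("spectra", 15)
  fi <- gp_function_set("image", 15, image_features = FALSE)
  tr_s <- minimal_spectra_tree(fs, 7, 5)
  tr_i <- node_prim("to_fv", fi,
    node_prim("s_int_mean", fi,
              node_prim("mean_spectra", fi, node_input("HSI")),
              node_term("LAMBDA", 7), node_term("W", 5)))
  expect_true(isTRUE(gp_typecheck(tr_i, fi, max_depth = 9)))
  ms <- mean_spectrum(cube)$values
  expect_equal(as.vector(gp_evaluate(tr_i, cube, fi)),
               as.vector(gp_evaluate(tr_s, matrix(ms, 1), fs)),
               tolerance = 1e-12)
})

test_that("feature standardisation follows the z-score contract", {
  set.seed(23)
  X <- cbind(rnorm(10, 5, 2), rnorm(10, -1, 0.5), rep(7, 10))
  std <- feature_standardiser(X)
  Z <- standardise_features(std, X)
  expect_equal(colMeans(Z[, 1:2]), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(Z[, 1:2], 2, sd), c(1, 1), tolerance = 1e-12)
  expect_true(all(Z[, 3] == 0))
  expect_true(std$degenerate[3])
  # column [2,4] applied to 3 -> 0
  s2 <- feature_standardiser(matrix(c(2, 4), 2, 1))
  expect_equal(as.vector(standardise_features(s2, matrix(3, 1, 1))), 0)
})

test_that("fitness rewards perfect predictors and penalises failures", {
  set.seed(24)
  n <- 30
  y <- runif(n, 0, 2)
  X <- matrix(runif(n * 10), n, 10)
  X[, 4] <- y                       # one feature IS the target
  fs <- gp_function_set("spectra", 10)
  tr <- minimal_spectra_tree(fs, 4, 1)
  train <- 1:21
  f_r2 <- gp_fitness(tr, X, y, train, fs, "R2")
  expect_gt(f_r2$fitness, 0.8)
  expect_equal(f_r2$n_features, 1)
  f_mse <- gp_fitness(tr, X, y, train, fs, "MSE")
  expect_lt(f_mse$fitness, 0.05)

  # the mean predictor scores exactly zero under the R2 definition
  expect_equal(r_squared(y, rep(mean(y), n)), 0)
  expect_equal(mse(c(1, -1), c(0, 0)), 1)

  # an out-of-range tree errors out and earns the sentinel
  bad <- minimal_spectra_tree(fs, 99, 1)
  expect_identical(gp_fitness(bad, X, y, train, fs, "R2")$fitness, -Inf)
  expect_identical(gp_fitness(bad, X, y, train, fs, "MSE")$fitness, Inf)
})

test_that("tournament selection prefers fit, small individuals", {
  set.seed(25)
  fs <- gp_function_set("spectra", 20)
  pop <- lapply(1:20, function(i)
    list(tree = minimal_spectra_tree(fs, i, 1), fitness = i / 20,
         n_features = 1L))
  # k much larger than the population makes missing the best very unlikely
  wins <- vapply(1:100, function(i)
    gp_tournament(pop, k = 100, fitness_fn = "R2")$fitness, 0)
  expect_gte(mean(wins == 1), 0.95)
  # k = 1 is uniform sampling
  singles <- vapply(1:300, function(i)
    gp_tournament(pop, k = 1, fitness_fn = "R2")$fitness, 0)
  expect_gt(length(unique(singles)), 10)
  # under MSE smaller fitness wins
  expect_equal(gp_tournament(pop, k = 100, fitness_fn = "MSE")$fitness,
               min(vapply(pop, `[[`, 0, "fitness")), tolerance = 0.2)
  # ties break toward the smaller tree
  big <- list(tree = node_prim("root2", fs,
                               minimal_spectra_tree(fs, 1, 1),
                               minimal_spectra_tree(fs, 2, 1)),
              fitness = 0.5, n_features = 2L)
  small <- list(tree = minimal_spectra_tree(fs, 3, 1), fitness = 0.5,
                n_features = 1L)
  w <- gp_tournament(list(big, small), k = 40, fitness_fn = "R2")
  expect_equal(tree_size(w$tree), tree_size(small$tree))
})

test_that("variation operators only produce legal offspring", {
  set.seed(26)
  for (structure in c("spectra", "image")) {
    fs <- gp_function_set(structure, 60)
    dr <- if (structure == "spectra") c(3, 6) else c(4, 7)
    md <- if (structure == "spectra") 8 else 9
    pop <- gp_init_population(60, fs, dr)
    for (i in 1:200) {
      a <- pop[[sample(60, 1)]]; b <- pop[[sample(60, 1)]]
      kids <- gp_crossover(a, b, fs, md)
      for (k in kids) expect_true(isTRUE(gp_typecheck(k, fs, md)))
      mu <- gp_mutate(a, fs, md)
      expect_true(isTRUE(gp_typecheck(mu, fs, md)))
    }
    # identical parents produce identical children
    kids <- gp_crossover(pop[[1]], pop[[1]], fs, md)
    expect_equal(tree_to_string(kids[[1]]), tree_to_string(pop[[1]]))
    expect_equal(tree_to_string(kids[[2]]), tree_to_string(pop[[1]]))
  }
})

test_that("evolution keeps its invariants on a small seeded run", {
  set.seed(27)
  spec <- synthetic_scene_spec(image_size = c(8, 8), shell_count = 0)
  ds <- make_dataset(spec, 30)
  X <- dataset_mean_spectra(ds$samples)
  cfg <- gp_config(population = 24, generations = 4, seed = 123)
  res <- gp_evolve(X, ds$y, cfg)
  expect_length(res$population, 24)
  expect_equal(nrow(res$trace), 5)           # gen 0 .. 4
  expect_true(all(diff(res$trace$best) >= -1e-12))
  expect_true(isTRUE(gp_typecheck(res$best$tree, res$fset, 8)))
  # bit-identical repetition under the same seed
  res2 <- gp_evolve(X, ds$y, cfg)
  expect_identical(res$trace, res2$trace)
  expect_identical(tree_to_string(res$best$tree),
                   tree_to_string(res2$best$tree))
})

test_that("selected wavelengths are counted by an independent walk", {
  fs <- gp_function_set("spectra", 40)
  dup <- node_prim("root2", fs,
                   minimal_spectra_tree(fs, 10, 3),
                   minimal_spectra_tree(fs, 10, 3))
  sel <- selected_wavelengths(dup)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$count, 2)
  expect_equal(sel$center_band, 10)
  expect_equal(sel$width, 3)

  one <- selected_wavelengths(minimal_spectra_tree(fs, 10, 3),
                              wavelengths_nm = seq(400, 790, by = 10))
  expect_equal(nrow(one), 1)
  expect_equal(one$center_nm, 490)

  set.seed(28)
  pop <- gp_init_population(40, fs, c(3, 6))
  sel_all <- selected_wavelengths(pop)
  # oracle: count interval nodes in the serialised trees
  n_nodes <- sum(vapply(pop, function(t)
    lengths(regmatches(tree_to_string(t),
                       gregexpr("s_int_(mean|median)\\(", tree_to_string(t)))),
    0L))
  expect_equal(sum(sel_all$count), n_nodes)

  # frequency table expands windows with edge truncation
  freq <- wavelength_frequency(pop, 40)
  trunc_width <- function(lam, w) {
    h <- (w - 1) / 2
    min(40, lam + h) - max(1, lam - h) + 1
  }
  expect_equal(sum(freq$count),
               sum(mapply(trunc_width, sel_all$center_band,
                          sel_all$width) * sel_all$count))
})
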