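test_that("SPXY keeps the extremes in calibration and is deterministic", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  s <- spxy_split(X, c(0, 1, 2), ratio = 2 / 3)
  expect_equal(s$calibration, c(1, 3))
  expect_equal(s$prediction, 2)

  set.seed(29)
  Xb <- matrix(rnorm(150 * 12), 150)
  yb <- rnorm(150)
  s1 <- spxy_split(Xb, yb)
  s2 <- spxy_split(Xb, yb)
  expect_identical(s1, s2)
  expect_equal(length(s1$calibration), 100)
  expect_equal(length(s1$prediction), 50)
  expect_length(intersect(s1$calibration, s1$prediction), 0)
  expect_setequal(c(s1$calibration, s1$prediction), 1:150)
  # joint-distance extremes always end up in calibration
  expect_true(which.min(yb) %in% s1$calibration ||
              which.max(yb) %in% s1$calibration)
  expect_error(spxy_split(matrix(1, 5, 2), rep(1, 5)), "degenerate")
})

test_that("PLSR recovers an exact linear relationship via RMSECV", {
  set.seed(30)
  X <- qr.Q(qr(matrix(rnorm(40 * 8), 40, 8))) %*% diag(seq(2, 9))
  y <- 2 * X[, 2] + X[, 5]
  m <- plsr_fit(X, y, max_lv = 6)
  expect_lte(m$lv, 6)
  expect_lt(min(m$rmsecv), 0.01 * sd(y))
  expect_equal(predict(m, X), y, tolerance = 1e-6)
})

test_that("PLSR on pure noise cannot beat the response spread", {
  set.seed(31)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- rnorm(40)
  m <- plsr_fit(X, y, max_lv = 10)
  expect_gt(min(m$rmsecv), 0.5 * sd(y))
  expect_lt(min(m$rmsecv), 2 * sd(y))
})

test_that("SVR grid search finds a near-perfect linear fit", {
  set.seed(32)
  x <- matrix(seq(-2, 2, length.out = 40))
  y <- 2 * as.vector(x)
  m <- svr_fit(x, y, kernel = "linear")
  expect_gt(r_squared(y, predict(m, x)), 0.99)
  # a one-point grid is chosen verbatim
  g <- data.frame(cost = 3, epsilon = 0.05)
  m1 <- svr_fit(x, y, kernel = "linear", grid = g)
  expect_equal(m1$params$cost, 3)
  expect_equal(m1$params$epsilon, 0.05)
  expect_equal(m1$params$cv_mse, min(m1$cv$cv_mse))
  # rbf path runs with the scale-heuristic gamma grid
  m2 <- svr_fit(x, y, kernel = "rbf")
  expect_true("gamma" %in% names(m2$params))
})

test_that("the five-fold protocol nails a noise-free linear problem", {
  set.seed(33)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- X %*% c(1, -2, 0.5, 3)
  cal <- 1:40; prd <- 41:60
  met <- crossval_protocol(X[cal, ], y[cal], X[prd, ], y[prd],
                           model_spec("plsr", max_lv = 4))
  expect_equal(met$Rc2, 1, tolerance = 1e-6)
  expect_equal(met$Rcv2, 1, tolerance = 1e-6)
  expect_equal(met$Rp2, 1, tolerance = 1e-6)
  expect_lt(met$MSEp, 1e-8)
  expect_equal(nrow(met$folds), 5)
  # averaging is plain bookkeeping over the fold records
  for (col in c("Rc2", "MSEc", "Rcv2", "MSEcv", "Rp2", "MSEp")) {
    expect_equal(met[[col]], mean(met$folds[[col]]))
  }
})

test_that("a frozen mean predictor scores non-positive Rcv2", {
  set.seed(34)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rnorm(40)
  frozen <- model_spec("custom",
                       fit = function(X, y) mean(y),
                       predict = function(m, X) rep(m, nrow(X)))
  met <- crossval_protocol(X[1:30, ], y[1:30], X[31:40, ], y[31:40],
                           frozen)
  expect_lte(met$Rcv2, 0)
  expect_equal(met$Rc2, 0, tolerance = 1e-12)
})

test_that("SPA projections match Gram-Schmidt and shun collinearity", {
  set.seed(35)
  # projection chain against a QR-based oracle
  Xc <- scale(matrix(rnorm(20 * 6), 20, 6), center = TRUE, scale = FALSE)
  chain <- hsigp:::spa_chain(Xc, 2L, 4)
  sel <- chain[1]
  for (step in 2:length(chain)) {
    Q <- qr.Q(qr(Xc[, sel, drop = FALSE]))
    resid <- Xc - Q %*% crossprod(Q, Xc)
    norms <- colSums(resid^2); norms[sel] <- -Inf
    expect_equal(chain[step], which.max(norms))
    sel <- c(sel, chain[step])
  }

  # duplicated columns are never selected together
  Xd <- matrix(rnorm(30 * 5), 30, 5)
  Xd[, 4] <- Xd[, 2]
  yd <- Xd[, 2] + rnorm(30, sd = 0.05)
  got <- spa_select(Xd, yd, max_vars = 3)
  expect_false(all(c(2, 4) %in% got$bands))
  expect_true(all(got$bands >= 1 & got$bands <= 5))
  expect_equal(anyDuplicated(got$bands), 0)
})

test_that("SPA recovers the informative columns of an orthogonal design", {
  set.seed(36)
  Q <- qr.Q(qr(matrix(rnorm(30 * 8), 30, 8)))
  X <- Q %*% diag(c(1, 3, 1, 1, 4, 1, 1, 1))   # cols 2 and 5 dominate
  y <- X[, 2] + X[, 5] + rnorm(30, sd = 0.02)
  got <- spa_select(X, y, max_vars = 4)
  expect_true(all(c(2, 5) %in% got$bands))
})

test_that("CARS retention schedule decays and output stays in range", {
  set.seed(37)
  n <- 40; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- 3 * X[, 7] - 2 * X[, 21] + rnorm(n, sd = 0.1)
  got <- cars_select(X, y, n_mc = 20, ncomp = 5)
  sched <- attr(got, "schedule")
  expect_true(all(diff(sched) <= 0))
  expect_lte(got$n, p)
  expect_true(all(got$bands >= 1 & got$bands <= p))
  expect_equal(anyDuplicated(got$bands), 0)
  # the strongly informative columns survive the competition
  expect_true(all(c(7, 21) %in% got$bands))
})

test_that("RC non-maximum suppression keeps separated peaks only", {
  # single dominant peak with a wide window
  co <- c(0.1, 0.2, 5, 0.2, 0.1, 0.15, 0.1)
  expect_equal(hsigp:::nms_local_maxima(co, 10, 0.2 * 5), 3)
  # two peaks farther apart than the window both survive
  co2 <- rep(0.05, 30); co2[8] <- 2; co2[25] <- 1.5
  expect_equal(hsigp:::nms_local_maxima(co2, 5, 0.3), c(8, 25))
  # brute-force local-maximum oracle on random coefficients
  set.seed(38)
  v <- abs(rnorm(50))
  got <- hsigp:::nms_local_maxima(v, 3, 0.2 * max(v))
  want <- integer()
  for (i in 1:50) {
    lo <- max(1, i - 3); hi <- min(50, i + 3)
    if (v[i] >= 0.2 * max(v) && v[i] == max(v[lo:hi]) &&
        i == (lo:hi)[which.max(v[lo:hi])]) want <- c(want, i)
  }
  expect_equal(got, want)
})

test_that("RC selection flags bands driving a linear response", {
  set.seed(39)
  n <- 40; p <- 40
  X <- matrix(rnorm(n * p), n, p)
  y <- 4 * X[, 12] + rnorm(n, sd = 0.1)
  got <- rc_select(X, y, nms_window = 5, max_lv = 8)
  expect_true(12 %in% got$bands)
  expect_equal(got$n, length(got$bands))
  co <- attr(got, "coefficients")
  expect_equal(which.max(abs(co)), 12)
})
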