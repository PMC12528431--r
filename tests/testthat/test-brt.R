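# small grids keep the cross-validation cheap; the protocol is unchanged
fast_cfg <- function(seed = 1, ...) {
  brt_config(learning_rate = c(0.01, 0.05), tree_complexity = c(1, 2),
             k = 5, max_trees = 400, seed = seed, ...)
}

test_that("a single predictor always carries 100% influence", {
  set.seed(1)
  x <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "only"))
  y <- 1.5 * x[, 1] + rnorm(60, 0, 0.2)
  fit <- fit_brt(y, x, fast_cfg())
  expect_equal(fit$influence$selection_freq, 100)
  expect_equal(fit$influence$split_improvement, 100)
})

test_that("both influence measures are normalized and the planted signal ranks first", {
  set.seed(2)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- 3 * X[, 1] + rnorm(200, 0, 0.3)
  fit <- fit_brt(y, X, fast_cfg(seed = 2))
  infl <- fit$influence
  expect_lt(abs(sum(infl$selection_freq) - 100), 1e-6)
  expect_lt(abs(sum(infl$split_improvement) - 100), 1e-6)
  expect_identical(infl$predictor[which.max(infl$selection_freq)], "x1")
  expect_identical(infl$predictor[which.max(infl$split_improvement)], "x1")
  expect_gt(infl$split_improvement[infl$predictor == "x1"], 50)
  expect_lte(fit$best$n_trees, fit$config$max_trees)
})

test_that("under exchangeability no predictor gains systematic influence", {
  p <- 4
  reps <- 60
  cfg <- brt_config(learning_rate = 0.05, tree_complexity = 2, k = 4,
                    max_trees = 150, seed = 1)
  infl <- matrix(NA_real_, reps, p)
  set.seed(3)
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(40 * p), 40, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(40)
    cfg$seed <- r
    infl[r, ] <- fit_brt(y, X, cfg)$influence$selection_freq
  }
  mc_se <- apply(infl, 2, sd) / sqrt(reps)
  expect_true(all(colMeans(infl) <= 100 / p + 2 * mc_se + 1e-9 |
                    colMeans(infl) <= 100 / p))
})

test_that("the fit is deterministic given config and data", {
  set.seed(4)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 2] + rnorm(50, 0, 0.5)
  f1 <- fit_brt(y, X, fast_cfg(seed = 7))
  f2 <- fit_brt(y, X, fast_cfg(seed = 7))
  expect_identical(f1$influence, f2$influence)
  expect_identical(f1$best, f2$best)
  expect_identical(f1$cv_table, f2$cv_table)
})

test_that("partial dependence is monotone for a monotone single-predictor signal", {
  set.seed(5)
  x <- matrix(sort(runif(80, -2, 2)), ncol = 1, dimnames = list(NULL, "x"))
  y <- x[, 1]
  fit <- fit_brt(y, x, brt_config(learning_rate = 0.1, tree_complexity = 1,
                                  k = 5, max_trees = 500, seed = 5))
  pd <- partial_dependence(fit, "x", n_grid = 15)
  expect_true(all(diff(pd$yhat) >= -1e-9))
  expect_error(partial_dependence(fit, "x", grid = c(-5, 0)),
               "outside the observed")
})

test_that("partial dependence recovers additive components up to a constant", {
  set.seed(6)
  X <- cbind(x1 = runif(250, -2, 2), x2 = runif(250, -2, 2))
  f1 <- function(v) sin(v)
  y <- f1(X[, 1]) + 0.5 * X[, 2] + rnorm(250, 0, 0.1)
  fit <- fit_brt(y, X, brt_config(learning_rate = 0.1, tree_complexity = 2,
                                  k = 5, max_trees = 600, seed = 6))
  grid <- seq(-1.5, 1.5, length.out = 11)
  pd <- partial_dependence(fit, "x1", grid = grid)
  centred_pd <- pd$yhat - mean(pd$yhat)
  centred_f <- f1(grid) - mean(f1(grid))
  expect_lt(max(abs(centred_pd - centred_f)), 0.35)
  expect_gt(cor(centred_pd, centred_f), 0.98)
})

test_that("an uninformative ensemble yields flat partial dependence at mean(y)", {
  set.seed(7)
  x <- matrix(1, 40, 1, dimnames = list(NULL, "flat"))  # constant predictor
  y <- rnorm(40, 3, 1)
  # bag_fraction 1 so every boosting step sees the full (zero-mean) gradient
  fit <- fit_brt(y, x, fast_cfg(bag_fraction = 1))
  pd <- partial_dependence(fit, "flat", grid = 1)
  expect_lt(abs(pd$yhat - mean(y)), 1e-6)
  # with no informative splits influence falls back to uniform
  expect_equal(fit$influence$selection_freq, 100)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "x"))
  expect_error(fit_brt(rep(1, 40), x, fast_cfg()), "constant response")
  expect_error(fit_brt(rnorm(8), x[1:8, , drop = FALSE], fast_cfg()),
               "too few")
})
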