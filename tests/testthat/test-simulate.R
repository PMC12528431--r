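test_that("coupled logistic map recovers its planted coefficients by exact regression", {
  sim <- simulate_coupled_logistic(n = 1000, r_x = 3.8, r_y = 3.5,
                                   beta_xy = 0, beta_yx = 0.32, seed = 1)
  X <- sim$X; Y <- sim$Y
  # the update is exactly bilinear in (Y, Y^2, XY), so least squares is exact
  y_next <- Y[-1]
  fit <- lm(y_next ~ 0 + I(Y[-1000]) + I(Y[-1000]^2) + I(X[-1000] * Y[-1000]))
  co <- unname(coef(fit))
  expect_lt(abs(co[1] - 3.5) / 3.5, 1e-10)
  expect_lt(abs(co[2] + 3.5) / 3.5, 1e-10)
  expect_lt(abs(co[3] + 0.32) / 0.32, 1e-10)
})

test_that("uncoupled logistic pair gives no cross coefficients and is reproducible", {
  sim <- simulate_coupled_logistic(n = 500, beta_xy = 0, beta_yx = 0,
                                   r_x = 3.8, r_y = 3.8, seed = 4)
  # with zero coupling, X's update involves only X
  x_next <- sim$X[-1]
  fit <- lm(x_next ~ 0 + I(sim$X[-500]) + I(sim$X[-500]^2) +
              I(sim$X[-500] * sim$Y[-500]))
  expect_lt(abs(unname(coef(fit))[3]), 1e-10)
  sim2 <- simulate_coupled_logistic(n = 500, beta_xy = 0, beta_yx = 0,
                                    r_x = 3.8, r_y = 3.8, seed = 4)
  expect_identical(sim$X, sim2$X)
  expect_identical(sim$Y, sim2$Y)
})

test_that("logistic map escape for r > 4 raises a divergence error naming the step", {
  expect_error(
    simulate_coupled_logistic(n = 200, r_x = 4.2, r_y = 3.5, beta_xy = 0,
                              beta_yx = 0, init = c(0.5, 0.3)),
    "diverged at step")
  expect_error(simulate_coupled_logistic(n = 10, init = c(0, 0.5)),
               "initial values")
})

test_that("seasonal predator-prey generator is deterministic given the seed", {
  a <- simulate_seasonal_pp(n_years = 25, seed = 7)
  b <- simulate_seasonal_pp(n_years = 25, seed = 7)
  expect_identical(a$N, b$N)
  expect_identical(a$P, b$P)
  expect_length(a$N, 25 * 12)
})

test_that("decoupled limit: with a = 0 and no noise the predator decays as exp(-m)", {
  d <- simulate_seasonal_pp(n_years = 5, a = 0, sigma_K = 0, sigma_proc = 0,
                            m = 0.3, burn_in_years = 0, seed = 1)
  ratios <- d$P[-1] / d$P[-length(d$P)]
  expect_true(all(abs(ratios - exp(-0.3)) < 1e-12))
  # and prey dynamics are independent of the predator initial state
  d2 <- simulate_seasonal_pp(n_years = 5, a = 0, sigma_K = 0, sigma_proc = 0,
                             burn_in_years = 0, seed = 1, init = c(0.5, 0.9))
  expect_identical(d$N, d2$N)
})

test_that("seasonal phase: prey climatology peaks in spring, predator in summer", {
  pp <- simulate_seasonal_pp(n_years = 200, seed = 7)
  clim_n <- tapply(pp$N, pp$month, mean)
  clim_p <- tapply(pp$P, pp$month, mean)
  expect_true(which.max(clim_n) %in% 3:6)
  expect_true(which.max(clim_p) %in% 6:9)
})

test_that("top-down generator produces the spring-fall anti-phase prey signal", {
  pp <- simulate_seasonal_pp(n_years = 200, seed = 7)
  spring <- tapply(log1p(pp$N)[pp$month %in% 4:6],
                   pp$year[pp$month %in% 4:6], mean)
  fall <- tapply(log1p(pp$N)[pp$month %in% 10:12],
                 pp$year[pp$month %in% 10:12], mean)
  expect_lt(cor(spring, fall, method = "spearman"), 0)
  # the same sign at the survey scale used elsewhere
  pp40 <- simulate_seasonal_pp(n_years = 40, seed = 7)
  s40 <- tapply(log1p(pp40$N)[pp40$month %in% 4:6],
                pp40$year[pp40$month %in% 4:6], mean)
  f40 <- tapply(log1p(pp40$N)[pp40$month %in% 10:12],
                pp40$year[pp40$month %in% 10:12], mean)
  expect_lt(cor(s40, f40, method = "spearman"), 0)
})

test_that("config validation rejects bad seasonal amplitude", {
  expect_error(simulate_seasonal_pp(n_years = 5, alpha = 1.5), "alpha")
  expect_error(simulate_seasonal_pp(n_years = 5, init = c(0, 1)), "positive")
})

test_that("noiseless survey observation reproduces the latent series exactly", {
  pp <- simulate_seasonal_pp(n_years = 10, seed = 3)
  rec <- observe_survey(pp$N, pp$year, pp$month, taxon = "prey",
                        obs_noise_sd = 0, missing_year_prob = 0,
                        samples_per_month = 1, sampled_months = 1:12,
                        scale = 1, seed = 1)
  expect_equal(nrow(rec), length(pp$N))
  expect_equal(rec$abundance_m3, pp$N)
  expect_identical(rec$year, pp$year)
})

test_that("missing-year process drops years at the binomial rate", {
  pp <- simulate_seasonal_pp(n_years = 40, seed = 3)
  dropped <- vapply(1:1000, function(s) {
    rec <- observe_survey(pp$N, pp$year, pp$month, taxon = "prey",
                          missing_year_prob = 0.1, seed = s)
    1 - length(unique(rec$year)) / 40
  }, numeric(1))
  se <- sqrt(0.1 * 0.9 / 40 / 1000)
  expect_lt(abs(mean(dropped) - 0.1), 2 * se)
})

test_that("observation model enforces its contracts", {
  pp <- simulate_seasonal_pp(n_years = 5, seed = 3)
  expect_error(observe_survey(-pp$N, pp$year, pp$month, taxon = "x"),
               "non-negative")
  expect_error(observe_survey(pp$N, pp$year, pp$month, taxon = "x",
                              missing_year_prob = 1, seed = 1),
               "all years dropped")
})

test_that("community ground truth labels follow the generating coupling", {
  com <- simulate_community(n_years = 25, n_predators = 3, coupled = 2,
                            seed = 5)
  gt <- com$ground_truth
  expect_identical(com$coupled, "pred2")
  expect_true(all(gt$coupled == (gt$driver == "pred2" | gt$effect == "pred2")))
  expect_true(all(gt$sign[gt$mode == "bottom_up"] == 1))
  expect_true(all(gt$sign[gt$mode == "top_down"] == -1))
  com0 <- simulate_community(n_years = 25, n_predators = 3, coupled = 0,
                             seed = 5)
  expect_true(all(!com0$ground_truth$coupled))
})

test_that("record CSV round-trips through the documented dialect", {
  rec <- make_records(n_years = 22, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  expect_equal(back$abundance_m3, rec$abundance_m3)
  expect_identical(names(back),
                   c("year", "month", "region", "taxon", "abundance_m3"))
  bad <- rec; bad$month[1] <- 13
  expect_error(write_records(bad, path), "1..12")
})
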