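rec_one <- function(year, month, abundance, taxon = "prey", region = "A") {
  data.frame(year = year, month = month, region = region, taxon = taxon,
             abundance_m3 = abundance, stringsAsFactors = FALSE)
}

test_that("season windows are the three fixed month sets", {
  expect_identical(season("spring")$months, 4:6)
  expect_identical(season("spring_summer")$months, 4:9)
  expect_identical(season("fall")$months, 10:12)
  expect_identical(season("SPRING")$months, 4:6)  # case-insensitive
  expect_error(season("winter"), "unknown season")
  expect_error(season("custom", months = c(0, 5)), "1..12")
})

test_that("seasonal mean is the per-record ln(x+1) average within the window", {
  # a zero-abundance record contributes ln(1) = 0
  s <- seasonal_mean(rec_one(2000, 5, 0), "prey", "A", "spring")
  expect_equal(s$values, 0)
  # two records of e - 1 average to 1 on the transformed scale
  s <- seasonal_mean(rec_one(c(2000, 2000), c(4, 6), rep(exp(1) - 1, 2)),
                     "prey", "A", "spring")
  expect_equal(s$values, 1)
  # transform-the-mean alternative: ln(mean + 1), not mean of ln(x+1)
  r2 <- rec_one(c(2000, 2000), c(4, 6), c(0, exp(2) - 1))
  expect_equal(seasonal_mean(r2, "prey", "A", "spring")$values, 1)
  expect_equal(seasonal_mean(r2, "prey", "A", "spring",
                             transform_mean = TRUE)$values,
               log1p((exp(2) - 1) / 2))
})

test_that("records outside the season window never contribute", {
  r <- rec_one(rep(2000:2004, each = 3), rep(4:6, 5), runif(15, 1, 9))
  expect_s3_class(seasonal_mean(r, "prey", "A", "spring"), "seasonal_series")
  expect_error(seasonal_mean(r, "prey", "A", "fall"), "no records")
  # month 7 is excluded from spring even when present
  r7 <- rbind(r, rec_one(2000, 7, 1e6))
  s <- seasonal_mean(r7, "prey", "A", "spring")
  expect_equal(s$values[1],
               mean(log1p(r$abundance_m3[r$year == 2000])))
})

test_that("year relabeling by a constant leaves seasonal values unchanged", {
  r <- make_records(n_years = 24, seed = 3, missing_year_prob = 0)
  a <- seasonal_mean(r, "prey", "A", "spring")
  r2 <- r; r2$year <- r2$year + 1000
  b <- seasonal_mean(r2, "prey", "A", "spring")
  expect_equal(a$values, b$values)
  expect_equal(b$years, a$years + 1000)
})

test_that("gap fill is the identity when no years are missing", {
  r <- make_records(n_years = 24, seed = 3, missing_year_prob = 0)
  s <- seasonal_mean(r, "prey", "A", "spring")
  f <- loess_fill(s)
  expect_identical(f$values, s$values)
  expect_true(all(!f$interpolated))
  expect_equal(f$interp_fraction, 0)
})

test_that("gap fill reproduces an exactly linear trend at interior gaps", {
  years <- 1980:1999
  vals <- 0.3 + 0.05 * (years - 1980)
  for (deg in 1:2) {
    for (gap in list(1990, c(1985, 1993))) {
      v <- vals; v[years %in% gap] <- NA
      s <- seasonccm:::new_seasonal_series("t", "A", season("spring"),
                                           years, v,
                                           rep(FALSE, length(years)))
      f <- loess_fill(s, span = 0.5, degree = deg)
      expect_lt(max(abs(f$values - vals)), 1e-8)
      expect_identical(which(f$interpolated), which(years %in% gap))
    }
  }
})

test_that("gap fill matches the direct tricube local-regression oracle", {
  set.seed(11)
  years <- 1971:1990
  vals <- cumsum(rnorm(20, 0, 0.4))
  gaps <- c(1977, 1985)
  v <- vals; v[years %in% gaps] <- NA
  s <- seasonccm:::new_seasonal_series("t", "A", season("fall"), years, v,
                                       rep(FALSE, 20))
  for (deg in 1:2) {
    f <- loess_fill(s, span = 0.5, degree = deg)
    for (g in gaps) {
      oracle <- bf_local_regression(years[!is.na(v)], vals[!is.na(v)],
                                    g, span = 0.5, degree = deg)
      expect_lt(abs(f$values[years == g] - oracle), 1e-8)
    }
    # observed values are never altered
    expect_identical(f$values[!is.na(v)], vals[!is.na(v)])
  }
  expect_equal(f$interp_fraction, 2 / 20)
})

test_that("gap fill truncates to the observed range and refuses sparse series", {
  years <- 2000:2010
  v <- c(NA, 1, 2, NA, 4, 5, 6, 7, 8, 9, NA)  # missing ends + one interior
  s <- seasonccm:::new_seasonal_series("t", "A", season("spring"), years, v,
                                       rep(FALSE, 11))
  f <- loess_fill(s, degree = 1)
  expect_identical(f$years, 2001:2009)          # ends dropped, not extrapolated
  expect_false(anyNA(f$values))
  s2 <- seasonccm:::new_seasonal_series("t", "A", season("spring"),
                                        2000:2002, c(1, NA, 3),
                                        rep(FALSE, 3))
  expect_error(loess_fill(s2), "too few observed years")
})

test_that("heavy interpolation triggers the configurable warning", {
  years <- 1980:1999
  v <- 0.2 * (years - 1980); v[c(3, 6, 9, 12, 15, 17, 19)] <- NA
  s <- seasonccm:::new_seasonal_series("t", "A", season("spring"), years, v,
                                       rep(FALSE, 20))
  expect_warning(loess_fill(s), "interpolated")
  expect_silent(loess_fill(s, warn_threshold = 0.5))
})

test_that("normalization gives exactly zero mean and unit variance", {
  s <- seasonccm:::new_seasonal_series("t", "A", season("spring"),
                                       2001:2003, c(1, 2, 3), rep(FALSE, 3))
  z <- normalize_series(s)
  expect_equal(z$values, c(-1, 0, 1))
  expect_true(z$normalized)
  # idempotence
  z2 <- normalize_series(z)
  expect_lt(max(abs(z2$values - z$values)), 1e-12)
  # tolerance of the invariant on a long noisy series
  set.seed(2)
  s2 <- seasonccm:::new_seasonal_series("t", "A", season("fall"), 1:50,
                                        rnorm(50, 5, 2), rep(FALSE, 50))
  z3 <- normalize_series(s2)
  expect_lt(abs(mean(z3$values)), 1e-9)
  expect_lt(abs(var(z3$values) - 1), 1e-9)
  # constant series is degenerate
  s3 <- seasonccm:::new_seasonal_series("t", "A", season("fall"), 1:3,
                                        c(5, 5, 5), rep(FALSE, 3))
  expect_error(normalize_series(s3), "variance is zero")
})

test_that("prep pipeline runs transform -> mean -> fill -> normalize", {
  r <- make_records(n_years = 30, seed = 6)
  s <- prep_series(r, "prey", "A", "spring")
  expect_true(s$normalized)
  expect_false(anyNA(s$values))
  expect_lt(abs(mean(s$values)), 1e-9)
  expect_equal(diff(s$years), rep(1, length(s$years) - 1))
  expect_equal(s$interp_fraction, mean(s$interpolated))
})
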