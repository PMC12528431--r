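#' Season window definitions
#'
#' The three analysis seasons: spring (April-June), spring-summer
#' (April-September, the predators' extended foraging window) and fall
#' (October-December, when the copepod's overwintering stock is set).
#'
#' @param name One of `"spring"`, `"spring_summer"`, `"fall"`
#'   (case-insensitive), or `"custom"` with `months` supplied.
#' @param months Integer months for a custom season.
#' @return List of class `"season"` with `name` and `months`.
#' @examples
#' season("spring")$months
#' @export
season <- function(name, months = NULL) {
  name <- tolower(name)
  std <- list(spring = 4:6, spring_summer = 4:9, fall = 10:12)
  if (name %in% names(std)) {
    months <- std[[name]]
  } else if (identical(name, "custom")) {
    if (is.null(months)) stop("custom season requires months")
  } else {
    stop("unknown season '", name,
         "'; use spring, spring_summer, fall or custom")
  }
  months <- sort(unique(as.integer(months)))
  if (any(!months %in% 1:12)) stop("season months must lie in 1..12")
  structure(list(name = name, months = months), class = "season")
}

as_season <- function(x) if (inherits(x, "season")) x else season(x)

new_seasonal_series <- function(taxon, region, season, years, values,
                                interpolated, normalized = FALSE,
                                transform = "log1p") {
  structure(list(taxon = taxon, region = region, season = season,
                 years = as.integer(years), values = as.numeric(values),
                 interpolated = as.logical(interpolated),
                 interp_fraction = mean(interpolated),
                 normalized = normalized, transform = transform),
            class = "seasonal_series")
}

#' @export
print.seasonal_series <- function(x, ...) {
  cat(sprintf("Seasonal series: %s / %s / %s (%d-%d, n = %d)\n",
              x$taxon, x$region, x$season$name,
              min(x$years), max(x$years), length(x$years)))
  cat(sprintf("  transform: %s | normalized: %s | interpolated: %.1f%% | missing: %d\n",
              x$transform, x$normalized, 100 * x$interp_fraction,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.data.frame.seasonal_series <- function(x, ...) {
  data.frame(year = x$years, value = x$values,
             interpolated = x$interpolated)
}

#' Seasonal mean abundance series
#'
#' Averages survey records within a season window into one value per year on
#' the ln(abundance + 1) scale. By default the transform is applied per
#' record before averaging (the plankton-survey convention, stabilizing
#' tow-level lognormal noise); `transform_mean = TRUE` instead transforms
#' the yearly mean abundance. Years inside the observed range with no
#' in-season records are retained as `NA` (missing), to be filled by
#' [loess_fill()].
#'
#' @param records Survey record data frame (see [write_records()] for the
#'   dialect).
#' @param taxon,region Labels selecting the records.
#' @param season A [season()] object or season name.
#' @param transform `"log1p"` (default) or `"none"`.
#' @param transform_mean Transform the yearly mean rather than each record.
#' @return A `"seasonal_series"` (raw: not filled, not normalized).
#' @export
seasonal_mean <- function(records, taxon, region, season,
                          transform = c("log1p", "none"),
                          transform_mean = FALSE) {
  transform <- match.arg(transform)
  season <- as_season(season)
  validate_records(records)
  sel <- records$taxon == taxon & records$region == region &
    records$month %in% season$months
  if (!any(sel))
    stop(sprintf("no records for taxon '%s', region '%s', season '%s'",
                 taxon, region, season$name))
  rec <- records[sel, , drop = FALSE]
  f <- if (transform == "log1p") log1p else identity
  yrs <- seq.int(min(rec$year), max(rec$year))
  agg <- if (transform_mean) {
    tapply(rec$abundance_m3, rec$year, function(v) f(mean(v)))
  } else {
    tapply(f(rec$abundance_m3), rec$year, mean)
  }
  values <- rep(NA_real_, length(yrs))
  values[match(as.integer(names(agg)), yrs)] <- as.numeric(agg)
  new_seasonal_series(taxon, region, season, yrs, values,
                      interpolated = rep(FALSE, length(yrs)),
                      transform = transform)
}

# Tricube-weighted local polynomial regression evaluated at `x0`, using the
# q nearest observed points (q = max(ceil(span * n), degree + 2); ties at
# the cutoff distance are all included; the farthest point gets tricube
# weight zero).
local_poly_fit <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- max(ceiling(span * n), degree + 2)
  q <- min(q, n)
  repeat {
    d <- abs(x - x0)
    dmax <- sort(d, partial = q)[q]
    use <- which(d <= dmax)
    w <- (1 - (d[use] / dmax)^3)^3
    pos <- w > 0
    if (sum(pos) >= degree + 1 || q == n) break
    q <- q + 1
  }
  if (sum(w > 0) < degree + 1)
    stop("too few points with positive weight for local polynomial fit")
  X <- outer(x[use] - x0, 0:degree, "^")
  fit <- stats::lm.wfit(X, y[use], w)
  unname(fit$coefficients[1])
}

#' Fill missing years by local (LOESS-style) regression
#'
#' Fills interior missing years of a seasonal series with a tricube-weighted
#' local polynomial fit over the observed years, so the series becomes
#' evenly spaced as embedding-based analyses require. The span is the
#' fraction of observed points entering each local fit; only observed points
#' are used, observed values are never altered, and no extrapolation is
#' performed: the series is truncated to the first-to-last observed year.
#'
#' @param series A `"seasonal_series"` from [seasonal_mean()].
#' @param span Fraction of observed points per local fit, in (0, 1].
#' @param degree Local polynomial degree, 1 or 2.
#' @param warn_threshold Warn when the interpolated fraction exceeds this
#'   (heavily gap-filled series carry little interannual information).
#' @return The series with contiguous years, `interpolated` marking filled
#'   years and `interp_fraction` updated.
#' @export
loess_fill <- function(series, span = 0.5, degree = 2, warn_threshold = 0.3) {
  stopifnot(inherits(series, "seasonal_series"))
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  obs <- !is.na(series$values)
  n_obs <- sum(obs)
  if (n_obs < max(degree + 2, 4))
    stop(sprintf("too few observed years (%d) for local regression fill", n_obs))

  # truncate to the observed range: gaps are filled, ends are not extrapolated
  rng <- range(series$years[obs])
  keep <- series$years >= rng[1] & series$years <= rng[2]
  years <- series$years[keep]
  values <- series$values[keep]
  interp <- series$interpolated[keep]

  miss <- which(is.na(values))
  if (length(miss)) {
    ox <- as.numeric(years[!is.na(values)])
    oy <- values[!is.na(values)]
    for (i in miss) {
      values[i] <- local_poly_fit(ox, oy, as.numeric(years[i]), span, degree)
    }
    interp[miss] <- TRUE
  }
  out <- new_seasonal_series(series$taxon, series$region, series$season,
                             years, values, interp,
                             normalized = series$normalized,
                             transform = series$transform)
  if (out$interp_fraction > warn_threshold)
    warning(sprintf("%.0f%% of years interpolated for %s/%s/%s (threshold %.0f%%)",
                    100 * out$interp_fraction, out$taxon, out$region,
                    out$season$name, 100 * warn_threshold))
  out
}

#' Normalize a seasonal series to zero mean and unit variance
#'
#' Standard z-normalization (sd with denominator `n - 1`) so that series of
#' different taxa are on the same scale before cross mapping. Always the
#' last preparation step.
#'
#' @param series A contiguous (gap-filled) `"seasonal_series"`.
#' @return The normalized series (`normalized = TRUE`).
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "seasonal_series"))
  v <- series$values
  if (anyNA(v)) stop("series has missing years; fill gaps before normalizing")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("constant series: variance is zero, normalization undefined")
  out <- series
  out$values <- (v - mean(v)) / s
  out$normalized <- TRUE
  out
}

#' Full seasonal preparation pipeline
#'
#' Convenience wrapper running the fixed preparation order:
#' ln(x+1) transform -> season-window yearly mean -> LOESS gap fill ->
#' z-normalization.
#'
#' @inheritParams seasonal_mean
#' @inheritParams loess_fill
#' @param normalize Apply the final normalization step.
#' @return A prepared `"seasonal_series"`.
#' @export
prep_series <- function(records, taxon, region, season,
                        transform = "log1p", transform_mean = FALSE,
                        span = 0.5, degree = 2, normalize = TRUE,
                        warn_threshold = 0.3) {
  s <- seasonal_mean(records, taxon, region, season,
                     transform = transform, transform_mean = transform_mean)
  s <- loess_fill(s, span = span, degree = degree,
                  warn_threshold = warn_threshold)
  if (normalize) s <- normalize_series(s) else s
}
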