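#' Coupled logistic map benchmark
#'
#' Simulates the two-species coupled logistic map, the standard benchmark for
#' validating convergent cross mapping:
#' \deqn{X_{t+1} = X_t (r_x - r_x X_t - \beta_{xy} Y_t)}
#' \deqn{Y_{t+1} = Y_t (r_y - r_y Y_t - \beta_{yx} X_t)}
#' `beta_yx` is the strength with which X forces Y (so `beta_yx > 0`,
#' `beta_xy = 0` plants the unidirectional hypothesis X -> Y). Initial
#' values are drawn uniformly in (0.1, 0.9) from `seed` and the first
#' `burn_in` steps are discarded as transient.
#'
#' @param n Number of retained steps after burn-in.
#' @param r_x,r_y Logistic growth rates.
#' @param beta_xy Effect of Y on X.
#' @param beta_yx Effect of X on Y.
#' @param burn_in Transient steps discarded.
#' @param seed Integer seed (initial conditions).
#' @param init Optional length-2 numeric `c(X0, Y0)` in (0,1), overriding the
#'   random initials.
#' @return List with numeric vectors `X` and `Y` of length `n`, and the
#'   parameters used.
#' @examples
#' sim <- simulate_coupled_logistic(n = 200, beta_yx = 0.32, seed = 1)
#' @export
simulate_coupled_logistic <- function(n = 400, r_x = 3.8, r_y = 3.5,
                                      beta_xy = 0, beta_yx = 0.32,
                                      burn_in = 100, seed = NULL,
                                      init = NULL) {
  stopifnot(n >= 1, burn_in >= 0,
            is.finite(r_x), is.finite(r_y), is.finite(beta_xy),
            is.finite(beta_yx))
  if (is.null(init)) {
    init <- with_seed(seed, function() stats::runif(2, 0.1, 0.9))
  }
  if (length(init) != 2 || any(init <= 0) || any(init >= 1))
    stop("initial values must lie in (0, 1)")
  total <- n + burn_in
  X <- Y <- numeric(total + 1)
  X[1] <- init[1]; Y[1] <- init[2]
  for (t in seq_len(total)) {
    X[t + 1] <- X[t] * (r_x - r_x * X[t] - beta_xy * Y[t])
    Y[t + 1] <- Y[t] * (r_y - r_y * Y[t] - beta_yx * X[t])
    if (!is.finite(X[t + 1]) || !is.finite(Y[t + 1]) ||
        X[t + 1] <= 0 || X[t + 1] >= 1 || Y[t + 1] <= 0 || Y[t + 1] >= 1)
      stop(sprintf(
        "coupled logistic map diverged at step %d (r_x=%g, r_y=%g, beta_xy=%g, beta_yx=%g): state left (0,1)",
        t, r_x, r_y, beta_xy, beta_yx))
  }
  keep <- seq.int(burn_in + 2, total + 1)
  list(X = X[keep], Y = Y[keep],
       params = list(r_x = r_x, r_y = r_y, beta_xy = beta_xy,
                     beta_yx = beta_yx, burn_in = burn_in, n = n))
}

#' Seasonally forced predator-prey simulator (monthly Ricker dynamics)
#'
#' Generates monthly latent abundances for a prey N (a spring-blooming
#' copepod) and a predator P under discrete Ricker-type dynamics with
#' sinusoidal seasonal forcing of the prey growth rate:
#' \deqn{N_{t+1} = N_t \exp(r (1 + \alpha \sin(2\pi t/12)) (1 - N_t/K) - a P_t + \sigma \epsilon_t)}
#' \deqn{P_{t+1} = P_t \exp(b a N_t - m + \sigma \eta_t)}
#' With the default parameters the mean monthly climatology of N peaks in
#' spring (months 3-6) and P in summer (months 6-9), producing the
#' spring-bloom, summer-predator, fall-decline cascade characteristic of
#' seasonally forced trophic systems.
#'
#' Interannual variability enters through two stochastic terms: year-level
#' lognormal anomalies of the carrying capacity, `K_y = K exp(delta_y)`,
#' `delta_y ~ Normal(0, sigma_K^2)`, standing in for food-supply (bloom
#' phenology) variation between years, and monthly lognormal process noise
#' of SD `sigma_proc` on both updates. Good food years raise the spring
#' prey peak, fuel the predator through summer, and end in below-average
#' fall prey — so across years the spring and fall prey means are
#' negatively correlated while prey-to-predator (bottom-up) correlations
#' are positive. Setting both SDs to 0 recovers the deterministic periodic
#' skeleton. The first `burn_in_years` years are discarded.
#'
#' @param n_years Retained years (>= 20 recommended for embedding-based
#'   analyses).
#' @param r Prey intrinsic growth rate (per month).
#' @param alpha Seasonal forcing amplitude, in `[0, 1]`.
#' @param K Prey carrying capacity.
#' @param a Attack rate (predation pressure per unit predator); 0 decouples
#'   the pair.
#' @param b Conversion efficiency of consumed prey into predator growth.
#' @param m Predator mortality (per month).
#' @param sigma_K SD of the year-level log carrying-capacity anomalies.
#' @param sigma_proc SD of monthly lognormal process noise on both updates.
#' @param burn_in_years Transient years discarded.
#' @param seed Integer seed.
#' @param init Length-2 `c(N0, P0)`, strictly positive.
#' @return List with vectors `N`, `P` (length `12 * n_years`), `year`
#'   (1-based), `month` (1-12), and `params`.
#' @examples
#' sim <- simulate_seasonal_pp(n_years = 40, seed = 7)
#' tapply(sim$N, sim$month, mean)  # climatology peaks in spring
#' @export
simulate_seasonal_pp <- function(n_years = 40, r = 0.8, alpha = 0.9, K = 1,
                                 a = 1.2, b = 0.5, m = 0.3,
                                 sigma_K = 0.3, sigma_proc = 0.1,
                                 burn_in_years = 10,
                                 seed = NULL, init = c(0.5, 0.2)) {
  if (alpha < 0 || alpha > 1) stop("seasonal amplitude alpha must be in [0, 1]")
  stopifnot(n_years >= 1, burn_in_years >= 0, K > 0, sigma_proc >= 0,
            sigma_K >= 0, all(is.finite(c(r, alpha, K, a, b, m))))
  if (any(init <= 0)) stop("initial abundances must be strictly positive")
  total <- 12L * (n_years + burn_in_years)
  all_years <- n_years + burn_in_years
  sim <- function() {
    N <- P <- numeric(total + 1)
    N[1] <- init[1]; P[1] <- init[2]
    K_y <- K * exp(if (sigma_K > 0) stats::rnorm(all_years, 0, sigma_K)
                   else numeric(all_years))
    eps <- if (sigma_proc > 0) stats::rnorm(total, 0, sigma_proc) else numeric(total)
    eta <- if (sigma_proc > 0) stats::rnorm(total, 0, sigma_proc) else numeric(total)
    for (t in seq_len(total)) {
      force_t <- r * (1 + alpha * sin(2 * pi * t / 12))
      Kt <- K_y[ceiling(t / 12)]
      N[t + 1] <- N[t] * exp(force_t * (1 - N[t] / Kt) - a * P[t] + eps[t])
      P[t + 1] <- P[t] * exp(b * a * N[t] - m + eta[t])
      if (!is.finite(N[t + 1]) || !is.finite(P[t + 1]))
        stop(sprintf("seasonal predator-prey simulation became non-finite at month %d", t))
    }
    list(N = N, P = P)
  }
  out <- with_seed(seed, sim)
  keep <- seq.int(12L * burn_in_years + 2L, total + 1L)
  month <- rep(1:12, n_years)
  list(N = out$N[keep], P = out$P[keep],
       year = rep(seq_len(n_years), each = 12L), month = month,
       params = list(r = r, alpha = alpha, K = K, a = a, b = b, m = m,
                     sigma_K = sigma_K, sigma_proc = sigma_proc,
                     burn_in_years = burn_in_years, n_years = n_years))
}

#' Simulate a community with one coupled predator among decoys
#'
#' Builds a monthly latent community around [simulate_seasonal_pp()]: a prey
#' taxon, one predator dynamically coupled to it (bidirectional Ricker
#' coupling through attack rate `a`), and `n_predators - 1` decoy predators
#' following independent seasonally forced Ricker dynamics (random seasonal
#' phase and growth rate, same process noise) with no coupling to the prey.
#' The decoys share the 12-month seasonal cycle but none of the prey's
#' interannual signal, which is exactly the confound the seasonal-surrogate
#' CCM test must not mistake for coupling.
#'
#' @param n_years Retained years.
#' @param n_predators Total number of predator taxa (>= 1).
#' @param coupled One-based index of the coupled predator among the
#'   predators, or 0 for a fully uncoupled community.
#' @param a Attack rate for the coupled pair (0 also yields an uncoupled
#'   community).
#' @param sigma_K Year-level carrying-capacity anomaly SD (all taxa; each
#'   taxon draws its own independent anomalies).
#' @param sigma_proc Monthly process noise SD (all taxa).
#' @param seed Integer seed; decoy parameters and all noise derive from it.
#' @param taxa Optional character vector of predator names (length
#'   `n_predators`).
#' @param prey_name Name for the prey taxon.
#' @param ... Further parameters passed to [simulate_seasonal_pp()].
#' @return List of class `"community_sim"`: `latent` (numeric matrix, one
#'   column per taxon, prey first), `year`, `month`, `ground_truth` (data
#'   frame of directed prey-predator pairs with `coupled` flag and expected
#'   correlation sign: bottom-up positive, top-down negative), and `seed`.
#' @export
simulate_community <- function(n_years = 60, n_predators = 5, coupled = 1,
                               a = 1.2, sigma_K = 0.3, sigma_proc = 0.1,
                               seed = 1, taxa = NULL, prey_name = "prey",
                               ...) {
  stopifnot(n_predators >= 1, coupled >= 0, coupled <= n_predators)
  if (is.null(taxa)) taxa <- paste0("pred", seq_len(n_predators))
  stopifnot(length(taxa) == n_predators)

  a_eff <- if (coupled > 0) a else 0
  pair <- simulate_seasonal_pp(n_years = n_years, a = a_eff,
                               sigma_K = sigma_K, sigma_proc = sigma_proc,
                               seed = derive_seed(seed, "prey-pair"), ...)
  n_m <- length(pair$N)
  latent <- matrix(NA_real_, nrow = n_m, ncol = n_predators + 1,
                   dimnames = list(NULL, c(prey_name, taxa)))
  latent[, 1] <- pair$N
  if (coupled > 0) latent[, 1 + coupled] <- pair$P

  for (j in seq_len(n_predators)) {
    if (j == coupled) next
    sj <- derive_seed(seed, paste0("decoy-", taxa[j]))
    decoy_par <- with_seed(sj, function()
      list(r = stats::runif(1, 0.5, 1.1),
           phase = stats::runif(1, 0, 2 * pi),
           alpha = stats::runif(1, 0.5, 0.9)))
    dec <- simulate_decoy(n_years = n_years, r = decoy_par$r,
                          alpha = decoy_par$alpha, phase = decoy_par$phase,
                          sigma_K = sigma_K, sigma_proc = sigma_proc,
                          seed = derive_seed(seed, paste0("decoy-run-", j)))
    latent[, 1 + j] <- dec
  }

  gt <- data.frame(
    driver = c(rep(prey_name, n_predators), taxa),
    effect = c(taxa, rep(prey_name, n_predators)),
    mode = rep(c("bottom_up", "top_down"), each = n_predators),
    coupled = rep(seq_len(n_predators) == coupled, 2),
    sign = rep(c(1, -1), each = n_predators),
    stringsAsFactors = FALSE
  )
  structure(list(latent = latent, year = pair$year, month = pair$month,
                 ground_truth = gt, seed = seed,
                 prey = prey_name, predators = taxa,
                 coupled = if (coupled > 0) taxa[coupled] else NA_character_),
            class = "community_sim")
}

# Independent seasonally forced Ricker dynamics for a decoy predator, with
# its own year-level carrying-capacity anomalies so its interannual variance
# structure matches the coupled taxa (a fair confound for the null).
simulate_decoy <- function(n_years, r, alpha, phase, sigma_K, sigma_proc,
                           seed, burn_in_years = 10) {
  total <- 12L * (n_years + burn_in_years)
  all_years <- n_years + burn_in_years
  x <- with_seed(seed, function() {
    K_y <- exp(stats::rnorm(all_years, 0, sigma_K))
    eps <- stats::rnorm(total, 0, sigma_proc)
    v <- numeric(total + 1)
    v[1] <- 0.5
    for (t in seq_len(total)) {
      force_t <- r * (1 + alpha * sin(2 * pi * t / 12 + phase))
      v[t + 1] <- v[t] * exp(force_t * (1 - v[t] / K_y[ceiling(t / 12)]) + eps[t])
    }
    v
  })
  x[seq.int(12L * burn_in_years + 2L, total + 1L)]
}

#' Survey observation model
#'
#' Converts a latent monthly abundance series into station-level survey
#' records: in each retained year, the sampled months each yield
#' `samples_per_month` records with abundance
#' `scale * latent * exp(eps)`, `eps ~ Normal(0, obs_noise_sd^2)`
#' (multiplicative lognormal tow noise); whole years are dropped
#' independently with probability `missing_year_prob`, emulating unsampled
#' survey years.
#'
#' @param latent Positive numeric vector of monthly latent abundances.
#' @param year,month Integer vectors aligned with `latent`.
#' @param taxon,region Labels stored in the records.
#' @param obs_noise_sd SD of the log-scale observation noise.
#' @param missing_year_prob Probability that a year is entirely unsampled.
#' @param samples_per_month Records per sampled month.
#' @param sampled_months Months visited by the survey (default: six
#'   bimonthly cruises).
#' @param scale Multiplier mapping latent state to abundance per cubic metre.
#' @param seed Integer seed.
#' @return Data frame with columns `year`, `month`, `region`, `taxon`,
#'   `abundance_m3`.
#' @examples
#' sim <- simulate_seasonal_pp(n_years = 30, seed = 2)
#' rec <- observe_survey(sim$N, sim$year, sim$month, taxon = "prey", seed = 3)
#' @export
observe_survey <- function(latent, year, month, taxon, region = "A",
                           obs_noise_sd = 0.2, missing_year_prob = 0.1,
                           samples_per_month = 1,
                           sampled_months = c(2, 4, 6, 8, 10, 12),
                           scale = 100, seed = NULL) {
  stopifnot(length(latent) == length(year), length(latent) == length(month),
            obs_noise_sd >= 0, samples_per_month >= 1, scale > 0)
  if (missing_year_prob < 0 || missing_year_prob > 1)
    stop("missing_year_prob must be a probability in [0, 1]")
  if (any(latent < 0)) stop("latent abundances must be non-negative")
  build <- function() {
    yrs <- sort(unique(year))
    kept <- yrs[stats::runif(length(yrs)) >= missing_year_prob]
    if (length(kept) == 0)
      stop("all years dropped by the missing-year process; no records generated")
    idx <- which(year %in% kept & month %in% sampled_months)
    idx <- rep(idx, each = samples_per_month)
    eps <- if (obs_noise_sd > 0) stats::rnorm(length(idx), 0, obs_noise_sd)
           else numeric(length(idx))
    data.frame(year = year[idx], month = month[idx],
               region = region, taxon = taxon,
               abundance_m3 = scale * latent[idx] * exp(eps),
               stringsAsFactors = FALSE)
  }
  with_seed(seed, build)
}

#' Survey records for a whole simulated community
#'
#' Applies [observe_survey()] to every taxon of a [simulate_community()]
#' output, with a per-taxon RNG substream derived from the community seed so
#' adding taxa does not disturb existing ones.
#'
#' @param community A `"community_sim"` object.
#' @param region Region label.
#' @param ... Observation-model parameters passed to [observe_survey()].
#' @return Data frame of survey records for all taxa.
#' @export
community_survey <- function(community, region = "A", ...) {
  stopifnot(inherits(community, "community_sim"))
  recs <- lapply(colnames(community$latent), function(tx) {
    observe_survey(community$latent[, tx], community$year, community$month,
                   taxon = tx, region = region,
                   seed = derive_seed(community$seed, paste0("obs-", region, "-", tx)),
                   ...)
  })
  do.call(rbind, recs)
}

#' Read or write survey record tables
#'
#' CSV dialect: header `year,month,region,taxon,abundance_m3`, months 1-12,
#' abundance a non-negative float (per cubic metre).
#'
#' @param records Data frame of survey records.
#' @param path File path.
#' @return `read_records` returns the validated data frame;
#'   `write_records` returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  utils::write.csv(records[, c("year", "month", "region", "taxon", "abundance_m3")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(rec)
  rec
}

validate_records <- function(records) {
  need <- c("year", "month", "region", "taxon", "abundance_m3")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records table missing columns: ", paste(miss, collapse = ", "))
  if (any(!records$month %in% 1:12)) stop("months must be integers in 1..12")
  if (any(records$abundance_m3 < 0)) stop("abundances must be non-negative")
  invisible(records)
}
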