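#' Time-delay embedding of a scalar series
#'
#' Reconstructs a shadow state space from a single time series by Takens'
#' delay-coordinate map: the row for time `t` is
#' `(x_t, x_{t-tau}, ..., x_{t-(E-1)tau})`.
#'
#' @param x Numeric series (no NAs).
#' @param E Embedding dimension (>= 1).
#' @param tau Lag between coordinates, in series steps (>= 1).
#' @return Numeric matrix with `length(x) - (E-1)*tau` rows and `E` columns;
#'   attribute `"times"` gives the time index of each row (the index of the
#'   first, most recent, coordinate).
#' @examples
#' delay_embed(c(1, 2, 3, 4, 5), E = 2)
#' @export
delay_embed <- function(x, E, tau = 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x)) stop("series contains NA; fill gaps before embedding")
  if (E < 1 || tau < 1) stop("E and tau must be >= 1")
  if ((E - 1) * tau + 1 > n)
    stop(sprintf("series too short for embedding: need (E-1)*tau+1 = %d <= n = %d",
                 (E - 1) * tau + 1, n))
  times <- seq.int((E - 1) * tau + 1, n)
  emb <- vapply(seq_len(E) - 1L,
                function(j) x[times - j * tau],
                numeric(length(times)))
  emb <- matrix(emb, nrow = length(times), ncol = E)
  attr(emb, "times") <- times
  emb
}

pearson_skill <- function(pred, obs) {
  keep <- is.finite(pred) & is.finite(obs)
  pred <- pred[keep]; obs <- obs[keep]
  if (length(pred) < 3) stop("too few predictable points for skill")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("degenerate (constant) predictions or observations; skill undefined")
  stats::cor(pred, obs)
}

#' Simplex-projection forecast skill
#'
#' Leave-one-out nearest-neighbour forecasting on the delay embedding: each
#' point is predicted `tp` steps ahead from its `E + 1` nearest embedded
#' neighbours (Euclidean distance, the point's own row excluded), weighted
#' `w_i = exp(-d_i/d_1)`. Skill is the Pearson correlation between
#' predictions and observations, the standard criterion for choosing the
#' embedding dimension.
#'
#' @inheritParams delay_embed
#' @param tp Prediction horizon in steps (>= 1 for forecasting).
#' @param detail If `TRUE`, return predictions and observations as well.
#' @return Forecast skill (Pearson rho), or a list when `detail = TRUE`.
#' @examples
#' x <- sin(2 * pi * (1:240) / 12)
#' simplex_forecast(x, E = 2)
#' @export
simplex_forecast <- function(x, E, tau = 1, tp = 1, exclusion_radius = 0,
                             detail = FALSE) {
  x <- as.numeric(x)
  if (tp < 1) stop("tp must be >= 1 for forecasting")
  emb <- delay_embed(x, E, tau)
  times <- attr(emb, "times")
  n <- length(x)
  target <- ifelse(times + tp <= n, x[pmin(times + tp, n)], NA_real_)
  pred_rows <- which(!is.na(target))
  if (length(pred_rows) < E + 2)
    stop("not enough embedded points for E+1 neighbours after exclusion")
  preds <- nn_forecast(emb, as.integer(times), target,
                       lib = seq_len(nrow(emb)) - 1L,
                       pred = pred_rows - 1L, k = E + 1L,
                       excl = as.integer(exclusion_radius))
  rho <- pearson_skill(preds, target[pred_rows])
  if (!detail) return(rho)
  list(skill = rho, predictions = preds, observations = target[pred_rows],
       times = times[pred_rows], E = E, tau = tau, tp = tp)
}

#' Choose the embedding dimension by simplex projection
#'
#' Runs [simplex_forecast()] over a range of candidate embedding dimensions
#' and selects the one maximizing forecast skill; ties go to the smallest E.
#'
#' @inheritParams simplex_forecast
#' @param E_range Candidate embedding dimensions.
#' @return List of class `"simplex_scan"`: `E_range`, `skill` (one rho per
#'   candidate), `E` (the selected dimension).
#' @export
select_E <- function(x, E_range = NULL, tau = 1, tp = 1,
                     exclusion_radius = 0) {
  n <- length(x)
  if (is.null(E_range)) E_range <- seq_len(max(1L, min(10L, floor(n / 3))))
  E_range <- as.integer(E_range)
  if (length(E_range) == 0) stop("E_range is empty")
  skill <- vapply(E_range,
                  function(E) simplex_forecast(x, E, tau, tp, exclusion_radius),
                  numeric(1))
  best <- E_range[which.max(skill)]   # which.max returns the first maximum
  structure(list(E_range = E_range, skill = skill, E = best),
            class = "simplex_scan")
}

#' @export
print.simplex_scan <- function(x, ...) {
  cat("Simplex projection scan\n")
  print(data.frame(E = x$E_range, skill = round(x$skill, 4)), row.names = FALSE)
  cat("selected E =", x$E, "\n")
  invisible(x)
}

ccm_skill_once <- function(emb, times, target, lib_rows, k, excl = 0L) {
  preds <- nn_forecast(emb, times, target,
                       lib = lib_rows - 1L,
                       pred = seq_len(nrow(emb)) - 1L, k = k,
                       excl = as.integer(excl))
  pearson_skill(preds, target)
}

#' Convergent cross mapping between two series
#'
#' Tests the directed hypothesis `driver -> effect` by cross-mapping: the
#' effect series is delay-embedded, and states of the driver are estimated
#' from each embedded point's `E + 1` nearest neighbours (contemporaneously,
#' `tp = 0`). If the driver forces the effect, the effect's reconstructed
#' manifold encodes the driver, and cross-map skill (Pearson correlation of
#' estimates with the observed driver) rises with library size.
#'
#' For each library size `L`, `n_samples` random subsets of `L` embedding
#' rows are drawn without replacement and the mean skill recorded; the
#' reported `skill` uses the full library in a single deterministic
#' evaluation.
#'
#' @param driver Numeric series for the hypothesized driver (X).
#' @param effect Numeric series for the hypothesized effect (Y); its delay
#'   embedding supplies the neighbours. Same length as `driver`, both
#'   normalized.
#' @param E Embedding dimension for the effect series (e.g. from
#'   [select_E()] on the effect).
#' @param tau Embedding lag.
#' @param tp Cross-map horizon; 0 estimates the contemporaneous driver state.
#' @param lib_sizes Increasing library sizes; default 8 sizes evenly spaced
#'   from `E + 2` to the number of embedding rows.
#' @param n_samples Random library subsets per library size.
#' @param seed Optional integer seed for the subsampling RNG.
#' @return Object of class `"ccm_result"` with elements `skill`
#'   (full-library cross-map skill), `lib_sizes`, `rho_by_lib` (mean skill
#'   per L), `sub_skills` (matrix, `n_samples` x `length(lib_sizes)`),
#'   `convergence_delta` (`rho(L_max) - rho(L_min)` on subsample means),
#'   `E`, `tau`, `tp`, and the series labels.
#' @examples
#' sim <- simulate_coupled_logistic(n = 300, beta_yx = 0.32, seed = 1)
#' ccm <- cross_map(sim$X, sim$Y, E = 2, n_samples = 25, seed = 1)
#' ccm$skill
#' @export
cross_map <- function(driver, effect, E, tau = 1, tp = 0,
                      lib_sizes = NULL, n_samples = 100,
                      exclusion_radius = 0, seed = NULL) {
  driver <- as.numeric(driver); effect <- as.numeric(effect)
  if (length(driver) != length(effect))
    stop("driver and effect must be aligned series of equal length")
  emb <- delay_embed(effect, E, tau)
  times <- as.integer(attr(emb, "times"))
  n <- length(driver)
  tt <- times + tp
  target <- ifelse(tt >= 1 & tt <= n, driver[pmin(pmax(tt, 1L), n)], NA_real_)
  n_rows <- nrow(emb)
  k <- E + 1L
  if (sum(!is.na(target)) < k + 1L) stop("too few rows for E+1 neighbours")

  if (is.null(lib_sizes)) {
    l_min <- k + 1L
    lib_sizes <- unique(round(seq(l_min, n_rows, length.out = 8)))
  }
  lib_sizes <- sort(unique(as.integer(lib_sizes)))
  if (any(lib_sizes < k + 1L)) stop("library sizes must be >= E+2")
  if (any(lib_sizes > n_rows))
    stop(sprintf("library size %d exceeds available embedding rows (%d)",
                 max(lib_sizes), n_rows))

  skill_full <- ccm_skill_once(emb, times, target, seq_len(n_rows), k,
                               exclusion_radius)

  sub <- matrix(NA_real_, nrow = n_samples, ncol = length(lib_sizes),
                dimnames = list(NULL, paste0("L", lib_sizes)))
  runner <- function() {
    for (j in seq_along(lib_sizes)) {
      L <- lib_sizes[j]
      for (s in seq_len(n_samples)) {
        lib <- sample.int(n_rows, L)
        sub[s, j] <<- tryCatch(ccm_skill_once(emb, times, target, lib, k,
                                              exclusion_radius),
                               error = function(e) NA_real_)
      }
    }
  }
  if (is.null(seed)) runner() else with_seed(seed, runner())

  rho_by_lib <- colMeans(sub, na.rm = TRUE)
  structure(list(
    driver = attr(driver, "label") %||% "driver",
    effect = attr(effect, "label") %||% "effect",
    E = E, tau = tau, tp = tp,
    lib_sizes = lib_sizes,
    rho_by_lib = unname(rho_by_lib),
    sub_skills = sub,
    n_samples = n_samples,
    skill = skill_full,
    convergence_delta = unname(rho_by_lib[length(rho_by_lib)] - rho_by_lib[1])
  ), class = "ccm_result")
}

#' Full-library cross-map skill
#'
#' The deterministic cross-map skill for `driver -> effect` using every
#' embedding row as library — the convergent end point of the [cross_map()]
#' curve, without the library-size subsampling. Convenient inside
#' Monte-Carlo loops.
#'
#' @inheritParams cross_map
#' @return Pearson cross-map skill (scalar).
#' @export
cross_map_skill <- function(driver, effect, E, tau = 1, tp = 0,
                            exclusion_radius = 0) {
  driver <- as.numeric(driver); effect <- as.numeric(effect)
  if (length(driver) != length(effect))
    stop("driver and effect must be aligned series of equal length")
  emb <- delay_embed(effect, E, tau)
  times <- as.integer(attr(emb, "times"))
  n <- length(driver)
  tt <- times + tp
  target <- ifelse(tt >= 1 & tt <= n, driver[pmin(pmax(tt, 1L), n)], NA_real_)
  ccm_skill_once(emb, times, target, seq_len(nrow(emb)), E + 1L,
                 exclusion_radius)
}

#' @export
print.ccm_result <- function(x, ...) {
  cat(sprintf("CCM %s -> %s (E = %d, tau = %d, tp = %d)\n",
              x$driver, x$effect, x$E, x$tau, x$tp))
  cat(sprintf("  full-library skill: %.3f\n", x$skill))
  cat(sprintf("  rho(L): %s over L = %s\n",
              paste(sprintf("%.3f", x$rho_by_lib), collapse = ", "),
              paste(x$lib_sizes, collapse = ", ")))
  cat(sprintf("  convergence delta rho(Lmax)-rho(Lmin): %.3f\n",
              x$convergence_delta))
  invisible(x)
}
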