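# Independent brute-force oracles, written directly from the definitions and
# deliberately naive (explicit loops, no shared code with the package
# internals).

# Delay embedding by explicit indexing.
bf_embed <- function(x, E, tau) {
  n <- length(x)
  times <- seq((E - 1) * tau + 1, n)
  m <- matrix(NA_real_, length(times), E)
  for (i in seq_along(times)) {
    for (j in seq_len(E)) m[i, j] <- x[times[i] - (j - 1) * tau]
  }
  list(emb = m, times = times)
}

# Exhaustive exponentially weighted nearest-neighbour prediction.
# lib_rows/pred_rows are 1-based row indices into the embedding.
bf_nn_predict <- function(emb, times, target, lib_rows, pred_rows, k) {
  sapply(pred_rows, function(p) {
    ds <- c()
    rows <- c()
    for (l in lib_rows) {
      if (times[l] == times[p]) next
      if (is.na(target[l])) next
      ds <- c(ds, sqrt(sum((emb[p, ] - emb[l, ])^2)))
      rows <- c(rows, l)
    }
    o <- order(ds, seq_along(ds))[seq_len(k)]
    d <- ds[o]
    y <- target[rows[o]]
    if (d[1] == 0) {
      w <- as.numeric(d == 0)
    } else {
      w <- exp(-d / d[1])
    }
    sum(w * y) / sum(w)
  })
}

# Brute-force simplex leave-one-out predictions for horizon tp.
bf_simplex <- function(x, E, tau = 1, tp = 1) {
  be <- bf_embed(x, E, tau)
  n <- length(x)
  target <- rep(NA_real_, nrow(be$emb))
  ok <- be$times + tp <= n
  target[ok] <- x[be$times[ok] + tp]
  pred_rows <- which(ok)
  preds <- bf_nn_predict(be$emb, be$times, target,
                         lib_rows = seq_len(nrow(be$emb)),
                         pred_rows = pred_rows, k = E + 1)
  list(predictions = preds, observations = target[pred_rows],
       skill = cor(preds, target[pred_rows]))
}

# Brute-force cross-map predictions (driver estimated from the effect's
# embedding) for a given 1-based library row subset.
bf_cross_map <- function(driver, effect, E, tau = 1, tp = 0,
                         lib_rows = NULL) {
  be <- bf_embed(effect, E, tau)
  n <- length(driver)
  tt <- be$times + tp
  target <- rep(NA_real_, nrow(be$emb))
  ok <- tt >= 1 & tt <= n
  target[ok] <- driver[tt[ok]]
  if (is.null(lib_rows)) lib_rows <- seq_len(nrow(be$emb))
  preds <- bf_nn_predict(be$emb, be$times, target,
                         lib_rows = lib_rows,
                         pred_rows = seq_len(nrow(be$emb)), k = E + 1)
  list(predictions = preds, observations = target,
       skill = cor(preds, target, use = "complete.obs"))
}

# Direct tricube-weighted local polynomial regression at a single target
# point: q = max(ceil(span*n), degree+2) nearest observed points by |x - x0|
# (ties at the cutoff included), tricube weights, weighted least squares via
# the normal equations.
bf_local_regression <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- min(max(ceiling(span * n), degree + 2), n)
  d <- abs(x - x0)
  dmax <- sort(d)[q]
  keep <- d <= dmax
  w <- (1 - (d[keep] / dmax)^3)^3
  X <- sapply(0:degree, function(p) (x[keep] - x0)^p)
  WX <- X * w
  beta <- solve(t(WX) %*% X, t(WX) %*% y[keep])
  beta[1]
}

# Synthetic survey fixture shared by prep/pipeline tests.
make_records <- function(n_years = 30, taxa = c("prey", "predA"),
                         region = "A", seed = 42, missing_year_prob = 0.1) {
  com <- simulate_community(n_years = n_years, n_predators = length(taxa) - 1,
                            coupled = 1, seed = seed,
                            taxa = taxa[-1], prey_name = taxa[1])
  community_survey(com, region = region,
                   missing_year_prob = missing_year_prob)
}
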