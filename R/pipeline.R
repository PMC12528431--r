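#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation computed as the Pearson correlation of average ranks
#' (tie-corrected), with a two-sided p-value from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Aligned numeric vectors, `n >= 4`.
#' @return List of class `"correlation_result"`: `rho`, `p_value`, `n`.
#' @examples
#' spearman_test(1:5, c(2, 1, 4, 3, 5))$rho  # 0.8
#' @export
spearman_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be aligned")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin   # smallest attainable: t diverges
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  structure(list(rho = rho, p_value = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (p = %.3g, n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Directed seasonal trophic hypothesis
#'
#' The three directed season pairings tested by the pipeline:
#' \describe{
#'   \item{bottom_up}{spring prey -> spring-summer predator;}
#'   \item{top_down}{spring-summer predator -> fall prey;}
#'   \item{spring_to_fall}{spring prey -> fall prey (same taxon,
#'     within-year carry-over);}
#' }
#' plus `fall_to_spring`, the same-year reversal of `spring_to_fall` used as
#' a falsification check.
#'
#' @param mode One of `"bottom_up"`, `"top_down"`, `"spring_to_fall"`,
#'   `"fall_to_spring"`.
#' @param prey Prey taxon label.
#' @param predator Predator taxon label (required for trophic modes).
#' @return List of class `"hypothesis"` with `driver` and `effect`, each a
#'   `(taxon, season)` pair, and `mode`.
#' @export
directed_hypothesis <- function(mode = c("bottom_up", "top_down",
                                         "spring_to_fall", "fall_to_spring"),
                                prey, predator = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("bottom_up", "top_down") && is.null(predator))
    stop("trophic hypotheses require a predator taxon")
  h <- switch(mode,
    bottom_up = list(driver = list(taxon = prey, season = "spring"),
                     effect = list(taxon = predator, season = "spring_summer")),
    top_down = list(driver = list(taxon = predator, season = "spring_summer"),
                    effect = list(taxon = prey, season = "fall")),
    spring_to_fall = list(driver = list(taxon = prey, season = "spring"),
                          effect = list(taxon = prey, season = "fall")),
    fall_to_spring = list(driver = list(taxon = prey, season = "fall"),
                          effect = list(taxon = prey, season = "spring")))
  structure(c(h, list(mode = mode)), class = "hypothesis")
}

# Align two prepared-but-unnormalized series on shared years, then normalize.
align_series <- function(a, b, min_overlap = 20) {
  shared <- intersect(a$years, b$years)
  if (length(shared) < min_overlap)
    stop(sprintf(
      "insufficient overlap: %d shared years (%s), need >= %d",
      length(shared),
      if (length(shared)) paste(range(shared), collapse = "-") else "none",
      min_overlap))
  va <- a$values[match(shared, a$years)]
  vb <- b$values[match(shared, b$years)]
  z <- function(v) (v - mean(v)) / stats::sd(v)
  list(years = shared, a = z(va), b = z(vb))
}

#' Run one directed correlation + CCM test
#'
#' Builds the driver and effect seasonal series from survey records (season
#' mean of ln(x+1) abundances, LOESS gap fill), aligns them on shared
#' years, normalizes, then: Spearman rank correlation; embedding dimension
#' selected by simplex projection on the effect series; convergent cross
#' mapping of the driver from the effect's embedding; significance against
#' the seasonal-surrogate null.
#'
#' @param records Survey record data frame.
#' @param hypothesis A [directed_hypothesis()].
#' @param region Region label.
#' @param E_range Candidate embedding dimensions (default
#'   `1..min(10, n/3)`).
#' @param tau Embedding lag.
#' @param lib_sizes,n_samples Library grid for [cross_map()].
#' @param n_surrogates,period,surrogate_target,shuffle Surrogate-null
#'   settings, see [ccm_significance()].
#' @param exclusion_radius Temporal exclusion window (in years) for all
#'   neighbour searches, see [ccm_significance()].
#' @param span,degree LOESS fill settings.
#' @param min_overlap Minimum shared years required.
#' @param seed Integer seed.
#' @return List of class `"direction_test"`: `hypothesis`, `region`,
#'   `correlation`, `scan` (simplex E scan), `ccm`, `surrogate`, `years`,
#'   `n_years`, `seed`.
#' @export
run_direction_test <- function(records, hypothesis, region,
                               E_range = NULL, tau = 1,
                               lib_sizes = NULL, n_samples = 100,
                               n_surrogates = 500, period = 12,
                               surrogate_target = "driver",
                               shuffle = "within_phase",
                               exclusion_radius = 2,
                               span = 0.5, degree = 2,
                               min_overlap = 20, seed = 1) {
  stopifnot(inherits(hypothesis, "hypothesis"))
  drv <- prep_series(records, hypothesis$driver$taxon, region,
                     hypothesis$driver$season, span = span, degree = degree,
                     normalize = FALSE)
  eff <- prep_series(records, hypothesis$effect$taxon, region,
                     hypothesis$effect$season, span = span, degree = degree,
                     normalize = FALSE)
  al <- align_series(drv, eff, min_overlap)
  n <- length(al$years)

  corr <- spearman_test(al$a, al$b)
  if (is.null(E_range)) E_range <- seq_len(max(2L, min(10L, floor(n / 3))))
  scan <- select_E(al$b, E_range = E_range, tau = tau, tp = 1,
                   exclusion_radius = exclusion_radius)
  ccm <- cross_map(al$a, al$b, E = scan$E, tau = tau, tp = 0,
                   lib_sizes = lib_sizes, n_samples = n_samples,
                   exclusion_radius = exclusion_radius,
                   seed = derive_seed(seed, "ccm-subsample"))
  surr <- ccm_significance(al$a, al$b, E = scan$E, tau = tau, tp = 0,
                           n_surrogates = n_surrogates, period = period,
                           target = surrogate_target, shuffle = shuffle,
                           exclusion_radius = exclusion_radius,
                           seed = derive_seed(seed, "surrogate"))
  structure(list(hypothesis = hypothesis, region = region,
                 correlation = corr, scan = scan, ccm = ccm,
                 surrogate = surr, years = al$years, n_years = n,
                 seed = seed),
            class = "direction_test")
}

#' @export
print.direction_test <- function(x, ...) {
  h <- x$hypothesis
  cat(sprintf("%s [%s]: %s(%s) -> %s(%s), n = %d years\n",
              h$mode, x$region, h$driver$taxon, h$driver$season,
              h$effect$taxon, h$effect$season, x$n_years))
  cat(sprintf("  Spearman rho = %.3f (p = %.3g); E = %d; CCM skill = %.3f, p = %.4g %s\n",
              x$correlation$rho, x$correlation$p_value, x$scan$E,
              x$surrogate$observed, x$surrogate$p_value,
              x$surrogate$asterisks))
  invisible(x)
}

#' Run the full seasonal trophic-control study
#'
#' For each region: the within-year spring-to-fall carry-over test for the
#' prey (optionally with its same-year reversal as a falsification check);
#' bottom-up and top-down correlation + CCM tests for every predator; and
#' two BRT influence rankings of the predators' spring-summer series, one
#' with the spring prey series as response (bottom-up proxy) and one with
#' the fall prey series (top-down proxy). Failures in individual cells are
#' caught and reported as `NA` rows with the error message, so one ragged
#' series does not abort the study.
#'
#' @param records Survey record data frame.
#' @param regions Character vector of region labels.
#' @param prey Prey taxon.
#' @param predators Character vector of predator taxa (may be empty).
#' @param brt_cfg A [brt_config()].
#' @param reverse_check Also run the fall-to-spring reversal for the prey.
#' @param seed Master seed; every cell derives its own substream, so any
#'   single cell re-run in isolation reproduces the full-run result.
#' @param ... Options forwarded to [run_direction_test()].
#' @return Object of class `"trophic_report"`: `table` (one row per tested
#'   cell: region, predator, direction, rho, p_rho, ccm_skill, ccm_p,
#'   asterisks, E, n_years, note), `influence` (per region and response
#'   season, both BRT influence measures), `pd` (partial dependence curves),
#'   `details` (the underlying `direction_test` and `brt_result` objects).
#' @export
run_full_study <- function(records, regions, prey, predators,
                           brt_cfg = brt_config(), reverse_check = TRUE,
                           seed = 1, ...) {
  rows <- list(); details <- list(); infl <- list(); pd <- list()

  cell_row <- function(region, predator, direction, test, note = "") {
    if (is.null(test)) {
      data.frame(region = region, predator = predator, direction = direction,
                 rho = NA_real_, p_rho = NA_real_, ccm_skill = NA_real_,
                 ccm_p = NA_real_, asterisks = NA_character_,
                 E = NA_integer_, n_years = NA_integer_, note = note,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(region = region, predator = predator, direction = direction,
                 rho = test$correlation$rho, p_rho = test$correlation$p_value,
                 ccm_skill = test$surrogate$observed,
                 ccm_p = test$surrogate$p_value,
                 asterisks = test$surrogate$asterisks,
                 E = test$scan$E, n_years = test$n_years, note = "",
                 stringsAsFactors = FALSE)
    }
  }

  run_cell <- function(region, predator, mode) {
    # cell seeds are keyed by predator and direction only, so a region whose
    # records duplicate another's reproduces its rows exactly
    key <- paste(predator %||% prey, mode, sep = "|")
    store <- paste(region, key, sep = "|")
    hyp <- directed_hypothesis(mode, prey = prey, predator = predator)
    test <- tryCatch(
      run_direction_test(records, hyp, region,
                         seed = derive_seed(seed, key), ...),
      error = function(e) e)
    if (inherits(test, "error")) {
      rows[[store]] <<- cell_row(region, predator %||% prey, mode, NULL,
                                 note = conditionMessage(test))
    } else {
      rows[[store]] <<- cell_row(region, predator %||% prey, mode, test)
      details[[store]] <<- test
    }
  }

  for (rg in regions) {
    run_cell(rg, NULL, "spring_to_fall")
    if (reverse_check) run_cell(rg, NULL, "fall_to_spring")
    for (pd_taxon in predators) {
      run_cell(rg, pd_taxon, "bottom_up")
      run_cell(rg, pd_taxon, "top_down")
    }
    if (length(predators) >= 1) {
      brt_res <- tryCatch(region_brts(records, rg, prey, predators, brt_cfg,
                                      seed = seed, ...),
                          error = function(e) e)
      if (inherits(brt_res, "error")) {
        infl[[rg]] <- data.frame(region = rg, response = NA_character_,
                                 predictor = NA_character_,
                                 selection_freq = NA_real_,
                                 split_improvement = NA_real_,
                                 note = conditionMessage(brt_res),
                                 stringsAsFactors = FALSE)
      } else {
        infl[[rg]] <- brt_res$influence
        pd[[rg]] <- brt_res$pd
        details[[paste0(rg, "|brt")]] <- brt_res$fits
      }
    }
  }

  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 influence = if (length(infl)) do.call(rbind, c(infl, make.row.names = FALSE)) else NULL,
                 pd = pd, details = details,
                 prey = prey, predators = predators, regions = regions,
                 seed = seed),
            class = "trophic_report")
}

# The two per-region BRTs: spring prey response (bottom-up proxy) and fall
# prey response (top-down proxy), predictors = spring-summer predator series.
region_brts <- function(records, region, prey, predators, brt_cfg, seed,
                        span = 0.5, degree = 2, min_overlap = 20, ...) {
  spring <- prep_series(records, prey, region, "spring", span = span,
                        degree = degree, normalize = FALSE)
  fall <- prep_series(records, prey, region, "fall", span = span,
                      degree = degree, normalize = FALSE)
  preds <- lapply(predators, function(tx)
    prep_series(records, tx, region, "spring_summer", span = span,
                degree = degree, normalize = FALSE))
  names(preds) <- predators

  shared <- Reduce(intersect, c(list(spring$years, fall$years),
                                lapply(preds, `[[`, "years")))
  if (length(shared) < min_overlap)
    stop(sprintf("insufficient overlap for BRT in region %s: %d shared years",
                 region, length(shared)))
  z <- function(series) {
    v <- series$values[match(shared, series$years)]
    (v - mean(v)) / stats::sd(v)
  }
  X <- vapply(preds, z, numeric(length(shared)))

  fits <- list(); rows <- list(); pdl <- list()
  for (resp in c("spring", "fall")) {
    y <- z(if (resp == "spring") spring else fall)
    cfg <- brt_cfg
    cfg$seed <- derive_seed(seed, paste(resp, "brt"))
    fit <- fit_brt(y, X, cfg)
    fits[[resp]] <- fit
    rows[[resp]] <- cbind(region = region, response = resp, fit$influence,
                          note = "", stringsAsFactors = FALSE)
    pdl[[resp]] <- lapply(stats::setNames(predators, predators),
                          function(p) partial_dependence(fit, p))
  }
  list(influence = do.call(rbind, c(rows, make.row.names = FALSE)),
       fits = fits, pd = pdl)
}

#' @export
print.trophic_report <- function(x, ...) {
  cat(sprintf("Trophic study report: prey '%s', %d predators, regions: %s\n",
              x$prey, length(x$predators), paste(x$regions, collapse = ", ")))
  tab <- x$table
  tab$rho <- round(tab$rho, 2); tab$ccm_skill <- round(tab$ccm_skill, 2)
  tab$p_rho <- signif(tab$p_rho, 2); tab$ccm_p <- signif(tab$ccm_p, 2)
  print(tab[, setdiff(names(tab), "note")], row.names = FALSE)
  invisible(x)
}

#' Write a trophic study report to disk
#'
#' Serializes the report table (one CSV), the BRT influence table (one CSV)
#' and the CCM library-convergence curves plus surrogate nulls (one JSON).
#'
#' @param report A `"trophic_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "trophic_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "trophic_table.csv"),
                   row.names = FALSE)
  if (!is.null(report$influence))
    utils::write.csv(report$influence, file.path(dir, "brt_influence.csv"),
                     row.names = FALSE)
  curves <- lapply(report$details, function(d) {
    if (!inherits(d, "direction_test")) return(NULL)
    list(region = d$region, mode = d$hypothesis$mode,
         driver = d$hypothesis$driver$taxon,
         effect = d$hypothesis$effect$taxon, E = d$scan$E,
         lib_sizes = d$ccm$lib_sizes, rho_by_lib = d$ccm$rho_by_lib,
         skill = d$ccm$skill, ccm_p = d$surrogate$p_value,
         asterisks = d$surrogate$asterisks,
         null_q95 = unname(stats::quantile(d$surrogate$null, 0.95)))
  })
  curves <- curves[!vapply(curves, is.null, logical(1))]
  jsonlite::write_json(curves, file.path(dir, "ccm_curves.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
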