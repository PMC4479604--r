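#' Correlation screen of configuration parameters against maxOPEN
#'
#' Pearson correlation of each synapse parameter (`glut_density`, `La`,
#' `ampar_density`, `As`, `Ls`, `nAMPA`) with the per-configuration mean
#' and cv of maxOPEN.
#'
#' @param table a `population_table` (>= 3 configurations).
#' @param predictors character vector of predictor columns.
#' @return Matrix (predictors x c("maxOPEN_mean", "maxOPEN_cv")) of Pearson
#'   r; zero-variance predictors give NA with a warning.
#' @export
correlation_screen <- function(table,
                               predictors = c("glut_density", "La",
                                              "ampar_density", "As", "Ls",
                                              "nAMPA")) {
  if (nrow(table) < 3) stop("need at least 3 configurations")
  resp <- c("maxOPEN_mean", "maxOPEN_cv")
  out <- matrix(NA_real_, length(predictors), length(resp),
                dimnames = list(predictors, resp))
  for (p in predictors) {
    x <- table[[p]]
    if (stats::sd(x) == 0) { warning("zero-variance predictor: ", p); next }
    for (r in resp) {
      y <- table[[r]]
      ok <- is.finite(x) & is.finite(y)
      out[p, r] <- stats::cor(x[ok], y[ok])
    }
  }
  out
}

#' Fit a three-coefficient power law f(x) = a x^b + c
#'
#' Nonlinear least squares with the documented deterministic
#' initialization: `c0 = min(y) - eps`, then `(a0, b0)` from the linear
#' regression of `log(y - c0)` on `log(x)`, refined by Levenberg-Marquardt;
#' on failure a small grid of alternative `c0` offsets is retried.
#'
#' @param x positive predictor vector (>= 4 points).
#' @param y response vector.
#' @param predictor,response names stored in the fit.
#' @return A `power_law_fit`: list with `a`, `b`, `c`, `rmse_train`,
#'   `r2_train` (and NA test metrics until [validate_fit()]).
#' @export
fit_power_law <- function(x, y, predictor = "x", response = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 points")
  if (any(x <= 0)) stop("x must be positive")
  if (stats::sd(y) == 0) {           # degenerate constant response
    fit <- list(a = 0, b = 1, c = mean(y))
    return(pl_finish(fit, x, y, predictor, response))
  }
  span <- diff(range(y))
  offsets <- c(1e-3, 0.05, 0.25, 1) * span
  best <- NULL
  for (off in offsets) {
    c0 <- min(y) - off
    ly <- log(y - c0); lx <- log(x)
    ab <- stats::coef(stats::lm(ly ~ lx))
    st <- list(a = exp(ab[[1]]), b = ab[[2]], c = c0)
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ a * x^b + c, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, coef = as.list(stats::coef(f)))
  }
  if (is.null(best))
    stop("power-law fit failed to converge for any initial c0 (tried offsets ",
         paste(signif(offsets, 3), collapse = ", "), ")")
  pl_finish(best$coef, x, y, predictor, response)
}

pl_finish <- function(coefs, x, y, predictor, response) {
  pred <- coefs$a * x^coefs$b + coefs$c
  structure(list(
    a = coefs$a, b = coefs$b, c = coefs$c,
    predictor = predictor, response = response,
    rmse_train = sqrt(mean((y - pred)^2)),
    r2_train = r_squared(y, pred),
    rmse_test = NA_real_, r2_test = NA_real_
  ), class = "power_law_fit")
}

r_squared <- function(y, pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

#' Predict from a power-law fit
#' @param object a `power_law_fit`; `newdata` a numeric vector.
#' @param ... unused.
#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  object$a * newdata^object$b + object$c
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law  %s = %.4g * %s^%.4g %+.4g\n", x$response, x$a,
              x$predictor, x$b, x$c))
  cat(sprintf("  train: RMSE %.4g, R2 %.4g", x$rmse_train, x$r2_train))
  if (is.finite(x$rmse_test))
    cat(sprintf(" | test: RMSE %.4g, R2 %.4g", x$rmse_test, x$r2_test))
  cat("\n")
  invisible(x)
}

#' Evaluate a power-law fit on a held-out population
#'
#' @param fit a `power_law_fit`.
#' @param test_table a `population_table` generated with a disjoint seed
#'   stream (same columns as the training table).
#' @return The fit with `rmse_test` and `r2_test` filled in. Out-of-sample
#'   R2 can be negative when the model fits worse than the mean.
#' @export
validate_fit <- function(fit, test_table) {
  x <- test_table[[fit$predictor]]; y <- test_table[[fit$response]]
  ok <- is.finite(x) & is.finite(y)
  pred <- predict(fit, x[ok])
  fit$rmse_test <- sqrt(mean((y[ok] - pred)^2))
  fit$r2_test <- r_squared(y[ok], pred)
  fit
}

#' Distribution of the pooled run-level maxOPEN
#'
#' @param pooled integer vector of run-level maxOPEN values (or a
#'   `population_table`, whose pooled runs are used).
#' @return A `maxopen_distribution`: integer-binned density, CDF,
#'   linear-interpolation (type 7) quartiles, mode and its frequency.
#' @export
maxopen_distribution <- function(pooled) {
  if (inherits(pooled, "population_table")) pooled <- pooled_runs(pooled)$maxOPEN
  if (!length(pooled)) stop("empty maxOPEN vector")
  counts <- seq(0L, max(pooled))
  dens <- tabulate(pooled + 1L, nbins = max(pooled) + 1L) / length(pooled)
  q <- stats::quantile(pooled, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(
    values = pooled,
    count = counts, density = dens, cdf = cumsum(dens),
    quartiles = c(Q1 = q[1], Q2 = q[2], Q3 = q[3]),
    mode = counts[which.max(dens)], mode_frequency = max(dens)
  ), class = "maxopen_distribution")
}

#' Empirical CDF value of a maxopen distribution at a count
#' @param dist a `maxopen_distribution`; `x` a count.
#' @export
maxopen_cdf <- function(dist, x) mean(dist$values <= x)

#' Per-configuration activation (exceedance) probabilities
#'
#' Probability that a run of each configuration reaches at least
#' `threshold` open receptors, estimated as the empirical exceedance
#' frequency over its runs, plus monotone-binned curves against nAMPA.
#'
#' @param table a `population_table` with pooled runs.
#' @param thresholds named or unnamed numeric vector (e.g. the pooled
#'   quartiles).
#' @param n_bins equal-count nAMPA bins for the curves (default 20).
#' @return List with `per_config` (data.frame: id, nAMPA, As,
#'   ampar_density, then one `P_ge_*` column per threshold) and `binned`
#'   (data.frame: threshold, bin midpoint nAMPA, probability).
#' @export
activation_probability <- function(table, thresholds, n_bins = 20) {
  runs <- pooled_runs(table)
  thr_names <- names(thresholds)
  if (is.null(thr_names)) thr_names <- paste0("T", seq_along(thresholds))
  per <- table[, c("id", "nAMPA", "As", "ampar_density")]
  for (k in seq_along(thresholds)) {
    p <- vapply(per$id, function(i)
      mean(runs$maxOPEN[runs$id == i] >= thresholds[k]), 0)
    per[[paste0("P_ge_", thr_names[k])]] <- p
  }
  ## equal-count bins of nAMPA
  n_bins <- min(n_bins, nrow(per))
  br <- unique(stats::quantile(per$nAMPA, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(per$nAMPA, br, include.lowest = TRUE)
  binned <- do.call(rbind, lapply(seq_along(thresholds), function(k) {
    col <- paste0("P_ge_", thr_names[k])
    data.frame(threshold = thr_names[k],
               nAMPA_mid = tapply(per$nAMPA, bin, mean),
               probability = tapply(per[[col]], bin, mean))
  }))
  list(per_config = per, binned = binned[!is.na(binned$probability), ])
}

#' Spatial map of receptor opening across the PSD
#'
#' Runs a batch with per-receptor open flags recorded at selected times and
#' grids the PSD into square cells, reporting the per-cell fraction of open
#' receptors (open receptors in cell / receptors in cell, averaged over
#' runs). Cells without receptors are NA.
#'
#' @param cfg one-row configuration.
#' @param n_runs number of runs to average.
#' @param times_us numeric vector of recording times (us); by default the
#'   batch's mean-curve peak p is found first and maps are taken at
#'   0.5 p (rising), p (peak), 2 p (post-peak) and 8000 us (late).
#' @param cell_nm cell side length (default 55 nm).
#' @param params,schemes simulation settings.
#' @return A `spatial_opening_map`: list with `cell_nm`, `times_us`,
#'   `maps` (list of n x n matrices of open fractions), `counts`
#'   (receptors per cell), `peak_time_us`.
#' @export
spatial_opening_map <- function(cfg, n_runs = 100, times_us = NULL,
                                cell_nm = 55, params = sim_params(),
                                schemes = default_schemes()) {
  world <- build_world(cfg, params = params, schemes = schemes)
  if (is.null(times_us)) {
    probe <- run_batch(world, max(10L, ceiling(n_runs / 10)))
    pk <- (which.max(probe$mean_curve) - 1L) * params$dt
    times_us <- c(0.5 * pk, pk, 2 * pk, 8000)
  }
  steps <- sort(unique(pmax(1L, pmin(params$n_steps,
                                     as.integer(round(times_us / params$dt))))))
  batch <- run_batch(world, n_runs, record_steps = steps)
  pos <- batch$runs[[1]]$receptor_pos
  n_cells <- max(1L, as.integer(ceiling(cfg$Ls / cell_nm)))
  half <- cfg$Ls / 2
  cx <- pmin(n_cells, 1L + floor((pos[, 1] + half) / cell_nm))
  cy <- pmin(n_cells, 1L + floor((pos[, 2] + half) / cell_nm))
  cell <- (cy - 1L) * n_cells + cx
  counts <- matrix(tabulate(cell, n_cells^2), n_cells, n_cells)
  maps <- lapply(seq_along(steps), function(si) {
    open_sum <- numeric(n_cells^2)
    for (r in batch$runs) {
      flags <- r$snapshots[si, ]
      open_sum <- open_sum + tabulate(cell[flags == 1], n_cells^2)
    }
    frac <- open_sum / (as.numeric(counts) * length(batch$runs))
    frac[counts == 0] <- NA
    matrix(frac, n_cells, n_cells)
  })
  structure(list(cell_nm = cell_nm, times_us = steps * params$dt,
                 maps = maps, counts = counts,
                 grid = n_cells,
                 peak_time_us = (which.max(batch$mean_curve) - 1L) * params$dt),
            class = "spatial_opening_map")
}
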