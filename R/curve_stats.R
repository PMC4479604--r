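#' Summarize one open-receptor time series
#'
#' @param series integer vector of open-receptor counts, one entry per time
#'   step (entry 1 is t = 0).
#' @param dt time step in us.
#' @return List with `maxOPEN` (peak count), `peak_time` (us, time of the
#'   first attainment of the maximum) and `auc` (`dt * sum(series)`,
#'   receptor-us).
#' @examples
#' summarize_run(c(0, 3, 7, 5, 2), dt = 1)  # maxOPEN 7, peak_time 2, auc 17
#' @export
summarize_run <- function(series, dt) {
  if (!length(series)) stop("empty series")
  m <- max(series)
  list(maxOPEN = m,
       peak_time = if (m == 0) 0 else dt * (which.max(series) - 1L),
       auc = dt * sum(as.numeric(series)))
}

#' Per-configuration replicate statistics
#'
#' Reduces the runs of one configuration to the mean, sample standard
#' deviation (n - 1 denominator) and coefficient of variation (sd/mean) of
#' maxOPEN and peak time, plus the mean area under the curve.
#'
#' @param batch a `run_batch`, or a data.frame with columns `maxOPEN`,
#'   `peak_time`, `auc`.
#' @return One-row data.frame (`config_summary`): `maxOPEN_mean/sd/cv`,
#'   `peaktime_mean/sd/cv`, `auc_mean`, `N_R`. A cv with zero mean is NA.
#' @export
summarize_config <- function(batch) {
  s <- if (inherits(batch, "run_batch")) batch$summary else batch
  cv <- function(x) {
    mu <- mean(x)
    if (mu == 0) return(NA_real_)
    stats::sd(x) / mu
  }
  n <- nrow(s)
  out <- data.frame(
    maxOPEN_mean = mean(s$maxOPEN),
    maxOPEN_sd = if (n >= 2) stats::sd(s$maxOPEN) else NA_real_,
    maxOPEN_cv = if (n >= 2) cv(s$maxOPEN) else NA_real_,
    peaktime_mean = mean(s$peak_time),
    peaktime_sd = if (n >= 2) stats::sd(s$peak_time) else NA_real_,
    peaktime_cv = if (n >= 2) cv(s$peak_time) else NA_real_,
    auc_mean = mean(s$auc),
    N_R = n)
  if (inherits(batch, "run_batch")) {
    out <- cbind(data.frame(id = batch$cfg$id %||% NA), out)
  }
  out
}

#' Simulate a population and build the pooled summary table
#'
#' Runs `n_runs` simulations for every configuration of `pop` and joins the
#' per-configuration summaries with the configuration parameters; the
#' interchange table for the analysis layer.
#'
#' @param pop a `synapse_population`.
#' @param n_runs runs per configuration.
#' @param params a `sim_params`.
#' @param schemes kinetic schemes (see [default_schemes()]).
#' @param progress print one line per configuration.
#' @return A `population_table`: data.frame with one row per configuration
#'   (config parameters + summaries) and attribute `pooled`, a data.frame
#'   of all run-level results (`id`, `nAMPA`, `maxOPEN`, `peak_time`,
#'   `auc`).
#' @export
simulate_population <- function(pop, n_runs, params = sim_params(),
                                schemes = default_schemes(), progress = FALSE) {
  rows <- list(); pooled <- list()
  for (i in seq_len(nrow(pop))) {
    cfg <- pop[i, ]
    world <- build_world(cfg, params = params, schemes = schemes)
    batch <- run_batch(world, n_runs)
    rows[[i]] <- cbind(as.data.frame(cfg), summarize_config(batch)[-1])
    pooled[[i]] <- cbind(data.frame(id = cfg$id, nAMPA = cfg$nAMPA),
                         batch$summary[c("run", "maxOPEN", "peak_time", "auc")])
    if (progress)
      message(sprintf("config %d/%d (Ls %.0f nm, nAMPA %d): maxOPEN mean %.1f",
                      i, nrow(pop), cfg$Ls, cfg$nAMPA,
                      rows[[i]]$maxOPEN_mean))
  }
  tab <- do.call(rbind, rows)
  attr(tab, "pooled") <- do.call(rbind, pooled)
  class(tab) <- c("population_table", "data.frame")
  tab
}

#' Run-level results pooled across configurations
#' @param table a `population_table`.
#' @return The pooled run-level data.frame stored by [simulate_population()].
#' @export
pooled_runs <- function(table) {
  p <- attr(table, "pooled")
  if (is.null(p)) stop("table carries no pooled run-level results")
  p
}

#' Write / read a population table (tidy CSV pair)
#' @param table a `population_table`.
#' @param dir output directory.
#' @param name file stem.
#' @return Invisibly the config-level CSV path.
#' @export
write_population_table <- function(table, dir, name = "results") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_csv <- file.path(dir, paste0(name, "_configs.csv"))
  utils::write.csv(as.data.frame(table), cfg_csv, row.names = FALSE)
  utils::write.csv(pooled_runs(table),
                   file.path(dir, paste0(name, "_runs.csv")), row.names = FALSE)
  invisible(cfg_csv)
}

#' @rdname write_population_table
#' @export
read_population_table <- function(dir, name = "results") {
  tab <- utils::read.csv(file.path(dir, paste0(name, "_configs.csv")))
  attr(tab, "pooled") <- utils::read.csv(file.path(dir, paste0(name, "_runs.csv")))
  class(tab) <- c("population_table", "data.frame")
  tab
}
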