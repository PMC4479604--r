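#' Headline population statistics of a simulated synapse population
#'
#' Samples `n_configs` synapse configurations, runs `n_runs` stochastic
#' simulations of each, and reduces the batch to the headline statistics of
#' the population study: structural correlations (nAMPA and area under the
#' curve vs maxOPEN, transporter-density null correlation) and the pooled
#' maxOPEN / peak-time distribution summaries. Everything is recomputed
#' from scratch; nothing is cached or tabulated.
#'
#' @param seed root seed for the population draw and all run streams.
#' @param n_configs number of synapse configurations.
#' @param n_runs runs per configuration.
#' @param params a [sim_params()].
#' @param progress print one line per configuration.
#' @return List with `r_nampa_maxopen`, `r_auc_maxopen`, `r_glut_maxopen`,
#'   `pooled_mean`, `peaktime_mean` (us), `pooled_median`, `pct_le_100`,
#'   and the underlying `table` (a `population_table`).
#' @export
headline_statistics <- function(seed = 1L, n_configs = 30L, n_runs = 50L,
                                params = sim_params(), progress = FALSE) {
  pop <- sample_configs(n_configs, seed = seed)
  tab <- suppressWarnings(
    simulate_population(pop, n_runs, params = params, progress = progress))
  runs <- pooled_runs(tab)
  list(
    r_nampa_maxopen = stats::cor(tab$nAMPA, tab$maxOPEN_mean),
    r_auc_maxopen = stats::cor(runs$auc, runs$maxOPEN),
    r_glut_maxopen = stats::cor(tab$glut_density, tab$maxOPEN_mean),
    pooled_mean = mean(runs$maxOPEN),
    peaktime_mean = mean(runs$peak_time),
    pooled_median = unname(stats::quantile(runs$maxOPEN, 0.5, type = 7)),
    pct_le_100 = 100 * mean(runs$maxOPEN <= 100),
    table = tab
  )
}
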