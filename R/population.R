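#' Derive the PSD side-length distribution from the Feret's diameter distribution
#'
#' The size of reconstructed cortical synaptic junctions is well described by a
#' log-normal distribution of Feret's diameter \eqn{D_F}. The PSD is modelled
#' as a square of side \eqn{L_s = \sqrt{SAS} = k \times D_F}, so on the log
#' scale the location parameter simply shifts by \eqn{\ln k} while the scale
#' parameter is unchanged.
#'
#' @param mu_DF log-scale mean of \eqn{D_F} (ln nm).
#' @param sigma_DF log-scale standard deviation of \eqn{D_F}.
#' @param k dimensionless SAS-to-\eqn{D_F} proportionality constant
#'   (0.624 for layer III rat somatosensory cortex).
#' @param range_Ls numeric length-2, admissible range of \eqn{L_s} in nm;
#'   sampling truncates to this interval.
#' @return An object of class `size_distribution` with fields `mu_DF`,
#'   `sigma_DF`, `k`, `mu_Ls`, `sigma_Ls`, `range_Ls`.
#' @examples
#' d <- derive_ls_lognormal(5.828, 0.446, 0.624)
#' d$mu_Ls       # 5.356
#' exp(d$mu_Ls)  # median Ls ~ 212 nm
#' @export
derive_ls_lognormal <- function(mu_DF, sigma_DF, k, range_Ls = c(60, 825)) {
  if (!is.numeric(sigma_DF) || sigma_DF <= 0)
    stop("sigma_DF must be positive")
  if (!is.numeric(k) || k <= 0 || k > 1)
    stop("k must lie in (0, 1]")
  if (length(range_Ls) != 2L || range_Ls[1] <= 0 || range_Ls[2] <= range_Ls[1])
    stop("range_Ls must be an increasing positive pair")
  structure(list(
    mu_DF = mu_DF, sigma_DF = sigma_DF, k = k,
    mu_Ls = mu_DF + log(k), sigma_Ls = sigma_DF,
    range_Ls = as.numeric(range_Ls)
  ), class = "size_distribution")
}

#' Default cortical synapse size distribution
#'
#' Log-normal Feret's diameter with mu = 5.828, sigma = 0.446 (layer III rat
#' somatosensory cortex, 1695 reconstructed junctions), k = 0.624, giving
#' Ls ~ logN(5.356, 0.446) on 60--825 nm.
#' @return A `size_distribution`.
#' @export
cortical_ls_distribution <- function() {
  derive_ls_lognormal(5.828, 0.446, 0.624, range_Ls = c(60, 825))
}

#' Default parameter ranges for synapse configuration sampling
#'
#' @return A list with elements `la_factor` (multiple of Ls for the total
#'   apposition side length), `ampar_density` (receptors/um^2) and
#'   `glut_density` (transporters/um^2), each a length-2 numeric range.
#' @export
default_ranges <- function() {
  list(la_factor = c(1, 2),
       ampar_density = c(500, 3000),
       glut_density = c(7000, 12000))
}

#' Number of AMPA receptors on a PSD
#'
#' `nAMPA = round([AMPAr] x As x 1e-6)` with `As = Ls^2` (nm^2) and the
#' density in receptors/um^2. Rounding is half-away-from-zero and the result
#' is floored at 1 receptor.
#'
#' @param ampar_density receptor density in receptors/um^2 (positive).
#' @param Ls PSD side length in nm (positive).
#' @return Integer receptor count (>= 1).
#' @examples
#' compute_nampa(2000, 450)  # 405
#' @export
compute_nampa <- function(ampar_density, Ls) {
  if (any(!is.finite(ampar_density)) || any(ampar_density <= 0))
    stop("ampar_density must be positive")
  if (any(!is.finite(Ls)) || any(Ls <= 0))
    stop("Ls must be positive")
  n <- floor(ampar_density * Ls^2 * 1e-6 + 0.5)
  as.integer(pmax(1, n))
}

## counter-based per-config seed: keeps every configuration reproducible in
## isolation; kept below 2^31 so it stores as an R integer
derive_config_seed <- function(root_seed, index) {
  mix_seed(as.numeric(root_seed), as.numeric(index), 0)
}

#' Sample a population of synapse configurations
#'
#' Draws `n` synapse configurations with the statistical structure of the
#' measured cortical population: `Ls` log-normal (truncated to
#' `dist$range_Ls` by rejection), `La = Ls x U(la_factor)`, and receptor and
#' transporter densities from independent uniforms.
#'
#' @param n number of configurations (>= 1).
#' @param dist a `size_distribution`, e.g. [cortical_ls_distribution()].
#' @param ranges list as returned by [default_ranges()].
#' @param seed integer seed; the draw is fully deterministic given `seed`.
#' @param truncate logical; truncate `Ls` to `dist$range_Ls` (default TRUE).
#' @param temperature simulation temperature in deg C, stored per config.
#' @return A `data.frame` of class `synapse_population` with one row per
#'   configuration: `id`, `Ls`, `La`, `ampar_density`, `glut_density`,
#'   `As`, `nAMPA`, `seed`, `T` (temperature, deg C), and attributes
#'   `dist`, `ranges`, `root_seed`.
#' @export
sample_configs <- function(n, dist = cortical_ls_distribution(),
                           ranges = default_ranges(), seed = 1L,
                           truncate = TRUE, temperature = 35) {
  if (!inherits(dist, "size_distribution")) stop("dist must be a size_distribution")
  if (n < 1) stop("n must be >= 1")
  lo <- dist$range_Ls[1]; hi <- dist$range_Ls[2]
  if (truncate) {
    p_in <- stats::plnorm(hi, dist$mu_Ls, dist$sigma_Ls) -
      stats::plnorm(lo, dist$mu_Ls, dist$sigma_Ls)
    if (p_in <= 0) stop("empty truncation interval for Ls")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  ls <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {  # rejection sampling of the truncated log-normal
    draw <- stats::rlnorm(length(need), dist$mu_Ls, dist$sigma_Ls)
    ok <- if (truncate) draw >= lo & draw <= hi else rep(TRUE, length(draw))
    ls[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  la <- ls * stats::runif(n, ranges$la_factor[1], ranges$la_factor[2])
  ar <- stats::runif(n, ranges$ampar_density[1], ranges$ampar_density[2])
  gt <- stats::runif(n, ranges$glut_density[1], ranges$glut_density[2])
  cfg <- data.frame(
    id = seq_len(n),
    Ls = ls, La = la,
    ampar_density = ar, glut_density = gt,
    As = ls^2,
    nAMPA = compute_nampa(ar, ls),
    seed = vapply(seq_len(n), function(i) derive_config_seed(seed, i), 0),
    T = temperature
  )
  attr(cfg, "dist") <- dist
  attr(cfg, "ranges") <- ranges
  attr(cfg, "root_seed") <- as.integer(seed)
  class(cfg) <- c("synapse_population", "data.frame")
  cfg
}

#' Write a sampled population to CSV plus a JSON manifest
#'
#' @param pop a `synapse_population`.
#' @param dir output directory (created if absent).
#' @param name file stem (default "population").
#' @return Invisibly, the CSV path.
#' @export
write_population <- function(pop, dir, name = "population") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(pop), csv, row.names = FALSE)
  dist <- attr(pop, "dist")
  manifest <- list(
    n = nrow(pop),
    root_seed = attr(pop, "root_seed"),
    distribution = dist[c("mu_DF", "sigma_DF", "k", "mu_Ls", "sigma_Ls", "range_Ls")],
    ranges = attr(pop, "ranges"),
    package_version = as.character(utils::packageVersion("cleftsim"))
  )
  jsonlite::write_json(manifest, file.path(dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}

#' Read a population CSV written by [write_population()]
#' @param csv path to the CSV.
#' @return A `synapse_population` data.frame.
#' @export
read_population <- function(csv) {
  pop <- utils::read.csv(csv)
  class(pop) <- c("synapse_population", "data.frame")
  pop
}
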