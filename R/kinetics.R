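#' Q10 temperature adjustment of a rate constant
#'
#' @param k_ref rate constant at the reference temperature.
#' @param T_ref reference temperature (deg C).
#' @param T target temperature (deg C).
#' @param Q10 fold-change per 10 deg C (positive).
#' @return `k_ref * Q10^((T - T_ref)/10)`.
#' @examples
#' q10_adjust(100, 25, 35, 2.5)  # 250
#' @export
q10_adjust <- function(k_ref, T_ref, T, Q10 = 2.5) {
  if (any(Q10 <= 0)) stop("Q10 must be positive")
  k_ref * Q10^((T - T_ref) / 10)
}

#' Per-step transition probability of a first-order process
#'
#' Discretization of first-order kinetics at time step `dt`:
#' `1 - exp(-k dt)`.
#'
#' @param k rate constant (1/s), `k >= 0`.
#' @param dt time step (s), `dt > 0`.
#' @return Probability in \[0, 1\].
#' @export
step_probability <- function(k, dt) {
  if (any(k < 0)) stop("k must be >= 0")
  if (any(dt <= 0)) stop("dt must be > 0")
  -expm1(-k * dt)
}

#' Load a kinetic scheme from a YAML file
#'
#' A scheme file declares `name`, `citation`, `T_ref` (deg C), `Q10`,
#' `states` (ordered labels), `initial`, optionally `open` (the single
#' conducting state), and `transitions`: a list of maps with `from`, `to`,
#' `rate`, `order` (1 = unimolecular, 1/s; 2 = bimolecular, 1/(M s)), and
#' optionally `releases_ligand` / `removes_ligand` for unimolecular
#' transitions that return glutamate to the extracellular space or
#' translocate it out of it. Bimolecular transitions always consume one
#' glutamate.
#'
#' Validation checks unit declarations, non-negative rates, at most one
#' open state, and that the bound-ligand count per state is consistent
#' along every path from the initial state.
#'
#' @param path YAML file path.
#' @return A `kinetic_scheme` object.
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  req <- c("name", "states", "initial", "transitions", "T_ref", "Q10")
  miss <- setdiff(req, names(y))
  if (length(miss)) stop("scheme file missing fields: ", paste(miss, collapse = ", "))
  states <- as.character(y$states)
  if (anyDuplicated(states)) stop("duplicate state labels")
  tr <- do.call(rbind, lapply(y$transitions, function(t) {
    if (is.null(t$from) || is.null(t$to) || is.null(t$rate) || is.null(t$order))
      stop("each transition needs from/to/rate/order")
    data.frame(from = t$from, to = t$to, rate = as.numeric(t$rate),
               order = as.integer(t$order),
               releases_ligand = isTRUE(t$releases_ligand),
               removes_ligand = isTRUE(t$removes_ligand))
  }))
  if (!all(tr$from %in% states) || !all(tr$to %in% states))
    stop("transition endpoints must be declared states")
  if (any(tr$rate < 0)) stop("rates must be >= 0")
  if (!all(tr$order %in% c(1L, 2L))) stop("order must be 1 or 2")
  if (any(tr$order == 2L & (tr$releases_ligand | tr$removes_ligand)))
    stop("bimolecular transitions bind ligand; they cannot release or remove it")
  scheme <- structure(list(
    name = y$name, citation = y$citation %||% "",
    states = states,
    initial = match(y$initial, states),
    open = if (is.null(y$open)) NA_integer_ else match(y$open, states),
    transitions = tr,
    T_ref = as.numeric(y$T_ref), Q10 = as.numeric(y$Q10),
    notes = y$notes %||% ""
  ), class = "kinetic_scheme")
  if (is.na(scheme$initial)) stop("initial state not in state list")
  if (!is.null(y$open) && is.na(scheme$open)) stop("open state not in state list")
  scheme$ligand_count <- scheme_ligand_counts(scheme)
  scheme
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## per-state bound-ligand count from the transition ligand deltas; errors on
## any inconsistent cycle
scheme_ligand_counts <- function(scheme) {
  ns <- length(scheme$states)
  tr <- scheme$transitions
  delta <- ifelse(tr$order == 2L, 1L, ifelse(tr$releases_ligand | tr$removes_ligand, -1L, 0L))
  lig <- rep(NA_integer_, ns)
  lig[scheme$initial] <- 0L
  queue <- scheme$initial
  fi <- match(tr$from, scheme$states); ti <- match(tr$to, scheme$states)
  while (length(queue)) {
    s <- queue[1]; queue <- queue[-1]
    for (j in which(fi == s)) {
      v <- lig[s] + delta[j]
      if (is.na(lig[ti[j]])) { lig[ti[j]] <- v; queue <- c(queue, ti[j]) }
      else if (lig[ti[j]] != v) stop("inconsistent ligand bookkeeping in scheme '",
                                     scheme$name, "' at transition ",
                                     tr$from[j], " -> ", tr$to[j])
    }
    for (j in which(ti == s)) {  # traverse edges backwards too
      v <- lig[s] - delta[j]
      if (is.na(lig[fi[j]])) { lig[fi[j]] <- v; queue <- c(queue, fi[j]) }
      else if (lig[fi[j]] != v) stop("inconsistent ligand bookkeeping in scheme '",
                                     scheme$name, "' at transition ",
                                     tr$from[j], " -> ", tr$to[j])
    }
  }
  if (anyNA(lig)) stop("scheme has states unreachable from the initial state")
  if (any(lig < 0)) stop("negative bound-ligand count implied by scheme")
  lig
}

#' Temperature-correct all rate constants of a scheme
#'
#' @param scheme a `kinetic_scheme`.
#' @param T simulation temperature (deg C).
#' @return The scheme with all rates multiplied by
#'   `Q10^((T - T_ref)/10)` and `T_ref` set to `T`.
#' @export
scheme_at_temperature <- function(scheme, T) {
  f <- scheme$Q10^((T - scheme$T_ref) / 10)
  scheme$transitions$rate <- scheme$transitions$rate * f
  scheme$T_ref <- T
  scheme
}

#' Path to a kinetic scheme shipped with the package
#' @param name `"ampa"` or `"glut"`.
#' @return File path.
#' @export
scheme_file <- function(name = c("ampa", "glut")) {
  name <- match.arg(name)
  system.file("extdata", "schemes", paste0(name, ".yaml"),
              package = "cleftsim", mustWork = TRUE)
}

## unimolecular generator pieces used by advance_states and the engine tables
uni_table <- function(scheme, glu_conc = 0) {
  tr <- scheme$transitions
  rate <- tr$rate
  rate[tr$order == 2L] <- rate[tr$order == 2L] * glu_conc  # pseudo-first-order
  keep <- tr$order == 1L | glu_conc > 0
  data.frame(from = match(tr$from, scheme$states)[keep],
             to = match(tr$to, scheme$states)[keep],
             rate = rate[keep],
             releases = tr$releases_ligand[keep] & tr$order[keep] == 1L,
             removes = tr$removes_ligand[keep] & tr$order[keep] == 1L)
}

#' Advance an ensemble of molecules through one or more time steps
#'
#' Reference (vectorized R) implementation of the competing-risks update
#' used by the particle engine: per time step each molecule makes at most
#' one transition; with total outgoing rate `k_tot` the no-transition
#' probability is `exp(-k_tot dt)` and transition `i` has probability
#' `(k_i / k_tot) (1 - exp(-k_tot dt))`. Bimolecular transitions are
#' treated as pseudo-first-order at a clamped glutamate concentration
#' `glu_conc` (collision-mediated binding in the full simulator is owned by
#' the particle engine, not this function).
#'
#' @param states integer vector of current state indices (1-based).
#' @param scheme a `kinetic_scheme` (rates already at the target
#'   temperature; see [scheme_at_temperature()]).
#' @param dt time step in seconds.
#' @param n_steps number of steps to advance.
#' @param glu_conc clamped glutamate concentration (M) applied to
#'   bimolecular transitions.
#' @param trace if TRUE, also return the per-step occupancy matrix
#'   (`n_steps + 1` rows x states columns).
#' @return List with `states` (final indices), `released` and `removed`
#'   ligand event counts, and optionally `occupancy`.
#' @export
advance_states <- function(states, scheme, dt, n_steps = 1L, glu_conc = 0,
                           trace = FALSE) {
  ut <- uni_table(scheme, glu_conc)
  ns <- length(scheme$states)
  ## per-state: total rate, outgoing transition list
  ktot <- vapply(seq_len(ns), function(s) sum(ut$rate[ut$from == s]), 0)
  p_move <- -expm1(-ktot * dt)
  occ <- if (trace) matrix(0L, n_steps + 1L, ns) else NULL
  if (trace) occ[1L, ] <- tabulate(states, ns)
  released <- 0L; removed <- 0L
  for (step in seq_len(n_steps)) {
    u <- stats::runif(length(states))
    moving <- which(u < p_move[states])
    if (length(moving)) {
      from0 <- states[moving]     # freeze origins: at most one jump per step
      for (s in unique(from0)) {
        idx <- moving[from0 == s]
        rows <- which(ut$from == s)
        pick <- rows[sample.int(length(rows), length(idx), replace = TRUE,
                                prob = ut$rate[rows])]
        released <- released + sum(ut$releases[pick])
        removed <- removed + sum(ut$removes[pick])
        states[idx] <- ut$to[pick]
      }
    }
    if (trace) occ[step + 1L, ] <- tabulate(states, ns)
  }
  out <- list(states = states, released = released, removed = removed)
  if (trace) out$occupancy <- occ
  out
}

#' Exact state marginals of a scheme at clamped glutamate
#'
#' Solves the master equation of the continuous-time Markov chain with
#' bimolecular transitions at a fixed glutamate concentration, by matrix
#' exponentiation. Used as an independent check of the stochastic update.
#'
#' @inheritParams advance_states
#' @param times numeric vector of times (s).
#' @param p0 initial distribution (defaults to all mass in the initial state).
#' @return Matrix `length(times)` x states of occupancy probabilities.
#' @export
scheme_marginals <- function(scheme, times, glu_conc = 0, p0 = NULL) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("scheme_marginals needs the Matrix package")
  ut <- uni_table(scheme, glu_conc)
  ns <- length(scheme$states)
  Q <- matrix(0, ns, ns)
  for (j in seq_len(nrow(ut))) Q[ut$from[j], ut$to[j]] <- Q[ut$from[j], ut$to[j]] + ut$rate[j]
  diag(Q) <- diag(Q) - rowSums(Q)
  if (is.null(p0)) { p0 <- numeric(ns); p0[scheme$initial] <- 1 }
  t(vapply(times, function(t)
    as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))),
    numeric(ns)))
}
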