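AVOGADRO <- 6.02214076e23
## 1 / (M) in nm^3 per molecule: 1 litre / N_A expressed in nm^3
M_INV_NM3 <- 1e24 / AVOGADRO

#' Simulation parameters
#'
#' @param D_g glutamate diffusion coefficient (um^2/ms), default 0.33.
#' @param dt time step (us), default 1.
#' @param T_total total simulated time (ms), default 10.
#' @param N_g glutamate molecules per vesicle, default 3000.
#' @param temperature simulation temperature (deg C), default 35.
#' @param bounce_limit maximum reflections resolved within one step.
#' @return A `sim_params` list; `n_steps = T_total * 1000 / dt`.
#' @export
sim_params <- function(D_g = 0.33, dt = 1, T_total = 10, N_g = 3000,
                       temperature = 35, bounce_limit = 64) {
  if (D_g < 0 || dt <= 0 || T_total <= 0 || N_g < 1) stop("invalid sim_params")
  structure(list(D_g = D_g, dt = dt, T_total = T_total, N_g = as.integer(N_g),
                 temperature = temperature, bounce_limit = as.integer(bounce_limit),
                 n_steps = as.integer(round(T_total * 1000 / dt))),
            class = "sim_params")
}

#' Per-axis standard deviation of one Brownian step
#'
#' @param D diffusion coefficient in um^2/ms.
#' @param dt time step in us.
#' @return `sqrt(2 D dt)` in nm (D converted to nm^2/us).
#' @examples
#' displacement_sigma(0.33, 1)  # 25.69 nm
#' @export
displacement_sigma <- function(D, dt) {
  if (any(D < 0) || any(dt <= 0)) stop("need D >= 0, dt > 0")
  sqrt(2 * (D * 1000) * dt)
}

#' MCell-style per-crossing binding probability
#'
#' For a surface molecule owning a capture tile of area `1/density`, the
#' probability applied to each Brownian-trajectory crossing so that the
#' simulated association flux matches the mass-action rate constant `kon`:
#' `p = kon' * sqrt(pi dt / D) / A_tile` with `kon'` the per-molecule
#' rate in nm^3/us.
#'
#' @param kon bimolecular rate constant, 1/(M s) (> 0, already at the
#'   simulation temperature).
#' @param D ligand diffusion coefficient, um^2/ms.
#' @param dt time step, us.
#' @param tile_density surface density of molecules, 1/um^2 (tile area is
#'   its reciprocal).
#' @return Per-crossing probability; errors if it exceeds 1 (use a smaller
#'   `dt`).
#' @export
calibrate_binding_probability <- function(kon, D, dt, tile_density) {
  if (any(kon < 0)) stop("kon must be >= 0")
  a_tile <- 1 / (tile_density * 1e-6)          # nm^2
  p <- binding_prob_tile(kon, D, dt, a_tile)
  if (any(p > 1))
    stop("binding probability exceeds 1 at dt = ", dt,
         " us; use a smaller time step")
  p
}

binding_prob_tile <- function(kon, D, dt, a_tile) {
  kon_nm <- kon * M_INV_NM3 * 1e-6             # nm^3/us per molecule
  d_nm <- D * 1000                             # nm^2/us
  ## one-way crossing flux through a tile per step is c * sigma / sqrt(2*pi)
  ## * a_tile; equating p * flux to the mass-action rate kon * c gives the
  ## per-crossing probability below (surfaces here are walls, reachable
  ## from one side only, so there is no both-sides factor of 2)
  kon_nm * sqrt(pi * dt / d_nm) / a_tile
}

## ---- engine input construction ----

## grid a rectangle so each tile is at most the packing area 1/density;
## place n molecules on distinct tiles, jittered within the tile
grid_rect <- function(rect, n_mol, inward, mol0, params, eps = 1e-3) {
  len_u <- rect$u1 - rect$u0; len_v <- rect$v1 - rect$v0
  if (n_mol > 0) {
    target <- sqrt(rect$area / n_mol)
    nu <- max(1L, as.integer(ceiling(len_u / target)))
    nv <- max(1L, as.integer(ceiling(len_v / target)))
    while (nu * nv < n_mol) { if (len_u / nu >= len_v / nv) nu <- nu + 1L else nv <- nv + 1L }
  } else { nu <- 1L; nv <- 1L }
  du <- len_u / nu; dv <- len_v / nv
  tile_mol <- rep(-1L, nu * nv)
  pos <- NULL
  if (n_mol > 0) {
    tiles <- sample.int(nu * nv, n_mol) - 1L
    tile_mol[tiles + 1L] <- mol0 + seq_len(n_mol) - 1L
    iu <- tiles %% nu; iv <- tiles %/% nu
    u <- rect$u0 + (iu + stats::runif(n_mol)) * du
    v <- rect$v0 + (iv + stats::runif(n_mol)) * dv
    pos <- matrix(0, n_mol, 3)
    ax <- plane_axes(rect$axis)
    pos[, ax[1] + 1L] <- u
    pos[, ax[2] + 1L] <- v
    pos[, rect$axis + 1L] <- rect$pos + eps * inward
  }
  list(rect = list(axis = rect$axis, pos = rect$pos, u0 = rect$u0, v0 = rect$v0,
                   du = du, dv = dv, nu = nu, nv = nv,
                   tile_mol = tile_mol,
                   p_scale = sqrt(pi * params$dt / (params$D_g * 1000)) / (du * dv),
                   inward = inward),
       pos = pos)
}

## ECS-side normal sign for each transporter rectangle of glut_rects(), in
## the same order the rects are generated
rect_inward <- function(geom, rect) {
  if (rect$axis == 2L) {
    ## z-planes: ECS side by comparison with known planes
    if (abs(rect$pos - (-geom$Hc)) < 1e-9) return(1)       # post apposed / PSD
    if (abs(rect$pos - 0) < 1e-9) return(-1)               # pre apposed
    if (abs(rect$pos - geom$peri[6]) < 1e-9) return(-1)    # peri top
    return(1)                                              # peri bottom
  }
  half_a <- geom$La / 2
  if (abs(abs(rect$pos) - half_a) < 1e-9) return(ifelse(rect$pos > 0, 1, -1))   # element walls
  ifelse(rect$pos > 0, -1, 1)                                                   # peri walls
}

scheme_engine_tables <- function(scheme, temperature) {
  sc <- scheme_at_temperature(scheme, temperature)
  tr <- sc$transitions
  uni <- tr[tr$order == 1L, ]
  bi <- tr[tr$order == 2L, ]
  list(
    n_states = length(sc$states),
    initial = sc$initial - 1L,
    open = if (is.na(sc$open)) -1L else sc$open - 1L,
    lig = as.integer(sc$ligand_count),
    uni_from = match(uni$from, sc$states) - 1L,
    uni_to = match(uni$to, sc$states) - 1L,
    uni_rate = uni$rate * 1e-6,                      # 1/s -> 1/us
    uni_releases = as.integer(uni$releases_ligand),
    uni_removes = as.integer(uni$removes_ligand),
    bind_from = match(bi$from, sc$states) - 1L,
    bind_to = match(bi$to, sc$states) - 1L,
    bind_kon = bi$rate * M_INV_NM3 * 1e-6            # 1/(M s) -> nm^3/us
  )
}

#' Assemble the engine world for one synapse configuration
#'
#' Builds the tiled receptor and transporter populations on the tagged
#' surfaces of the geometry. Tile layout (which tiles are occupied and the
#' jittered molecule positions) is deterministic given `cfg$seed`.
#'
#' @param cfg one-row `synapse_population` slice (or equivalent list).
#' @param geom a `synapse_geometry` (default built from `cfg`).
#' @param schemes list with elements `ampa` and `glut` (`kinetic_scheme`s);
#'   defaults to the shipped files.
#' @param params a `sim_params`.
#' @param glut_placement passed to [glut_rects()].
#' @param nampa_override test hook; forces the receptor count (e.g. 0).
#' @return A `synapse_world` list used by [run_synapse()].
#' @export
build_world <- function(cfg, geom = build_geometry(cfg),
                        schemes = default_schemes(), params = sim_params(),
                        glut_placement = c("apposed", "element_walls", "peri"),
                        nampa_override = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(cfg$seed %% 2147483647))

  n_ampa <- if (is.null(nampa_override)) compute_nampa(cfg$ampar_density, cfg$Ls)
            else as.integer(nampa_override)
  ## AMPA population on the PSD
  pr <- psd_rect(geom)
  nx <- max(1L, as.integer(ceiling(sqrt(n_ampa))))
  g_ampa <- grid_rect_fixed(pr, n_ampa, nx, nx, inward = 1, mol0 = 0L, params = params)
  ampa_tab <- scheme_engine_tables(schemes$ampa, params$temperature)
  ampa_pop <- c(ampa_tab, list(
    rects = list(g_ampa$rect),
    mol_pos = if (is.null(g_ampa$pos)) matrix(0, 0, 3) else g_ampa$pos))

  ## GluT population on surrounding membranes
  rects <- glut_rects(geom, placement = glut_placement)
  g_tabs <- list(); g_pos <- list(); mol0 <- 0L
  for (r in rects) {
    n <- as.integer(floor(cfg$glut_density * 1e-6 * r$area + 0.5))
    gr <- grid_rect(r, n, rect_inward(geom, r), mol0, params)
    mol0 <- mol0 + n
    g_tabs[[length(g_tabs) + 1L]] <- gr$rect
    if (!is.null(gr$pos)) g_pos[[length(g_pos) + 1L]] <- gr$pos
  }
  glut_tab <- scheme_engine_tables(schemes$glut, params$temperature)
  glut_pop <- c(glut_tab, list(
    rects = g_tabs,
    mol_pos = if (length(g_pos)) do.call(rbind, g_pos) else matrix(0, 0, 3)))

  check_bind_probs(list(ampa_pop, glut_pop))
  structure(list(
    geom_engine = list(peri = geom$peri, pre = geom$pre, post = geom$post),
    geom = geom,
    pops = list(ampa = ampa_pop, glut = glut_pop),
    params = params,
    n_ampa = n_ampa, n_glut = mol0,
    cfg = as.list(cfg)
  ), class = "synapse_world")
}

## fixed-grid variant used for the PSD so the receptor grid is square
grid_rect_fixed <- function(rect, n_mol, nu, nv, inward, mol0, params, eps = 1e-3) {
  stopifnot(nu * nv >= n_mol)
  len_u <- rect$u1 - rect$u0; len_v <- rect$v1 - rect$v0
  du <- len_u / nu; dv <- len_v / nv
  tile_mol <- rep(-1L, nu * nv)
  pos <- NULL
  if (n_mol > 0) {
    tiles <- sample.int(nu * nv, n_mol) - 1L
    tile_mol[tiles + 1L] <- mol0 + seq_len(n_mol) - 1L
    iu <- tiles %% nu; iv <- tiles %/% nu
    u <- rect$u0 + (iu + stats::runif(n_mol)) * du
    v <- rect$v0 + (iv + stats::runif(n_mol)) * dv
    pos <- matrix(0, n_mol, 3)
    ax <- plane_axes(rect$axis)
    pos[, ax[1] + 1L] <- u
    pos[, ax[2] + 1L] <- v
    pos[, rect$axis + 1L] <- rect$pos + eps * inward
  }
  list(rect = list(axis = rect$axis, pos = rect$pos, u0 = rect$u0, v0 = rect$v0,
                   du = du, dv = dv, nu = nu, nv = nv, tile_mol = tile_mol,
                   p_scale = sqrt(pi * params$dt / (params$D_g * 1000)) / (du * dv),
                   inward = inward),
       pos = pos)
}

check_bind_probs <- function(pops) {
  for (p in pops) {
    if (!length(p$bind_kon)) next
    kmax <- max(p$bind_kon)
    smax <- max(vapply(p$rects, function(r) r$p_scale, 0))
    if (kmax * smax > 1)
      stop("per-crossing binding probability exceeds 1; reduce dt")
  }
}

#' Default kinetic schemes shipped with the package
#' @return List with `ampa` and `glut` `kinetic_scheme`s.
#' @export
default_schemes <- function() {
  list(ampa = read_scheme(scheme_file("ampa")),
       glut = read_scheme(scheme_file("glut")))
}

#' Run one stochastic simulation of a synapse
#'
#' Releases `params$N_g` glutamate molecules at the centre of the AZ at
#' t = 0 and advances the coupled Brownian-diffusion / surface-binding /
#' Markov-gating system for `params$n_steps` steps, recording the number of
#' open AMPA receptors after every step.
#'
#' @param world a `synapse_world` from [build_world()].
#' @param run_index integer; together with the configuration seed this
#'   determines the run's independent random stream.
#' @param record_steps optional integer vector of step indices at which to
#'   snapshot the per-receptor open flags (for spatial maps).
#' @param check_conservation verify glutamate bookkeeping during the run.
#' @return A `run_result`: list with `open_counts` (length
#'   `n_steps + 1`, entry 1 is t = 0), `maxOPEN`, `peak_time` (us), `auc`
#'   (receptor-us), `removed`, `seed` info, `conservation_ok`, and
#'   optionally `snapshots` (+ `receptor_pos`).
#' @export
run_synapse <- function(world, run_index = 1L, record_steps = integer(0),
                        check_conservation = FALSE) {
  p <- world$params
  res <- cpp_run_engine(
    world$geom_engine,
    unname(world$pops),
    list(dt = p$dt, n_steps = p$n_steps, n_g = p$N_g,
         release = c(0, 0, -1e-3),     # AZ centre, nudged into the cleft
         sigma = displacement_sigma(p$D_g, p$dt),
         bounce_limit = p$bounce_limit,
         root_seed = as.numeric(world$cfg$seed),
         config_id = as.numeric(world$cfg$id %||% 0),
         run_index = as.numeric(run_index),
         record_steps = as.integer(record_steps),
         record_pop = if (length(record_steps)) 0L else -1L,
         check_conservation = isTRUE(check_conservation)))
  if (!res$conservation_ok)
    stop("glutamate conservation violated (free + bound + removed != N_g)")
  s <- summarize_run(res$open_counts, p$dt)
  out <- list(open_counts = res$open_counts,
              maxOPEN = s$maxOPEN, peak_time = s$peak_time, auc = s$auc,
              removed = res$removed, discarded_steps = res$discarded_steps,
              conservation_ok = res$conservation_ok,
              run_index = run_index, config_seed = world$cfg$seed)
  if (length(record_steps)) {
    out$snapshots <- res$snapshots
    out$receptor_pos <- world$pops$ampa$mol_pos
    out$record_steps <- as.integer(record_steps)
  }
  class(out) <- "run_result"
  out
}

#' Run a batch of independent simulations of one configuration
#'
#' @param world a `synapse_world`, or a one-row population slice (a world
#'   is then built with defaults).
#' @param n_runs number of independent runs (>= 1).
#' @param record_steps,check_conservation passed to [run_synapse()].
#' @return A `run_batch` list: `runs` (list of `run_result`), `mean_curve`
#'   (pointwise mean open count), `summary` (per-run data.frame with
#'   `maxOPEN`, `peak_time`, `auc`), and the `cfg` fields.
#' @export
run_batch <- function(world, n_runs, record_steps = integer(0),
                      check_conservation = FALSE) {
  if (!inherits(world, "synapse_world")) world <- build_world(world)
  if (n_runs < 1) stop("n_runs must be >= 1")
  runs <- lapply(seq_len(n_runs), function(r)
    run_synapse(world, run_index = r, record_steps = record_steps,
                check_conservation = check_conservation))
  curves <- vapply(runs, function(r) as.numeric(r$open_counts),
                   numeric(world$params$n_steps + 1L))
  structure(list(
    runs = runs,
    mean_curve = rowMeans(curves),
    summary = data.frame(
      run = seq_len(n_runs),
      maxOPEN = vapply(runs, `[[`, 0, "maxOPEN"),
      peak_time = vapply(runs, `[[`, 0, "peak_time"),
      auc = vapply(runs, `[[`, 0, "auc")),
    cfg = world$cfg,
    params = world$params
  ), class = "run_batch")
}

#' Reflect a displacement segment through the synapse geometry
#'
#' Specular reflection of the segment `start -> start + disp` off every
#' membrane face; test/diagnostic surface of the engine's reflection core.
#'
#' @param geom a `synapse_geometry`.
#' @param start length-3 start coordinate (must lie in the ECS).
#' @param disp length-3 displacement (nm).
#' @param bounce_limit maximum bounces before the step is discarded.
#' @return List with `end`, `hits` (ordered matrix of face crossings:
#'   axis, plane, x, y, z) and `discarded`.
#' @export
reflect_segment <- function(geom, start, disp, bounce_limit = 64L) {
  if (!point_in_ecs(geom, start)) stop("start must lie in the ECS")
  cpp_reflect_segment(list(peri = geom$peri, pre = geom$pre, post = geom$post),
                      as.numeric(start), as.numeric(disp),
                      as.integer(bounce_limit))
}

#' Long-run positions of a non-reacting tracer in the ECS
#'
#' @param geom a `synapse_geometry`.
#' @param n number of independent tracer particles.
#' @param n_steps steps per particle.
#' @param params a `sim_params` (sets sigma).
#' @param seed integer seed.
#' @param start start coordinate (defaults just below the release point).
#' @return n x 3 matrix of final positions.
#' @export
simulate_tracer <- function(geom, n, n_steps, params = sim_params(), seed = 1,
                            start = c(0, 0, -1e-3)) {
  cpp_tracer(list(peri = geom$peri, pre = geom$pre, post = geom$post),
             as.integer(n), as.integer(n_steps),
             displacement_sigma(params$D_g, params$dt),
             as.numeric(start), as.numeric(seed),
             as.integer(params$bounce_limit))
}
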