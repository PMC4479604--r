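small_cfg <- function(seed = 1) {
  pop <- sample_configs(30, seed = seed)
  pop[which.min(pop$Ls), ]              # smallest synapse: fastest runs
}

test_that("sim_params defaults reproduce the published setup", {
  p <- sim_params()
  expect_equal(p$D_g, 0.33)
  expect_equal(p$dt, 1)
  expect_equal(p$T_total, 10)
  expect_equal(p$N_g, 3000)
  expect_equal(p$temperature, 35)
  expect_equal(p$n_steps, 10000L)
  expect_error(sim_params(dt = 0), "invalid")
})

test_that("displacement sigma follows sqrt(2 D dt)", {
  expect_equal(displacement_sigma(0.33, 1), sqrt(2 * 330))
  expect_equal(displacement_sigma(0.33, 4), 2 * sqrt(2 * 330))
})

test_that("binding probability calibration matches the closed form", {
  ## kon' = kon * 1e24/NA * 1e-6 nm^3/us; p = kon' sqrt(pi dt / D) / A_tile
  kon <- 1.8e7; D <- 0.33; dt <- 1; a_tile <- 100  # nm^2
  kon_nm <- kon * 1e24 / 6.02214076e23 * 1e-6
  expect_equal(calibrate_binding_probability(kon, D, dt, 1e6 / a_tile),
               kon_nm * sqrt(pi * dt / 330) / a_tile)
  expect_error(calibrate_binding_probability(1e12, D, dt, 1e6 / a_tile),
               "exceeds 1")
  expect_error(calibrate_binding_probability(-1, D, dt, 1), "kon")
})

test_that("surface binding reproduces mass action in a well-mixed box", {
  p <- sim_params()
  sig <- displacement_sigma(p$D_g, p$dt)
  L <- 200; nu <- 40L; nv <- 40L; kon <- 2e5
  pb <- calibrate_binding_probability(kon, p$D_g, p$dt,
                                      tile_density = 1e6 / (L / nu)^2)
  n_a <- 4000L; n_steps <- 2000L
  rem <- cleftsim:::cpp_calibration_box(L, n_a, nu, nv, pb, sig, n_steps, 11)
  ## bimolecular depletion ODE oracle (well-mixed regime: mixing time ~ 20 us
  ## << binding time ~ 15 ms)
  k <- kon * 1e24 / 6.02214076e23 * 1e-6 / L^3
  A <- n_a; B <- nu * nv
  for (t in seq_len(n_steps)) { dA <- k * A * B * p$dt; A <- A - dA; B <- B - dA }
  bound_sim <- n_a - rem[n_steps]
  bound_ode <- n_a - A
  sd_bin <- sqrt(bound_ode * (1 - bound_ode / n_a))
  expect_lt(abs(bound_sim - bound_ode), 3 * sd_bin)
})

test_that("mean squared displacement of free diffusion equals 6 D t", {
  p <- sim_params()
  sig <- displacement_sigma(p$D_g, p$dt)
  sq <- cleftsim:::cpp_free_sqdisp(50000L, 100L, sig, 99)
  theory <- 6 * p$D_g * 1000 * 100
  expect_lt(abs(mean(sq) - theory) / theory, 0.01)
})

test_that("reflection keeps particles inside the extracellular space", {
  g <- build_geometry(list(Ls = 400, La = 720))
  ## head-on specular bounce off the PSD plane from the cleft
  r <- reflect_segment(g, start = c(0, 0, -10), disp = c(0, 0, -15))
  expect_equal(r$end, c(0, 0, -20 + 5), tolerance = 1e-5)
  expect_false(r$discarded)
  expect_gte(nrow(r$hits), 1)
  ## property: random segments from random ECS starts stay in the ECS
  set.seed(13)
  n_ok <- 0
  for (i in 1:300) {
    repeat {
      s <- c(runif(1, g$peri[1], g$peri[2]), runif(1, g$peri[3], g$peri[4]),
             runif(1, g$peri[5], g$peri[6]))
      if (point_in_ecs(g, s)) break
    }
    r <- reflect_segment(g, s, rnorm(3, 0, 40))
    if (!r$discarded) {
      expect_true(point_in_ecs(g, r$end))
      n_ok <- n_ok + 1
    }
  }
  expect_gt(n_ok, 290)    # discards are rare at this step size
  expect_error(reflect_segment(g, c(0, 0, g$pre[6] / 2), c(1, 0, 0)), "ECS")
})

test_that("a non-reacting tracer equilibrates uniformly over the ECS", {
  g <- build_geometry(list(Ls = 400, La = 720))
  pos <- simulate_tracer(g, n = 2000, n_steps = 5000, seed = 17)
  expect_equal(dim(pos), c(2000, 3))
  expect_true(all(point_in_ecs(g, pos)))
  ## chi-square over the 8 octants of the world; by symmetry each octant
  ## holds an equal share of ECS volume
  oct <- 1 + (pos[, 1] > 0) + 2 * (pos[, 2] > 0) +
    4 * (pos[, 3] > (g$peri[5] + g$peri[6]) / 2)
  counts <- tabulate(oct, 8)
  chi2 <- sum((counts - 250)^2 / 250)
  expect_lt(chi2, qchisq(1 - 1e-4, df = 7))
})

test_that("world assembly places every molecule on its membrane", {
  cfg <- small_cfg()
  w <- build_world(cfg)
  expect_s3_class(w, "synapse_world")
  expect_equal(w$n_ampa, cfg$nAMPA)
  ## receptors on the PSD plane, inside the PSD square
  rp <- w$pops$ampa$mol_pos
  expect_equal(nrow(rp), cfg$nAMPA)
  expect_true(all(abs(rp[, 3] - (-20 + 1e-3)) < 1e-9))
  expect_true(all(abs(rp[, 1]) <= cfg$Ls / 2 & abs(rp[, 2]) <= cfg$Ls / 2))
  ## transporter count consistent with density x membrane area
  rects <- glut_rects(w$geom)
  n_expect <- sum(vapply(rects, function(r)
    floor(cfg$glut_density * 1e-6 * r$area + 0.5), 0))
  expect_equal(w$n_glut, n_expect)
  ## layout is deterministic in the config seed
  w2 <- build_world(cfg)
  expect_identical(w$pops$ampa$mol_pos, w2$pops$ampa$mol_pos)
  expect_identical(w$pops$glut$mol_pos, w2$pops$glut$mol_pos)
})

test_that("runs are reproducible per (config, run) and independent across runs", {
  w <- build_world(small_cfg(), params = sim_params(T_total = 2))
  r1a <- run_synapse(w, run_index = 1)
  r1b <- run_synapse(w, run_index = 1)
  expect_identical(r1a$open_counts, r1b$open_counts)
  r2 <- run_synapse(w, run_index = 2)
  expect_false(identical(r1a$open_counts, r2$open_counts))
  expect_length(r1a$open_counts, w$params$n_steps + 1)
  expect_equal(r1a$open_counts[1], 0)
  expect_equal(r1a$maxOPEN, max(r1a$open_counts))
})

test_that("glutamate bookkeeping is exact throughout a full run", {
  w <- build_world(small_cfg(), params = sim_params(T_total = 2))
  r <- run_synapse(w, run_index = 3, check_conservation = TRUE)
  expect_true(r$conservation_ok)
  expect_lte(r$removed, w$params$N_g)
})

test_that("a synapse with no receptors never opens anything", {
  cfg <- small_cfg()
  w <- build_world(cfg, params = sim_params(T_total = 1), nampa_override = 0)
  r <- run_synapse(w, run_index = 1)
  expect_true(all(r$open_counts == 0))
  expect_equal(r$maxOPEN, 0)
  expect_equal(r$peak_time, 0)
})

test_that("run_batch aggregates runs into curve and summary", {
  w <- build_world(small_cfg(), params = sim_params(T_total = 1))
  b <- run_batch(w, 4)
  expect_s3_class(b, "run_batch")
  expect_length(b$runs, 4)
  expect_equal(nrow(b$summary), 4)
  expect_length(b$mean_curve, w$params$n_steps + 1)
  expect_equal(b$mean_curve,
               rowMeans(vapply(b$runs, function(r) as.numeric(r$open_counts),
                               numeric(w$params$n_steps + 1))))
  expect_error(run_batch(w, 0), "n_runs")
})
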