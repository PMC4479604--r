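write_scheme_yaml <- function(text) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

test_that("q10_adjust scales rates by Q10 per 10 degrees", {
  expect_equal(q10_adjust(100, 25, 35, 2.5), 250)
  expect_equal(q10_adjust(100, 35, 25, 2.5), 40)
  expect_equal(q10_adjust(c(1, 2), 23, 35, 2.5), c(1, 2) * 2.5^1.2)
  expect_error(q10_adjust(1, 20, 30, 0), "Q10")
})

test_that("step_probability is the exact first-order discretization", {
  expect_equal(step_probability(100, 1e-3), 1 - exp(-0.1))
  expect_equal(step_probability(0, 1e-3), 0)
  ## numerically stable for tiny k * dt
  expect_equal(step_probability(1e-9, 1e-9), 1e-18, tolerance = 1e-6)
  expect_error(step_probability(-1, 1e-3), "k must")
  expect_error(step_probability(1, 0), "dt must")
})

test_that("shipped AMPA scheme loads with consistent ligand bookkeeping", {
  sc <- read_scheme(scheme_file("ampa"))
  expect_s3_class(sc, "kinetic_scheme")
  expect_length(sc$states, 7)                 # 6 closed + 1 open
  expect_false(is.na(sc$open))
  expect_equal(sc$ligand_count[sc$initial], 0L)
  expect_equal(max(sc$ligand_count), 2L)      # doubly liganded at most
  expect_equal(sc$ligand_count[sc$open], 2L)  # opening needs two glutamates
  expect_equal(sum(sc$transitions$order == 2L), 3)
  expect_equal(sc$T_ref, 23); expect_equal(sc$Q10, 2.5)
})

test_that("shipped transporter scheme is the two-state uptake cycle", {
  sc <- read_scheme(scheme_file("glut"))
  expect_length(sc$states, 2)
  expect_equal(sc$ligand_count, c(0L, 1L))
  tr <- sc$transitions
  expect_equal(sum(tr$order == 2L), 1)
  expect_true(any(tr$releases_ligand))        # return to ECS branch
  expect_true(any(tr$removes_ligand))         # translocation branch
  ## equal-rate branches of the bound state
  expect_equal(tr$rate[tr$releases_ligand], tr$rate[tr$removes_ligand])
})

test_that("scheme validation rejects malformed files", {
  expect_error(read_scheme(write_scheme_yaml("
name: broken
T_ref: 23
states: [A, B]
initial: A
transitions:
  - {from: A, to: B, rate: 1, order: 1}
")), "missing fields")
  expect_error(read_scheme(write_scheme_yaml("
name: broken
T_ref: 23
Q10: 2.5
states: [A, B]
initial: A
transitions:
  - {from: A, to: C, rate: 1, order: 1}
")), "declared states")
  expect_error(read_scheme(write_scheme_yaml("
name: broken
T_ref: 23
Q10: 2.5
states: [A, B]
initial: A
transitions:
  - {from: A, to: B, rate: -5, order: 1}
")), "rates must")
  expect_error(read_scheme(write_scheme_yaml("
name: broken
T_ref: 23
Q10: 2.5
states: [A, B]
initial: A
transitions:
  - {from: A, to: B, rate: 1, order: 2, releases_ligand: true}
")), "bimolecular")
  ## inconsistent cycle: A -> B binds, B -> A neither releases nor removes
  expect_error(read_scheme(write_scheme_yaml("
name: broken
T_ref: 23
Q10: 2.5
states: [A, B]
initial: A
transitions:
  - {from: A, to: B, rate: 1, order: 2}
  - {from: B, to: A, rate: 1, order: 1}
")), "ligand bookkeeping")
  ## unreachable state
  expect_error(read_scheme(write_scheme_yaml("
name: broken
T_ref: 23
Q10: 2.5
states: [A, B, C]
initial: A
transitions:
  - {from: A, to: B, rate: 1, order: 1}
")), "unreachable")
})

test_that("scheme_at_temperature applies the blanket Q10 factor", {
  sc <- read_scheme(scheme_file("ampa"))
  sc35 <- scheme_at_temperature(sc, 35)
  expect_equal(sc35$transitions$rate, sc$transitions$rate * 2.5^1.2)
  expect_equal(sc35$T_ref, 35)
  ## idempotent once at target temperature
  again <- scheme_at_temperature(sc35, 35)
  expect_equal(again$transitions$rate, sc35$transitions$rate)
})

test_that("advance_states matches an exponential decay law", {
  path <- write_scheme_yaml("
name: decay
T_ref: 23
Q10: 2.5
states: [A, B]
initial: A
open: A
transitions:
  - {from: A, to: B, rate: 1000, order: 1}
")
  sc <- read_scheme(path)
  set.seed(21)
  n <- 5000
  out <- advance_states(rep(1L, n), sc, dt = 1e-4, n_steps = 10, trace = TRUE)
  surv_expect <- n * exp(-1000 * 1e-4 * (0:10))
  expect_true(all(abs(out$occupancy[, 1] - surv_expect) <
                    3 * sqrt(n * 0.25) + 3))
  expect_equal(out$released + out$removed, 0L)
})

test_that("stochastic ensemble matches the exact master equation (3 sd)", {
  sc <- scheme_at_temperature(read_scheme(scheme_file("ampa")), 35)
  n <- 3000
  t_end <- 3e-4                               # 300 us at 1 mM clamp
  set.seed(31)
  ## dt must resolve the fastest pseudo-first-order rate (~8.5e4 /s at
  ## 1 mM) for the one-jump-per-step chain to approximate the CTMC
  out <- advance_states(rep(sc$initial, n), sc, dt = 1e-7,
                        n_steps = t_end * 1e7, glu_conc = 1e-3)
  ## exact law of the discretized chain itself (at most one jump per dt):
  ## P = diag(exp(-ktot dt)) + (1 - exp(-ktot dt)) * k_ij / ktot
  step_matrix <- function(sc, dt, glu_conc) {
    ut <- cleftsim:::uni_table(sc, glu_conc)
    ns <- length(sc$states)
    K <- matrix(0, ns, ns)
    for (j in seq_len(nrow(ut))) K[ut$from[j], ut$to[j]] <-
        K[ut$from[j], ut$to[j]] + ut$rate[j]
    ktot <- rowSums(K)
    P <- matrix(0, ns, ns)
    for (s in seq_len(ns)) {
      stay <- exp(-ktot[s] * dt)
      P[s, ] <- if (ktot[s] > 0) (1 - stay) * K[s, ] / ktot[s] else 0
      P[s, s] <- P[s, s] + stay
    }
    P
  }
  mat_pow <- function(P, e) {
    res <- diag(nrow(P)); B <- P
    while (e > 0) {
      if (e %% 2) res <- res %*% B
      B <- B %*% B; e <- e %/% 2
    }
    res
  }
  occ <- tabulate(out$states, length(sc$states))
  p0 <- numeric(length(sc$states)); p0[sc$initial] <- 1
  law <- as.numeric(p0 %*% mat_pow(step_matrix(sc, 1e-7, 1e-3), 3000L))
  ## sampled occupancy vs the exact law of the same chain: binomial 3 sd
  for (s in seq_along(occ)) {
    sd_s <- sqrt(max(n * law[s] * (1 - law[s]), 1))
    expect_lt(abs(occ[s] - n * law[s]), 3 * sd_s + 3)
  }
  ## and the discretized law itself converges to the CTMC master equation
  exact <- scheme_marginals(sc, t_end, glu_conc = 1e-3)[1, ]
  expect_lt(max(abs(law - exact)), 0.02)
})

test_that("scheme_marginals conserves probability and starts at initial", {
  sc <- scheme_at_temperature(read_scheme(scheme_file("ampa")), 35)
  m <- scheme_marginals(sc, c(0, 1e-4, 1e-3), glu_conc = 5e-3)
  expect_equal(rowSums(m), rep(1, 3), tolerance = 1e-8)
  expect_equal(m[1, sc$initial], 1)
  expect_true(all(m >= -1e-12))
})
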