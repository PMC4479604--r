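## synthetic population table with a known structure
fake_table <- function(n = 40, seed = 3) {
  set.seed(seed)
  tab <- data.frame(
    id = seq_len(n),
    Ls = runif(n, 100, 800))
  tab$As <- tab$Ls^2
  tab$La <- tab$Ls * 1.5
  tab$ampar_density <- runif(n, 500, 3000)
  tab$glut_density <- runif(n, 7000, 12000)
  tab$nAMPA <- compute_nampa(tab$ampar_density, tab$Ls)
  tab$maxOPEN_mean <- 0.3 * tab$nAMPA
  tab$maxOPEN_cv <- 1 / sqrt(tab$nAMPA)
  class(tab) <- c("population_table", "data.frame")
  tab
}

test_that("correlation screen ranks the Table-2 predictors", {
  tab <- fake_table()
  scr <- correlation_screen(tab)
  expect_equal(rownames(scr),
               c("glut_density", "La", "ampar_density", "As", "Ls", "nAMPA"))
  expect_equal(colnames(scr), c("maxOPEN_mean", "maxOPEN_cv"))
  expect_equal(scr["nAMPA", "maxOPEN_mean"], 1)       # response is linear in nAMPA
  expect_lt(abs(scr["glut_density", "maxOPEN_mean"]), 0.4)
  tab$glut_density <- 9000
  expect_warning(scr2 <- correlation_screen(tab), "zero-variance")
  expect_true(is.na(scr2["glut_density", "maxOPEN_mean"]))
  expect_error(correlation_screen(tab[1:2, ]), "at least 3")
})

test_that("power-law fit recovers known coefficients exactly (noise-free)", {
  set.seed(9)
  x <- sort(runif(60, 20, 900))
  a <- 2.175; b <- 0.663; c <- -4.661
  y <- a * x^b + c
  f <- fit_power_law(x, y, "As", "maxOPEN_mean")
  expect_s3_class(f, "power_law_fit")
  expect_equal(f$a, a, tolerance = 1e-4)
  expect_equal(f$b, b, tolerance = 1e-4)
  expect_equal(f$c, c, tolerance = 1e-4)
  expect_lt(f$rmse_train, 1e-6)
  expect_equal(f$r2_train, 1, tolerance = 1e-9)
  expect_equal(predict(f, 100), a * 100^b + c, tolerance = 1e-3)
})

test_that("power-law fit is robust to noise and degenerate input", {
  set.seed(10)
  x <- runif(80, 50, 500)
  y <- 3 * x^0.5 + 1 + rnorm(80, 0, 0.5)
  f <- fit_power_law(x, y)
  expect_equal(f$b, 0.5, tolerance = 0.15)
  expect_gt(f$r2_train, 0.95)
  ## constant response: degenerate branch, not an error
  fc <- fit_power_law(x, rep(2, 80))
  expect_equal(fc$a, 0); expect_equal(fc$c, 2)
  expect_error(fit_power_law(c(-1, 2, 3, 4), 1:4), "positive")
  expect_error(fit_power_law(1:3, 1:3), "at least 4")
})

test_that("held-out validation fills the Table-4 metrics", {
  x <- seq(50, 500, length.out = 50)
  y <- 2 * x^0.7 - 3
  f <- fit_power_law(x, y, "As", "maxOPEN_mean")
  test_tab <- data.frame(As = seq(60, 480, length.out = 30))
  test_tab$maxOPEN_mean <- 2 * test_tab$As^0.7 - 3
  f2 <- validate_fit(f, test_tab)
  expect_lt(f2$rmse_test, 1e-6)
  expect_equal(f2$r2_test, 1, tolerance = 1e-9)
  out <- capture.output(print(f2))
  expect_true(any(grepl("test", out)))
})

test_that("maxOPEN distribution reports density, CDF, quartiles and mode", {
  v <- c(0L, 2L, 2L, 3L, 3L, 3L, 5L, 8L)
  d <- maxopen_distribution(v)
  expect_equal(sum(d$density), 1)
  expect_equal(d$count, 0:8)
  expect_equal(d$density[4], 3 / 8)          # count 3
  expect_true(all(diff(d$cdf) >= 0))
  expect_equal(d$cdf[length(d$cdf)], 1)
  expect_equal(unname(d$quartiles),
               unname(quantile(v, c(0.25, 0.5, 0.75), type = 7)))
  expect_equal(d$mode, 3)
  expect_equal(d$mode_frequency, 3 / 8)
  expect_equal(maxopen_cdf(d, 3), 6 / 8)
  expect_error(maxopen_distribution(integer(0)), "empty")
})

test_that("activation probabilities are exceedance frequencies", {
  tab <- fake_table(n = 25)
  pooled <- do.call(rbind, lapply(seq_len(25), function(i) data.frame(
    id = i, nAMPA = tab$nAMPA[i], run = 1:4,
    maxOPEN = round(tab$maxOPEN_mean[i]) + c(-2L, -1L, 1L, 2L),
    peak_time = 80, auc = 100)))
  attr(tab, "pooled") <- pooled
  act <- activation_probability(tab, c(Q1 = 10, Q2 = 30), n_bins = 5)
  per <- act$per_config
  expect_true(all(per$P_ge_Q1 >= per$P_ge_Q2))   # monotone in the threshold
  expect_true(all(per$P_ge_Q1 >= 0 & per$P_ge_Q1 <= 1))
  ## exact exceedance for one config
  i <- per$id[1]
  expect_equal(per$P_ge_Q1[1],
               mean(pooled$maxOPEN[pooled$id == i] >= 10))
  expect_true(all(act$binned$probability >= 0 & act$binned$probability <= 1))
  ## threshold 0 is always reached
  act0 <- activation_probability(tab, c(T0 = 0))
  expect_true(all(act0$per_config$P_ge_T0 == 1))
})

test_that("spatial opening map grids the PSD into 55-nm cells", {
  pop <- sample_configs(30, seed = 1)
  cfg <- pop[which.min(pop$Ls), ]
  m <- spatial_opening_map(cfg, n_runs = 4, times_us = c(50, 100, 8000),
                           params = sim_params(T_total = 9))
  expect_s3_class(m, "spatial_opening_map")
  expect_equal(m$cell_nm, 55)
  expect_length(m$maps, 3)
  n_cells <- ceiling(cfg$Ls / 55)
  for (mp in m$maps) {
    expect_equal(dim(mp), c(n_cells, n_cells))
    vals <- mp[!is.na(mp)]
    expect_true(all(vals >= 0 & vals <= 1))
  }
  expect_equal(sum(m$counts), cfg$nAMPA)
})
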