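test_that("residual vector matches hand-computed differences", {
  noiseless <- sim_lanes(kd_nM = 40, C = 5, f = 0.85, noise_sd = 0)
  expect_equal(residual_vector(noiseless, 40, 5, 0.85),
               rep(0, 45), tolerance = 1e-12)
  expect_length(residual_vector(noiseless, 20, 2, 0.5), 45)

  lane <- tibble::tibble(condition = "x", conc_nM = 10, replicate = 1,
                         band0 = 50, band1 = 50, band2 = 0)
  # alpha = 1 at Kd = 10; C = 1, f = 1 predicts (0.25, 0.5, 0.25)
  expect_equal(residual_vector(lane, 10, 1, 1), c(0.25, 0, -0.25))
})

test_that("noiseless synthetic data is recovered within 1%", {
  fit <- fit_titration(sim_lanes(kd_nM = 40, C = 5, f = 0.85, noise_sd = 0))
  p <- fit$params
  expect_equal(p$kd_nM, 40, tolerance = 0.01)
  expect_equal(p$C, 5, tolerance = 0.01)
  expect_equal(p$f, 0.85, tolerance = 0.01)
  expect_lt(fit$ssr, 1e-10)
  expect_true(fit$converged)

  noncoop <- fit_titration(sim_lanes(kd_nM = 40, C = 1, f = 1, noise_sd = 0))
  expect_gte(noncoop$params$C, 0.99)
  expect_lte(noncoop$params$C, 1.01)
})

test_that("fitting is deterministic and optimal on its own objective", {
  lanes <- sim_lanes(seed = 31)
  f1 <- fit_titration(lanes)
  f2 <- fit_titration(lanes)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$ssr, f2$ssr)
  # the estimate can never do worse than the generating truth
  ssr_truth <- sum(residual_vector(lanes, 40, 5, 0.85)^2)
  expect_lte(f1$ssr, ssr_truth)
})

test_that("degenerate designs are rejected as unidentifiable", {
  one_conc <- tibble::tibble(
    condition = "x", conc_nM = rep(40, 3), replicate = 1:3,
    band0 = 20, band1 = 50, band2 = 30
  )
  expect_error(fit_titration(one_conc),
               class = "emsacoop_identifiability_error")
})

test_that("estimates are scale-equivariant in concentration units", {
  lanes <- sim_lanes(kd_nM = 40, C = 5, f = 0.85, noise_sd = 0)
  base <- fit_titration(lanes)
  scaled <- dplyr::mutate(lanes, conc_nM = conc_nM * 10)
  refit <- fit_titration(scaled, kd_bounds = c(1e-2, 1e7))
  expect_equal(refit$params$kd_nM, base$params$kd_nM * 10, tolerance = 1e-4)
  expect_equal(refit$params$C, base$params$C, tolerance = 1e-4)
  expect_equal(refit$params$f, base$params$f, tolerance = 1e-4)
})

test_that("weighted and replicate-mean fits recover noiseless truth", {
  lanes <- sim_lanes(kd_nM = 40, C = 5, f = 0.85, noise_sd = 0)
  wfit <- fit_titration(lanes, weighted = TRUE)
  mfit <- fit_titration(lanes, use_means = TRUE)
  expect_equal(wfit$params$C, 5, tolerance = 0.01)
  expect_equal(mfit$params$C, 5, tolerance = 0.01)
  expect_equal(mfit$n_points, 15L)  # 5 concentrations x 3 bands
})

test_that("grid search finds exact truth when the grid contains it", {
  lanes <- sim_lanes(kd_nM = 40, C = 5, f = 0.85, noise_sd = 0)
  hit <- grid_oracle(lanes, kd_grid = c(10, 40, 100), C_grid = c(1, 5),
                     f_grid = c(0.5, 0.85))
  expect_lt(hit$ssr, 1e-20)
  expect_equal(hit$params$kd_nM, 40)
  expect_equal(hit$params$C, 5)
  one <- grid_oracle(lanes, kd_grid = 30, C_grid = 2, f_grid = 0.7)
  expect_equal(one$ssr, sum(residual_vector(lanes, 30, 2, 0.7)^2))
  expect_error(grid_oracle(lanes, kd_grid = numeric(0)),
               class = "emsacoop_validation_error")
})

test_that("the optimizer never loses to a brute-force grid", {
  set.seed(17)
  for (i in 1:5) {
    lanes <- sim_lanes(kd_nM = 10^runif(1, 1, 2.2), C = sample(c(1, 5), 1),
                       f = runif(1, 0.6, 1), seed = 400 + i)
    fit <- fit_titration(lanes)
    oracle <- grid_oracle(lanes,
                          kd_grid = 10^seq(0, 3, length.out = 25),
                          C_grid = 10^seq(-2, 2, length.out = 25),
                          f_grid = seq(0, 1, length.out = 11))
    expect_lte(fit$ssr, oracle$ssr + 1e-9)
  }
})

test_that("tidiers expose estimates, bounds and fit diagnostics", {
  fit <- fit_titration(sim_lanes(seed = 3))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "at_bound"))
  expect_equal(td$term, c("kd_nM", "C", "f"))
  gl <- glance(fit)
  expect_tibble_rows(gl, 1)
  expect_equal(gl$kd2_nM, gl$kd_nM / gl$C)
  expect_s3_class(autoplot(fit), "ggplot")
})
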