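test_that("statistical weight is the concentration/Kd ratio", {
  expect_equal(statistical_weight(40, 40), 1)
  expect_equal(statistical_weight(0, 10), 0)
  expect_equal(statistical_weight(640, 40), 16)
  expect_equal(statistical_weight(c(2.5, 10), 40), c(0.0625, 0.25))
  expect_error(statistical_weight(10, 0), class = "emsacoop_validation_error")
  expect_error(statistical_weight(-1, 10), class = "emsacoop_validation_error")
})

test_that("pure occupancy matches hand-evaluated binding polynomial", {
  expect_equal(unlist(occupancy_pure(0, C = 5)[, c("p0", "p1", "p2")]),
               c(p0 = 1, p1 = 0, p2 = 0))
  # C = 1 collapses to independent binomial binding
  expect_equal(unlist(occupancy_pure(1, C = 1)[, c("p0", "p1", "p2")]),
               c(p0 = 0.25, p1 = 0.5, p2 = 0.25))
  # denominator 1 + 2 + 5 = 8
  expect_equal(unlist(occupancy_pure(1, C = 5)[, c("p0", "p1", "p2")]),
               c(p0 = 0.125, p1 = 0.25, p2 = 0.625))
  expect_error(occupancy_pure(1, C = 0), class = "emsacoop_validation_error")
  expect_error(occupancy_pure(-1, C = 1), class = "emsacoop_validation_error")
})

test_that("mixture occupancy interpolates the two- and one-site species", {
  expect_equal(occupancy_mixture(1, C = 5, f = 1)[, c("p0", "p1", "p2")],
               occupancy_pure(1, C = 5)[, c("p0", "p1", "p2")])
  # f = 0 forbids double occupancy entirely
  m0 <- occupancy_mixture(1, C = 5, f = 0)
  expect_equal(unlist(m0[, c("p0", "p1", "p2")]),
               c(p0 = 1 / 3, p1 = 2 / 3, p2 = 0))
  # hand-evaluated 50/50 mixture at alpha = 1, C = 1
  m <- occupancy_mixture(1, C = 1, f = 0.5)
  expect_equal(unlist(m[, c("p0", "p1", "p2")]),
               c(p0 = 0.5 / 4 + 0.5 / 3, p1 = 1 / 4 + 1 / 3, p2 = 0.125))
  expect_error(occupancy_mixture(1, C = 1, f = 1.2),
               class = "emsacoop_validation_error")
  expect_error(occupancy_mixture(1, C = 1, f = -0.1),
               class = "emsacoop_validation_error")
})

test_that("occupancy agrees with the microstate enumeration oracle", {
  set.seed(11)
  alpha <- c(0, 10^runif(200, -3, 3))
  for (C in c(0.02, 1, 5, 400)) {
    for (f in c(0, 0.37, 0.85, 1)) {
      got <- as.matrix(occupancy_mixture(alpha, C, f)[, c("p0", "p1", "p2")])
      want <- microstate_occupancy(alpha, C, f)
      expect_lt(max(abs(got - want)), 1e-12)
    }
  }
})

test_that("occupancy distributions normalize and stay nonnegative", {
  set.seed(7)
  n <- 1e5
  alpha <- runif(n, 0, 1e3)
  C <- 10^runif(n, -3, 3)
  f <- runif(n)
  # scalar C/f per call: draw per-row via the shared kernel in blocks
  for (i in seq(1, n, by = 2e4)) {
    j <- i:min(i + 2e4 - 1, n)
    p <- as.matrix(
      occupancy_mixture(alpha[j], C = C[i], f = f[i])[, c("p0", "p1", "p2")]
    )
    expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
    expect_gte(min(p), 0)
  }
})

test_that("C = 1, f = 1 reduces to the binomial distribution", {
  alpha <- c(0, 0.1, 1, 3, 50)
  got <- as.matrix(occupancy_mixture(alpha, 1, 1)[, c("p0", "p1", "p2")])
  want <- cbind(1, 2 * alpha, alpha^2) / (1 + alpha)^2
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("mean sites filled rises monotonically and saturates at 1 + f", {
  expect_equal(mean_sites_filled(0, C = 5, f = 0.85), 0)
  expect_equal(mean_sites_filled(1, C = 1, f = 1), 1)
  expect_equal(mean_sites_filled(1e9, C = 5, f = 1), 2, tolerance = 1e-6)
  for (f in c(0, 0.6, 1)) {
    expect_equal(mean_sites_filled(1e9, C = 5, f = f), 1 + f,
                 tolerance = 1e-6)
    m <- mean_sites_filled(10^seq(-3, 3, length.out = 400), C = 5, f = f)
    expect_true(all(diff(m) > 0))
  }
  # P0 strictly decreasing in alpha
  p0 <- occupancy_mixture(10^seq(-3, 3, length.out = 400), C = 5, f = 0.85)$p0
  expect_true(all(diff(p0) < 0))
})

test_that("second-site Kd scales inversely with cooperativity", {
  expect_equal(second_site_kd(40, 5), 8)
  expect_equal(second_site_kd(40, 1), 40)
  expect_equal(second_site_kd(10, 0.5), 20)
  expect_equal(model_params(40, 5, 0.85)$kd2_nM, 8)
  expect_error(model_params(-1, 5, 0.85), class = "emsacoop_validation_error")
})
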