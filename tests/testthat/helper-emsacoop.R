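# shared fixtures, built in code

# shorthand: simulate one condition with explicit generating parameters
sim_lanes <- function(kd_nM = 40, C = 5, f = 0.85, noise_sd = 0.02,
                      seed = 1L, n_reps = 3, ladder = make_ladder(2.5, 4, 5),
                      name = "test") {
  simulate_titration(
    scenario(name, kd_nM = kd_nM, C = C, f = f, ladder = ladder,
             n_reps = n_reps, noise_sd = noise_sd, seed = seed)
  )
}

# independent occupancy oracle: enumerate the four microstates of a
# two-site probe (empty, site A, site B, both) with Boltzmann weights
# {1, alpha, alpha, C * alpha^2}, normalize, and collapse to counts 0/1/2;
# the mixture adds a one-site species with weights {1, alpha, alpha}
microstate_occupancy <- function(alpha, C, f = 1) {
  two_site <- function(a) {
    w <- c(1, a, a, C * a^2)
    w <- w / sum(w)
    c(w[1], w[2] + w[3], w[4])
  }
  one_site <- function(a) {
    w <- c(1, a, a)  # empty, bound at A, bound at B (no doubly bound state)
    w <- w / sum(w)
    c(w[1], w[2] + w[3], 0)
  }
  t(vapply(alpha, function(a) f * two_site(a) + (1 - f) * one_site(a),
           numeric(3)))
}

expect_tibble_rows <- function(x, n) {
  expect_s3_class(x, "tbl_df")
  expect_identical(nrow(x), as.integer(n))
}
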