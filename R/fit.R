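#' Residuals of the mixture model on a titration series
#'
#' One residual per lane and band: observed normalized fraction minus the
#' mixture-model prediction at that lane's statistical weight
#' `alpha = conc_nM / kd_nM`. Residuals are ordered lane by lane, bands
#' `(p0, p1, p2)` within each lane, so the vector has length
#' `3 * n_lanes`.
#'
#' @param data A titration tibble.
#' @param kd_nM,C,f Model parameters (see [model_params()]).
#' @return Numeric residual vector of length `3 * nrow(data)`.
#' @examples
#' lanes <- simulate_titration(scenario("demo", 40, 5, 0.85, noise_sd = 0))
#' max(abs(residual_vector(lanes, kd_nM = 40, C = 5, f = 0.85)))
#' @export
residual_vector <- function(data, kd_nM, C, f) {
  data <- normalize_lanes(data)
  check_scalar_positive(kd_nM, "kd_nM")
  check_scalar_positive(C, "C")
  check_fraction(f, "f")
  obs <- cbind(data$p0, data$p1, data$p2)
  pred <- occupancy_probs(data$conc_nM / kd_nM, C, f)
  as.vector(t(obs - pred))
}

# residuals on the transformed parameter scale used by the optimizer:
# theta = (log10 Kd, log10 C, f). Optional per-observation weights
# (already expanded to length 3 * n_lanes) enter as sqrt(w) * residual.
theta_residuals <- function(theta, conc, obs, sqrt_w = NULL) {
  pred <- occupancy_probs(conc / 10^theta[1L], 10^theta[2L], theta[3L])
  r <- as.vector(t(obs - pred))
  if (!is.null(sqrt_w)) r <- r * sqrt_w
  r
}

#' Fit the two-site cooperative binding model to a titration series
#'
#' Estimates `(Kd, C, f)` by bounded nonlinear least squares on the
#' normalized band fractions of all lanes of one condition. The objective
#' is minimized with Levenberg-Marquardt ([minpack.lm::nls.lm()]) over the
#' transformed parameters `(log10 Kd, log10 C, f)` from a fixed,
#' deterministic grid of starting points (Kd over the decades spanned by
#' the ladder, C in \{0.1, 1, 10\}, f in \{0.5, 0.9\}); the best final sum
#' of squares wins, with ties broken toward the C closest to 1 (the
#' conservative, no-cooperativity reading). Identical inputs and options
#' always reproduce the identical fit.
#'
#' @param data A titration tibble; at least 3 distinct concentrations are
#'   required to constrain 3 parameters.
#' @param weighted If `TRUE`, observations are weighted by the inverse
#'   variance of the replicate fractions per (concentration, band)
#'   (SDs floored at `sd_floor`). Default unweighted.
#' @param use_means If `TRUE`, fit the replicate means per concentration
#'   instead of every lane. Default fits all lanes.
#' @param kd_bounds,C_bounds Box bounds on Kd (nM) and C.
#' @param sd_floor Lower floor on replicate SDs used for weighting.
#' @param start Optional single starting point `c(kd_nM, C, f)` replacing
#'   the multistart grid (used internally by bootstrap refits).
#' @return An object of class `emsa_fit`: point estimates (`params`),
#'   residual sum of squares (`ssr`), `n_points`, `converged`, `n_starts`,
#'   and `at_bound` (names of parameters pinned at a box bound).
#' @examples
#' fit <- fit_titration(simulate_titration(preset_scenarios()$wt_sps))
#' fit
#' @export
fit_titration <- function(data, weighted = FALSE, use_means = FALSE,
                          kd_bounds = c(1e-3, 1e6), C_bounds = c(1e-3, 1e3),
                          sd_floor = 1e-3, start = NULL) {
  data <- normalize_lanes(data)
  if (length(unique(data$condition)) != 1L) {
    rlang::abort("`fit_titration()` fits one condition at a time; split first.",
                 class = "emsacoop_validation_error")
  }
  if (length(unique(data$conc_nM)) < 3L) {
    rlang::abort(
      "At least 3 distinct concentrations are needed to constrain Kd, C and f.",
      class = "emsacoop_identifiability_error"
    )
  }

  sqrt_w <- NULL
  if (weighted || use_means) summ <- summarize_replicates(data)
  if (use_means) {
    fit_data <- tibble::tibble(
      condition = data$condition[1L], conc_nM = summ$conc_nM, replicate = 1L,
      p0 = summ$mean0, p1 = summ$mean1, p2 = summ$mean2
    )
  } else {
    fit_data <- data
  }
  if (weighted) {
    idx <- match(fit_data$conc_nM, summ$conc_nM)
    sd_mat <- pmax(cbind(summ$sd0, summ$sd1, summ$sd2)[idx, , drop = FALSE],
                   sd_floor)
    sqrt_w <- as.vector(t(1 / sd_mat))
  }

  conc <- fit_data$conc_nM
  obs <- cbind(fit_data$p0, fit_data$p1, fit_data$p2)
  lower <- c(log10(kd_bounds[1L]), log10(C_bounds[1L]), 0)
  upper <- c(log10(kd_bounds[2L]), log10(C_bounds[2L]), 1)

  starts <- if (is.null(start)) {
    multistart_grid(conc, lower, upper)
  } else {
    matrix(c(log10(start[1L]), log10(start[2L]), start[3L]), nrow = 1L)
  }

  run_one <- function(theta0) {
    out <- tryCatch(
      minpack.lm::nls.lm(
        par = theta0, lower = lower, upper = upper,
        fn = theta_residuals, conc = conc, obs = obs, sqrt_w = sqrt_w,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(out) || !is.finite(out$deviance)) return(NULL)
    list(theta = unname(out$par), ssr = out$deviance,
         converged = out$info %in% 1:3)
  }
  cand <- purrr::compact(purrr::map(seq_len(nrow(starts)),
                                    function(i) run_one(starts[i, ])))
  if (length(cand) == 0) {
    rlang::abort("All optimizer starts failed.",
                 class = "emsacoop_identifiability_error")
  }
  ssrs <- purrr::map_dbl(cand, "ssr")
  best_ssr <- min(ssrs)
  # tie rule: among numerically tied minima pick the C closest to 1
  tied <- which(ssrs <= best_ssr + 1e-12 + 1e-9 * best_ssr)
  pick <- tied[which.min(abs(purrr::map_dbl(cand[tied], ~ .x$theta[2L])))]
  best <- cand[[pick]]

  theta <- best$theta
  tol <- 1e-6
  at_bound <- c(
    if (theta[1L] - lower[1L] < tol || upper[1L] - theta[1L] < tol) "kd_nM",
    if (theta[2L] - lower[2L] < tol || upper[2L] - theta[2L] < tol) "C",
    if (theta[3L] < tol || 1 - theta[3L] < tol) "f"
  )

  structure(
    list(
      params = model_params(10^theta[1L], 10^theta[2L], theta[3L]),
      ssr = best$ssr,
      n_points = length(conc) * 3L,
      converged = best$converged,
      n_starts = nrow(starts),
      at_bound = as.character(at_bound),
      condition = fit_data$condition[1L],
      data = data,
      options = list(weighted = weighted, use_means = use_means,
                     kd_bounds = kd_bounds, C_bounds = C_bounds)
    ),
    class = "emsa_fit"
  )
}

# deterministic start grid: Kd at each decade spanned by the ladder,
# C in {0.1, 1, 10}, f in {0.5, 0.9}; clipped into the box.
multistart_grid <- function(conc, lower, upper) {
  pos <- conc[conc > 0]
  lkd <- if (length(pos) > 0) {
    seq(floor(log10(min(pos))), ceiling(log10(max(pos))))
  } else {
    0:2
  }
  g <- as.matrix(expand.grid(
    lkd = pmin(pmax(lkd, lower[1L]), upper[1L]),
    lC = pmin(pmax(c(-1, 0, 1), lower[2L]), upper[2L]),
    f = c(0.5, 0.9)
  ))
  unname(g)
}

#' Brute-force grid search over the model parameters
#'
#' Exhaustively evaluates the (unweighted) sum of squared residuals on a
#' finite grid over `(log10 Kd, log10 C, f)` and returns the grid argmin.
#' This is an independent check on [fit_titration()]: the optimizer's SSR
#' must never exceed the best grid point's. Used in validation, not as an
#' estimator.
#'
#' @param data A titration tibble (single condition).
#' @param kd_grid,C_grid Positive grids for Kd (nM) and C; defaults are
#'   log-spaced, 40 points each, over Kd 0.1--10000 nM and C 0.001--1000.
#' @param f_grid Grid for f in `[0, 1]`; default 20 equispaced points.
#' @return A list with `params` (one-row tibble at the argmin), `ssr`, and
#'   `n_grid`.
#' @export
grid_oracle <- function(data,
                        kd_grid = 10^seq(-1, 4, length.out = 40),
                        C_grid = 10^seq(-3, 3, length.out = 40),
                        f_grid = seq(0, 1, length.out = 20)) {
  data <- normalize_lanes(data)
  if (length(kd_grid) < 1 || length(C_grid) < 1 || length(f_grid) < 1) {
    rlang::abort("Empty parameter grid.", class = "emsacoop_validation_error")
  }
  conc <- data$conc_nM
  obs0 <- data$p0; obs1 <- data$p1; obs2 <- data$p2
  L <- length(conc)
  kc <- expand.grid(kd = kd_grid, C = C_grid)
  G <- nrow(kc)
  # G x L matrices; length-G parameter vectors recycle down columns
  alpha <- outer(1 / kc$kd, conc)
  d1 <- 1 + 2 * alpha
  d2 <- d1 + kc$C * alpha^2
  m0 <- matrix(obs0, G, L, byrow = TRUE)
  m1 <- matrix(obs1, G, L, byrow = TRUE)
  m2 <- matrix(obs2, G, L, byrow = TRUE)
  best <- list(ssr = Inf)
  for (f in f_grid) {
    p0 <- f / d2 + (1 - f) / d1
    p1 <- 2 * alpha * (f / d2 + (1 - f) / d1)
    p2 <- f * kc$C * alpha^2 / d2
    ssr <- rowSums((p0 - m0)^2 + (p1 - m1)^2 + (p2 - m2)^2)
    i <- which.min(ssr)
    if (ssr[i] < best$ssr) {
      best <- list(ssr = ssr[i], kd = kc$kd[i], C = kc$C[i], f = f)
    }
  }
  list(params = model_params(best$kd, best$C, best$f),
       ssr = best$ssr,
       n_grid = G * length(f_grid))
}

#' @export
print.emsa_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<emsa_fit> condition: %s\n", x$condition))
  cat(sprintf("  Kd = %.4g nM, C = %.4g (second-site Kd = %.4g nM), f = %.4g\n",
              p$kd_nM, p$C, p$kd2_nM, p$f))
  cat(sprintf("  SSR = %.4g over %d residuals; converged: %s; starts: %d\n",
              x$ssr, x$n_points, x$converged, x$n_starts))
  if (length(x$at_bound) > 0) {
    cat(sprintf("  at bound: %s\n", paste(x$at_bound, collapse = ", ")))
  }
  invisible(x)
}
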