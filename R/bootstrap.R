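#' Draw one synthetic replicate of a titration series
#'
#' Generates a parametric resample with the same statistical properties as
#' the observed data: for each lane of the design and each band, a Gaussian
#' draw with that (concentration, band)'s replicate mean and SD of the
#' normalized fractions, truncated at zero, and renormalized per lane.
#' Lane structure (concentrations, replicates) follows `design`.
#' Deterministic per seed.
#'
#' @param summary A replicate summary from [summarize_replicates()].
#' @param design A titration tibble supplying the lane structure (usually
#'   the observed series the summary came from).
#' @param seed Integer seed.
#' @param sd_override Optional single SD replacing the summary SDs, needed
#'   when the summary comes from single replicates (SD unestimable).
#' @return A titration tibble with the same rows as `design`.
#' @export
resample_titration <- function(summary, design, seed, sd_override = NULL) {
  design <- validate_titration(design)
  if (any(summary$single_replicate) && is.null(sd_override)) {
    rlang::abort(
      paste("Summary has single-replicate concentrations: their SD cannot be",
            "estimated, so resampling would be noiseless there. Supply",
            "`sd_override` or provide replicate lanes."),
      class = "emsacoop_validation_error"
    )
  }
  idx <- match(design$conc_nM, summary$conc_nM)
  if (anyNA(idx)) {
    rlang::abort("`design` has concentrations absent from `summary`.",
                 class = "emsacoop_validation_error")
  }
  mean_mat <- cbind(summary$mean0, summary$mean1, summary$mean2)[idx, , drop = FALSE]
  sd_mat <- if (is.null(sd_override)) {
    cbind(summary$sd0, summary$sd1, summary$sd2)[idx, , drop = FALSE]
  } else {
    matrix(sd_override, nrow(design), 3L)
  }
  n <- nrow(design)
  draws <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(3L * n, mean = as.vector(mean_mat),
                        sd = as.vector(sd_mat)), nrow = n, ncol = 3L)
  })
  draws[draws < 0] <- 0
  total <- rowSums(draws)
  dead <- total <= 0
  if (any(dead)) {
    draws[dead, ] <- mean_mat[dead, , drop = FALSE]
    total[dead] <- rowSums(draws[dead, , drop = FALSE])
  }
  frac <- draws / total
  lane_total <- 10000
  tibble::tibble(
    condition = design$condition,
    conc_nM = design$conc_nM,
    replicate = design$replicate,
    band0 = frac[, 1L] * lane_total,
    band1 = frac[, 2L] * lane_total,
    band2 = frac[, 3L] * lane_total
  )
}

# fixed seed-splitting rule: resample i of master seed s always gets the
# same sub-seed, so increasing n_boot extends rather than reshuffles
boot_subseed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * as.double(i)) %% 2147483647)
}

#' Percentile bootstrap confidence intervals for (Kd, C, f)
#'
#' Generates `n_boot` synthetic datasets with the same per-(concentration,
#' band) mean and SD as the fitted series ([resample_titration()]), refits
#' the model to each, and reports percentile confidence intervals of the
#' resampled estimates. Defaults follow the standard protocol: 5,000
#' resamples, 95% intervals. Refits start from the point estimate by
#' default (`refit_multistart = TRUE` restores the full start grid at
#' roughly 20x the cost). Bit-reproducible for a given
#' `(fit, n_boot, seed)`.
#'
#' @param fit An `emsa_fit` from [fit_titration()].
#' @param n_boot Number of resamples, `>= 2` (default 5000).
#' @param seed Master integer seed; per-resample seeds are derived by a
#'   fixed splitting rule.
#' @param level Confidence level (default 0.95).
#' @param sd_override Passed to [resample_titration()].
#' @param refit_multistart Use the full multistart grid for every refit.
#' @return An object of class `emsa_boot`: `estimates` (tibble of
#'   per-resample `kd_nM`, `C`, `f`), `ci` (tibble of per-parameter
#'   percentile bounds), `n_boot`, `n_failed`, `seed`, `level`, and the
#'   originating point estimates.
#' @examples
#' fit <- fit_titration(simulate_titration(preset_scenarios()$wt_sps))
#' bootstrap_titration(fit, n_boot = 50, seed = 7)
#' @export
bootstrap_titration <- function(fit, n_boot = 5000, seed = 1L, level = 0.95,
                                sd_override = NULL, refit_multistart = FALSE) {
  stopifnot(inherits(fit, "emsa_fit"))
  if (n_boot < 2) {
    rlang::abort("`n_boot` must be at least 2.",
                 class = "emsacoop_validation_error")
  }
  if (level <= 0 || level >= 1) {
    rlang::abort("`level` must be in (0, 1).",
                 class = "emsacoop_validation_error")
  }
  summary <- summarize_replicates(fit$data)
  design <- fit$data
  p <- fit$params
  start <- if (refit_multistart) NULL else c(p$kd_nM, p$C, p$f)

  one <- function(i) {
    res <- resample_titration(summary, design, seed = boot_subseed(seed, i),
                              sd_override = sd_override)
    refit <- tryCatch(
      fit_titration(res, weighted = fit$options$weighted,
                    use_means = fit$options$use_means,
                    kd_bounds = fit$options$kd_bounds,
                    C_bounds = fit$options$C_bounds,
                    start = start),
      error = function(e) NULL
    )
    if (is.null(refit)) return(NULL)
    q <- refit$params
    c(kd_nM = q$kd_nM, C = q$C, f = q$f)
  }
  rows <- purrr::compact(purrr::map(seq_len(n_boot), one))
  n_failed <- n_boot - length(rows)
  if (n_failed > n_boot / 2) {
    rlang::abort(
      sprintf("Bootstrap failed: %d of %d resample refits did not converge.",
              n_failed, n_boot),
      class = "emsacoop_identifiability_error"
    )
  }
  est <- tibble::as_tibble(do.call(rbind, rows))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- tibble::tibble(
    term = c("kd_nM", "C", "f"),
    lower = purrr::map_dbl(c("kd_nM", "C", "f"),
                           ~ stats::quantile(est[[.x]], probs[1L], names = FALSE)),
    upper = purrr::map_dbl(c("kd_nM", "C", "f"),
                           ~ stats::quantile(est[[.x]], probs[2L], names = FALSE))
  )
  structure(
    list(estimates = est, ci = ci, n_boot = as.integer(n_boot),
         n_failed = as.integer(n_failed), seed = as.integer(seed),
         level = level, point = fit$params, condition = fit$condition),
    class = "emsa_boot"
  )
}

#' @export
print.emsa_boot <- function(x, ...) {
  cat(sprintf("<emsa_boot> condition: %s; %d resamples (%d failed); %.0f%% CIs\n",
              x$condition, x$n_boot, x$n_failed, 100 * x$level))
  for (i in seq_len(nrow(x$ci))) {
    cat(sprintf("  %-6s [%.4g, %.4g]\n",
                x$ci$term[i], x$ci$lower[i], x$ci$upper[i]))
  }
  invisible(x)
}
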