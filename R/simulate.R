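#' Geometric concentration ladder
#'
#' Builds the titration ladder `start * fold^(0:(n-1))`, matching the
#' assay design of fixed fold-steps between lanes. The standard design is
#' `make_ladder(2.5, 4, 5)`: 4-fold steps from 2.5 to 640 nM.
#'
#' @param start First concentration, nM, `> 0`.
#' @param fold Multiplicative step, `> 1`.
#' @param n Number of concentrations, `>= 1`.
#' @return Strictly increasing numeric vector of length `n`.
#' @examples
#' make_ladder(2.5, 4, 5)
#' @export
make_ladder <- function(start, fold, n) {
  check_scalar_positive(start, "start")
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) || fold <= 1) {
    rlang::abort("`fold` must be a single number > 1.",
                 class = "emsacoop_validation_error")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    rlang::abort("`n` must be a positive integer.",
                 class = "emsacoop_validation_error")
  }
  start * fold^(seq_len(n) - 1)
}

#' Define a synthetic titration scenario
#'
#' A scenario bundles everything needed to simulate one EMSA titration:
#' the generating parameters, the concentration ladder, the replicate
#' count, the noise level on the fraction scale, and a seed.
#'
#' @param name Condition label written into the simulated table.
#' @param kd_nM,C,f Generating binding parameters (see [model_params()]).
#' @param ladder Strictly increasing positive concentrations, nM.
#' @param n_reps Replicate lanes per concentration, `>= 1`.
#' @param noise_sd SD of additive Gaussian noise on the normalized
#'   fractions, `>= 0`.
#' @param seed Integer seed making the simulation reproducible.
#' @return An object of class `emsa_scenario` (a named list).
#' @examples
#' scenario("demo", kd_nM = 40, C = 5, f = 0.85)
#' @export
scenario <- function(name, kd_nM, C, f,
                     ladder = make_ladder(2.5, 4, 5),
                     n_reps = 3, noise_sd = 0.02, seed = 1L) {
  check_scalar_positive(kd_nM, "kd_nM")
  check_scalar_positive(C, "C")
  check_fraction(f, "f")
  if (length(ladder) < 1 || any(!is.finite(ladder)) || any(ladder <= 0) ||
      is.unsorted(ladder, strictly = TRUE)) {
    rlang::abort("`ladder` must be strictly increasing and positive.",
                 class = "emsacoop_validation_error")
  }
  if (n_reps < 1 || n_reps != round(n_reps)) {
    rlang::abort("`n_reps` must be a positive integer.",
                 class = "emsacoop_validation_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0 || !is.finite(noise_sd)) {
    rlang::abort("`noise_sd` must be a nonnegative number.",
                 class = "emsacoop_validation_error")
  }
  structure(
    list(name = name, kd_nM = kd_nM, C = C, f = f,
         ladder = as.numeric(ladder), n_reps = as.integer(n_reps),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "emsa_scenario"
  )
}

#' @export
print.emsa_scenario <- function(x, ...) {
  cat(sprintf(
    "<emsa_scenario> %s: Kd = %g nM, C = %g, f = %g\n  ladder: %s nM; %d rep(s); noise SD %g; seed %d\n",
    x$name, x$kd_nM, x$C, x$f, paste(x$ladder, collapse = ", "),
    x$n_reps, x$noise_sd, x$seed))
  invisible(x)
}

#' Simulate an EMSA titration series
#'
#' For every concentration and replicate the generator evaluates the
#' mixture-model occupancy fractions, adds independent Gaussian noise
#' (`noise_sd`) to each of the three fractions, clips negatives at zero,
#' renormalizes the lane to sum to one, and scales by a constant per-lane
#' total of 10,000 arbitrary densitometry units. Deterministic per seed;
#' the caller's RNG state is untouched.
#'
#' @param scen An [scenario()] object.
#' @param seed Optional seed overriding `scen$seed`.
#' @return A titration tibble in the standard lane schema.
#' @examples
#' simulate_titration(scenario("demo", 40, 5, 0.85, noise_sd = 0))
#' @export
simulate_titration <- function(scen, seed = NULL) {
  stopifnot(inherits(scen, "emsa_scenario"))
  seed <- if (is.null(seed)) scen$seed else as.integer(seed)
  design <- tidyr::expand_grid(conc_nM = scen$ladder,
                               replicate = seq_len(scen$n_reps))
  alpha <- statistical_weight(design$conc_nM, scen$kd_nM)
  p <- occupancy_probs(alpha, scen$C, scen$f)
  n <- nrow(design)
  noisy <- withr::with_seed(seed, {
    p + matrix(stats::rnorm(3L * n, sd = scen$noise_sd), nrow = n, ncol = 3L)
  })
  noisy[noisy < 0] <- 0
  total <- rowSums(noisy)
  # a lane where all three noisy fractions clipped to zero reverts to its mean
  dead <- total <= 0
  if (any(dead)) {
    noisy[dead, ] <- p[dead, ]
    total[dead] <- 1
  }
  frac <- noisy / total
  lane_total <- 10000
  tibble::tibble(
    condition = scen$name,
    conc_nM = design$conc_nM,
    replicate = design$replicate,
    band0 = frac[, 1L] * lane_total,
    band1 = frac[, 2L] * lane_total,
    band2 = frac[, 3L] * lane_total
  )
}

#' Preset scenarios mirroring the standard assay conditions
#'
#' Four conditions on the shared 4-fold ladder 2.5-640 nM, three replicate
#' lanes each: a cooperative wild-type complex on a sequence-paired-site
#' probe (`wt_sps`, C = 5), the dimerization-deficient complex on the same
#' probe (`ra_sps`, C = 1), and both complexes on a tandem two-site CSL
#' probe where binding is independent (`wt_2xcsl`, `ra_2xcsl`, C = 1).
#' Kd = 40 nM (mid-ladder, maximally identifiable) and f = 0.85 are
#' synthetic defaults chosen inside the identifiable range; they are not
#' measured values.
#'
#' @param noise_sd Noise SD shared by all presets (default 0.02).
#' @return Named list of [scenario()] objects.
#' @examples
#' preset_scenarios()$wt_sps
#' @export
preset_scenarios <- function(noise_sd = 0.02) {
  ladder <- make_ladder(2.5, 4, 5)
  mk <- function(name, C, seed) {
    scenario(name, kd_nM = 40, C = C, f = 0.85, ladder = ladder,
             n_reps = 3, noise_sd = noise_sd, seed = seed)
  }
  list(
    wt_sps   = mk("wt_sps",   C = 5, seed = 101L),
    ra_sps   = mk("ra_sps",   C = 1, seed = 102L),
    wt_2xcsl = mk("wt_2xcsl", C = 1, seed = 103L),
    ra_2xcsl = mk("ra_2xcsl", C = 1, seed = 104L)
  )
}

#' Load a scenario from a YAML or JSON config file
#'
#' The file must define the [scenario()] fields by name (`name`, `kd_nM`,
#' `C`, `f`, `ladder`, `n_reps`, `noise_sd`, `seed`); missing optional
#' fields take the constructor defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `emsa_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Scenario file not found: %s", path),
                 class = "emsacoop_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      rlang::abort("Package `yaml` is required for YAML scenario files.",
                   class = "emsacoop_io_error")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    rlang::abort("Scenario file must be .yaml, .yml or .json.",
                 class = "emsacoop_schema_error")
  }
  needed <- c("name", "kd_nM", "C", "f")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Scenario file missing field(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "emsacoop_schema_error")
  }
  args <- raw[intersect(names(raw),
                        c(needed, "ladder", "n_reps", "noise_sd", "seed"))]
  do.call(scenario, args)
}
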