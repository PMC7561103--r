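#' Assemble a run configuration
#'
#' Normalizes the options shared by the pipeline drivers [run_simulate()],
#' [run_fit()], [run_bootstrap()] and [run_report()]. `config` may be a
#' named list or a path to a YAML/JSON file with the same field names.
#'
#' @param config Named list or file path. Recognized fields: `input`
#'   (CSV path), `scenario` (preset name), `scenario_file` (YAML/JSON
#'   scenario), `n_boot`, `seed`, `level`, `out_dir`, `weighted`,
#'   `use_means`, `c_band` (the descriptive no-cooperativity band around
#'   C = 1), `verbosity`.
#' @return A list of class `emsa_config` with defaults filled in.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        rlang::abort("Package `yaml` is required for YAML config files.",
                     class = "emsacoop_io_error")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(
    input = NULL, scenario = NULL, scenario_file = NULL,
    n_boot = 5000L, seed = 1L, level = 0.95, out_dir = ".",
    weighted = FALSE, use_means = FALSE, c_band = c(0.8, 1.25),
    verbosity = 1L
  )
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  if (cfg$n_boot < 2) {
    rlang::abort("`n_boot` must be at least 2.",
                 class = "emsacoop_validation_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "emsa_config")
}

log_msg <- function(cfg, ...) {
  if (isTRUE(cfg$verbosity >= 1L)) message(sprintf(...))
}

ensure_out_dir <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) {
    ok <- dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      rlang::abort(sprintf("Cannot create output directory: %s", cfg$out_dir),
                   class = "emsacoop_io_error")
    }
  }
  invisible(cfg$out_dir)
}

file_checksum <- function(path) unname(tools::md5sum(path))

# provenance block embedded in every artifact so a run can be reproduced
provenance <- function(cfg, input_path = NULL) {
  out <- list(
    package = "emsacoop",
    version = as.character(utils::packageVersion("emsacoop")),
    seed = cfg$seed
  )
  if (!is.null(input_path)) out$input_md5 <- file_checksum(input_path)
  out
}

#' Simulate a scenario and write it to disk
#'
#' Resolves the scenario (preset name or scenario file), simulates it with
#' the configured seed, and writes the lanes as CSV plus a JSON manifest
#' recording the scenario, seed, package version and output checksum.
#'
#' @param config See [run_config()]. Requires `scenario` or
#'   `scenario_file`.
#' @return Invisibly, a list with the simulated tibble and the file paths.
#' @export
run_simulate <- function(config = list()) {
  cfg <- run_config(config)
  presets <- preset_scenarios()
  scen <- if (!is.null(cfg$scenario_file)) {
    read_scenario(cfg$scenario_file)
  } else if (!is.null(cfg$scenario)) {
    if (!cfg$scenario %in% names(presets)) {
      rlang::abort(
        sprintf("Unknown scenario `%s`. Available presets: %s.",
                cfg$scenario, paste(names(presets), collapse = ", ")),
        class = "emsacoop_schema_error"
      )
    }
    presets[[cfg$scenario]]
  } else {
    rlang::abort("Provide `scenario` or `scenario_file`.",
                 class = "emsacoop_schema_error")
  }
  ensure_out_dir(cfg)
  lanes <- simulate_titration(scen, seed = cfg$seed)
  csv_path <- file.path(cfg$out_dir, paste0(scen$name, ".csv"))
  write_titration(lanes, csv_path)
  manifest <- c(
    provenance(cfg),
    list(scenario = unclass(scen), n_lanes = nrow(lanes),
         output = basename(csv_path), output_md5 = file_checksum(csv_path))
  )
  manifest_path <- file.path(cfg$out_dir, paste0(scen$name, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_msg(cfg, "Simulated %d lanes of `%s` -> %s", nrow(lanes), scen$name,
          csv_path)
  invisible(list(lanes = lanes, csv = csv_path, manifest = manifest_path))
}

fit_json_list <- function(fit, cfg, input_path) {
  p <- fit$params
  c(provenance(cfg, input_path), list(
    condition = fit$condition,
    kd_nM = p$kd_nM, C = p$C, f = p$f, kd2_nM = p$kd2_nM,
    ssr = fit$ssr, n_points = fit$n_points, converged = fit$converged,
    n_starts = fit$n_starts, at_bound = as.list(fit$at_bound)
  ))
}

#' Fit every condition in an input table and report cooperativity
#'
#' Reads the configured CSV, fits the mixture model per condition, writes
#' one FitResult JSON per condition, and prints a summary table with the
#' cooperativity readout: the estimated fold-change in second-site
#' affinity (C, shown to 1 significant figure as "~N-fold") and a
#' descriptive no-cooperativity call for C inside `c_band`
#' (default `[0.8, 1.25]`).
#'
#' @param config See [run_config()]. Requires `input`.
#' @return Invisibly, a list with the fits and a summary tibble.
#' @export
run_fit <- function(config = list()) {
  cfg <- run_config(config)
  if (is.null(cfg$input)) {
    rlang::abort("`input` CSV path is required.",
                 class = "emsacoop_schema_error")
  }
  ensure_out_dir(cfg)
  lanes <- read_titration(cfg$input)
  fits <- lanes |>
    dplyr::group_split(.data$condition) |>
    purrr::map(~ fit_titration(.x, weighted = cfg$weighted,
                               use_means = cfg$use_means))
  paths <- purrr::map_chr(fits, function(fit) {
    path <- file.path(cfg$out_dir, paste0(fit$condition, "_fit.json"))
    jsonlite::write_json(fit_json_list(fit, cfg, cfg$input), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    path
  })
  summary <- purrr::map_dfr(fits, glance) |>
    dplyr::mutate(
      fold = paste0("~", signif(.data$C, 1), "-fold"),
      cooperativity = dplyr::case_when(
        .data$C >= cfg$c_band[1L] & .data$C <= cfg$c_band[2L] ~
          "none (C ~ 1)",
        .data$C > cfg$c_band[2L] ~ "positive",
        TRUE ~ "negative"
      )
    )
  print(summary)
  cat(sprintf("(no-cooperativity band: C in [%g, %g])\n",
              cfg$c_band[1L], cfg$c_band[2L]))
  invisible(list(fits = fits, summary = summary, paths = paths))
}

boot_json_list <- function(boot, cfg, input_path) {
  ci <- boot$ci
  ci_list <- stats::setNames(
    purrr::map(seq_len(nrow(ci)), ~ c(ci$lower[.x], ci$upper[.x])),
    ci$term
  )
  p <- boot$point
  c(provenance(cfg, input_path), list(
    condition = boot$condition,
    kd_nM = p$kd_nM, C = p$C, f = p$f,
    n_boot = boot$n_boot, n_failed = boot$n_failed,
    ci_level = boot$level, ci = ci_list
  ))
}

#' Bootstrap confidence intervals for every condition in an input table
#'
#' Fits each condition, runs the percentile bootstrap (default 5,000
#' resamples at 95%), writes one BootstrapResult JSON per condition, and
#' prints the CI table.
#'
#' @param config See [run_config()]. Requires `input`; honors `n_boot`,
#'   `seed`, `level`.
#' @return Invisibly, a list with the `emsa_boot` objects and paths.
#' @export
run_bootstrap <- function(config = list()) {
  cfg <- run_config(config)
  if (is.null(cfg$input)) {
    rlang::abort("`input` CSV path is required.",
                 class = "emsacoop_schema_error")
  }
  ensure_out_dir(cfg)
  lanes <- read_titration(cfg$input)
  boots <- lanes |>
    dplyr::group_split(.data$condition) |>
    purrr::map(function(d) {
      fit <- fit_titration(d, weighted = cfg$weighted,
                           use_means = cfg$use_means)
      bootstrap_titration(fit, n_boot = cfg$n_boot, seed = cfg$seed,
                          level = cfg$level)
    })
  paths <- purrr::map_chr(boots, function(boot) {
    path <- file.path(cfg$out_dir, paste0(boot$condition, "_bootstrap.json"))
    jsonlite::write_json(boot_json_list(boot, cfg, cfg$input), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    path
  })
  for (boot in boots) print(tidy(boot))
  invisible(list(boots = boots, paths = paths))
}

#' Render occupancy-curve figures for every condition
#'
#' Fits each condition of the configured input and saves one occupancy
#' figure per condition (observed mean sites filled with the fitted curve,
#' see [autoplot.emsa_fit()]) into the output directory.
#'
#' @param config See [run_config()]. Requires `input`.
#' @param device Figure format, `"pdf"` (default) or `"png"`.
#' @return Invisibly, the written figure paths.
#' @export
run_report <- function(config = list(), device = c("pdf", "png")) {
  cfg <- run_config(config)
  device <- match.arg(device)
  if (is.null(cfg$input)) {
    rlang::abort("`input` CSV path is required.",
                 class = "emsacoop_schema_error")
  }
  ensure_out_dir(cfg)
  lanes <- read_titration(cfg$input)
  paths <- lanes |>
    dplyr::group_split(.data$condition) |>
    purrr::map_chr(function(d) {
      fit <- fit_titration(d, weighted = cfg$weighted,
                           use_means = cfg$use_means)
      path <- file.path(cfg$out_dir,
                        paste0(fit$condition, "_occupancy.", device))
      ggplot2::ggsave(path, autoplot(fit), width = 5, height = 4)
      log_msg(cfg, "Wrote %s", path)
      path
    })
  invisible(paths)
}
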