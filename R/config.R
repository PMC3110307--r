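# Run configuration: YAML in, scenario specs + options out.

#' Built-in run presets
#'
#' Named shortcuts for common runs:
#' \describe{
#'   \item{`full`}{all 100 scenarios at 1825 replicates with the study's
#'     cohort sizes.}
#'   \item{`desk_null`}{the 20 null scenarios at 400 replicates (type-I
#'     error screening).}
#'   \item{`desk_grid`}{all 100 scenarios at 150 replicates with the weak
#'     scenarios' initial cohort size reduced to 2500 (full-surface
#'     screening at desk scale).}
#' }
#'
#' @param name preset name.
#' @return list with `specs` (list of `scenario_spec`) and `n_replicates`.
#' @export
run_preset <- function(name = c("full", "desk_null", "desk_grid")) {
  name <- match.arg(name)
  switch(name,
    full = list(specs = scenario_grid(1825L), n_replicates = 1825L),
    desk_null = list(specs = null_grid(400L), n_replicates = 400L),
    desk_grid = {
      specs <- lapply(scenario_grid(150L), function(s) {
        if (s$selection_strength == "weak") s$n_initial <- 2500L
        s
      })
      list(specs = specs, n_replicates = 150L)
    }
  )
}

#' Read a run configuration file
#'
#' Parses a YAML configuration describing a run. Recognised keys:
#' `preset` (see [run_preset()]), `master_seed`, `n_replicates`,
#' `caliper_multiplier`, `allocation` (list of 10 levels),
#' `calibration` (`m`, `seed`, `tol`), and `scenarios` — either the string
#' `"all"`/`"null"` or a list of cells with keys `covariate_scenario`,
#' `selection_strength`, `baseline_outcome_prob`, `target_rd`, and optional
#' `n_initial`, `control_copies`. Explicit keys override the preset.
#'
#' @param path path to a YAML file.
#' @return list with `specs`, `master_seed`, `caliper_multiplier`,
#'   `allocation`, `calibration_m`, `calibration_seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- if (!is.null(cfg$preset)) run_preset(cfg$preset) else NULL
  specs <- if (!is.null(cfg$scenarios)) {
    if (identical(cfg$scenarios, "all")) {
      scenario_grid()
    } else if (identical(cfg$scenarios, "null")) {
      null_grid()
    } else {
      lapply(cfg$scenarios, function(s) {
        do.call(scenario_spec, s)
      })
    }
  } else if (!is.null(base)) {
    base$specs
  } else {
    scenario_grid()
  }
  n_reps <- cfg$n_replicates
  if (!is.null(n_reps)) {
    specs <- lapply(specs, function(s) {
      s$n_replicates <- as.integer(n_reps)
      s
    })
  }
  allocation <- if (!is.null(cfg$allocation)) {
    unlist(cfg$allocation)
  } else {
    default_allocation()
  }
  list(
    specs = specs,
    master_seed = if (!is.null(cfg$master_seed)) {
      as.integer(cfg$master_seed)
    } else {
      1L
    },
    caliper_multiplier = if (!is.null(cfg$caliper_multiplier)) {
      cfg$caliper_multiplier
    } else {
      0.2
    },
    allocation = allocation,
    calibration_m = if (!is.null(cfg$calibration$m)) cfg$calibration$m else 1e6,
    calibration_seed = if (!is.null(cfg$calibration$seed)) {
      as.integer(cfg$calibration$seed)
    } else {
      904200L
    }
  )
}

#' Write / read a calibration table
#'
#' Calibrated coefficient sets are serialised as a human-readable
#' tab-delimited table (one row per scenario cell) for reuse across runs.
#'
#' @param coeffs_table a data frame from [calibrate_grid()].
#' @param path file path.
#' @return `write_coefficients` returns the path invisibly;
#'   `read_coefficients` the table.
#' @export
write_coefficients <- function(coeffs_table, path) {
  utils::write.table(coeffs_table, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
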