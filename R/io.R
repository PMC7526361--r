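#' Read and write patient-record tables
#'
#' Patient records travel as comma-separated text with a header row
#' (columns `arm`, `age`, `postmenopausal`, `grade2`, `grade3`,
#' `treated`, `time`, `event`; times in days, full double precision).
#' Reading validates the schema and flags the first offending row of any
#' malformed column.
#'
#' @param path File path.
#' @param records Patient-record tibble (extra columns such as
#'   `latent_time` are dropped on write).
#' @return `read_ipd()` returns the validated tibble; `write_ipd()`
#'   returns `path` invisibly.
#' @export
read_ipd <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  required <- c("arm", "age", "postmenopausal", "grade2", "grade3",
                "treated", "time", "event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("IPD file %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "maicsim_parse_error")
  }
  if (nrow(df) == 0) {
    df[required] <- lapply(df[required], as.numeric)
    return(df[required])
  }
  for (col in c("age", "time")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      abort(sprintf("IPD file %s: non-numeric `%s` at data row %d",
                    path, col, bad),
            class = "maicsim_parse_error")
    }
  }
  for (col in c("postmenopausal", "grade2", "grade3", "treated", "event")) {
    ok <- df[[col]] %in% c(0, 1)
    if (!all(ok)) {
      abort(sprintf("IPD file %s: `%s` outside {0, 1} at data row %d",
                    path, col, which(!ok)[1]),
            class = "maicsim_parse_error")
    }
  }
  df[required]
}

#' @rdname read_ipd
#' @export
write_ipd <- function(records, path) {
  cols <- c("arm", "age", "postmenopausal", "grade2", "grade3",
            "treated", "time", "event")
  readr::write_csv(records[intersect(cols, names(records))], path)
  invisible(path)
}

#' Read and write the published curve artefacts
#'
#' Curve coordinates are two-column CSV (`time`, `survival`) - the shape
#' a digitizer export produces; the risk table is two-column CSV
#' (`time`, `n_at_risk`); reconstructed IPD is two-column CSV (`time`,
#' `event`).
#'
#' @param x The tibble to write.
#' @param path File path.
#' @name curve_io
#' @export
write_curve <- function(x, path) {
  readr::write_csv(x[c("time", "survival")], path)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time", "survival") %in% names(df))) {
    abort(sprintf("curve file %s must have columns time, survival", path),
          class = "maicsim_parse_error")
  }
  df[c("time", "survival")]
}

#' @rdname curve_io
#' @export
write_risk_table <- function(x, path) {
  readr::write_csv(x[c("time", "n_at_risk")], path)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_risk_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time", "n_at_risk") %in% names(df))) {
    abort(sprintf("risk-table file %s must have columns time, n_at_risk", path),
          class = "maicsim_parse_error")
  }
  df[c("time", "n_at_risk")]
}

#' Read a study configuration file
#'
#' YAML configuration whose keys mirror the [arm_spec()] and
#' [run_study()] arguments. An empty file (or missing sections)
#' reproduces the shipped defaults: arm A n = 1000, arm B n = 800,
#' Weibull scale 4e-8 and shape 2.2, the default coefficient vectors,
#' and a 2500-day horizon. Unknown keys are an error, never silently
#' ignored.
#'
#' Recognised top-level keys: `scenario` (1 or 2), `n_reps`, `seed`,
#' `risk_times`, `surv_digits`, `time_digits`, `publish_events`,
#' `validate`, `arm_a`, `arm_b` (each a mapping of [arm_spec()] fields
#' to override).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param scenario_id Scenario used when the file does not set one.
#' @return A list with elements `scenario` (a [scenario_spec()]) and
#'   `run_args` (arguments for [run_study()]).
#' @export
read_config <- function(path = NULL, scenario_id = 1) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("scenario", "n_reps", "seed", "risk_times", "surv_digits",
             "time_digits", "publish_events", "validate", "arm_a", "arm_b")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "maicsim_config_error")
  }
  sid <- cfg$scenario %||% scenario_id
  if (!sid %in% c(1, 2)) {
    abort("invalid configuration: key `scenario` must be 1 or 2",
          class = "maicsim_config_error")
  }
  override_arm <- function(base, over, arm_name) {
    if (is.null(over)) return(base)
    # YAML 1.1 resolves a bare `n` key to a boolean; map it back
    names(over)[names(over) == "FALSE"] <- "n"
    bad <- setdiff(names(over), names(unclass(base)))
    if (length(bad) > 0) {
      abort(sprintf("unknown `%s` configuration key(s): %s", arm_name,
                    paste(bad, collapse = ", ")),
            class = "maicsim_config_error")
    }
    spec <- unclass(base)
    spec[names(over)] <- over
    validate_arm_spec(structure(spec, class = "arm_spec"))
  }
  scenario <- scenario_spec(
    sid,
    arm_a = override_arm(default_arm_a(), cfg$arm_a, "arm_a"),
    arm_b = override_arm(default_arm_b(sid), cfg$arm_b, "arm_b")
  )
  run_args <- cfg[intersect(names(cfg),
                            c("n_reps", "seed", "risk_times", "surv_digits",
                              "time_digits", "publish_events", "validate"))]
  if (!is.null(run_args$risk_times)) {
    run_args$risk_times <- as.numeric(run_args$risk_times)
  }
  list(scenario = scenario, run_args = run_args)
}

#' Write a reproducibility manifest for a study run
#'
#' Records the package version, master seed, scenario and run arguments
#' as JSON so a run can be reproduced bit-identically.
#'
#' @param result A [run_study()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(
    list(
      package = "maicsim",
      version = as.character(utils::packageVersion("maicsim")),
      scenario = result$scenario$scenario_id,
      n_reps = result$n_reps,
      seed = result$seed,
      n_excluded = length(result$exclusions),
      arm_a = unclass(result$scenario$arm_a),
      arm_b = unclass(result$scenario$arm_b)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
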