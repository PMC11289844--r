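#' Read game parameters / run configuration from a YAML or JSON file
#'
#' The file holds either the literal token `"baseline"`, a flat mapping of
#' the ten canonical parameter keys (`u1, u2, s1, s2, c1, c2, c3, p1, p2,
#' p3`; all required, unknown keys are an error), or a mapping with a
#' `parameters` block of either form plus optional `settings` (passed to
#' [integration_settings()]) and `seed` entries.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with elements `params` (a [game_params()] object),
#'   `settings` (an [integration_settings()] list) and `seed` (integer or
#'   `NA`).
#' @export
read_game_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "settlegame_config")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  spec <- if (is.list(raw) && !is.null(raw$parameters)) raw$parameters else raw
  params <- parse_param_block(spec)
  settings <- integration_settings()
  if (is.list(raw) && !is.null(raw$settings)) {
    known <- intersect(names(raw$settings), names(formals(integration_settings)))
    unknown <- setdiff(names(raw$settings), known)
    if (length(unknown) > 0) {
      abort(paste0("Unknown settings key(s): ", paste(unknown, collapse = ", ")),
            class = "settlegame_config")
    }
    settings <- do.call(integration_settings, raw$settings[known])
  }
  seed <- if (is.list(raw) && !is.null(raw$seed)) as.integer(raw$seed) else NA_integer_
  list(params = params, settings = settings, seed = seed)
}

parse_param_block <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    if (identical(tolower(spec), "baseline")) return(baseline_params())
    abort(paste0("Unknown parameter token: ", spec), class = "settlegame_config")
  }
  spec <- as.list(spec)
  unknown <- setdiff(names(spec), param_names())
  if (length(unknown) > 0) {
    abort(paste0("Unknown parameter key(s): ", paste(unknown, collapse = ", ")),
          class = "settlegame_config")
  }
  missing <- setdiff(param_names(), names(spec))
  if (length(missing) > 0) {
    abort(paste0("Missing parameter key(s): ", paste(missing, collapse = ", ")),
          class = "settlegame_config")
  }
  bad <- names(spec)[!vapply(spec, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric parameter value(s): ", paste(bad, collapse = ", ")),
          class = "settlegame_config")
  }
  do.call(game_params, c(spec[param_names()], list(validate = "none")))
}

#' Full structured analysis report
#'
#' Bundles everything the package computes for one parameter set: the
#' parameters and their constraint violations (if any), the equilibrium
#' candidates, the corner stability table, the scenario classification, the
#' ESS set, and a basin-scan summary. Deterministic: identical inputs give
#' identical reports.
#'
#' @param params A [game_params()] object.
#' @param starts Initial-condition grid for the basin scan, or `NULL` to
#'   skip the scan.
#' @param settings An [integration_settings()] list.
#' @param tol Degeneracy tolerance.
#' @return A list of class `game_report` with elements `parameters`,
#'   `violations`, `equilibria`, `stability`, `scenario`, `ess`, `basin`.
#' @examples
#' \donttest{
#' rep <- run_report(baseline_params(), starts = sweep_grid())
#' rep$scenario$scenario_id  # 6
#' }
#' @export
run_report <- function(params, starts = interior_grid(),
                       settings = integration_settings(), tol = 1e-12) {
  params <- as_game_params(params)
  sc <- classify_scenario(params, tol)
  basin <- if (is.null(starts)) NULL else
    glance(basin_scan(params, starts = starts, settings = settings))
  structure(list(
    parameters = tidy(params),
    violations = validate_params(params),
    equilibria = enumerate_equilibria(params),
    stability = corner_stability(params, tol),
    scenario = list(scenario_id = sc$scenario_id, boundary = sc$boundary,
                    condition_values = sc$condition_values,
                    predicted_ess = sc$predicted_ess[[1]]),
    ess = find_ess(params, tol),
    basin = basin
  ), class = "game_report")
}

#' Serialise a report (or any tabular result) to disk
#'
#' `write_game_report()` writes a `game_report` as a single JSON document
#' with numbers at 12 significant digits; `write_game_csv()` writes any of
#' the package's tibble results (stability tables, trajectories, sweeps,
#' phase fields) as CSV.
#'
#' @param report A [run_report()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_game_report <- function(report, path) {
  stopifnot(inherits(report, "game_report"))
  jsonlite::write_json(unclass(report), path, digits = 12, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_game_report
#' @param x A tibble (e.g. from [corner_stability()], [sweep_parameter()],
#'   [phase_field()] or a trajectory).
#' @export
write_game_csv <- function(x, path) {
  readr::write_csv(as_tibble(as.data.frame(x)), path)
  invisible(path)
}
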