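# Seven-scenario taxonomy of the game's stable outcomes.
#
# Three payoff-difference expressions determine every corner's stability:
#   e_indirect = s2 - s1 + u1 - u2 - c2   (patient gain of going cross-regional
#                                          when hospitals do NOT settle directly)
#   e_direct   = s2 - s1 + u1 - u2 - c1   (same gain under direct settlement)
#   h_gain     = p1 + p2 - p3 - c3        (hospital gain of direct settlement
#                                          when all patients travel)
# Their strict sign pattern (e_indirect, h_gain, e_direct) indexes the
# scenarios; the pattern (+, +, -) cannot occur while c1 < c2 and maps to no
# scenario.

scenario_sign_table <- function() {
  tibble(
    scenario_id = 1:7,
    s_indirect = c(-1, -1, -1, -1,  1,  1,  1),
    s_hospital = c(-1, -1,  1,  1, -1, -1,  1),
    s_direct   = c(-1,  1, -1,  1, -1,  1,  1),
    ess = list("O", "O", "O", c("O", "C"), "A", "A", "C")
  )
}

corner_coords <- function(points) {
  all <- tibble(point = c("O", "A", "B", "C"),
                x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  dplyr::semi_join(all, tibble(point = points), by = "point")
}

#' The three scenario-defining payoff-difference expressions
#'
#' @param params A [game_params()] object.
#' @return A tibble with columns `expression`, `value`: the patient advantage
#'   of cross-regional care under indirect settlement
#'   (`s2 - s1 + u1 - u2 - c2`), the same under direct settlement
#'   (`s2 - s1 + u1 - u2 - c1`), and the hospital gain of direct settlement at
#'   full patient uptake (`p1 + p2 - p3 - c3`).
#' @examples
#' scenario_conditions(baseline_params())
#' @export
scenario_conditions <- function(params) {
  params <- as_game_params(params)
  base <- params$s2 - params$s1 + params$u1 - params$u2
  tibble(
    expression = c("patient_gain_indirect", "hospital_gain_direct",
                   "patient_gain_direct"),
    value = c(base - params$c2,
              params$p1 + params$p2 - params$p3 - params$c3,
              base - params$c1)
  )
}

#' Assign a parameter set to one of the seven stability scenarios
#'
#' Each scenario is a strict sign pattern of the three expressions returned
#' by [scenario_conditions()], and fixes which corners of the unit square are
#' ESS, unstable, or saddle points. If any expression is within `tol` of zero
#' the set lies on a regime boundary and no scenario is assigned
#' (`scenario_id = NA`, `boundary = TRUE`). The seven patterns are mutually
#' exclusive; the eighth sign pattern (cross-regional care attractive only
#' under direct settlement being *worse* than under indirect settlement)
#' requires `c1 > c2` together with a hospital gain, and maps to no scenario.
#'
#' @param params A [game_params()] object.
#' @param tol Boundary tolerance on the condition expressions.
#' @return An object of class `scenario_class`: a list with `scenario_id`
#'   (integer or `NA`), `boundary` (logical), `condition_values` (tibble from
#'   [scenario_conditions()]) and `predicted_ess` (list-wrapped tibble of ESS
#'   corners for the matched scenario).
#' @examples
#' classify_scenario(baseline_params())           # scenario 6
#' classify_scenario(baseline_params(p1 = 9))     # scenario 7
#' classify_scenario(baseline_params(p1 = 8))     # boundary, no scenario
#' @export
classify_scenario <- function(params, tol = 1e-12) {
  params <- as_game_params(params)
  cond <- scenario_conditions(params)
  v <- setNames(cond$value, cond$expression)
  boundary <- any(abs(v) <= tol)
  sgn <- function(z) ifelse(z > tol, 1L, ifelse(z < -tol, -1L, 0L))
  id <- NA_integer_
  ess <- corner_coords(character(0))
  if (!boundary) {
    tab <- scenario_sign_table()
    hit <- tab$s_indirect == sgn(v[["patient_gain_indirect"]]) &
      tab$s_hospital == sgn(v[["hospital_gain_direct"]]) &
      tab$s_direct == sgn(v[["patient_gain_direct"]])
    if (any(hit)) {
      id <- tab$scenario_id[hit]
      ess <- corner_coords(tab$ess[hit][[1]])
    }
  }
  structure(list(scenario_id = id, boundary = boundary,
                 condition_values = cond,
                 predicted_ess = list(ess)),
            class = "scenario_class")
}

#' @export
print.scenario_class <- function(x, ...) {
  cat("<scenario_class>\n")
  if (is.na(x$scenario_id)) {
    cat("scenario: none", if (x$boundary) "(boundary case)" else "(unmatched sign pattern)", "\n")
  } else {
    ess <- x$predicted_ess[[1]]
    cat("scenario:", x$scenario_id, "  predicted ESS:",
        paste0(ess$point, "(", ess$x, ",", ess$y, ")", collapse = ", "), "\n")
  }
  print(x$condition_values)
  invisible(x)
}

#' @rdname classify_scenario
#' @param x A `scenario_class` object.
#' @param ... Unused.
#' @method tidy scenario_class
#' @export
tidy.scenario_class <- function(x, ...) {
  dplyr::mutate(x$condition_values,
                scenario_id = x$scenario_id, boundary = x$boundary)
}

#' @rdname classify_scenario
#' @method glance scenario_class
#' @export
glance.scenario_class <- function(x, ...) {
  ess <- x$predicted_ess[[1]]
  tibble(scenario_id = x$scenario_id, boundary = x$boundary,
         n_ess = nrow(ess),
         ess = paste(ess$point, collapse = ","))
}
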