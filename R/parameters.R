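#' Game parameters for the patient--hospital settlement game
#'
#' Constructs the ten-scalar parameter set of the two-population evolutionary
#' game between patients with malignant tumours and hospitals. All parameters
#' are dimensionless payoff coefficients.
#'
#' The canonical regime places six range constraints on the parameters:
#' `u1 > u2` (cross-regional care is more useful than in-area care),
#' `s1 < s2` (medical costs are lower after cross-regional treatment, because
#' the treating region's insurance catalogue is broader), `c1 < c2`
#' (nonmedical costs -- travel, lodging, time -- are lower under direct
#' settlement), `p1 > p3` (direct settlement attracts more, and sicker,
#' cross-regional patients), `p2 > 0`, and `c3 > 0`. Sensitivity sweeps
#' deliberately cross these constraints, so the default validation mode is
#' `"warn"`.
#'
#' @param u1,u2 Patient utility of cross-regional / in-area care.
#' @param s1,s2 Patient medical cost after cross-regional / in-area care.
#' @param c1,c2 Patient nonmedical cost of cross-regional treatment with /
#'   without direct settlement.
#' @param c3 Hospital input cost of implementing direct settlement
#'   (information-system upgrades, capital-turnover pressure).
#' @param p1 Hospital financial benefit of direct settlement.
#' @param p2 Hospital technological-advancement benefit of direct settlement.
#' @param p3 Hospital financial benefit without direct settlement.
#' @param validate One of `"warn"` (default; out-of-regime values are kept and
#'   a warning is issued), `"strict"` (they are an error) or `"none"`.
#'
#' @return An object of class `game_params`: a named list of the ten scalars.
#' @seealso [baseline_params()], [validate_params()]
#' @examples
#' p <- game_params(u1 = 6, u2 = 4, s1 = 3, s2 = 4, c1 = 0.5, c2 = 1,
#'                  c3 = 4, p1 = 7, p2 = 2, p3 = 6)
#' tidy(p)
#' @export
game_params <- function(u1, u2, s1, s2, c1, c2, c3, p1, p2, p3,
                        validate = c("warn", "strict", "none")) {
  validate <- arg_match(validate)
  vals <- list(u1 = u1, u2 = u2, s1 = s1, s2 = s2, c1 = c1, c2 = c2,
               c3 = c3, p1 = p1, p2 = p2, p3 = p3)
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Game parameter(s) not finite scalar numeric: ",
                 paste(bad, collapse = ", ")),
          class = "settlegame_invalid_parameter")
  }
  out <- structure(lapply(vals, as.numeric), class = "game_params")
  if (validate != "none") {
    viol <- validate_params(out, mode = validate)
    if (validate == "warn" && nrow(viol) > 0) {
      warn(paste0("Parameters outside the canonical regime: ",
                  paste(viol$constraint, collapse = ", ")),
           class = "settlegame_out_of_regime")
    }
  }
  out
}

#' Baseline parameter set
#'
#' The reference parameterisation used throughout the package's examples:
#' `u1 = 6, u2 = 4, s1 = 3, s2 = 4, c1 = 0.5, c2 = 1, c3 = 4, p1 = 7,
#' p2 = 2, p3 = 6`. Under these values patients evolve toward cross-regional
#' treatment while hospitals evolve away from direct settlement (the (1, 0)
#' corner).
#'
#' @param ... Named overrides for individual parameters, e.g. `u2 = 7`.
#' @return A [game_params()] object.
#' @examples
#' baseline_params()
#' baseline_params(p1 = 9)
#' @export
baseline_params <- function(...) {
  vals <- list(u1 = 6, u2 = 4, s1 = 3, s2 = 4, c1 = 0.5, c2 = 1,
               c3 = 4, p1 = 7, p2 = 2, p3 = 6)
  dots <- list(...)
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), names(vals))
    if (length(unknown) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("Unknown parameter name(s): ",
                   paste(unknown, collapse = ", ")))
    }
    vals[names(dots)] <- dots
  }
  do.call(game_params, c(vals, list(validate = "none")))
}

#' Names of the ten game parameters
#' @return Character vector of canonical parameter names.
#' @export
param_names <- function() {
  c("u1", "u2", "s1", "s2", "c1", "c2", "c3", "p1", "p2", "p3")
}

#' Validate a parameter set against the canonical range constraints
#'
#' Checks the six canonical constraints (`u1 > u2`, `s1 < s2`, `c1 < c2`,
#' `p1 > p3`, `p2 > 0`, `c3 > 0`) and returns one row per violation.
#'
#' @param params A [game_params()] object (or coercible named list).
#' @param mode `"warn"` returns the violations for logging; `"strict"` raises
#'   an error when any constraint fails.
#' @return A tibble with columns `constraint`, `lhs`, `rhs`, `message`;
#'   zero rows iff all six constraints hold.
#' @examples
#' validate_params(baseline_params())              # 0 rows
#' validate_params(baseline_params(c3 = -1))       # c3 > 0 fails
#' @export
validate_params <- function(params, mode = c("warn", "strict")) {
  mode <- arg_match(mode)
  params <- as_game_params(params)
  checks <- tibble(
    constraint = c("u1 > u2", "s1 < s2", "c1 < c2", "p1 > p3", "p2 > 0", "c3 > 0"),
    lhs = c(params$u1, params$s1, params$c1, params$p1, params$p2, params$c3),
    rhs = c(params$u2, params$s2, params$c2, params$p3, 0, 0),
    ok = c(params$u1 > params$u2, params$s1 < params$s2, params$c1 < params$c2,
           params$p1 > params$p3, params$p2 > 0, params$c3 > 0)
  )
  viol <- dplyr::filter(checks, !.data$ok)
  viol <- dplyr::mutate(
    dplyr::select(viol, -"ok"),
    message = paste0("constraint ", .data$constraint, " violated (",
                     .data$lhs, " vs ", .data$rhs, ")"))
  if (mode == "strict" && nrow(viol) > 0) {
    abort(paste0("Parameter set violates the canonical regime: ",
                 paste(viol$constraint, collapse = ", ")),
          class = "settlegame_out_of_regime")
  }
  viol
}

#' Coerce to a game_params object without revalidation
#' @param x A `game_params` object or a named list/vector with the ten
#'   canonical names.
#' @return A `game_params` object.
#' @export
as_game_params <- function(x) {
  if (inherits(x, "game_params")) return(x)
  x <- as.list(x)
  missing <- setdiff(param_names(), names(x))
  if (length(missing) > 0) {
    abort(paste0("Missing game parameter(s): ", paste(missing, collapse = ", ")))
  }
  do.call(game_params, c(x[param_names()], list(validate = "none")))
}

#' Replace one parameter in a set
#' @param params A [game_params()] object.
#' @param parameter Canonical parameter name.
#' @param value New numeric value.
#' @return A `game_params` object (no revalidation; sweeps cross constraints).
#' @export
set_param <- function(params, parameter, value) {
  params <- as_game_params(params)
  parameter <- arg_match(parameter, param_names())
  params[[parameter]] <- as.numeric(value)
  params
}

#' @export
print.game_params <- function(x, ...) {
  cat("<game_params>\n")
  print(unlist(x))
  viol <- validate_params(x)
  if (nrow(viol) > 0) {
    cat("outside canonical regime:", paste(viol$constraint, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname game_params
#' @param x A `game_params` object.
#' @method tidy game_params
#' @export
tidy.game_params <- function(x, ...) {
  tibble(parameter = param_names(), value = unlist(x[param_names()], use.names = FALSE))
}

# Population state checks ----------------------------------------------------

check_state <- function(x, y, tol = 0) {
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Strategy frequencies must be finite.", class = "settlegame_domain")
  }
  if (any(x < -tol | x > 1 + tol) || any(y < -tol | y > 1 + tol)) {
    abort("Strategy frequencies (x, y) must lie on the unit square.",
          class = "settlegame_domain")
  }
  invisible(TRUE)
}
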