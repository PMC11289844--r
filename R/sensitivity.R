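#' Affine payoff-advantage coefficients
#'
#' Both payoff advantages are affine in the opposing population's frequency:
#' the patient advantage of cross-regional care is
#' `ep1 - ep2 = a_p + b_p * y` with `a_p = u1 - s1 - c2 - u2 + s2` and
#' `b_p = c2 - c1`; the hospital advantage of direct settlement is
#' `eh1 - eh2 = a_h + b_h * x` with `a_h = -c3` and `b_h = p1 + p2 - p3`.
#' When an advantage has a constant sign over the whole square, the
#' corresponding frequency converges monotonically to 0 or 1 regardless of
#' initial conditions, which makes these coefficients an exact closed-form
#' cross-check for the numeric sweeps.
#'
#' @param params A [game_params()] object.
#' @return A tibble with columns `player` (`"patient"`, `"hospital"`),
#'   `intercept`, `slope` (advantage `= intercept + slope * opponent
#'   frequency`), and the advantage envelope `min`/`max` over the square.
#' @examples
#' analytic_advantage(baseline_params())  # patient 2 + 0.5 y; hospital 3 x - 4
#' @export
analytic_advantage <- function(params) {
  params <- as_game_params(params)
  ap <- params$u1 - params$s1 - params$c2 - params$u2 + params$s2
  bp <- params$c2 - params$c1
  ah <- -params$c3
  bh <- params$p1 + params$p2 - params$p3
  tibble(
    player = c("patient", "hospital"),
    intercept = c(ap, ah),
    slope = c(bp, bh),
    min = c(ap + min(0, bp), ah + min(0, bh)),
    max = c(ap + max(0, bp), ah + max(0, bh))
  )
}

# One-sided drift of each frequency implied by the advantage envelope:
# +1 toward 1 (advantage >= 0 everywhere, > 0 somewhere), -1 toward 0,
# 0 identically degenerate, NA mixed sign.
advantage_drift <- function(adv, tol = 1e-12) {
  dplyr::case_when(
    adv$min >= -tol & adv$max > tol  ~ 1,
    adv$max <= tol & adv$min < -tol  ~ -1,
    abs(adv$min) <= tol & abs(adv$max) <= tol ~ 0,
    TRUE ~ NA_real_
  )
}

#' Default initial-condition grid for sensitivity sweeps
#'
#' A compact 3x3 interior grid. The basin scans in this model are
#' initial-condition independent wherever a corner limit exists at all, so a
#' small spread of starts is enough to certify unanimity in a sweep; the
#' full 0.1-step grid of [interior_grid()] remains available via the
#' `starts` argument.
#' @return A tibble of `(x0, y0)` pairs.
#' @export
sweep_grid <- function() {
  tidyr::expand_grid(x0 = c(0.2, 0.5, 0.8), y0 = c(0.2, 0.5, 0.8))
}

#' One-parameter sensitivity sweep
#'
#' Replaces one game parameter by each trial value in turn (all other
#' parameters held at `baseline`), and for each value records the scenario
#' classification, Jacobian-based ESS set, unanimous basin-scan limit, and
#' the analytic drift direction of each population. Default trial values are
#' consecutive integers because the observable switches in this game fall on
#' integer parameter values under the baseline set.
#'
#' Sweeps intentionally cross the canonical parameter constraints, so no
#' range validation is applied to the trial values.
#'
#' @param baseline A [game_params()] object used for the non-swept parameters.
#' @param parameter Canonical name of the swept parameter.
#' @param values Strictly monotone numeric vector of trial values.
#' @param starts Initial-condition grid for the basin scans
#'   (default [sweep_grid()]).
#' @param settings An [integration_settings()] list.
#' @param tol Degeneracy/boundary tolerance.
#' @return An object of class `game_sweep`: a tibble with one row per trial
#'   value -- `value`, `scenario_id`, `boundary`, `ess` (comma-separated
#'   corner labels), `n_ess`, `patient_limit`, `hospital_limit` (corner
#'   coordinate when the basin scan converged unanimously, otherwise `NA`),
#'   `all_converged`, `unanimous`, `patient_drift`, `hospital_drift` -- with
#'   attributes `parameter`, `baseline` and `analytic_switch` (see
#'   [analytic_switch()]).
#' @examples
#' \donttest{
#' sw <- sweep_parameter(baseline_params(), "u1", values = 1:10)
#' detect_threshold(sw, "patient", "up")  # 5
#' }
#' @export
sweep_parameter <- function(baseline, parameter, values,
                            starts = sweep_grid(),
                            settings = integration_settings(),
                            tol = 1e-12) {
  baseline <- as_game_params(baseline)
  parameter <- arg_match(parameter, param_names())
  values <- as.numeric(values)
  if (length(values) == 0 || is.unsorted(values, strictly = TRUE) &&
      is.unsorted(rev(values), strictly = TRUE)) {
    abort("`values` must be non-empty and strictly monotone.")
  }
  rows <- purrr::map_dfr(values, function(v) {
    p <- set_param(baseline, parameter, v)
    sc <- classify_scenario(p, tol)
    ess <- find_ess(p, tol)
    bs <- basin_scan(p, starts = starts, settings = settings)
    lim <- attr(bs, "limit", exact = TRUE)
    strict <- attr(bs, "unanimous") && attr(bs, "all_converged")
    adv <- analytic_advantage(p)
    drift <- advantage_drift(adv, tol)
    tibble(
      value = v,
      scenario_id = sc$scenario_id,
      boundary = sc$boundary,
      ess = paste(ess$point, collapse = ","),
      n_ess = nrow(ess),
      patient_limit = if (strict) lim[["x"]] else NA_real_,
      hospital_limit = if (strict) lim[["y"]] else NA_real_,
      all_converged = attr(bs, "all_converged"),
      unanimous = attr(bs, "unanimous"),
      patient_drift = drift[adv$player == "patient"],
      hospital_drift = drift[adv$player == "hospital"]
    )
  })
  structure(rows,
            parameter = parameter,
            baseline = baseline,
            analytic_switch = analytic_switch(baseline, parameter,
                                              range(values)),
            class = c("game_sweep", class(tibble())))
}

#' Analytic sign-boundary values of a swept parameter
#'
#' Finds the parameter values (inside `range`) at which the lower or upper
#' envelope of a player's payoff advantage crosses zero. Between two
#' consecutive boundaries the advantage envelope has a fixed sign pattern, so
#' these are the only values at which the sweep's limiting behaviour can
#' change. Each envelope is continuous and piecewise linear in the parameter;
#' roots are located by bracketing on a fine grid.
#'
#' @param baseline A [game_params()] object.
#' @param parameter Canonical name of the swept parameter.
#' @param range Length-2 numeric range to search.
#' @param n_grid Number of bracketing points.
#' @return A tibble with columns `player`, `bound` (`"min"`/`"max"`), `at`.
#'   For the hospital input cost this reports the boundary
#'   `c3 = p1 + p2 - p3` beyond which direct settlement cannot pay off even
#'   at full patient uptake.
#' @examples
#' analytic_switch(baseline_params(), "c3", c(1, 6))  # hospital max at 3
#' @export
analytic_switch <- function(baseline, parameter, range, n_grid = 1001) {
  baseline <- as_game_params(baseline)
  parameter <- arg_match(parameter, param_names())
  stopifnot(length(range) == 2, range[1] < range[2])
  env_fun <- function(player, bound) {
    function(v) {
      adv <- analytic_advantage(set_param(baseline, parameter, v))
      adv[[bound]][adv$player == player]
    }
  }
  grid <- seq(range[1], range[2], length.out = n_grid)
  out <- purrr::pmap_dfr(
    tidyr::expand_grid(player = c("patient", "hospital"),
                       bound = c("min", "max")),
    function(player, bound) {
      g <- env_fun(player, bound)
      vals <- vapply(grid, g, numeric(1))
      roots <- c()
      if (abs(vals[1]) < 1e-12) roots <- c(roots, grid[1])
      sgn <- sign(vals)
      for (i in seq_len(n_grid - 1)) {
        if (sgn[i] != 0 && sgn[i + 1] != 0 && sgn[i] != sgn[i + 1]) {
          roots <- c(roots, uniroot(g, c(grid[i], grid[i + 1]),
                                    tol = 1e-12)$root)
        } else if (sgn[i + 1] == 0 && sgn[i] != 0) {
          roots <- c(roots, grid[i + 1])
        }
      }
      if (length(roots) == 0) return(tibble())
      tibble(player = player, bound = bound, at = unique(roots))
    })
  out
}

#' Detect the switch threshold of a sweep
#'
#' Formalises "the stable strategy shifts once the parameter reaches N".
#' With `direction = "up"`, scans away from the first (baseline-end) trial
#' value and returns the first value at which the player's *confirmed*
#' limiting coordinate -- a unanimous, fully converged corner limit --
#' differs from its baseline-end value. Trial values with no corner limit
#' (the advantage touches zero on an edge, so the frequency stalls short of
#' a corner) are skipped and flagged.
#'
#' With `direction = "down"`, returns the last value at which the
#' baseline-end behaviour still *persists*, counting weak persistence: where
#' no corner limit exists but the analytic advantage is one-sidedly signed
#' (see [analytic_advantage()]), the frequency still drifts toward the
#' baseline-end corner and the value counts as unswitched.
#'
#' @param sweep A [sweep_parameter()] result.
#' @param player `"patient"` or `"hospital"`.
#' @param direction `"up"` (first confirmed flip) or `"down"` (last
#'   persistence of the baseline-end behaviour).
#' @return The threshold trial value (or `NA` if no flip), with attribute
#'   `ambiguous = TRUE` when any skipped / non-unanimous values were
#'   encountered before the threshold.
#' @export
detect_threshold <- function(sweep, player = c("patient", "hospital"),
                             direction = c("up", "down")) {
  player <- arg_match(player)
  direction <- arg_match(direction)
  stopifnot(inherits(sweep, "game_sweep"))
  strict <- sweep[[paste0(player, "_limit")]]
  drift <- sweep[[paste0(player, "_drift")]]
  weak <- dplyr::coalesce(strict, dplyr::case_when(drift > 0 ~ 1,
                                                   drift < 0 ~ 0,
                                                   TRUE ~ NA_real_))
  base <- if (!is.na(strict[1])) strict[1] else weak[1]
  if (is.na(base)) {
    return(structure(NA_real_, ambiguous = TRUE))
  }
  ambiguous <- FALSE
  if (direction == "up") {
    for (i in seq_along(strict)[-1]) {
      if (is.na(strict[i])) { ambiguous <- TRUE; next }
      if (strict[i] != base) {
        return(structure(sweep$value[i], ambiguous = ambiguous))
      }
    }
    return(structure(NA_real_, ambiguous = ambiguous))
  }
  # direction == "down": last value (scanning from the baseline end) whose
  # weak coordinate still equals the baseline-end coordinate
  last <- sweep$value[1]
  for (i in seq_along(weak)[-1]) {
    if (is.na(weak[i])) {
      ambiguous <- TRUE
      return(structure(last, ambiguous = ambiguous))
    }
    if (weak[i] != base) return(structure(last, ambiguous = ambiguous))
    last <- sweep$value[i]
  }
  structure(NA_real_, ambiguous = ambiguous)
}

#' Compare numeric sweep thresholds with analytic sign boundaries
#'
#' For each player, reports the first confirmed numeric flip in the sweep
#' alongside the analytic boundary values of the advantage envelope, and
#' flags the case where the confirmed numeric flip lies strictly beyond an
#' analytic boundary -- which happens when the boundary value itself is
#' degenerate (the advantage touches zero, the scenario classification is
#' `none`, and no corner limit exists there), so the flip can only be
#' *confirmed* at the next trial value. Reading the switch off the confirmed
#' flip alone would overstate the true threshold in that case.
#'
#' @param sweep A [sweep_parameter()] result.
#' @return A tibble with columns `player`, `numeric_threshold`, `ambiguous`,
#'   `analytic_boundaries` (list-column of boundary values inside the sweep
#'   range) and `beyond_analytic` (flag described above).
#' @examples
#' \donttest{
#' sweep_discrepancies(sweep_parameter(baseline_params(), "c3", 1:6))
#' }
#' @export
sweep_discrepancies <- function(sweep) {
  stopifnot(inherits(sweep, "game_sweep"))
  asw <- attr(sweep, "analytic_switch")
  purrr::map_dfr(c("patient", "hospital"), function(pl) {
    th <- detect_threshold(sweep, pl, "up")
    bnd <- sort(unique(asw$at[asw$player == pl]))
    tibble(player = pl,
           numeric_threshold = as.numeric(th),
           ambiguous = isTRUE(attr(th, "ambiguous")),
           analytic_boundaries = list(bnd),
           beyond_analytic = !is.na(th) && length(bnd) > 0 &&
             any(bnd < as.numeric(th) - 1e-9 &
                   bnd > min(sweep$value) + 1e-9))
  })
}

#' @rdname sweep_parameter
#' @param x A `game_sweep` object.
#' @param ... Unused.
#' @method glance game_sweep
#' @export
glance.game_sweep <- function(x, ...) {
  tibble(
    parameter = attr(x, "parameter"),
    n_values = nrow(x),
    patient_up = as.numeric(detect_threshold(x, "patient", "up")),
    patient_down = as.numeric(detect_threshold(x, "patient", "down")),
    hospital_up = as.numeric(detect_threshold(x, "hospital", "up")),
    hospital_down = as.numeric(detect_threshold(x, "hospital", "down"))
  )
}
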