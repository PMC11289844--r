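#' Solver and convergence settings for replicator trajectories
#'
#' The replicator right-hand side is a smooth cubic polynomial on the unit
#' square, so a non-stiff adaptive Runge--Kutta (Dormand--Prince 4(5)) is
#' used. A trajectory is declared converged when it is within `conv_eps` of a
#' corner of the square *and* the velocity infinity-norm has fallen below
#' `stall_eps`; integration otherwise stops at `t_max`.
#'
#' @param rel_tol,abs_tol Relative / absolute solver tolerances. The
#'   defaults are tight enough that dense-output interpolation never leaves
#'   the unit square by more than about `1e-9`.
#' @param t_max Maximum integration time.
#' @param conv_eps Convergence radius around a corner (must be `< 0.5`).
#' @param stall_eps Velocity infinity-norm threshold at convergence.
#' @param chunk Time-span per solver chunk; convergence and stalling are
#'   checked after every chunk so converged runs terminate early.
#' @param dt Output time step inside a chunk.
#' @return A list of class `integration_settings`.
#' @export
integration_settings <- function(rel_tol = 1e-10, abs_tol = 1e-12, t_max = 500,
                                 conv_eps = 1e-4, stall_eps = 1e-9,
                                 chunk = 25, dt = 0.5) {
  stopifnot(rel_tol > 0, abs_tol > 0, t_max > 0, conv_eps > 0, conv_eps < 0.5,
            stall_eps > 0, chunk > 0, dt > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, t_max = t_max,
                 conv_eps = conv_eps, stall_eps = stall_eps,
                 chunk = chunk, dt = dt),
            class = "integration_settings")
}

corner_distances <- function(x, y) {
  # Euclidean distance to the nearest corner, and which corner it is.
  cx <- c(0, 1, 0, 1); cy <- c(0, 0, 1, 1)
  d <- vapply(seq_along(x), function(i)
    sqrt((x[i] - cx)^2 + (y[i] - cy)^2), numeric(4))
  d <- matrix(d, nrow = 4)
  idx <- apply(d, 2, which.min)
  list(dist = d[cbind(idx, seq_along(x))],
       corner = c("O", "A", "B", "C")[idx],
       cx = cx[idx], cy = cy[idx])
}

#' Integrate a replicator trajectory
#'
#' Integrates the two-population replicator ODE forward from `(x0, y0)` with
#' an adaptive Runge--Kutta solver, clipping each output state to the unit
#' square (the square is exactly invariant, so clipping only removes
#' floating-point overshoot of solver-tolerance magnitude).
#'
#' @param params A [game_params()] object.
#' @param x0,y0 Initial strategy frequencies on the unit square.
#' @param settings An [integration_settings()] list.
#' @return An object of class `game_trajectory`: a tibble `(time, x, y)` with
#'   attributes `converged` (logical), `limit` (named numeric `c(x, y)` of
#'   the corner reached, or `NULL`), `limit_point` (corner label or `NA`),
#'   `terminal_velocity` and `max_overshoot` (largest clipped excursion
#'   outside the square).
#' @examples
#' tr <- replicator_trajectory(baseline_params(), 0.5, 0.5)
#' glance(tr)  # converges to the corner (1, 0)
#' @export
replicator_trajectory <- function(params, x0, y0,
                                  settings = integration_settings()) {
  params <- as_game_params(params)
  stopifnot(length(x0) == 1L, length(y0) == 1L)
  check_state(x0, y0)
  f <- rhs_fn(params)
  deriv <- function(t, state, parms) list(f(state[1], state[2]))

  times <- c(0)
  xs <- c(x0); ys <- c(y0)
  state <- c(x = x0, y = y0)
  t0 <- 0
  converged <- FALSE
  limit_point <- NA_character_
  limit <- NULL
  max_overshoot <- 0

  check_row <- function(x, y) {
    cd <- corner_distances(x, y)
    v <- f(x, y)
    if (cd$dist < settings$conv_eps && max(abs(v)) < settings$stall_eps) cd else NULL
  }

  # the start itself may already satisfy the convergence test (corner starts)
  hit <- check_row(x0, y0)
  if (!is.null(hit)) {
    converged <- TRUE; limit_point <- hit$corner; limit <- c(x = hit$cx, y = hit$cy)
  }

  while (!converged && t0 < settings$t_max) {
    t1 <- min(t0 + settings$chunk, settings$t_max)
    tt <- seq(t0, t1, by = settings$dt)
    if (tt[length(tt)] < t1) tt <- c(tt, t1)
    sol <- deSolve::ode(y = state, times = tt, func = deriv, parms = NULL,
                        method = "ode45",
                        rtol = settings$rel_tol, atol = settings$abs_tol)
    if (!is.matrix(sol) || nrow(sol) < 2) {
      abort("ODE solver failed to advance the trajectory.",
            class = "settlegame_integration_error")
    }
    sx <- sol[-1, "x"]; sy <- sol[-1, "y"]
    over <- max(0, -min(sx, sy, 0), max(sx - 1, sy - 1, 0))
    max_overshoot <- max(max_overshoot, over)
    sx <- pmin(pmax(sx, 0), 1)
    sy <- pmin(pmax(sy, 0), 1)
    for (i in seq_along(sx)) {
      hit <- check_row(sx[i], sy[i])
      if (!is.null(hit)) {
        converged <- TRUE
        limit_point <- hit$corner
        limit <- c(x = hit$cx, y = hit$cy)
        sx <- sx[seq_len(i)]; sy <- sy[seq_len(i)]
        break
      }
    }
    keep <- seq_along(sx)
    times <- c(times, sol[-1, "time"][keep])
    xs <- c(xs, sx); ys <- c(ys, sy)
    prev <- state
    state <- c(x = sx[length(sx)], y = sy[length(sy)])
    t0 <- times[length(times)]
    # interior stall: the state has frozen away from every corner
    # (e.g. an attracting edge segment of equilibria); no corner limit exists
    if (!converged && max(abs(state - prev)) < 1e-9) break
  }

  tv <- f(state[1], state[2])
  structure(
    tibble(time = times, x = xs, y = ys),
    converged = converged,
    limit = limit,
    limit_point = limit_point,
    terminal_velocity = c(dx_dt = tv[1], dy_dt = tv[2]),
    max_overshoot = max_overshoot,
    params = params,
    class = c("game_trajectory", class(tibble()))
  )
}

#' @rdname replicator_trajectory
#' @param x A `game_trajectory` object.
#' @param ... Unused.
#' @method glance game_trajectory
#' @export
glance.game_trajectory <- function(x, ...) {
  lim <- attr(x, "limit", exact = TRUE)
  tibble(converged = attr(x, "converged"),
         limit_point = attr(x, "limit_point"),
         limit_x = if (is.null(lim)) NA_real_ else lim[["x"]],
         limit_y = if (is.null(lim)) NA_real_ else lim[["y"]],
         t_final = x$time[nrow(x)],
         max_overshoot = attr(x, "max_overshoot"))
}

#' Interior grid of initial conditions
#'
#' @param step Grid step (default 0.1, giving the interior points
#'   `{0.1, ..., 0.9}` in each coordinate).
#' @param include_boundary Include 0 and 1 themselves (boundary starts are
#'   invariant in one coordinate and are excluded by default).
#' @return A tibble of `(x0, y0)` pairs.
#' @export
interior_grid <- function(step = 0.1, include_boundary = FALSE) {
  stopifnot(step > 0, step < 1)
  v <- seq(0, 1, by = step)
  if (!include_boundary) v <- v[v > 0 & v < 1]
  tidyr::expand_grid(x0 = v, y0 = v)
}

#' Scan a grid of initial conditions for their limiting outcomes
#'
#' Integrates a replicator trajectory from every grid point and records the
#' corner each reaches (or that no corner was reached). Used to verify that
#' the evolutionary outcome does not depend on initial strategy frequencies.
#'
#' @param params A [game_params()] object.
#' @param starts A tibble with columns `x0`, `y0` (default: the interior
#'   0.1-step grid of [interior_grid()]).
#' @param settings An [integration_settings()] list.
#' @return An object of class `basin_scan`: a tibble with columns `x0`, `y0`,
#'   `converged`, `limit_point`, `limit_x`, `limit_y`, `t_final`, and
#'   attributes `unanimous` (all converged runs share one corner),
#'   `all_converged`, and `limit` (the shared corner as `c(x, y)`, or `NULL`).
#' @examples
#' \donttest{
#' bs <- basin_scan(baseline_params(), starts = interior_grid(0.25))
#' attr(bs, "limit")  # c(x = 1, y = 0)
#' }
#' @export
basin_scan <- function(params, starts = interior_grid(),
                       settings = integration_settings()) {
  params <- as_game_params(params)
  stopifnot(all(c("x0", "y0") %in% names(starts)))
  res <- purrr::pmap_dfr(starts[c("x0", "y0")], function(x0, y0) {
    tr <- replicator_trajectory(params, x0, y0, settings)
    dplyr::mutate(glance(tr), x0 = x0, y0 = y0, .before = 1)
  })
  conv <- dplyr::filter(res, .data$converged)
  unanimous <- nrow(conv) > 0 && dplyr::n_distinct(conv$limit_point) == 1L
  limit <- if (unanimous) c(x = conv$limit_x[1], y = conv$limit_y[1]) else NULL
  structure(res,
            unanimous = unanimous,
            all_converged = all(res$converged),
            limit = limit,
            params = params,
            class = c("basin_scan", class(tibble())))
}

#' @rdname basin_scan
#' @param x A `basin_scan` object.
#' @param ... Unused.
#' @method glance basin_scan
#' @export
glance.basin_scan <- function(x, ...) {
  lim <- attr(x, "limit", exact = TRUE)
  tibble(n_starts = nrow(x),
         n_converged = sum(x$converged),
         unanimous = attr(x, "unanimous"),
         all_converged = attr(x, "all_converged"),
         limit_x = if (is.null(lim)) NA_real_ else lim[["x"]],
         limit_y = if (is.null(lim)) NA_real_ else lim[["y"]])
}

#' Velocity field of the replicator dynamics on a lattice
#'
#' @param params A [game_params()] object.
#' @param resolution Number of lattice points per axis (>= 2), spanning
#'   `[0, 1]` inclusive.
#' @return A tibble `(x, y, dx_dt, dy_dt)` with `resolution^2` rows.
#' @examples
#' phase_field(baseline_params(), resolution = 3)
#' @export
phase_field <- function(params, resolution = 21) {
  stopifnot(resolution >= 2)
  params <- as_game_params(params)
  g <- tidyr::expand_grid(x = seq(0, 1, length.out = resolution),
                          y = seq(0, 1, length.out = resolution))
  replicator_rhs(params, g$x, g$y)
}
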