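#' Enumerate the equilibrium points of the replicator system
#'
#' Setting both replicator equations to zero yields the four corners of the
#' unit square, O(0,0), A(1,0), B(0,1), C(1,1), plus one interior candidate
#' D(x0, y0) with
#' `x0 = c3 / (p1 + p2 - p3)` and
#' `y0 = (c2 + s1 - s2 - u1 + u2) / (c2 - c1)`.
#' D is a genuine equilibrium of the system only when it lies strictly inside
#' the open unit square.
#'
#' @param params A [game_params()] object.
#' @return A tibble with one row per candidate point and columns `point`
#'   (`"O"`, `"A"`, `"B"`, `"C"`, `"D"`), `x`, `y`, `kind`
#'   (`"corner"`/`"interior"`), `exists`, and `degenerate` (`TRUE` when an
#'   interior denominator is zero, in which case `x`/`y` are `NA`).
#' @examples
#' enumerate_equilibria(baseline_params())  # D = (4/3, -4), exists = FALSE
#' @export
enumerate_equilibria <- function(params) {
  params <- as_game_params(params)
  den_x <- params$p1 + params$p2 - params$p3
  den_y <- params$c2 - params$c1
  degenerate <- den_x == 0 || den_y == 0
  x0 <- if (den_x == 0) NA_real_ else params$c3 / den_x
  y0 <- if (den_y == 0) NA_real_ else
    (params$c2 + params$s1 - params$s2 - params$u1 + params$u2) / den_y
  exists_d <- !degenerate && x0 > 0 && x0 < 1 && y0 > 0 && y0 < 1
  tibble(
    point = c("O", "A", "B", "C", "D"),
    x = c(0, 1, 0, 1, x0),
    y = c(0, 0, 1, 1, y0),
    kind = c(rep("corner", 4), "interior"),
    exists = c(rep(TRUE, 4), exists_d),
    degenerate = c(rep(FALSE, 4), degenerate)
  )
}

#' Analytic Jacobian of the replicator system
#'
#' Partial derivatives of the replicator right-hand side, evaluated at a
#' state `(x, y)`:
#' \deqn{J_{11} = (2x-1)(c_2+s_1-s_2-u_1+u_2+(c_1-c_2)y)}
#' \deqn{J_{12} = x(x-1)(c_1-c_2)}
#' \deqn{J_{21} = y(1-y)(p_1+p_2-p_3)}
#' \deqn{J_{22} = (2y-1)(c_3-(p_1+p_2-p_3)x)}
#' Both off-diagonal entries vanish exactly at the four corners.
#'
#' @param params A [game_params()] object.
#' @param x,y A single state on the unit square.
#' @return A 2x2 numeric matrix (rows/cols ordered x then y).
#' @examples
#' game_jacobian(baseline_params(), 1, 0)  # diag(-2, -1)
#' @export
game_jacobian <- function(params, x, y) {
  e <- jacobian_entries(as_game_params(params), x, y)
  matrix(c(e$j11, e$j21, e$j12, e$j22), nrow = 2,
         dimnames = list(c("x", "y"), c("x", "y")))
}

# Vectorised Jacobian entries.
jacobian_entries <- function(params, x, y) {
  check_state(x, y)
  d1 <- params$c2 + params$s1 - params$s2 - params$u1 + params$u2 +
    (params$c1 - params$c2) * y
  kh <- params$p1 + params$p2 - params$p3
  tibble(
    x = x, y = y,
    j11 = (2 * x - 1) * d1,
    j12 = x * (x - 1) * (params$c1 - params$c2),
    j21 = y * (1 - y) * kh,
    j22 = (2 * y - 1) * (params$c3 - kh * x)
  )
}

#' Classify local stability from determinant and trace
#'
#' The determinant/trace rule for equilibria of the two-dimensional
#' replicator system: an equilibrium is an evolutionarily stable strategy
#' (ESS) when `det(J) > 0` and `tr(J) < 0`; a source (`"unstable"`) when both
#' are positive; a saddle when `det(J) < 0`. Values within `tol` of zero are
#' `"degenerate"`: a zero trace or determinant never certifies an ESS.
#'
#' @param det,trace Numeric vectors of determinants and traces.
#' @param tol Nonnegative absolute degeneracy tolerance (default `1e-12`).
#' @return Character vector: `"ess"`, `"unstable"`, `"saddle"` or
#'   `"degenerate"`.
#' @examples
#' classify_stability(det = c(2, -8, 0), trace = c(-3, 5, 0))
#' @export
classify_stability <- function(det, trace, tol = 1e-12) {
  stopifnot(tol >= 0, length(det) == length(trace))
  dplyr::case_when(
    det < -tol               ~ "saddle",
    abs(det) <= tol          ~ "degenerate",
    trace < -tol             ~ "ess",
    trace > tol              ~ "unstable",
    TRUE                     ~ "degenerate"
  )
}

#' Local stability table for the corner equilibria
#'
#' Evaluates the Jacobian at each corner of the unit square. At a corner both
#' off-diagonal entries are exactly zero, so the determinant is the product
#' and the trace the sum of the two diagonal entries; each corner is then
#' classified by [classify_stability()]. The interior candidate D is excluded:
#' its trace is identically zero, so it can never be an ESS and the
#' determinant/trace rule assigns it no stable class.
#'
#' @param params A [game_params()] object.
#' @param tol Degeneracy tolerance passed to [classify_stability()].
#' @return A tibble with one row per corner: `point`, `x`, `y`, `j11`, `j12`,
#'   `j21`, `j22`, `det`, `trace`, `classification`.
#' @examples
#' corner_stability(baseline_params())
#' @export
corner_stability <- function(params, tol = 1e-12) {
  params <- as_game_params(params)
  corners <- dplyr::filter(enumerate_equilibria(params), .data$kind == "corner")
  ent <- jacobian_entries(params, corners$x, corners$y)
  out <- dplyr::bind_cols(corners["point"], ent)
  out <- dplyr::mutate(out,
                       det = .data$j11 * .data$j22,
                       trace = .data$j11 + .data$j22,
                       classification = classify_stability(.data$det, .data$trace, tol))
  out
}

#' Evolutionarily stable strategies of a parameter set
#'
#' The corner equilibria classified `"ess"` by the determinant/trace rule.
#' When the parameter set falls in one of the seven scenario regimes (see
#' [classify_scenario()]), the Jacobian-based set is cross-checked against
#' the scenario's predicted ESS set and an internal-consistency error is
#' raised on mismatch.
#'
#' @param params A [game_params()] object.
#' @param tol Degeneracy tolerance.
#' @param cross_check Cross-validate against the scenario taxonomy
#'   (default `TRUE`).
#' @return A tibble of ESS corners (`point`, `x`, `y`), possibly zero rows.
#' @examples
#' find_ess(baseline_params())  # A(1, 0)
#' @export
find_ess <- function(params, tol = 1e-12, cross_check = TRUE) {
  params <- as_game_params(params)
  tab <- corner_stability(params, tol)
  ess <- dplyr::select(dplyr::filter(tab, .data$classification == "ess"),
                       "point", "x", "y")
  if (cross_check) {
    sc <- classify_scenario(params, tol)
    if (!is.na(sc$scenario_id)) {
      predicted <- sc$predicted_ess[[1]]
      if (!identical(sort(ess$point), sort(predicted$point))) {
        abort(paste0("Internal inconsistency: Jacobian ESS set {",
                     paste(ess$point, collapse = ","),
                     "} differs from scenario ", sc$scenario_id,
                     " prediction {", paste(predicted$point, collapse = ","), "}"),
              class = "settlegame_internal")
      }
    }
  }
  ess
}
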