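#' Payoff matrix of the bimatrix stage game
#'
#' The four strategy combinations and their (patient, hospital) payoffs.
#' Patients either travel for cross-regional treatment or stay for in-area
#' care; hospitals either implement direct (real-time) insurance settlement
#' for cross-regional patients or do not.
#'
#' The cells are exact algebraic combinations of the parameters:
#' \describe{
#'   \item{(cross-regional, direct)}{patient `u1 - s1 - c1`, hospital
#'     `p1 + p2 - c3`}
#'   \item{(cross-regional, indirect)}{patient `u1 - s1 - c2`, hospital `p3`}
#'   \item{(in-area, direct)}{patient `u2 - s2`, hospital `-c3`}
#'   \item{(in-area, indirect)}{patient `u2 - s2`, hospital `0`}
#' }
#'
#' @param params A [game_params()] object.
#' @return A tibble with one row per strategy pair and columns
#'   `patient_strategy`, `hospital_strategy`, `patient_payoff`,
#'   `hospital_payoff`.
#' @examples
#' payoff_matrix(baseline_params())
#' @export
payoff_matrix <- function(params) {
  params <- as_game_params(params)
  with(params, tibble(
    patient_strategy  = c("cross_regional", "cross_regional", "in_area", "in_area"),
    hospital_strategy = c("direct", "indirect", "direct", "indirect"),
    patient_payoff    = c(u1 - s1 - c1, u1 - s1 - c2, u2 - s2, u2 - s2),
    hospital_payoff   = c(p1 + p2 - c3, p3, -c3, 0)
  ))
}

#' Expected payoffs under mixed population strategies
#'
#' Given the frequency `x` of patients choosing cross-regional treatment and
#' the frequency `y` of hospitals implementing direct settlement, computes the
#' expected payoff of each pure strategy and the population means:
#' `ep1 = y(u1-s1-c1) + (1-y)(u1-s1-c2)`, `ep2 = u2-s2`,
#' `ep_mean = x ep1 + (1-x) ep2`, `eh1 = x(p1+p2-c3) + (1-x)(-c3)`,
#' `eh2 = x p3`, `eh_mean = y eh1 + (1-y) eh2`.
#'
#' @param params A [game_params()] object.
#' @param x,y Strategy frequencies on the unit square; vectorised (recycled to
#'   a common length).
#' @return A tibble with columns `x`, `y`, `ep1`, `ep2`, `ep_mean`,
#'   `eh1`, `eh2`, `eh_mean`, one row per state.
#' @examples
#' expected_payoffs(baseline_params(), x = 0.5, y = c(0, 1))
#' @export
expected_payoffs <- function(params, x, y) {
  params <- as_game_params(params)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  check_state(x, y)
  pm <- payoff_matrix(params)
  pp <- setNames(pm$patient_payoff,
                 paste(pm$patient_strategy, pm$hospital_strategy, sep = "."))
  hp <- setNames(pm$hospital_payoff,
                 paste(pm$patient_strategy, pm$hospital_strategy, sep = "."))
  ep1 <- y * pp[["cross_regional.direct"]] + (1 - y) * pp[["cross_regional.indirect"]]
  ep2 <- y * pp[["in_area.direct"]] + (1 - y) * pp[["in_area.indirect"]]
  eh1 <- x * hp[["cross_regional.direct"]] + (1 - x) * hp[["in_area.direct"]]
  eh2 <- x * hp[["cross_regional.indirect"]] + (1 - x) * hp[["in_area.indirect"]]
  tibble(x = x, y = y, ep1 = ep1, ep2 = ep2,
         ep_mean = x * ep1 + (1 - x) * ep2,
         eh1 = eh1, eh2 = eh2,
         eh_mean = y * eh1 + (1 - y) * eh2)
}

#' Replicator dynamics right-hand side
#'
#' The two-population replicator system on the unit square:
#' `dx/dt = x(1-x)(ep1 - ep2)` and `dy/dt = y(1-y)(eh1 - eh2)`, so a
#' strategy's frequency grows in proportion to its payoff advantage over the
#' population mean. The edges `x = 0, 1` and `y = 0, 1` are invariant.
#'
#' @inheritParams expected_payoffs
#' @return A tibble with columns `x`, `y`, `dx_dt`, `dy_dt`.
#' @examples
#' replicator_rhs(baseline_params(), 0.5, 0.5)  # (0.5625, -0.625)
#' @export
replicator_rhs <- function(params, x, y) {
  ep <- expected_payoffs(params, x, y)
  tibble(x = ep$x, y = ep$y,
         dx_dt = ep$x * (1 - ep$x) * (ep$ep1 - ep$ep2),
         dy_dt = ep$y * (1 - ep$y) * (ep$eh1 - ep$eh2))
}

# Bare numeric RHS used by the ODE integrator and Jacobian internals:
# avoids tibble overhead on the hot path.
rhs_fn <- function(params) {
  ap <- params$u1 - params$s1 - params$c2 - params$u2 + params$s2 # advantage at y = 0
  bp <- params$c2 - params$c1
  kh <- params$p1 + params$p2 - params$p3
  c3 <- params$c3
  function(x, y) {
    c(x * (1 - x) * (ap + bp * y),
      y * (1 - y) * (kh * x - c3))
  }
}
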