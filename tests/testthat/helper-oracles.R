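# Independent oracles, kept deliberately separate from the package internals:
# the expanded cubic polynomial form of the replicator equations, and a
# central-finite-difference Jacobian of the package's own right-hand side.

expanded_rhs <- function(p, x, y) {
  fx <- x * (x - 1) * (p$c2 + p$s1 - p$s2 - p$u1 + p$u2 + p$c1 * y - p$c2 * y)
  fy <- y * (y - 1) * (p$c3 - p$p1 * x - p$p2 * x + p$p3 * x)
  c(dx_dt = fx, dy_dt = fy)
}

fd_jacobian <- function(p, x, y, h = 1e-6) {
  f <- function(x, y) {
    r <- replicator_rhs(p, x, y)
    c(r$dx_dt, r$dy_dt)
  }
  # central differences, shifted inward at the square's edges
  xm <- max(x - h, 0); xp <- min(x + h, 1)
  ym <- max(y - h, 0); yp <- min(y + h, 1)
  dx <- (f(xp, y) - f(xm, y)) / (xp - xm)
  dy <- (f(x, yp) - f(x, ym)) / (yp - ym)
  matrix(c(dx[1], dx[2], dy[1], dy[2]), nrow = 2,
         dimnames = list(c("x", "y"), c("x", "y")))
}

random_states <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(x = runif(n), y = runif(n))
}

fast_settings <- function() integration_settings()
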