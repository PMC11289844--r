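test_that("equilibrium enumeration returns four corners plus one interior candidate", {
  eq <- enumerate_equilibria(baseline_params())
  expect_identical(nrow(eq), 5L)
  corners <- dplyr::filter(eq, kind == "corner")
  expect_identical(nrow(corners), 4L)
  expect_setequal(paste(corners$x, corners$y), c("0 0", "1 0", "0 1", "1 1"))
  d <- dplyr::filter(eq, point == "D")
  expect_equal(d$x, 4 / 3)
  expect_equal(d$y, -4)
  expect_false(d$exists)
})

test_that("interior candidate coordinates follow the closed forms", {
  eq <- enumerate_equilibria(baseline_params(c3 = 1.5, s2 = 6))
  d <- dplyr::filter(eq, point == "D")
  expect_equal(d$x, 0.5)
  expect_equal(d$y, -8)
  expect_false(d$exists)
})

test_that("a zero interior denominator is flagged, not an error", {
  # p1 + p2 == p3 kills the x0 denominator
  eq <- enumerate_equilibria(baseline_params(p3 = 9))
  d <- dplyr::filter(eq, point == "D")
  expect_true(d$degenerate)
  expect_false(d$exists)
  expect_true(is.na(d$x))
  # c1 == c2 kills the y0 denominator
  d2 <- dplyr::filter(enumerate_equilibria(baseline_params(c1 = 1)), point == "D")
  expect_true(d2$degenerate)
})

test_that("the interior candidate exists precisely in the bistable regime, with zero trace", {
  for (p in generate_scenario_params(4, n = 3, seed = 21)) {
    d <- dplyr::filter(enumerate_equilibria(p), point == "D")
    expect_true(d$exists)
    J <- game_jacobian(p, d$x, d$y)
    expect_equal(sum(diag(J)), 0, tolerance = 1e-10)
  }
  for (p in generate_scenario_params(6, n = 3, seed = 22)) {
    expect_false(dplyr::filter(enumerate_equilibria(p), point == "D")$exists)
  }
})

test_that("analytic Jacobian matches hand values at the corners", {
  p <- baseline_params()
  expect_equal(game_jacobian(p, 1, 0),
               matrix(c(-2, 0, 0, -1), 2, dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(unname(diag(game_jacobian(p, 0, 0))), c(2, -4))
  expect_equal(unname(diag(game_jacobian(p, 0, 1))), c(2.5, 4))
})

test_that("analytic Jacobian agrees with central finite differences", {
  params <- generate_random_params(40, seed = 31)
  st <- random_states(40, seed = 32)
  for (i in seq_along(params)) {
    J <- game_jacobian(params[[i]], st$x[i], st$y[i])
    expect_equal(J, fd_jacobian(params[[i]], st$x[i], st$y[i]),
                 tolerance = 1e-6)
  }
})

test_that("off-diagonal Jacobian entries vanish exactly at all corners", {
  for (p in generate_random_params(10, seed = 33)) {
    ct <- corner_stability(p)
    expect_identical(ct$j12, rep(0, 4))
    expect_identical(ct$j21, rep(0, 4))
    expect_identical(ct$det, ct$j11 * ct$j22)
    expect_identical(ct$trace, ct$j11 + ct$j22)
  }
})

test_that("baseline corner stability reproduces the det/trace table", {
  ct <- corner_stability(baseline_params())
  row <- function(pt) dplyr::filter(ct, point == pt)
  expect_equal(row("A")[, c("det", "trace")], tibble::tibble(det = 2, trace = -3))
  expect_identical(row("A")$classification, "ess")
  expect_equal(row("O")$det, -8)
  expect_identical(row("O")$classification, "saddle")
  expect_equal(row("B")[, c("det", "trace")], tibble::tibble(det = 10, trace = 6.5))
  expect_identical(row("B")$classification, "unstable")
  expect_identical(row("C")$classification, "saddle")
})

test_that("the det/trace rule classifies all sign combinations", {
  expect_identical(
    classify_stability(det = c(2, 2, -8, 0, 2), trace = c(-3, 3, 5, 0, 0)),
    c("ess", "unstable", "saddle", "degenerate", "degenerate"))
})

test_that("find_ess returns the stable corners and honours the cross-check", {
  ess <- find_ess(baseline_params())
  expect_identical(ess$point, "A")
  expect_equal(c(ess$x, ess$y), c(1, 0))
  ess7 <- find_ess(baseline_params(p1 = 9))
  expect_identical(ess7$point, "C")
  expect_equal(c(ess7$x, ess7$y), c(1, 1))
})
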