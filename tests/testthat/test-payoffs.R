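test_that("payoff matrix cells equal their algebraic definitions", {
  pm <- payoff_matrix(baseline_params())
  cell <- function(ps, hs) dplyr::filter(pm, patient_strategy == ps,
                                         hospital_strategy == hs)
  cd <- cell("cross_regional", "direct")
  expect_equal(c(cd$patient_payoff, cd$hospital_payoff), c(2.5, 5.0))
  ii <- cell("in_area", "indirect")
  expect_equal(c(ii$patient_payoff, ii$hospital_payoff), c(0, 0))
  ci <- cell("cross_regional", "indirect")
  expect_equal(c(ci$patient_payoff, ci$hospital_payoff), c(2, 6))
  id <- cell("in_area", "direct")
  expect_equal(c(id$patient_payoff, id$hospital_payoff), c(0, -4))
})

test_that("in-area patient payoff never depends on the hospital strategy", {
  for (p in generate_random_params(10, seed = 11)) {
    pm <- dplyr::filter(payoff_matrix(p), patient_strategy == "in_area")
    expect_identical(pm$patient_payoff[1], pm$patient_payoff[2])
    # and the (in_area, indirect) hospital payoff is the zero benchmark
    expect_identical(pm$hospital_payoff[pm$hospital_strategy == "indirect"], 0)
  }
})

test_that("expected payoffs match the mixed-strategy formulas", {
  p <- baseline_params()
  e0 <- expected_payoffs(p, x = 0.5, y = 0)
  expect_equal(e0$ep1, 2)
  expect_equal(e0$ep2, 0)
  e1 <- expected_payoffs(p, x = 0.5, y = 1)
  expect_equal(e1$ep1, 2.5)
  # pure-strategy populations collapse the mean onto the pure payoff
  for (q in generate_random_params(5, seed = 7)) {
    e <- expected_payoffs(q, x = c(1, 0), y = runif(2))
    expect_equal(e$ep_mean, c(e$ep1[1], e$ep2[2]))
    e <- expected_payoffs(q, x = runif(2), y = c(1, 0))
    expect_equal(e$eh_mean, c(e$eh1[1], e$eh2[2]))
  }
})

test_that("replicator velocities match hand-computed values and vanish on edges", {
  p <- baseline_params()
  v <- replicator_rhs(p, 0.5, 0.5)
  expect_equal(v$dx_dt, 0.5625)
  expect_equal(v$dy_dt, -0.625)
  corners <- replicator_rhs(p, c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(corners$dx_dt, rep(0, 4))
  expect_equal(corners$dy_dt, rep(0, 4))
  edge <- replicator_rhs(p, 1, 0.3)
  expect_identical(edge$dx_dt, 0)
})

test_that("matrix-based velocities agree with the expanded cubic polynomial", {
  params <- generate_random_params(20, seed = 42)
  st <- random_states(20, seed = 43)
  for (i in seq_along(params)) {
    got <- replicator_rhs(params[[i]], st$x[i], st$y[i])
    want <- expanded_rhs(params[[i]], st$x[i], st$y[i])
    expect_equal(c(got$dx_dt, got$dy_dt), unname(want), tolerance = 1e-12)
  }
})

test_that("velocity signs follow the payoff-advantage signs in the interior", {
  params <- generate_random_params(25, seed = 5)
  set.seed(6)
  for (p in params) {
    x <- runif(1, 0.01, 0.99); y <- runif(1, 0.01, 0.99)
    e <- expected_payoffs(p, x, y)
    v <- replicator_rhs(p, x, y)
    expect_identical(sign(v$dx_dt), sign(e$ep1 - e$ep2))
    expect_identical(sign(v$dy_dt), sign(e$eh1 - e$eh2))
  }
})

test_that("dynamics are invariant under common shifts of paired payoffs", {
  params <- generate_random_params(10, seed = 9)
  st <- random_states(10, seed = 10)
  shift <- function(p, fields, d) {
    for (f in fields) p[[f]] <- p[[f]] + d
    p
  }
  for (i in seq_along(params)) {
    p <- params[[i]]
    base <- replicator_rhs(p, st$x[i], st$y[i])
    for (pair in list(c("u1", "u2"), c("s1", "s2"), c("p1", "p3"))) {
      v <- replicator_rhs(shift(p, pair, 2.718), st$x[i], st$y[i])
      expect_equal(c(v$dx_dt, v$dy_dt), c(base$dx_dt, base$dy_dt),
                   tolerance = 1e-12)
    }
  }
})
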