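# The integer sweeps are shared across several blocks; compute them once.
bl <- baseline_params()
sw_u1 <- sweep_parameter(bl, "u1", 1:10)
sw_u2 <- sweep_parameter(bl, "u2", 4:9)
sw_s1 <- sweep_parameter(bl, "s1", 1:8)
sw_s2 <- sweep_parameter(bl, "s2", 1:8)
sw_c2 <- sweep_parameter(bl, "c2", 1:6)
sw_p1 <- sweep_parameter(bl, "p1", 7:12)
sw_c3 <- sweep_parameter(bl, "c3", 1:6)

test_that("the payoff advantages reduce to the published affine forms", {
  adv <- analytic_advantage(bl)
  pat <- dplyr::filter(adv, player == "patient")
  expect_equal(c(pat$intercept, pat$slope), c(2, 0.5))   # 2 + 0.5 y
  hos <- dplyr::filter(adv, player == "hospital")
  expect_equal(c(hos$intercept, hos$slope), c(-4, 3))    # 3 x - 4
  # the degenerate boundary case behind the cross-regional utility switch
  adv4 <- analytic_advantage(baseline_params(u1 = 4))
  pat4 <- dplyr::filter(adv4, player == "patient")
  expect_equal(c(pat4$intercept, pat4$slope), c(0, 0.5)) # 0.5 y, zero at y = 0
  expect_equal(c(pat4$min, pat4$max), c(0, 0.5))
})

test_that("patient-side switches land on the observed integer thresholds", {
  expect_equal(as.numeric(detect_threshold(sw_u1, "patient", "up")), 5)
  expect_equal(as.numeric(detect_threshold(sw_u2, "patient", "up")), 7)
  expect_equal(as.numeric(detect_threshold(sw_s1, "patient", "up")), 6)
  # in-area cost: patients stay in-area only at the lowest value
  expect_equal(max(sw_s2$value[!is.na(sw_s2$patient_limit) &
                                 sw_s2$patient_limit == 0]), 1)
  # without direct settlement, extra travel costs are tolerated up to 3
  expect_equal(as.numeric(detect_threshold(sw_c2, "patient", "down")), 3)
})

test_that("degenerate sweep values are skipped, not misread as switches", {
  # at u1 = 4 the patient advantage touches zero on the y = 0 edge: the
  # scenario is a boundary, no corner limit exists, and the confirmed switch
  # is at 5, not 4
  row4 <- dplyr::filter(sw_u1, value == 4)
  expect_true(is.na(row4$scenario_id) && row4$boundary)
  expect_true(is.na(row4$patient_limit))
  th <- detect_threshold(sw_u1, "patient", "up")
  expect_true(attr(th, "ambiguous"))
})

test_that("hospitals are indifferent to every patient-side parameter", {
  for (sw in list(sw_u1, sw_u2, sw_s1, sw_s2, sw_c2)) {
    defined <- !is.na(sw$hospital_limit)
    expect_true(any(defined))
    expect_true(all(sw$hospital_limit[defined] == 0))
    expect_true(all(sw$hospital_drift == -1))
    expect_true(is.na(as.numeric(detect_threshold(sw, "hospital", "up"))))
  }
})

test_that("hospitals adopt direct settlement once its financial benefit covers the cost", {
  expect_equal(as.numeric(detect_threshold(sw_p1, "hospital", "up")), 9)
  # patients travel at every swept benefit value
  expect_true(all(sw_p1$patient_limit[!is.na(sw_p1$patient_limit)] == 1))
})

test_that("the hospital input-cost switch is analytically at 3, flagged as degenerate there", {
  asw <- attr(sw_c3, "analytic_switch")
  hos <- dplyr::filter(asw, player == "hospital", bound == "max")
  expect_equal(hos$at, 3)  # c3 = p1 + p2 - p3
  row3 <- dplyr::filter(sw_c3, value == 3)
  expect_true(is.na(row3$scenario_id) && row3$boundary)
  expect_true(is.na(row3$hospital_limit))
  # the numerically confirmed flip is only at the next integer, and the
  # discrepancy against the analytic boundary is flagged
  disc <- dplyr::filter(sweep_discrepancies(sw_c3), player == "hospital")
  expect_equal(disc$numeric_threshold, 4)
  expect_true(disc$ambiguous)
  expect_true(disc$beyond_analytic)
  expect_equal(disc$analytic_boundaries[[1]], 3)
})

test_that("one-sided analytic drift always agrees with the numeric basin limits", {
  for (sw in list(sw_u1, sw_u2, sw_s1, sw_s2, sw_c2, sw_p1, sw_c3)) {
    strictly <- !is.na(sw$patient_limit) & !is.na(sw$patient_drift) &
      sw$patient_drift != 0
    expect_true(all(sw$patient_limit[strictly] ==
                      (sw$patient_drift[strictly] + 1) / 2))
    strictly_h <- !is.na(sw$hospital_limit) & !is.na(sw$hospital_drift) &
      sw$hospital_drift != 0
    expect_true(all(sw$hospital_limit[strictly_h] ==
                      (sw$hospital_drift[strictly_h] + 1) / 2))
  }
})

test_that("sweep values outside the canonical regime still classify into scenarios", {
  low <- dplyr::filter(sw_u1, value %in% 1:3)  # u1 < u2 violates the regime
  expect_true(all(low$scenario_id == 1L))
  expect_true(all(low$ess == "O"))
})

test_that("glance summarises a sweep's thresholds", {
  g <- glance(sw_u1)
  expect_identical(g$parameter, "u1")
  expect_equal(g$patient_up, 5)
  expect_true(is.na(g$hospital_up))
})
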