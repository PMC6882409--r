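test_that("exact piecewise data give the exact breakpoint and slopes", {
  x <- seq(0.5, 12, by = 0.25)
  y <- ifelse(x < 5, 10 * x, 50)
  fit <- fit_pcrit(x, y)
  expect_false(fit$degenerate)
  expect_equal(fit$pcrit_kpa, 5, tolerance = 1e-4)
  expect_equal(unname(fit$conforming["slope"]), 10, tolerance = 1e-6)
  expect_equal(unname(fit$regulating["slope"]), 0, tolerance = 1e-4)
  expect_lte(fit$sse_segmented, fit$sse_single + 1e-9)
  # the two lines intersect at the breakpoint
  expect_equal(predict(fit, fit$pcrit_kpa - 1e-9),
               predict(fit, fit$pcrit_kpa + 1e-9), tolerance = 1e-6)
})

test_that("collinear data are flagged degenerate", {
  x <- seq(1, 10, by = 0.5)
  fit <- fit_pcrit(x, 3 * x + 2)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$pcrit_kpa))
  expect_equal(unname(fit$conforming["slope"]), 3, tolerance = 1e-9)
  expect_error(fit_pcrit(x[1:4], x[1:4]), "at least 6")
})

test_that("grid+refined breakpoint matches the exhaustive oracle", {
  for (s in 1:15) {
    d <- piecewise_points(s)
    fit <- fit_pcrit(d)
    ex <- exhaustive_breakpoint(d$po2_kpa, d$mo2)
    expect_lt(abs(fit$pcrit_kpa - ex), 0.01)
    expect_lte(fit$sse_segmented, fit$sse_single + 1e-9)
  }
})

test_that("the breakpoint is shift-equivariant and scale-invariant", {
  d <- piecewise_points(7)
  fit <- fit_pcrit(d)
  shifted <- fit_pcrit(d$po2_kpa + 2.5, d$mo2)
  expect_equal(shifted$pcrit_kpa, fit$pcrit_kpa + 2.5, tolerance = 1e-5)
  scaled <- fit_pcrit(d$po2_kpa, d$mo2 * 3.7)
  expect_equal(scaled$pcrit_kpa, fit$pcrit_kpa, tolerance = 1e-5)
})

test_that("binned closed-phase points land on the generating lines", {
  truth <- fish_truth(smr = 250, mmr = 750, pcrit_kpa = 6, loe_po2 = 1.5)
  tr <- simulate_closed_phase(truth, protocol_config(),
                              scenario_config(noise_sd = 0, seed = 1))
  pts <- closed_phase_mo2(tr)
  expect_gt(nrow(pts), 20)
  # points clear of the kink sit exactly on regulation/conformity lines
  reg <- pts$po2_kpa > truth$pcrit_kpa + 0.5
  conf <- pts$po2_kpa < truth$pcrit_kpa - 0.5
  expect_equal(pts$mo2[reg], rep(truth$smr, sum(reg)), tolerance = 1e-6)
  expect_equal(pts$mo2[conf],
               truth$smr * pts$po2_kpa[conf] / truth$pcrit_kpa,
               tolerance = 5e-3)
  # a bin spanning the whole trace degenerates to one point
  one <- closed_phase_mo2(tr, bin_s = max(tr$time_s) + 1)
  expect_identical(nrow(one), 1L)
  # and the fitted breakpoint recovers the true Pcrit
  fit <- fit_pcrit(pts)
  expect_equal(fit$pcrit_kpa, truth$pcrit_kpa, tolerance = 0.05)
})

test_that("SMR-crossing estimator agrees with construction", {
  x <- seq(0.5, 12, by = 0.25)
  y <- ifelse(x < 5, 10 * x, 50)
  fit <- fit_pcrit(x, y)
  expect_equal(as.numeric(pcrit_smr_crossing(fit, 50)), 5,
               tolerance = 1e-3)
  above <- pcrit_smr_crossing(fit, 80)
  expect_true("smr_above_plateau" %in% attr(above, "flags"))
  # a non-positive conforming slope cannot cross SMR from below
  set.seed(2)
  down <- fit_pcrit(x, 31 - 0.5 * x + rnorm(length(x), 0, 0.1))
  res <- pcrit_smr_crossing(down, 30)
  expect_true(is.na(res))
  expect_identical(attr(res, "flags"), "nonpositive_conforming_slope")
})

test_that("bootstrap intervals are reproducible and tight when exact", {
  x <- seq(0.5, 12, by = 0.25)
  y <- ifelse(x < 5, 10 * x, 50)
  fit <- fit_pcrit(x, y)
  ci <- confint(fit, seed = 4, B = 100)
  expect_lt(diff(as.numeric(ci)), 1e-4)   # noiseless: zero width
  d <- piecewise_points(3)
  fitn <- fit_pcrit(d)
  ci1 <- confint(fitn, seed = 11, B = 100)
  ci2 <- confint(fitn, seed = 11, B = 100)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  expect_lt(ci1[1], fitn$pcrit_kpa)
  expect_gt(ci1[2], fitn$pcrit_kpa)
  expect_error(confint(fitn, B = 50), "at least 100")
})

test_that("loss of equilibrium is read back in both unit systems", {
  truth <- fish_truth(pcrit_kpa = 6, loe_po2 = 2)
  tr <- simulate_closed_phase(truth, protocol_config(),
                              scenario_config(noise_sd = 0, seed = 1))
  loe <- detect_loe(tr)
  ev <- attr(tr, "loe_event")
  expect_equal(loe$loe_o2, ev$o2_mgl)
  expect_equal(loe$loe_po2,
               o2_mgl_to_kpa(loe$loe_o2, water_conditions(24)))
  expect_gte(loe$time_to_loe_min, 0)
  # LOE lies below the fitted breakpoint
  fit <- fit_pcrit(closed_phase_mo2(tr))
  expect_lt(loe$loe_po2, fit$pcrit_kpa)
  # stripped annotation is an error unless a time is supplied
  bare <- tr
  attr(bare, "loe_event") <- NULL
  expect_error(detect_loe(bare), "no LOE")
  manual <- detect_loe(bare, time_s = ev$time_s)
  expect_equal(manual$loe_o2, ev$o2_mgl)
})
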