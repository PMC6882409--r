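test_that("the rate equation reproduces hand arithmetic", {
  # 8 -> 7 mg/L over 20 min in 0.2985 L effective volume, 1.5 g fish
  expect_equal(compute_mo2(8, 7, v = 0.2985, t = 1 / 3, bw = 0.0015),
               597, tolerance = 1e-12)
  expect_identical(compute_mo2(7.2, 7.2, 0.3, 0.5, 0.002), 0)
  expect_lt(compute_mo2(7, 7.4, 0.3, 0.5, 0.002), 0)
  expect_error(compute_mo2(8, 7, v = 0, t = 1, bw = 1), "`v`")
  expect_error(compute_mo2(8, 7, v = 1, t = -1, bw = 1), "`t`")
  expect_error(compute_mo2(8, 7, v = 1, t = 1, bw = 0), "`bw`")
})

test_that("the rate equation scales as its algebra dictates", {
  base <- compute_mo2(8, 7, 0.3, 0.5, 0.002)
  expect_equal(compute_mo2(8, 6, 0.3, 0.5, 0.002), 2 * base)
  expect_equal(compute_mo2(8, 7, 0.6, 0.5, 0.002), 2 * base)
  expect_equal(compute_mo2(8, 7, 0.3, 1.0, 0.002), base / 2)
  expect_equal(compute_mo2(8, 7, 0.3, 0.5, 0.004), base / 2)
})

test_that("slope fitting recovers exact lines and degrades gracefully", {
  t_s <- seq(0, 1199, by = 5)
  line <- .new_trace_for_test(t_s, 8 - 0.5 * t_s / 3600)
  f <- fit_cycle_slope(line, 0, 1200, trim_s = 60)
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$o2_t0 - f$o2_t1, 0.5 * f$elapsed_h, tolerance = 1e-12)

  flat <- .new_trace_for_test(t_s, rep(7.5, length(t_s)))
  f2 <- fit_cycle_slope(flat, 0, 1200, trim_s = 60)
  expect_equal(f2$slope, 0, tolerance = 1e-12)
  expect_identical(f2$r_squared, 0)   # zero-variance convention

  expect_null(fit_cycle_slope(line, 0, 100, trim_s = 60))  # too few
})

test_that("noisy slopes stay within their sampling error", {
  set.seed(21)
  t_s <- seq(0, 1199, by = 1)
  for (rep in 1:5) {
    y <- 8 - 1.2 * t_s / 3600 + rnorm(length(t_s), 0, 0.02)
    tr <- .new_trace_for_test(t_s, y)
    f <- fit_cycle_slope(tr, 0, 1200, trim_s = 60)
    use <- t_s >= 60
    t_h <- t_s[use] / 3600
    # closed-form OLS sd of the slope
    slope_sd <- 0.02 / sqrt(sum((t_h - mean(t_h))^2))
    expect_lt(abs(f$slope - (-1.2)), 3 * slope_sd)
  }
})

test_that("background subtraction is interpolated and bounded at 15%", {
  # exact binary arithmetic so the threshold comparison is sharp
  rec <- make_records(rep(115, 20), v_eff = 0.25, bw = 0.5)
  rec$mo2_raw <- rep(115, 20); rec$mo2 <- rec$mo2_raw
  blanks <- data.frame(time_h = c(0, 10), slope = c(30, 30))
  out <- background_correct(rec, blanks)
  expect_equal(out$mo2, rep(100, 20))
  expect_equal(out$background_mo2, rep(15, 20))
  # background exactly 15% of the provisional resting rate: acceptable
  expect_false(any(grepl("background_exceeds_15pct", out$qc_flags)))
  # a hair over the threshold: flagged
  blanks_hi <- data.frame(time_h = c(0, 10),
                          slope = c(30, 30) * (1 + 1e-6))
  out_hi <- background_correct(rec, blanks_hi)
  expect_true(all(grepl("background_exceeds_15pct", out_hi$qc_flags)))
})

test_that("zero blanks leave records untouched; no blanks flag globally", {
  rec <- make_records(c(100, 110, 120))
  out <- background_correct(rec, data.frame(time_h = 0, slope = 0))
  expect_equal(out$mo2, rec$mo2)
  expect_warning(un <- background_correct(rec, NULL), "uncorrected")
  expect_true(all(grepl("no_background", un$qc_flags)))
  expect_equal(un$mo2, rec$mo2)
})

test_that("corrected rates recover truth when background is known", {
  truth <- fish_truth(smr = 250, mmr = 750, recovery_halflife_h = 0.5)
  pr <- quick_protocol()
  v_eff <- pr$chamber_volume - truth$body_mass
  bg <- background_model(daily_slopes = 0.10 * truth$smr *
                           truth$body_mass / v_eff)
  tr <- simulate_intermittent_trace(truth, pr, bg,
                                    scenario_config(noise_sd = 0.02,
                                                    seed = 31))
  rec <- extract_mo2(tr, pr, blanks = blank_records(bg, 1))
  late <- rec$mo2[rec$start_s / 3600 > 20 & rec$qc_pass]
  expect_equal(mean(late), truth$smr, tolerance = 0.01)
})

test_that("QC flags the floor, poor fits and oxygen gains", {
  t_s <- seq(0, 1199, by = 5)
  dipping <- .new_trace_for_test(t_s, seq(2, 0.9, length.out =
                                            length(t_s)))
  f <- fit_cycle_slope(dipping, 0, 1200)
  rec <- make_records(100)
  rec$min_o2 <- f$min_o2
  out <- qc_filter(rec)
  expect_true(grepl("below_1mgL_floor", out$qc_flags[1]))
  expect_false(out$qc_pass[1])

  set.seed(8)
  noise_only <- .new_trace_for_test(t_s, 7 + rnorm(length(t_s), 0, 0.05))
  fn <- fit_cycle_slope(noise_only, 0, 1200)
  recn <- make_records(100)
  recn$r_squared <- fn$r_squared
  outn <- qc_filter(recn, r2_threshold = 0.9)
  expect_true(grepl("low_r2", outn$qc_flags[1]))

  gain <- make_records(-5)
  gain$o2_t0 <- 7; gain$o2_t1 <- 7.3
  outg <- qc_filter(gain)
  expect_true(grepl("oxygen_gain", outg$qc_flags[1]))

  clean <- qc_filter(make_records(c(200, 210)))
  expect_identical(clean$qc_flags, c("", ""))
  expect_true(all(clean$qc_pass))
})

test_that("an all-clean noiseless run carries no flags", {
  truth <- fish_truth(recovery_halflife_h = 0.5)
  pr <- quick_protocol(total_hours = 4)
  tr <- simulate_intermittent_trace(truth, pr,
                                    scenario = scenario_config(
                                      noise_sd = 0, seed = 1))
  rec <- extract_mo2(tr, pr, blanks = data.frame(time_h = 0, slope = 0))
  expect_true(all(rec$qc_flags == ""))
  expect_true(all(rec$qc_pass))
})
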