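test_that("truth and protocol constructors enforce their invariants", {
  expect_error(fish_truth(smr = 300, mmr = 200), "`mmr` > `smr`")
  expect_error(fish_truth(pcrit_kpa = 3, loe_po2 = 4), "loe_po2")
  expect_error(fish_truth(body_mass = 0), "body_mass")
  expect_error(protocol_config(sample_interval = 120), "<= 60")
  expect_error(protocol_config(chamber_volume = -1), "positive")
  expect_error(background_model(daily_slopes = -0.1), "non-negative")
})

test_that("same seed gives byte-identical traces", {
  tr1 <- simulate_intermittent_trace(
    fish_truth(), quick_protocol(total_hours = 3),
    scenario = scenario_config(noise_sd = 0.02, seed = 42))
  tr2 <- simulate_intermittent_trace(
    fish_truth(), quick_protocol(total_hours = 3),
    scenario = scenario_config(noise_sd = 0.02, seed = 42))
  expect_identical(tr1, tr2)
  cl1 <- simulate_closed_phase(fish_truth(), quick_protocol(),
                               scenario_config(noise_sd = 0.02, seed = 9))
  cl2 <- simulate_closed_phase(fish_truth(), quick_protocol(),
                               scenario_config(noise_sd = 0.02, seed = 9))
  expect_identical(cl1, cl2)
})

test_that("noiseless cycles reproduce the generating metabolic rate", {
  truth <- fish_truth(smr = 250, mmr = 750, recovery_halflife_h = 0.5)
  pr <- quick_protocol()
  tr <- simulate_intermittent_trace(truth, pr,
                                    scenario = scenario_config(
                                      noise_sd = 0, seed = 1))
  rec <- suppressWarnings(extract_mo2(tr, pr))
  # first (post-chase) cycle recovers MMR exactly
  expect_equal(rec$mo2[rec$is_mmr_cycle], truth$mmr, tolerance = 1e-9)
  # decay-complete late cycles recover SMR exactly
  late <- rec$mo2[rec$start_s / 3600 > 20]
  expect_equal(late, rep(truth$smr, length(late)), tolerance = 1e-9)
  # the post-chase sequence declines monotonically toward SMR
  expect_true(all(diff(rec$mo2) <= 1e-9))
})

test_that("oxygen mass balance closes in noiseless runs", {
  truth <- fish_truth(smr = 250, mmr = 750)
  pr <- quick_protocol(total_hours = 3)
  bg <- background_model(daily_slopes = 0.12)
  tr <- simulate_intermittent_trace(truth, pr, bg,
                                    scenario_config(noise_sd = 0,
                                                    seed = 1))
  v_eff <- pr$chamber_volume - truth$body_mass
  det_h <- pr$determination_minutes / 60
  cycles <- segment_cycles(tr, pr)
  for (k in seq_len(nrow(cycles))) {
    sel <- tr$time_s >= cycles$start_s[k] & tr$time_s < cycles$end_s[k]
    o2 <- tr$o2_mgl[sel]; t_h <- tr$time_s[sel] / 3600
    slope <- stats::cov(t_h, o2) / stats::var(t_h)
    consumed <- -slope * det_h * v_eff        # mg O2 over the cycle
    mo2_k <- truth$smr + (truth$mmr - truth$smr) *
      2^(-(cycles$start_s[k] / 3600) / truth$recovery_halflife_h)
    expected <- mo2_k * truth$body_mass * det_h + 0.12 * v_eff * det_h
    expect_equal(consumed, expected, tolerance = 1e-9)
  }
})

test_that("determinations never fall below the 1 mg/L protocol floor", {
  # a large fish in a small chamber forces the clamp
  truth <- fish_truth(body_mass = 0.004, smr = 900, mmr = 2000)
  expect_warning(
    tr <- simulate_intermittent_trace(truth, quick_protocol(
      total_hours = 2),
      scenario = scenario_config(noise_sd = 0, seed = 1)),
    "clamped")
  det <- tr$o2_mgl[tr$phase == "determination"]
  expect_true(all(det >= 1 - 1e-12))
  expect_gt(length(attr(tr, "clamped_cycles")), 0)
})

test_that("closed phase is regulation then conformity down to LOE", {
  truth <- fish_truth(smr = 250, mmr = 750, pcrit_kpa = 6, loe_po2 = 2)
  pr <- protocol_config()
  tr <- simulate_closed_phase(truth, pr,
                              scenario_config(noise_sd = 0, seed = 1))
  cond <- water_conditions(24)
  v_eff <- pr$chamber_volume - truth$body_mass
  po2 <- o2_mgl_to_kpa(tr$o2_mgl, cond)
  dt_h <- diff(tr$time_s[1:2]) / 3600
  inst_mo2 <- -diff(tr$o2_mgl) / dt_h * v_eff / truth$body_mass
  # at PO2 = 2 x Pcrit the fish regulates at SMR
  i <- which.min(abs(po2 - 2 * truth$pcrit_kpa))
  expect_equal(inst_mo2[i], truth$smr, tolerance = 1e-3)
  # at PO2 = Pcrit / 2 the conforming rate is SMR / 2
  j <- which.min(abs(po2 - truth$pcrit_kpa / 2))
  expect_equal(inst_mo2[j], truth$smr / 2, tolerance = 1e-2)
  # LOE is recorded within one sample's depletion of the threshold
  ev <- attr(tr, "loe_event")
  expect_lte(ev$po2_kpa, truth$loe_po2)
  max_drop_kpa <- o2_mgl_to_kpa(
    truth$smr * truth$body_mass / v_eff * dt_h, cond)
  expect_gte(ev$po2_kpa, truth$loe_po2 - max_drop_kpa - 1e-9)
})

test_that("LOE above the starting oxygen is rejected", {
  truth <- fish_truth(pcrit_kpa = 12, loe_po2 = 9)
  expect_error(
    simulate_closed_phase(truth, protocol_config(),
                          scenario_config(oxygen_treatment = "low",
                                          noise_sd = 0, seed = 1)),
    "starting PO2")
})

test_that("cohorts are reproducible and empty cohorts are fine", {
  empty <- simulate_cohort(scenario_config(n_fish = 0))
  expect_identical(nrow(empty$manifest), 0L)
  sc <- scenario_config(n_fish = 3, seed = 11, noise_sd = 0.02)
  co1 <- simulate_cohort(sc, quick_protocol(total_hours = 2))
  co2 <- simulate_cohort(sc, quick_protocol(total_hours = 2))
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$traces, co2$traces)
  expect_length(co1$traces, 3)
})

test_that("drawn truths respect the physiological invariants", {
  set.seed(99)
  truths <- draw_fish_truths(1000)
  smr <- vapply(truths, `[[`, 0, "smr")
  mmr <- vapply(truths, `[[`, 0, "mmr")
  pcrit <- vapply(truths, `[[`, 0, "pcrit_kpa")
  loe <- vapply(truths, `[[`, 0, "loe_po2")
  mass <- vapply(truths, `[[`, 0, "body_mass")
  expect_true(all(mmr > smr & smr > 0))
  expect_true(all(loe > 0 & loe < pcrit))
  expect_true(all(mass > 0))
})
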