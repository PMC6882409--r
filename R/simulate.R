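# Simulation of chamber oxygen traces for fish with known physiology.
#
# The simulator reproduces the measurement protocol used for small
# freshwater fish: an exhaustive chase followed by ~24 h of intermittent-flow
# respirometry (20-min sealed determinations alternating with 2-min flushes
# in a 300 mL chamber), and a terminal closed phase in which the chamber is
# never flushed and the fish passes from oxy-regulation through
# oxy-conformity to loss of equilibrium. Because the generating physiology
# is known exactly, every downstream estimator can be checked by parameter
# recovery.

#' Ground-truth physiology of a simulated fish
#'
#' @param body_mass Body mass in kg (default 0.0015, a 1.5 g juvenile).
#' @param body_length Standard length in cm (default 5.5).
#' @param smr True standard metabolic rate, mg O2 kg^-1 h^-1.
#' @param mmr True maximum metabolic rate, mg O2 kg^-1 h^-1; must exceed
#'   `smr`.
#' @param pcrit_kpa True critical oxygen tension in kPa.
#' @param loe_po2 Oxygen partial pressure (kPa) at which the fish loses
#'   equilibrium; must be positive and below `pcrit_kpa`.
#' @param recovery_halflife_h Half-life (h) of the exponential decay of
#'   metabolic rate from MMR back to SMR after the chase. Default 2.
#'
#' @return An object of class `fish_truth`.
#' @examples
#' fish_truth(smr = 250, mmr = 750, pcrit_kpa = 6, loe_po2 = 2)
#' @export
fish_truth <- function(body_mass = 0.0015, body_length = 5.5,
                       smr = 250, mmr = 750, pcrit_kpa = 6, loe_po2 = 2,
                       recovery_halflife_h = 2) {
  if (body_mass <= 0) stop("`body_mass` must be positive", call. = FALSE)
  if (body_length <= 0) stop("`body_length` must be positive", call. = FALSE)
  if (!(mmr > smr && smr > 0)) {
    stop("need `mmr` > `smr` > 0", call. = FALSE)
  }
  if (!(loe_po2 > 0 && loe_po2 < pcrit_kpa)) {
    stop("need 0 < `loe_po2` < `pcrit_kpa`", call. = FALSE)
  }
  if (recovery_halflife_h <= 0) {
    stop("`recovery_halflife_h` must be positive", call. = FALSE)
  }
  structure(
    list(body_mass = body_mass, body_length = body_length,
         smr = smr, mmr = mmr, pcrit_kpa = pcrit_kpa, loe_po2 = loe_po2,
         recovery_halflife_h = recovery_halflife_h),
    class = "fish_truth"
  )
}

#' Respirometry protocol configuration
#'
#' Defaults follow the standard small-fish protocol: 300 mL chambers,
#' 20-min determinations, 2-min flushes, a 2-min exhaustive chase with 40 s
#' of air exposure before the first (MMR) determination, and ~24 h in the
#' chamber.
#'
#' @param chamber_volume Chamber volume in litres (default 0.300).
#' @param determination_minutes Sealed measurement period, minutes.
#' @param flush_minutes Flush period, minutes.
#' @param sample_interval Logger sampling interval in seconds (<= 60).
#' @param total_hours Total duration of the intermittent phase, hours.
#' @param chase_minutes Duration of the exhaustive chase, minutes.
#' @param air_exposure_seconds Air exposure after the chase, seconds.
#'
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(chamber_volume = 0.300,
                            determination_minutes = 20,
                            flush_minutes = 2,
                            sample_interval = 1,
                            total_hours = 24,
                            chase_minutes = 2,
                            air_exposure_seconds = 40) {
  vals <- c(chamber_volume, determination_minutes, flush_minutes,
            sample_interval, total_hours, chase_minutes,
            air_exposure_seconds)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all protocol parameters must be positive", call. = FALSE)
  }
  if (sample_interval > 60) {
    stop("`sample_interval` must be <= 60 s", call. = FALSE)
  }
  structure(
    list(chamber_volume = chamber_volume,
         determination_minutes = determination_minutes,
         flush_minutes = flush_minutes,
         sample_interval = sample_interval,
         total_hours = total_hours,
         chase_minutes = chase_minutes,
         air_exposure_seconds = air_exposure_seconds),
    class = "protocol_config"
  )
}

#' Background (blank-chamber) respiration model
#'
#' Microbial oxygen consumption of the chamber water, expressed as the
#' depletion slope a sealed blank chamber would show. One slope applies per
#' day; a multiplicative drift can let the background grow between system
#' rinses.
#'
#' @param daily_slopes Non-negative blank depletion slope(s),
#'   mg O2 L^-1 h^-1. A scalar is recycled across days.
#' @param drift Fractional change per day applied multiplicatively
#'   (default 0).
#'
#' @return An object of class `background_model`.
#' @export
background_model <- function(daily_slopes = 0, drift = 0) {
  if (any(daily_slopes < 0)) {
    stop("`daily_slopes` must be non-negative", call. = FALSE)
  }
  structure(list(daily_slopes = daily_slopes, drift = drift),
            class = "background_model")
}

#' Daily blank-chamber measurements implied by a background model
#'
#' Expands a [background_model()] into one blank slope per day, centred at
#' midday, in the layout expected by [background_correct()].
#'
#' @param background A [background_model()].
#' @param days Number of days to expand to.
#' @return Data frame with columns `day`, `time_h` (midday of each day) and
#'   `slope` (mg O2 L^-1 h^-1).
#' @export
blank_records <- function(background, days) {
  stopifnot(inherits(background, "background_model"), days >= 1)
  d <- seq_len(days)
  base <- rep_len(background$daily_slopes, days)
  data.frame(day = d,
             time_h = (d - 0.5) * 24,
             slope = base * (1 + background$drift)^(d - 1))
}

# background slope (mg/L/h) at time_h, linearly interpolated between daily
# blanks with constant extrapolation at the ends
.bg_slope_at <- function(time_h, blanks) {
  if (is.null(blanks) || nrow(blanks) == 0L) return(rep(0, length(time_h)))
  if (nrow(blanks) == 1L) return(rep(blanks$slope, length(time_h)))
  stats::approx(blanks$time_h, blanks$slope, xout = time_h, rule = 2)$y
}

#' Experimental scenario configuration
#'
#' One cell of the factorial design: a temperature (20, 24 or 28 degC)
#' crossed with an oxygen treatment (normoxia 6-8 mg/L or low-oxygen
#' 3-4 mg/L) and an acclimation duration (7, 14 or 30 days). The bath
#' oxygen defaults to the midpoint of the treatment band.
#'
#' @param temperature Water temperature, one of 20, 24, 28 degC.
#' @param oxygen_treatment `"normoxia"` (bath 7 mg/L) or `"low"`
#'   (bath 3.5 mg/L).
#' @param acclimation_days One of 7, 14, 30.
#' @param n_fish Number of fish (>= 1, or 0 for an empty cohort).
#' @param noise_sd Gaussian sensor noise sd on concentration, mg O2 L^-1.
#'   Default 0.02.
#' @param seed Integer seed; all randomness in a cohort flows from it.
#' @param bath_o2 Optional explicit bath concentration (mg/L) overriding the
#'   treatment midpoint.
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(temperature = 24,
                            oxygen_treatment = c("normoxia", "low"),
                            acclimation_days = 30,
                            n_fish = 1,
                            noise_sd = 0.02,
                            seed = 1L,
                            bath_o2 = NULL) {
  oxygen_treatment <- match.arg(oxygen_treatment)
  if (!temperature %in% c(20, 24, 28)) {
    stop("`temperature` must be one of 20, 24, 28 degC", call. = FALSE)
  }
  if (!acclimation_days %in% c(7, 14, 30)) {
    stop("`acclimation_days` must be one of 7, 14, 30", call. = FALSE)
  }
  if (n_fish < 0) stop("`n_fish` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(bath_o2)) {
    bath_o2 <- if (oxygen_treatment == "normoxia") 7 else 3.5
  }
  structure(
    list(temperature = temperature, oxygen_treatment = oxygen_treatment,
         acclimation_days = acclimation_days, n_fish = as.integer(n_fish),
         noise_sd = noise_sd, seed = as.integer(seed), bath_o2 = bath_o2),
    class = "scenario_config"
  )
}

# Effective respirometer volume: chamber minus the fish, assuming neutral
# buoyancy (fish density 1 g/mL so volume_L = mass_kg / 1.0).
effective_volume <- function(chamber_volume, body_mass) {
  v <- chamber_volume - body_mass / 1.0
  if (v <= 0) stop("fish volume exceeds chamber volume", call. = FALSE)
  v
}

# Instantaneous metabolic rate during post-chase recovery (mg O2 kg^-1 h^-1)
.recovery_mo2 <- function(truth, t_h) {
  truth$smr + (truth$mmr - truth$smr) * 2^(-t_h / truth$recovery_halflife_h)
}

.new_oxygen_trace <- function(df, body_mass, body_length, chamber_volume,
                              temperature, chamber_id = "ch1",
                              loe_event = NULL, clamped_cycles = integer()) {
  structure(df,
            class = c("oxygen_trace", "data.frame"),
            body_mass = body_mass,
            body_length = body_length,
            chamber_volume = chamber_volume,
            temperature = temperature,
            chamber_id = chamber_id,
            loe_event = loe_event,
            clamped_cycles = clamped_cycles)
}

#' @export
print.oxygen_trace <- function(x, ...) {
  cat(sprintf(
    "<oxygen_trace> %d samples over %.2f h; phases: %s\n",
    nrow(x), diff(range(x$time_s)) / 3600,
    paste(unique(x$phase), collapse = ", ")))
  cat(sprintf("  fish %.3f g in %.0f mL chamber at %.0f degC\n",
              attr(x, "body_mass") * 1000,
              attr(x, "chamber_volume") * 1000, attr(x, "temperature")))
  if (!is.null(attr(x, "loe_event"))) {
    ev <- attr(x, "loe_event")
    cat(sprintf("  LOE at %.1f min, %.2f mg O2/L\n",
                ev$time_s / 60, ev$o2_mgl))
  }
  invisible(x)
}

#' @export
plot.oxygen_trace <- function(x, ...) {
  cols <- c(determination = "steelblue", flush = "grey60", closed = "firebrick")
  graphics::plot(x$time_s / 3600, x$o2_mgl, type = "p", pch = ".",
                 col = cols[x$phase], xlab = "time (h)",
                 ylab = "dissolved O2 (mg/L)", ...)
  invisible(x)
}

#' Simulate an intermittent-flow respirometry trace
#'
#' Generates the full post-chase record of one fish: the first determination
#' starts at the fish's maximum metabolic rate, which decays exponentially
#' toward the standard rate with the truth's recovery half-life. Within each
#' sealed determination the chamber oxygen declines linearly at
#' (Mo2 x mass / V_eff + background slope), where V_eff is the chamber
#' volume minus the fish volume; the metabolic rate is held at its value at
#' the start of the determination. Flushes ramp the chamber back to the bath
#' concentration. Oxygen is never allowed below 1 mg/L during a
#' determination: offending cycles are clamped at the floor and flagged.
#'
#' @param truth A [fish_truth()].
#' @param protocol A [protocol_config()].
#' @param background A [background_model()] or NULL for none.
#' @param scenario A [scenario_config()]; supplies bath oxygen, temperature,
#'   sensor noise and the seed.
#'
#' @return An `oxygen_trace` data frame with columns `time_s`, `o2_mgl`,
#'   `temp_c`, `phase` (`"determination"`/`"flush"`) and `cycle_index`.
#'   Clamped cycle indices are recorded in the `clamped_cycles` attribute.
#' @examples
#' tr <- simulate_intermittent_trace(
#'   fish_truth(), protocol_config(sample_interval = 5, total_hours = 4),
#'   scenario = scenario_config(noise_sd = 0, seed = 1))
#' print(tr)
#' @export
simulate_intermittent_trace <- function(truth, protocol,
                                        background = NULL,
                                        scenario = scenario_config()) {
  stopifnot(inherits(truth, "fish_truth"),
            inherits(protocol, "protocol_config"),
            inherits(scenario, "scenario_config"))
  set.seed(scenario$seed)
  dt <- protocol$sample_interval
  det_s <- protocol$determination_minutes * 60
  flush_s <- protocol$flush_minutes * 60
  cycle_s <- det_s + flush_s
  n_cycles <- floor(protocol$total_hours * 3600 / cycle_s)
  if (n_cycles < 1) stop("protocol too short for one cycle", call. = FALSE)
  v_eff <- effective_volume(protocol$chamber_volume, truth$body_mass)
  bath <- scenario$bath_o2
  blanks <- if (is.null(background)) NULL else {
    blank_records(background, max(1, ceiling(protocol$total_hours / 24)))
  }

  time_list <- vector("list", n_cycles)
  o2_list <- vector("list", n_cycles)
  phase_list <- vector("list", n_cycles)
  cyc_list <- vector("list", n_cycles)
  clamped <- integer()

  for (k in seq_len(n_cycles)) {
    start_s <- (k - 1) * cycle_s
    t_det <- seq(start_s, start_s + det_s - dt, by = dt)
    mo2_k <- .recovery_mo2(truth, start_s / 3600)
    bg_k <- .bg_slope_at(start_s / 3600, blanks)
    rate <- mo2_k * truth$body_mass / v_eff + bg_k   # mg/L per h
    o2_det <- bath - rate * (t_det - start_s) / 3600
    end_val <- bath - rate * det_s / 3600
    if (end_val < 1) {
      o2_det <- pmax(o2_det, 1)
      end_val <- max(end_val, 1)
      clamped <- c(clamped, k)
    }
    t_fl <- seq(start_s + det_s, start_s + cycle_s - dt, by = dt)
    # linear ramp back to bath, reaching it at the start of the next cycle
    frac <- (t_fl - (start_s + det_s) + dt) / flush_s
    o2_fl <- end_val + (bath - end_val) * frac
    time_list[[k]] <- c(t_det, t_fl)
    o2_list[[k]] <- c(o2_det, o2_fl)
    phase_list[[k]] <- rep(c("determination", "flush"),
                           c(length(t_det), length(t_fl)))
    cyc_list[[k]] <- rep(k, length(t_det) + length(t_fl))
  }

  o2 <- unlist(o2_list)
  if (scenario$noise_sd > 0) {
    o2 <- o2 + stats::rnorm(length(o2), 0, scenario$noise_sd)
  }
  df <- data.frame(time_s = unlist(time_list),
                   o2_mgl = pmax(o2, 0),
                   temp_c = scenario$temperature,
                   phase = unlist(phase_list),
                   cycle_index = unlist(cyc_list))
  if (length(clamped)) {
    warning(sprintf("oxygen clamped at the 1 mg/L floor in %d cycle(s)",
                    length(clamped)), call. = FALSE)
  }
  .new_oxygen_trace(df, truth$body_mass, truth$body_length,
                    protocol$chamber_volume, scenario$temperature,
                    clamped_cycles = clamped)
}

#' Simulate a closed-respirometry phase ending in loss of equilibrium
#'
#' With the flushing cycle off, chamber oxygen is depleted by the fish
#' alone. While the oxygen partial pressure is at or above the true
#' critical tension, the fish oxy-regulates at its standard metabolic rate
#' and the concentration falls linearly; below the critical tension the
#' fish oxy-conforms, its rate proportional to PO2 through the origin, and
#' the decline becomes exponential. The trace ends at the first sample
#' whose PO2 reaches the fish's loss-of-equilibrium threshold; the event is
#' stored in the trace's `loe_event` attribute.
#'
#' @inheritParams simulate_intermittent_trace
#' @return An `oxygen_trace` with phase `"closed"` and an LOE event
#'   attribute (`time_s`, `o2_mgl`, `po2_kpa`).
#' @examples
#' tr <- simulate_closed_phase(fish_truth(), protocol_config(),
#'                             scenario_config(noise_sd = 0))
#' attr(tr, "loe_event")$o2_mgl
#' @export
simulate_closed_phase <- function(truth, protocol,
                                  scenario = scenario_config()) {
  stopifnot(inherits(truth, "fish_truth"),
            inherits(protocol, "protocol_config"),
            inherits(scenario, "scenario_config"))
  set.seed(scenario$seed + 1L)
  cond <- water_conditions(scenario$temperature)
  c0 <- scenario$bath_o2
  p0 <- o2_mgl_to_kpa(c0, cond)
  if (truth$loe_po2 >= p0) {
    stop("LOE threshold is at or above the starting PO2: nothing to observe",
         call. = FALSE)
  }
  v_eff <- effective_volume(protocol$chamber_volume, truth$body_mass)
  c_crit <- o2_kpa_to_mgl(truth$pcrit_kpa, cond)
  c_loe <- o2_kpa_to_mgl(truth$loe_po2, cond)
  r <- truth$smr * truth$body_mass / v_eff     # mg/L per h, regulating
  dt_h <- protocol$sample_interval / 3600

  # exact piecewise trajectory: linear until c_crit, then exponential
  t_break_h <- if (c0 > c_crit) (c0 - c_crit) / r else 0
  conc_at <- function(t_h) {
    ifelse(t_h <= t_break_h & c0 > c_crit,
           c0 - r * t_h,
           pmin(c0, c_crit) * exp(-(r / c_crit) * (t_h - t_break_h)))
  }
  # time to reach c_loe, to size the sample grid
  t_loe_h <- t_break_h + (c_crit / r) * log(min(c0, c_crit) / c_loe)
  t_h <- seq(0, t_loe_h + dt_h, by = dt_h)
  conc <- conc_at(t_h)
  i_loe <- match(TRUE, conc <= c_loe)
  t_h <- t_h[seq_len(i_loe)]
  conc <- conc[seq_len(i_loe)]
  if (scenario$noise_sd > 0) {
    conc <- conc + stats::rnorm(length(conc), 0, scenario$noise_sd)
  }
  conc <- pmax(conc, 0)
  df <- data.frame(time_s = t_h * 3600,
                   o2_mgl = conc,
                   temp_c = scenario$temperature,
                   phase = "closed",
                   cycle_index = NA_integer_)
  loe <- list(time_s = t_h[i_loe] * 3600,
              o2_mgl = conc[i_loe],
              po2_kpa = o2_mgl_to_kpa(conc[i_loe], cond))
  .new_oxygen_trace(df, truth$body_mass, truth$body_length,
                    protocol$chamber_volume, scenario$temperature,
                    loe_event = loe)
}

#' Draw ground-truth physiology for a cohort of fish
#'
#' Default distributions describe juvenile fish of ~1.5 g and ~5.5 cm
#' (condition factor near 0.9): mass ~ Normal(1.5 g, 0.15 g) truncated to
#' [0.8, 2.5] g; Fulton's K ~ Normal(0.90, 0.05) truncated to [0.7, 1.1],
#' giving length; SMR ~ Normal(250, 30) mg O2 kg^-1 h^-1 truncated above
#' 100; MMR = SMR x factor with factor ~ U(2.5, 4); Pcrit ~ U(4, 8) kPa;
#' LOE threshold ~ U(0.3, 0.6) x Pcrit.
#'
#' @param n Number of fish.
#' @return List of [fish_truth()] objects (uses the current RNG state).
#' @export
draw_fish_truths <- function(n) {
  truths <- vector("list", n)
  rtrunc <- function(mean, sd, lo, hi) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) return(x)
    }
  }
  for (i in seq_len(n)) {
    w_g <- rtrunc(1.5, 0.15, 0.8, 2.5)
    k <- rtrunc(0.90, 0.05, 0.7, 1.1)
    len <- (100 * w_g / k)^(1 / 3)
    smr <- rtrunc(250, 30, 100, Inf)
    mmr <- smr * stats::runif(1, 2.5, 4)
    pcrit <- stats::runif(1, 4, 8)
    loe <- pcrit * stats::runif(1, 0.3, 0.6)
    truths[[i]] <- fish_truth(body_mass = w_g / 1000, body_length = len,
                              smr = smr, mmr = mmr, pcrit_kpa = pcrit,
                              loe_po2 = loe)
  }
  truths
}

#' Simulate a cohort of fish under one scenario
#'
#' Draws ground-truth physiology per fish (via `truth_sampler`, default
#' [draw_fish_truths()]) and simulates each fish's intermittent trace and,
#' optionally, its closed phase. Each fish gets a deterministic seed derived
#' from the scenario seed, so a cohort is exactly reproducible.
#'
#' @param scenario A [scenario_config()]; `n_fish` and `seed` come from it.
#' @param protocol A [protocol_config()].
#' @param background A [background_model()] or NULL.
#' @param closed_phase Also simulate the closed LOE phase per fish?
#' @param truth_sampler Function `n -> list of fish_truth`.
#'
#' @return List with elements `truths`, `traces` (intermittent),
#'   `closed` (closed-phase traces or NULL) and `manifest` (data frame
#'   linking fish id, seed and true parameter values).
#' @export
simulate_cohort <- function(scenario, protocol = protocol_config(),
                            background = NULL, closed_phase = FALSE,
                            truth_sampler = draw_fish_truths) {
  stopifnot(inherits(scenario, "scenario_config"))
  n <- scenario$n_fish
  if (n == 0L) {
    return(list(truths = list(), traces = list(), closed = NULL,
                manifest = data.frame(fish_id = character(),
                                      seed = integer())))
  }
  set.seed(scenario$seed)
  truths <- truth_sampler(n)
  traces <- vector("list", n)
  closed <- if (closed_phase) vector("list", n) else NULL
  seeds <- scenario$seed + 7919L * seq_len(n)
  for (i in seq_len(n)) {
    sc_i <- scenario
    sc_i$seed <- seeds[i]
    traces[[i]] <- simulate_intermittent_trace(truths[[i]], protocol,
                                               background, sc_i)
    if (closed_phase) {
      closed[[i]] <- simulate_closed_phase(truths[[i]], protocol, sc_i)
    }
  }
  manifest <- data.frame(
    fish_id = sprintf("fish%03d", seq_len(n)),
    seed = seeds,
    body_mass_kg = vapply(truths, `[[`, 0, "body_mass"),
    body_length_cm = vapply(truths, `[[`, 0, "body_length"),
    true_smr = vapply(truths, `[[`, 0, "smr"),
    true_mmr = vapply(truths, `[[`, 0, "mmr"),
    true_pcrit_kpa = vapply(truths, `[[`, 0, "pcrit_kpa"),
    true_loe_po2 = vapply(truths, `[[`, 0, "loe_po2"),
    temperature = scenario$temperature,
    oxygen_treatment = scenario$oxygen_treatment,
    acclimation_days = scenario$acclimation_days)
  list(truths = truths, traces = traces, closed = closed,
       manifest = manifest)
}
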