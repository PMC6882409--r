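# Per-cycle oxygen-depletion slopes and mass-specific metabolic rate.
#
# The core rate equation is
#   Mo2 = ([O2]_t0 - [O2]_t1) * (V / t) * (1 / BW)
# with [O2]_t0 the concentration at the end of a flush (start of a sealed
# determination), [O2]_t1 the concentration at the end of the
# determination, V the chamber volume minus the fish volume (L), t the
# elapsed time (h) and BW the body weight (kg), giving mg O2 kg^-1 h^-1.

#' Mass-specific oxygen consumption rate from chamber depletion
#'
#' @param o2_t0 Oxygen concentration at the start of the sealed period,
#'   mg O2 per litre.
#' @param o2_t1 Oxygen concentration at its end, mg O2 per litre.
#' @param v Effective respirometer volume (chamber minus fish), litres.
#' @param t Elapsed time between the two readings, hours.
#' @param bw Body weight, kg.
#' @return Metabolic rate in mg O2 kg^-1 h^-1. Negative if oxygen rose.
#' @examples
#' compute_mo2(8, 7, v = 0.2985, t = 1 / 3, bw = 0.0015)  # 597
#' @export
compute_mo2 <- function(o2_t0, o2_t1, v, t, bw) {
  if (any(v <= 0)) stop("`v` must be positive", call. = FALSE)
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  if (any(bw <= 0)) stop("`bw` must be positive", call. = FALSE)
  (o2_t0 - o2_t1) * (v / t) * (1 / bw)
}

#' Fit the oxygen-depletion slope of one determination cycle
#'
#' Ordinary least-squares line of concentration against time over the
#' cycle's window, after trimming an initial mixing transient. The window
#' endpoints of the rate equation are evaluated from the fitted line rather
#' than raw samples, which is identical in the noiseless limit and robust
#' to sensor noise otherwise.
#'
#' @param trace An `oxygen_trace`.
#' @param start_s,end_s Cycle window (seconds, half-open).
#' @param trim_s Seconds discarded from the window start (default 60).
#' @param min_samples Minimum samples required after trimming (default 10).
#' @return List with `slope` (mg O2 L^-1 h^-1, negative = depletion),
#'   `r_squared` (0 by convention for a zero-variance response), `o2_t0`,
#'   `o2_t1` (fitted endpoint concentrations), `elapsed_h`, `n`, `min_o2`
#'   (minimum raw concentration in the untrimmed window), or NULL if too
#'   few samples remain.
#' @export
fit_cycle_slope <- function(trace, start_s, end_s, trim_s = 60,
                            min_samples = 10) {
  sel <- trace$time_s >= start_s & trace$time_s < end_s
  min_o2 <- if (any(sel)) min(trace$o2_mgl[sel]) else NA_real_
  use <- trace$time_s >= start_s + trim_s & trace$time_s < end_s
  if (sum(use) < min_samples) return(NULL)
  t_h <- (trace$time_s[use] - start_s) / 3600
  y <- trace$o2_mgl[use]
  fit <- stats::lm.fit(cbind(1, t_h), y)
  b <- fit$coefficients
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
  t0_h <- trim_s / 3600
  t1_h <- (end_s - start_s) / 3600
  list(slope = unname(b[2]),
       r_squared = max(0, min(1, r2)),
       o2_t0 = unname(b[1] + b[2] * t0_h),
       o2_t1 = unname(b[1] + b[2] * t1_h),
       elapsed_h = t1_h - t0_h,
       n = sum(use),
       min_o2 = min_o2)
}

#' Extract per-cycle metabolic rates from an intermittent trace
#'
#' Segments the trace, fits each determination's depletion slope, converts
#' to mass-specific rate, applies background correction when blank
#' measurements are supplied, and QC-flags cycles. Flagged cycles are never
#' dropped from the table; downstream summaries exclude them by flag.
#'
#' @param trace An `oxygen_trace` (fish metadata in attributes, or supply
#'   `body_mass`/`chamber_volume`).
#' @param protocol A [protocol_config()].
#' @param blanks Data frame of blank-chamber measurements with columns
#'   `time_h` and `slope` (depletion, mg O2 L^-1 h^-1), e.g. from
#'   [blank_records()]; NULL for no correction (flagged globally).
#' @param trim_s,min_samples Passed to [fit_cycle_slope()].
#' @param r2_threshold Minimum acceptable r-squared (default 0.90).
#' @param body_mass,chamber_volume Override the trace attributes.
#' @return A `mo2_records` data frame, one row per determination cycle.
#' @export
extract_mo2 <- function(trace, protocol = protocol_config(), blanks = NULL,
                        trim_s = 60, min_samples = 10, r2_threshold = 0.90,
                        body_mass = attr(trace, "body_mass"),
                        chamber_volume = attr(trace, "chamber_volume")) {
  stopifnot(inherits(trace, "oxygen_trace"))
  if (!is.finite(body_mass) || !is.finite(chamber_volume)) {
    stop("body mass and chamber volume are required", call. = FALSE)
  }
  cycles <- segment_cycles(trace, protocol)
  v_eff <- effective_volume(chamber_volume, body_mass)
  rows <- vector("list", nrow(cycles))
  for (i in seq_len(nrow(cycles))) {
    f <- fit_cycle_slope(trace, cycles$start_s[i], cycles$end_s[i],
                         trim_s = trim_s, min_samples = min_samples)
    if (is.null(f)) next
    mo2_raw <- compute_mo2(f$o2_t0, f$o2_t1, v_eff, f$elapsed_h, body_mass)
    rows[[i]] <- data.frame(
      cycle_index = cycles$cycle_index[i],
      start_s = cycles$start_s[i], end_s = cycles$end_s[i],
      is_mmr_cycle = cycles$is_mmr_cycle[i],
      slope = f$slope, r_squared = f$r_squared,
      o2_t0 = f$o2_t0, o2_t1 = f$o2_t1, elapsed_h = f$elapsed_h,
      effective_volume = v_eff, body_mass = body_mass,
      min_o2 = f$min_o2, mo2_raw = mo2_raw,
      background_mo2 = 0, mo2 = mo2_raw)
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec)) rec <- .empty_mo2_records(v_eff, body_mass)
  rec <- .as_mo2_records(rec)
  rec <- background_correct(rec, blanks)
  qc_filter(rec, r2_threshold = r2_threshold)
}

.empty_mo2_records <- function(v_eff, body_mass) {
  data.frame(cycle_index = integer(), start_s = numeric(),
             end_s = numeric(), is_mmr_cycle = logical(),
             slope = numeric(), r_squared = numeric(), o2_t0 = numeric(),
             o2_t1 = numeric(), elapsed_h = numeric(),
             effective_volume = numeric(), body_mass = numeric(),
             min_o2 = numeric(), mo2_raw = numeric(),
             background_mo2 = numeric(), mo2 = numeric())
}

.as_mo2_records <- function(df) {
  if (is.null(df$qc_flags)) df$qc_flags <- ""
  if (is.null(df$qc_pass)) df$qc_pass <- TRUE
  class(df) <- c("mo2_records", "data.frame")
  df
}

.add_flag <- function(flags, which, flag) {
  flags[which] <- ifelse(flags[which] == "", flag,
                         paste(flags[which], flag, sep = ","))
  flags
}

#' Subtract background (blank-chamber) respiration
#'
#' The blank depletion slope is linearly interpolated in time at each
#' cycle's midpoint, converted through the same volume/time/body-weight
#' scaling as the fish rates, and subtracted. Cycles whose background
#' exceeds 15 percent of the provisional resting rate (the lowest-10-percent
#' mean of the corrected rates) are flagged `background_exceeds_15pct`;
#' exactly 15 percent is acceptable. Without blanks, records are returned
#' uncorrected and flagged `no_background`.
#'
#' @param records A `mo2_records` data frame.
#' @param blanks Data frame with columns `time_h` and `slope`, or NULL.
#' @return The corrected `mo2_records`.
#' @export
background_correct <- function(records, blanks = NULL) {
  stopifnot(inherits(records, "mo2_records"))
  if (nrow(records) == 0L) return(records)
  if (is.null(blanks) || nrow(blanks) == 0L) {
    records$qc_flags <- .add_flag(records$qc_flags, TRUE, "no_background")
    warning("no blank measurements: background left uncorrected",
            call. = FALSE)
    return(records)
  }
  mid_h <- (records$start_s + records$end_s) / 2 / 3600
  bg_slope <- .bg_slope_at(mid_h, blanks)
  bg_mo2 <- bg_slope * records$effective_volume / records$body_mass
  records$background_mo2 <- bg_mo2
  records$mo2 <- records$mo2_raw - bg_mo2
  # provisional resting rate from the corrected non-MMR cycles
  pool <- records$mo2[!records$is_mmr_cycle]
  if (length(pool)) {
    k <- max(ceiling(0.10 * length(pool)), 1L)
    prov_smr <- mean(sort(pool)[seq_len(k)])
    if (prov_smr > 0) {
      over <- bg_mo2 > 0.15 * prov_smr
      records$qc_flags <- .add_flag(records$qc_flags, over,
                                    "background_exceeds_15pct")
    }
  }
  records
}

#' Quality-control flags for determination cycles
#'
#' Flags (without dropping) cycles where the chamber fell below the 1 mg/L
#' floor, the depletion fit is poor, oxygen rose instead of falling, or the
#' corrected rate is negative. `qc_pass` summarises eligibility for
#' SMR/MMR estimation.
#'
#' @param records A `mo2_records` data frame.
#' @param r2_threshold Minimum acceptable r-squared (default 0.90).
#' @param o2_floor Concentration floor, mg O2 per litre (default 1).
#' @return The flagged `mo2_records`.
#' @export
qc_filter <- function(records, r2_threshold = 0.90, o2_floor = 1) {
  stopifnot(inherits(records, "mo2_records"))
  if (nrow(records) == 0L) return(records)
  records$qc_flags <- .add_flag(records$qc_flags,
                                records$min_o2 < o2_floor,
                                "below_1mgL_floor")
  records$qc_flags <- .add_flag(records$qc_flags,
                                records$r_squared < r2_threshold,
                                "low_r2")
  records$qc_flags <- .add_flag(records$qc_flags,
                                records$o2_t1 > records$o2_t0,
                                "oxygen_gain")
  records$qc_flags <- .add_flag(records$qc_flags,
                                records$o2_t1 <= records$o2_t0 &
                                  records$mo2 < 0,
                                "negative_mo2")
  hard <- c("below_1mgL_floor", "low_r2", "oxygen_gain", "negative_mo2")
  records$qc_pass <- !vapply(strsplit(records$qc_flags, ","),
                             function(f) any(f %in% hard), TRUE)
  records
}

#' @export
print.mo2_records <- function(x, ...) {
  cat(sprintf("<mo2_records> %d cycles (%d QC-pass, %d flagged)\n",
              nrow(x), sum(x$qc_pass), sum(!x$qc_pass)))
  if (nrow(x)) {
    print(utils::head(as.data.frame(x)[c("cycle_index", "is_mmr_cycle",
                                         "mo2", "r_squared", "qc_flags")],
                      5))
    if (nrow(x) > 5) cat(sprintf("  ... %d more cycles\n", nrow(x) - 5L))
  }
  invisible(x)
}
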