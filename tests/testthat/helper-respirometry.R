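# Shared fixtures, built in code at test time.

# coarser logger sampling keeps simulated traces small in tests
quick_protocol <- function(sample_interval = 5, ...) {
  protocol_config(sample_interval = sample_interval, ...)
}

# minimal mo2_records table for estimator contract tests
make_records <- function(mo2, is_mmr = rep(FALSE, length(mo2)),
                         qc_pass = rep(TRUE, length(mo2)),
                         v_eff = 0.2985, bw = 0.0015) {
  n <- length(mo2)
  df <- data.frame(
    cycle_index = seq_len(n),
    start_s = (seq_len(n) - 1) * 1320,
    end_s = (seq_len(n) - 1) * 1320 + 1200,
    is_mmr_cycle = is_mmr,
    slope = -mo2 * bw / v_eff, r_squared = rep(1, n),
    o2_t0 = rep(8, n), o2_t1 = 8 - mo2 * bw / v_eff / 3,
    elapsed_h = rep(1 / 3, n),
    effective_volume = rep(v_eff, n), body_mass = rep(bw, n),
    min_o2 = rep(7, n), mo2_raw = mo2, background_mo2 = rep(0, n),
    mo2 = mo2, qc_flags = rep("", n), qc_pass = qc_pass)
  class(df) <- c("mo2_records", "data.frame")
  df
}

# bare trace around a raw time/oxygen series, for slope-fit contract tests
.new_trace_for_test <- function(time_s, o2_mgl, temp_c = 24,
                                body_mass = 0.0015,
                                chamber_volume = 0.3) {
  structure(
    data.frame(time_s = time_s, o2_mgl = o2_mgl, temp_c = temp_c,
               phase = NA_character_, cycle_index = NA_integer_),
    class = c("oxygen_trace", "data.frame"),
    body_mass = body_mass, body_length = 5.5,
    chamber_volume = chamber_volume, temperature = temp_c,
    chamber_id = "test", loe_event = NULL, clamped_cycles = integer())
}

# piecewise oxyconformer/oxyregulator points with Gaussian noise
piecewise_points <- function(seed, n = 40, pcrit = 6, plateau = 250,
                             noise = 10, xmin = 1, xmax = 12) {
  set.seed(seed)
  x <- sort(runif(n, xmin, xmax))
  y <- ifelse(x < pcrit, plateau * x / pcrit, plateau) +
    rnorm(n, 0, noise)
  data.frame(po2_kpa = x, mo2 = y)
}

# independent oracle: exhaustive breakpoint search on a fixed fine grid
exhaustive_breakpoint <- function(x, y, step = 0.001,
                                  band = c(0.05, 0.95)) {
  qs <- quantile(x, band, names = FALSE)
  grid <- seq(qs[1], qs[2], by = step)
  sse <- vapply(grid, function(p) {
    sum(.lm.fit(cbind(1, x, pmax(x - p, 0)), y)$residuals^2)
  }, 0)
  grid[which.min(sse)]
}

# independent oracle for the lowest-fraction mean
lowest_frac_mean <- function(v, frac = 0.10) {
  k <- max(ceiling(frac * length(v)), 1L)
  mean(sort(v)[seq_len(k)])
}
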