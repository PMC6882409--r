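# Critical oxygen tension by continuous two-segment breakpoint regression.
#
# Below its critical tension a fish oxy-conforms (metabolic rate roughly
# proportional to ambient PO2); above it, it oxy-regulates (rate
# independent of PO2). Pcrit is estimated as the breakpoint of a
# continuous two-segment least-squares fit of metabolic rate against PO2:
# the point of intersection of the conforming and regulating lines.

#' Binned metabolic-rate points from a closed-respirometry trace
#'
#' Partitions the closed-phase trace into consecutive fixed-duration bins,
#' fits each bin's depletion slope by OLS, converts slopes to mass-specific
#' rate through the effective volume and body weight, and pairs each rate
#' with the fitted mid-bin concentration expressed as partial pressure.
#'
#' @param trace A closed-phase `oxygen_trace`.
#' @param bin_s Bin duration, seconds (default 120). A bin spanning the
#'   whole trace yields a single point.
#' @param cond A [water_conditions()]; default built from the trace
#'   temperature.
#' @param body_mass,chamber_volume Override trace attributes.
#' @param min_bin_samples Minimum samples per bin (default 5).
#' @return Data frame with columns `po2_kpa`, `mo2`, `o2_mgl`, `t_mid_s`,
#'   `n`.
#' @export
closed_phase_mo2 <- function(trace, bin_s = 120,
                             cond = water_conditions(attr(trace,
                                                          "temperature")),
                             body_mass = attr(trace, "body_mass"),
                             chamber_volume = attr(trace, "chamber_volume"),
                             min_bin_samples = 5) {
  stopifnot(inherits(trace, "oxygen_trace"))
  if (nrow(trace) < 30) {
    stop("closed-phase trace has fewer than 30 samples", call. = FALSE)
  }
  v_eff <- effective_volume(chamber_volume, body_mass)
  t0 <- trace$time_s[1]
  bin_id <- floor((trace$time_s - t0) / bin_s)
  # an incomplete trailing fragment is not a fixed-duration bin: its slope
  # variance is far larger than the others', so it is dropped (unless the
  # whole trace is shorter than one bin)
  if (max(bin_id) > 0) {
    last_span <- diff(range(trace$time_s[bin_id == max(bin_id)]))
    if (last_span < 0.5 * bin_s) bin_id[bin_id == max(bin_id)] <- -1L
  }
  keep <- bin_id >= 0
  rows <- lapply(split(which(keep), bin_id[keep]), function(i) {
    if (length(i) < min_bin_samples) return(NULL)
    t_h <- (trace$time_s[i] - trace$time_s[i[1]]) / 3600
    y <- trace$o2_mgl[i]
    fit <- stats::lm.fit(cbind(1, t_h), y)
    b <- fit$coefficients
    mid_h <- mean(range(t_h))
    c_mid <- b[1] + b[2] * mid_h
    data.frame(po2_kpa = NA_real_,
               mo2 = -b[2] * v_eff / body_mass,
               o2_mgl = unname(c_mid),
               t_mid_s = trace$time_s[i[1]] + mid_h * 3600,
               n = length(i))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no bins with enough samples", call. = FALSE)
  }
  out$po2_kpa <- o2_mgl_to_kpa(pmax(out$o2_mgl, 0), cond)
  rownames(out) <- NULL
  out
}

# SSE of the continuous two-segment fit with breakpoint psi.
# Basis: intercept, x, hinge (x - psi)_+ ; the two lines meet at psi.
.seg_sse <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  sum(.lm.fit(X, y)$residuals^2)
}

.seg_coef <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  .lm.fit(X, y)$coefficients
}

# golden-section minimisation of f on [lo, hi]
.golden <- function(f, lo, hi, tol = 1e-6) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

#' Fit a continuous two-segment (broken-stick) regression for Pcrit
#'
#' For each candidate breakpoint, a constrained OLS is fitted in which the
#' conforming (low-PO2) and regulating (high-PO2) lines intersect exactly
#' at the breakpoint; the breakpoint minimising the residual sum of squares
#' is the critical oxygen tension. Candidates are the observed PO2 values
#' within the central quantile band, refined by golden-section search
#' within the bracketing intervals of the best candidates; exact ties go to
#' the smallest breakpoint. Collinear data (no slope change to find) yield
#' a degenerate fit carrying the single-line solution.
#'
#' @param po2 Ambient oxygen partial pressure, kPa (or a data frame with
#'   columns `po2_kpa` and `mo2`, e.g. from [closed_phase_mo2()]).
#' @param mo2 Mass-specific metabolic rate, mg O2 kg^-1 h^-1.
#' @param search_band Quantile band of PO2 searched for the breakpoint
#'   (default `c(0.05, 0.95)`), avoiding edge degeneracy.
#' @param refine_top Number of best grid candidates whose bracketing
#'   intervals are refined (default 3).
#' @return An object of class `pcrit_fit`: breakpoint (`pcrit_kpa`),
#'   per-segment slopes and intercepts, SSEs of the segmented and
#'   single-line fits, and the data. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `confint` (bootstrap), `residuals`.
#' @examples
#' x <- seq(1, 12, by = 0.5)
#' y <- ifelse(x < 5, 50 * x / 5, 50)
#' fit <- fit_pcrit(x, y)
#' coef(fit)
#' @export
fit_pcrit <- function(po2, mo2 = NULL, search_band = c(0.05, 0.95),
                      refine_top = 3) {
  if (is.data.frame(po2)) {
    mo2 <- po2$mo2
    po2 <- po2$po2_kpa
  }
  ok <- is.finite(po2) & is.finite(mo2)
  x <- po2[ok]; y <- mo2[ok]
  if (length(x) < 6) stop("need at least 6 points", call. = FALSE)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]

  single <- stats::lm.fit(cbind(1, x), y)
  sse_single <- sum(single$residuals^2)
  ss_y <- sum((y - mean(y))^2)

  qs <- stats::quantile(x, search_band, names = FALSE, type = 7)
  cand <- unique(x[x >= qs[1] & x <= qs[2]])
  degenerate <- FALSE
  if (length(cand) < 2 || sse_single <= 1e-12 * max(ss_y, 1)) {
    degenerate <- TRUE
  }

  if (!degenerate) {
    sse_cand <- vapply(cand, function(p) .seg_sse(x, y, p), 0)
    best <- order(sse_cand, cand)[seq_len(min(refine_top,
                                              length(cand)))]
    xs <- sort(unique(x))
    psi_best <- cand[best[1]]
    sse_best <- sse_cand[best[1]]
    for (b in best) {
      p0 <- cand[b]
      i <- findInterval(p0, xs)
      lo <- if (i > 1) xs[i - 1] else xs[1]
      hi <- if (i < length(xs)) xs[i + 1] else xs[length(xs)]
      lo <- max(lo, qs[1]); hi <- min(hi, qs[2])
      if (hi > lo) {
        p_ref <- .golden(function(p) .seg_sse(x, y, p), lo, hi,
                         tol = 1e-6)
        s_ref <- .seg_sse(x, y, p_ref)
        if (s_ref < sse_best - 1e-12 ||
            (abs(s_ref - sse_best) <= 1e-12 && p_ref < psi_best)) {
          psi_best <- p_ref; sse_best <- s_ref
        }
      }
    }
    cf <- .seg_coef(x, y, psi_best)
    # hinge coefficient ~ 0 means no detectable slope change
    if (!is.finite(cf[3]) ||
        sse_single - sse_best <= 1e-9 * max(sse_single, 1e-12)) {
      degenerate <- TRUE
    }
  }

  if (degenerate) {
    fit <- structure(
      list(pcrit_kpa = NA_real_,
           conforming = c(intercept = unname(single$coefficients[1]),
                          slope = unname(single$coefficients[2])),
           regulating = c(intercept = unname(single$coefficients[1]),
                          slope = unname(single$coefficients[2])),
           sse_segmented = sse_single, sse_single = sse_single,
           n = length(x), degenerate = TRUE, method = "grid",
           data = data.frame(po2_kpa = x, mo2 = y),
           search_band = search_band),
      class = "pcrit_fit")
    return(fit)
  }

  b0 <- unname(cf[1]); b1 <- unname(cf[2]); b2 <- unname(cf[3])
  structure(
    list(pcrit_kpa = psi_best,
         conforming = c(intercept = b0, slope = b1),
         regulating = c(intercept = b0 - b2 * psi_best, slope = b1 + b2),
         sse_segmented = sse_best, sse_single = sse_single,
         n = length(x), degenerate = FALSE, method = "grid",
         data = data.frame(po2_kpa = x, mo2 = y),
         search_band = search_band),
    class = "pcrit_fit")
}

#' @export
print.pcrit_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<pcrit_fit> degenerate: no breakpoint (data fit by one line)\n")
  } else {
    cat(sprintf("<pcrit_fit> Pcrit = %.3f kPa (n = %d points)\n",
                x$pcrit_kpa, x$n))
    cat(sprintf("  conforming:  mo2 = %.3f + %.3f * PO2\n",
                x$conforming["intercept"], x$conforming["slope"]))
    cat(sprintf("  regulating:  mo2 = %.3f + %.3f * PO2\n",
                x$regulating["intercept"], x$regulating["slope"]))
  }
  invisible(x)
}

#' @export
coef.pcrit_fit <- function(object, ...) {
  c(pcrit_kpa = object$pcrit_kpa,
    conforming_intercept = unname(object$conforming["intercept"]),
    conforming_slope = unname(object$conforming["slope"]),
    regulating_intercept = unname(object$regulating["intercept"]),
    regulating_slope = unname(object$regulating["slope"]))
}

#' @export
summary.pcrit_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  SSE segmented: %.4g, single line: %.4g (n = %d)\n",
              object$sse_segmented, object$sse_single, object$n))
  invisible(object)
}

#' @export
predict.pcrit_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$po2_kpa
       else if (is.data.frame(newdata)) newdata$po2_kpa
       else newdata
  if (object$degenerate) {
    return(object$conforming["intercept"] +
             object$conforming["slope"] * x)
  }
  below <- x < object$pcrit_kpa
  ifelse(below,
         object$conforming["intercept"] + object$conforming["slope"] * x,
         object$regulating["intercept"] + object$regulating["slope"] * x)
}

#' @export
residuals.pcrit_fit <- function(object, ...) {
  object$data$mo2 - predict(object)
}

#' @export
plot.pcrit_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$po2_kpa, d$mo2, pch = 19, col = "grey40",
                 xlab = "PO2 (kPa)", ylab = "Mo2 (mg O2/kg/h)", ...)
  xs <- seq(min(d$po2_kpa), max(d$po2_kpa), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "firebrick", lwd = 2)
  if (!x$degenerate) {
    graphics::abline(v = x$pcrit_kpa, lty = 2, col = "steelblue")
    graphics::mtext(sprintf("Pcrit = %.2f kPa", x$pcrit_kpa), side = 3,
                    adj = 0.98, line = -1.5, col = "steelblue")
  }
  invisible(x)
}

#' Bootstrap confidence interval for the Pcrit breakpoint
#'
#' Percentile interval over case-resampled refits of the segmented
#' regression. Degenerate resamples are dropped and counted.
#'
#' @param object A `pcrit_fit`.
#' @param parm Ignored (only the breakpoint has an interval).
#' @param level Confidence level (default 0.95).
#' @param B Number of bootstrap resamples (default 199, minimum 100).
#' @param seed Integer seed for reproducibility.
#' @param ... Unused.
#' @return Matrix with the lower and upper bounds; the attribute
#'   `n_degenerate` counts dropped degenerate refits.
#' @export
confint.pcrit_fit <- function(object, parm = "pcrit_kpa", level = 0.95,
                              B = 199, seed = NULL, ...) {
  if (B < 100) stop("`B` must be at least 100", call. = FALSE)
  if (object$degenerate) stop("degenerate fit has no breakpoint",
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  n <- nrow(d)
  bp <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    f <- tryCatch(fit_pcrit(d$po2_kpa[i], d$mo2[i],
                            search_band = object$search_band),
                  error = function(e) NULL)
    if (!is.null(f) && !f$degenerate) bp[b] <- f$pcrit_kpa
  }
  ok <- is.finite(bp)
  alpha <- (1 - level) / 2
  ci <- stats::quantile(bp[ok], c(alpha, 1 - alpha), names = FALSE)
  out <- matrix(ci, nrow = 1,
                dimnames = list("pcrit_kpa",
                                sprintf("%.1f %%",
                                        100 * c(alpha, 1 - alpha))))
  attr(out, "n_degenerate") <- sum(!ok)
  out
}

#' Alternative Pcrit: where the conforming line crosses SMR
#'
#' The PO2 at which the fitted conforming segment drops the metabolic rate
#' below the fish's standard metabolic rate. Reported alongside the
#' intersection-point breakpoint, which is the default definition.
#'
#' @param fit A `pcrit_fit`.
#' @param smr Standard metabolic rate, mg O2 kg^-1 h^-1.
#' @return PO2 in kPa, with a `flags` attribute; NA (flagged) when the
#'   conforming slope is not positive, and flagged `smr_above_plateau`
#'   when SMR exceeds the fitted regulating level at the breakpoint.
#' @export
pcrit_smr_crossing <- function(fit, smr) {
  stopifnot(inherits(fit, "pcrit_fit"))
  b0 <- unname(fit$conforming["intercept"])
  b1 <- unname(fit$conforming["slope"])
  flags <- character()
  if (!is.finite(b1) || b1 <= 0) {
    return(structure(NA_real_, flags = "nonpositive_conforming_slope"))
  }
  if (!fit$degenerate) {
    plateau <- unname(fit$regulating["intercept"] +
                        fit$regulating["slope"] * fit$pcrit_kpa)
    if (smr > plateau) flags <- c(flags, "smr_above_plateau")
  }
  structure((smr - b0) / b1, flags = flags)
}

#' Loss-of-equilibrium record from a closed-phase trace
#'
#' @param trace A closed-phase `oxygen_trace` carrying an LOE event (from
#'   the simulator or a trace file), or supply `time_s` explicitly.
#' @param cond A [water_conditions()]; default from the trace temperature.
#' @param time_s Optional event time overriding the annotation.
#' @return List of class `loe_record`: `loe_o2` (mg/L), `loe_po2` (kPa)
#'   and `time_to_loe_min` since the start of the closed phase.
#' @export
detect_loe <- function(trace,
                       cond = water_conditions(attr(trace, "temperature")),
                       time_s = NULL) {
  stopifnot(inherits(trace, "oxygen_trace"))
  ev <- attr(trace, "loe_event")
  if (is.null(time_s)) {
    if (is.null(ev)) stop("trace has no LOE event annotation",
                          call. = FALSE)
    t_ev <- ev$time_s
    o2_ev <- ev$o2_mgl
  } else {
    i <- which.min(abs(trace$time_s - time_s))
    t_ev <- trace$time_s[i]
    o2_ev <- trace$o2_mgl[i]
  }
  structure(list(loe_o2 = o2_ev,
                 loe_po2 = o2_mgl_to_kpa(o2_ev, cond),
                 time_to_loe_min = (t_ev - trace$time_s[1]) / 60),
            class = "loe_record")
}

#' @export
print.loe_record <- function(x, ...) {
  cat(sprintf("LOE at %.2f mg O2/L (%.2f kPa) after %.1f min\n",
              x$loe_o2, x$loe_po2, x$time_to_loe_min))
  invisible(x)
}
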