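# Per-fish metabolic summaries: SMR, MMR, aerobic scope, condition factor.

#' Standard metabolic rate: mean of the lowest 10 percent of determinations
#'
#' Eligible measurements are the corrected, QC-passing determination cycles
#' excluding the post-chase MMR cycle. The lowest `ceiling(0.10 * n)`
#' values (minimum one) are averaged; ties at the cutoff are resolved by
#' cycle order, keeping exactly k order statistics.
#'
#' @param records A `mo2_records` data frame.
#' @param quantile_frac Fraction defining "lowest" (default 0.10).
#' @param exclude_before_h Optionally exclude cycles starting before this
#'   many hours (settling window); default 0 (no exclusion).
#' @return SMR in mg O2 kg^-1 h^-1.
#' @export
estimate_smr <- function(records, quantile_frac = 0.10,
                         exclude_before_h = 0) {
  stopifnot(inherits(records, "mo2_records"))
  el <- records$qc_pass & !records$is_mmr_cycle &
    records$start_s / 3600 >= exclude_before_h
  if (!any(el)) stop("no eligible cycles for SMR", call. = FALSE)
  vals <- records$mo2[el]
  cyc <- records$cycle_index[el]
  k <- max(ceiling(quantile_frac * length(vals)), 1L)
  ord <- order(vals, cyc)
  mean(vals[ord[seq_len(k)]])
}

#' Maximum metabolic rate from the first post-chase determination
#'
#' @param records A `mo2_records` data frame.
#' @return MMR in mg O2 kg^-1 h^-1, with attribute `flags` containing
#'   `"mmr_qc"` if the MMR cycle failed quality control (the value is
#'   still reported).
#' @export
estimate_mmr <- function(records) {
  stopifnot(inherits(records, "mo2_records"))
  i <- which(records$is_mmr_cycle)
  if (length(i) == 0L) stop("no MMR (first post-chase) cycle", call. = FALSE)
  i <- i[1]
  mmr <- records$mo2[i]
  flags <- character()
  if (!records$qc_pass[i]) {
    warning("MMR cycle failed QC; value reported with flag", call. = FALSE)
    flags <- "mmr_qc"
  }
  structure(mmr, flags = flags)
}

#' Absolute aerobic scope
#'
#' @param smr,mmr Standard and maximum metabolic rates,
#'   mg O2 kg^-1 h^-1.
#' @return MMR - SMR, with attribute `flags` containing `"negative_scope"`
#'   when MMR < SMR.
#' @export
aerobic_scope <- function(smr, mmr) {
  stopifnot(is.finite(smr), is.finite(mmr))
  aas <- mmr - smr
  structure(aas, flags = if (aas < 0) "negative_scope" else character())
}

#' Fulton's body condition factor
#'
#' K = 100 W / L^3, with weight in grams and length in centimetres; the
#' factor 100 brings the index close to one for typically proportioned
#' fish.
#'
#' @param weight_g Body wet weight in grams.
#' @param length_cm Length in centimetres.
#' @return Fulton's K (unitless).
#' @examples
#' fulton_k(1.5, 5.5)
#' @export
fulton_k <- function(weight_g, length_cm) {
  if (any(weight_g <= 0)) stop("`weight_g` must be positive", call. = FALSE)
  if (any(length_cm <= 0)) stop("`length_cm` must be positive",
                                call. = FALSE)
  100 * weight_g / length_cm^3
}

#' Per-fish metabolic summary
#'
#' @param records A `mo2_records` data frame for one fish.
#' @param weight_g,length_cm Body weight (g) and length (cm); default from
#'   the records' body-mass column and a supplied length.
#' @param ... Passed to [estimate_smr()].
#' @return Object of class `metabolic_summary` with SMR, MMR, AAS,
#'   Fulton's K, cycle counts and accumulated flags.
#' @export
metabolic_summary <- function(records,
                              weight_g = records$body_mass[1] * 1000,
                              length_cm = NULL, ...) {
  stopifnot(inherits(records, "mo2_records"))
  smr <- estimate_smr(records, ...)
  mmr <- estimate_mmr(records)
  aas <- aerobic_scope(smr, as.numeric(mmr))
  el <- records$qc_pass & !records$is_mmr_cycle
  k_used <- max(ceiling(0.10 * sum(el)), 1L)
  flags <- c(attr(mmr, "flags"), attr(aas, "flags"))
  out <- list(smr = smr, mmr = as.numeric(mmr), aas = as.numeric(aas),
              n_cycles_used = sum(records$qc_pass),
              n_smr_cycles = k_used,
              weight_g = weight_g, length_cm = length_cm,
              fulton_k = if (is.null(length_cm)) NA_real_
                         else fulton_k(weight_g, length_cm),
              flags = flags)
  class(out) <- "metabolic_summary"
  out
}

#' @export
print.metabolic_summary <- function(x, ...) {
  cat("Metabolic summary\n")
  cat(sprintf("  SMR: %8.1f mg O2/kg/h  (lowest %d cycles)\n",
              x$smr, x$n_smr_cycles))
  cat(sprintf("  MMR: %8.1f mg O2/kg/h\n", x$mmr))
  cat(sprintf("  AAS: %8.1f mg O2/kg/h\n", x$aas))
  if (!is.na(x$fulton_k)) {
    cat(sprintf("  Fulton's K: %.3f (%.2f g, %.2f cm)\n",
                x$fulton_k, x$weight_g, x$length_cm))
  }
  if (length(x$flags)) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}
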