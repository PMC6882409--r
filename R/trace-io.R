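# Reading, writing and segmenting oxygen trace files.
#
# Traces travel as tab-delimited text with a small header of "#!" metadata
# lines (fish mass and length, chamber volume, temperature, chamber id),
# followed by the columns time_s, o2_mgl, temp_c, phase, cycle_index.

#' Write an oxygen trace to a delimited text file
#'
#' @param trace An `oxygen_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "oxygen_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(body_mass = attr(trace, "body_mass"),
            body_length = attr(trace, "body_length"),
            chamber_volume = attr(trace, "chamber_volume"),
            temperature = attr(trace, "temperature"))
  writeLines(sprintf("#! %s=%.12g", names(meta), meta), con)
  writeLines(sprintf("#! chamber_id=%s", attr(trace, "chamber_id")), con)
  ev <- attr(trace, "loe_event")
  if (!is.null(ev)) {
    writeLines(sprintf("#! loe_time_s=%.12g loe_o2_mgl=%.12g",
                       ev$time_s, ev$o2_mgl), con)
  }
  utils::write.table(as.data.frame(trace), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an oxygen trace from a delimited text file
#'
#' Accepts the dialect written by [write_trace()] (tab-separated,
#' `#!` metadata header) or any delimited file with the required columns;
#' alternative column names can be mapped through `col_map`. The file is
#' validated: time must be strictly increasing and oxygen non-negative,
#' and violations are reported with their line number.
#'
#' @param path Input path.
#' @param sep Field separator (default tab).
#' @param col_map Named character vector mapping standard names
#'   (`time_s`, `o2_mgl`, `temp_c`, `phase`, `cycle_index`) to the file's
#'   column names, for files from other loggers.
#' @return An `oxygen_trace`.
#' @export
read_trace <- function(path, sep = "\t", col_map = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("no samples: file is empty", call. = FALSE)
  meta_idx <- grep("^#!", lines)
  meta <- list()
  for (ml in lines[meta_idx]) {
    kv <- regmatches(ml, gregexpr("[A-Za-z0-9_]+=[^ ]+", ml))[[1]]
    for (pair in kv) {
      eq <- regexpr("=", pair, fixed = TRUE)
      meta[[substr(pair, 1, eq - 1)]] <- substring(pair, eq + 1)
    }
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  if (length(body) <= 1L) stop("no samples in trace file", call. = FALSE)
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  required <- c("time_s", "o2_mgl")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$temp_c)) df$temp_c <- NA_real_
  if (is.null(df$phase)) df$phase <- NA_character_
  if (is.null(df$cycle_index)) df$cycle_index <- NA_integer_
  # line number of sample i in the original file: header + metadata offset
  header_line <- setdiff(seq_along(lines), meta_idx)[1]
  sample_line <- function(i) header_line + i
  bad_t <- which(diff(df$time_s) <= 0)
  if (length(bad_t)) {
    stop(sprintf("time is not strictly increasing at line %d",
                 sample_line(bad_t[1] + 1L)), call. = FALSE)
  }
  bad_o2 <- which(df$o2_mgl < 0 | !is.finite(df$o2_mgl))
  if (length(bad_o2)) {
    stop(sprintf("negative or non-finite O2 at line %d",
                 sample_line(bad_o2[1])), call. = FALSE)
  }
  num_or_na <- function(key) {
    if (is.null(meta[[key]])) NA_real_ else as.numeric(meta[[key]])
  }
  loe <- NULL
  if (!is.null(meta$loe_time_s)) {
    loe_o2 <- as.numeric(meta$loe_o2_mgl)
    tc <- df$temp_c[1]
    loe <- list(time_s = as.numeric(meta$loe_time_s), o2_mgl = loe_o2,
                po2_kpa = if (is.finite(tc)) {
                  o2_mgl_to_kpa(loe_o2, water_conditions(tc))
                } else NA_real_)
  }
  .new_oxygen_trace(df[c("time_s", "o2_mgl", "temp_c", "phase",
                         "cycle_index")],
                    body_mass = num_or_na("body_mass"),
                    body_length = num_or_na("body_length"),
                    chamber_volume = num_or_na("chamber_volume"),
                    temperature = num_or_na("temperature"),
                    chamber_id = if (is.null(meta$chamber_id)) "ch1"
                                 else meta$chamber_id,
                    loe_event = loe)
}

#' Segment a trace into determination cycles
#'
#' Uses phase labels when present. Otherwise flush onsets are detected as
#' sustained oxygen increases exceeding 3x the local noise sd (flushing
#' replenishes the chamber with oxygenated bath water, producing a sharp
#' uptick); determinations are the intervals between flush end and the next
#' flush onset. Cycles whose duration deviates from the protocol's
#' determination period by more than `duration_tol` (fractional) are
#' dropped, which discards incomplete trailing cycles. The first cycle is
#' flagged as the post-chase MMR determination. All windows are half-open
#' `[start, end)` in seconds from trace start.
#'
#' @param trace An `oxygen_trace`.
#' @param protocol A [protocol_config()] giving the expected cycle timing.
#' @param use_labels Use the `phase` column if available (default TRUE).
#' @param duration_tol Fractional tolerance on determination duration.
#' @return Data frame with one row per determination cycle: `cycle_index`,
#'   `start_s`, `end_s`, `n_samples`, `is_mmr_cycle`. Zero rows (with a
#'   warning) if no cycles are detectable.
#' @export
segment_cycles <- function(trace, protocol = protocol_config(),
                           use_labels = TRUE, duration_tol = 0.1) {
  stopifnot(inherits(trace, "oxygen_trace"))
  det_s <- protocol$determination_minutes * 60
  have_labels <- use_labels && !all(is.na(trace$phase))
  if (have_labels) {
    is_det <- trace$phase == "determination" & !is.na(trace$phase)
    if (!any(is_det)) {
      warning("no determination cycles in trace", call. = FALSE)
      return(.empty_cycles())
    }
    idx <- split(which(is_det), trace$cycle_index[is_det])
    starts <- vapply(idx, function(i) trace$time_s[i[1]], 0)
    ends <- vapply(idx, function(i) {
      last <- i[length(i)]
      # half-open end: next sample's time, or extrapolated interval
      if (last < nrow(trace)) trace$time_s[last + 1L]
      else trace$time_s[last] + diff(trace$time_s[1:2])
    }, 0)
    n <- lengths(idx)
  } else {
    bounds <- .detect_flush_bounds(trace)
    if (is.null(bounds)) {
      warning("no determination cycles detected", call. = FALSE)
      return(.empty_cycles())
    }
    starts <- bounds$det_start
    ends <- bounds$det_end
    n <- vapply(seq_along(starts), function(k) {
      sum(trace$time_s >= starts[k] & trace$time_s < ends[k])
    }, 0L)
  }
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]; n <- n[ord]
  keep <- abs((ends - starts) - det_s) <= duration_tol * det_s
  out <- data.frame(cycle_index = seq_along(starts)[keep],
                    start_s = starts[keep], end_s = ends[keep],
                    n_samples = as.integer(n[keep]),
                    is_mmr_cycle = FALSE)
  if (nrow(out) == 0L) {
    warning("no determination cycles of the expected duration",
            call. = FALSE)
    return(.empty_cycles())
  }
  out$cycle_index <- seq_len(nrow(out))
  out$is_mmr_cycle[1] <- TRUE
  rownames(out) <- NULL
  out
}

.empty_cycles <- function() {
  data.frame(cycle_index = integer(), start_s = numeric(),
             end_s = numeric(), n_samples = integer(),
             is_mmr_cycle = logical())
}

# Label-free cycle detection from oxygen upticks. A flush produces a
# sustained rise back to bath concentration; candidate flush regions are
# samples whose oxygen increase over a short look-ahead window exceeds 3x
# the local noise sd, merged and then refined to the local pre-rise minimum
# (flush onset) and post-rise maximum (flush end).
.detect_flush_bounds <- function(trace) {
  o2 <- trace$o2_mgl
  t <- trace$time_s
  n <- length(o2)
  dt <- stats::median(diff(t))
  # robust per-sample noise sd from first differences
  noise <- stats::mad(diff(o2)) / sqrt(2)
  thr <- max(3 * noise, 1e-9)
  w <- max(3L, as.integer(round(30 / dt)))
  if (n <= 3L * w) return(NULL)
  # detection runs on a running-mean smoothed series so that the rise
  # statistic is compared with a noise floor it can actually beat
  s <- as.numeric(stats::filter(o2, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- o2[is.na(s)]
  inc <- s[(w + 1L):n] - s[1:(n - w)]        # rise over the window
  cand <- which(inc > thr)
  if (!length(cand)) return(NULL)
  # merge candidates separated by at most 2w samples into flush regions
  breaks <- which(diff(cand) > 2L * w)
  reg_start <- cand[c(1L, breaks + 1L)]
  reg_end <- pmin(cand[c(breaks, length(cand))] + w, n)
  flush_start <- numeric(); flush_end <- numeric()
  for (j in seq_along(reg_start)) {
    lo <- max(1L, reg_start[j] - w)
    hi <- min(n, reg_end[j] + w)
    if (max(s[lo:hi]) - min(s[lo:hi]) <= thr) next  # not sustained
    # boundaries from the raw series: pre-rise minimum, post-rise maximum
    i_min <- lo + which.min(o2[lo:hi]) - 1L
    i_max <- i_min + which.max(o2[i_min:hi]) - 1L
    if (i_min >= i_max) next
    flush_start <- c(flush_start,
                     if (i_min < n) t[i_min + 1L] else t[n] + dt)
    flush_end <- c(flush_end,
                   if (i_max < n) t[i_max + 1L] else t[n] + dt)
  }
  if (!length(flush_start)) return(NULL)
  ord <- order(flush_start)
  flush_start <- flush_start[ord]; flush_end <- flush_end[ord]
  det_start <- c(t[1], flush_end)
  det_end <- c(flush_start, t[n] + dt)
  keep <- det_end > det_start
  list(det_start = det_start[keep], det_end = det_end[keep])
}
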