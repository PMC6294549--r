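# Ratiometric quantification of two-channel calcium traces. A calcium
# reporter (GCaMP6s) is imaged together with a calcium-insensitive
# reference (tdTomato); focal drift in Z multiplies both channels by the
# same factor, which the ratiometric formula cancels:
#   R(t) = F(t)_GCaMP * F0_tdTom / (F0_GCaMP * F(t)_tdTom)
# with F0 the average background-adjusted fluorescence over half of the
# pre-stimulus period. The formula as printed is a ratio of ratios, i.e.
# R(t)/R0 rather than (R - R0)/R0; both the as-printed series and its
# minus-one form are reported.

#' Construct a two-channel fluorescence trace
#'
#' @param time Sample times (s), uniformly spaced.
#' @param F_gcamp,F_tdtom Reporter and reference fluorescence per sample
#'   (arbitrary units); equal length.
#' @param bg_gcamp,bg_tdtom Scalar non-tissue background per channel.
#' @param stim_start Stimulus time (s), within the record.
#' @param sampling_rate Hz (any positive rate; recordings here were 4 Hz
#'   with a few at 2.6 Hz).
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(time, F_gcamp, F_tdtom, bg_gcamp = 0,
                               bg_tdtom = 0, stim_start, sampling_rate) {
  if (length(F_gcamp) != length(time) || length(F_tdtom) != length(time))
    stopf("channels and time base must have equal length")
  check_pos(sampling_rate, "sampling_rate")
  if (stim_start < min(time) || stim_start > max(time))
    stopf("`stim_start` must lie within the record")
  structure(list(time = time, F_gcamp = F_gcamp, F_tdtom = F_tdtom,
                 bg_gcamp = bg_gcamp, bg_tdtom = bg_tdtom,
                 stim_start = stim_start, sampling_rate = sampling_rate),
            class = "fluorescence_trace")
}

#' Subtract scalar channel backgrounds
#'
#' Non-tissue background is subtracted from each channel; values at or
#' below the background are clipped to a small positive floor so later
#' ratios stay defined.
#'
#' @param trace A [fluorescence_trace()].
#' @param floor Positive clipping floor applied after subtraction.
#' @return The adjusted trace (backgrounds reset to 0).
#' @export
background_adjust <- function(trace, floor = 1e-6) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  for (ch in c("F_gcamp", "F_tdtom")) {
    bg <- trace[[sub("F_", "bg_", ch)]]
    if (bg >= max(trace[[ch]]))
      stopf("background exceeds all %s values; signal indistinguishable from background", ch)
    v <- trace[[ch]] - bg
    if (any(v <= 0)) {
      warnf("%d %s sample(s) at or below background; clipped to floor",
            sum(v <= 0), ch)
      v[v <= 0] <- floor
    }
    trace[[ch]] <- v
  }
  trace$bg_gcamp <- 0; trace$bg_tdtom <- 0
  trace
}

#' Pre-stimulus baseline fluorescence per channel
#'
#' F0 is the average fluorescence prior to stimulation computed over half
#' the length of the pre-stimulus period. Which half is meant is
#' ambiguous in the source description; the default uses the first half
#' (farthest from the stimulus, least anticipatory activity), and
#' `half = "last"` selects the half adjacent to the stimulus.
#'
#' @param trace A background-adjusted [fluorescence_trace()].
#' @param half `"first"` (default) or `"last"` half of the pre-stimulus
#'   window.
#' @return Named numeric vector `c(F0_gcamp, F0_tdtom)`.
#' @export
baseline_F0 <- function(trace, half = c("first", "last")) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  half <- match.arg(half)
  pre <- which(trace$time < trace$stim_start)
  if (length(pre) < 2) stopf("at least two pre-stimulus samples are required")
  n_half <- max(floor(length(pre) / 2), 1L)
  idx <- if (half == "first") pre[seq_len(n_half)]
         else pre[seq.int(length(pre) - n_half + 1L, length(pre))]
  c(F0_gcamp = mean(trace$F_gcamp[idx]), F0_tdtom = mean(trace$F_tdtom[idx]))
}

#' Ratiometric calcium response
#'
#' Applies background adjustment, computes F0 per channel and evaluates
#' the drift-cancelling ratio
#' `R(t) = F(t)_gcamp * F0_tdtom / (F0_gcamp * F(t)_tdtom)`.
#' Any positive factor multiplying both channels cancels exactly.
#'
#' @inheritParams baseline_F0
#' @return A list of class `ratio_result`: `time`, `ratio_series` (the
#'   as-printed formula value, 1 at baseline), `delta_r_over_r`
#'   (`ratio_series - 1`), `F0_gcamp`, `F0_tdtom`, `stim_start`,
#'   `sampling_rate`.
#' @export
ratiometric <- function(trace, half = "first") {
  stopifnot(inherits(trace, "fluorescence_trace"))
  adj <- background_adjust(trace)
  f0 <- baseline_F0(adj, half = half)
  if (f0[["F0_gcamp"]] <= 0 || any(adj$F_tdtom <= 0))
    stopf("zero denominator in ratiometric formula")
  ratio <- (adj$F_gcamp * f0[["F0_tdtom"]]) / (f0[["F0_gcamp"]] * adj$F_tdtom)
  structure(list(time = adj$time, ratio_series = ratio,
                 delta_r_over_r = ratio - 1,
                 F0_gcamp = f0[["F0_gcamp"]], F0_tdtom = f0[["F0_tdtom"]],
                 stim_start = adj$stim_start,
                 sampling_rate = adj$sampling_rate),
            class = "ratio_result")
}

#' Align ratiometric traces on stimulus onset and average
#'
#' Traces are shifted so the stimulus sits at t = 0; when sampling rates
#' differ (4 Hz vs 2.6 Hz recordings) every trace is resampled onto the
#' grid of the slowest rate by linear interpolation. The mean and SD are
#' computed pointwise over the trials covering each time point.
#'
#' @param results List of `ratio_result` objects from [ratiometric()].
#' @param value Which series to average: `"ratio_series"` (default) or
#'   `"delta_r_over_r"`.
#' @return Data frame with `time` (s, stimulus at 0), `mean`, `sd`, `n`.
#' @export
align_and_average <- function(results, value = c("ratio_series", "delta_r_over_r")) {
  value <- match.arg(value)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "ratio_result")))
  rates <- vapply(results, `[[`, numeric(1), "sampling_rate")
  dt <- 1 / min(rates)
  rel <- lapply(results, function(r) r$time - r$stim_start)
  lo <- min(vapply(rel, min, numeric(1)))
  hi <- max(vapply(rel, max, numeric(1)))
  grid <- seq(floor(lo / dt) * dt, hi, by = dt)
  mat <- vapply(seq_along(results), function(i) {
    approx(rel[[i]], results[[i]][[value]], xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(results))
  n <- rowSums(!is.na(mat))
  keep <- n > 0
  data.frame(time = grid[keep],
             mean = rowMeans(mat, na.rm = TRUE)[keep],
             sd = apply(mat, 1L, sd, na.rm = TRUE)[keep],
             n = n[keep])
}

#' Write / read a fluorescence trace as CSV + JSON metadata
#'
#' The trace samples go to `<path>.csv` (columns `time`, `F_gcamp`,
#' `F_tdtom`) and backgrounds, stimulus time and sampling rate to
#' `<path>.json`.
#'
#' @param trace A [fluorescence_trace()].
#' @param path Output path stem (no extension).
#' @return `write_trace()` returns the paths invisibly; `read_trace()`
#'   the reconstructed trace.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  write.csv(data.frame(time = trace$time, F_gcamp = trace$F_gcamp,
                       F_tdtom = trace$F_tdtom),
            paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(trace[c("bg_gcamp", "bg_tdtom", "stim_start",
                               "sampling_rate")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, c(".csv", ".json")))
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fluorescence_trace(time = d$time, F_gcamp = d$F_gcamp, F_tdtom = d$F_tdtom,
                     bg_gcamp = meta$bg_gcamp, bg_tdtom = meta$bg_tdtom,
                     stim_start = meta$stim_start,
                     sampling_rate = meta$sampling_rate)
}
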