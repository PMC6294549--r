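# Per-trial kinematics of the startle response: angle normalization,
# filament and swim speeds, latency arithmetic, response classification
# and group summaries.

#' Normalize elevation angles within each larva
#'
#' Each larva's maximal recorded parapodial elevation angle defines its
#' own scale: angles are divided by the per-larva maximum, so the maximum
#' maps to 1.
#'
#' @param angles Raw elevation angles (degrees, >= 0).
#' @param larva_id Vector of larva identifiers, same length as `angles`.
#' @return Normalized angles in \[0, 1\]. Larvae whose angles are all zero
#'   yield zeros with a warning.
#' @examples
#' normalize_angles(c(10, 20, 40), rep("a", 3))
#' @export
normalize_angles <- function(angles, larva_id = rep(1L, length(angles))) {
  if (any(angles < 0, na.rm = TRUE)) stopf("angles must be >= 0")
  if (length(larva_id) != length(angles))
    stopf("`larva_id` must match `angles` in length")
  out <- numeric(length(angles))
  for (id in unique(larva_id)) {
    idx <- larva_id == id
    m <- max(angles[idx], na.rm = TRUE)
    if (m == 0) {
      warnf("larva %s has all-zero angles; normalized values set to 0", id)
      out[idx] <- 0
    } else {
      out[idx] <- angles[idx] / m
    }
  }
  out
}

#' Filament speed from per-frame displacements
#'
#' The stimulus intensity measure: the maximum displacement observed
#' between consecutive frames, normalized to the recording speed.
#'
#' @param displacements Displacements between consecutive frames (µm);
#'   at least one step (two frames) required.
#' @param fps Recording speed (frames/s).
#' @return Speed in µm/ms: `max(displacements) * fps / 1000`.
#' @examples
#' filament_speed(c(1, 9, 4), fps = 300)  # 2.7 um/ms
#' @export
filament_speed <- function(displacements, fps) {
  if (length(displacements) < 1)
    stopf("at least two frames (one displacement) are required")
  check_pos(fps, "fps")
  max(displacements) * fps / 1000
}

#' Classify a trial into a startle response class
#'
#' Combines the normalized elevation angle (against the mixture cutoff)
#' with the prototroch-closure flag into five classes: `no_response`,
#' `closure_only`, `closure_lowE`, `closure_wideE`, `wideE_only`.
#' Sub-cutoff elevation without any ciliary closure is classified
#' `no_response` (low-angle responses were always closure-accompanied;
#' an isolated sub-threshold elevation is treated as noise).
#'
#' @param angle_norm Normalized elevation angle(s) in \[0, 1\].
#' @param closed Logical prototroch-closure flag(s).
#' @param cutoff Low/wide-angle cutoff on the normalized scale
#'   (default 0.4, the published mixture-model cutoff).
#' @return Factor with the five response-class levels.
#' @export
classify_response <- function(angle_norm, closed, cutoff = 0.4) {
  if (any(angle_norm < 0 | angle_norm > 1, na.rm = TRUE))
    stopf("normalized angles must lie in [0, 1]")
  cls <- ifelse(angle_norm >= cutoff,
                ifelse(closed, "closure_wideE", "wideE_only"),
                ifelse(angle_norm > 0,
                       ifelse(closed, "closure_lowE", "no_response"),
                       ifelse(closed, "closure_only", "no_response")))
  factor(cls, levels = c("no_response", "closure_only", "closure_lowE",
                         "closure_wideE", "wideE_only"))
}

#' Onset latency in milliseconds
#'
#' @param onset_frame,stim_start_frame Frame indices (onset >= stimulus
#'   start).
#' @param fps Recording speed (frames/s); scalar or per-trial vector.
#' @return Latency in ms: `(onset - stim_start) / fps * 1000`.
#' @export
onset_latency <- function(onset_frame, stim_start_frame, fps) {
  if (any(fps <= 0)) stopf("`fps` must be positive")
  if (any(onset_frame < stim_start_frame, na.rm = TRUE))
    stopf("onset frame precedes stimulus start")
  (onset_frame - stim_start_frame) / fps * 1000
}

#' Summarize latencies per group with notched-boxplot intervals
#'
#' Reports the median, sample size and the conventional notched-boxplot
#' 95% interval around the median, `median +/- 1.58 * IQR / sqrt(n)`.
#'
#' @param values Latencies (ms) or any numeric summary variable.
#' @param group Grouping vector (e.g. interaction of response class and
#'   stimulation site), same length as `values`.
#' @return Data frame with `group`, `n`, `median`, `notch_low`,
#'   `notch_high`.
#' @export
summarize_latencies <- function(values, group = rep("all", length(values))) {
  if (length(group) != length(values)) stopf("`group` must match `values`")
  keep <- !is.na(values)
  values <- values[keep]; group <- group[keep]
  out <- lapply(split(values, group), function(v) {
    med <- median(v)
    iqr <- diff(quantile(v, c(0.25, 0.75), names = FALSE))
    half <- 1.58 * iqr / sqrt(length(v))
    data.frame(n = length(v), median = med,
               notch_low = med - half, notch_high = med + half)
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}

#' Left-right and intersegmental coordination delays
#'
#' Pairwise onset-frame differences converted to milliseconds. Onsets in
#' the same frame are below the temporal resolution of the recording:
#' they are reported as a bound (`delay_ms = 1000/fps`, `is_bound =
#' TRUE`), not as zero. Missing onsets yield `available = FALSE`.
#'
#' @param trials Data frame with columns `fps`, `elevation_onset_left`,
#'   `elevation_onset_right` and any number of `elevation_onset_sg<k>`
#'   columns.
#' @return Long data frame with `trial`, `pair`, `delay_ms`, `is_bound`,
#'   `available`.
#' @export
coordination_delays <- function(trials) {
  sg_cols <- grep("^elevation_onset_sg[0-9]+$", names(trials), value = TRUE)
  rows <- list()
  add <- function(i, pair, a, b, fps) {
    if (is.na(a) || is.na(b)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        trial = i, pair = pair, delay_ms = NA_real_,
        is_bound = FALSE, available = FALSE)
      return(invisible())
    }
    k <- abs(a - b)
    rows[[length(rows) + 1L]] <<- data.frame(
      trial = i, pair = pair,
      delay_ms = if (k == 0) 1000 / fps else k / fps * 1000,
      is_bound = k == 0, available = TRUE)
  }
  for (i in seq_len(nrow(trials))) {
    fps <- trials$fps[i]
    add(i, "left-right", trials$elevation_onset_left[i],
        trials$elevation_onset_right[i], fps)
    if (length(sg_cols) >= 2) {
      cmb <- utils::combn(sg_cols, 2)
      for (j in seq_len(ncol(cmb))) {
        add(i, paste(sub("elevation_onset_", "", cmb[, j]), collapse = "-"),
            trials[[cmb[1, j]]][i], trials[[cmb[2, j]]][i], fps)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Response-class proportions per stimulus bin
#'
#' @param response_class Factor from [classify_response()].
#' @param bin Grouping vector (stimulus distance or speed bin).
#' @return Data frame with `bin`, `response_class`, `n`, `proportion`;
#'   proportions sum to 1 within each bin.
#' @export
response_profile <- function(response_class, bin = rep("all", length(response_class))) {
  if (length(bin) != length(response_class)) stopf("`bin` must match classes")
  tab <- table(bin = bin, response_class = response_class)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  tot <- tapply(out$n, out$bin, sum)
  empty <- names(tot)[tot == 0]
  if (length(empty)) {
    warnf("dropping empty bin(s): %s", paste(empty, collapse = ", "))
    out <- out[!(out$bin %in% empty), ]
  }
  out$proportion <- out$n / as.numeric(tot[out$bin])
  rownames(out) <- NULL
  out
}

#' Swim speed trace from tracked positions
#'
#' Euclidean (Pythagorean) step distance per time unit, for freely
#' swimming larvae tracked at a fixed frame rate.
#'
#' @param x,y Position coordinates per frame (any spatial unit).
#' @param fps Recording speed (frames/s).
#' @return Speed per frame interval (unit/s); length `length(x) - 1`
#'   (empty for a single point).
#' @export
swim_speed <- function(x, y, fps) {
  check_pos(fps, "fps")
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  if (length(x) < 2) return(numeric(0))
  sqrt(diff(x)^2 + diff(y)^2) * fps
}
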