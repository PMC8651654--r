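#' Detect calcium transients on a conditioned trace
#'
#' Detection runs on the detrended trace smoothed with a centred
#' `smooth_frames`-frame boxcar. Supra-threshold runs (smoothed value
#' strictly above `f0_offset + k_sd * noise_sd`) lasting at least
#' `duration_frames` consecutive frames become candidate events; the
#' "more than 9 frames" duration rule is therefore pinned to >= 10 frames
#' (1.0 s at 10 Hz). Each candidate must have a peak height of at least
#' `k_sd` noise standard deviations (guaranteed by the threshold, checked
#' explicitly and applied before merging). Candidates whose peaks are closer
#' than `min_distance_frames` are merged by greedy suppression: peaks are
#' visited in decreasing height order and any unclaimed candidate within the
#' exclusion distance is absorbed into the higher event (onset/offset
#' extended, higher peak kept).
#'
#' @param cond a `conditioned_trace` from [condition_trace()].
#' @param smooth_frames boxcar width in frames (default 5).
#' @param k_sd threshold and minimum peak height in noise-sd units
#'   (default 3).
#' @param duration_frames minimum run length in frames (default 10).
#' @param min_distance_frames minimum distance between peaks in frames
#'   (default 15); peaks closer than this are merged.
#' @return data.frame with one row per event: `onset_frame`, `offset_frame`,
#'   `peak_frame` (1-based), `peak_height` (noise-sd units), `peak_dff`.
#'   Zero-row when no event passes all rules.
#' @export
detect_transients <- function(cond, smooth_frames = 5, k_sd = 3,
                              duration_frames = 10, min_distance_frames = 15) {
  stopifnot(inherits(cond, "conditioned_trace"))
  if (cond$noise_sd <= 0)
    stop("noise_sd is 0: detection refused for degenerate trace", call. = FALSE)
  sm <- boxcar_smooth(cond$detrended, smooth_frames)
  thr <- cond$f0_offset + k_sd * cond$noise_sd
  runs <- true_runs(sm > thr)
  empty <- data.frame(onset_frame = integer(0), offset_frame = integer(0),
                      peak_frame = integer(0), peak_height = numeric(0),
                      peak_dff = numeric(0))
  if (nrow(runs) == 0L) return(empty)
  runs <- runs[(runs$end - runs$start + 1L) >= duration_frames, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty)

  peak_frame <- integer(nrow(runs))
  peak_height <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    pk <- idx[which.max(sm[idx])]
    peak_frame[i] <- pk
    peak_height[i] <- (sm[pk] - cond$f0_offset) / cond$noise_sd
  }
  keep <- peak_height >= k_sd  # applied before merging
  runs <- runs[keep, , drop = FALSE]
  peak_frame <- peak_frame[keep]
  peak_height <- peak_height[keep]
  if (nrow(runs) == 0L) return(empty)

  # greedy suppression by height, merging absorbed events
  ord <- order(-peak_height, peak_frame)
  assigned <- rep(NA_integer_, length(ord))
  winners <- integer(0)
  for (i in ord) {
    if (!is.na(assigned[i])) next
    assigned[i] <- i
    winners <- c(winners, i)
    close_by <- which(is.na(assigned) &
                        abs(peak_frame - peak_frame[i]) < min_distance_frames)
    assigned[close_by] <- i
  }
  out <- do.call(rbind, lapply(winners, function(w) {
    members <- which(assigned == w)
    data.frame(onset_frame = min(runs$start[members]),
               offset_frame = max(runs$end[members]),
               peak_frame = peak_frame[w], peak_height = peak_height[w])
  }))
  out <- out[order(out$peak_frame), , drop = FALSE]
  sm_dff <- if (all(is.na(cond$dff))) rep(NA_real_, length(sm)) else
    (sm - cond$f0_offset) / cond$f0_raw
  out$peak_dff <- sm_dff[out$peak_frame]
  rownames(out) <- NULL
  out
}

#' Transient rate in events per minute
#'
#' @param events event data.frame from [detect_transients()] (or anything with
#'   one row per event).
#' @param duration_s recording duration in seconds.
#' @return `60 * nrow(events) / duration_s`.
#' @export
transient_rate <- function(events, duration_s) {
  stop_if_not_scalar_pos(duration_s, "duration_s")
  60 * nrow(events) / duration_s
}

#' Area under the deltaF/F curve per minute
#'
#' Trapezoidal integral of the positive part of the deltaF/F trace over time,
#' normalised to one minute. Only the positive part is integrated: a signed
#' integral of a zero-baseline trace would cancel noise symmetrically and
#' measure nothing.
#'
#' @param dff deltaF/F trace.
#' @param duration_s recording duration in seconds.
#' @return AUC in deltaF/F x s per minute.
#' @export
auc_per_min <- function(dff, duration_s) {
  stop_if_not_scalar_pos(duration_s, "duration_s")
  n <- length(dff)
  if (n < 2L) return(0)
  y <- pmax(dff, 0)
  dt <- duration_s / n
  integral <- sum((y[-1] + y[-n]) / 2) * dt
  60 * integral / duration_s
}

#' Activity category from transient rate
#'
#' Rarely active: < 0.25 transients/min; intermediately active: 0.25 to 4
#' transients/min (boundaries inclusive); highly active: > 4 transients/min.
#'
#' @param rate transient rate(s) in events/min (vectorised).
#' @return factor with levels `rare`, `intermediate`, `high`.
#' @export
classify_activity <- function(rate) {
  stopifnot(all(rate >= 0 | is.na(rate)))
  out <- ifelse(rate < 0.25, "rare", ifelse(rate > 4, "high", "intermediate"))
  factor(out, levels = c("rare", "intermediate", "high"))
}

#' Per-neuron per-session activity summary
#'
#' @param events event table from [detect_transients()].
#' @param cond the `conditioned_trace` the events were detected on.
#' @return one-row data.frame: `neuron_id`, `session_id`,
#'   `transients_per_min`, `auc_per_min`, `category`, `is_active` (at least
#'   one detected transient).
#' @export
summarize_activity <- function(events, cond) {
  stopifnot(inherits(cond, "conditioned_trace"))
  duration_s <- length(cond$detrended) / cond$frame_rate_hz
  rate <- transient_rate(events, duration_s)
  auc <- if (all(is.na(cond$dff))) NA_real_ else auc_per_min(cond$dff, duration_s)
  data.frame(neuron_id = cond$neuron_id, session_id = cond$session_id,
             transients_per_min = rate, auc_per_min = auc,
             category = classify_activity(rate), is_active = nrow(events) > 0L)
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching of detected event onsets to true event onsets
#' within a frame tolerance, in order of onset distance. Used by the
#' synthetic benchmarks.
#'
#' @param detected_onsets,true_onsets event onset frames (1-based).
#' @param tol_frames matching tolerance (default 5 frames).
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `precision`.
#' @export
evaluate_detection <- function(detected_onsets, true_onsets, tol_frames = 5) {
  nd <- length(detected_onsets); nt <- length(true_onsets)
  if (nd == 0L || nt == 0L) {
    tp <- 0L
  } else {
    d <- abs(outer(detected_onsets, true_onsets, "-"))
    used_d <- rep(FALSE, nd); used_t <- rep(FALSE, nt); tp <- 0L
    ord <- order(d)
    for (k in ord) {
      if (d[k] > tol_frames) break
      i <- (k - 1L) %% nd + 1L
      j <- (k - 1L) %/% nd + 1L
      if (used_d[i] || used_t[j]) next
      used_d[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nd - tp, fn = nt - tp,
       sensitivity = if (nt > 0) tp / nt else NA_real_,
       precision = if (nd > 0) tp / nd else NA_real_)
}
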