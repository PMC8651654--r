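#' Segment whisking epochs from a binary behaviour track
#'
#' Maximal runs of 1 lasting at least `ceil(min_duration_s * frame_rate_hz)`
#' frames become whisking epochs (330 ms = 4 frames at 10 Hz); shorter runs
#' are too brief to align with the slow calcium indicator and are
#' reclassified as stationary.
#'
#' @param track binary per-frame whisking state (0/1 or logical).
#' @param frame_rate_hz frame rate in Hz.
#' @param min_duration_s minimum whisk duration in seconds (default 0.33).
#' @return an `epoch_set`: data.frame (`onset_frame`, `offset_frame`,
#'   `class` in `whisk`/`stationary`), sorted, non-overlapping, covering all
#'   frames; attributes `frame_rate_hz` and `n_frames`.
#' @export
detect_whisk_epochs <- function(track, frame_rate_hz, min_duration_s = 0.33) {
  stop_if_not_scalar_pos(frame_rate_hz, "frame_rate_hz")
  if (!all(track %in% c(0, 1)))
    stop("track must be binary", call. = FALSE)
  n <- length(track)
  min_frames <- as.integer(ceiling(min_duration_s * frame_rate_hz))
  state <- rep("stationary", n)
  runs <- true_runs(track == 1)
  runs <- runs[(runs$end - runs$start + 1L) >= min_frames, , drop = FALSE]
  for (i in seq_len(nrow(runs))) state[runs$start[i]:runs$end[i]] <- "whisk"
  r <- rle(state)
  ends <- cumsum(r$lengths)
  epochs <- data.frame(onset_frame = ends - r$lengths + 1L,
                       offset_frame = ends,
                       class = factor(r$values,
                                      levels = c("whisk", "stationary")))
  structure(epochs, frame_rate_hz = frame_rate_hz, n_frames = n,
            class = c("epoch_set", "data.frame"))
}

#' Whisk-associated activity windows
#'
#' The slow indicator reports whisking-evoked activity after the behavioural
#' event itself, so activity is read out in a window after whisking offset:
#' for each whisk epoch the window runs from the first post-offset frame to
#' `w_max_s` seconds after offset, truncated at the next whisk onset and at
#' the track end. Windows shorter than `w_min_s` after truncation carry too
#' little usable signal and are discarded (returned separately so they can be
#' excluded from the stationary mask as well).
#'
#' @param epochs an `epoch_set` from [detect_whisk_epochs()].
#' @param w_min_s minimum retained window length in seconds (default 1).
#' @param w_max_s window length after whisking offset in seconds (default 2).
#' @return logical per-frame mask of whisk-associated frames, with attribute
#'   `discarded`: logical mask of frames in windows dropped for being shorter
#'   than `w_min_s`.
#' @export
whisk_response_windows <- function(epochs, w_min_s = 1, w_max_s = 2) {
  stopifnot(inherits(epochs, "epoch_set"))
  fr <- attr(epochs, "frame_rate_hz")
  n <- attr(epochs, "n_frames")
  w_min <- as.integer(round(w_min_s * fr))
  w_max <- as.integer(round(w_max_s * fr))
  mask <- rep(FALSE, n)
  discarded <- rep(FALSE, n)
  wh <- epochs[epochs$class == "whisk", , drop = FALSE]
  for (i in seq_len(nrow(wh))) {
    start <- wh$offset_frame[i] + 1L
    if (start > n) next
    end <- min(wh$offset_frame[i] + w_max, n)
    nxt <- wh$onset_frame[wh$onset_frame > wh$offset_frame[i]]
    if (length(nxt)) end <- min(end, min(nxt) - 1L)
    if (end < start) next
    if (end - start + 1L < w_min) discarded[start:end] <- TRUE
    else mask[start:end] <- TRUE
  }
  attr(mask, "discarded") <- discarded
  mask
}

#' Stationary frame mask
#'
#' Frames that are neither inside a whisking epoch, nor in a whisk-associated
#' response window, nor in a discarded (too short) response window.
#'
#' @param epochs an `epoch_set` from [detect_whisk_epochs()].
#' @param whisk_assoc_mask mask from [whisk_response_windows()].
#' @return logical per-frame mask.
#' @export
stationary_mask <- function(epochs, whisk_assoc_mask) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- attr(epochs, "n_frames")
  if (length(whisk_assoc_mask) != n)
    stop("mask length does not match epoch frame count", call. = FALSE)
  whisk <- rep(FALSE, n)
  wh <- epochs[epochs$class == "whisk", , drop = FALSE]
  for (i in seq_len(nrow(wh))) whisk[wh$onset_frame[i]:wh$offset_frame[i]] <- TRUE
  discarded <- attr(whisk_assoc_mask, "discarded") %||% rep(FALSE, n)
  !(whisk | as.logical(whisk_assoc_mask) | discarded)
}
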