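#' Neuropil compensation of a somatic fluorescence trace
#'
#' Removes the contamination of the somatic region-of-interest (ROI) signal by
#' the surrounding neuropil:
#' \deqn{F_{comp}[t] = F_{ROI}[t] + factor \times (median(F_{np}) - F_{np}[t])}
#' The median re-centring means a constant neuropil trace leaves the ROI
#' signal untouched, and only neuropil *fluctuations* are subtracted.
#'
#' @param f_roi per-frame raw ROI fluorescence.
#' @param f_neuropil per-frame raw fluorescence of the surrounding neuropil
#'   region; same length as `f_roi`.
#' @param factor dimensionless compensation factor; default 0.7.
#' @return numeric vector, compensated trace, same length as the inputs.
#' @export
compensate_neuropil <- function(f_roi, f_neuropil, factor = 0.7) {
  if (length(f_roi) == 0L) stop("empty trace", call. = FALSE)
  if (length(f_roi) != length(f_neuropil))
    stop("f_roi and f_neuropil must have equal length", call. = FALSE)
  f_roi + factor * (median(f_neuropil) - f_neuropil)
}

#' Low-pass filter and slow-trend removal
#'
#' Zero-phase Butterworth low-pass at `cutoff_hz` (order 2, applied
#' forward-backward), followed by subtraction of a running `pct`-th percentile
#' computed in a centred window of +/- `window_s` seconds (truncated at the
#' trace edges). When the cutoff is at or above 95% of the Nyquist frequency
#' the filter step is skipped with a message: at the typical 10 Hz frame rate
#' a 5 Hz cutoff equals Nyquist and filtering would be a no-op at best.
#'
#' @param trace numeric vector, compensated raw-unit fluorescence.
#' @param frame_rate_hz acquisition frame rate in Hz.
#' @param cutoff_hz low-pass cutoff in Hz (default 5).
#' @param window_s detrending half-window in seconds (default 50).
#' @param pct detrending percentile (default 8).
#' @return list with `detrended` (trace minus running percentile),
#'   `lowpassed` (filtered but not detrended; needed downstream as the
#'   absolute-baseline reference for deltaF/F), and `lowpass_applied`.
#' @export
lowpass_and_detrend <- function(trace, frame_rate_hz, cutoff_hz = 5,
                                window_s = 50, pct = 8) {
  stop_if_not_scalar_pos(frame_rate_hz, "frame_rate_hz")
  if (length(trace) < 3L) stop("trace must have at least 3 frames", call. = FALSE)
  nyquist <- frame_rate_hz / 2
  apply_lp <- cutoff_hz < 0.95 * nyquist
  if (apply_lp) {
    bf <- signal::butter(2, cutoff_hz / nyquist, type = "low")
    lp <- as.numeric(signal::filtfilt(bf, trace))
  } else {
    message("low-pass skipped: cutoff ", cutoff_hz,
            " Hz >= 0.95 x Nyquist (", nyquist, " Hz)")
    lp <- as.numeric(trace)
  }
  hw <- as.integer(round(window_s * frame_rate_hz))
  baseline <- rolling_percentile(lp, hw, pct / 100)
  list(detrended = lp - baseline, lowpassed = lp, lowpass_applied = apply_lp)
}

#' Baseline (F0) offset and noise-band estimation
#'
#' Identifies quiescent frames and estimates the residual baseline offset and
#' the noise standard deviation of a detrended trace:
#' \enumerate{
#'   \item running 8th percentile of the detrended trace in a +/- 0.5 s
#'     window (`short_window_s` total width) gives a fast local baseline `B`;
#'   \item residual `r = detrended - B`;
#'   \item frames with `r` below its `band_pct`-th percentile form the
#'     "noise band" (quiescent frames), which excludes transient peaks even
#'     for highly active cells;
#'   \item `f0_offset` is the median of the detrended trace over quiescent
#'     frames; `noise_sd` is the standard deviation of `r` there.
#' }
#'
#' @param detrended numeric vector from [lowpass_and_detrend()].
#' @param frame_rate_hz frame rate in Hz.
#' @param short_window_s total width of the fast baseline window in seconds
#'   (default 1).
#' @param band_pct percentile of the residual defining the noise band
#'   (default 60).
#' @return list with `f0_offset`, `noise_sd`, `quiescent_mask` (logical,
#'   never empty) and `degenerate` (TRUE when the trace is constant and
#'   `noise_sd` is 0).
#' @export
estimate_f0_and_noise <- function(detrended, frame_rate_hz,
                                  short_window_s = 1, band_pct = 60) {
  stop_if_not_scalar_pos(frame_rate_hz, "frame_rate_hz")
  n <- length(detrended)
  short_frames <- as.integer(round(short_window_s * frame_rate_hz))
  if (n <= short_frames)
    stop("trace shorter than the short baseline window", call. = FALSE)
  hw <- max(1L, as.integer(round(short_frames / 2)))
  b <- rolling_percentile(detrended, hw, 0.08)
  r <- detrended - b
  q <- as.numeric(quantile(r, band_pct / 100))
  mask <- r < q
  if (!any(mask)) mask <- rep(TRUE, n)  # degenerate (e.g. constant) trace
  f0_offset <- median(detrended[mask])
  noise_sd <- if (sum(mask) > 1L) sd(r[mask]) else 0
  degenerate <- !is.finite(noise_sd) || noise_sd == 0
  if (degenerate) {
    noise_sd <- 0
    warning("degenerate trace: noise_sd is 0", call. = FALSE)
  }
  list(f0_offset = f0_offset, noise_sd = noise_sd,
       quiescent_mask = mask, degenerate = degenerate)
}

#' deltaF/F from a detrended trace
#'
#' @param detrended detrended raw-unit trace.
#' @param f0_offset residual baseline offset (raw units) from
#'   [estimate_f0_and_noise()].
#' @param f0_raw absolute baseline fluorescence (raw units, > 0) used as the
#'   denominator; taken from the low-passed but not detrended trace over
#'   quiescent frames, since detrending removes the absolute level.
#' @return numeric vector `(detrended - f0_offset) / f0_raw`.
#' @export
compute_dff <- function(detrended, f0_offset, f0_raw) {
  if (!is.finite(f0_raw) || f0_raw <= 0)
    stop("f0_raw must be > 0; neuron should be flagged and excluded",
         call. = FALSE)
  (detrended - f0_offset) / f0_raw
}

#' Full conditioning chain for one ROI/neuropil trace pair
#'
#' Runs neuropil compensation, low-pass + slow-trend removal, F0/noise
#' estimation and deltaF/F computation, returning a `conditioned_trace`
#' object consumed by the detection and synchrony stages.
#'
#' @param f_roi,f_neuropil raw per-frame fluorescence of ROI and surround.
#' @param frame_rate_hz frame rate in Hz.
#' @param neuropil_factor neuropil compensation factor (default 0.7).
#' @param cutoff_hz,window_s,pct see [lowpass_and_detrend()].
#' @param short_window_s,band_pct see [estimate_f0_and_noise()].
#' @param neuron_id,session_id optional identifiers carried through.
#' @return object of class `conditioned_trace`: list with `dff`, `detrended`,
#'   `f0_offset`, `f0_raw`, `noise_sd`, `quiescent_mask`, `frame_rate_hz`,
#'   `flags` (character vector of QC flags) and `params_used`.
#' @export
condition_trace <- function(f_roi, f_neuropil, frame_rate_hz,
                            neuropil_factor = 0.7, cutoff_hz = 5,
                            window_s = 50, pct = 8,
                            short_window_s = 1, band_pct = 60,
                            neuron_id = NA, session_id = NA) {
  comp <- compensate_neuropil(f_roi, f_neuropil, neuropil_factor)
  ld <- lowpass_and_detrend(comp, frame_rate_hz, cutoff_hz, window_s, pct)
  fn <- withCallingHandlers(
    estimate_f0_and_noise(ld$detrended, frame_rate_hz, short_window_s, band_pct),
    warning = function(w) invokeRestart("muffleWarning"))
  flags <- character(0)
  if (fn$degenerate) flags <- c(flags, "degenerate_trace")
  f0_raw <- median(ld$lowpassed[fn$quiescent_mask])
  if (!is.finite(f0_raw) || f0_raw <= 0) {
    flags <- c(flags, "nonpositive_f0")
    dff <- rep(NA_real_, length(f_roi))
  } else {
    dff <- compute_dff(ld$detrended, fn$f0_offset, f0_raw)
  }
  structure(list(
    dff = dff, detrended = ld$detrended, f0_offset = fn$f0_offset,
    f0_raw = f0_raw, noise_sd = fn$noise_sd,
    quiescent_mask = fn$quiescent_mask, frame_rate_hz = frame_rate_hz,
    neuron_id = neuron_id, session_id = session_id, flags = flags,
    params_used = list(neuropil_factor = neuropil_factor,
                       cutoff_hz = cutoff_hz, window_s = window_s, pct = pct,
                       short_window_s = short_window_s, band_pct = band_pct,
                       lowpass_applied = ld$lowpass_applied)),
    class = "conditioned_trace")
}

#' @export
print.conditioned_trace <- function(x, ...) {
  cat("<conditioned_trace>", length(x$detrended), "frames @",
      x$frame_rate_hz, "Hz | f0_offset", signif(x$f0_offset, 4),
      "| noise_sd", signif(x$noise_sd, 4),
      if (length(x$flags)) paste("| flags:", paste(x$flags, collapse = ",")),
      "\n")
  invisible(x)
}
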