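#' Population specification for the cohort generator
#'
#' Defines how many neurons to simulate and how they distribute over the
#' three activity categories (rarely / intermediately / highly active), with
#' per-category transient-rate ranges. Per-neuron base rates are drawn
#' log-uniformly within the category range.
#'
#' @param n_neurons number of neurons.
#' @param category_fractions numeric length-3 vector `(rare, intermediate,
#'   high)` summing to 1.
#' @param rate_ranges_per_min list of length-2 vectors (lo, hi) in
#'   transients/min for rare, intermediate and high cells; must respect the
#'   category boundaries (rare < 0.25, intermediate within 0.25-4, high > 4).
#' @param cohort_label free-text label, e.g. `"WT-like"`.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_neurons,
                            category_fractions,
                            rate_ranges_per_min = list(
                              rare = c(0.01, 0.24),
                              intermediate = c(0.25, 4.0),
                              high = c(4.1, 12)),
                            cohort_label = "custom") {
  if (n_neurons < 1) stop("need at least one neuron", call. = FALSE)
  f <- as.numeric(category_fractions)
  if (length(f) != 3L || any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-9)
    stop("category_fractions must be 3 values in [0,1] summing to 1",
         call. = FALSE)
  rr <- rate_ranges_per_min
  stopifnot(length(rr) == 3L, all(vapply(rr, length, 1L) == 2L))
  if (rr[[1]][2] >= 0.25 || rr[[2]][1] < 0.25 || rr[[2]][2] > 4 || rr[[3]][1] <= 4)
    stop("rate ranges inconsistent with category boundaries", call. = FALSE)
  structure(list(n_neurons = as.integer(n_neurons), category_fractions = f,
                 rate_ranges_per_min = rr, cohort_label = cohort_label),
            class = "population_spec")
}

#' Cohort presets with empirical category weights
#'
#' Category weights follow the neuron counts reported for wild-type
#' (94 rarely, 309 intermediately, 81 highly active of 484) and amyloidosis
#' (APPPS1-like: 177, 951, 444 of 1572) cohorts.
#'
#' @param n_neurons number of neurons to simulate.
#' @return a [population_spec()].
#' @export
wt_like_population <- function(n_neurons) {
  population_spec(n_neurons, c(94, 309, 81) / 484, cohort_label = "WT-like")
}

#' @rdname wt_like_population
#' @export
app_like_population <- function(n_neurons) {
  population_spec(n_neurons, c(177, 951, 444) / 1572,
                  cohort_label = "APPPS1-like")
}

#' Indicator kinetics and trace-noise specification
#'
#' GCaMP6s-like defaults: difference-of-exponentials kernel with 0.18 s rise
#' and 1.8 s decay, so a single transient stays above a 3-sd threshold for
#' over a second at 10 Hz. The default amplitude (0.5 deltaF/F) over baseline
#' 100 with noise sd 10 gives a peak signal-to-noise ratio of 5.
#'
#' @param rise_tau_s,decay_tau_s kernel time constants in seconds.
#' @param amplitude_dff mean transient amplitude in deltaF/F units.
#' @param amplitude_sigma lognormal sigma of per-event amplitudes.
#' @param baseline_f0 resting fluorescence in raw units (> 0).
#' @param noise_sd white-noise standard deviation in raw units.
#' @param neuropil_mix fraction of the neuropil fluctuation mixed into the
#'   somatic signal, in `[0, 1]`; the default 0.7 mirrors the compensation
#'   factor.
#' @param drift_amplitude,drift_period_s slow sinusoidal drift (raw units,
#'   seconds).
#' @return object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(rise_tau_s = 0.18, decay_tau_s = 1.8,
                          amplitude_dff = 0.5, amplitude_sigma = 0.3,
                          baseline_f0 = 100, noise_sd = 10,
                          neuropil_mix = 0.7, drift_amplitude = 5,
                          drift_period_s = 120) {
  stopifnot(rise_tau_s > 0, decay_tau_s > 0, baseline_f0 > 0,
            noise_sd >= 0, neuropil_mix >= 0, neuropil_mix <= 1)
  structure(list(rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                 amplitude_dff = amplitude_dff,
                 amplitude_sigma = amplitude_sigma,
                 baseline_f0 = baseline_f0, noise_sd = noise_sd,
                 neuropil_mix = neuropil_mix,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s),
            class = "kinetics_spec")
}

#' Session layout and cross-session dynamics specification
#'
#' @param n_sessions number of imaging sessions (default 3, two weeks apart
#'   in the emulated design).
#' @param frames_per_session frames per session (default 5000).
#' @param frame_rate_hz frame rate in Hz (default 10; 5000 frames = 8.3 min).
#' @param rate_drift_mean per-category mean rate drift in transients/min per
#'   session step, length-3 `(rare, intermediate, high)` or scalar.
#' @param rate_drift_sd sd of the rate drift (transients/min per step).
#' @param shared_event_rate_per_min rate of shared network events that drive
#'   pairwise synchrony.
#' @param shared_participation_p probability that a neuron joins a given
#'   shared event.
#' @param shared_events_in `"any"` (default) or `"whisk"`: restrict shared
#'   events to whisking epochs.
#' @param min_event_separation_s hard minimum separation between a neuron's
#'   transients in seconds (default 3, chosen so the smoothed trace recovers
#'   below the 3-sd detection threshold between consecutive events given the
#'   1.8 s indicator decay, keeping events resolvable at 10 Hz).
#' @return object of class `session_plan`.
#' @export
session_plan <- function(n_sessions = 3, frames_per_session = 5000,
                         frame_rate_hz = 10,
                         rate_drift_mean = c(0, 0, 0), rate_drift_sd = 1,
                         shared_event_rate_per_min = 1,
                         shared_participation_p = 0.2,
                         shared_events_in = c("any", "whisk"),
                         min_event_separation_s = 3) {
  stop_if_not_scalar_pos(frame_rate_hz, "frame_rate_hz")
  stopifnot(n_sessions >= 1, frames_per_session >= 10,
            shared_participation_p >= 0, shared_participation_p <= 1,
            rate_drift_sd >= 0)
  if (length(rate_drift_mean) == 1L) rate_drift_mean <- rep(rate_drift_mean, 3)
  stopifnot(length(rate_drift_mean) == 3L)
  structure(list(n_sessions = as.integer(n_sessions),
                 frames_per_session = as.integer(frames_per_session),
                 frame_rate_hz = frame_rate_hz,
                 rate_drift_mean = as.numeric(rate_drift_mean),
                 rate_drift_sd = rate_drift_sd,
                 shared_event_rate_per_min = shared_event_rate_per_min,
                 shared_participation_p = shared_participation_p,
                 shared_events_in = match.arg(shared_events_in),
                 min_event_separation_s = min_event_separation_s),
            class = "session_plan")
}

#' Calcium indicator impulse response
#'
#' Difference of exponentials, peak-normalised to 1, sampled at the frame
#' rate until it decays below 0.1% of the peak.
#'
#' @param frame_rate_hz frame rate in Hz.
#' @param rise_tau_s,decay_tau_s time constants in seconds.
#' @return numeric vector starting at the event onset frame.
#' @export
transient_kernel <- function(frame_rate_hz, rise_tau_s = 0.18,
                             decay_tau_s = 1.8) {
  t_end <- decay_tau_s * log(1000) + rise_tau_s
  tt <- seq(0, t_end, by = 1 / frame_rate_hz)
  k <- exp(-tt / decay_tau_s) - exp(-tt / rise_tau_s)
  k / max(k)
}

#' Alternating-renewal whisking track
#'
#' Quiet and whisking states alternate with exponentially distributed
#' durations (defaults: 20 s quiet, 1 s whisk), emulating long quiet
#' wakefulness interrupted by brief whisking bouts.
#'
#' @param duration_s total track duration in seconds.
#' @param frame_rate_hz frame rate in Hz.
#' @param quiet_mean_s,whisk_mean_s mean state durations in seconds.
#' @return list with `track` (binary per-frame vector) and `epochs`
#'   (data.frame `onset_s`, `offset_s` of generated whisk bouts).
#' @export
simulate_whisking <- function(duration_s, frame_rate_hz,
                              quiet_mean_s = 20, whisk_mean_s = 1) {
  t <- 0
  whisk <- FALSE
  on <- c(); off <- c()
  while (t < duration_s) {
    d <- rexp(1, 1 / if (whisk) whisk_mean_s else quiet_mean_s)
    if (whisk) {
      on <- c(on, t); off <- c(off, min(t + d, duration_s))
    }
    t <- t + d
    whisk <- !whisk
  }
  n <- as.integer(round(duration_s * frame_rate_hz))
  frame_t <- (seq_len(n) - 0.5) / frame_rate_hz
  track <- integer(n)
  for (i in seq_along(on)) track[frame_t >= on[i] & frame_t < off[i]] <- 1L
  list(track = track, epochs = data.frame(onset_s = on %||% numeric(0),
                                          offset_s = off %||% numeric(0)))
}

# n event times in [0, duration) with a hard minimum separation
draw_event_times <- function(n, duration_s, min_sep_s) {
  if (n <= 0) return(numeric(0))
  max_n <- floor(0.9 * duration_s / min_sep_s)
  n <- min(n, max_n)
  if (n <= 0) return(numeric(0))
  slack <- duration_s - (n - 1) * min_sep_s
  sort(runif(n, 0, slack)) + (seq_len(n) - 1) * min_sep_s
}

# merge own and shared event times, enforcing the minimum separation
enforce_separation <- function(times, min_sep_s) {
  times <- sort(times)
  if (length(times) < 2L) return(times)
  keep <- times[1]
  for (t in times[-1]) if (t - keep[length(keep)] >= min_sep_s) keep <- c(keep, t)
  keep
}

#' Simulate a multi-session cohort with full ground truth
#'
#' Generates per-session ROI and neuropil fluorescence traces, a whisking
#' track, optional plaque volumes and a ground-truth manifest for a cohort of
#' neurons tracked across sessions. Per neuron, transient times are Poisson
#' at the neuron's session rate (with a hard minimum separation so events are
#' resolvable at the frame rate); fluorescence is baseline plus the
#' amplitude-scaled indicator kernel at each event, plus a shared neuropil
#' fluctuation (AR(1) + sinusoid per field of view), a slow sinusoidal
#' drift, and white noise. Rates evolve across sessions by truncated-normal
#' drift (floored at 0). Shared network events, joined by each neuron with
#' probability `plan$shared_participation_p`, control pairwise synchrony.
#'
#' @param pop a [population_spec()].
#' @param kin a [kinetics_spec()].
#' @param plan a [session_plan()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param n_fov number of fields of view the neurons are split across
#'   (round-robin); each FOV has its own neuropil fluctuation.
#' @param fov_um in-plane extent of a FOV in micrometres.
#' @param z_range_um depth range of the somata in the structural stack.
#' @param volumes if TRUE, render a plaque voxel volume per session.
#' @param n_plaques number of plaques in the structural volume.
#' @param volume_shape,volume_voxel_um voxel grid used when `volumes = TRUE`.
#' @return list with `sessions` (per session: `f_roi` and `f_neuropil`
#'   frames x neurons matrices, `whisk_track`, optional `volume`) and
#'   `manifest` (ground truth; see Details).
#' @details The manifest contains `neurons` (id, FOV, centroid, drawn
#'   category), `summary` (per neuron x session: drawn and realized rate,
#'   realized category, event count), `event_times`, `shared_event_times`,
#'   `whisk_epochs`, and `plaques` (per-session centers and radii,
#'   non-decreasing over sessions). Realized (`true_`) rates are defined from
#'   the generated event count, `60 * n_events / duration`.
#' @export
simulate_cohort <- function(pop, kin, plan, seed, n_fov = 1,
                            fov_um = c(300, 300), z_range_um = c(100, 160),
                            volumes = FALSE, n_plaques = 4,
                            volume_shape = c(128, 128, 64),
                            volume_voxel_um = c(2.734, 2.734, 2.5)) {
  stopifnot(inherits(pop, "population_spec"), inherits(kin, "kinetics_spec"),
            inherits(plan, "session_plan"))
  set.seed(as.integer(seed))
  n <- pop$n_neurons
  fr <- plan$frame_rate_hz
  nf <- plan$frames_per_session
  duration_s <- nf / fr
  cats <- c("rare", "intermediate", "high")

  drawn_cat <- sample(cats, n, replace = TRUE, prob = pop$category_fractions)
  base_rate <- numeric(n)
  for (k in 1:3) {
    idx <- drawn_cat == cats[k]
    rr <- pop$rate_ranges_per_min[[k]]
    base_rate[idx] <- exp(runif(sum(idx), log(rr[1]), log(rr[2])))
  }

  fov_id <- rep_len(seq_len(n_fov), n)
  cx <- runif(n, 0, fov_um[1])
  cy <- runif(n, 0, fov_um[2])
  # crude minimum-separation relaxation so somata do not overlap
  for (pass in 1:5) {
    d <- as.matrix(dist(cbind(cx, cy)))
    d[upper.tri(d, diag = TRUE)] <- Inf
    d[outer(fov_id, fov_id, "!=")] <- Inf
    clash <- which(d < 15, arr.ind = TRUE)
    if (nrow(clash) == 0L) break
    i <- unique(clash[, 1])
    cx[i] <- runif(length(i), 0, fov_um[1])
    cy[i] <- runif(length(i), 0, fov_um[2])
  }
  cz <- runif(n, z_range_um[1], z_range_um[2])

  vol_extent <- volume_shape * volume_voxel_um
  pl_center <- cbind(runif(n_plaques, 0.1, 0.9) * vol_extent[1],
                     runif(n_plaques, 0.1, 0.9) * vol_extent[2],
                     runif(n_plaques, 0.2, 0.8) * vol_extent[3])
  pl_radius0 <- runif(n_plaques, 6, 12)
  pl_growth <- runif(n_plaques, 0.5, 2.5)  # um per session step

  kernel <- transient_kernel(fr, kin$rise_tau_s, kin$decay_tau_s)
  cat_idx <- match(drawn_cat, cats)

  sessions <- vector("list", plan$n_sessions)
  summary_rows <- vector("list", plan$n_sessions)
  event_times <- vector("list", plan$n_sessions)
  shared_times_all <- vector("list", plan$n_sessions)
  whisk_epochs <- vector("list", plan$n_sessions)
  plaque_rows <- vector("list", plan$n_sessions)
  rate_s <- base_rate

  for (s in seq_len(plan$n_sessions)) {
    if (s > 1) {
      drift <- rnorm(n, plan$rate_drift_mean[cat_idx], plan$rate_drift_sd)
      rate_s <- pmax(0, rate_s + drift)
    }
    wh <- simulate_whisking(duration_s, fr)
    n_shared <- rpois(1, plan$shared_event_rate_per_min * duration_s / 60)
    if (plan$shared_events_in == "whisk" && nrow(wh$epochs) > 0L) {
      ep <- wh$epochs
      w <- pmax(ep$offset_s - ep$onset_s, 1e-6)
      pick <- sample.int(nrow(ep), n_shared, replace = TRUE, prob = w)
      shared_t <- sort(ep$onset_s[pick] + runif(n_shared) * w[pick])
    } else {
      shared_t <- sort(runif(n_shared, 0, duration_s))
    }

    f_roi <- matrix(0, nf, n)
    f_np <- matrix(0, nf, n)
    ev_list <- vector("list", n)
    n_ev <- integer(n)

    # per-FOV neuropil fluctuation: AR(1) + sinusoid
    tt <- (seq_len(nf) - 1) / fr
    np_common <- matrix(0, nf, n_fov)
    for (f in seq_len(n_fov)) {
      ar <- as.numeric(stats::filter(rnorm(nf, 0, kin$noise_sd * 0.6),
                                     0.97, method = "recursive"))
      np_common[, f] <- 0.5 * kin$baseline_f0 + ar +
        2 * kin$noise_sd * sin(2 * pi * tt / 17 + runif(1, 0, 2 * pi))
    }

    for (i in seq_len(n)) {
      n_own <- rpois(1, rate_s[i] * duration_s / 60)
      own_t <- draw_event_times(n_own, duration_s, plan$min_event_separation_s)
      joined <- shared_t[runif(length(shared_t)) < plan$shared_participation_p]
      ev <- enforce_separation(c(own_t, joined), plan$min_event_separation_s)
      ev_list[[i]] <- ev
      n_ev[i] <- length(ev)

      impulse <- numeric(nf)
      if (length(ev)) {
        fi <- pmin(nf, floor(ev * fr) + 1L)
        amps <- kin$amplitude_dff *
          rlnorm(length(ev), -kin$amplitude_sigma^2 / 2, kin$amplitude_sigma)
        impulse[fi] <- impulse[fi] + amps
      }
      conv <- if (length(ev))
        convolve(impulse, rev(kernel), type = "open")[seq_len(nf)]
      else numeric(nf)
      sig <- kin$baseline_f0 * (1 + conv)
      npt <- np_common[, fov_id[i]]
      drift_tr <- kin$drift_amplitude *
        sin(2 * pi * tt / kin$drift_period_s + runif(1, 0, 2 * pi))
      f_roi[, i] <- sig + kin$neuropil_mix * (npt - median(npt)) +
        drift_tr + rnorm(nf, 0, kin$noise_sd)
      f_np[, i] <- npt + rnorm(nf, 0, kin$noise_sd * 0.5)
    }

    radii <- pl_radius0 + (s - 1) * pl_growth
    vol <- NULL
    if (volumes)
      vol <- simulate_plaque_volume(pl_center, radii,
                                    voxel_size_um = volume_voxel_um,
                                    shape_voxels = volume_shape)
    true_rate <- 60 * n_ev / duration_s
    summary_rows[[s]] <- data.frame(
      neuron_id = seq_len(n), session = s, fov_id = fov_id,
      drawn_category = factor(drawn_cat, levels = cats),
      drawn_rate = rate_s, n_events = n_ev, true_rate = true_rate,
      true_category = classify_activity(true_rate))
    sessions[[s]] <- list(f_roi = f_roi, f_neuropil = f_np,
                          whisk_track = wh$track, volume = vol)
    event_times[[s]] <- ev_list
    shared_times_all[[s]] <- shared_t
    whisk_epochs[[s]] <- wh$epochs
    plaque_rows[[s]] <- data.frame(session = s, plaque_id = seq_len(n_plaques),
                                   x_um = pl_center[, 1], y_um = pl_center[, 2],
                                   z_um = pl_center[, 3], radius_um = radii)
  }

  manifest <- list(
    neurons = data.frame(neuron_id = seq_len(n), fov_id = fov_id,
                         x_um = cx, y_um = cy, z_um = cz,
                         drawn_category = factor(drawn_cat, levels = cats)),
    summary = do.call(rbind, summary_rows),
    event_times = event_times,
    shared_event_times = shared_times_all,
    whisk_epochs = whisk_epochs,
    plaques = do.call(rbind, plaque_rows),
    duration_s = duration_s, frame_rate_hz = fr,
    cohort_label = pop$cohort_label, seed = as.integer(seed))
  list(sessions = sessions, manifest = manifest,
       pop = pop, kin = kin, plan = plan)
}

#' Render a binary plaque volume from sphere parameters
#'
#' The mask is the union of spheres on an anisotropic voxel grid; a voxel is
#' positive when its centre lies within a sphere. Voxel centres sit at
#' `(index - 0.5) * voxel_size_um` along each axis. Optionally renders a
#' noisy raw Methoxy-like channel for the cleanup pipeline.
#'
#' @param centers m x 3 matrix of sphere centres in micrometres (x, y, z);
#'   a zero-row matrix or NULL yields an all-zero mask.
#' @param radii_um sphere radii in micrometres (> 0).
#' @param voxel_size_um voxel size `(x, y, z)` in micrometres; defaults match
#'   a 350 um / 520 px stack with 0.5 um z-steps.
#' @param shape_voxels volume dimensions in voxels `(nx, ny, nz)`.
#' @param render_raw if TRUE also return a raw channel: `background +
#'   signal * mask + bleed_frac * bleed_from + noise`.
#' @param background,signal,noise_sd raw-channel rendering levels.
#' @param bleed_from optional array (same shape) bleeding into the channel.
#' @param bleed_frac bleed-through fraction.
#' @return a `plaque_volume`: list with logical 3D `mask` and
#'   `voxel_size_um`; when `render_raw`, also `raw`.
#' @export
simulate_plaque_volume <- function(centers, radii_um,
                                   voxel_size_um = c(0.673, 0.673, 0.5),
                                   shape_voxels = c(128, 128, 64),
                                   render_raw = FALSE, background = 20,
                                   signal = 200, noise_sd = 5,
                                   bleed_from = NULL, bleed_frac = 0.3) {
  stopifnot(all(voxel_size_um > 0), length(shape_voxels) == 3L)
  if (is.null(centers) || NROW(centers) == 0L) {
    centers <- matrix(numeric(0), 0, 3)
    radii_um <- numeric(0)
  }
  centers <- matrix(as.numeric(centers), ncol = 3)
  stopifnot(length(radii_um) == nrow(centers), all(radii_um > 0))
  mask <- array(FALSE, dim = shape_voxels)
  ax <- lapply(1:3, function(d) (seq_len(shape_voxels[d]) - 0.5) * voxel_size_um[d])
  extent <- shape_voxels * voxel_size_um
  for (m in seq_len(nrow(centers))) {
    c_um <- centers[m, ]; r <- radii_um[m]
    if (any(c_um + r < 0) || any(c_um - r > extent)) {
      warning("sphere ", m, " lies entirely outside the volume", call. = FALSE)
      next
    }
    rng <- lapply(1:3, function(d)
      which(ax[[d]] >= c_um[d] - r & ax[[d]] <= c_um[d] + r))
    if (any(vapply(rng, length, 1L) == 0L)) next
    dx2 <- (ax[[1]][rng[[1]]] - c_um[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - c_um[2])^2
    dz2 <- (ax[[3]][rng[[3]]] - c_um[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    mask[rng[[1]], rng[[2]], rng[[3]]] <-
      mask[rng[[1]], rng[[2]], rng[[3]]] | (d2 <= r^2)
  }
  out <- structure(list(mask = mask, voxel_size_um = voxel_size_um,
                        origin_um = c(0, 0, 0)), class = "plaque_volume")
  if (render_raw) {
    raw <- background + signal * mask +
      array(rnorm(prod(shape_voxels), 0, noise_sd), dim = shape_voxels)
    if (!is.null(bleed_from)) raw <- raw + bleed_frac * bleed_from
    out$raw <- raw
  }
  out
}
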