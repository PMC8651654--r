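#' Extract ROI and neuropil traces from a movie
#'
#' Averages, per frame, the pixel values inside each labelled ROI and inside
#' its surrounding neuropil region.
#'
#' @param movie 3D array `(rows, cols, frames)`.
#' @param roi_labels,neuropil_labels integer label matrices matching the
#'   movie's in-plane shape; label `k` marks ROI `k` / its neuropil region.
#' @return list with `f_roi` and `f_neuropil`, frames x neurons matrices
#'   (columns ordered by label).
#' @export
extract_traces <- function(movie, roi_labels, neuropil_labels) {
  stopifnot(length(dim(movie)) == 3L,
            identical(dim(movie)[1:2], dim(roi_labels)),
            identical(dim(movie)[1:2], dim(neuropil_labels)))
  ids <- sort(unique(roi_labels[roi_labels > 0]))
  if (length(ids) == 0L) stop("no ROI labels found", call. = FALSE)
  nf <- dim(movie)[3]
  flat <- matrix(movie, ncol = nf)
  mean_trace <- function(labels, id, what) {
    px <- which(labels == id)
    if (length(px) == 0L)
      stop("empty ", what, " region for label ", id, call. = FALSE)
    colMeans(flat[px, , drop = FALSE])
  }
  f_roi <- vapply(ids, function(id) mean_trace(roi_labels, id, "ROI"),
                  numeric(nf))
  f_np <- vapply(ids, function(id) mean_trace(neuropil_labels, id, "neuropil"),
                 numeric(nf))
  list(f_roi = f_roi, f_neuropil = f_np, ids = ids)
}

#' Write / read per-session trace tables (long-format CSV)
#'
#' Long format: `session`, `neuron`, `frame`, `f_roi`, `f_neuropil`.
#'
#' @param sessions list of per-session lists with `f_roi` and `f_neuropil`
#'   frames x neurons matrices (e.g. `simulate_cohort()$sessions`).
#' @param path CSV file path.
#' @return `write_traces_csv` returns `path` invisibly; `read_traces_csv`
#'   returns the `sessions` list structure.
#' @export
write_traces_csv <- function(sessions, path) {
  rows <- lapply(seq_along(sessions), function(s) {
    m <- sessions[[s]]
    nf <- nrow(m$f_roi); nn <- ncol(m$f_roi)
    data.table::data.table(
      session = s,
      neuron = rep(seq_len(nn), each = nf),
      frame = rep(seq_len(nf), nn),
      f_roi = as.vector(m$f_roi),
      f_neuropil = as.vector(m$f_neuropil))
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  x <- data.table::fread(path)
  stopifnot(all(c("session", "neuron", "frame", "f_roi", "f_neuropil")
                %in% names(x)))
  lapply(split(x, x$session), function(xs) {
    nf <- max(xs$frame); nn <- max(xs$neuron)
    xs <- xs[order(xs$neuron, xs$frame)]
    list(f_roi = matrix(xs$f_roi, nf, nn),
         f_neuropil = matrix(xs$f_neuropil, nf, nn))
  })
}

#' Default pipeline configuration
#'
#' All pinned constants of every stage, in one strict-schema list. Units are
#' part of the key names (`_s` seconds, `_hz` Hertz, `_um` micrometres).
#'
#' @return nested named list; see the methods vignette for the meaning and
#'   provenance of each constant.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    aggregation = "fov",
    simulate = list(cohort = "wt", n_neurons = 20L, n_sessions = 3L,
                    frames_per_session = 5000L, frame_rate_hz = 10,
                    n_fov = 1L, volumes = FALSE,
                    shared_event_rate_per_min = 1,
                    shared_participation_p = 0.2,
                    rate_drift_sd = 1),
    processing = list(neuropil_factor = 0.7, cutoff_hz = 5, window_s = 50,
                      pct = 8, short_window_s = 1, band_pct = 60),
    detection = list(smooth_frames = 5L, k_sd = 3, duration_frames = 10L,
                     min_distance_frames = 15L),
    binarize = list(smooth_frames = 20L, k_sd = 2),
    behavior = list(min_duration_s = 0.33, w_min_s = 1, w_max_s = 2),
    correlation = list(min_frames = 100L, n_shuffles = 20L),
    dynamics = list(n_shuffles = 100L, n_boot = 1000L),
    plaque = list(cutoff_um = 40, bin_edges_um = c(0, 20, 40, 60, 1e6))
  )
}

check_keys <- function(x, ref, path = "") {
  extra <- setdiff(names(x), names(ref))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  for (k in names(x))
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      check_keys(x[[k]], ref[[k]], paste0(path, k, "$"))
  invisible(TRUE)
}

#' Load, validate and complete a pipeline configuration
#'
#' Unknown keys are rejected (strict schema); missing keys fall back to
#' [default_config()]. Configurations round-trip losslessly through YAML.
#'
#' @param config a (partial) named list, or a path to a YAML/JSON file.
#' @return validated full configuration list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  ref <- default_config()
  check_keys(config, ref)
  merge_in <- function(ref, x) {
    for (k in names(x)) {
      ref[[k]] <- if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
        merge_in(ref[[k]], x[[k]]) else x[[k]]
    }
    ref
  }
  merge_in(ref, config)
}

#' @rdname run_config
#' @param path output YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

fmt_num_cols <- function(df) {
  for (k in names(df))
    if (is.double(df[[k]])) df[[k]] <- sprintf("%.10g", df[[k]])
  df
}

write_table <- function(df, dir, name) {
  data.table::fwrite(fmt_num_cols(as.data.frame(df)),
                     file.path(dir, name))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a multi-session cohort, conditions every trace,
#' detects transients, builds the longitudinal table and all cross-session
#' statistics, computes pairwise synchrony with shuffle and epoch controls,
#' and (when structural volumes are present) the plaque-distance analyses.
#' All result tables, a JSON run manifest (config echo, versions, seed,
#' counts) and a log file are written to `out_dir`. Per-neuron QC flags
#' never abort the run; missing inputs fail fast.
#'
#' @param config configuration from [run_config()] (or a partial list /
#'   YAML path, passed through it).
#' @param out_dir output directory, created if needed.
#' @param traces optional pre-loaded `sessions` list (as from
#'   [read_traces_csv()]); replaces simulation. Whisk tracks and centroids
#'   are then unavailable unless contained in the list.
#' @return invisibly, a list with the main in-memory results
#'   (`summaries`, `longitudinal`, `dynamics`, `correlation`, `plaques`).
#' @export
run_pipeline <- function(config = list(), out_dir, traces = NULL) {
  cfg <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  if (is.null(traces)) {
    pop <- switch(cfg$simulate$cohort,
                  wt = wt_like_population(cfg$simulate$n_neurons),
                  app = app_like_population(cfg$simulate$n_neurons),
                  stop("unknown cohort preset", call. = FALSE))
    drift_mean <- if (cfg$simulate$cohort == "app") c(0, 0.3, 0) else c(0, 0, 0)
    plan <- session_plan(
      n_sessions = cfg$simulate$n_sessions,
      frames_per_session = cfg$simulate$frames_per_session,
      frame_rate_hz = cfg$simulate$frame_rate_hz,
      rate_drift_mean = drift_mean,
      rate_drift_sd = cfg$simulate$rate_drift_sd,
      shared_event_rate_per_min = cfg$simulate$shared_event_rate_per_min,
      shared_participation_p = cfg$simulate$shared_participation_p)
    sim <- simulate_cohort(pop, kinetics_spec(), plan, seed = cfg$seed,
                           n_fov = cfg$simulate$n_fov,
                           volumes = cfg$simulate$volumes)
    sessions <- sim$sessions
    centroids <- as.matrix(sim$manifest$neurons[, c("x_um", "y_um", "z_um")])
    fov_id <- sim$manifest$neurons$fov_id
    note("simulated cohort '", pop$cohort_label, "', ",
         pop$n_neurons, " neurons, seed ", cfg$seed)
  } else {
    sim <- NULL
    sessions <- traces
    nn <- ncol(sessions[[1]]$f_roi)
    centroids <- NULL
    fov_id <- rep(1L, nn)
    note("loaded ", length(sessions), " session(s) of externally provided traces")
  }
  fr <- cfg$simulate$frame_rate_hz
  n_sessions <- length(sessions)
  nn <- ncol(sessions[[1]]$f_roi)

  events_rows <- list(); summary_rows <- list()
  rasters <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    raster <- matrix(0L, nrow(sessions[[s]]$f_roi), nn)
    for (i in seq_len(nn)) {
      cond <- suppressMessages(condition_trace(
        sessions[[s]]$f_roi[, i], sessions[[s]]$f_neuropil[, i], fr,
        neuropil_factor = cfg$processing$neuropil_factor,
        cutoff_hz = cfg$processing$cutoff_hz,
        window_s = cfg$processing$window_s, pct = cfg$processing$pct,
        short_window_s = cfg$processing$short_window_s,
        band_pct = cfg$processing$band_pct,
        neuron_id = i, session_id = s))
      if (length(cond$flags))
        note("QC session ", s, " neuron ", i, ": ",
             paste(cond$flags, collapse = ","))
      if (cond$noise_sd <= 0) next
      ev <- detect_transients(cond,
                              smooth_frames = cfg$detection$smooth_frames,
                              k_sd = cfg$detection$k_sd,
                              duration_frames = cfg$detection$duration_frames,
                              min_distance_frames =
                                cfg$detection$min_distance_frames)
      summary_rows[[length(summary_rows) + 1L]] <-
        cbind(summarize_activity(ev, cond), fov_id = fov_id[i])
      if (nrow(ev))
        events_rows[[length(events_rows) + 1L]] <- data.frame(
          session = s, neuron_id = i,
          onset_s = (ev$onset_frame - 1) / fr,
          offset_s = (ev$offset_frame - 1) / fr,
          peak_s = (ev$peak_frame - 1) / fr,
          peak_height = ev$peak_height, peak_dff = ev$peak_dff)
      raster[, i] <- binarize_trace(cond,
                                    smooth_frames = cfg$binarize$smooth_frames,
                                    k_sd = cfg$binarize$k_sd)
    }
    rasters[[s]] <- raster
  }
  events <- if (length(events_rows)) do.call(rbind, events_rows) else
    data.frame(session = integer(0), neuron_id = integer(0),
               onset_s = numeric(0), offset_s = numeric(0),
               peak_s = numeric(0), peak_height = numeric(0),
               peak_dff = numeric(0))
  summaries <- do.call(rbind, summary_rows)
  lt <- longitudinal_table(summaries)

  # cross-session dynamics, session 1 vs each later session
  dynamics <- list()
  for (s1 in setdiff(seq_len(n_sessions), 1L)) {
    key <- paste0("s1_vs_s", s1)
    ch <- activity_change(lt, 1L, s1)
    null_si <- shuffle_null_similarity(lt, 1L, s1,
                                       n_shuffles = cfg$dynamics$n_shuffles,
                                       seed = cfg$seed)
    tm <- transition_matrix(lt, 1L, s1)
    reo <- sapply(c("rare", "intermediate", "high"), function(cc)
      tryCatch(reoccurrence_rate(lt, cc, 1L, s1)$pooled,
               error = function(e) NA_real_))
    nh <- novel_high_analysis(lt, 1L, s1, n_boot = cfg$dynamics$n_boot,
                              seed = cfg$seed)
    dynamics[[key]] <- list(
      mean_abs_delta = mean(abs(ch$delta_rate)),
      frac_delta_within_2 = mean(abs(ch$delta_rate) <= 2),
      similarity_observed = attr(null_si, "observed"),
      similarity_null_mean = mean(null_si),
      transition_fractions = tm$fractions,
      recruitment_rate = tm$recruitment_rate,
      reoccurrence = reo,
      novel_high_n = nh$n_novel,
      novel_high_mean_gain = nh$mean_gain)
  }

  # pairwise synchrony per session
  corr_summ <- list(); pair_rows <- list()
  for (s in seq_len(n_sessions)) {
    pr <- suppressWarnings(pairwise_correlation(
      rasters[[s]],
      centroids = if (!is.null(centroids)) centroids[, 1:2, drop = FALSE],
      min_frames = cfg$correlation$min_frames))
    null_r <- shuffle_control(rasters[[s]], cfg$correlation$n_shuffles,
                              seed = cfg$seed)
    epoch_means <- c(whisk = NA_real_, stationary = NA_real_)
    if (!is.null(sessions[[s]]$whisk_track)) {
      ep <- detect_whisk_epochs(sessions[[s]]$whisk_track, fr,
                                cfg$behavior$min_duration_s)
      wa <- whisk_response_windows(ep, cfg$behavior$w_min_s,
                                   cfg$behavior$w_max_s)
      whisk_frames <- !stationary_mask(ep, wa) &
        !(attr(wa, "discarded") %||% FALSE)
      masks <- list(whisk = whisk_frames, stationary = stationary_mask(ep, wa))
      er <- epoch_restricted_correlation(rasters[[s]], masks,
                                         min_frames = cfg$correlation$min_frames)
      epoch_means <- c(whisk = er$whisk$mean_r,
                       stationary = er$stationary$mean_r)
    }
    corr_summ[[s]] <- data.frame(
      session = s, mean_r = pr$mean_r, shuffled_mean_r = mean(null_r),
      mean_r_whisk = epoch_means[["whisk"]],
      mean_r_stationary = epoch_means[["stationary"]],
      n_undefined = pr$n_undefined)
    p <- pr$pairs; p$session <- s
    pair_rows[[s]] <- p
  }
  corr_summary <- do.call(rbind, corr_summ)

  # plaque distances (only when structural volumes were generated/supplied)
  plaques <- NULL
  if (!is.null(sessions[[1]]$volume) && !is.null(centroids)) {
    dist_rows <- lapply(seq_len(n_sessions), function(s) {
      d <- nearest_plaque_distances(centroids, sessions[[s]]$volume)
      data.frame(session = s, neuron_id = seq_len(nn),
                 distance_um = as.numeric(d),
                 proximity = classify_proximity(as.numeric(d),
                                                cfg$plaque$cutoff_um),
                 border_flag = attr(d, "border_flags"))
    })
    distances <- do.call(rbind, dist_rows)
    strat <- proximity_stratified_dynamics(lt, distances, 1L, n_sessions,
                                           cutoff_um = cfg$plaque$cutoff_um)
    plaques <- list(distances = distances, stratified = strat)
    write_table(distances, out_dir, "plaque_distances.csv")
  }

  write_table(events, out_dir, "events.csv")
  write_table(summaries, out_dir, "activity_summaries.csv")
  write_table(as.data.frame(lt), out_dir, "longitudinal.csv")
  write_table(corr_summary, out_dir, "correlation_summary.csv")
  write_table(do.call(rbind, pair_rows), out_dir, "correlation_pairs.csv")
  tm_rows <- do.call(rbind, lapply(names(dynamics), function(k) {
    f <- dynamics[[k]]$transition_fractions
    data.frame(pair = k, from = rep(rownames(f), 3),
               to = rep(colnames(f), each = 3), fraction = as.vector(f))
  }))
  write_table(tm_rows, out_dir, "transitions.csv")
  dyn_json <- lapply(dynamics, function(d) {
    d$transition_fractions <- NULL
    lapply(d, function(v) if (is.numeric(v)) unname(round(v, 10)) else v)
  })
  jsonlite::write_json(dyn_json, file.path(out_dir, "dynamics.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  manifest <- list(
    package = "calcitrack",
    version = as.character(utils::packageVersion("calcitrack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed, config = cfg,
    counts = list(n_neurons = nn, n_sessions = n_sessions,
                  n_events = nrow(events)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(summaries = summaries, longitudinal = lt,
                 dynamics = dynamics, correlation = corr_summary,
                 plaques = plaques, events = events))
}

#' Write / read a plaque volume as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z-slice (32-bit float, mask stored as 0/1); the voxel
#' size travels in `<path>.json`.
#'
#' @param vol a `plaque_volume`.
#' @param path TIFF file path.
#' @return `write_plaque_tiff` returns `path` invisibly; `read_plaque_tiff`
#'   returns the `plaque_volume`.
#' @export
write_plaque_tiff <- function(vol, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  stopifnot(inherits(vol, "plaque_volume"))
  pages <- lapply(seq_len(dim(vol$mask)[3]), function(z)
    matrix(as.numeric(vol$mask[, , z]), nrow = dim(vol$mask)[1]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(voxel_size_um = vol$voxel_size_um,
                            origin_um = vol$origin_um,
                            shape = dim(vol$mask)),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = 10)
  invisible(path)
}

#' @rdname write_plaque_tiff
#' @export
read_plaque_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import", call. = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mask <- array(FALSE, dim = meta$shape)
  for (z in seq_along(pages)) mask[, , z] <- pages[[z]] > 0.5
  structure(list(mask = mask, voxel_size_um = meta$voxel_size_um,
                 origin_um = meta$origin_um), class = "plaque_volume")
}
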