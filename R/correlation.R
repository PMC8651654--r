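#' Binarize a conditioned trace for synchrony analysis
#'
#' Boxcar-smooths the detrended trace over `smooth_frames` (2 s at 10 Hz)
#' and sets frames above `f0_offset + k_sd * noise_sd` to 1. Thresholding in
#' noise-sd units makes the result invariant to rescaling of the raw trace.
#'
#' @param cond a `conditioned_trace`.
#' @param smooth_frames boxcar width in frames (default 20).
#' @param k_sd threshold in noise-sd units (default 2).
#' @return integer 0/1 vector, one value per frame.
#' @export
binarize_trace <- function(cond, smooth_frames = 20, k_sd = 2) {
  stopifnot(inherits(cond, "conditioned_trace"))
  if (cond$noise_sd <= 0)
    stop("noise_sd is 0: neuron excluded from binarization", call. = FALSE)
  sm <- boxcar_smooth(cond$detrended, smooth_frames)
  as.integer(sm > cond$f0_offset + k_sd * cond$noise_sd)
}

#' Pairwise Pearson correlation of a binary activity raster
#'
#' @param raster frames x neurons matrix with entries in `{0, 1}`.
#' @param frame_mask optional logical per-frame mask restricting the
#'   analysis; fewer than `min_frames` retained frames flags the result
#'   invalid.
#' @param centroids optional neurons x 2 matrix of in-plane centroid
#'   positions (micrometres) used to attach pair distances.
#' @param min_frames minimum retained frames (default 100).
#' @return a `pairwise_result`: list with `pairs` (data.frame `i`, `j`, `r`,
#'   `distance_um`), `mean_r` (over defined pairs), `n_undefined` (pairs with
#'   a constant member, excluded from the mean), `n_frames`, `valid`.
#' @export
pairwise_correlation <- function(raster, frame_mask = NULL, centroids = NULL,
                                 min_frames = 100) {
  raster <- as.matrix(raster)
  if (ncol(raster) < 2L) stop("need at least 2 neurons", call. = FALSE)
  if (!all(raster %in% c(0, 1))) stop("raster must be binary", call. = FALSE)
  if (!is.null(frame_mask)) {
    stopifnot(length(frame_mask) == nrow(raster))
    raster <- raster[as.logical(frame_mask), , drop = FALSE]
  }
  nn <- ncol(raster)
  ij <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  pairs <- data.frame(i = ij[, 1], j = ij[, 2], r = NA_real_,
                      distance_um = NA_real_)
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    pairs$distance_um <- sqrt(
      (centroids[pairs$i, 1] - centroids[pairs$j, 1])^2 +
        (centroids[pairs$i, 2] - centroids[pairs$j, 2])^2)
  }
  if (nrow(raster) < min_frames) {
    warning("fewer than ", min_frames, " retained frames: FOV flagged",
            call. = FALSE)
    return(structure(list(pairs = pairs, mean_r = NA_real_,
                          n_undefined = NA_integer_,
                          n_frames = nrow(raster), valid = FALSE),
                     class = "pairwise_result"))
  }
  sds <- apply(raster, 2, sd)
  cm <- suppressWarnings(cor(raster))
  rvals <- cm[cbind(pairs$i, pairs$j)]
  rvals[sds[pairs$i] == 0 | sds[pairs$j] == 0] <- NA_real_
  pairs$r <- rvals
  structure(list(pairs = pairs, mean_r = mean(rvals, na.rm = TRUE),
                 n_undefined = sum(is.na(rvals)), n_frames = nrow(raster),
                 valid = TRUE),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat("<pairwise_result>", nrow(x$pairs), "pairs over", x$n_frames,
      "frames | mean R", signif(x$mean_r, 4), "|", x$n_undefined,
      "undefined\n")
  invisible(x)
}

#' Circular-shift shuffle control for pairwise correlation
#'
#' Each shuffle applies an independent uniform circular time-shift to every
#' neuron's binary vector and recomputes the mean pairwise correlation. The
#' shift preserves each neuron's event count and autocorrelation while
#' destroying cross-neuron alignment.
#'
#' @param raster frames x neurons binary matrix.
#' @param n_shuffles number of shuffles (>= 1).
#' @param seed integer seed.
#' @param frame_mask optional per-frame mask applied after shifting.
#' @return numeric vector of null mean-R values.
#' @export
shuffle_control <- function(raster, n_shuffles, seed, frame_mask = NULL) {
  stopifnot(n_shuffles >= 1)
  raster <- as.matrix(raster)
  nf <- nrow(raster); nn <- ncol(raster)
  set.seed(as.integer(seed))
  vapply(seq_len(n_shuffles), function(k) {
    shifts <- sample.int(nf, nn, replace = TRUE) - 1L
    shifted <- raster
    for (j in seq_len(nn)) {
      s <- shifts[j]
      if (s > 0) shifted[, j] <- raster[c((nf - s + 1L):nf, 1L:(nf - s)), j]
    }
    suppressWarnings(
      pairwise_correlation(shifted, frame_mask = frame_mask)$mean_r)
  }, numeric(1))
}

#' Pairwise correlation restricted to behavioural epoch classes
#'
#' @param raster frames x neurons binary matrix.
#' @param masks named list of logical per-frame masks (e.g. `whisk`,
#'   `stationary`) partitioning (a subset of) the frames.
#' @param centroids,min_frames passed to [pairwise_correlation()].
#' @return named list of `pairwise_result`, one per epoch class; classes
#'   with fewer than `min_frames` frames come back flagged invalid.
#' @export
epoch_restricted_correlation <- function(raster, masks, centroids = NULL,
                                         min_frames = 100) {
  stopifnot(is.list(masks), !is.null(names(masks)))
  lapply(masks, function(m)
    suppressWarnings(pairwise_correlation(raster, frame_mask = m,
                                          centroids = centroids,
                                          min_frames = min_frames)))
}

#' Mean pairwise correlation as a function of pair distance
#'
#' @param result a `pairwise_result` carrying pair distances.
#' @param bin_edges_um increasing numeric vector of distance bin edges
#'   (micrometres); pairs are assigned by `edges[k] <= d < edges[k+1]`,
#'   with the last bin closed on the right.
#' @return data.frame `bin_lo`, `bin_hi`, `mean_r`, `n_pairs` (empty bins
#'   have `n_pairs = 0` and `NA` mean); attribute `full_coverage` is TRUE
#'   when every bin holds at least one pair (the criterion for keeping a FOV
#'   in distance analyses).
#' @export
correlation_vs_distance <- function(result, bin_edges_um) {
  stopifnot(inherits(result, "pairwise_result"),
            length(bin_edges_um) >= 2, !is.unsorted(bin_edges_um))
  p <- result$pairs
  if (all(is.na(p$distance_um)))
    stop("pair distances unavailable; supply centroids", call. = FALSE)
  nb <- length(bin_edges_um) - 1L
  idx <- findInterval(p$distance_um, bin_edges_um, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(seq_len(nb), function(k) {
    sel <- which(idx == k & !is.na(p$r))
    data.frame(bin_lo = bin_edges_um[k], bin_hi = bin_edges_um[k + 1],
               mean_r = if (length(sel)) mean(p$r[sel]) else NA_real_,
               n_pairs = length(sel))
  }))
  attr(out, "full_coverage") <- all(out$n_pairs > 0)
  out
}

#' Pairwise correlations restricted to an activity category
#'
#' Keeps only the pairs whose two members both belong to `category`.
#'
#' @param result a `pairwise_result`.
#' @param categories per-neuron category vector (factor or character,
#'   indexed by neuron column), or a summary data.frame with `neuron_id` and
#'   `category`.
#' @param category `"rare"`, `"intermediate"` or `"high"`.
#' @return list with `r` (pair correlation values, undefined pairs removed),
#'   `n_pairs`, `empty` (TRUE when no such pair exists).
#' @export
category_restricted_correlation <- function(result, categories, category) {
  stopifnot(inherits(result, "pairwise_result"))
  category <- match.arg(category, c("rare", "intermediate", "high"))
  if (is.data.frame(categories)) {
    ord <- order(categories$neuron_id)
    categories <- as.character(categories$category)[ord]
  } else categories <- as.character(categories)
  p <- result$pairs
  sel <- categories[p$i] == category & categories[p$j] == category
  r <- p$r[sel]
  n_def <- sum(!is.na(r))
  if (!any(sel)) {
    warning("no pair with both members in category '", category, "'",
            call. = FALSE)
    return(list(r = numeric(0), n_pairs = 0L, empty = TRUE))
  }
  list(r = r[!is.na(r)], n_pairs = sum(sel), n_defined = n_def,
       empty = FALSE)
}
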