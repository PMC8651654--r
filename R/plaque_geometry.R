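# vectorised 3x3 median via a 19-comparator sorting network (Devillard),
# replicate-padded at the matrix edges; no range assumptions on the input
median_filter_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- function(dr) pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- function(dc) pmin(pmax(seq_len(nc) + dc, 1L), nc)
  p <- vector("list", 9)
  k <- 0
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1
    p[[k]] <- m[ri(dr), ci(dc), drop = FALSE]
  }
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  p[[5]]
}

#' Clean the plaque (Methoxy) channel of a structural stack
#'
#' Per z-slice: subtract each channel's background (the slice median),
#' subtract the activity-indicator channel from the plaque channel to remove
#' bleed-through (clipped at zero), then apply a 3x3 median filter.
#'
#' @param methoxy_stack,gcamp_stack 3D arrays `(x, y, z)` of identical shape.
#' @return cleaned 3D array.
#' @export
clean_methoxy_channel <- function(methoxy_stack, gcamp_stack) {
  stopifnot(identical(dim(methoxy_stack), dim(gcamp_stack)),
            length(dim(methoxy_stack)) == 3L)
  out <- methoxy_stack
  for (z in seq_len(dim(methoxy_stack)[3])) {
    mbs <- methoxy_stack[, , z] - median(methoxy_stack[, , z])
    gbs <- gcamp_stack[, , z] - median(gcamp_stack[, , z])
    out[, , z] <- median_filter_3x3(pmax(mbs - gbs, 0))
  }
  out
}

#' Binarize a cleaned plaque channel
#'
#' Per z-slice, a voxel is plaque-positive when its value exceeds the slice
#' background plus 3 robust standard deviations. Background is the slice
#' median; the sd is `1.4826 x MAD` of the sub-median voxels, so bright
#' plaque signal cannot inflate its own threshold.
#'
#' @param cleaned_stack 3D array from [clean_methoxy_channel()].
#' @param voxel_size_um voxel size `(x, y, z)` in micrometres.
#' @return a `plaque_volume` (logical `mask`, `voxel_size_um`, `origin_um`).
#' @export
binarize_plaques <- function(cleaned_stack,
                             voxel_size_um = c(0.673, 0.673, 0.5)) {
  stopifnot(length(dim(cleaned_stack)) == 3L, all(voxel_size_um > 0))
  mask <- array(FALSE, dim = dim(cleaned_stack))
  for (z in seq_len(dim(cleaned_stack)[3])) {
    sl <- cleaned_stack[, , z]
    bg <- median(sl)
    sub <- sl[sl <= bg]
    sd_r <- 1.4826 * median(abs(sub - bg))
    mask[, , z] <- sl > bg + 3 * sd_r
  }
  structure(list(mask = mask, voxel_size_um = voxel_size_um,
                 origin_um = c(0, 0, 0)), class = "plaque_volume")
}

#' 3D Euclidean distance from an ROI centroid to the nearest plaque voxel
#'
#' Distances are measured between the centroid and the centres of
#' plaque-positive voxels, scaled per axis by the (anisotropic) voxel size.
#' Voxel centres sit at `(index - 0.5) * voxel_size_um`.
#'
#' @param centroid_um length-3 centroid `(x, y, z)` in micrometres.
#' @param vol a `plaque_volume`.
#' @return minimum distance in micrometres; `Inf` when the mask is empty.
#'   A centroid more than 10 um outside the volume bounds triggers a
#'   warning (the distance is still computed).
#' @export
nearest_plaque_distance <- function(centroid_um, vol) {
  stopifnot(inherits(vol, "plaque_volume"), length(centroid_um) == 3L)
  extent <- dim(vol$mask) * vol$voxel_size_um
  if (any(centroid_um < -10) || any(centroid_um > extent + 10))
    warning("centroid lies > 10 um outside the volume bounds", call. = FALSE)
  idx <- which(vol$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(Inf)
  vx <- (idx[, 1] - 0.5) * vol$voxel_size_um[1]
  vy <- (idx[, 2] - 0.5) * vol$voxel_size_um[2]
  vz <- (idx[, 3] - 0.5) * vol$voxel_size_um[3]
  sqrt(min((vx - centroid_um[1])^2 + (vy - centroid_um[2])^2 +
             (vz - centroid_um[3])^2))
}

#' Nearest-plaque distances for a set of ROI centroids
#'
#' @param centroids_um n x 3 matrix of centroids in micrometres.
#' @param vol a `plaque_volume`.
#' @return numeric vector of distances (micrometres; `Inf` for an empty
#'   mask), one per centroid. Attribute `border_flags` marks centroids whose
#'   nearest positive voxel lies on the volume border (suspect assignments
#'   worth reviewing, e.g. structures cut by the stack).
#' @export
nearest_plaque_distances <- function(centroids_um, vol) {
  stopifnot(inherits(vol, "plaque_volume"))
  centroids_um <- matrix(as.numeric(centroids_um), ncol = 3)
  idx <- which(vol$mask, arr.ind = TRUE)
  n <- nrow(centroids_um)
  if (nrow(idx) == 0L) {
    out <- rep(Inf, n)
    attr(out, "border_flags") <- rep(FALSE, n)
    return(out)
  }
  v <- sweep(idx - 0.5, 2, vol$voxel_size_um, "*")
  dims <- dim(vol$mask)
  on_border <- idx[, 1] %in% c(1L, dims[1]) | idx[, 2] %in% c(1L, dims[2]) |
    idx[, 3] %in% c(1L, dims[3])
  out <- numeric(n)
  flags <- logical(n)
  for (i in seq_len(n)) {
    d2 <- (v[, 1] - centroids_um[i, 1])^2 + (v[, 2] - centroids_um[i, 2])^2 +
      (v[, 3] - centroids_um[i, 3])^2
    k <- which.min(d2)
    out[i] <- sqrt(d2[k])
    flags[i] <- on_border[k]
  }
  attr(out, "border_flags") <- flags
  out
}

#' Close/distant classification by plaque distance
#'
#' @param distance_um distance(s) in micrometres (vectorised); `Inf` (no
#'   plaque in the volume) classifies as distant.
#' @param cutoff_um cutoff in micrometres (default 40); `close` means
#'   `distance <= cutoff`.
#' @return factor with levels `close`, `distant`.
#' @export
classify_proximity <- function(distance_um, cutoff_um = 40) {
  stopifnot(all(distance_um >= 0))
  factor(ifelse(distance_um <= cutoff_um, "close", "distant"),
         levels = c("close", "distant"))
}

#' Activity dynamics stratified by plaque proximity
#'
#' Re-runs the longitudinal statistics within plaque-distance strata: either
#' the close/distant split at `cutoff_um`, or distance bins given by
#' `bin_edges_um`. Only neurons with a finite distance at *all* sessions of
#' the table enter the analysis; stratum membership is taken from the
#' distance at session `s0`.
#'
#' @param table a [longitudinal_table()].
#' @param distance_records data.frame `neuron_id`, `session`, `distance_um`.
#' @param s0,s1 sessions compared.
#' @param cutoff_um close/distant cutoff (default 40), used when
#'   `bin_edges_um` is NULL.
#' @param bin_edges_um optional distance bin edges replacing the two-way
#'   split.
#' @return list of per-stratum results (`n`, `category_fractions` at both
#'   sessions, `reoccurrence` per category, `deltas`) plus `ks_between`,
#'   the KS comparison of the activity-change distributions for every
#'   stratum pair.
#' @export
proximity_stratified_dynamics <- function(table, distance_records, s0, s1,
                                          cutoff_um = 40,
                                          bin_edges_um = NULL) {
  d <- as.data.frame(distance_records)
  stopifnot(all(c("neuron_id", "session", "distance_um") %in% names(d)))
  sessions <- unique(table$session)
  dd <- d[d$session %in% sessions & is.finite(d$distance_um), ]
  cnt <- base::table(dd$neuron_id)
  ok_ids <- names(cnt)[cnt == length(sessions)]
  tab <- table[as.character(table$neuron_id) %in% ok_ids, ]
  d0 <- d[d$session == s0 & d$neuron_id %in% tab$neuron_id, ]
  if (is.null(bin_edges_um)) {
    stratum <- classify_proximity(d0$distance_um, cutoff_um)
  } else {
    stratum <- cut(d0$distance_um, breaks = bin_edges_um,
                   include.lowest = TRUE, right = FALSE)
  }
  names(stratum) <- d0$neuron_id
  res <- list()
  for (lev in levels(stratum)) {
    ids <- d0$neuron_id[stratum == lev]
    if (length(ids) == 0L) next
    sub <- tab[tab$neuron_id %in% ids, ]
    frac <- function(s) {
      cs <- sub$category[sub$session == s]
      prop.table(base::table(factor(cs,
                                    levels = c("rare", "intermediate", "high"))))
    }
    reo <- sapply(c("rare", "intermediate", "high"), function(cat)
      tryCatch(reoccurrence_rate(sub, cat, s0, s1)$pooled,
               error = function(e) NA_real_))
    res[[lev]] <- list(n = length(ids),
                       category_fractions = rbind(s0 = frac(s0), s1 = frac(s1)),
                       reoccurrence = reo,
                       deltas = activity_change(sub, s0, s1)$delta_rate)
  }
  combos <- if (length(res) >= 2) utils::combn(names(res), 2) else NULL
  ks <- list()
  if (!is.null(combos)) for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    ks[[paste(a, b, sep = " vs ")]] <-
      compare_change_distributions(res[[a]]$deltas, res[[b]]$deltas)
  }
  list(strata = res, ks_between = ks,
       stratification = if (is.null(bin_edges_um))
         paste0("cutoff_", cutoff_um, "um") else "bins")
}
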