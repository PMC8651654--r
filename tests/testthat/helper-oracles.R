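# Independent oracles and fixture builders used across the suite.

# phi coefficient of two binary vectors from their 2x2 co-occurrence table
phi_coefficient <- function(x, y) {
  n11 <- as.numeric(sum(x == 1 & y == 1)); n10 <- as.numeric(sum(x == 1 & y == 0))
  n01 <- as.numeric(sum(x == 0 & y == 1)); n00 <- as.numeric(sum(x == 0 & y == 0))
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

# brute-force two-sample KS D by scanning the pooled sample points
ks_D_oracle <- function(a, b) {
  pts <- sort(c(a, b))
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# exact KS p-value by enumeration of all label assignments (small n*m only)
ks_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  d_obs <- ks_D_oracle(a, b)
  combos <- combn(length(pooled), n)
  ds <- apply(combos, 2, function(idx)
    ks_D_oracle(pooled[idx], pooled[-idx]))
  mean(ds >= d_obs - 1e-12)
}

# exact Mann-Whitney p-value by enumeration (no ties assumed, small n*m)
mwu_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_stat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  u_obs <- u_stat(a, b)
  mu <- n * (length(pooled) - n) / 2
  combos <- combn(length(pooled), n)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  # two-sided: as extreme in either direction
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# exhaustive nearest-positive-voxel scan (triple loop; deliberately naive)
brute_plaque_distance <- function(centroid_um, vol) {
  dims <- dim(vol$mask)
  best <- Inf
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (!vol$mask[i, j, k]) next
      d <- sqrt(((i - 0.5) * vol$voxel_size_um[1] - centroid_um[1])^2 +
                  ((j - 0.5) * vol$voxel_size_um[2] - centroid_um[2])^2 +
                  ((k - 0.5) * vol$voxel_size_um[3] - centroid_um[3])^2)
      best <- min(best, d)
    }
  best
}

# hand-built conditioned trace for deterministic detection fixtures:
# detrended is taken as given, f0_offset 0, noise_sd 1, dff = detrended
fixture_cond <- function(detrended, frame_rate_hz = 10) {
  structure(list(dff = detrended, detrended = detrended, f0_offset = 0,
                 f0_raw = 1, noise_sd = 1,
                 quiescent_mask = rep(TRUE, length(detrended)),
                 frame_rate_hz = frame_rate_hz, neuron_id = 1L,
                 session_id = 1L, flags = character(0),
                 params_used = list()),
            class = "conditioned_trace")
}

# a pulse whose 5-frame boxcar smoothing still satisfies height/duration
# rules: rectangular pulse of given height/length on a zero baseline
add_pulse <- function(x, start, len, height) {
  x[start:(start + len - 1)] <- height
  x
}

# minimal longitudinal table from rate vectors (one FOV unless given)
lt_from_rates <- function(..., fov_id = NULL) {
  rates <- list(...)
  n <- length(rates[[1]])
  rows <- do.call(rbind, lapply(seq_along(rates), function(s)
    data.frame(neuron_id = seq_len(n), session = s, rate = rates[[s]],
               fov_id = fov_id %||% rep(1L, n))))
  longitudinal_table(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
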