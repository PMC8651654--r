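mk_stack <- function(dims, value = 0) array(value, dim = dims)

test_that("channel cleanup removes bleed-through but keeps plaque signal", {
  dims <- c(40, 40, 4)
  # flat background in both channels, nothing in gcamp: cleaned ~ 0
  set.seed(33)
  m <- mk_stack(dims, 10) + array(rnorm(prod(dims), 0, 0.1), dims)
  g <- mk_stack(dims, 0)
  cl <- clean_methoxy_channel(m, g)
  expect_lt(max(cl), 1)

  # an object present equally in both channels is removed
  m2 <- mk_stack(dims, 10); g2 <- mk_stack(dims, 5)
  m2[15:20, 15:20, 2] <- 110; g2[15:20, 15:20, 2] <- 105
  cl2 <- clean_methoxy_channel(m2, g2)
  expect_lt(max(cl2[15:20, 15:20, 2]), 5)

  # an object only in the plaque channel survives within 10%
  m3 <- mk_stack(dims, 10); g3 <- mk_stack(dims, 5)
  m3[15:20, 15:20, 2] <- 110
  cl3 <- clean_methoxy_channel(m3, g3)
  expect_gt(median(cl3[16:19, 16:19, 2]), 0.9 * 100)
})

test_that("binarization controls false positives and recovers bright disks", {
  set.seed(34)
  dims <- c(64, 64, 3)
  noise <- array(rnorm(prod(dims), 50, 4), dims)
  vol <- binarize_plaques(noise)
  expect_lt(mean(vol$mask), 0.02)

  # bright disk 10 sigma above background
  stack <- array(rnorm(prod(dims), 50, 4), dims)
  truth <- array(FALSE, dims)
  cx <- 32; cy <- 32; r <- 10
  for (i in 1:64) for (j in 1:64)
    if ((i - cx)^2 + (j - cy)^2 <= r^2) truth[i, j, 2] <- TRUE
  stack[, , 2][truth[, , 2]] <- stack[, , 2][truth[, , 2]] + 40
  vol2 <- binarize_plaques(stack)
  jacc <- sum(vol2$mask & truth) / sum(vol2$mask | truth)
  expect_gte(jacc, 0.9)

  expect_equal(sum(binarize_plaques(mk_stack(dims, 0))$mask), 0)
})

test_that("nearest-plaque distance matches hand geometry", {
  vox <- c(1, 1, 1)
  mask <- array(FALSE, c(50, 20, 10))
  mask[40, 10, 5] <- TRUE
  vol <- structure(list(mask = mask, voxel_size_um = vox,
                        origin_um = c(0, 0, 0)), class = "plaque_volume")
  # centroid on the positive voxel centre
  expect_equal(nearest_plaque_distance(c(39.5, 9.5, 4.5), vol), 0)
  # single positive voxel exactly 30 um away along x
  expect_equal(nearest_plaque_distance(c(9.5, 9.5, 4.5), vol), 30)
  # empty mask: infinite flag
  empty <- structure(list(mask = array(FALSE, c(5, 5, 5)),
                          voxel_size_um = vox, origin_um = c(0, 0, 0)),
                     class = "plaque_volume")
  expect_identical(nearest_plaque_distance(c(1, 1, 1), empty), Inf)
  expect_warning(nearest_plaque_distance(c(500, 0, 0), vol), "outside")
})

test_that("indexed distances agree exactly with the exhaustive scan", {
  set.seed(35)
  for (k in 1:5) {
    vox <- runif(3, 0.4, 2.5)
    mask <- array(runif(16 * 12 * 8) < 0.02, c(16, 12, 8))
    vol <- structure(list(mask = mask, voxel_size_um = vox,
                          origin_um = c(0, 0, 0)), class = "plaque_volume")
    cents <- cbind(runif(3, 0, 16 * vox[1]), runif(3, 0, 12 * vox[2]),
                   runif(3, 0, 8 * vox[3]))
    fast <- nearest_plaque_distances(cents, vol)
    for (i in 1:3)
      expect_equal(fast[i], brute_plaque_distance(cents[i, ], vol))
  }
})

test_that("distance is monotone under mask growth and translation", {
  set.seed(36)
  mask <- array(runif(20^3) < 0.01, c(20, 20, 20))
  vol <- structure(list(mask = mask, voxel_size_um = c(1, 1, 1),
                        origin_um = c(0, 0, 0)), class = "plaque_volume")
  cent <- c(10, 10, 10)
  d1 <- nearest_plaque_distance(cent, vol)
  grown <- vol
  grown$mask[3, 17, 8] <- TRUE
  expect_lte(nearest_plaque_distance(cent, grown), d1)

  # shift mask and centroid by one voxel: distance unchanged
  shifted <- vol
  shifted$mask <- array(FALSE, c(20, 20, 20))
  shifted$mask[2:20, , ] <- vol$mask[1:19, , ]
  expect_equal(nearest_plaque_distance(cent + c(1, 0, 0), shifted), d1)
})

test_that("proximity cutoff is inclusive at the boundary", {
  expect_identical(as.character(classify_proximity(40.0)), "close")
  expect_identical(as.character(classify_proximity(40.1)), "distant")
  expect_identical(as.character(classify_proximity(Inf)), "distant")
  expect_identical(as.character(classify_proximity(12, cutoff_um = 20)),
                   "close")
})

test_that("stratified dynamics: all-distant stratum equals the whole table", {
  lt <- lt_from_rates(c(1, 2, 5, 0.1), c(1.5, 2, 6, 0.1))
  dr <- rbind(
    data.frame(neuron_id = 1:4, session = 1, distance_um = c(80, 90, 70, 95)),
    data.frame(neuron_id = 1:4, session = 2, distance_um = c(82, 85, 75, 90)))
  out <- proximity_stratified_dynamics(lt, dr, 1, 2)
  expect_null(out$strata$close)
  expect_identical(out$strata$distant$n, 4L)
  expect_equal(out$strata$distant$deltas,
               activity_change(lt, 1, 2)$delta_rate)

  # neurons without distances at every session are excluded
  dr2 <- dr[-1, ]
  out2 <- proximity_stratified_dynamics(lt, dr2, 1, 2)
  expect_identical(out2$strata$distant$n, 3L)
})

test_that("stratified dynamics separates close and distant groups", {
  # close neurons keep their high rates, distant ones fall out of category
  lt <- lt_from_rates(c(9, 8, 7, 9, 8, 7), c(9, 8, 7, 2, 2, 2))
  dr <- rbind(
    data.frame(neuron_id = 1:6, session = 1,
               distance_um = c(10, 20, 30, 80, 90, 100)),
    data.frame(neuron_id = 1:6, session = 2,
               distance_um = c(10, 20, 30, 80, 90, 100)))
  out <- proximity_stratified_dynamics(lt, dr, 1, 2)
  expect_equal(out$strata$close$reoccurrence[["high"]], 1.0)
  expect_equal(out$strata$distant$reoccurrence[["high"]], 0.0)
  expect_identical(names(out$ks_between), "close vs distant")
  expect_lt(out$ks_between$`close vs distant`$p_value, 0.2)
})

test_that("plaque volume TIFF round-trips with its voxel sidecar", {
  vol <- simulate_plaque_volume(matrix(c(20, 20, 10), 1), 6,
                                voxel_size_um = c(1.5, 1.5, 2),
                                shape_voxels = c(32, 32, 12))
  path <- file.path(tempdir(), "plaque_test.tif")
  write_plaque_tiff(vol, path)
  back <- read_plaque_tiff(path)
  expect_identical(back$mask, vol$mask)
  expect_equal(back$voxel_size_um, vol$voxel_size_um)
  unlink(c(path, paste0(path, ".json")))
})
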