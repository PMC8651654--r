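noiseless_kin <- function() kinetics_spec(amplitude_sigma = 0, noise_sd = 0,
                                          neuropil_mix = 0, drift_amplitude = 0)

test_that("noiseless construction is baseline plus kernel bumps", {
  pop <- population_spec(1, c(0, 1, 0),
                         rate_ranges_per_min = list(rare = c(0.01, 0.24),
                                                    intermediate = c(0.3, 0.5),
                                                    high = c(4.1, 12)))
  plan <- session_plan(n_sessions = 1, frames_per_session = 3000)
  # seed chosen so the Poisson draw yields exactly 2 well-separated events
  # (> 15 s apart, so the kernel bumps do not overlap measurably)
  sim <- NULL
  for (seed in 1:80) {
    cand <- simulate_cohort(pop, noiseless_kin(), plan, seed = seed)
    ev <- cand$manifest$event_times[[1]][[1]]
    if (length(ev) == 2L && diff(ev) > 15) { sim <- cand; break }
  }
  expect_false(is.null(sim))
  tr <- sim$sessions[[1]]$f_roi[, 1]
  expect_equal(min(tr), 100, tolerance = 1e-8)           # baseline
  expect_equal(max(tr), 100 * 1.5, tolerance = 1e-4)     # 0.5 dF/F bump
  # trace returns to baseline between/after events: mostly flat
  expect_gt(mean(abs(tr - 100) < 1e-6), 0.5)
  expect_identical(length(sim$manifest$event_times[[1]][[1]]), 2L)
})

test_that("manifest rates are exactly event counts per minute", {
  sim <- simulate_cohort(wt_like_population(25), kinetics_spec(),
                         session_plan(n_sessions = 2,
                                      frames_per_session = 1200),
                         seed = 3)
  s <- sim$manifest$summary
  n_ev <- vapply(seq_len(nrow(s)), function(r)
    length(sim$manifest$event_times[[s$session[r]]][[s$neuron_id[r]]]),
    integer(1))
  expect_identical(s$n_events, n_ev)
  expect_equal(s$true_rate, 60 * s$n_events / sim$manifest$duration_s)
  expect_identical(as.character(s$true_category),
                   as.character(classify_activity(s$true_rate)))
})

test_that("rates persist exactly across sessions without drift", {
  plan <- session_plan(n_sessions = 3, frames_per_session = 600,
                       rate_drift_mean = 0, rate_drift_sd = 0)
  sim <- simulate_cohort(wt_like_population(15), kinetics_spec(), plan,
                         seed = 8)
  s <- sim$manifest$summary
  r1 <- s$drawn_rate[s$session == 1]
  for (ss in 2:3) expect_equal(s$drawn_rate[s$session == ss], r1)
})

test_that("identical seeds give bit-identical cohorts", {
  args <- list(wt_like_population(10), kinetics_spec(),
               session_plan(n_sessions = 2, frames_per_session = 500))
  a <- do.call(simulate_cohort, c(args, seed = 123))
  b <- do.call(simulate_cohort, c(args, seed = 123))
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$manifest, b$manifest)
  c2 <- do.call(simulate_cohort, c(args, seed = 124))
  expect_false(identical(a$sessions[[1]]$f_roi, c2$sessions[[1]]$f_roi))
})

test_that("whisking generator hits the 1 s mean epoch duration", {
  set.seed(31)
  wh <- simulate_whisking(15000, 10)
  durs <- wh$epochs$offset_s - wh$epochs$onset_s
  expect_gt(length(durs), 500)
  expect_gt(mean(durs), 0.8)
  expect_lt(mean(durs), 1.2)
})

test_that("event-time draws respect the minimum separation", {
  sim <- simulate_cohort(population_spec(10, c(0, 0, 1)), kinetics_spec(),
                         session_plan(n_sessions = 1,
                                      frames_per_session = 5000),
                         seed = 17)
  for (ev in sim$manifest$event_times[[1]]) {
    if (length(ev) > 1) expect_gte(min(diff(ev)), 3)
  }
})

test_that("mean pairwise synchrony rises monotonically with participation", {
  ps <- c(0.05, 0.2, 0.4, 0.6, 0.8)
  mean_r <- vapply(ps, function(p) {
    plan <- session_plan(n_sessions = 1, frames_per_session = 3000,
                         shared_event_rate_per_min = 4,
                         shared_participation_p = p)
    sim <- simulate_cohort(population_spec(20, c(0, 1, 0)), kinetics_spec(),
                           plan, seed = 99)
    # binary event trains straight from the ground truth (1 s bins)
    raster <- vapply(sim$manifest$event_times[[1]], function(ev) {
      v <- integer(300)
      v[pmin(300, floor(ev / 1) + 1)] <- 1L
      v
    }, integer(300))
    suppressWarnings(pairwise_correlation(raster, min_frames = 50)$mean_r)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
  expect_gte(suppressWarnings(cor(ps, mean_r, method = "spearman")), 0.95)
})

test_that("sphere rendering matches analytic volume and union bounds", {
  vox <- c(0.673, 0.673, 0.5)
  vol <- simulate_plaque_volume(matrix(c(35, 35, 20), 1), 10,
                                voxel_size_um = vox,
                                shape_voxels = c(104, 104, 80))
  analytic <- 4 / 3 * pi * 10^3 / prod(vox)
  expect_lt(abs(sum(vol$mask) / analytic - 1), 0.05)

  expect_equal(sum(simulate_plaque_volume(NULL, numeric(0),
                                          shape_voxels = c(20, 20, 10))$mask),
               0)

  two <- simulate_plaque_volume(rbind(c(30, 35, 20), c(40, 35, 20)),
                                c(10, 10), voxel_size_um = vox,
                                shape_voxels = c(104, 104, 80))
  one_a <- simulate_plaque_volume(matrix(c(30, 35, 20), 1), 10,
                                  voxel_size_um = vox,
                                  shape_voxels = c(104, 104, 80))
  one_b <- simulate_plaque_volume(matrix(c(40, 35, 20), 1), 10,
                                  voxel_size_um = vox,
                                  shape_voxels = c(104, 104, 80))
  expect_lt(sum(two$mask), sum(one_a$mask) + sum(one_b$mask))
  expect_warning(simulate_plaque_volume(matrix(c(500, 500, 500), 1), 5,
                                        shape_voxels = c(20, 20, 10)),
                 "outside")
})

test_that("plaque radii never shrink across sessions", {
  sim <- simulate_cohort(wt_like_population(5), kinetics_spec(),
                         session_plan(n_sessions = 3,
                                      frames_per_session = 300),
                         seed = 2)
  p <- sim$manifest$plaques
  for (id in unique(p$plaque_id)) {
    r <- p$radius_um[p$plaque_id == id][order(p$session[p$plaque_id == id])]
    expect_true(all(diff(r) >= 0))
  }
})

test_that("invalid specifications are rejected with messages", {
  expect_error(population_spec(0, c(0.2, 0.6, 0.2)), "neuron")
  expect_error(population_spec(10, c(0.5, 0.6, 0.2)), "sum")
  expect_error(session_plan(frame_rate_hz = 0), "frame_rate_hz")
})
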