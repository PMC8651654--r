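test_that("binarization thresholds the smoothed trace in noise-sd units", {
  # constructed block: 30 supra-threshold frames on a flat trace
  x <- rep(0, 200)
  x[81:110] <- 5
  b <- binarize_trace(fixture_cond(x), smooth_frames = 1, k_sd = 2)
  expect_identical(which(b == 1L), 81:110)

  # all-zero (sub-threshold) trace stays all zero
  expect_true(all(binarize_trace(fixture_cond(rep(0.5, 100))) == 0L))

  # rescaling the raw trace leaves the binary vector unchanged
  set.seed(6)
  sim <- simulate_cohort(population_spec(1, c(0, 1, 0)), kinetics_spec(),
                         session_plan(n_sessions = 1,
                                      frames_per_session = 2000), seed = 6)
  f <- sim$sessions[[1]]$f_roi[, 1]; np <- sim$sessions[[1]]$f_neuropil[, 1]
  b1 <- binarize_trace(suppressMessages(condition_trace(f, np, 10)))
  b2 <- binarize_trace(suppressMessages(condition_trace(10 * f, 10 * np, 10)))
  expect_identical(b1, b2)

  cond0 <- fixture_cond(rep(0, 100)); cond0$noise_sd <- 0
  expect_error(binarize_trace(cond0), "excluded")
})

test_that("pairwise correlation equals the phi coefficient exactly", {
  set.seed(23)
  for (k in 1:5) {
    raster <- matrix(rbinom(400 * 6, 1, runif(1, 0.1, 0.5)), 400, 6)
    pr <- suppressWarnings(pairwise_correlation(raster))
    for (row in seq_len(nrow(pr$pairs))) {
      i <- pr$pairs$i[row]; j <- pr$pairs$j[row]
      expect_equal(pr$pairs$r[row], phi_coefficient(raster[, i], raster[, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical vectors correlate at 1; constant neurons are excluded", {
  v <- rbinom(300, 1, 0.3)
  raster <- cbind(v, v, 0)
  pr <- suppressWarnings(pairwise_correlation(raster))
  expect_equal(pr$pairs$r[pr$pairs$i == 1 & pr$pairs$j == 2], 1.0)
  expect_identical(pr$n_undefined, 2L)
  expect_equal(pr$mean_r, 1.0)
})

test_that("results are invariant to neuron ordering", {
  set.seed(8)
  raster <- matrix(rbinom(500 * 5, 1, 0.2), 500, 5)
  pr1 <- pairwise_correlation(raster)
  perm <- c(3, 1, 5, 2, 4)
  pr2 <- pairwise_correlation(raster[, perm])
  expect_equal(sort(pr1$pairs$r), sort(pr2$pairs$r), tolerance = 1e-12)
  expect_equal(pr1$mean_r, pr2$mean_r, tolerance = 1e-12)
})

test_that("frame-mask precondition flags under-sampled FOVs", {
  raster <- matrix(rbinom(300 * 3, 1, 0.3), 300, 3)
  mask <- c(rep(TRUE, 50), rep(FALSE, 250))
  expect_warning(pr <- pairwise_correlation(raster, frame_mask = mask),
                 "flagged")
  expect_false(pr$valid)
  expect_true(is.na(pr$mean_r))
})

test_that("circular-shift shuffle control is seeded and centred", {
  set.seed(12)
  raster <- matrix(rbinom(2000 * 10, 1, 0.15), 2000, 10)
  n1 <- shuffle_control(raster, 10, seed = 3)
  n2 <- shuffle_control(raster, 10, seed = 3)
  expect_identical(n1, n2)
  se <- sd(n1) / sqrt(length(n1))
  expect_lt(abs(mean(n1)), 2 * se + 0.01)
})

test_that("shuffle-null mean shrinks toward zero with trace length", {
  set.seed(13)
  spread <- vapply(c(300, 1200, 4800), function(nf) {
    raster <- matrix(rbinom(nf * 8, 1, 0.2), nf, 8)
    mean(abs(shuffle_control(raster, 15, seed = 4)))
  }, numeric(1))
  expect_true(spread[3] < spread[1])
})

test_that("epoch restriction reproduces the unrestricted result when full", {
  set.seed(19)
  raster <- matrix(rbinom(600 * 4, 1, 0.25), 600, 4)
  er <- epoch_restricted_correlation(
    raster, list(all = rep(TRUE, 600), tiny = c(rep(TRUE, 50),
                                                rep(FALSE, 550))))
  full <- pairwise_correlation(raster)
  expect_equal(er$all$pairs$r, full$pairs$r)
  expect_false(er$tiny$valid)
})

test_that("whisk-locked synchrony is visible only in whisk-associated frames", {
  plan <- session_plan(n_sessions = 1, frames_per_session = 5000,
                       shared_event_rate_per_min = 6,
                       shared_participation_p = 0.8,
                       shared_events_in = "whisk")
  sim <- simulate_cohort(population_spec(12, c(0.2, 0.8, 0)),
                         kinetics_spec(), plan, seed = 21)
  s <- sim$sessions[[1]]
  raster <- matrix(0L, 5000, 12)
  for (i in 1:12) {
    cond <- suppressMessages(condition_trace(s$f_roi[, i],
                                             s$f_neuropil[, i], 10))
    raster[, i] <- binarize_trace(cond)
  }
  ep <- detect_whisk_epochs(s$whisk_track, 10)
  wa <- whisk_response_windows(ep)
  st <- stationary_mask(ep, wa)
  whisk_assoc <- !st & !(attr(wa, "discarded"))
  er <- epoch_restricted_correlation(raster,
                                     list(whisk = whisk_assoc,
                                          stationary = st))
  expect_gt(er$whisk$mean_r, er$stationary$mean_r)
})

test_that("correlation vs distance bins and flags", {
  set.seed(25)
  raster <- matrix(rbinom(500 * 6, 1, 0.3), 500, 6)
  cents <- cbind(runif(6, 0, 100), runif(6, 0, 100))
  pr <- pairwise_correlation(raster, centroids = cents)
  # all pairs into one wide bin: bin mean equals overall mean
  cvd <- correlation_vs_distance(pr, c(0, 1000))
  expect_equal(cvd$mean_r, pr$mean_r)
  expect_identical(cvd$n_pairs, nrow(pr$pairs))
  # an unreachable bin stays empty and breaks full coverage
  cvd2 <- correlation_vs_distance(pr, c(0, 150, 2000))
  expect_identical(cvd2$n_pairs[2], 0L)
  expect_true(is.na(cvd2$mean_r[2]))
  expect_false(attr(cvd2, "full_coverage"))
})

test_that("distance-decaying shared input gives decaying correlation", {
  # neurons on a line; shared events joined with probability decaying in
  # position, so nearby pairs co-activate more often
  set.seed(27)
  nf <- 4000; nn <- 16
  pos <- seq(0, 300, length.out = nn)
  shared <- rbinom(nf, 1, 0.05)
  raster <- vapply(seq_len(nn), function(i) {
    p_join <- exp(-pos[i] / 150)
    own <- rbinom(nf, 1, 0.02)
    as.integer((shared & rbinom(nf, 1, p_join)) | own)
  }, integer(nf))
  pr <- pairwise_correlation(raster, centroids = cbind(pos, 0))
  cvd <- correlation_vs_distance(pr, seq(0, 300, by = 75))
  expect_lte(suppressWarnings(
    cor(seq_len(nrow(cvd)), cvd$mean_r, method = "spearman")), -0.9)
})

test_that("category-restricted pairs are counted combinatorially", {
  raster <- matrix(rbinom(400 * 5, 1, 0.3), 400, 5)
  pr <- suppressWarnings(pairwise_correlation(raster))
  cats <- c("high", "high", "high", "intermediate", "intermediate")
  hh <- category_restricted_correlation(pr, cats, "high")
  expect_identical(hh$n_pairs, 3L)
  ii <- category_restricted_correlation(pr, cats, "intermediate")
  expect_identical(ii$n_pairs, 1L)
  # consistency: restricted mean equals mean over manually selected pairs
  manual <- pr$pairs$r[pr$pairs$i <= 3 & pr$pairs$j <= 3]
  expect_equal(mean(hh$r), mean(manual, na.rm = TRUE))
  expect_warning(rr <- category_restricted_correlation(pr, cats, "rare"),
                 "no pair")
  expect_true(rr$empty)
})
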