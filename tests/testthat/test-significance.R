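criteria_wm <- cell_criteria(std_min = 1.5)

test_that("fit_region_voxels selects segment voxels inside the radius", {
  dims <- c(16, 16, 16)
  arr <- add_gaussian_blob(array(0, dims), c(8, 8, 8), c(2, 2, 2), 100)
  raw <- volume(arr)
  v <- apply_threshold(raw, 0.02)
  segs <- extract_segments(watershed_segments(v), v)
  seg <- segs[[1]]

  tiny <- fit_region_voxels(raw, seg, 0.5)
  expect_equal(nrow(tiny$offsets), 1L)
  expect_equal(as.numeric(tiny$offsets[1, ]), c(0, 0, 0))
  expect_equal(tiny$intensity[1], max(arr))

  all_in <- fit_region_voxels(raw, seg, 100)
  expect_equal(nrow(all_in$offsets), seg$size)

  r7 <- fit_region_voxels(raw, seg, 7)
  d <- sweep(seg$voxels, 2, seg$peak)
  expect_equal(nrow(r7$offsets), sum(rowSums(d^2) <= 49))  # brute-force count
})

test_that("log-linear Gaussian fits are exact on noise-free blobs", {
  iso <- gauss_samples(c(2, 2, 2))
  f <- fit_gaussian(iso$offsets, iso$intensity)
  expect_true(f$valid)
  expect_equal(f$principal_stds, c(2, 2, 2), tolerance = 1e-3)
  expect_lt(abs(f$amplitude - 100) / 100, 0.001)

  ani <- gauss_samples(c(1, 2, 3), radius = 9)
  fa <- fit_gaussian(ani$offsets, ani$intensity)
  expect_true(fa$valid)
  expect_equal(fa$principal_stds, c(1, 2, 3), tolerance = 1e-3)
  expect_equal(fa$sigma_matrix, diag(c(1, 4, 9)), tolerance = 1e-6)
})

test_that("principal stds are rotation-invariant", {
  th <- pi / 6
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  S0 <- diag(c(1, 4, 9))
  rot <- gauss_samples(R %*% S0 %*% t(R), radius = 9)
  fr <- fit_gaussian(rot$offsets, rot$intensity)
  expect_true(fr$valid)
  expect_equal(fr$principal_stds, c(1, 2, 3), tolerance = 1e-3)
})

test_that("degenerate regions are flagged invalid, not errors", {
  few <- gauss_samples(c(2, 2, 2), radius = 1)  # 7 voxels
  expect_false(fit_gaussian(few$offsets, few$intensity)$valid)
  # rank-deficient: all offsets on one axis
  off <- cbind(-7:7, 0, 0)
  expect_false(fit_gaussian(off, exp(-(-7:7)^2 / 8))$valid)
  # non-positive-definite curvature: intensity rising away from the peak
  s <- gauss_samples(c(2, 2, 2))
  expect_false(fit_gaussian(s$offsets, 1 / (s$intensity + 1))$valid)
})

test_that("bootstrap p-values are exact fail fractions and reproducible", {
  dims <- c(20, 20, 20)
  arr <- add_gaussian_blob(array(0, dims), c(10, 10, 10), c(2, 2, 2), 100)
  raw <- volume(arr)
  th <- apply_threshold(raw, 0.02)
  seg <- extract_segments(watershed_segments(th), th)[[1]]

  b <- bootstrap_segment(raw, seg, 7, criteria_wm, n_iter = 400, seed = 11)
  expect_equal(b$p_value, 0)  # clean cell: every resample passes

  # p equals the fail count / n_iter, recomputed from the per-resample record
  crit2 <- cell_criteria(std_min = 1.97, std_max = 2.02)
  b2 <- bootstrap_segment(raw, seg, 2.2, crit2, n_iter = 300, seed = 5)
  pass_r <- !is.na(b2$per_resample_stds[, 1]) &
    b2$per_resample_stds[, 1] >= crit2$std_min &
    b2$per_resample_stds[, 3] <= crit2$std_max
  expect_equal(b2$pass, pass_r)
  expect_equal(b2$p_value, mean(!pass_r))
  expect_equal(b2$p_value, b2$n_fail / b2$n_iterations)

  # identical seeds reproduce; different seeds agree within binomial error
  b3 <- bootstrap_segment(raw, seg, 2.2, crit2, n_iter = 300, seed = 5)
  expect_identical(b2$per_resample_stds, b3$per_resample_stds)
  b4 <- bootstrap_segment(raw, seg, 2.2, crit2, n_iter = 300, seed = 99)
  p <- mean(c(b2$p_value, b4$p_value))
  se <- sqrt(max(p * (1 - p), 1e-6) / 300)
  expect_lt(abs(b2$p_value - b4$p_value), 3 * se + 1/300)
})

test_that("a single-voxel spike can never satisfy a wide-cell criterion", {
  dims <- c(12, 12, 12)
  arr <- array(0, dims)
  arr[6, 6, 6] <- 100
  raw <- volume(arr)
  seg <- make_segment(matrix(c(6, 6, 6), 1), peak = c(6L, 6L, 6L), dims = dims)
  b <- bootstrap_segment(raw, seg, 7, criteria_wm, n_iter = 100, seed = 1)
  expect_equal(b$p_value, 1)
})

test_that("widening the std band never increases the p-value", {
  dims <- c(20, 20, 20)
  set.seed(17)
  arr <- add_gaussian_blob(array(0, dims), c(10, 10, 10), c(2, 2, 2), 100) +
    array(abs(rnorm(prod(dims), sd = 8)), dims)
  raw <- volume(arr)
  th <- apply_threshold(bandpass_filter(raw, 0.8, 6), 0.1)
  seg <- extract_segments(watershed_segments(th), th)[[1]]
  narrow <- bootstrap_segment(raw, seg, 7, cell_criteria(1.8, 2.6), n_iter = 200, seed = 3)
  wide <- bootstrap_segment(raw, seg, 7, cell_criteria(1.2, 4.0), n_iter = 200, seed = 3)
  expect_lte(wide$p_value, narrow$p_value)
  # with identical seeds the per-iteration stds are identical, so the pass
  # sets are nested by construction of the criteria
  expect_true(all(narrow$pass <= wide$pass))
})

test_that("full-data fit agrees with the mean of bootstrap fits on clean cells", {
  dims <- c(20, 20, 20)
  arr <- add_gaussian_blob(array(0, dims), c(10, 10, 10), c(1.8, 2.2, 2.6), 100)
  raw <- volume(arr)
  th <- apply_threshold(raw, 0.02)
  seg <- extract_segments(watershed_segments(th), th)[[1]]
  full <- fit_gaussian(fit_region_voxels(raw, seg, 7))
  b <- bootstrap_segment(raw, seg, 7, criteria_wm, n_iter = 500, seed = 2)
  se <- b$sd_stds / sqrt(b$n_valid)
  expect_true(all(abs(full$principal_stds - b$mean_stds) <= 2 * se + 1e-6))
})

test_that("classify_segments emits exactly the sub-threshold-p segments", {
  expect_equal(nrow(classify_segments(rand_vol(c(6, 6, 6), 1), list(),
                                      detection_config())), 0L)

  # one clean cell (passes) and one bright single-voxel spike (fails)
  dims <- c(20, 40, 20)
  arr <- add_gaussian_blob(array(0, dims), c(10, 10, 10), c(2, 2, 2), 100)
  arr[11, 31, 11] <- 300
  raw <- volume(arr)
  cfg <- detection_config(sigma_low = 0.4, sigma_high = 10,
                          threshold_fraction = 0.02, min_segment_voxels = 1,
                          p_threshold = 0.05, rng_seed = 7,
                          bootstrap_iters = 200)
  th <- apply_threshold(bandpass_filter(raw, cfg$sigma_low, cfg$sigma_high),
                        cfg$threshold_fraction)
  segs <- extract_segments(remove_small_segments(watershed_segments(th), 1), th)
  det <- classify_segments(raw, segs, cfg)
  expect_equal(nrow(det), 1L)
  expect_equal(as.numeric(det[1, c("z", "y", "x")]), c(10, 10, 10))
  expect_lt(det$p_value, 0.05)
  expect_false(any(duplicated(det$segment_label)))
})

test_that("planted cells are recovered and noise spikes rejected", {
  set.seed(31)
  dims <- c(24, 72, 72)
  arr <- array(0, dims)
  centers <- as.matrix(expand.grid(z = c(8, 16), y = seq(8, 64, by = 14),
                                   x = seq(8, 64, by = 14)))[1:20, ]
  for (i in 1:20)
    arr <- add_gaussian_blob(arr, centers[i, ], c(2, 2, 2), runif(1, 90, 110))
  spikes <- cbind(sample(3:22, 20, TRUE), sample(66:71, 20, TRUE),
                  sample(3:71, 20, TRUE))
  for (i in 1:20) arr[spikes[i, 1], spikes[i, 2], spikes[i, 3]] <- 150
  cfg <- detection_config(sigma_low = 0.4, sigma_high = 10,
                          threshold_fraction = 0.03, min_segment_voxels = 1,
                          std_min = 1.5, p_threshold = 0.05,
                          bootstrap_iters = 300, rng_seed = 1)
  det <- detect_cells(volume(arr), cfg, quiet = TRUE)
  m <- match_detections(det, centers, tolerance = 2)
  expect_gte(m$tp, 19)
  expect_lte(m$fp, 1)
})
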