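test_that("histogram_of matches a brute-force tally", {
  v <- rand_vol(c(6, 7, 8), seed = 1)
  h <- histogram_of(v, n_bins = 32)
  expect_length(h$counts, 32)
  expect_equal(sum(h$counts), length(v$data))
  expect_equal(h$bin_edges[1], min(v$data))
  expect_equal(h$bin_edges[33], max(v$data))
  # brute-force per-bin tally (right-closed last bin)
  tally <- vapply(seq_len(32), function(b) {
    lo <- h$bin_edges[b]; hi <- h$bin_edges[b + 1]
    if (b < 32) sum(v$data >= lo & v$data < hi) else sum(v$data >= lo & v$data <= hi)
  }, numeric(1))
  expect_equal(h$counts, tally)
  expect_equal(h$cumulative[32], 1)
  expect_true(all(diff(h$cumulative) >= 0))
})

test_that("histogram_of handles degenerate and tiny inputs", {
  h <- histogram_of(volume(array(5, c(2, 2, 2))), n_bins = 10)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$cumulative[length(h$cumulative)], 1)
  h8 <- histogram_of(volume(array(0:7, c(2, 2, 2))), n_bins = 8)
  expect_equal(h8$counts, rep(1, 8))
  expect_error(histogram_of(rand_vol(c(2, 2, 2), 1), n_bins = 0),
               class = "c3d_error_config")
})

test_that("match_histogram reproduces a reference CDF and preserves rank order", {
  # ramp matched to a doubled-range ramp: the map is ~2x scaling
  src <- volume(array(seq(0, 100, length.out = 1000), c(10, 10, 10)))
  ref <- histogram_of(volume(array(seq(0, 200, length.out = 1000), c(10, 10, 10))),
                      n_bins = 256)
  out <- match_histogram(src, ref)
  bin_w <- diff(ref$bin_edges[1:2])
  # sort-and-assign oracle: i-th smallest source value -> i-th smallest ref value
  oracle <- sort(seq(0, 200, length.out = 1000))[rank(src$data, ties.method = "first")]
  expect_lt(max(abs(out$data - oracle)), bin_w + 1e-9)
  expect_lt(max(abs(out$data - 2 * src$data)), bin_w + 1e-9)

  # identity: matching a volume to its own histogram changes nothing (bin width)
  v <- rand_vol(c(8, 8, 8), seed = 2)
  h <- histogram_of(v, n_bins = 512)
  expect_lt(max(abs(match_histogram(v, h)$data - v$data)),
            diff(h$bin_edges[1:2]) + 1e-9)

  # constant volume maps to the reference median
  cst <- match_histogram(volume(array(3, c(4, 4, 4))), h)
  expect_equal(sd(cst$data), 0)
  med <- approx(c(0, h$cumulative), h$bin_edges, xout = 0.5, ties = "ordered")$y
  expect_equal(cst$data[1], med, tolerance = 1e-12)

  # monotonicity: rank order preserved up to ties
  set.seed(3)
  w <- rand_vol(c(6, 6, 6), seed = 3)
  ref2 <- histogram_of(rand_vol(c(6, 6, 6), seed = 4), n_bins = 64)
  o <- match_histogram(w, ref2)
  ord <- order(w$data)
  expect_true(all(diff(o$data[ord]) >= -1e-12))
})

test_that("reference histograms survive the CSV round trip", {
  h <- histogram_of(rand_vol(c(5, 5, 5), seed = 9), n_bins = 64)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_histogram(h, path)
  h2 <- read_reference_histogram(path)
  expect_equal(h2$bin_edges, h$bin_edges)
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$cumulative, h$cumulative)
})

test_that("autofluorescence subtraction removes vessels and keeps cells", {
  # all-zero background channel: output equals the signal
  sig <- rand_vol(c(6, 8, 8), seed = 5)
  zero <- volume(array(0, c(6, 8, 8)))
  expect_equal(subtract_background_channel(sig, zero)$data, sig$data)
  # identical channels: output vanishes (to within one histogram bin, the
  # resolution at which quantile matching reconstructs intensities)
  bin_w <- diff(range(sig$data)) / 1024
  expect_lt(max(subtract_background_channel(sig, sig)$data), bin_w + 1e-9)
  expect_error(subtract_background_channel(sig, volume(array(0, c(6, 8, 9)))),
               class = "c3d_error_shape_mismatch")

  # blob + vessel vs vessel-only channel: vessel suppressed, blob retained
  dims <- c(16, 48, 48)
  vessel <- array(0, dims)
  for (yy in seq(4, 44, by = 1))  # straight tube along y at z=8, x=12
    vessel <- add_gaussian_blob(vessel, c(8, yy, 12), c(2, 2, 2), 32)
  blob <- add_gaussian_blob(array(0, dims), c(8, 24, 34), c(2.5, 2.5, 2.5), 100)
  signal <- volume(blob + vessel)
  out <- subtract_background_channel(signal, volume(vessel))
  vessel_peak_before <- signal$data[9, 25, 13]
  vessel_peak_after <- out$data[9, 25, 13]
  expect_lt(vessel_peak_after, 0.2 * vessel_peak_before)
  expect_lt(abs(out$data[9, 25, 35] - blob[9, 25, 35]) / blob[9, 25, 35], 0.1)
})

test_that("band-pass filter annihilates constants and matches the sampled kernel", {
  cst <- volume(array(50, c(16, 16, 16)))
  out <- bandpass_filter(cst, 1, 4)
  expect_lt(max(abs(out$data)), 1e-6 * 50)

  # impulse response equals the difference-of-Gaussians kernel
  n <- 33
  imp <- array(0, c(n, n, n))
  imp[17, 17, 17] <- 1
  resp <- bandpass_filter(volume(imp), 1.5, 4)$data
  kern <- dog_kernel(n, 1.5, 4)
  expect_lt(max(abs(resp - kern)) / max(abs(kern)), 1e-4)
})

test_that("band-pass attenuation of a long-wavelength cosine follows the transfer ratio", {
  n <- 64
  lambda <- 16
  sl <- 1; sh <- 5
  k <- 2 * pi / lambda
  z <- array(rep(0:(n - 1), times = 8 * 8), c(n, 8, 8))
  vol <- volume(10 + 5 * cos(k * z))
  out <- bandpass_filter(vol, sl, sh)$data
  predicted <- exp(-k^2 * sl^2 / 2) - exp(-k^2 * sh^2 / 2)
  # regression of the filtered field on the input cosine, away from edges
  core <- 17:48
  fit <- lm(as.vector(out[core, , ]) ~ as.vector(cos(k * z[core, , ])))
  expect_lt(abs(coef(fit)[2] / 5 - predicted) / predicted, 0.01)
})

test_that("band-pass filter is linear", {
  a <- rand_vol(c(12, 12, 12), seed = 6)
  b <- rand_vol(c(12, 12, 12), seed = 7)
  fa <- bandpass_filter(a, 1, 3)$data
  fb <- bandpass_filter(b, 1, 3)$data
  fab <- bandpass_filter(volume(2 * a$data + 3 * b$data), 1, 3)$data
  expect_lt(max(abs(fab - 2 * fa - 3 * fb)), 1e-8 * max(abs(fab)))
  expect_error(bandpass_filter(a, 3, 1), class = "c3d_error_config")
})

test_that("apply_threshold zeroes sub-threshold and negative voxels, idempotently", {
  v <- rand_vol(c(6, 6, 6), seed = 8, lo = -50, hi = 200)
  v$data[1, 1, 1] <- 200  # pin the maximum
  out <- apply_threshold(v, 0.05)
  expect_true(all(out$data[v$data < 10 | v$data < 0] == 0))
  expect_true(all(out$data[v$data >= 10] == v$data[v$data >= 10]))
  # fraction 0 keeps a non-negative volume unchanged, but kills negatives
  nn <- rand_vol(c(4, 4, 4), seed = 9)
  expect_equal(apply_threshold(nn, 0)$data, nn$data)
  expect_true(all(apply_threshold(v, 0)$data[v$data < 0] == 0))
  # fraction 1: only the global maximum survives
  m1 <- apply_threshold(v, 1)
  expect_equal(which(m1$data > 0), which(v$data == max(v$data)))
  # idempotence
  expect_equal(apply_threshold(out, 0.05)$data, out$data)
  expect_error(apply_threshold(v, 1.5), class = "c3d_error_config")
})
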