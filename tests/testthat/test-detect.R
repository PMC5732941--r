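test_that("configs validate their invariants and presets match the published sets", {
  expect_error(detection_config(sigma_low = 2, sigma_high = 1),
               class = "c3d_error_config")
  expect_error(detection_config(threshold_fraction = 1.2), class = "c3d_error_config")
  expect_error(detection_config(std_min = 5, std_max = 4), class = "c3d_error_config")
  expect_error(detection_config(min_segment_voxels = 0), class = "c3d_error_config")
  cfg <- detection_config(sigma_low = c(0.4, 0.5, 0.5), sigma_high = 10)
  expect_equal(cfg$sigma_low, c(0.4, 0.5, 0.5))

  wm <- detection_preset("edu_wm")
  expect_equal(wm$threshold_fraction, 0.10)
  expect_equal(wm$min_segment_voxels, 10L)
  expect_equal(wm$p_threshold, 0.01)
  expect_equal(detection_preset("cfp_wm")$threshold_fraction, 0.05)
  sec <- detection_preset("edu_section")
  expect_equal(sec$sigma_low, rep(2, 3))
  expect_equal(sec$sigma_high, rep(6, 3))
  expect_equal(c(sec$std_min, sec$std_max), c(4, 9))
  expect_equal(sec$p_threshold, 0.3)
  expect_equal(detection_preset("brdu_section")$p_threshold, 0.5)
  expect_equal(detection_preset("cfos_section")$threshold_fraction, 0.04)
  expect_identical(unclass(detection_preset("dapi_section")),
                   unclass(detection_preset("edu_section")))
})

test_that("configs round-trip through YAML, including presets with overrides", {
  cfg <- detection_config(sigma_low = 1, sigma_high = 5, threshold_fraction = 0.07,
                          rng_seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_detection_config(cfg, path)
  expect_equal(unclass(read_detection_config(path)), unclass(cfg))
  writeLines(c("preset: edu_section", "p_threshold: 0.2"), path)
  cfg2 <- read_detection_config(path)
  expect_equal(cfg2$sigma_high, rep(6, 3))
  expect_equal(cfg2$p_threshold, 0.2)
  writeLines("no_such_key: 1", path)
  expect_error(read_detection_config(path), class = "c3d_error_config")
})

test_that("detect_cells finds a clean blob exactly once, at its center", {
  arr <- add_gaussian_blob(array(0, c(24, 32, 32)), c(12, 16, 16), c(2, 2, 2), 100)
  det <- detect_cells(volume(arr), detection_preset("edu_wm"), quiet = TRUE)
  expect_equal(nrow(det), 1L)
  expect_true(all(abs(as.numeric(det[1, c("z", "y", "x")]) - c(12, 16, 16)) <= 1))
  expect_equal(det$p_value, 0)
  expect_equal(det$peak_intensity, 100)
})

test_that("detect_cells on an all-zero volume returns no detections", {
  det <- detect_cells(volume(array(0, c(12, 12, 12))), detection_preset("edu_wm"),
                      quiet = TRUE)
  expect_equal(nrow(det), 0L)
})

test_that("detection is deterministic and monotone in the p threshold", {
  spec <- preset_specs("edu_wm", seed = 8, shape = c(24, 64, 64), n_cells = 10,
                       target_snr_db = 19)
  gen <- generate_volume(spec)
  cfg <- detection_preset("edu_wm", rng_seed = 5)
  d1 <- detect_cells(gen$signal, cfg, quiet = TRUE)
  d2 <- detect_cells(gen$signal, cfg, quiet = TRUE)
  expect_identical(d1, d2)
  expect_false(any(duplicated(d1$segment_label)))
  # centroids lie inside the volume bounds
  expect_true(all(d1$z >= 0 & d1$z < 24 & d1$y >= 0 & d1$y < 64 &
                    d1$x >= 0 & d1$x < 64))
  # p1 <= p2 implies the detection set at p1 is a subset of the set at p2
  loose <- detect_cells(gen$signal, detection_preset("edu_wm", rng_seed = 5,
                                                     p_threshold = 0.2),
                        quiet = TRUE)
  expect_true(all(d1$segment_label %in% loose$segment_label))
  strict_rows <- loose[loose$segment_label %in% d1$segment_label, ]
  expect_equal(strict_rows$p_value, d1$p_value)
})

test_that("background subtraction and histogram matching slot into the pipeline", {
  arr <- add_gaussian_blob(array(0, c(20, 40, 40)), c(10, 12, 12), c(2, 2, 2), 100)
  vessel <- array(0, c(20, 40, 40))
  for (yy in 4:36) vessel <- add_gaussian_blob(vessel, c(10, yy, 30), c(2, 2, 2), 40)
  raw <- volume(arr + vessel)
  cfg <- detection_preset("edu_wm", rng_seed = 2)
  with_bg <- detect_cells(raw, cfg, background = volume(vessel), quiet = TRUE)
  m <- match_detections(with_bg, matrix(c(10, 12, 12), 1), 3)
  expect_equal(m$tp, 1L)
  expect_equal(m$fp, 0L)  # the vessel is gone
  expect_error(detect_cells(raw, cfg, background = volume(array(0, c(20, 40, 41)))),
               class = "c3d_error_shape_mismatch")

  # histogram matching against a reference makes a rescaled copy detectable
  # with the same absolute expectations
  ref <- histogram_of(raw)
  rescaled <- volume(raw$data * 37)
  matched_det <- detect_cells(rescaled, cfg, reference_hist = ref, quiet = TRUE)
  plain_det <- detect_cells(raw, cfg, quiet = TRUE)
  expect_equal(matched_det[, c("z", "y", "x")], plain_det[, c("z", "y", "x")])
})

test_that("detections survive the CSV round trip to 6 significant digits", {
  det <- data.frame(z = c(3, 11.0), y = c(4, 5), x = c(9, 2),
                    z_um = c(21, 77), y_um = c(8, 10), x_um = c(18, 4),
                    p_value = c(0.001234567, 0), std1 = c(1.5, 2.123456),
                    std2 = c(2, 3), std3 = c(2.5, 3.3),
                    peak_intensity = c(101.5, 88.25),
                    segment_voxels = c(120L, 95L), segment_label = c(2L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, path)
  back <- read_detections(path)
  expect_equal(back$segment_label, c(1L, 2L))  # written in label order
  ord <- order(det$segment_label)
  for (col in names(det))
    expect_equal(back[[col]], det[[col]][ord], tolerance = 1e-6)

  # empty detections: header only
  write_detections(det[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_detections(path)), 0L)
})

test_that("the CLI drives synth -> detect -> eval end to end", {
  dir <- withr::local_tempdir()
  specfile <- file.path(dir, "spec.yaml")
  yaml::write_yaml(list(shape = c(20, 48, 48), n_cells = 5,
                        cell_sigma_range = c(2, 2.5), min_separation = 12,
                        target_snr_db = Inf, snr_sigma_high = 10), specfile)
  img <- file.path(dir, "img.tif"); tru <- file.path(dir, "truth.csv")
  cli_main(c("synth", "--spec", specfile, "--out-image", img,
             "--out-truth", tru, "--seed", "4"))
  expect_true(file.exists(img) && file.exists(tru))

  cfgfile <- file.path(dir, "cfg.yaml")
  write_detection_config(detection_preset("edu_wm", rng_seed = 1), cfgfile)
  out <- file.path(dir, "det.csv")
  cli_main(c("detect", "--input", img, "--config", cfgfile, "--output", out))
  expect_true(file.exists(out))

  json <- capture.output(cli_main(c("eval", "--detections", out, "--truth", tru,
                                    "--tolerance", "3")))
  rep <- jsonlite::fromJSON(json[1])
  expect_equal(rep$tp + rep$fn, 5)
  expect_gte(rep$f, 0.8)
  expect_error(cli_main(c("frobnicate")), class = "c3d_error_cli")
})
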