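test_that("integer stacks round-trip bit-exactly through multipage TIFF", {
  a <- array(as.numeric(sample.int(4096, 48)), c(3, 4, 4))
  s <- frame_stack(a, frame_interval = 1 / 7.5, subtracted = TRUE,
                   metadata = list(note = "fixture"))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, f)
  back <- read_stack(f)
  expect_identical(back$frames, a)
  expect_identical(back$frame_interval, s$frame_interval)
  expect_identical(back$pixel_size, s$pixel_size)
  expect_true(back$subtracted)
  expect_identical(back$metadata$note, "fixture")
})

test_that("arbitrary stacks round-trip bit-exactly through the array archive", {
  set.seed(5)
  a <- array(rnorm(2 * 6 * 5, sd = 37), c(2, 6, 5))
  s <- frame_stack(a, frame_interval = 0.2, polarity = "negative_contrast")
  f <- withr::local_tempfile(fileext = ".rds")
  write_stack(s, f)
  back <- read_stack(f)
  expect_identical(back$frames, a)
  expect_identical(back$polarity, "negative_contrast")
  expect_false(back$subtracted)
})

test_that("float TIFF stacks round-trip to single precision", {
  set.seed(6)
  a <- array(rnorm(3 * 4 * 4, mean = 50, sd = 20), c(3, 4, 4))
  s <- frame_stack(a, frame_interval = 0.5, subtracted = TRUE)
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, f)
  expect_equal(read_stack(f)$frames, a, tolerance = 1e-6)
})

test_that("stacks without timing metadata or a time axis are refused", {
  a <- array(1, c(3, 4, 4))
  s <- frame_stack(a, frame_interval = 0.1, subtracted = TRUE)
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, f)
  file.remove(paste0(f, ".json"))
  expect_error(read_stack(f), "sidecar")
  # sidecar present but lacking the frame interval
  write_stack(s, f)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  meta$frame_interval <- NULL
  jsonlite::write_json(meta, paste0(f, ".json"), auto_unbox = TRUE)
  expect_error(read_stack(f), "frame_interval")
  expect_error(frame_stack(array(1, c(1, 4, 4)), 0.1), "at least 2 frames")
})

test_that("a temporally constant raw run subtracts to zero everywhere", {
  a <- array(rep(runif(16, 10, 20), each = 5), c(5, 4, 4))
  for (pol in c("negative_contrast", "positive_contrast")) {
    s <- frame_stack(a, 0.1, polarity = pol)
    expect_equal(subtract_mask(s)$frames, array(0, dim(a)))
  }
})

test_that("negative-contrast density drops become positive subtracted excursions", {
  a <- array(100, c(4, 6, 6))
  a[3, 3, 3] <- 100 - 37           # CO2 bolus passes: density falls by 37
  s <- frame_stack(a, 0.1, polarity = "negative_contrast")
  sub <- subtract_mask(s)
  expect_equal(sub$frames[3, 3, 3], 37)
  expect_true(sub$subtracted)
  expect_identical(sub$metadata$mask_rule, "first_frame")
  # the mask frame itself maps to zero
  expect_equal(sub$frames[1, , ], matrix(0, 6, 6))
})

test_that("mask rules agree on a noiseless run over constant background", {
  run <- simulate_run(tiny_config())
  raw <- as_raw_run(run$stack, baseline = 400)
  roi1 <- phantom_default_rois(run$ground_truth)$outflow
  c_first <- extract_curve(subtract_mask(raw, "first_frame"), roi1)
  c_extr <- extract_curve(subtract_mask(raw, "per_pixel_extremum"), roi1)
  c_expl <- extract_curve(subtract_mask(raw, "explicit_index",
                                        mask_index = 1L), roi1)
  expect_equal(c_extr$values, c_first$values)
  expect_equal(c_expl$values, c_first$values)
})

test_that("subtraction guards its contract", {
  s <- frame_stack(array(1, c(3, 4, 4)), 0.1)
  expect_error(subtract_mask(s, "explicit_index", mask_index = 9L),
               "mask_index")
  sub <- subtract_mask(s)
  expect_error(subtract_mask(sub), "already subtracted")
})

test_that("polarity of the raw run does not affect downstream parameters", {
  run <- simulate_run(tiny_config())
  rois <- phantom_default_rois(run$ground_truth)
  p_ref <- compute_params(extract_curve(run$stack, rois$outflow))
  for (pol in c("negative_contrast", "positive_contrast")) {
    raw <- as_raw_run(run$stack, baseline = 250, polarity = pol)
    p <- compute_params(extract_curve(subtract_mask(raw), rois$outflow))
    expect_equal(p$ttp, p_ref$ttp)
    expect_equal(p$pd, p_ref$pd)
    expect_equal(p$auc, p_ref$auc)
  }
})

test_that("a simulated run survives write/read with its ground truth intact", {
  run <- simulate_run(tiny_config(stenosis_attenuation = 0.44,
                                  stenosis_delay = 0.5))
  f <- withr::local_tempfile(fileext = ".rds")
  write_stack(run$stack, f)
  back <- read_stack(f)
  rois <- phantom_default_rois(run$ground_truth)
  analyse <- function(stack) {
    p_in <- compute_params(extract_curve(stack, rois$inflow))
    p_out <- compute_params(extract_curve(stack, rois$outflow))
    compute_ratios(p_in, p_out, "pre")
  }
  expect_identical(analyse(back), analyse(run$stack))
  expect_equal(analyse(back)$pd_ratio, 0.44, tolerance = 0.02)
})
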