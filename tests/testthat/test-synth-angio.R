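test_that("noiseless transit is a pure time shift of the inflow curve", {
  cfg <- tiny_config(stenosis = list(position = 0.5,
                                     residual_lumen_fraction = 1),
                     stenosis_attenuation = 1, stenosis_delay = 0)
  run <- simulate_run(cfg)
  b <- cfg$bolus
  t <- frame_times(run$stack)
  # centerline row is exactly 16, so these pixels sit on the axis (weight 1)
  for (col in c(8, 30, 55, 80)) {
    s <- col - 8                      # arc length from the inflow end
    trace <- run$stack$frames[, 16, col]
    expected <- b$amplitude *
      gamma_variate(t - s / cfg$transit_speed, b$t0, b$alpha, b$beta)
    expect_equal(trace, expected, tolerance = 1e-12)
  }
})

test_that("inflow-pixel trace peaks at the gamma-variate mode t0 + alpha*beta", {
  cfg <- tiny_config()                # t0 = 1, alpha = 3, beta = 1.5
  run <- simulate_run(cfg)
  trace <- run$stack$frames[, 16, 8]  # s = 0 pixel
  t_peak <- frame_times(run$stack)[which.max(trace)]
  expect_lt(abs(t_peak - 5.5), 0.5 / cfg$frame_rate + 1e-12)
})

test_that("same seed gives bit-identical stacks, another seed a different noise field", {
  noisy <- phantom_noise(sigma_gauss = 5, pulsatility_amplitude = 0.1,
                         dropout_prob = 0.1)
  a <- simulate_run(tiny_config(noise = noisy, seed = 42L))
  b <- simulate_run(tiny_config(noise = noisy, seed = 42L))
  c <- simulate_run(tiny_config(noise = noisy, seed = 43L))
  expect_identical(a$stack$frames, b$stack$frames)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("with all noise terms zero the stack is deterministic regardless of seed", {
  a <- simulate_run(tiny_config(seed = 1L))
  b <- simulate_run(tiny_config(seed = 999L))
  expect_identical(a$stack$frames, b$stack$frames)
})

test_that("simulation does not disturb the session RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_run(tiny_config(
    noise = phantom_noise(sigma_gauss = 2), seed = 7L)))
  expect_identical(.Random.seed, before)
})

test_that("frame totals match the analytic line integral of the transit model", {
  cfg <- tiny_config()
  run <- simulate_run(cfg)
  geom <- co2perf:::.vessel_geometry(cfg)
  b <- cfg$bolus
  amp <- ifelse(geom$distal, b$amplitude * cfg$stenosis_attenuation,
                b$amplitude)
  delay <- geom$s / cfg$transit_speed +
    ifelse(geom$distal, cfg$stenosis_delay, 0)
  for (k in c(10, 30, 50)) {
    t_k <- (k - 1) / cfg$frame_rate
    analytic <- sum(amp * geom$weight *
                      gamma_variate(t_k - delay, b$t0, b$alpha, b$beta))
    expect_equal(sum(run$stack$frames[k, , ]), analytic,
                 tolerance = 1e-6)
  }
})

test_that("tighter stenosis never raises distal PD/AUC nor lowers distal TTP", {
  # attenuation and delay follow their residual-lumen defaults here
  residuals <- c(0.9, 0.6, 0.4, 0.25)
  params <- lapply(residuals, function(rlf) {
    run <- simulate_run(tiny_config(
      stenosis = list(position = 0.5, residual_lumen_fraction = rlf)))
    rois <- phantom_default_rois(run$ground_truth)
    compute_params(extract_curve(run$stack, rois$outflow))
  })
  pd <- sapply(params, `[[`, "pd")
  auc <- sapply(params, `[[`, "auc")
  ttp <- sapply(params, `[[`, "ttp")
  expect_true(all(diff(pd) <= 1e-9))
  expect_true(all(diff(auc) <= 1e-9))
  expect_true(all(diff(ttp) >= -1e-9))
})

test_that("ground truth carries the analytic oracle values", {
  cfg <- tiny_config(stenosis_attenuation = 0.44)
  run <- simulate_run(cfg)
  gt <- run$ground_truth
  # TTP at the inflow position: mode of the gamma-variate, within half frame
  p_in <- phantom_expected_params(gt, s = 0)
  expect_lt(abs(p_in$ttp - (1 + 3 * 1.5)), 0.5 / cfg$frame_rate + 1e-12)
  expect_equal(attr(p_in, "ttp_analytic"), 5.5)
  # PD distal/proximal ratio equals the attenuation exactly
  r <- phantom_expected_ratios(gt, s_inflow = 0.25 * gt$total_len,
                               s_outflow = 0.75 * gt$total_len, "pre")
  expect_identical(r$pd_ratio, 0.44)
})

test_that("pre/post pair encodes the treatment set-points in its ground truth", {
  cfg_pre <- tiny_config(stenosis_attenuation = 0.44)
  pair <- simulate_pre_post_pair(cfg_pre, post_attenuation = 0.80)
  gt_pre <- pair$pre$ground_truth
  gt_post <- pair$post$ground_truth
  s_in <- 0.25 * gt_pre$total_len; s_out <- 0.75 * gt_pre$total_len
  expect_identical(
    phantom_expected_ratios(gt_pre, s_in, s_out, "pre")$pd_ratio, 0.44)
  expect_identical(
    phantom_expected_ratios(gt_post, s_in, s_out, "post")$pd_ratio, 0.80)
  # same geometry: ROIs carry over unchanged
  expect_identical(gt_pre$centerline, gt_post$centerline)
})

test_that("zero post-treatment delay makes transit-corrected TTPs equal", {
  pair <- simulate_pre_post_pair(tiny_config(), post_delay = 0)
  gt <- pair$post$ground_truth
  v <- gt$config$transit_speed
  s_in <- 0.25 * gt$total_len; s_out <- 0.75 * gt$total_len
  ttp_in <- attr(phantom_expected_params(gt, s_in), "ttp_analytic")
  ttp_out <- attr(phantom_expected_params(gt, s_out), "ttp_analytic")
  expect_equal(ttp_out - s_out / v, ttp_in - s_in / v, tolerance = 1e-12)
})

test_that("treated vessels and invalid configs are rejected with named fields", {
  expect_error(simulate_pre_post_pair(tiny_config(
    stenosis = list(position = 0.5, residual_lumen_fraction = 0.8))),
    "already")
  expect_error(simulate_pre_post_pair(tiny_config(),
                                      post_residual_lumen_fraction = 0.5),
               "post_residual_lumen_fraction")
  expect_error(phantom_config(stenosis = list(position = 1.5,
                                              residual_lumen_fraction = 0.5)),
               "stenosis\\$position")
  expect_error(phantom_config(
    vessel = list(centerline = matrix(numeric(0), 0, 2), diameter = 8)),
    "centerline")
  expect_error(phantom_config(frame_rate = 7.5, duration = 0.1),
               "frame count")
  expect_error(phantom_config(stenosis = list(position = 0.5,
                                              residual_lumen_fraction = 0)),
               "residual_lumen_fraction")
})
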