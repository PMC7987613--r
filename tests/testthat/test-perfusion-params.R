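test_that("uniform frames give the frame value for any ROI; single pixels give their trace", {
  vk <- c(0, 2, 7, 3, 1)
  a <- array(rep(vk, times = 100), c(5, 10, 10))
  s <- frame_stack(a, 0.2, subtracted = TRUE)
  crv <- extract_curve(s, roi(c(5, 5), 3))
  expect_equal(crv$values, vk)
  set.seed(2)
  a2 <- array(rnorm(5 * 10 * 10), c(5, 10, 10))
  s2 <- frame_stack(a2, 0.2, subtracted = TRUE)
  crv2 <- extract_curve(s2, roi(c(7, 4), 0.5))   # covers only pixel (7, 4)
  expect_equal(crv2$values, a2[, 7, 4])
})

test_that("ROI means equal the brute-force pixel enumeration on random stacks", {
  set.seed(11)
  for (rep in 1:25) {
    a <- array(rnorm(6 * 12 * 14), c(6, 12, 14))
    s <- frame_stack(a, 0.1, subtracted = TRUE)
    r <- roi(center = c(runif(1, 3, 10), runif(1, 3, 12)),
             radius = runif(1, 1, 3.5))
    expect_equal(extract_curve(s, r)$values, bf_roi_mean(s, r))
  }
})

test_that("curve extraction enforces its contract", {
  s <- frame_stack(array(1, c(3, 8, 8)), 0.1, subtracted = TRUE)
  expect_error(extract_curve(s, roi(c(200, 200), 2)), "no pixel")
  raw <- frame_stack(array(1, c(3, 8, 8)), 0.1)
  expect_error(extract_curve(raw, roi(c(4, 4), 2)), "subtracted")
})

test_that("TTP/PD/AUC match hand-computed values and degenerate rules", {
  crv <- time_density_curve(0:3, c(0, 1, 3, 2))
  p <- compute_params(crv)
  expect_equal(p$pd, 3)
  expect_equal(p$ttp, 2)
  expect_equal(p$auc, 5.0)
  p0 <- compute_params(time_density_curve(0:3, rep(0, 4)))
  expect_equal(c(p0$ttp, p0$pd, p0$auc), c(0, 0, 0))
  # first-attainment tie-break
  expect_equal(compute_params(time_density_curve(0:4, c(1, 5, 2, 5, 0)))$ttp, 1)
  expect_error(compute_params(time_density_curve(0:3, c(0, NaN, 1, 0))),
               "non-finite")
})

test_that("sampled gamma-variate recovers the analytic mode and quadrature AUC", {
  A <- 57.3
  t <- (0:89) / 7.5
  g <- function(x) gamma_variate(x, t0 = 1, alpha = 3, beta = 1.5)
  crv <- time_density_curve(t, A * g(t))
  p <- compute_params(crv)
  expect_lt(abs(p$ttp - 5.5), 0.5 / 7.5)
  expect_equal(p$ttp, 41 / 7.5)               # nearest frame to the mode
  expect_equal(p$pd, A * max(g(t)))
  auc_ref <- A * integrate(g, 0, max(t), rel.tol = 1e-10)$value
  expect_lt(abs(p$auc - auc_ref) / auc_ref, 0.01)
})

test_that("trapezoidal AUC agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(3)
  t <- (0:40) * 0.4
  v <- abs(rnorm(41))
  expect_equal(compute_params(time_density_curve(t, v))$auc,
               pracma::trapz(t, v))
})

test_that("optional smoothing is a centered moving average and stays off by default", {
  v <- c(0, 0, 10, 0, 0, 6, 0)
  crv <- time_density_curve(0:6, v)
  expect_equal(compute_params(crv)$pd, 10)
  p3 <- compute_params(crv, smooth_width = 3L)
  expect_equal(p3$pd, 10 / 3, tolerance = 1e-12)
  expect_error(compute_params(crv, smooth_width = 4L), "odd")
})

test_that("parameters scale with density and shift with prepended zero frames", {
  set.seed(4)
  t <- (0:30) * 0.2
  v <- abs(rnorm(31)) + 0.1
  v[1] <- 0                       # contrast-free first frame
  p <- compute_params(time_density_curve(t, v))
  for (c_scale in c(0.5, 3, 117)) {
    ps <- compute_params(time_density_curve(t, c_scale * v))
    expect_equal(ps$pd, c_scale * p$pd)
    expect_equal(ps$auc, c_scale * p$auc)
    expect_equal(ps$ttp, p$ttp)
  }
  for (m in c(1L, 4L)) {
    tm <- (0:(30 + m)) * 0.2
    pm <- compute_params(time_density_curve(tm, c(rep(0, m), v)))
    expect_equal(pm$ttp, p$ttp + m * 0.2)
    expect_equal(pm$pd, p$pd)
    expect_equal(pm$auc, p$auc)
  }
})

test_that("disjoint-ROI curves combine by pixel-count weighting", {
  set.seed(9)
  a <- array(rnorm(4 * 20 * 20), c(4, 20, 20))
  s <- frame_stack(a, 0.1, subtracted = TRUE)
  r1 <- roi(c(5, 5), 2.5); r2 <- roi(c(14, 14), 3.2)
  idx1 <- roi_pixels(r1, c(20, 20)); idx2 <- roi_pixels(r2, c(20, 20))
  expect_length(intersect(idx1, idx2), 0)
  c1 <- extract_curve(s, r1)$values
  c2 <- extract_curve(s, r2)$values
  n1 <- length(idx1); n2 <- length(idx2)
  union_mean <- sapply(1:4, function(k) {
    f <- a[k, , ]; mean(f[c(idx1, idx2)])
  })
  expect_equal((n1 * c1 + n2 * c2) / (n1 + n2), union_mean)
})

test_that("parametric maps equal per-pixel parameters and handle flat input", {
  a <- array(0, c(3, 1, 2))
  a[, 1, 1] <- c(0, 1, 0); a[, 1, 2] <- c(0, 0, 1)
  s <- frame_stack(a, 0.4, subtracted = TRUE)
  m <- parametric_maps(s)
  expect_equal(as.numeric(m$ttp), c(0.4, 0.8))
  expect_equal(as.numeric(m$pd), c(1, 1))
  # all-background stack: zero-valued maps
  s0 <- frame_stack(array(0, c(3, 5, 5)), 0.4, subtracted = TRUE)
  m0 <- parametric_maps(s0)
  expect_true(all(m0$pd == 0) && all(m0$auc == 0) && all(m0$ttp == 0))
  expect_true(all(m0$composite == 0))
})

test_that("map extrema match independently computed per-pixel parameters", {
  run <- simulate_run(tiny_config())
  m <- parametric_maps(run$stack)
  shape <- image_shape(run$stack)
  per_pixel <- sapply(seq_len(prod(shape)), function(p) {
    rr <- (p - 1) %% shape[1] + 1; cc <- (p - 1) %/% shape[1] + 1
    v <- run$stack$frames[, rr, cc]
    c(pd = max(v), auc = co2perf:::.trapz(frame_times(run$stack), v))
  })
  expect_equal(max(m$pd), max(per_pixel["pd", ]))
  expect_equal(min(m$pd), min(per_pixel["pd", ]))
  expect_equal(max(m$auc), max(per_pixel["auc", ]))
})

test_that("noiseless phantom PD along the centerline tracks amplitude x attenuation", {
  cfg <- tiny_config(stenosis_attenuation = 0.44, stenosis_delay = 0.5)
  run <- simulate_run(cfg)
  m <- parametric_maps(run$stack)
  # centerline row 16; columns well proximal/distal of the lesion (col 48)
  pd_prox <- m$pd[16, 20]
  pd_dist <- m$pd[16, 76]
  expect_equal(pd_dist / pd_prox, 0.44, tolerance = 1e-3)
})
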