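# Rasterize the vessel: for every pixel near the centerline find its
# perpendicular distance d and the arc length s of its projection, then keep
# pixels inside the (locally narrowed) lumen with a parabolic transverse
# weight 1 - (d/r)^2 vanishing at the wall.
.vessel_geometry <- function(config) {
  cl <- config$vessel$centerline
  seg <- diff(cl)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stop("vessel$centerline has coincident vertices")
  cum_s <- c(0, cumsum(seg_len))
  total_len <- cum_s[length(cum_s)]

  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  px_r <- rep(seq_len(nr), times = nc)
  px_c <- rep(seq_len(nc), each = nr)

  best_d2 <- rep(Inf, nr * nc)
  best_s <- numeric(nr * nc)
  for (i in seq_len(nrow(seg))) {
    vr <- seg[i, 1]; vc <- seg[i, 2]; L2 <- seg_len[i]^2
    t <- ((px_r - cl[i, 1]) * vr + (px_c - cl[i, 2]) * vc) / L2
    t <- pmin(pmax(t, 0), 1)
    dr <- px_r - (cl[i, 1] + t * vr)
    dc <- px_c - (cl[i, 2] + t * vc)
    d2 <- dr * dr + dc * dc
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cum_s[i] + t[upd] * seg_len[i]
  }

  D <- config$vessel$diameter
  rlf <- config$stenosis$residual_lumen_fraction
  s_sten <- config$stenosis$position * total_len
  # focal narrowing: smooth cos^2 waist with compact support (+/- 2 D), so
  # the lumen is exactly baseline away from the lesion
  w_len <- 2 * D
  x <- (best_s - s_sten) / w_len
  bump <- ifelse(abs(x) < 1, cos(pi * x / 2)^2, 0)
  r_local <- (D / 2) * (1 - (1 - rlf) * bump)

  inside <- which(best_d2 <= r_local^2)
  if (length(inside) == 0L)
    stop("vessel lies outside the image: no lumen pixels")
  d <- sqrt(best_d2[inside])
  s <- best_s[inside]
  w <- 1 - (d / r_local[inside])^2
  distal <- s > s_sten
  list(idx = inside, s = s, weight = w, distal = distal,
       total_len = total_len, s_sten = s_sten,
       cum_s = cum_s, centerline = cl)
}

# point (row, col) on the centerline at arc length s
.centerline_point <- function(geom, s) {
  cum_s <- geom$cum_s; cl <- geom$centerline
  s <- min(max(s, 0), geom$total_len)
  i <- findInterval(s, cum_s, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(cl) - 1L)
  f <- (s - cum_s[i]) / (cum_s[i + 1] - cum_s[i])
  cl[i, ] + f * (cl[i + 1, ] - cl[i, ])
}

# amplitude and transit delay at arc length s (step change at the lesion)
.amp_at <- function(config, s, s_sten) {
  ifelse(s > s_sten, config$bolus$amplitude * config$stenosis_attenuation,
         config$bolus$amplitude)
}
.delay_at <- function(config, s, s_sten) {
  s / config$transit_speed + ifelse(s > s_sten, config$stenosis_delay, 0)
}

#' Simulate one angiographic run of the stenosed-vessel phantom
#'
#' Generates a subtracted DSA frame stack in which a gamma-variate contrast
#' bolus travels along the vessel centerline at `transit_speed`, is
#' attenuated and delayed beyond the stenosis, falls off parabolically to
#' zero at the lumen wall, and is overlaid with pulsatile modulation,
#' frame-dropout events and Gaussian noise per the config's noise model.
#' Background pixels are zero before noise. The returned ground truth
#' carries the noiseless model — analytic inflow curve, centerline traces,
#' and expected perfusion parameters/ratios — for recovery testing.
#'
#' The density at a lumen pixel with arc length `s`, transverse weight `w`
#' and time `t` is `A(s) * w * g(t - delay(s))` where `g` is the unit-peak
#' [gamma_variate()], `delay(s) = s / transit_speed` plus `stenosis_delay`
#' distal to the lesion, and `A(s)` is `bolus$amplitude`, times
#' `stenosis_attenuation` distal to the lesion.
#'
#' @param config a [phantom_config()].
#' @return a list with components `stack` (a subtracted, positive-contrast
#'   [frame_stack()]) and `ground_truth` (a `PhantomGroundTruth`).
#' @examples
#' run <- simulate_run(phantom_config(duration = 4, seed = 7))
#' run$stack
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  geom <- .vessel_geometry(config)
  n_fr <- as.integer(round(config$frame_rate * config$duration))
  dt <- 1 / config$frame_rate
  times <- (seq_len(n_fr) - 1) * dt

  amp <- .amp_at(config, geom$s, geom$s_sten)
  delay <- .delay_at(config, geom$s, geom$s_sten)
  b <- config$bolus

  # vessel density: (n_frames x n_vessel_pixels)
  tt <- outer(times, delay, "-")
  dens <- gamma_variate(tt, b$t0, b$alpha, b$beta)
  dim(dens) <- dim(tt)
  dens <- dens * rep(amp * geom$weight, each = n_fr)

  nz <- config$noise
  if (nz$pulsatility_amplitude > 0)
    dens <- dens * (1 + nz$pulsatility_amplitude *
                      sin(2 * pi * nz$cardiac_freq * times))

  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  fmat <- matrix(0, n_fr, nr * nc)

  stochastic <- nz$dropout_prob > 0 || nz$sigma_gauss > 0
  if (stochastic) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(config$seed)
    if (nz$dropout_prob > 0) {
      dropped <- runif(n_fr) < nz$dropout_prob
      dens[dropped, ] <- dens[dropped, , drop = FALSE] * nz$dropout_factor
    }
  }
  fmat[, geom$idx] <- dens
  if (stochastic && nz$sigma_gauss > 0)
    fmat <- fmat + rnorm(length(fmat), sd = nz$sigma_gauss)
  dim(fmat) <- c(n_fr, nr, nc)

  stack <- frame_stack(fmat, frame_interval = dt,
                       pixel_size = config$pixel_size,
                       polarity = "positive_contrast", subtracted = TRUE,
                       metadata = list(source = "co2perf phantom",
                                       seed = config$seed))
  gt <- .make_ground_truth(config, geom, times)
  list(stack = stack, ground_truth = gt)
}

.make_ground_truth <- function(config, geom, times) {
  b <- config$bolus
  s_grid <- seq(0, geom$total_len, by = 1)
  amp_s <- .amp_at(config, s_grid, geom$s_sten)
  delay_s <- .delay_at(config, s_grid, geom$s_sten)
  traces <- gamma_variate(outer(times, delay_s, "-"), b$t0, b$alpha, b$beta)
  dim(traces) <- c(length(times), length(s_grid))
  traces <- traces * rep(amp_s, each = length(times))
  structure(
    list(config = config, times = times,
         total_len = geom$total_len, s_sten = geom$s_sten,
         cum_s = geom$cum_s, centerline = geom$centerline,
         mode_time = b$t0 + b$alpha * b$beta,
         inflow_curve = b$amplitude * gamma_variate(times, b$t0, b$alpha,
                                                    b$beta),
         s_grid = s_grid, centerline_traces = traces),
    class = "PhantomGroundTruth")
}

#' @export
print.PhantomGroundTruth <- function(x, ...) {
  cat(sprintf(
    "PhantomGroundTruth: vessel %.0f px, lesion at s = %.1f px, bolus mode %.3g s\n",
    x$total_len, x$s_sten, x$mode_time))
  invisible(x)
}

#' Noiseless expected perfusion parameters at a centerline position
#'
#' Evaluates the phantom's analytic transit model at arc length `s` and
#' returns the perfusion parameters a perfect measurement at that point
#' would see: TTP of the noiseless trace sampled at the frame times (the
#' analytic mode is `t0 + alpha * beta + delay(s)`), PD equal to the
#' sampled maximum, and AUC from adaptive quadrature of the analytic curve
#' over the run window.
#'
#' @param gt a `PhantomGroundTruth` from [simulate_run()].
#' @param s arc length along the centerline, pixels.
#' @return a [perfusion_params()] object; attribute `ttp_analytic` holds
#'   the continuous-time mode.
#' @export
phantom_expected_params <- function(gt, s) {
  cfg <- gt$config; b <- cfg$bolus
  amp <- .amp_at(cfg, s, gt$s_sten)
  delay <- .delay_at(cfg, s, gt$s_sten)
  vals <- amp * gamma_variate(gt$times - delay, b$t0, b$alpha, b$beta)
  auc <- amp * stats::integrate(
    function(t) gamma_variate(t - delay, b$t0, b$alpha, b$beta),
    lower = 0, upper = max(gt$times), rel.tol = 1e-9)$value
  p <- perfusion_params(ttp = gt$times[which.max(vals)], pd = max(vals),
                        auc = auc)
  attr(p, "ttp_analytic") <- b$t0 + b$alpha * b$beta + delay
  p
}

#' Noiseless expected outflow/inflow ratios of the phantom
#'
#' Ratios of the analytic model's perfusion parameters between an outflow
#' position (distal to the lesion) and an inflow position (proximal). In
#' the noiseless model the PD ratio is exactly `stenosis_attenuation`.
#'
#' @inheritParams phantom_expected_params
#' @param s_inflow,s_outflow arc lengths (px) of the two measurement
#'   points; must straddle the lesion.
#' @param phase `"pre"` or `"post"`.
#' @return a [ratio_set()]. The TTP ratio uses the analytic modes; the AUC
#'   ratio uses quadrature over the finite run window, so late distal
#'   arrival can truncate it below the attenuation factor.
#' @export
phantom_expected_ratios <- function(gt, s_inflow, s_outflow,
                                    phase = c("pre", "post")) {
  phase <- match.arg(phase)
  if (!(s_inflow < gt$s_sten && s_outflow > gt$s_sten))
    stop("s_inflow must be proximal and s_outflow distal to the lesion")
  cfg <- gt$config; b <- cfg$bolus
  auc_of <- function(s) {
    d <- .delay_at(cfg, s, gt$s_sten)
    .amp_at(cfg, s, gt$s_sten) * stats::integrate(
      function(t) gamma_variate(t - d, b$t0, b$alpha, b$beta),
      lower = 0, upper = max(gt$times), rel.tol = 1e-9)$value
  }
  mode_in <- b$t0 + b$alpha * b$beta + .delay_at(cfg, s_inflow, gt$s_sten)
  mode_out <- b$t0 + b$alpha * b$beta + .delay_at(cfg, s_outflow, gt$s_sten)
  ratio_set(
    ttp_ratio = mode_out / mode_in,
    pd_ratio = .amp_at(cfg, s_outflow, gt$s_sten) /
      .amp_at(cfg, s_inflow, gt$s_sten),
    auc_ratio = auc_of(s_outflow) / auc_of(s_inflow),
    phase = phase)
}

#' Default inflow/outflow ROIs for a phantom run
#'
#' Places the reference (inflow) ROI proximal to the lesion and the target
#' (outflow) ROI distal to it, centered on the vessel centerline, with a
#' radius of 0.4 x lumen diameter so the ROI spans at least 2/3 of the
#' vessel diameter.
#'
#' @inheritParams phantom_expected_params
#' @param s_frac_inflow,s_frac_outflow arc-length fractions of the two ROI
#'   centers (defaults 0.25 and 0.75).
#' @param radius ROI radius in px; default `0.4 * vessel diameter`.
#' @return list with `inflow` and `outflow` [roi()] objects and the arc
#'   lengths `s_inflow`, `s_outflow`.
#' @export
phantom_default_rois <- function(gt, s_frac_inflow = 0.25,
                                 s_frac_outflow = 0.75, radius = NULL) {
  if (is.null(radius)) radius <- 0.4 * gt$config$vessel$diameter
  s_in <- s_frac_inflow * gt$total_len
  s_out <- s_frac_outflow * gt$total_len
  p_in <- .centerline_point(gt, s_in)
  p_out <- .centerline_point(gt, s_out)
  list(inflow = roi(center = p_in, radius = radius, role = "INFLOW",
                    label = "reference ROI proximal to lesion"),
       outflow = roi(center = p_out, radius = radius, role = "OUTFLOW",
                     label = "target ROI distal to lesion"),
       s_inflow = s_in, s_outflow = s_out)
}

#' Simulate a paired pre-/post-revascularization phantom study
#'
#' Produces two runs of the same vessel geometry: the supplied
#' pre-treatment configuration (which must describe a significant
#' stenosis, residual lumen < 0.7) and a post-treatment run with the
#' stenosis parameters relaxed. Geometry and frame timing are identical,
#' so ROIs defined on the pre run can be copied unchanged to the post run;
#' the post run uses a deterministic seed offset so its noise field is
#' independent but reproducible.
#'
#' @param config_pre a [phantom_config()] with
#'   `residual_lumen_fraction < 0.7`.
#' @param post_residual_lumen_fraction residual lumen after treatment
#'   (>= 0.7, the "< 30 % residual stenosis" endpoint; default 0.85).
#' @param post_attenuation,post_delay stenosis attenuation and extra delay
#'   after treatment; `NULL` keeps the residual-lumen defaults of
#'   [phantom_config()].
#' @param seed_offset added to the pre seed for the post run's noise.
#' @return list with `pre`, `post` (each a `simulate_run()` result) —
#'   i.e. `pre$stack`, `pre$ground_truth`, and likewise for `post`.
#' @export
simulate_pre_post_pair <- function(config_pre,
                                   post_residual_lumen_fraction = 0.85,
                                   post_attenuation = NULL,
                                   post_delay = NULL,
                                   seed_offset = 10000L) {
  stopifnot(inherits(config_pre, "PhantomConfig"))
  if (config_pre$stenosis$residual_lumen_fraction >= 0.7)
    stop("config_pre already satisfies the post-treatment endpoint ",
         "(residual_lumen_fraction >= 0.7); nothing to treat")
  if (post_residual_lumen_fraction < 0.7)
    stop("post_residual_lumen_fraction must be >= 0.7 ",
         "(residual stenosis < 30 % of the vessel diameter)")
  config_post <- phantom_config(
    image_shape = config_pre$image_shape,
    pixel_size = config_pre$pixel_size,
    frame_rate = config_pre$frame_rate,
    duration = config_pre$duration,
    vessel = config_pre$vessel,
    stenosis = list(position = config_pre$stenosis$position,
                    residual_lumen_fraction = post_residual_lumen_fraction),
    bolus = config_pre$bolus,
    transit_speed = config_pre$transit_speed,
    stenosis_delay = post_delay,
    stenosis_attenuation = post_attenuation,
    noise = config_pre$noise,
    seed = config_pre$seed + as.integer(seed_offset))
  list(pre = simulate_run(config_pre), post = simulate_run(config_post))
}
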