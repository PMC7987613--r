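#' Unit-peak gamma-variate bolus curve
#'
#' The standard first-pass bolus-tracking model of contrast concentration
#' over time, normalized so its peak value is 1:
#' `g(t) = ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0) / beta)`
#' for `t > t0` and 0 otherwise. The mode (time of peak) is
#' `t0 + alpha * beta`.
#'
#' @param t time(s) in seconds; vectorized.
#' @param t0 bolus arrival delay (s).
#' @param alpha shape parameter (> 0), dimensionless.
#' @param beta scale parameter (s, > 0).
#' @return density values in `[0, 1]`, same length as `t`.
#' @examples
#' gamma_variate(5.5, t0 = 1, alpha = 3, beta = 1.5) # peak: exactly 1
#' @export
gamma_variate <- function(t, t0, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  u <- t - t0
  out <- numeric(length(t))
  pos <- which(u > 0)
  out[pos] <- (u[pos] / (alpha * beta))^alpha * exp(alpha - u[pos] / beta)
  out
}

#' Noise model for the angiographic phantom
#'
#' Describes the disturbances overlaid on the noiseless contrast transit:
#' additive Gaussian detector noise, multiplicative pulsatile density
#' fluctuation synchronized to the cardiac cycle, and whole-frame dropout
#' events modelling the fragmentation of a gaseous CO2 bolus.
#'
#' @param sigma_gauss standard deviation of additive Gaussian noise, in
#'   density units, applied to every pixel of every frame.
#' @param pulsatility_amplitude fractional amplitude of the cardiac
#'   modulation; vessel density is multiplied by
#'   `1 + pulsatility_amplitude * sin(2 * pi * cardiac_freq * t)`.
#' @param cardiac_freq cardiac frequency in Hz (default 1.1 Hz, ~66 bpm).
#' @param dropout_prob per-frame probability that the frame's vessel
#'   density is attenuated by `dropout_factor` (bolus fragmentation).
#' @param dropout_factor multiplicative attenuation in `(0, 1)` applied to
#'   vessel pixels of a dropped frame.
#' @return a list of class `phantom_noise`.
#' @export
phantom_noise <- function(sigma_gauss = 0, pulsatility_amplitude = 0,
                          cardiac_freq = 1.1, dropout_prob = 0,
                          dropout_factor = 0.7) {
  if (sigma_gauss < 0) stop("noise$sigma_gauss must be >= 0")
  if (pulsatility_amplitude < 0) stop("noise$pulsatility_amplitude must be >= 0")
  if (cardiac_freq < 0) stop("noise$cardiac_freq must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("noise$dropout_prob must be in [0, 1]")
  if (dropout_factor <= 0 || dropout_factor >= 1)
    stop("noise$dropout_factor must be in (0, 1)")
  structure(list(sigma_gauss = sigma_gauss,
                 pulsatility_amplitude = pulsatility_amplitude,
                 cardiac_freq = cardiac_freq,
                 dropout_prob = dropout_prob,
                 dropout_factor = dropout_factor),
            class = "phantom_noise")
}

#' Configuration of the synthetic angiography phantom
#'
#' Defines one simulated DSA run: a straight-or-polyline vessel with a
#' focal stenosis, a gamma-variate contrast bolus advected along the
#' vessel at constant speed, and a noise model. Defaults follow a typical
#' pelvic/femoral CO2 acquisition: 7.5 frames/s over 12 s at 125 um pixels.
#'
#' The stenosis has three effects, all relative to the proximal segment:
#' it narrows the lumen geometrically (a Gaussian waist scaled by
#' `residual_lumen_fraction`), it attenuates the distal bolus amplitude by
#' `stenosis_attenuation`, and it delays distal arrival by
#' `stenosis_delay` seconds. When the latter two are not given they
#' default to functions of the residual lumen —
#' `stenosis_attenuation = residual_lumen_fraction` and
#' `stenosis_delay = 3 * (1 - residual_lumen_fraction)` s — so that a
#' tighter stenosis always means lower distal peak density and later
#' distal arrival.
#'
#' @param image_shape integer `(rows, cols)` of each frame.
#' @param pixel_size pixel edge in mm (default 0.125).
#' @param frame_rate frames per second (default 7.5).
#' @param duration run duration in seconds (default 12; typical 10-20).
#'   `frame_rate * duration` must give an integer frame count >= 2.
#' @param vessel list with `centerline` (an n x 2 matrix of `(row, col)`
#'   vertices of the centerline polyline, 1-based pixel units) and
#'   `diameter` (baseline lumen diameter in pixels). Default: a horizontal
#'   vessel across the image at mid-height, diameter 12 px.
#' @param stenosis list with `position` (arc-length fraction in `[0, 1]`
#'   along the centerline) and `residual_lumen_fraction` in `(0, 1]`
#'   (1 = no stenosis; a post-treatment run should have >= 0.7, the
#'   "< 30 % residual stenosis" technical-success endpoint).
#' @param bolus list with `t0` (arrival delay at the inflow end, s),
#'   `alpha`, `beta` (gamma-variate shape/scale) and `amplitude`
#'   (peak density at the inflow end, arbitrary density units).
#' @param transit_speed bolus advection speed along the centerline, px/s.
#' @param stenosis_delay extra transit delay (s) for points distal to the
#'   lesion; `NULL` for the residual-lumen default.
#' @param stenosis_attenuation multiplicative amplitude factor in `(0, 1]`
#'   distal to the lesion; `NULL` for the residual-lumen default.
#' @param noise a [phantom_noise()] object.
#' @param seed integer seed making noise reproducible. With all noise
#'   terms zero the simulation is deterministic regardless of the seed.
#'
#' @return a validated list of class `PhantomConfig`.
#' @seealso [simulate_run()], [simulate_pre_post_pair()]
#' @export
phantom_config <- function(image_shape = c(64L, 192L),
                           pixel_size = 0.125,
                           frame_rate = 7.5,
                           duration = 12,
                           vessel = NULL,
                           stenosis = list(position = 0.5,
                                           residual_lumen_fraction = 0.3),
                           bolus = list(t0 = 1, alpha = 3, beta = 1.5,
                                        amplitude = 100),
                           transit_speed = 40,
                           stenosis_delay = NULL,
                           stenosis_attenuation = NULL,
                           noise = phantom_noise(),
                           seed = 1L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 8L))
    stop("image_shape must be (rows, cols), each >= 8")
  if (is.null(vessel)) {
    margin <- 16
    r0 <- image_shape[1] / 2
    vessel <- list(
      centerline = rbind(c(r0, margin), c(r0, image_shape[2] - margin)),
      diameter = 12)
  }
  cl <- vessel$centerline
  if (is.null(cl) || !is.matrix(cl) || nrow(cl) < 2L || ncol(cl) != 2L)
    stop("vessel$centerline must be a matrix of >= 2 (row, col) vertices; ",
         "an empty or degenerate centerline is not a vessel")
  if (is.null(vessel$diameter) || vessel$diameter <= 0)
    stop("vessel$diameter must be > 0 pixels")
  if (is.null(stenosis$position) || stenosis$position < 0 ||
      stenosis$position > 1)
    stop("stenosis$position must be an arc-length fraction in [0, 1]")
  rlf <- stenosis$residual_lumen_fraction
  if (is.null(rlf) || rlf <= 0 || rlf > 1)
    stop("stenosis$residual_lumen_fraction must be in (0, 1]")
  n_fr <- frame_rate * duration
  if (frame_rate <= 0 || duration <= 0 ||
      abs(n_fr - round(n_fr)) > 1e-9 || round(n_fr) < 2)
    stop("frame_rate x duration must give an integer frame count >= 2 ",
         "(got ", format(n_fr), ")")
  for (f in c("t0", "alpha", "beta", "amplitude"))
    if (is.null(bolus[[f]])) stop("bolus$", f, " is required")
  if (bolus$alpha <= 0 || bolus$beta <= 0)
    stop("bolus$alpha and bolus$beta must be > 0")
  if (transit_speed <= 0) stop("transit_speed must be > 0 px/s")
  if (is.null(stenosis_delay)) stenosis_delay <- 3 * (1 - rlf)
  if (is.null(stenosis_attenuation)) stenosis_attenuation <- rlf
  if (stenosis_delay < 0) stop("stenosis_delay must be >= 0 s")
  if (stenosis_attenuation <= 0 || stenosis_attenuation > 1)
    stop("stenosis_attenuation must be in (0, 1]")
  if (!inherits(noise, "phantom_noise")) noise <- do.call(phantom_noise, noise)
  structure(
    list(image_shape = image_shape, pixel_size = pixel_size,
         frame_rate = frame_rate, duration = duration, vessel = vessel,
         stenosis = list(position = stenosis$position,
                         residual_lumen_fraction = rlf),
         bolus = bolus, transit_speed = transit_speed,
         stenosis_delay = stenosis_delay,
         stenosis_attenuation = stenosis_attenuation,
         noise = noise, seed = as.integer(seed)),
    class = "PhantomConfig")
}

#' @export
print.PhantomConfig <- function(x, ...) {
  cat(sprintf(
    paste0("PhantomConfig: %d x %d px, %.3g fps x %.3g s | stenosis at %.0f%%",
           " arc length, residual lumen %.2f | attenuation %.2f, delay %.2f s",
           " | seed %d\n"),
    x$image_shape[1], x$image_shape[2], x$frame_rate, x$duration,
    100 * x$stenosis$position, x$stenosis$residual_lumen_fraction,
    x$stenosis_attenuation, x$stenosis_delay, x$seed))
  invisible(x)
}
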