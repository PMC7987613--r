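#' Time-density curve of an ROI
#'
#' The mean subtracted contrast density inside a region of interest, one
#' value per frame, on the run's uniform time axis. This is the object the
#' perfusion parameters (TTP, PD, AUC) are computed from.
#'
#' @param times frame times in seconds, strictly increasing, uniformly
#'   spaced, length >= 2.
#' @param values mean density per frame, same length as `times`.
#' @param source identifier of the origin (ROI label or pixel coordinate).
#' @return an object of class `TimeDensityCurve`.
#' @export
time_density_curve <- function(times, values, source = "") {
  if (length(times) != length(values) || length(times) < 2L)
    stop("times and values must have equal length >= 2")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("times must be uniformly spaced")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 source = source),
            class = "TimeDensityCurve")
}

#' @export
print.TimeDensityCurve <- function(x, ...) {
  cat(sprintf("TimeDensityCurve [%s]: %d frames over %.3g s, peak %.4g\n",
              x$source, length(x$times), max(x$times),
              suppressWarnings(max(x$values))))
  invisible(x)
}

#' Extract the ROI's time-density curve from a subtracted stack
#'
#' For every frame, averages the subtracted density over the ROI's pixel
#' set — all pixels whose centers (integer grid) fall inside the circle,
#' i.e. `(row - center_row)^2 + (col - center_col)^2 <= radius^2`.
#'
#' @param stack a subtracted [frame_stack()].
#' @param roi an [roi()].
#' @return a [time_density_curve()].
#' @export
extract_curve <- function(stack, roi) {
  stopifnot(inherits(stack, "FrameStack"), inherits(roi, "ROI"))
  if (!stack$subtracted)
    stop("stack must be subtracted before curve extraction ",
         "(see subtract_mask())")
  idx <- roi_pixels(roi, image_shape(stack))
  if (length(idx) == 0L)
    stop("ROI '", roi$label, "' covers no pixel centers")
  f <- .frames_matrix(stack)[, idx, drop = FALSE]
  time_density_curve(frame_times(stack), rowMeans(f),
                     source = if (nzchar(roi$label)) roi$label else roi$role)
}

#' Perfusion parameters of one time-density curve
#'
#' The triple the 2D-perfusion analysis reports per ROI:
#' * **PD** (peak density) — the maximum mean density over the run.
#' * **TTP** (time to peak) — the time from the start of the run until the
#'   maximum density; ties broken by the first frame attaining it, so an
#'   all-constant curve has TTP 0.
#' * **AUC** — the integral of the curve over the run (trapezoidal rule),
#'   in density x seconds.
#'
#' @param ttp,pd,auc the three parameters (used to construct directly).
#' @return an object of class `PerfusionParams`.
#' @export
perfusion_params <- function(ttp, pd, auc) {
  structure(list(ttp = ttp, pd = pd, auc = auc), class = "PerfusionParams")
}

#' @export
print.PerfusionParams <- function(x, ...) {
  cat(sprintf("PerfusionParams: TTP %.4g s | PD %.4g | AUC %.4g density*s\n",
              x$ttp, x$pd, x$auc))
  invisible(x)
}

#' @rdname perfusion_params
#' @param curve a [time_density_curve()].
#' @param smooth_width optional moving-average width in frames (odd
#'   integer; 0 or 1 disables). Off by default: pulsatile fluctuation is
#'   part of the signal, and smoothing changes the peak reading.
#' @examples
#' crv <- time_density_curve(0:3, c(0, 1, 3, 2))
#' compute_params(crv)  # pd 3, ttp 2 s, auc 5
#' @export
compute_params <- function(curve, smooth_width = 0L) {
  stopifnot(inherits(curve, "TimeDensityCurve"))
  v <- curve$values
  if (any(!is.finite(v)))
    stop("curve contains non-finite values; cannot compute parameters")
  if (smooth_width > 1L) {
    if (smooth_width %% 2L == 0L)
      stop("smooth_width must be odd (centered moving average)")
    k <- rep(1 / smooth_width, smooth_width)
    pad <- (smooth_width - 1L) / 2L
    v <- stats::filter(c(rep(v[1], pad), v, rep(v[length(v)], pad)), k)
    v <- as.numeric(v[(pad + 1):(pad + length(curve$values))])
  }
  i <- which.max(v)    # first index attaining the maximum
  perfusion_params(ttp = curve$times[i], pd = v[i],
                   auc = .trapz(curve$times, v))
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Export a curve as CSV
#'
#' Writes two columns, `time_s` and `density`.
#'
#' @param curve a [time_density_curve()].
#' @param path output CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve$times, density = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}
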