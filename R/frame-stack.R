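#' Angiographic frame stack
#'
#' A time-ordered stack of 2D frames — one DSA run — together with the
#' acquisition metadata the perfusion analysis needs: the frame interval
#' (seconds between frames) and the pixel size (mm). Frame `k` is acquired
#' at `t = (k - 1) * frame_interval`, with `t = 0` at the first frame,
#' which coincides with the start of contrast injection.
#'
#' Contrast polarity distinguishes iodinated agents (radio-opaque: density
#' rises with contrast, `"positive_contrast"`) from gaseous CO2
#' (radiolucent: density falls, `"negative_contrast"`). After mask
#' subtraction ([subtract_mask()]) contrast arrival is always a positive
#' density excursion whatever the raw polarity.
#'
#' Pixel coordinates throughout the package are 1-based `(row, col)` with
#' pixel centers on the integer grid, matching R array indexing.
#'
#' @param frames numeric 3D array with dimensions `(time, rows, cols)`.
#' @param frame_interval seconds between successive frames (> 0).
#' @param pixel_size pixel edge length in mm (default 0.125, i.e. 125 um).
#' @param polarity `"positive_contrast"` or `"negative_contrast"`.
#' @param subtracted logical; `TRUE` if a mask has already been subtracted
#'   so values are contrast densities, `FALSE` for a raw run.
#' @param metadata named list of free-form provenance (seed, mask rule, ...).
#'
#' @return An object of class `FrameStack`.
#' @examples
#' a <- array(0, c(4, 8, 8)); a[2, 4, 4] <- 1
#' s <- frame_stack(a, frame_interval = 1 / 7.5, subtracted = TRUE)
#' n_frames(s)
#' frame_times(s)
#' @export
frame_stack <- function(frames, frame_interval, pixel_size = 0.125,
                        polarity = c("positive_contrast", "negative_contrast"),
                        subtracted = FALSE, metadata = list()) {
  polarity <- match.arg(polarity)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3D array (time, rows, cols)")
  if (dim(frames)[1] < 2L)
    stop("a frame stack needs at least 2 frames (got ", dim(frames)[1], ")")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be a single positive number of seconds")
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size, polarity = polarity,
         subtracted = isTRUE(subtracted), metadata = metadata),
    class = "FrameStack")
}

#' @rdname frame_stack
#' @param x a `FrameStack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "FrameStack"))
  dim(x$frames)[1]
}

#' @rdname frame_stack
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "FrameStack"))
  (seq_len(n_frames(x)) - 1) * x$frame_interval
}

#' @rdname frame_stack
#' @export
image_shape <- function(x) {
  stopifnot(inherits(x, "FrameStack"))
  dim(x$frames)[2:3]
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "FrameStack: %d frames of %d x %d px | %.4g s/frame (%.3g fps) | %s%s\n",
    d[1], d[2], d[3], x$frame_interval, 1 / x$frame_interval,
    x$polarity, if (x$subtracted) " | subtracted" else " | raw"))
  invisible(x)
}

# frames as an (n_frames x n_pixels) matrix, pixels in column-major
# (row, col) order of a rows x cols frame
.frames_matrix <- function(stack) {
  f <- stack$frames
  d <- dim(f)
  dim(f) <- c(d[1], d[2] * d[3])
  f
}
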