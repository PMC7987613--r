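#' Write / read a frame stack with its acquisition metadata
#'
#' Two on-disk representations are supported, both accompanied by a JSON
#' sidecar (`<path>.json`) carrying the metadata without which perfusion
#' analysis is meaningless (frame interval, pixel size, polarity,
#' subtraction state, encoding):
#'
#' * `"tiff"` — a multipage TIFF, one page per frame. Stacks whose values
#'   are all non-negative integers up to 65535 are stored as 16-bit
#'   integers and round-trip exactly; any other stack is affinely scaled
#'   into `[0, 1]` and stored as 32-bit float, i.e. read back at single
#'   precision (the scale and offset live in the sidecar).
#' * `"rds"` — the frame array serialized losslessly (R's portable
#'   compressed serialization); always round-trips bit-exactly.
#'
#' `read_stack()` refuses files without a sidecar or without a frame
#' interval, and refuses single-frame files: a time axis is required.
#'
#' @param stack a [frame_stack()].
#' @param path output file (`.tif`/`.tiff` or `.rds`); the sidecar is
#'   written next to it as `<path>.json`.
#' @param format `"tiff"` or `"rds"`; default guessed from the extension.
#' @return `write_stack()` returns `path` invisibly; `read_stack()`
#'   returns a [frame_stack()].
#' @examples
#' s <- frame_stack(array(as.numeric(0:23), c(3, 2, 4)), 1 / 7.5,
#'                  subtracted = TRUE)
#' f <- tempfile(fileext = ".tif")
#' write_stack(s, f)
#' identical(read_stack(f)$frames, s$frames)
#' @export
write_stack <- function(stack, path, format = NULL) {
  stopifnot(inherits(stack, "FrameStack"))
  format <- .io_format(path, format)
  meta <- list(format_version = 1L,
               n_frames = n_frames(stack),
               image_shape = image_shape(stack),
               frame_interval = stack$frame_interval,
               pixel_size = stack$pixel_size,
               polarity = stack$polarity,
               subtracted = stack$subtracted,
               metadata = stack$metadata)
  if (format == "rds") {
    meta$encoding <- "rds"
    saveRDS(stack$frames, path)
  } else {
    f <- stack$frames
    pages <- lapply(seq_len(dim(f)[1]), function(k) f[k, , ])
    int_like <- all(is.finite(f)) && all(f >= 0) && all(f <= 65535) &&
      all(f == round(f))
    if (int_like) {
      meta$encoding <- "uint16"
      tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                      bits.per.sample = 16L)
    } else {
      if (any(!is.finite(f))) stop("cannot write non-finite values to TIFF")
      off <- min(f); sc <- max(f) - off
      if (sc == 0) sc <- 1
      meta$encoding <- "float32_scaled"
      meta$scale <- sc
      meta$offset <- off
      suppressWarnings(
        tiff::writeTIFF(lapply(pages, function(m) (m - off) / sc), path,
                        bits.per.sample = 32L))
    }
  }
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, format = NULL) {
  format <- .io_format(path, format)
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing sidecar '", basename(sidecar),
         "': frame_interval and pixel_size metadata are required")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$frame_interval))
    stop("sidecar lacks frame_interval; time-to-peak would be meaningless")
  if (!is.null(meta$n_frames) && meta$n_frames < 2L)
    stop("single-frame file: a DSA run needs at least 2 frames")
  if (format == "rds") {
    frames <- readRDS(path)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) < 2L)
      stop("single-frame file: a DSA run needs at least 2 frames")
    nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
    frames <- array(0, c(length(pages), nr, nc))
    for (k in seq_along(pages)) frames[k, , ] <- pages[[k]]
    enc <- if (is.null(meta$encoding)) "uint16" else meta$encoding
    frames <- switch(enc,
      uint16 = round(frames * 65535),
      float32_scaled = frames * meta$scale + meta$offset,
      stop("unknown TIFF encoding '", enc, "' in sidecar"))
  }
  frame_stack(frames,
              frame_interval = meta$frame_interval,
              pixel_size = if (is.null(meta$pixel_size)) NA_real_ else
                meta$pixel_size,
              polarity = if (is.null(meta$polarity)) "positive_contrast" else
                meta$polarity,
              subtracted = isTRUE(meta$subtracted),
              metadata = if (is.null(meta$metadata)) list() else
                as.list(meta$metadata))
}

.io_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("tiff", "rds")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext == "rds") "rds"
  else stop("cannot guess format from extension '.", ext,
            "'; pass format = \"tiff\" or \"rds\"")
}

.sidecar_path <- function(path) paste0(path, ".json")
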