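#' Circular region of interest
#'
#' ROIs are circles in pixel coordinates — 1-based `(row, col)` with pixel
#' centers on the integer grid. Each ROI carries a role: the reference ROI
#' proximal to the vascular lesion measures arterial **inflow**, the
#' target ROI distal to it measures **outflow**; the analysis endpoints
#' are the outflow/inflow parameter ratios.
#'
#' @param center numeric `(row, col)` of the circle center, pixels
#'   (fractional allowed).
#' @param radius circle radius in pixels (> 0).
#' @param role `"INFLOW"` or `"OUTFLOW"`.
#' @param label free-text identifier.
#' @return an object of class `ROI`.
#' @export
roi <- function(center, radius, role = c("INFLOW", "OUTFLOW"), label = "") {
  role <- match.arg(role)
  if (length(center) != 2L || !is.numeric(center))
    stop("center must be (row, col)")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0 pixels")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 role = role, label = label),
            class = "ROI")
}

#' @export
print.ROI <- function(x, ...) {
  cat(sprintf("ROI %s%s: center (%.1f, %.1f), radius %.1f px\n", x$role,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Linear pixel indices covered by an ROI
#'
#' All pixels of a `rows x cols` frame whose integer-grid centers lie
#' inside the circle (boundary included), as linear indices in
#' column-major order.
#'
#' @param roi an [roi()].
#' @param shape integer `(rows, cols)`.
#' @return integer vector of linear pixel indices.
#' @export
roi_pixels <- function(roi, shape) {
  r1 <- max(1L, floor(roi$center[1] - roi$radius))
  r2 <- min(shape[1], ceiling(roi$center[1] + roi$radius))
  c1 <- max(1L, floor(roi$center[2] - roi$radius))
  c2 <- min(shape[2], ceiling(roi$center[2] + roi$radius))
  if (r1 > r2 || c1 > c2) return(integer(0))
  rr <- rep(r1:r2, times = c2 - c1 + 1)
  cc <- rep(c1:c2, each = r2 - r1 + 1)
  keep <- (rr - roi$center[1])^2 + (cc - roi$center[2])^2 <= roi$radius^2
  (cc[keep] - 1L) * shape[1] + rr[keep]
}

#' Validate an ROI against the sizing and placement rules
#'
#' An ROI passes iff (a) it spans at least two thirds of the vessel
#' diameter (`2 * radius >= (2/3) * vessel_diameter`) and (b) the circle
#' lies fully inside the image (when a shape is supplied). Validation
#' reports, it never throws.
#'
#' @param roi an [roi()].
#' @param vessel_diameter local vessel diameter in pixels (> 0).
#' @param shape optional image `(rows, cols)` for the bounds check.
#' @return list with `pass` (logical) and `failures` (character vector
#'   naming each violated rule; empty when passing).
#' @examples
#' validate_roi(roi(c(10, 10), 4), vessel_diameter = 12)$pass   # TRUE: 8 >= 8
#' validate_roi(roi(c(10, 10), 3), vessel_diameter = 12)$failures
#' @export
validate_roi <- function(roi, vessel_diameter, shape = NULL) {
  stopifnot(inherits(roi, "ROI"), vessel_diameter > 0)
  failures <- character(0)
  if (2 * roi$radius < (2 / 3) * vessel_diameter)
    failures <- c(failures, sprintf(
      "2/3-diameter rule: ROI diameter %.3g px < 2/3 of vessel diameter %.3g px",
      2 * roi$radius, vessel_diameter))
  if (!is.null(shape)) {
    if (roi$center[1] - roi$radius < 0.5 ||
        roi$center[1] + roi$radius > shape[1] + 0.5 ||
        roi$center[2] - roi$radius < 0.5 ||
        roi$center[2] + roi$radius > shape[2] + 0.5)
      failures <- c(failures, "bounds rule: circle extends outside the image")
  }
  list(pass = length(failures) == 0L, failures = failures)
}

#' Copy ROIs from the pre-interventional run to the post run
#'
#' Reproduces the pre-interventional ROIs on the corresponding
#' post-revascularization run so shape and position stay comparable. The
#' copy is a rigid translation: radii and roles are untouched, centers are
#' shifted by `offset` (default none), covering table or detector shift
#' between runs.
#'
#' @param rois a list of [roi()] objects defined on the pre run.
#' @param offset numeric `(drow, dcol)` in pixels; default `c(0, 0)`.
#' @param shape optional post-run image `(rows, cols)`; when given, an ROI
#'   pushed outside the image is an error naming that ROI.
#' @return list of translated ROIs.
#' @export
copy_roi_pair <- function(rois, offset = c(0, 0), shape = NULL) {
  if (inherits(rois, "ROI")) rois <- list(rois)
  stopifnot(length(offset) == 2L)
  lapply(rois, function(r) {
    stopifnot(inherits(r, "ROI"))
    out <- roi(center = r$center + offset, radius = r$radius,
               role = r$role, label = r$label)
    if (!is.null(shape)) {
      v <- validate_roi(out, vessel_diameter = 1e-9, shape = shape)
      if (any(grepl("bounds", v$failures)))
        stop("copied ROI '", if (nzchar(r$label)) r$label else r$role,
             "' falls outside the post image")
    }
    out
  })
}

#' Outflow/inflow ratios of the perfusion parameters
#'
#' The three analysis endpoints of a run: `TTP_outflow / TTP_inflow`,
#' `PD_outflow / PD_inflow` and `AUC_outflow / AUC_inflow`, computed by
#' element-wise division. A zero inflow parameter flags a failed injection
#' or misplaced reference ROI and is an error rather than an infinite
#' ratio.
#'
#' @param params_inflow,params_outflow [perfusion_params()] of the
#'   reference (proximal) and target (distal) ROI.
#' @param phase `"pre"` or `"post"` (intervention).
#' @return a `RatioSet`.
#' @export
compute_ratios <- function(params_inflow, params_outflow,
                           phase = c("pre", "post")) {
  phase <- match.arg(phase)
  stopifnot(inherits(params_inflow, "PerfusionParams"),
            inherits(params_outflow, "PerfusionParams"))
  for (f in c("ttp", "pd", "auc"))
    if (!is.finite(params_inflow[[f]]) || params_inflow[[f]] <= 0)
      stop("inflow ", toupper(f), " is not positive; reference ROI ",
           "saw no contrast (failed injection or misplaced ROI)")
  ratio_set(ttp_ratio = params_outflow$ttp / params_inflow$ttp,
            pd_ratio = params_outflow$pd / params_inflow$pd,
            auc_ratio = params_outflow$auc / params_inflow$auc,
            phase = phase)
}

#' @rdname compute_ratios
#' @param ttp_ratio,pd_ratio,auc_ratio the three ratios (direct
#'   construction).
#' @export
ratio_set <- function(ttp_ratio, pd_ratio, auc_ratio,
                      phase = c("pre", "post")) {
  phase <- match.arg(phase)
  structure(list(ttp_ratio = ttp_ratio, pd_ratio = pd_ratio,
                 auc_ratio = auc_ratio, phase = phase),
            class = "RatioSet")
}

#' @export
print.RatioSet <- function(x, ...) {
  cat(sprintf(
    "RatioSet (%s): TTP out/in %.3g | PD out/in %.3g | AUC out/in %.3g\n",
    x$phase, x$ttp_ratio, x$pd_ratio, x$auc_ratio))
  invisible(x)
}

#' Read / write ROI definitions
#'
#' ROI files are YAML or JSON (chosen by extension): a list of records
#' with `center` (row, col; 1-based pixel coordinates), `radius`, `role`
#' and optional `label`.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return `read_rois()` returns a list of [roi()] objects.
#' @export
read_rois <- function(path) {
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
  else stop("ROI file must be .yaml/.yml or .json")
  if (!is.list(recs) || length(recs) == 0L)
    stop("ROI file '", basename(path), "' contains no ROI records")
  lapply(recs, function(r) {
    if (is.null(r$center) || is.null(r$radius) || is.null(r$role))
      stop("malformed ROI record in '", basename(path),
           "': center, radius and role are required")
    roi(center = unlist(r$center), radius = r$radius, role = r$role,
        label = if (is.null(r$label)) "" else r$label)
  })
}

#' @rdname read_rois
#' @param rois list of [roi()] objects.
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "ROI")) rois <- list(rois)
  recs <- lapply(rois, function(r)
    list(center = r$center, radius = r$radius, role = r$role,
         label = r$label, coordinates = "1-based (row, col), pixel units"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(recs, path)
  else if (ext == "json")
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else stop("ROI file must be .yaml/.yml or .json")
  invisible(path)
}
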