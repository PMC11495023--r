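#' Construct a gated phase-image series
#'
#' A `phase_series` holds the raw (unscaled) stored pixel values of a
#' cardiac-gated PC-MRI acquisition, one 2-D frame per cardiac phase, plus the
#' acquisition metadata. No velocity scaling is applied at this stage; all
#' scaling is done by [to_velocity()] so that raw data remain auditable.
#'
#' @param frames 3-D numeric array indexed `(frame, row, col)`.
#' @param meta An [acquisition_meta] object; `meta$n_frames` must equal
#'   `dim(frames)[1]`.
#' @param wrapped_input Logical; set `TRUE` when the file already contains
#'   wrapped (aliased) values so that the `|value| <= raw_scale` bound is
#'   expected rather than diagnostic.
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(frames, meta, wrapped_input = FALSE) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("expected 3-D gated series (frame, row, col); got ",
         length(dim(frames)), "-D data")
  if (dim(frames)[1] != meta$n_frames)
    stop("frame count mismatch: file has ", dim(frames)[1],
         " frames but metadata declares ", meta$n_frames)
  if (!all(is.finite(frames)))
    stop("phase series contains non-finite values")
  structure(list(frames = frames, meta = meta,
                 wrapped_input = isTRUE(wrapped_input)),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("phase_series: %d frames of %d x %d pixels (%s)\n",
              d[1], d[2], d[3], x$meta$site))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param pixels Two-column integer matrix of 1-based `(row, col)` pixel
#'   coordinates, row 1 at the image top.
#' @param shape Image dimensions `c(rows, cols)` the mask belongs to.
#' @param kind `"target"` (lumen: aqueduct or CCJ CSF space) or
#'   `"reference"` (adjacent static tissue used for noise and bias).
#' @param label Optional free-text label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(pixels, shape, kind = c("target", "reference"),
                     label = "") {
  kind <- match.arg(kind)
  pixels <- matrix(as.integer(pixels), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(pixels) == 0L) stop("empty ROI: mask has no pixels")
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape > 0L))
  if (any(pixels[, 1] < 1L | pixels[, 1] > shape[1] |
          pixels[, 2] < 1L | pixels[, 2] > shape[2]))
    stop("ROI pixel coordinates fall outside the ", shape[1], " x ",
         shape[2], " image")
  if (anyDuplicated(pixels)) pixels <- unique(pixels)
  # deterministic ordering: row-major
  pixels <- pixels[order(pixels[, 1], pixels[, 2]), , drop = FALSE]
  structure(list(pixels = pixels, shape = shape, kind = kind,
                 label = as.character(label)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask (%s): %d pixels in a %d x %d image%s\n",
              x$kind, nrow(x$pixels), x$shape[1], x$shape[2],
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Number of pixels in an ROI
#' @param mask An [roi_mask].
#' @return Integer pixel count.
#' @export
n_pixels <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  nrow(mask$pixels)
}

# NIfTI stores (x, y, z); the package convention is (frame, row, col).
# aperm on read/write keeps the round trip exact and the axes explicit.
.series_to_nifti_array <- function(frames) aperm(frames, c(2, 3, 1))
.nifti_array_to_series <- function(arr) aperm(arr, c(3, 1, 2))

#' Read a gated phase-image series from a NIfTI file
#'
#' The file must contain a 3-D volume whose third dimension indexes cardiac
#' phase (the layout written by [write_phase_series()]). Values are returned
#' raw, exactly as stored; use [to_velocity()] to convert to cm/s.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param meta An [acquisition_meta]; its `n_frames` must match the file.
#' @inheritParams phase_series
#' @return A [phase_series].
#' @export
read_phase_series <- function(path, meta, wrapped_input = FALSE) {
  if (!file.exists(path)) stop("phase-series file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected 3-D gated series in ", path, "; file is ",
         length(dim(arr)), "-D")
  phase_series(.nifti_array_to_series(arr), meta,
               wrapped_input = wrapped_input)
}

#' Write a gated phase-image series to a NIfTI file
#'
#' @param series A [phase_series].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_phase_series <- function(series, path) {
  stopifnot(inherits(series, "phase_series"))
  RNifti::writeNifti(RNifti::asNifti(.series_to_nifti_array(series$frames),
                                     datatype = "double"),
                     path, datatype = "double")
  invisible(path)
}

#' Read an ROI mask from a NIfTI file
#'
#' Nonzero voxels become mask pixels. An all-zero mask or a shape mismatch
#' with the phase frames is an error.
#'
#' @param path Path to a 2-D `.nii`/`.nii.gz` mask.
#' @param shape Expected image dimensions `c(rows, cols)`.
#' @inheritParams roi_mask
#' @return An [roi_mask].
#' @export
read_roi_mask <- function(path, shape, kind = c("target", "reference"),
                          label = "") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("mask file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  arr <- drop(arr)
  if (length(dim(arr)) != 2L)
    stop("expected a 2-D mask in ", path)
  if (!identical(as.integer(dim(arr)), as.integer(shape)))
    stop("mask shape ", dim(arr)[1], " x ", dim(arr)[2],
         " does not match frame shape ", shape[1], " x ", shape[2])
  idx <- which(arr != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty ROI: mask in ", path, " is all zero")
  roi_mask(idx, shape = shape, kind = kind, label = label)
}

#' Write an ROI mask to a NIfTI file
#'
#' @param mask An [roi_mask].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  arr <- matrix(0L, mask$shape[1], mask$shape[2])
  arr[mask$pixels] <- 1L
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path,
                     datatype = "uint8")
  invisible(path)
}

.metrics_columns <- c("id", "site", "n_pixels", "stroke_volume_mL",
                      "antegrade_volume_mL", "retrograde_volume_mL",
                      "net_mL_per_cycle", "net_mL_per_min", "net_L_per_day",
                      "direction")

#' Convert per-subject flow metrics to a data frame
#'
#' @param records Named or unnamed list of [flow_metrics] objects; names (or
#'   each record's `id` field) become subject identifiers.
#' @return A data frame with one row per subject and the metric columns used
#'   by [write_metrics_table()].
#' @export
metrics_to_table <- function(records) {
  if (inherits(records, "flow_metrics")) records <- list(records)
  stopifnot(length(records) > 0L,
            all(vapply(records, inherits, logical(1), "flow_metrics")))
  ids <- names(records)
  if (is.null(ids)) ids <- rep(NA_character_, length(records))
  rows <- lapply(seq_along(records), function(i) {
    m <- records[[i]]
    id <- if (!is.na(ids[i]) && nzchar(ids[i])) ids[i]
          else if (!is.null(m$id)) m$id else as.character(i)
    data.frame(id = id, site = m$site, n_pixels = m$n_pixels,
               stroke_volume_mL = m$stroke_volume,
               antegrade_volume_mL = m$antegrade_volume,
               retrograde_volume_mL = m$retrograde_volume,
               net_mL_per_cycle = m$net_per_cycle,
               net_mL_per_min = m$net_per_min,
               net_L_per_day = m$net_per_day,
               direction = m$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# "%.17g" is the shortest decimal form guaranteed to round-trip an IEEE
# double, so the full-precision columns survive CSV exactly.
.fmt_full <- function(x) sprintf("%.17g", x)

#' Write a per-subject metrics table to CSV
#'
#' Columns are written in a fixed order: identifiers, pixel count, the
#' full-precision metric columns, the direction label, and rounded display
#' copies (`display_net_mL_per_cycle` to 3 decimals, `display_net_mL_per_min`
#' to 2). Full-precision columns round-trip bit-for-bit through
#' [read_metrics_table()].
#'
#' @param records A list of [flow_metrics] or a data frame from
#'   [metrics_to_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  tab <- if (is.data.frame(records)) records else metrics_to_table(records)
  if (nrow(tab) == 0L) stop("no records to write")
  missing <- setdiff(.metrics_columns, names(tab))
  if (length(missing))
    stop("metrics table missing column(s): ", paste(missing, collapse = ", "))
  out <- tab[, .metrics_columns, drop = FALSE]
  num <- setdiff(.metrics_columns, c("id", "site", "direction", "n_pixels"))
  for (cn in num) out[[cn]] <- .fmt_full(tab[[cn]])
  out$display_net_mL_per_cycle <- sprintf("%.3f", tab$net_mL_per_cycle)
  out$display_net_mL_per_min <- sprintf("%.2f", tab$net_mL_per_min)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a per-subject metrics table written by [write_metrics_table()]
#'
#' @param path CSV path.
#' @return A data frame with numeric full-precision metric columns.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("metrics table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  num <- c("n_pixels", "stroke_volume_mL", "antegrade_volume_mL",
           "retrograde_volume_mL", "net_mL_per_cycle", "net_mL_per_min",
           "net_L_per_day")
  for (cn in intersect(num, names(tab))) tab[[cn]] <- as.numeric(tab[[cn]])
  tab$n_pixels <- as.integer(tab$n_pixels)
  tab
}
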