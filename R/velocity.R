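#' Per-pixel velocity time series for one ROI
#'
#' Internal constructor; users normally obtain a `velocity_field` from
#' [to_velocity()]. Velocities are stored as an `n_frames x n_pixels` matrix
#' (cm/s), one column per mask pixel in the mask's row-major order, together
#' with frame times and the ordered list of corrections applied so far.
#'
#' @param velocities Numeric matrix, `n_frames` rows, one column per pixel.
#' @param mask The [roi_mask] the columns refer to.
#' @param meta The [acquisition_meta] of the acquisition.
#' @param corrections Character vector drawn from
#'   `c("venc_scaling", "bias_subtraction", "aliasing_correction")`.
#' @return An object of class `velocity_field`.
#' @keywords internal
velocity_field <- function(velocities, mask, meta,
                           corrections = character()) {
  stopifnot(inherits(mask, "roi_mask"), inherits(meta, "acquisition_meta"),
            is.matrix(velocities),
            nrow(velocities) == meta$n_frames,
            ncol(velocities) == n_pixels(mask))
  if (!all(is.finite(velocities)))
    stop("velocity field contains non-finite values; NaN pixels are not ",
         "interpolated")
  structure(list(velocities = velocities, times = frame_times(meta),
                 mask = mask, meta = meta,
                 corrections_applied = corrections),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d frames x %d pixels (%s ROI, %s)\n",
              nrow(x$velocities), ncol(x$velocities), x$mask$kind,
              x$meta$site))
  cat("  corrections:",
      if (length(x$corrections_applied))
        paste(x$corrections_applied, collapse = " -> ") else "(none)", "\n")
  invisible(x)
}

#' Convert stored phase values to velocities
#'
#' Applies the linear pixel-to-velocity transform of phase-contrast MRI:
#' `v = raw * VENC / raw_scale` (cm/s), extracting only the pixels of the
#' given ROI. This is the first of the three corrections
#' (`venc_scaling -> aliasing_correction -> bias_subtraction`).
#'
#' @param series A [phase_series].
#' @param mask An [roi_mask] within the frame bounds.
#' @return A [velocity_field] with `corrections_applied = "venc_scaling"`.
#' @examples
#' meta <- acquisition_meta(venc = 10, dx = 0.06, dy = 0.06, n_frames = 4,
#'                          heart_rate = 60, raw_scale = 100)
#' frames <- array(50, dim = c(4, 8, 8))  # raw 50 -> 5 cm/s
#' mask <- roi_mask(cbind(4, 4), shape = c(8, 8), kind = "target")
#' to_velocity(phase_series(frames, meta), mask)$velocities
#' @export
to_velocity <- function(series, mask) {
  stopifnot(inherits(series, "phase_series"), inherits(mask, "roi_mask"))
  d <- dim(series$frames)
  if (!identical(as.integer(d[2:3]), mask$shape))
    stop("mask shape ", mask$shape[1], " x ", mask$shape[2],
         " does not match frame shape ", d[2], " x ", d[3])
  meta <- series$meta
  np <- n_pixels(mask)
  v <- matrix(NA_real_, meta$n_frames, np)
  for (j in seq_len(np)) {
    v[, j] <- series$frames[, mask$pixels[j, 1], mask$pixels[j, 2]]
  }
  v <- v * (meta$venc / meta$raw_scale)
  velocity_field(v, mask, meta, corrections = "venc_scaling")
}

#' Estimate the static velocity bias from a reference ROI
#'
#' In PC-MRI, eddy currents leave a static phase offset that appears as a
#' spurious constant velocity shared by CSF and adjacent tissue. The
#' reference ROI in static tissue serves two purposes: its mean velocity
#' estimates that bias (to be subtracted from the CSF velocities), and its
#' spread quantifies the noise level for signal-to-noise screening.
#'
#' @param reference_field A [velocity_field] built from a `kind =
#'   "reference"` mask.
#' @param mode `"global"`: one scalar bias, the mean over all frames and
#'   pixels (the default; eddy-current offsets are static). `"per_frame"`:
#'   one bias per cardiac phase, the pixel mean of each frame.
#' @return An object of class `bias_estimate` with fields `value` (cm/s; in
#'   per-frame mode the time mean of the frame curve), `mode`,
#'   `reference_mean_curve` (per-frame pixel means) and `noise_spread`
#'   (SD of reference velocities about their frame means, cm/s).
#' @export
estimate_bias <- function(reference_field, mode = c("global", "per_frame")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference_field, "velocity_field"))
  if (reference_field$mask$kind != "reference")
    stop("bias must be estimated from a reference ROI, got a '",
         reference_field$mask$kind, "' mask")
  v <- reference_field$velocities
  curve <- rowMeans(v)
  resid <- v - curve
  nres <- length(resid)
  noise_spread <- if (nres > 1L) sqrt(sum(resid^2) / (nres - 1L)) else 0
  structure(list(value = mean(v), mode = mode,
                 reference_mean_curve = curve,
                 noise_spread = noise_spread,
                 n_pixels = ncol(v)),
            class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf("bias_estimate (%s): %.6g cm/s, noise spread %.6g cm/s\n",
              x$mode, x$value, x$noise_spread))
  invisible(x)
}

#' Subtract the reference-ROI bias from a velocity field
#'
#' In global mode the scalar bias is subtracted from every sample; in
#' per-frame mode each frame's reference mean is subtracted from that frame.
#' Applying the correction twice is an error.
#'
#' @param field A [velocity_field] (typically the CSF target ROI).
#' @param bias A [estimate_bias()] result from the same acquisition.
#' @return The corrected [velocity_field]; `corrections_applied` gains
#'   `"bias_subtraction"`.
#' @export
subtract_bias <- function(field, bias) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(bias, "bias_estimate"))
  if ("bias_subtraction" %in% field$corrections_applied)
    stop("bias_subtraction already applied to this field")
  v <- field$velocities
  if (bias$mode == "global") {
    v <- v - bias$value
  } else {
    if (length(bias$reference_mean_curve) != nrow(v))
      stop("per-frame bias curve length ", length(bias$reference_mean_curve),
           " does not match ", nrow(v), " frames")
    v <- v - bias$reference_mean_curve
  }
  velocity_field(v, field$mask, field$meta,
                 corrections = c(field$corrections_applied,
                                 "bias_subtraction"))
}

# Nearest-multiple unwrap of one pixel's periodic series. Anchor frame is
# trusted; every step away from it shifts the farther sample by k*2*VENC so
# the inter-frame jump lands in [-VENC, VENC].
.unwrap_pixel <- function(v, anchor, venc) {
  n <- length(v)
  cyc <- function(i) ((i - 1L) %% n) + 1L
  n_fwd <- ceiling((n - 1L) / 2)
  n_bwd <- (n - 1L) - n_fwd
  if (n_fwd > 0L) for (s in seq_len(n_fwd)) {
    i_prev <- cyc(anchor + s - 1L); i <- cyc(anchor + s)
    d <- v[i] - v[i_prev]
    v[i] <- v[i] - 2 * venc * round(d / (2 * venc))
  }
  if (n_bwd > 0L) for (s in seq_len(n_bwd)) {
    i_next <- cyc(anchor - s + 1L); i <- cyc(anchor - s)
    d <- v[i] - v[i_next]
    v[i] <- v[i] - 2 * venc * round(d / (2 * venc))
  }
  v
}

#' Correct aliased (wrapped) velocities by temporal unwrapping
#'
#' True velocities beyond +/- VENC are stored wrapped by multiples of
#' 2*VENC. The correction unwraps each pixel's time series: the anchor frame
#' is the cardiac phase at which the ROI-mean absolute velocity is smallest
#' (flow near its zero crossing is least likely wrapped); walking the
#' periodic series in both directions from the anchor, any inter-frame jump
#' beyond +/- VENC is removed by shifting the farther sample by the nearest
#' multiple of 2*VENC. Afterwards all consecutive jumps are at most VENC in
#' absolute value; the operation is idempotent.
#'
#' A series whose true inter-frame jumps themselves exceed VENC is
#' ambiguous and cannot be detected; this is a documented limitation, not an
#' error.
#'
#' @param field A [velocity_field] on the velocity scale (after
#'   [to_velocity()], before [subtract_bias()], since wrap arithmetic is
#'   only valid on the +/- VENC scale).
#' @return The unwrapped [velocity_field]; `corrections_applied` gains
#'   `"aliasing_correction"`.
#' @export
correct_aliasing <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  if ("bias_subtraction" %in% field$corrections_applied)
    stop("aliasing correction must precede bias subtraction: wrap ",
         "arithmetic is only valid on the +/- VENC scale")
  venc <- field$meta$venc
  v <- field$velocities
  anchor <- which.min(rowMeans(abs(v)))
  for (j in seq_len(ncol(v))) v[, j] <- .unwrap_pixel(v[, j], anchor, venc)
  corr <- unique(c(field$corrections_applied, "aliasing_correction"))
  velocity_field(v, field$mask, field$meta, corrections = corr)
}

#' ROI mean velocity per cardiac phase
#'
#' Averages the recorded velocities over the ROI pixels for each frame,
#' yielding the mean-velocity waveform over one cardiac cycle.
#'
#' @param field A [velocity_field].
#' @return Numeric vector of length `n_frames`, cm/s.
#' @export
mean_velocity_curve <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  rowMeans(field$velocities)
}

#' Flag a low signal-to-noise acquisition
#'
#' Compares the cycle amplitude (max minus min) of the CSF ROI's
#' mean-velocity curve with the noise expected in a mean of `n_pixels`
#' independent samples. The field is flagged — not rejected — when the
#' amplitude falls below `k * noise_spread / sqrt(n_pixels)`. The threshold
#' is this package's own screening rule and is configurable.
#'
#' @param field The CSF-target [velocity_field].
#' @param bias The [estimate_bias()] result carrying `noise_spread`.
#' @param k Multiplier on the noise standard error (default 3).
#' @return Logical: `TRUE` when the acquisition should be flagged as noisy.
#' @export
flag_low_snr <- function(field, bias, k = 3) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(bias, "bias_estimate"), k > 0)
  curve <- mean_velocity_curve(field)
  amplitude <- max(curve) - min(curve)
  amplitude < k * bias$noise_spread / sqrt(ncol(field$velocities))
}

#' Run the full velocity-correction chain on one acquisition
#'
#' Convenience wrapper: VENC scaling of target and reference ROIs, aliasing
#' correction of the target, bias estimation from the reference and
#' subtraction from the target, in that order.
#'
#' @param series A [phase_series].
#' @param target_mask,reference_mask Target and reference [roi_mask]s.
#' @param bias_mode Passed to [estimate_bias()].
#' @param correct_alias Set `FALSE` to skip aliasing correction.
#' @param noise_flag_k Passed to [flag_low_snr()].
#' @return A list with elements `field` (the corrected target
#'   [velocity_field]), `bias` (the [estimate_bias()] result) and
#'   `noise_flagged` (logical).
#' @export
process_velocities <- function(series, target_mask, reference_mask,
                               bias_mode = c("global", "per_frame"),
                               correct_alias = TRUE, noise_flag_k = 3) {
  bias_mode <- match.arg(bias_mode)
  target <- to_velocity(series, target_mask)
  reference <- to_velocity(series, reference_mask)
  if (correct_alias) target <- correct_aliasing(target)
  bias <- estimate_bias(reference, mode = bias_mode)
  field <- subtract_bias(target, bias)
  list(field = field, bias = bias,
       noise_flagged = flag_low_snr(field, bias, k = noise_flag_k))
}
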