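#' Ground-truth description of a synthetic PC-MRI acquisition
#'
#' Defines the phantom used by [simulate_acquisition()]: a circular lumen
#' with a pulsatile-plus-offset through-plane velocity waveform and either a
#' plug (uniform) or parabolic (Poiseuille) spatial profile, a static
#' baseline velocity offset shared by every pixel (emulating the
#' eddy-current phase bias), additive Gaussian velocity noise, and optional
#' velocity wrapping beyond +/- VENC.
#'
#' The per-pixel true velocity at frame time `t` is
#' `profile(p) * (offset + sum_k a_k * sin(2*pi*k*t/T + phi_k))`, where the
#' fundamental `(pulsatile_amplitude, phase)` is harmonic `k = 1`.
#'
#' @param mean_velocity_offset Time-mean centre-line velocity, cm/s
#'   (positive = toward the head).
#' @param pulsatile_amplitude Amplitude of the fundamental cardiac harmonic,
#'   cm/s.
#' @param phase Phase of the fundamental, radians.
#' @param harmonics Optional list of `c(amplitude, phase)` pairs for
#'   harmonics `k = 2, 3, ...`.
#' @param center Lumen centre `(row, col)`, pixels (may be fractional).
#' @param radius_px Lumen radius in pixels.
#' @param profile `"plug"` (uniform over the lumen) or `"parabolic"`
#'   (Poiseuille, zero at the wall, continuum spatial mean = centre/2).
#' @param baseline_offset Static velocity offset added to all pixels, cm/s.
#' @param noise_sd Additive Gaussian velocity noise SD, cm/s (>= 0).
#' @param wrap_applied Wrap velocities beyond +/- VENC into the encoded
#'   range (aliasing), as a real scanner would.
#' @return An object of class `flow_ground_truth`.
#' @export
flow_ground_truth <- function(mean_velocity_offset = 0.3,
                              pulsatile_amplitude = 3,
                              phase = 0,
                              harmonics = list(),
                              center = c(32.5, 32),
                              radius_px = 2.9,
                              profile = c("parabolic", "plug"),
                              baseline_offset = 0,
                              noise_sd = 0.7,
                              wrap_applied = FALSE) {
  profile <- match.arg(profile)
  stopifnot(noise_sd >= 0, radius_px > 0, length(center) == 2L)
  structure(list(mean_velocity_offset = mean_velocity_offset,
                 pulsatile_amplitude = pulsatile_amplitude,
                 phase = phase, harmonics = harmonics,
                 center = as.numeric(center),
                 radius_px = as.numeric(radius_px),
                 profile = profile,
                 baseline_offset = baseline_offset,
                 noise_sd = noise_sd,
                 wrap_applied = isTRUE(wrap_applied)),
            class = "flow_ground_truth")
}

# Wrap a velocity into (-venc, venc]: the scanner's aliasing operator.
wrap_velocity <- function(v, venc) {
  ((v + venc) %% (2 * venc)) - venc
}

# Spatial profile weight of each lumen pixel (pixel centres; plug = 1,
# parabolic = 1 - (r/R)^2 evaluated at the pixel centre).
.profile_weights <- function(truth, pixels) {
  r2 <- (pixels[, 1] - truth$center[1])^2 + (pixels[, 2] - truth$center[2])^2
  if (truth$profile == "plug") rep(1, nrow(pixels))
  else pmax(0, 1 - r2 / truth$radius_px^2)
}

# Waveform sampled at frame times: offset + fundamental + extra harmonics.
.waveform <- function(truth, times, period) {
  w <- truth$mean_velocity_offset +
    truth$pulsatile_amplitude * sin(2 * pi * times / period + truth$phase)
  if (length(truth$harmonics)) {
    for (k in seq_along(truth$harmonics)) {
      h <- truth$harmonics[[k]]
      w <- w + h[1] * sin(2 * pi * (k + 1) * times / period + h[2])
    }
  }
  w
}

#' Default acquisition metadata for the synthetic phantom
#'
#' Mirrors a typical aqueduct protocol: 30 cardiac phases, VENC 10 cm/s,
#' 0.06 cm isotropic pixels, heart rate 70 bpm, raw scale 2048.
#'
#' @param ... Overrides passed to [acquisition_meta()].
#' @return An [acquisition_meta].
#' @export
default_sim_meta <- function(...) {
  args <- list(venc = 10, dx = 0.06, dy = 0.06, n_frames = 30,
               heart_rate = 70, raw_scale = 2048, site = "aqueduct")
  override <- list(...)
  args[names(override)] <- override
  if ("cycle_duration" %in% names(override)) args$heart_rate <- NULL
  do.call(acquisition_meta, args)
}

#' Simulate one cardiac-gated PC-MRI acquisition
#'
#' Generates raw phase frames for a circular-lumen phantom with known ground
#' truth, plus target and reference ROI masks. Lumen pixels carry
#' `profile * waveform + baseline_offset + noise`; reference and background
#' pixels carry `baseline_offset + noise` only. Velocities are wrapped into
#' `(-VENC, VENC]` when `truth$wrap_applied`, then scaled to raw pixel
#' values by `raw_scale / VENC`. Deterministic for a given `seed`.
#'
#' The returned ground truth is augmented with the quantities a recovery
#' test needs in closed form: the pixel-measured spatial-mean factor
#' (`sum(profile)/n_pixels`, exactly 1 for plug, about 1/2 for parabolic at
#' finite resolution), `true_net_mL_per_cycle = mean_velocity_offset *
#' sum(profile) * dx * dy * cycle_duration` and `true_net_mL_per_min`.
#'
#' @param truth A [flow_ground_truth].
#' @param meta An [acquisition_meta] (see [default_sim_meta()]).
#' @param image_shape Frame dimensions `c(rows, cols)`.
#' @param seed Integer seed; required, for exact reproducibility.
#' @param reference_offset Placement of the square reference ROI relative to
#'   the lumen centre, pixels `(row, col)`.
#' @param reference_halfwidth Half-width of the square reference ROI.
#' @return A list with `series` ([phase_series]), `target` and `reference`
#'   ([roi_mask]s) and `truth` (augmented [flow_ground_truth]).
#' @export
simulate_acquisition <- function(truth, meta = default_sim_meta(),
                                 image_shape = c(64, 64), seed,
                                 reference_offset = c(-12, -12),
                                 reference_halfwidth = 3L) {
  stopifnot(inherits(truth, "flow_ground_truth"),
            inherits(meta, "acquisition_meta"))
  if (missing(seed)) stop("`seed` is required for a reproducible simulation")
  peak <- abs(truth$baseline_offset) + abs(truth$mean_velocity_offset) +
    abs(truth$pulsatile_amplitude) +
    sum(vapply(truth$harmonics, function(h) abs(h[1]), numeric(1)))
  if (truth$wrap_applied && peak >= 2 * meta$venc)
    stop("peak velocity ", signif(peak, 4), " cm/s >= 2*VENC with ",
         "wrap_applied: the wrap is unresolvable")

  shape <- as.integer(image_shape)
  grid <- as.matrix(expand.grid(row = seq_len(shape[1]),
                                col = seq_len(shape[2])))
  r2 <- (grid[, 1] - truth$center[1])^2 + (grid[, 2] - truth$center[2])^2
  lumen_px <- grid[r2 <= truth$radius_px^2, , drop = FALSE]
  if (nrow(lumen_px) == 0L) stop("lumen contains no pixel centres")
  target <- roi_mask(lumen_px, shape, kind = "target", label = "lumen")

  rc <- round(truth$center + reference_offset)
  hw <- as.integer(reference_halfwidth)
  ref_px <- as.matrix(expand.grid(row = (rc[1] - hw):(rc[1] + hw),
                                  col = (rc[2] - hw):(rc[2] + hw)))
  reference <- roi_mask(ref_px, shape, kind = "reference",
                        label = "static tissue")
  both <- rbind(target$pixels, reference$pixels)
  if (anyDuplicated(both))
    stop("lumen and reference ROIs overlap; move the reference region")

  times <- frame_times(meta)
  wave <- .waveform(truth, times, meta$cycle_duration)
  weights <- .profile_weights(truth, target$pixels)

  set.seed(as.integer(seed))
  frames <- array(0, dim = c(meta$n_frames, shape[1], shape[2]))
  vel <- array(truth$baseline_offset,
               dim = c(meta$n_frames, shape[1], shape[2]))
  for (j in seq_len(nrow(target$pixels))) {
    vel[, target$pixels[j, 1], target$pixels[j, 2]] <-
      truth$baseline_offset + weights[j] * wave
  }
  if (truth$noise_sd > 0)
    vel <- vel + array(stats::rnorm(length(vel), sd = truth$noise_sd),
                       dim = dim(vel))
  if (truth$wrap_applied) vel <- wrap_velocity(vel, meta$venc)
  frames[] <- vel * (meta$raw_scale / meta$venc)

  truth$seed <- as.integer(seed)
  truth$profile_weight_sum <- sum(weights)
  truth$spatial_mean_factor <- sum(weights) / nrow(target$pixels)
  truth$true_net_mL_per_cycle <- truth$mean_velocity_offset *
    sum(weights) * meta$dx * meta$dy * meta$cycle_duration
  truth$true_net_mL_per_min <- truth$true_net_mL_per_cycle * meta$heart_rate

  list(series = phase_series(frames, meta,
                             wrapped_input = truth$wrap_applied),
       target = target, reference = reference, truth = truth)
}

#' Repeated acquisitions of one subject (reproducibility design)
#'
#' Emulates a repeat-measurement protocol in which the same subject is
#' scanned several times: the acquisitions share every ground-truth
#' parameter and differ only in the noise realization.
#'
#' @param truth A [flow_ground_truth].
#' @param meta An [acquisition_meta].
#' @param n_repeats Number of repeats.
#' @param seeds Integer vector of distinct seeds, one per repeat.
#' @param ... Passed on to [simulate_acquisition()].
#' @return A list of `n_repeats` acquisition lists.
#' @export
make_reproducibility_set <- function(truth, meta = default_sim_meta(),
                                     n_repeats = 5,
                                     seeds = seq_len(n_repeats), ...) {
  stopifnot(length(seeds) == n_repeats)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  lapply(seeds, function(s)
    simulate_acquisition(truth, meta, seed = s, ...))
}
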