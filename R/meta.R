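#' Acquisition metadata for a cardiac-gated PC-MRI series
#'
#' Bundles the scan parameters needed to turn stored phase-image pixel values
#' into velocities and volumetric flow: the velocity-encoding limit (VENC),
#' in-plane pixel size, the number of cardiac phases, the cardiac cycle
#' duration, the raw-value scale, and the anatomical site.
#'
#' Exactly one of `cycle_duration` or `heart_rate` must be given; the other is
#' derived through `cycle_duration = 60 / heart_rate`.
#'
#' @param venc Velocity-encoding limit in cm/s (> 0). True velocities beyond
#'   +/- VENC wrap by multiples of 2*VENC (aliasing).
#' @param dx,dy In-plane pixel width and height in cm (> 0).
#' @param n_frames Number of cardiac phases (integer >= 4).
#' @param cycle_duration Cardiac cycle duration in seconds (> 0).
#' @param heart_rate Heart rate in beats/min; alternative to `cycle_duration`.
#' @param raw_scale Stored pixel value that maps to +VENC (> 0). A stored
#'   value of `-raw_scale` maps to -VENC.
#' @param site Measurement site: `"aqueduct"` (Sylvian aqueduct) or `"ccj"`
#'   (cranio-cervical junction).
#' @return An object of class `acquisition_meta`.
#' @examples
#' meta <- acquisition_meta(venc = 10, dx = 0.06, dy = 0.06, n_frames = 30,
#'                          heart_rate = 70, raw_scale = 2048,
#'                          site = "aqueduct")
#' meta$cycle_duration  # 60/70 s
#' @export
acquisition_meta <- function(venc, dx, dy, n_frames,
                             cycle_duration = NULL, heart_rate = NULL,
                             raw_scale = 1, site = c("aqueduct", "ccj")) {
  site <- match.arg(site)
  if (is.null(cycle_duration) && is.null(heart_rate))
    stop("supply either `cycle_duration` (s) or `heart_rate` (beats/min)")
  if (is.null(cycle_duration)) cycle_duration <- 60 / heart_rate
  if (is.null(heart_rate)) heart_rate <- 60 / cycle_duration
  stopifnot(is.numeric(venc), length(venc) == 1L, venc > 0,
            is.numeric(dx), length(dx) == 1L, dx > 0,
            is.numeric(dy), length(dy) == 1L, dy > 0,
            is.numeric(raw_scale), length(raw_scale) == 1L, raw_scale > 0,
            is.numeric(cycle_duration), cycle_duration > 0)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 4L)
    stop("`n_frames` must be an integer >= 4, got ", n_frames)
  if (abs(heart_rate * cycle_duration - 60) > 1e-9)
    stop("inconsistent `heart_rate` and `cycle_duration`: ",
         heart_rate, " bpm vs ", cycle_duration, " s")
  structure(
    list(venc = as.numeric(venc), dx = as.numeric(dx), dy = as.numeric(dy),
         n_frames = n_frames, cycle_duration = as.numeric(cycle_duration),
         heart_rate = as.numeric(heart_rate),
         raw_scale = as.numeric(raw_scale), site = site),
    class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat("PC-MRI acquisition (", x$site, ")\n", sep = "")
  cat(sprintf("  VENC %.3g cm/s | pixel %.3g x %.3g cm | %d frames over %.4g s (HR %.4g bpm) | raw scale %.6g\n",
              x$venc, x$dx, x$dy, x$n_frames, x$cycle_duration,
              x$heart_rate, x$raw_scale))
  invisible(x)
}

#' Read acquisition metadata from a YAML file
#'
#' Expected keys: `venc_cm_s`, `dx_cm`, `dy_cm`, `n_frames`, `raw_scale`,
#' `site`, and one of `cycle_duration_s` or `heart_rate_bpm`.
#'
#' @param path Path to a YAML file.
#' @return An [acquisition_meta] object.
#' @export
read_acquisition_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("venc_cm_s", "dx_cm", "dy_cm", "n_frames", "raw_scale", "site")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop("metadata YAML missing key(s): ", paste(missing, collapse = ", "))
  acquisition_meta(venc = y$venc_cm_s, dx = y$dx_cm, dy = y$dy_cm,
                   n_frames = y$n_frames,
                   cycle_duration = y$cycle_duration_s,
                   heart_rate = y$heart_rate_bpm,
                   raw_scale = y$raw_scale, site = y$site)
}

#' Write acquisition metadata to a YAML file
#'
#' @param meta An [acquisition_meta] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_acquisition_meta <- function(meta, path) {
  stopifnot(inherits(meta, "acquisition_meta"))
  yaml::write_yaml(
    list(venc_cm_s = meta$venc, dx_cm = meta$dx, dy_cm = meta$dy,
         n_frames = meta$n_frames, cycle_duration_s = meta$cycle_duration,
         raw_scale = meta$raw_scale, site = meta$site),
    path, precision = 17)  # doubles must survive the YAML round trip
  invisible(path)
}

# Frame sampling times: midpoints of the n uniform bins covering one cycle.
frame_times <- function(meta) {
  dt <- meta$cycle_duration / meta$n_frames
  (seq_len(meta$n_frames) - 0.5) * dt
}
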