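# Shared fixtures: small metadata, hand-built velocity fields and flow
# curves so each operation can be tested in isolation from the pipeline.

test_meta <- function(n_frames = 30, venc = 10, dx = 0.06, dy = 0.06,
                      heart_rate = 70, raw_scale = 2048,
                      site = "aqueduct") {
  acquisition_meta(venc = venc, dx = dx, dy = dy, n_frames = n_frames,
                   heart_rate = heart_rate, raw_scale = raw_scale,
                   site = site)
}

# Velocity field wrapping a bare matrix (frames x pixels) with a mask of the
# right size; corrections default to the full chain so flow_curve accepts it.
make_field <- function(v, meta = test_meta(n_frames = nrow(v)),
                       kind = "target",
                       corrections = c("venc_scaling", "aliasing_correction",
                                       "bias_subtraction")) {
  v <- as.matrix(v)
  px <- cbind(row = seq_len(ncol(v)), col = rep(1L, ncol(v)))
  mask <- roi_mask(px, shape = c(max(ncol(v), 2L), 2L), kind = kind)
  csfflow:::velocity_field(v, mask, meta, corrections = corrections)
}

# Flow curve directly from q samples (mL/s), bypassing the velocity stage.
make_curve <- function(q, meta = test_meta(n_frames = length(q))) {
  stopifnot(length(q) == meta$n_frames)
  structure(list(q = as.numeric(q),
                 times = csfflow:::frame_times(meta),
                 meta = meta, n_pixels = 1L),
            class = "flow_curve")
}

# Independent quadrature oracle: Riemann refinement of the piecewise-linear
# periodic interpolant of q (the continuous curve the trapezoid integrates).
riemann_periodic <- function(q, cycle_duration, refine = 4096L) {
  n <- length(q)
  dt <- cycle_duration / n
  t_nodes <- (seq_len(n + 1L) - 1L) * dt
  q_ext <- c(q, q[1])
  tt <- seq(0, cycle_duration, length.out = n * refine + 1L)
  qq <- stats::approx(t_nodes, q_ext, xout = tt)$y
  mids <- (qq[-1] + qq[-length(qq)]) / 2
  sum(mids) * diff(tt[1:2])
}
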