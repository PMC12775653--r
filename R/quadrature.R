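# Composite Gauss-Legendre frame quadrature.
#
# The analytic tissue solution is exact pointwise; frame averages are its
# time integrals, computed with fixed composite Gauss-Legendre panels on the
# smooth closed form. Panels never exceed `panel_min` minutes and are split
# at the input-function onset t0 (the only non-smooth point of the curve).

# Golub-Welsch nodes/weights for n-point Gauss-Legendre on [-1, 1].
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

# Quadrature nodes covering every frame of `schedule` (times in minutes),
# with weights scaled so that per-frame accumulation yields the frame
# *average* (integral divided by full frame duration). t0_min marks the
# onset kink; the panel containing it is split there. Early panels are
# kept short where fast exponential components are still alive; by
# `coarse_after` minutes those components have decayed by many time
# constants and wider panels lose no accuracy.
frame_quadrature <- function(schedule, t0_min = 0, panel_min = 0.5,
                             coarse_after = 10, panel_coarse = 2.5,
                             n_gl = 8) {
  gl <- gauss_legendre(n_gl)
  starts <- schedule$start_s / 60
  ends <- (schedule$start_s + schedule$duration_s) / 60
  node_t <- node_w <- numeric(0)
  node_frame <- integer(0)
  for (f in seq_along(starts)) {
    cuts <- c(starts[f], ends[f])
    if (t0_min > starts[f] && t0_min < ends[f])
      cuts <- c(starts[f], t0_min, ends[f])
    for (s in seq_len(length(cuts) - 1)) {
      a <- cuts[s]; b <- cuts[s + 1]
      width <- if (a >= coarse_after) panel_coarse else panel_min
      np <- max(1L, ceiling((b - a) / width))
      edges <- seq(a, b, length.out = np + 1)
      for (p in seq_len(np)) {
        half <- (edges[p + 1] - edges[p]) / 2
        mid <- (edges[p + 1] + edges[p]) / 2
        node_t <- c(node_t, mid + half * gl$x)
        node_w <- c(node_w, gl$w * half / (ends[f] - starts[f]))
        node_frame <- c(node_frame, rep.int(f - 1L, n_gl))
      }
    }
  }
  list(t = node_t, w = node_w, frame = node_frame,
       n_frames = length(starts))
}
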