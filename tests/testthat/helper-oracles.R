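# Independent closed-form oracles used across the suite.

# Unsigned angle between the vertex->toward vector (up-positive vertical)
# and the horizontal, via the arccos of the normalised dot product with
# (1, 0) -- independent of the atan2 route used by the implementation.
acos_elevation_oracle <- function(vertex, toward) {
  d <- c(toward[1] - vertex[1], vertex[2] - toward[2])
  acos(d[1] / sqrt(sum(d^2))) * 180 / pi
}

# From-scratch Pearson r via explicit covariance / variance sums.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Sort-based type-7 quantile: linear interpolation between order statistics.
quantile_oracle <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}

# Small-canvas rendering settings used where full-size frames would be
# needlessly slow; geometry is identical up to scale.
small_frame <- function(spec, ...) {
  render_posture_frame(spec, canvas = c(520, 760), marker_px = 30,
                       baseline_px = 150, c7_xy = c(250, 420), ...)
}
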