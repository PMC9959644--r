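# shared tiny fixtures, all built in code

# two-point dataset interpolated exactly by gamma = (-1, 2)
toy_data <- function() drying_data(c(1, 0.5), c(1, 0))

# noise-free dataset from an arbitrary truth on a well-conditioned S grid
exact_poly_data <- function(gamma, kmax = 30, s_min = 0.55) {
  s <- seq(1, s_min, length.out = kmax)
  drying_data(s, drop(outer(s, seq_along(gamma) - 1, `^`) %*% gamma))
}

table1_cubic <- c(-4.0180, 12.5609, -11.1670, 3.5632)

# logical raster of a centred disk; oracle area by direct pixel count
disk_mask <- function(size, r, cx = (size + 1) / 2, cy = cx) {
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= r^2
}
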