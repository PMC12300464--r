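# Shared fixtures: all synthetic, built in code.

# camera geometry whose homography maps the treatment field exactly onto
# the frame, axis-aligned (no tilt, no parallax) — the "identity" view
affine_field_geom <- function(size = c(180L, 180L), half_mm = 25,
                              thermal_size = size,
                              parallax_offset = c(0, 0)) {
  src <- rbind(c(-half_mm, half_mm), c(half_mm, half_mm),
               c(half_mm, -half_mm), c(-half_mm, -half_mm))
  dst <- rbind(c(1, 1), c(size[1], 1), c(size[1], size[2]), c(1, size[2]))
  camera_geometry(homography = homography_from_points(src, dst),
                  parallax_offset = parallax_offset,
                  visible_size = size, thermal_size = thermal_size)
}

# uniform-absorptivity phantom (no blob contrast) for heat-model tests
uniform_phantom <- function(n_cells = 60, absorptivity = 1, ...) {
  generate_phantom(blob_spec(1), n_cells = n_cells,
                   absorptivity_in = absorptivity,
                   absorptivity_out = absorptivity, ...)
}

ambient_field <- function(phantom) {
  temperature_field(matrix(phantom$ambient_c, phantom$n_cells,
                           phantom$n_cells))
}

# truth mask on the scan grid: the blob's analytic disk union rasterized
# finely (6x6 subsamples per scan cell), then binarized at 0.5 occupancy,
# so boundary-cell occupancies are unbiased
truth_scan_matrix <- function(phantom, n = 30) {
  fine <- 6 * n
  res <- phantom$field_mm / fine
  xs <- (seq_len(fine) - (fine + 1) / 2) * res
  ys <- -(seq_len(fine) - (fine + 1) / 2) * res
  mask <- matrix(0, fine, fine)
  for (l in seq_along(phantom$lobes$radii)) {
    d2 <- outer(ys - phantom$lobes$centers[l, 2],
                xs - phantom$lobes$centers[l, 1],
                function(dy, dx) dx^2 + dy^2)
    mask[d2 <= phantom$lobes$radii[l]^2] <- 1
  }
  scan_matrix((area_resize(mask, n, n) >= 0.5) * 1)
}

# a thermal frame built directly from known pixels/metadata
make_thermal_frame <- function(pixels, t_min, t_max) {
  structure(list(pixels = pixels, t_min = t_min, t_max = t_max,
                 degenerate = t_max - t_min < 1e-9,
                 netd = 0.065, accuracy = 2),
            class = "thermal_frame")
}
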