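# Simulated visible and thermal cameras: projective (keystone) geometry,
# vertical parallax between the two sensors, sensor noise, and 8-bit
# thermal quantization with (Tmin, Tmax) sidecar metadata.

#' Estimate a homography from four point correspondences
#'
#' Solves the direct linear transform for the 3 x 3 projective matrix H
#' mapping `src` points to `dst` points (both 4 x 2, columns x, y), with
#' H[3,3] fixed to 1.
#'
#' @param src,dst 4 x 2 matrices of corresponding points.
#' @return A 3 x 3 homography matrix.
#' @export
homography_from_points <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) == 4, nrow(dst) == 4, ncol(src) == 2, ncol(dst) == 2)
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography.
#' @param x,y Coordinates (vectors).
#' @return A list with mapped `x`, `y`.
#' @export
apply_homography <- function(H, x, y) {
  w <- H[3, 1] * x + H[3, 2] * y + H[3, 3]
  list(x = (H[1, 1] * x + H[1, 2] * y + H[1, 3]) / w,
       y = (H[2, 1] * x + H[2, 2] * y + H[2, 3]) / w)
}

#' Dual-camera geometry
#'
#' Describes how the target plane is seen by the two sensors. `homography`
#' maps scene-plane millimetres (origin at the field center, y up) to
#' visible-image pixel coordinates (x = column, y = row, origin top-left).
#' The thermal camera shares the view after an anisotropic rescale to its
#' sensor size plus a pixel offset caused by its mounting a few
#' centimetres below the visible camera (parallax).
#'
#' The default homography projects the scene with a mild (~10 deg)
#' camera tilt, producing a visible keystone: the top edge of the square
#' field images shorter than the bottom edge.
#'
#' @param homography 3 x 3 scene-to-visible-pixel map; `NULL` builds the
#'   default tilted view.
#' @param parallax_offset Length-2 (dx, dy) shift of the thermal view,
#'   thermal pixels; the default models the thermal camera sitting below
#'   the visible one.
#' @param visible_size,thermal_size (width, height) in pixels.
#' @param scene_window_mm Half-width of the scene square covered by the
#'   visible sensor, mm.
#' @param keystone Relative inset of the top corners of the projected
#'   scene window (0 = no tilt).
#' @return An object of class `camera_geometry`.
#' @export
camera_geometry <- function(homography = NULL,
                            parallax_offset = c(0, 12),
                            visible_size = c(192L, 192L),
                            thermal_size = c(256L, 192L),
                            scene_window_mm = 35,
                            keystone = 0.12) {
  visible_size <- as.integer(visible_size)
  thermal_size <- as.integer(thermal_size)
  if (is.null(homography)) {
    w <- visible_size[1]; h <- visible_size[2]; m <- 6
    inset <- keystone * (w - 2 * m) / 2
    src <- rbind(c(-scene_window_mm,  scene_window_mm),
                 c( scene_window_mm,  scene_window_mm),
                 c( scene_window_mm, -scene_window_mm),
                 c(-scene_window_mm, -scene_window_mm))
    dst <- rbind(c(m + inset, m), c(w - m - inset, m),
                 c(w - m, h - m), c(m, h - m))
    homography <- homography_from_points(src, dst)
  }
  stopifnot(is.matrix(homography), all(dim(homography) == c(3, 3)),
            abs(det(homography)) > 1e-12, length(parallax_offset) == 2)
  structure(list(homography = homography,
                 homography_inv = solve(homography),
                 parallax_offset = parallax_offset,
                 visible_size = visible_size, thermal_size = thermal_size,
                 scene_window_mm = scene_window_mm),
            class = "camera_geometry")
}

# plane-mm coordinates seen by every visible pixel (matrices row x col)
visible_pixel_scene_coords <- function(geom) {
  w <- geom$visible_size[1]; h <- geom$visible_size[2]
  u <- matrix(rep(seq_len(w), each = h), h, w)   # x pixel (column)
  v <- matrix(rep(seq_len(h), w), h, w)          # y pixel (row)
  apply_homography(geom$homography_inv, u, v)
}

# bilinear sample of a field grid (row 1 = top, +y up) at plane mm coords
sample_plane_grid <- function(grid, xs, ys, px, py, outside) {
  n_r <- nrow(grid); n_c <- ncol(grid)
  res_x <- xs[2] - xs[1]; res_y <- ys[1] - ys[2]
  cj <- (px - xs[1]) / res_x + 1        # fractional column
  ri <- (ys[1] - py) / res_y + 1        # fractional row
  out <- matrix(outside, nrow(px), ncol(px))
  # the grid physically extends half a cell beyond the outermost centers;
  # that band is sampled by edge clamping
  ok <- cj >= 0.5 & cj <= n_c + 0.5 & ri >= 0.5 & ri <= n_r + 0.5
  cj <- pmin(pmax(cj, 1), n_c); ri <- pmin(pmax(ri, 1), n_r)
  j0 <- pmin(pmax(floor(cj), 1), n_c - 1); i0 <- pmin(pmax(floor(ri), 1), n_r - 1)
  fx <- cj - j0; fy <- ri - i0
  idx <- function(i, j) grid[cbind(as.vector(i), as.vector(j))]
  val <- (1 - fx) * (1 - fy) * idx(i0, j0) +
    fx * (1 - fy) * idx(i0, j0 + 1) +
    (1 - fx) * fy * idx(i0 + 1, j0) +
    fx * fy * idx(i0 + 1, j0 + 1)
  out[ok] <- val[ok]
  out
}

#' Render the visible-camera frame of a phantom
#'
#' Projects the phantom surface through the camera homography: the clay
#' field images as a mid-grey plate on a light background and the
#' absorbing target as a dark region (intensity falls linearly with
#' absorptivity). Optional Gaussian pixel noise makes frames
#' reproducible only for a fixed seed.
#'
#' @param phantom A [generate_phantom()] model.
#' @param geom A [camera_geometry()].
#' @param noise_sd Pixel noise standard deviation, 8-bit counts.
#' @param seed Optional seed for the pixel noise.
#' @return An object of class `visible_frame`: an integer matrix (rows =
#'   image rows) in `[0, 255]`.
#' @export
render_visible <- function(phantom, geom = camera_geometry(),
                           noise_sd = 2, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_model"),
            inherits(geom, "camera_geometry"))
  sc <- visible_pixel_scene_coords(geom)
  a <- sample_plane_grid(phantom$absorptivity_map, phantom$xs, phantom$ys,
                         sc$x, sc$y, outside = NA)
  px <- matrix(235, nrow(a), ncol(a))            # light background
  inside <- !is.na(a)
  px[inside] <- 198 - 176 * a[inside]            # clay ~180, target ~40
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    px <- px + stats::rnorm(length(px), 0, noise_sd)
  }
  structure(matrix(as.integer(pmin(255, pmax(0, round(px)))),
                   nrow(px), ncol(px)),
            class = "visible_frame")
}

#' Render the thermal-camera frame of a temperature field
#'
#' Resamples the surface temperature field into the thermal sensor's
#' view — the visible-camera projection rescaled to the thermal sensor
#' size and shifted by the parallax offset — then adds Gaussian sensor
#' noise (sigma = NETD), an optional constant calibration bias within the
#' camera's accuracy, and quantizes linearly to 8 bits so the coldest
#' pixel maps to intensity 0 and the hottest to 255. The frame's noisy
#' extreme temperatures are recorded as the (Tmin, Tmax) metadata that a
#' radiometric camera reports with each image.
#'
#' A uniform field (Tmax = Tmin) cannot be quantized; such frames are
#' returned with `degenerate = TRUE`, all pixels at 0 and equal metadata.
#'
#' @param field A [temperature_field()].
#' @param phantom The [generate_phantom()] model (for the grid geometry
#'   and the ambient temperature seen outside the field).
#' @param geom A [camera_geometry()].
#' @param netd Sensor thermal sensitivity, K.
#' @param bias_c Constant radiometric bias, deg C (|bias| <= accuracy).
#' @param accuracy_c Stated radiometric accuracy, deg C.
#' @param seed Optional seed for the sensor noise.
#' @return An object of class `thermal_frame`: list with `pixels`
#'   (integer matrix in `[0, 255]`), `t_min`, `t_max` (deg C),
#'   `degenerate`, `netd`, `accuracy`.
#' @export
render_thermal <- function(field, phantom, geom = camera_geometry(),
                           netd = 0.065, bias_c = 0, accuracy_c = 2,
                           seed = NULL) {
  stopifnot(inherits(field, "temperature_field"),
            inherits(phantom, "phantom_model"),
            inherits(geom, "camera_geometry"),
            abs(bias_c) <= accuracy_c)
  tw <- geom$thermal_size[1]; th <- geom$thermal_size[2]
  sx <- tw / geom$visible_size[1]; sy <- th / geom$visible_size[2]
  u_t <- matrix(rep(seq_len(tw), each = th), th, tw)
  v_t <- matrix(rep(seq_len(th), tw), th, tw)
  # thermal pixel -> visible pixel -> scene mm
  u_v <- (u_t - geom$parallax_offset[1]) / sx
  v_v <- (v_t - geom$parallax_offset[2]) / sy
  sc <- apply_homography(geom$homography_inv, u_v, v_v)
  tm <- sample_plane_grid(field$temps, phantom$xs, phantom$ys,
                          sc$x, sc$y, outside = phantom$ambient_c)
  if (netd > 0) {
    if (!is.null(seed)) set.seed(seed)
    tm <- tm + stats::rnorm(length(tm), 0, netd)
  }
  tm <- tm + bias_c
  t_min <- min(tm); t_max <- max(tm)
  if (t_max - t_min < 1e-9) {
    return(structure(list(pixels = matrix(0L, th, tw), t_min = t_min,
                          t_max = t_min, degenerate = TRUE,
                          netd = netd, accuracy = accuracy_c),
                     class = "thermal_frame"))
  }
  px <- as.integer(round((tm - t_min) / (t_max - t_min) * 255))
  structure(list(pixels = matrix(px, th, tw), t_min = t_min, t_max = t_max,
                 degenerate = FALSE, netd = netd, accuracy = accuracy_c),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat("thermal_frame: ", nrow(x$pixels), " x ", ncol(x$pixels),
      " px, T in [", format(x$t_min, digits = 4), ", ",
      format(x$t_max, digits = 4), "] degC",
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}

#' Save a frame as PNG with a JSON metadata sidecar
#'
#' Thermal frames carry their (Tmin, Tmax) metadata in `<path>.json`,
#' emulating a camera API that returns an image plus a temperature query.
#' Requires the `png` package.
#'
#' @param frame A `visible_frame` or `thermal_frame`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG frames")
  px <- if (inherits(frame, "thermal_frame")) frame$pixels else unclass(frame)
  png::writePNG(px / 255, path)
  if (inherits(frame, "thermal_frame"))
    jsonlite::write_json(list(t_min = frame$t_min, t_max = frame$t_max,
                              netd = frame$netd, accuracy = frame$accuracy),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read an 8-bit grayscale image as a frame
#'
#' Accepts PNG (via the `png` package). RGB images are converted to
#' grayscale by channel averaging. If `<path>.json` exists, the image is
#' returned as a `thermal_frame` with its metadata; otherwise as a
#' `visible_frame`.
#'
#' @param path PNG path.
#' @return A `visible_frame` or `thermal_frame`.
#' @export
read_frame_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read PNG frames")
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
  px <- matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    structure(list(pixels = px, t_min = meta$t_min, t_max = meta$t_max,
                   degenerate = meta$t_max - meta$t_min < 1e-9,
                   netd = meta$netd %||% 0.065,
                   accuracy = meta$accuracy %||% 2),
              class = "thermal_frame")
  } else {
    structure(px, class = "visible_frame")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
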