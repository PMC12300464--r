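# Processing chain from camera frames to control inputs: segmentation,
# keystone (perspective) correction, reduction to the 30 x 30 scan
# matrix, parallax alignment of the thermal view, thermogram conversion
# and ROI statistics.

frame_pixels <- function(x) {
  if (inherits(x, "thermal_frame")) x$pixels
  else if (inherits(x, "visible_frame")) unclass(x)
  else as.matrix(x)
}

#' Otsu threshold of an 8-bit image
#'
#' @param px Integer matrix in `[0, 255]`.
#' @return Threshold intensity (pixels strictly below are "dark").
#' @export
otsu_threshold <- function(px) {
  px <- frame_pixels(px)
  EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1), levels = 256) * 255
}

#' Segment the dark target in a visible frame
#'
#' Inverse binary threshold (the absorbing target is darker than its
#' surroundings) followed by morphological closing to fill pinholes and a
#' Gaussian smoothing pass to regularize the contour.
#'
#' @param frame A `visible_frame` (or 8-bit matrix).
#' @param threshold `"otsu"` for an automatic threshold or a fixed
#'   intensity; pixels with intensity < threshold are selected.
#' @param close_kernel Side of the square closing kernel, px.
#' @param smooth_sigma Gaussian smoothing sigma, px (0 disables).
#' @return Binary mask (0/1 matrix) of the target.
#' @export
segment_visible <- function(frame, threshold = "otsu", close_kernel = 3,
                            smooth_sigma = 1) {
  px <- frame_pixels(frame)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(px) else threshold
  mask <- (px < thr) * 1
  if (close_kernel > 1)
    mask <- EBImage::closing(mask, EBImage::makeBrush(close_kernel, "box"))
  if (smooth_sigma > 0)
    mask <- (EBImage::gblur(mask, sigma = smooth_sigma) >= 0.5) * 1
  if (sum(mask) == 0)
    stop("no target found: segmentation produced an empty mask")
  mask
}

mask_centroid <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) stop("no connected component found")
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 1
}

order_corners <- function(pts) {
  # pts: matrix with columns x, y. Smallest x+y -> top-left, largest ->
  # bottom-right; largest x-y -> top-right, smallest -> bottom-left.
  # Deterministic tie-break by y then x.
  s <- pts[, 1] + pts[, 2]
  d <- pts[, 1] - pts[, 2]
  pick <- function(o) pts[o[1], ]
  tl <- pick(order(s, pts[, 2], pts[, 1]))
  br <- pick(order(-s, pts[, 2], pts[, 1]))
  tr <- pick(order(-d, pts[, 2], pts[, 1]))
  bl <- pick(order(d, pts[, 2], pts[, 1]))
  rbind(tl = tl, tr = tr, br = br, bl = bl)
}

quad_is_convex <- function(quad) {
  q <- rbind(quad, quad[1:2, , drop = FALSE])
  cr <- sapply(1:4, function(i) {
    a <- q[i + 1, ] - q[i, ]; b <- q[i + 2, ] - q[i + 1, ]
    a[1] * b[2] - a[2] * b[1]
  })
  all(cr > 0) || all(cr < 0)
}

#' Locate the maximum scan area in a frame
#'
#' Thresholds the frame (the scan-area plate is darker than the
#' background), keeps the largest connected component, and extracts its
#' four corner points, logically ordered top-left, top-right,
#' bottom-right, bottom-left so downstream perspective correction gets a
#' consistent correspondence.
#'
#' @param x A `visible_frame` (thresholded at `threshold`) or an
#'   already-binary mask of the area.
#' @param threshold Intensity threshold when `x` is a frame.
#' @return A 4 x 2 matrix of corner (x, y) pixel coordinates, class
#'   `quadrilateral`, rows ordered tl, tr, br, bl.
#' @export
find_scan_area <- function(x, threshold = 210) {
  mask <- if (all(x %in% c(0, 1))) as.matrix(x)
  else (frame_pixels(x) < threshold) * 1
  if (sum(mask) == 0) stop("scan area not detectable: empty mask")
  comp <- largest_component(mask)
  idx <- which(comp == 1, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  quad <- order_corners(pts)
  if (nrow(unique(quad)) < 4)
    stop("fewer than 4 distinct corner candidates in the scan-area contour")
  if (!quad_is_convex(quad))
    stop("scan-area corners do not form a convex quadrilateral")
  structure(quad, class = c("quadrilateral", class(quad)))
}

# inverse bilinear warp of img so that H(src) = dst grid, fill outside
warp_by_homography <- function(img, H_inv, out_w, out_h, fill = 0) {
  u <- matrix(rep(seq_len(out_w), each = out_h), out_h, out_w)
  v <- matrix(rep(seq_len(out_h), out_w), out_h, out_w)
  src <- apply_homography(H_inv, u, v)
  n_r <- nrow(img); n_c <- ncol(img)
  cj <- src$x; ri <- src$y
  out <- matrix(fill, out_h, out_w)
  ok <- cj >= 1 & cj <= n_c & ri >= 1 & ri <= n_r
  j0 <- pmin(pmax(floor(cj), 1), n_c - 1)
  i0 <- pmin(pmax(floor(ri), 1), n_r - 1)
  fx <- cj - j0; fy <- ri - i0
  g <- function(i, j) img[cbind(as.vector(i), as.vector(j))]
  val <- (1 - fx) * (1 - fy) * g(i0, j0) + fx * (1 - fy) * g(i0, j0 + 1) +
    (1 - fx) * fy * g(i0 + 1, j0) + fx * fy * g(i0 + 1, j0 + 1)
  out[ok] <- val[ok]
  out
}

#' Correct keystone (perspective) distortion
#'
#' Estimates the homography sending the detected scan-area quadrilateral
#' to an axis-aligned `out_size` rectangle and resamples the image with
#' projective bilinear interpolation, making the field edges parallel.
#'
#' @param img Numeric matrix (frame, mask or thermogram).
#' @param quad A `quadrilateral` from [find_scan_area()] (rows tl, tr,
#'   br, bl).
#' @param out_size (width, height) of the rectified image, px.
#' @param fill Value for pixels mapping outside the source image.
#' @return Rectified numeric matrix of size `out_size`.
#' @export
correct_keystone <- function(img, quad, out_size = c(180, 180), fill = 0) {
  quad <- as.matrix(quad)
  stopifnot(nrow(quad) == 4, ncol(quad) == 2)
  if (!quad_is_convex(quad))
    stop("cannot rectify: quadrilateral is not convex")
  w <- out_size[1]; h <- out_size[2]
  dst <- rbind(c(1, 1), c(w, 1), c(w, h), c(1, h))
  H <- homography_from_points(quad, dst)        # image -> rectangle
  warp_by_homography(as.matrix(img), solve(H), w, h, fill = fill)
}

# exact area-weighted resampling: overlap of source and target intervals
overlap_weights <- function(n_src, n_dst) {
  r <- n_src / n_dst
  W <- matrix(0, n_dst, n_src)
  for (d in seq_len(n_dst)) {
    lo <- (d - 1) * r; hi <- d * r
    s0 <- floor(lo) + 1; s1 <- ceiling(hi)
    for (s in s0:min(s1, n_src))
      W[d, s] <- max(0, min(hi, s) - max(lo, s - 1)) / r
  }
  W
}

#' Area-weighted image resize
#'
#' Each output pixel is the exact area average of the source pixels it
#' covers (the "area interpolation" used when reducing the rectified mask
#' to the scan matrix). Works for down- and up-scaling.
#'
#' @param img Numeric matrix.
#' @param out_w,out_h Output width (columns) and height (rows).
#' @return Resized matrix.
#' @export
area_resize <- function(img, out_w, out_h) {
  img <- as.matrix(img)
  Wr <- overlap_weights(nrow(img), out_h)
  Wc <- overlap_weights(ncol(img), out_w)
  Wr %*% img %*% t(Wc)
}

#' Reduce a rectified target mask to the 30 x 30 scan matrix
#'
#' Area-interpolated downscale to the scan-grid size, a small
#' morphological opening to drop isolated noise cells, then binarization
#' at the given occupancy fraction.
#'
#' @param rect Rectified mask (values in `[0, 1]`) cropped to the scan
#'   area.
#' @param n Scan-matrix side length.
#' @param open_kernel Side of the opening kernel (cells); 1 disables.
#' @param occupancy Minimum covered fraction for a cell to become 1.
#' @return A [scan_matrix()].
#' @export
to_scan_matrix <- function(rect, n = 30, open_kernel = 3, occupancy = 0.5) {
  occ <- area_resize(rect, n, n)
  if (open_kernel > 1)
    occ <- EBImage::opening(occ, EBImage::makeBrush(open_kernel, "box"))
  scan_matrix((occ >= occupancy) * 1)
}

# translate a matrix by (dx, dy) pixels, filling vacated pixels
shift_matrix <- function(m, dx, dy, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)); src_c <- seq_len(ncol(m))
  dst_r <- src_r + dy; dst_c <- src_c + dx
  keep_r <- dst_r >= 1 & dst_r <= nrow(m)
  keep_c <- dst_c >= 1 & dst_c <= ncol(m)
  out[dst_r[keep_r], dst_c[keep_c]] <- m[src_r[keep_r], src_c[keep_c]]
  out
}

#' Align the thermal view with the visible view (parallax correction)
#'
#' The thermal camera sits a few centimetres below the visible camera,
#' so the same scene appears displaced between the two sensors. The
#' correction computes the centroids of the segmented region of interest
#' in both (same-sized) views and shifts the thermal image by their
#' difference so the centroids coincide; the shifted content is clipped
#' to the image bounds, and a shift that would push the ROI fully out of
#' frame is an error.
#'
#' @param thermal A `thermal_frame`, or a numeric matrix (e.g. a
#'   thermogram), at the same pixel size as `visible_mask`.
#' @param thermal_mask Binary ROI mask segmented from the thermal view.
#' @param visible_mask Binary ROI mask from the visible view, rescaled to
#'   the thermal size.
#' @return A list: `frame` (same type as `thermal`, shifted), `mask`
#'   (shifted thermal mask), `shift` (applied integer (dx, dy)).
#' @export
correct_parallax <- function(thermal, thermal_mask, visible_mask) {
  if (sum(thermal_mask) == 0) stop("empty thermal ROI mask")
  if (sum(visible_mask) == 0) stop("empty visible ROI mask")
  shift <- round(mask_centroid(visible_mask) - mask_centroid(thermal_mask))
  apply_parallax_shift(thermal, thermal_mask, shift)
}

#' @rdname correct_parallax
#' @param shift Integer (dx, dy) to apply directly (e.g. a previously
#'   estimated shift when the current frame has too little thermal
#'   contrast to segment).
#' @export
apply_parallax_shift <- function(thermal, thermal_mask, shift) {
  px <- if (inherits(thermal, "thermal_frame")) thermal$pixels
  else as.matrix(thermal)
  stopifnot(all(dim(px) == dim(thermal_mask)))
  new_mask <- shift_matrix(thermal_mask, shift[1], shift[2], 0)
  if (sum(thermal_mask) > 0 && sum(new_mask) == 0)
    stop("parallax shift pushes the ROI fully outside the image")
  bg <- stats::median(px[thermal_mask == 0])
  out <- px
  out[thermal_mask == 1] <- bg               # vacate the original ROI
  shifted <- shift_matrix(px, shift[1], shift[2], bg)
  out[new_mask == 1] <- shifted[new_mask == 1]
  frame <- if (inherits(thermal, "thermal_frame")) {
    thermal$pixels <- out; thermal
  } else out
  list(frame = frame, mask = new_mask, shift = unname(shift))
}

#' Convert a quantized thermal frame to a thermogram
#'
#' Inverts the camera's linear intensity coding using the per-frame
#' metadata:
#' `T = (Tmax - Tmin) / (Imax - Imin) * (I - Imin) + Tmin`,
#' where Imin and Imax are the frame's observed extreme intensities, so
#' the coldest pixel maps exactly to Tmin and the hottest to Tmax. A
#' degenerate frame (no intensity spread) yields a uniform thermogram at
#' Tmin with a warning.
#'
#' @param frame A `thermal_frame`.
#' @return An object of class `thermogram`: list with `temps` (deg C
#'   matrix), `t_min`, `t_max`.
#' @export
to_thermogram <- function(frame) {
  stopifnot(inherits(frame, "thermal_frame"))
  px <- frame$pixels
  i_min <- min(px); i_max <- max(px)
  if (frame$degenerate || i_max == i_min) {
    warning("degenerate thermal frame: returning uniform thermogram")
    temps <- matrix(frame$t_min, nrow(px), ncol(px))
  } else {
    temps <- (frame$t_max - frame$t_min) / (i_max - i_min) *
      (px - i_min) + frame$t_min
  }
  structure(list(temps = temps, t_min = frame$t_min, t_max = frame$t_max),
            class = "thermogram")
}

#' Temperature statistics over a region of interest
#'
#' @param x A `thermogram`, or a numeric temperature matrix.
#' @param mask Binary mask of the ROI, same dimensions as the
#'   temperature grid (a [scan_matrix()] for grid-level statistics).
#' @return A list of class `roi_stats`: `mean`, `max`, `min` (deg C) and
#'   `n` (pixel count).
#' @export
roi_stats <- function(x, mask) {
  temps <- if (inherits(x, "thermogram")) x$temps else as.matrix(x)
  mask <- unclass(as.matrix(mask))
  stopifnot(all(dim(temps) == dim(mask)))
  sel <- temps[mask == 1]
  if (length(sel) == 0) stop("empty ROI mask")
  structure(list(mean = mean(sel), max = max(sel), min = min(sel),
                 n = length(sel)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI: mean %.2f, min %.2f, max %.2f degC over %d px\n",
              x$mean, x$min, x$max, x$n))
  invisible(x)
}

#' Jaccard index between two binary masks
#'
#' @param a,b 0/1 matrices of equal size.
#' @return Intersection over union.
#' @export
jaccard <- function(a, b) {
  a <- unclass(as.matrix(a)) == 1; b <- unclass(as.matrix(b)) == 1
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
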