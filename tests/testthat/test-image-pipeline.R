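make_disk_frame <- function(size = 120, r = 25, bg = 220, fg = 40,
                            cx = size / 2, cy = size / 2) {
  d2 <- outer(seq_len(size), seq_len(size),
              function(i, j) (j - cx)^2 + (i - cy)^2)
  px <- matrix(bg, size, size)
  px[d2 <= r^2] <- fg
  structure(matrix(as.integer(px), size, size), class = "visible_frame")
}

test_that("segmentation isolates a dark disk and rejects blank frames", {
  fr <- make_disk_frame()
  mask <- segment_visible(fr, threshold = 128, smooth_sigma = 0)
  truth <- (unclass(fr) < 128) * 1
  expect_lt(abs(sum(mask) - sum(truth)), 2 * pi * 25 * 3)  # kernel-band slack
  expect_gt(jaccard(mask, truth), 0.95)

  blank <- structure(matrix(255L, 50, 50), class = "visible_frame")
  expect_error(segment_visible(blank), "no target found")
})

test_that("closing fills a one-pixel hole inside the target", {
  fr <- make_disk_frame()
  px <- unclass(fr); px[60, 60] <- 255L   # inject pinhole
  fr2 <- structure(px, class = "visible_frame")
  mask <- segment_visible(fr2, threshold = 128, smooth_sigma = 0)
  expect_identical(mask[60, 60], 1)
})

test_that("scan-area corners of an axis-aligned square are exact", {
  m <- matrix(0, 100, 100); m[21:80, 31:90] <- 1
  quad <- find_scan_area(m)
  expect_equal(unclass(quad),
               rbind(c(31, 21), c(90, 21), c(90, 80), c(31, 80)),
               ignore_attr = TRUE)
})

test_that("corners of a keystone-warped square match the known homography", {
  # rasterize the warped square analytically: pixel centers inside the
  # projected quadrilateral
  true_corners <- rbind(c(-25, 25), c(25, 25), c(25, -25), c(-25, -25))
  geom <- camera_geometry()   # known tilt
  mapped <- apply_homography(geom$homography,
                             true_corners[, 1], true_corners[, 2])
  qx <- mapped$x; qy <- mapped$y
  inside <- matrix(TRUE, 192, 192)
  for (k in 1:4) {
    k2 <- k %% 4 + 1
    ex <- qx[k2] - qx[k]; ey <- qy[k2] - qy[k]
    cross <- outer(seq_len(192), seq_len(192),
                   function(i, j) ex * (i - qy[k]) - ey * (j - qx[k]))
    inside <- inside & (cross >= 0)
  }
  quad <- find_scan_area(inside * 1)
  expect_lt(max(abs(quad[, 1] - qx), abs(quad[, 2] - qy)), 1)

  # the rendered-camera path locates the same corners to pixel accuracy
  ph <- uniform_phantom(absorptivity = 0.9)
  fr <- render_visible(ph, geom, noise_sd = 0)
  quad2 <- find_scan_area(fr, threshold = 128)
  expect_lt(max(abs(quad2[, 1] - qx), abs(quad2[, 2] - qy)), 2.5)
})

test_that("corner ordering does not depend on pixel enumeration order", {
  m <- matrix(0, 80, 80); m[11:60, 16:65] <- 1
  q1 <- find_scan_area(m)
  q2 <- find_scan_area(m[rev(seq_len(80)), ] |> apply(2, rev) |> t() |> t())
  # same square re-stored; corners must come out in the same canonical order
  expect_identical(rownames(q1), c("tl", "tr", "br", "bl"))
  expect_identical(unclass(q1), unclass(find_scan_area(m)))
})

test_that("rectifying an already-rectangular region is the identity", {
  fr <- make_disk_frame()
  quad <- rbind(c(1, 1), c(120, 1), c(120, 120), c(1, 120))
  rect <- correct_keystone(unclass(fr), quad, out_size = c(120, 120))
  inner <- 5:116
  expect_lt(mean(abs(rect[inner, inner] - unclass(fr)[inner, inner])), 2)
})

test_that("rectified tilted view matches an untilted rendering", {
  ph <- generate_phantom(blob_spec(seed = 6))
  tilted <- camera_geometry()
  fr <- render_visible(ph, tilted, noise_sd = 0)
  quad <- find_scan_area(fr, threshold = 210)
  rect <- correct_keystone(unclass(fr), quad, out_size = c(180, 180))
  straight <- render_visible(ph, affine_field_geom(), noise_sd = 0)
  inner <- 10:171                             # away from borders
  expect_lt(mean(abs(rect[inner, inner] -
                       unclass(straight)[inner, inner])), 2)
})

test_that("rectification maps scene lines to straight lines", {
  geom <- camera_geometry()
  ph <- uniform_phantom(absorptivity = 0.9)
  fr <- render_visible(ph, geom, noise_sd = 0)
  quad <- find_scan_area(fr, threshold = 128)
  w <- 180
  H_rect <- homography_from_points(as.matrix(quad),
                                   rbind(c(1, 1), c(w, 1), c(w, w), c(1, w)))
  # a diagonal line across the scene, through camera then rectification
  t <- seq(-20, 20, length.out = 21)
  cam <- apply_homography(geom$homography, t, 0.5 * t + 3)
  rect <- apply_homography(H_rect, cam$x, cam$y)
  fit <- lm(rect$y ~ rect$x)
  expect_lt(max(abs(residuals(fit))), 0.5)
})

test_that("keystone correction preserves the covered area fraction", {
  # disk inside a mildly keystoned quadrilateral
  size <- 150
  quad <- rbind(c(20, 15), c(135, 22), c(140, 140), c(12, 133))
  mask <- matrix(0, size, size)
  d2 <- outer(seq_len(size), seq_len(size),
              function(i, j) (j - 75)^2 + (i - 78)^2)
  mask[d2 <= 30^2] <- 1
  rect <- correct_keystone(mask, quad, out_size = c(120, 120))
  frac_after <- mean(rect >= 0.5)
  shoelace <- function(q) abs(sum(q[, 1] * q[c(2:4, 1), 2] -
                                    q[c(2:4, 1), 1] * q[, 2])) / 2
  frac_before <- (pi * 30^2) / shoelace(quad)
  expect_lt(abs(frac_after - frac_before) / frac_before, 0.03)
})

test_that("non-convex quadrilaterals are rejected", {
  bad <- rbind(c(1, 1), c(100, 1), c(20, 30), c(1, 100))
  expect_error(correct_keystone(matrix(0, 120, 120), bad), "convex")
})

test_that("scan-matrix reduction binarizes by cell occupancy", {
  expect_identical(sum(to_scan_matrix(matrix(1, 180, 180))), 900L)
  # dark square covering exactly cells 10..20 (6 px per cell at 180 px)
  rect <- matrix(0, 180, 180)
  rect[(9 * 6 + 1):(20 * 6), (9 * 6 + 1):(20 * 6)] <- 1
  sm <- to_scan_matrix(rect)
  truth <- matrix(0L, 30, 30); truth[10:20, 10:20] <- 1L
  expect_identical(unclass(sm), truth)
})

test_that("pipeline recovers the true mask across seeded scenes", {
  jac <- vapply(1:5, function(s) {
    ph <- generate_phantom(blob_spec(seed = s))
    geom <- camera_geometry()
    fr <- render_visible(ph, geom, noise_sd = 2, seed = s)
    seg <- segment_visible(fr, threshold = 100)
    quad <- find_scan_area(fr, threshold = 210)
    rect <- correct_keystone(seg, quad, out_size = c(180, 180))
    jaccard(to_scan_matrix(rect), truth_scan_matrix(ph))
  }, numeric(1))
  expect_true(all(jac >= 0.85))
})

test_that("parallax correction recovers an injected shift", {
  base <- matrix(0, 100, 100)
  d2 <- outer(1:100, 1:100, function(i, j) (j - 50)^2 + (i - 40)^2)
  vmask <- (d2 <= 15^2) * 1
  # thermal view: same blob, 12 px lower
  tmask <- shiftd <- matrix(0, 100, 100)
  tmask[13:100, ] <- vmask[1:88, ]
  tfield <- 23 + 20 * tmask
  res <- correct_parallax(tfield, tmask, vmask)
  expect_equal(res$shift, c(0, -12))
  cv <- c(mean(which(vmask == 1, arr.ind = TRUE)[, 2]),
          mean(which(vmask == 1, arr.ind = TRUE)[, 1]))
  cm <- c(mean(which(res$mask == 1, arr.ind = TRUE)[, 2]),
          mean(which(res$mask == 1, arr.ind = TRUE)[, 1]))
  expect_lt(max(abs(cv - cm)), 1)
  # hot pixels moved with the mask
  expect_gt(mean(res$frame[res$mask == 1]), 40)

  # zero offset is the identity
  res0 <- correct_parallax(tfield, tmask, tmask)
  expect_equal(res0$shift, c(0, 0))
  expect_equal(res0$frame, tfield)

  expect_error(correct_parallax(tfield, matrix(0, 100, 100), vmask), "empty")
  expect_error(apply_parallax_shift(tfield, tmask, c(500, 500)),
               "outside the image")
})

test_that("thermogram conversion inverts the linear intensity coding", {
  px <- matrix(c(10L, 110L, 210L, 60L), 2, 2)
  fr <- make_thermal_frame(px, t_min = 20, t_max = 60)
  th <- to_thermogram(fr)
  expect_equal(th$temps[1, 1], 20)        # Imin -> Tmin
  expect_equal(th$temps[1, 2], 60)        # Imax -> Tmax
  expect_equal(th$temps[2, 1], 40)        # midpoint intensity
  # exact linearity in intensity
  a <- (60 - 20) / (210 - 10)
  expect_equal(th$temps, a * (px - 10) + 20, ignore_attr = TRUE)

  degen <- make_thermal_frame(matrix(0L, 2, 2), 25, 25)
  expect_warning(thd <- to_thermogram(degen), "degenerate")
  expect_equal(thd$temps, matrix(25, 2, 2))
})

test_that("ROI statistics match a brute-force loop", {
  expect_equal(roi_stats(matrix(42, 4, 4), matrix(1, 4, 4))$mean, 42)
  two <- matrix(c(40, 44, 0, 0), 2, 2)
  msk <- matrix(c(1, 1, 0, 0), 2, 2)
  st <- roi_stats(two, msk)
  expect_equal(c(st$mean, st$min, st$max, st$n), c(42, 40, 44, 2))

  set.seed(9)
  temps <- matrix(runif(900, 20, 60), 30, 30)
  mask <- matrix(rbinom(900, 1, 0.3), 30, 30)
  st2 <- roi_stats(temps, mask)
  vals <- c()
  for (i in 1:30) for (j in 1:30) if (mask[i, j] == 1)
    vals <- c(vals, temps[i, j])
  expect_equal(st2$mean, mean(vals))
  expect_equal(st2$max, max(vals))
  expect_equal(st2$min, min(vals))
  expect_error(roi_stats(temps, matrix(0, 30, 30)), "empty ROI")
})
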