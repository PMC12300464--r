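# Geometry of the two-mirror galvanometric scanner: matrix cells <->
# target-plane coordinates <-> optical/mechanical scan angles <-> command
# voltages <-> DAC codes.

#' Galvanometer and DAC configuration
#'
#' Bundles the geometric and electrical constants of the two-mirror
#' scanner: the mirror-to-target distance, the inter-mirror offset, the
#' servo scale factor relating command voltage to mechanical angle, the
#' optical-to-mechanical angle ratio, and the resolution and output range
#' of the digital-to-analog converter driving the servo amplifiers.
#'
#' @param d_mm Distance from the second mirror to the target plane, mm.
#' @param e_mm Offset between the two mirror pivots, mm.
#' @param s_v_per_deg Servo scale factor, volts per degree of
#'   *mechanical* mirror angle.
#' @param optical_per_mechanical Ratio of optical beam deflection to
#'   mechanical mirror rotation. For a mirror the reflected beam turns
#'   twice as fast as the mirror, so 2 is the conventional value.
#' @param n_bits DAC resolution in bits.
#' @param v_min,v_max DAC output range, volts (bipolar by default).
#' @param max_step_rate Largest optical-angle change the galvo can follow
#'   in one voltage update, degrees per millisecond. Used by
#'   [check_slew()] only; it does not alter any mapping.
#'
#' @return An object of class `galvo_config`.
#' @export
#' @examples
#' cfg <- galvo_config()
#' angle_to_voltage(scan_angles(10, 0), cfg)
galvo_config <- function(d_mm = 150, e_mm = 10, s_v_per_deg = 0.5,
                         optical_per_mechanical = 2,
                         n_bits = 12L, v_min = -20, v_max = 20,
                         max_step_rate = 40) {
  stopifnot(d_mm > 0, e_mm >= 0, v_min < v_max, n_bits >= 1,
            optical_per_mechanical > 0, s_v_per_deg > 0, max_step_rate > 0)
  structure(list(d_mm = d_mm, e_mm = e_mm, s_v_per_deg = s_v_per_deg,
                 optical_per_mechanical = optical_per_mechanical,
                 n_bits = as.integer(n_bits), v_min = v_min, v_max = v_max,
                 max_step_rate = max_step_rate),
            class = "galvo_config")
}

#' Scan grid specification
#'
#' The treatment field is discretized into an `n_rows` x `n_cols` matrix
#' of cells with pitch `pitch_mm` between neighbouring cell centers. The
#' default 30 x 30 grid over a 5 x 5 cm field gives a cell pitch of
#' 50/30 = 1.67 mm.
#'
#' @param n_rows,n_cols Matrix dimensions.
#' @param pitch_mm Distance between adjacent cell centers, mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows = 30L, n_cols = 30L, pitch_mm = 50 / 30) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch_mm > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch_mm = pitch_mm),
            class = "grid_spec")
}

#' A pair of optical scan angles
#'
#' @param theta_x,theta_y Optical deflection angles in degrees; each must
#'   lie strictly within (-90, 90).
#' @return An object of class `scan_angles`.
#' @export
scan_angles <- function(theta_x, theta_y) {
  stopifnot(is.numeric(theta_x), is.numeric(theta_y),
            length(theta_x) == length(theta_y),
            all(is.finite(theta_x)), all(is.finite(theta_y)),
            all(abs(theta_x) < 90), all(abs(theta_y) < 90))
  structure(list(theta_x = theta_x, theta_y = theta_y),
            class = "scan_angles")
}

#' A point on the target plane
#'
#' Cartesian coordinates in millimetres with the origin at the center of
#' the maximum scan area; x grows to the right, y upward.
#'
#' @param x,y Coordinates, mm.
#' @return An object of class `plane_point`.
#' @export
plane_point <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)))
  structure(list(x = x, y = y), class = "plane_point")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Map matrix cells to target-plane coordinates
#'
#' Converts 1-based (row, column) indices of the scan matrix into the
#' Cartesian coordinates of the corresponding cell center:
#' `x = (nc - (n_cols + 1)/2) * pitch`, `y = -(nr - (n_rows + 1)/2) * pitch`.
#' For the default 30 x 30 grid the centering constant is 15.5, so row 1 /
#' column 1 is the top-left cell at (-24.17, +24.17) mm.
#'
#' @param nr,nc 1-based row and column indices (vectors allowed).
#' @param grid A [grid_spec()].
#' @return A [plane_point()] with one entry per input index.
#' @export
grid_to_plane <- function(nr, nc, grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"), length(nr) == length(nc))
  if (any(nr < 1 | nr > grid$n_rows))
    stop("row index out of range [1, ", grid$n_rows, "]: ",
         nr[which(nr < 1 | nr > grid$n_rows)[1]])
  if (any(nc < 1 | nc > grid$n_cols))
    stop("column index out of range [1, ", grid$n_cols, "]: ",
         nc[which(nc < 1 | nc > grid$n_cols)[1]])
  cr <- (grid$n_rows + 1) / 2
  cc <- (grid$n_cols + 1) / 2
  plane_point(x = (nc - cc) * grid$pitch_mm,
              y = -(nr - cr) * grid$pitch_mm)
}

#' Project scan angles onto the target plane
#'
#' Forward model of the two-mirror deflection geometry. The y mirror sits
#' a distance `d` from the target; the x mirror is offset by `e` behind
#' it, so its lever arm grows with the y deflection:
#' `y = d * tan(theta_y)`, `x = (sqrt(d^2 + y^2) + e) * tan(theta_x)`.
#'
#' @param angles A [scan_angles()] (optical angles, degrees).
#' @param cfg A [galvo_config()].
#' @return A [plane_point()].
#' @export
angles_to_plane <- function(angles, cfg = galvo_config()) {
  stopifnot(inherits(angles, "scan_angles"), inherits(cfg, "galvo_config"))
  y <- cfg$d_mm * tan(deg2rad(angles$theta_y))
  x <- (sqrt(cfg$d_mm^2 + y^2) + cfg$e_mm) * tan(deg2rad(angles$theta_x))
  plane_point(x, y)
}

#' Optical scan angles reaching a target-plane point
#'
#' Closed-form inverse of [angles_to_plane()]:
#' `theta_y = atan(y / d)`, `theta_x = atan(x / (sqrt(d^2 + y^2) + e))`.
#' The round trip through [angles_to_plane()] reproduces the point to
#' numerical precision.
#'
#' @param p A [plane_point()].
#' @param cfg A [galvo_config()].
#' @return A [scan_angles()].
#' @export
plane_to_angles <- function(p, cfg = galvo_config()) {
  stopifnot(inherits(p, "plane_point"), inherits(cfg, "galvo_config"))
  theta_y <- atan2(p$y, cfg$d_mm)
  theta_x <- atan2(p$x, sqrt(cfg$d_mm^2 + p$y^2) + cfg$e_mm)
  scan_angles(rad2deg(theta_x), rad2deg(theta_y))
}

#' Convert optical scan angles to DAC command voltages
#'
#' The servo amplifier expects `V = s * theta_m` where `theta_m` is the
#' *mechanical* mirror angle; the optical angle is divided by the
#' optical-to-mechanical ratio first. Voltages outside the DAC output
#' range are an error naming the saturated axis.
#'
#' @param angles A [scan_angles()] (optical angles, degrees).
#' @param cfg A [galvo_config()].
#' @return A list with numeric vectors `vx` and `vy`, volts.
#' @export
angle_to_voltage <- function(angles, cfg = galvo_config()) {
  stopifnot(inherits(angles, "scan_angles"), inherits(cfg, "galvo_config"))
  vx <- cfg$s_v_per_deg * angles$theta_x / cfg$optical_per_mechanical
  vy <- cfg$s_v_per_deg * angles$theta_y / cfg$optical_per_mechanical
  if (any(vx < cfg$v_min | vx > cfg$v_max))
    stop("x-axis command voltage saturates the DAC range [",
         cfg$v_min, ", ", cfg$v_max, "] V")
  if (any(vy < cfg$v_min | vy > cfg$v_max))
    stop("y-axis command voltage saturates the DAC range [",
         cfg$v_min, ", ", cfg$v_max, "] V")
  list(vx = vx, vy = vy)
}

#' Quantize a command voltage to a DAC code
#'
#' `D = round(((V - Vmin) / (Vmax - Vmin)) * (2^N - 1))` with round-half-up
#' rounding, so the endpoints of the output range map exactly to 0 and
#' `2^N - 1` and the map is monotone in V.
#'
#' @param v Voltage(s) within `[v_min, v_max]`.
#' @param cfg A [galvo_config()].
#' @return Integer code(s) in `[0, 2^n_bits - 1]`.
#' @export
voltage_to_dac_code <- function(v, cfg = galvo_config()) {
  stopifnot(inherits(cfg, "galvo_config"), is.numeric(v), all(is.finite(v)))
  if (any(v < cfg$v_min | v > cfg$v_max))
    stop("voltage outside DAC range [", cfg$v_min, ", ", cfg$v_max, "] V: ",
         v[which(v < cfg$v_min | v > cfg$v_max)[1]])
  full <- 2^cfg$n_bits - 1
  frac <- (v - cfg$v_min) / (cfg$v_max - cfg$v_min)
  as.integer(floor(frac * full + 0.5))  # round half up
}

#' @export
print.galvo_config <- function(x, ...) {
  cat("Galvo scanner configuration\n",
      "  target distance d = ", x$d_mm, " mm, mirror offset e = ",
      x$e_mm, " mm\n",
      "  servo scale s = ", x$s_v_per_deg, " V/deg (mechanical), ",
      "optical/mechanical = ", x$optical_per_mechanical, "\n",
      "  DAC: ", x$n_bits, " bits over [", x$v_min, ", ", x$v_max, "] V\n",
      "  slew limit: ", x$max_step_rate, " deg (optical) per ms\n", sep = "")
  invisible(x)
}
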