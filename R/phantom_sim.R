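# Synthetic absorbing phantom: an irregular dark target on a clay slab,
# heated by the scanned Gaussian laser spot and evolved with an explicit
# 2-D finite-difference heat model.

#' Specification of an irregular target blob
#'
#' Generates the geometry of a dark, highly absorbing target: a union of
#' overlapping disks ("lobes") whose centers cluster around a common
#' point, giving the kind of irregular outline skin lesions have. All
#' lobes overlap the first one, so the resulting mask is connected.
#'
#' @param seed RNG seed; the phantom is a pure function of these
#'   parameters.
#' @param n_lobes Number of disks in the union.
#' @param radius_mm Length-2 range from which lobe radii are drawn, mm.
#' @param center_jitter_mm Maximum displacement of the blob center from
#'   the field center, mm.
#' @return An object of class `blob_spec`.
#' @export
blob_spec <- function(seed = 1L, n_lobes = 3L, radius_mm = c(6, 10),
                      center_jitter_mm = 4) {
  stopifnot(length(radius_mm) == 2, all(radius_mm > 0),
            radius_mm[1] <= radius_mm[2], n_lobes >= 1,
            center_jitter_mm >= 0)
  structure(list(seed = as.integer(seed), n_lobes = as.integer(n_lobes),
                 radius_mm = radius_mm, center_jitter_mm = center_jitter_mm),
            class = "blob_spec")
}

#' Build a synthetic clay phantom with an absorbing target
#'
#' Discretizes the square treatment field into `n_cells` x `n_cells`
#' surface cells and assigns each an optical absorptivity: high inside
#' the generated blob, low on the surrounding clay. Thermophysical
#' parameters default to generic modelling-clay values; they are
#' configurable because the real material's properties are not tabulated.
#'
#' @param spec A [blob_spec()].
#' @param field_mm Side length of the treatment field, mm.
#' @param n_cells Cells per side of the simulation grid.
#' @param absorptivity_in,absorptivity_out Absorbed power fraction inside
#'   and outside the target.
#' @param thickness_mm Slab thickness, mm.
#' @param density Density, kg/m^3.
#' @param heat_capacity Specific heat, J/(kg K).
#' @param conductivity Thermal conductivity, W/(m K).
#' @param h_conv Linearized convective + radiative surface loss
#'   coefficient, W/(m^2 K).
#' @param emissivity Surface emissivity (metadata for the thermal
#'   camera; losses are folded into `h_conv`).
#' @param ambient_c Ambient temperature, deg C.
#' @return An object of class `phantom_model` with fields
#'   `absorptivity_map` (matrix, row 1 = top of field), `truth_mask`
#'   (the generated blob as a 0/1 matrix), the thermophysical constants,
#'   and the grid geometry (`field_mm`, `res_mm`, cell center coordinate
#'   vectors `xs`, `ys`).
#' @export
generate_phantom <- function(spec = blob_spec(), field_mm = 50,
                             n_cells = 60L,
                             absorptivity_in = 0.9, absorptivity_out = 0.1,
                             thickness_mm = 5, density = 1600,
                             heat_capacity = 1000, conductivity = 0.6,
                             h_conv = 15, emissivity = 0.95,
                             ambient_c = 23) {
  stopifnot(inherits(spec, "blob_spec"), field_mm > 0, n_cells >= 4,
            absorptivity_in >= 0, absorptivity_in <= 1,
            absorptivity_out >= 0, absorptivity_out <= 1)
  res <- field_mm / n_cells
  # cell centers; row index grows downward (y decreases), matching images
  xs <- (seq_len(n_cells) - (n_cells + 1) / 2) * res
  ys <- -(seq_len(n_cells) - (n_cells + 1) / 2) * res

  rng <- local({
    set.seed(spec$seed)
    jit <- stats::runif(2, -spec$center_jitter_mm, spec$center_jitter_mm)
    radii <- stats::runif(spec$n_lobes, spec$radius_mm[1], spec$radius_mm[2])
    if (any(radii <= 0)) stop("degenerate blob spec: zero lobe radius")
    offs <- matrix(0, spec$n_lobes, 2)
    if (spec$n_lobes > 1) {
      ang <- stats::runif(spec$n_lobes - 1, 0, 2 * pi)
      dist <- stats::runif(spec$n_lobes - 1, 0, 0.7 * radii[1])
      offs[-1, ] <- cbind(dist * cos(ang), dist * sin(ang))
    }
    list(centers = cbind(jit[1] + offs[, 1], jit[2] + offs[, 2]),
         radii = radii)
  })
  mask <- matrix(0L, n_cells, n_cells)
  for (l in seq_len(spec$n_lobes)) {
    d2 <- outer(ys - rng$centers[l, 2], xs - rng$centers[l, 1],
                function(dy, dx) dx^2 + dy^2)
    mask[d2 <= rng$radii[l]^2] <- 1L
  }
  amap <- matrix(absorptivity_out, n_cells, n_cells)
  amap[mask == 1L] <- absorptivity_in

  structure(list(absorptivity_map = amap, truth_mask = mask,
                 lobes = rng, field_mm = field_mm, n_cells = n_cells,
                 res_mm = res, xs = xs, ys = ys,
                 thickness_mm = thickness_mm, density = density,
                 heat_capacity = heat_capacity, conductivity = conductivity,
                 h_conv = h_conv, emissivity = emissivity,
                 ambient_c = ambient_c),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("phantom_model: ", x$n_cells, " x ", x$n_cells, " cells over ",
      x$field_mm, " x ", x$field_mm, " mm; target covers ",
      sum(x$truth_mask), " cells\n", sep = "")
  invisible(x)
}

#' Laser beam parameters
#'
#' @param power_max_w Maximum optical output power, W.
#' @param power_fraction Commanded power as a fraction of maximum.
#' @param spot_diameter_mm Beam diameter at the target (interpreted as the
#'   1/e^2 width of the Gaussian profile, so sigma = diameter / 4).
#' @return An object of class `laser_beam`.
#' @export
laser_beam <- function(power_max_w = 2, power_fraction = 1,
                       spot_diameter_mm = 5) {
  stopifnot(power_max_w > 0, power_fraction >= 0, power_fraction <= 1,
            spot_diameter_mm > 0)
  structure(list(power_max_w = power_max_w, power_fraction = power_fraction,
                 spot_diameter_mm = spot_diameter_mm, sigma_mm =
                   spot_diameter_mm / 4),
            class = "laser_beam")
}

#' Surface temperature field
#'
#' @param temps Matrix of temperatures, deg C (row 1 = top of field).
#' @param time_s Simulation time attached to the field, s.
#' @return An object of class `temperature_field`.
#' @export
temperature_field <- function(temps, time_s = 0) {
  stopifnot(is.matrix(temps), all(is.finite(temps)))
  structure(list(temps = temps, time_s = time_s),
            class = "temperature_field")
}

#' Cycle-averaged absorbed power map for a scan path
#'
#' Each dwell of the raster path deposits one Gaussian spot of energy
#' `power_max * power_fraction * dt` at the corresponding cell center;
#' the spot is discretized on the phantom grid (separable Gaussian,
#' normalized to conserve energy on the grid) and weighted by the local
#' absorptivity. Because one scan cycle (~1 s) is much shorter than the
#' phantom's thermal response, the moving spot is replaced by its
#' time-average over a cycle: the returned map is absorbed power in watts
#' per phantom cell, with total at most
#' `power_max * power_fraction`.
#'
#' @param path A [scan_path()].
#' @param beam A [laser_beam()]. `power_fraction` scales the map
#'   linearly, so a unit-power map can be computed once and rescaled.
#' @param phantom A [phantom_model()][generate_phantom].
#' @param grid The [grid_spec()] the path indices refer to.
#' @return Matrix of absorbed power, W per cell, dimensioned like the
#'   phantom grid.
#' @export
deposit_cycle_fluence <- function(path, beam, phantom, grid = grid_spec()) {
  stopifnot(inherits(path, "scan_path"), inherits(beam, "laser_beam"),
            inherits(phantom, "phantom_model"))
  p <- grid_to_plane(path$visits[, "row"], path$visits[, "col"], grid)
  s2 <- 2 * beam$sigma_mm^2
  # separable Gaussian weights, each dwell normalized to unit energy
  wx <- exp(-outer(phantom$xs, p$x, "-")^2 / s2)   # n_cells x k
  wy <- exp(-outer(phantom$ys, p$y, "-")^2 / s2)
  wx <- sweep(wx, 2, colSums(wx), "/")
  wy <- sweep(wy, 2, colSums(wy), "/")
  energy_per_dwell <- beam$power_max_w * beam$power_fraction *
    path$dt_ms / 1000
  energy <- (wy %*% t(wx)) * energy_per_dwell      # J per cell per cycle
  energy * phantom$absorptivity_map / (path$cycle_time_ms / 1000)
}

heat_stability_bound <- function(phantom) {
  alpha <- phantom$conductivity / (phantom$density * phantom$heat_capacity)
  dx <- phantom$res_mm / 1000
  dx^2 / (4 * alpha)
}

#' Advance the surface temperature field by one explicit time step
#'
#' Explicit finite-difference update of the 2-D heat equation on the
#' phantom surface with zero-flux lateral boundaries:
#' `dT/dt = alpha * lap(T) + Q / (rho c V_cell) - h (T - T_amb) / (rho c L)`
#' where `Q` is the absorbed power per cell, `V_cell` the cell volume and
#' `L` the slab thickness. The step is rejected if `dt_s` exceeds the
#' explicit-scheme stability bound `dx^2 / (4 alpha)`.
#'
#' @param field A [temperature_field()].
#' @param source Absorbed power map, W per cell (e.g. from
#'   [deposit_cycle_fluence()]), or `NULL`/0 for free cooling.
#' @param phantom A [phantom_model()][generate_phantom].
#' @param dt_s Time step, s.
#' @return The updated [temperature_field()].
#' @export
step_heat <- function(field, source, phantom, dt_s) {
  stopifnot(inherits(field, "temperature_field"),
            inherits(phantom, "phantom_model"), dt_s > 0)
  bound <- heat_stability_bound(phantom)
  if (dt_s > bound)
    stop(sprintf(
      "unstable time step: dt = %.4g s exceeds the explicit bound %.4g s",
      dt_s, bound))
  tm <- field$temps
  n <- nrow(tm)
  stopifnot(n == phantom$n_cells, ncol(tm) == phantom$n_cells)
  dx <- phantom$res_mm / 1000
  alpha <- phantom$conductivity / (phantom$density * phantom$heat_capacity)
  # 5-point Laplacian with reflected (zero-flux) boundaries
  up    <- tm[c(1, seq_len(n - 1)), ]
  down  <- tm[c(seq_len(n - 1) + 1, n), ]
  left  <- tm[, c(1, seq_len(n - 1))]
  right <- tm[, c(seq_len(n - 1) + 1, n)]
  lap <- (up + down + left + right - 4 * tm) / dx^2

  rc <- phantom$density * phantom$heat_capacity
  thick <- phantom$thickness_mm / 1000
  heat <- if (is.null(source)) 0 else source / (rc * thick * dx^2)
  loss <- phantom$h_conv * (tm - phantom$ambient_c) / (rc * thick)
  temperature_field(tm + dt_s * (alpha * lap + heat - loss),
                    time_s = field$time_s + dt_s)
}

#' Advance the temperature field over a longer interval
#'
#' Splits `duration_s` into equal steps no longer than `safety` times the
#' explicit stability bound and applies [step_heat()] repeatedly with a
#' constant source map.
#'
#' @inheritParams step_heat
#' @param duration_s Interval to simulate, s.
#' @param safety Fraction of the stability bound to use per step.
#' @return The updated [temperature_field()].
#' @export
advance_heat <- function(field, source, phantom, duration_s, safety = 0.8) {
  stopifnot(duration_s > 0, safety > 0, safety <= 1)
  n_steps <- max(1L, ceiling(duration_s / (safety *
                                             heat_stability_bound(phantom))))
  dt <- duration_s / n_steps
  for (i in seq_len(n_steps)) field <- step_heat(field, source, phantom, dt)
  field
}

#' Simulate the physically moving laser spot
#'
#' Reference mode for validating the cycle-averaged approximation used by
#' [deposit_cycle_fluence()]: the beam dwells on each path cell in turn,
#' each dwell advancing the heat model by the dwell time with a single
#' stationary Gaussian spot. Orders of magnitude slower than the averaged
#' mode; intended for short validation runs on small grids.
#'
#' @inheritParams deposit_cycle_fluence
#' @param field Starting [temperature_field()].
#' @param n_cycles Number of full scan cycles to simulate.
#' @return The final [temperature_field()].
#' @export
advance_heat_moving <- function(field, path, beam, phantom,
                                grid = grid_spec(), n_cycles = 1) {
  stopifnot(inherits(path, "scan_path"))
  p <- grid_to_plane(path$visits[, "row"], path$visits[, "col"], grid)
  s2 <- 2 * beam$sigma_mm^2
  wx <- exp(-outer(phantom$xs, p$x, "-")^2 / s2)
  wy <- exp(-outer(phantom$ys, p$y, "-")^2 / s2)
  wx <- sweep(wx, 2, colSums(wx), "/")
  wy <- sweep(wy, 2, colSums(wy), "/")
  pw <- beam$power_max_w * beam$power_fraction
  dt <- path$dt_ms / 1000
  for (cyc in seq_len(n_cycles)) {
    for (k in seq_len(nrow(path$visits))) {
      spot <- (wy[, k] %o% wx[, k]) * pw * phantom$absorptivity_map
      field <- step_heat(field, spot, phantom, dt)
    }
  }
  field
}

#' Write a temperature field (or any numeric grid) as CSV
#'
#' @param field A [temperature_field()] or plain matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  m <- if (inherits(field, "temperature_field")) field$temps else field
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
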