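# Full simulated treatment session: detect the ROI from a visible frame,
# plan the raster scan, then iterate {heat -> thermal frame -> pipeline
# -> PID -> laser power} for the session duration.

#' Session configuration
#'
#' Assembles every module's parameters into one serializable object.
#' Values not supplied keep the defaults that define the reference study
#' conditions: a 5 x 5 cm field scanned as a 30 x 30 matrix with 1 ms
#' dwell, a 2 W / 5 mm Gaussian beam, the generic-clay phantom, the dual
#' camera with mild keystone and a 12 px vertical parallax, and the tuned
#' PID gains (25, 0.3, 20) sampling every 5 s toward 42 deg C with a
#' 46 deg C cap over a 300 s session.
#'
#' @param seed Master seed; every random element of the session (blob
#'   shape, pixel noise, thermal sensor noise) derives from it.
#' @param blob A [blob_spec()]; its seed defaults to the master seed.
#' @param phantom_args Named list of overrides for [generate_phantom()].
#' @param beam A [laser_beam()] (maximum power and spot size; the
#'   commanded fraction is what the controller drives).
#' @param grid A [grid_spec()].
#' @param galvo A [galvo_config()].
#' @param camera_args Named list of overrides for [camera_geometry()].
#' @param gains A [pid_gains()].
#' @param sp A [setpoint()].
#' @param dt_ms Scan dwell time per cell, ms.
#' @param u_scale Raw PID output corresponding to full laser power.
#' @param blob_threshold Intensity threshold isolating the dark target in
#'   the visible frame.
#' @param field_threshold Intensity threshold isolating the clay plate
#'   (the maximum scan area) from the light background.
#' @param rect_px Side of the rectified scan-area image, px (a multiple
#'   of the scan-matrix size so block averaging is exact).
#' @param thermal_contrast_min Minimum (Tmax - Tmin) spread, deg C, for a
#'   thermal frame to be re-segmented for parallax estimation; frames
#'   with less contrast reuse the last estimated shift.
#' @param noise_sd Visible-camera pixel noise, 8-bit counts.
#' @param netd Thermal camera sensitivity, K.
#' @param bias_c Constant thermal calibration bias, deg C.
#' @param anti_windup Enable conditional-integration anti-windup.
#' @return An object of class `session_config`.
#' @export
session_config <- function(seed = 1L,
                           blob = NULL,
                           phantom_args = list(),
                           beam = laser_beam(),
                           grid = grid_spec(),
                           galvo = galvo_config(),
                           camera_args = list(),
                           gains = pid_gains(),
                           sp = setpoint(),
                           dt_ms = 1,
                           u_scale = 100,
                           blob_threshold = 100,
                           field_threshold = 210,
                           rect_px = 180,
                           thermal_contrast_min = 2,
                           noise_sd = 2,
                           netd = 0.065,
                           bias_c = 0,
                           anti_windup = TRUE) {
  if (is.null(blob)) blob <- blob_spec(seed = seed)
  structure(list(seed = as.integer(seed), blob = blob,
                 phantom_args = phantom_args, beam = beam, grid = grid,
                 galvo = galvo, camera_args = camera_args, gains = gains,
                 sp = sp, dt_ms = dt_ms, u_scale = u_scale,
                 blob_threshold = blob_threshold,
                 field_threshold = field_threshold, rect_px = rect_px,
                 thermal_contrast_min = thermal_contrast_min,
                 noise_sd = noise_sd, netd = netd, bias_c = bias_c,
                 anti_windup = anti_windup),
            class = "session_config")
}

#' Read a session configuration from YAML or JSON
#'
#' Recognized keys mirror the arguments of [session_config()],
#' [galvo_config()] (`geometry.*`, `dac.*`), [grid_spec()] (`grid.*`),
#' [pid_gains()] (`controller.*`) and [setpoint()] (`setpoint.*`).
#' Missing keys keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `session_config`.
#' @export
read_session_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  g <- cfg$geometry; d <- cfg$dac; gr <- cfg$grid
  galvo <- galvo_config(
    d_mm = g$d_mm %||% 150, e_mm = g$e_mm %||% 10,
    s_v_per_deg = g$s_v_per_deg %||% 0.5,
    optical_per_mechanical = g$optical_per_mechanical %||% 2,
    n_bits = d$n_bits %||% 12L, v_min = d$v_min %||% -20,
    v_max = d$v_max %||% 20,
    max_step_rate = g$max_step_rate %||% 40)
  grid <- grid_spec(n_rows = gr$n %||% 30L, n_cols = gr$n %||% 30L,
                    pitch_mm = gr$pitch_mm %||% (50 / 30))
  ctl <- cfg$controller; sp <- cfg$setpoint
  gains <- pid_gains(kp = ctl$kp %||% 25, ki = ctl$ki %||% 0.3,
                     kd = ctl$kd %||% 20, t_sample = ctl$t_sample %||% 5)
  spt <- setpoint(target_c = sp$target_c %||% 42,
                  limit_c = sp$limit_c %||% 46,
                  duration_s = sp$duration_s %||% 300)
  session_config(seed = cfg$seed %||% 1L, grid = grid, galvo = galvo,
                 gains = gains, sp = spt,
                 dt_ms = cfg$dt_ms %||% 1,
                 u_scale = ctl$u_scale %||% 100,
                 phantom_args = cfg$phantom %||% list(),
                 camera_args = cfg$camera %||% list())
}

#' Run one closed-loop treatment session
#'
#' Executes the full simulated workflow:
#' \enumerate{
#'   \item generate the phantom and render the visible frame;
#'   \item segment the target, find the scan-area corners, correct the
#'     keystone distortion and reduce to the 30 x 30 scan matrix;
#'   \item plan the raster path and its cycle-averaged power deposition;
#'   \item every sampling period: render a thermal frame, align it for
#'     parallax, convert to a thermogram, rectify onto the scan grid,
#'     take ROI statistics, run the PID step and command the laser power
#'     for the next period, then advance the heat model.
#' }
#' Power is forced to zero whenever the measured ROI temperature (the
#' controlled process variable) exceeds the safety limit. The trace is
#' deterministic for a fixed seed.
#'
#' @param cfg A [session_config()].
#' @return An object of class `session_trace`: `records` (data frame,
#'   one row per control step: `time_s`, `mean_c`, `max_c`, `min_c`,
#'   `error_c`, `u_raw`, `power_pct`, `safety_cut`), `summary`
#'   (steady-state mean over the final 60 s, maximum ROI temperature,
#'   overshoot, settling time), plus the scan matrix, phantom and
#'   intermediate artifacts.
#' @export
run_session <- function(cfg = session_config()) {
  stopifnot(inherits(cfg, "session_config"))
  set.seed(cfg$seed)

  phantom <- do.call(generate_phantom, c(list(spec = cfg$blob),
                                         cfg$phantom_args))
  geom <- do.call(camera_geometry, cfg$camera_args)

  # --- visible path: target mask and scan-area rectification
  vis <- render_visible(phantom, geom, noise_sd = cfg$noise_sd)
  seg <- segment_visible(vis, threshold = cfg$blob_threshold)
  quad <- find_scan_area(vis, threshold = cfg$field_threshold)
  rect <- correct_keystone(seg, quad, out_size = c(cfg$rect_px, cfg$rect_px))
  sm <- to_scan_matrix(rect, n = cfg$grid$n_rows)
  if (sum(sm) == 0) stop("scan matrix is empty after image processing")

  # --- scan plan and cycle-averaged power deposition at full power
  path <- plan_raster(sm, dt_ms = cfg$dt_ms)
  slew <- check_slew(path, cfg$grid, cfg$galvo)
  if (!slew$feasible)
    warning("scan path exceeds the galvo slew limit; pattern would distort")
  unit_beam <- laser_beam(power_max_w = cfg$beam$power_max_w,
                          power_fraction = 1,
                          spot_diameter_mm = cfg$beam$spot_diameter_mm)
  unit_map <- deposit_cycle_fluence(path, unit_beam, phantom, cfg$grid)

  # visible ROI mask in thermal-pixel coordinates, for parallax estimation
  vm <- area_resize(seg, geom$thermal_size[1], geom$thermal_size[2])
  vm <- (vm >= 0.5) * 1

  # quad in thermal pixels: the thermal view is the visible view rescaled
  sx <- geom$thermal_size[1] / geom$visible_size[1]
  sy <- geom$thermal_size[2] / geom$visible_size[2]
  quad_t <- cbind(quad[, 1] * sx, quad[, 2] * sy)

  field <- temperature_field(matrix(phantom$ambient_c, phantom$n_cells,
                                    phantom$n_cells))
  state <- controller_state()
  gains <- cfg$gains
  sp <- cfg$sp
  times <- seq(0, sp$duration_s, by = gains$t_sample)
  rec <- vector("list", length(times))
  last_shift <- c(0, 0)
  rect3 <- 3 * cfg$grid$n_rows   # rectify fine, then block-average 3 -> 1

  for (k in seq_along(times)) {
    frame <- render_thermal(field, phantom, geom, netd = cfg$netd,
                            bias_c = cfg$bias_c)
    if (frame$degenerate) {
      stats <- structure(list(mean = frame$t_min, max = frame$t_min,
                              min = frame$t_min, n = sum(sm)),
                         class = "roi_stats")
    } else {
      if (frame$t_max - frame$t_min >= cfg$thermal_contrast_min) {
        tmask <- (frame$pixels > otsu_threshold(frame$pixels)) * 1
        cor <- tryCatch(correct_parallax(frame, tmask, vm),
                        error = function(e)
                          apply_parallax_shift(frame, tmask, last_shift))
        last_shift <- cor$shift
      } else {
        tmask <- vm  # no usable contrast: reuse the last known alignment
        cor <- apply_parallax_shift(frame, tmask, last_shift)
      }
      thermo <- to_thermogram(cor$frame)
      rect_t <- correct_keystone(thermo$temps, quad_t,
                                 out_size = c(rect3, rect3),
                                 fill = phantom$ambient_c)
      grid30 <- area_resize(rect_t, cfg$grid$n_cols, cfg$grid$n_rows)
      stats <- roi_stats(grid30, sm)
    }

    err <- error_from_thermogram(stats, sp)
    ps <- pid_step(state, err, gains)
    pf <- to_power_fraction(ps$u, ps$state, gains, u_scale = cfg$u_scale,
                            anti_windup = cfg$anti_windup)
    state <- pf$state
    safety_cut <- stats$mean > sp$limit_c
    fraction <- if (safety_cut) 0 else pf$fraction

    rec[[k]] <- data.frame(time_s = times[k], mean_c = stats$mean,
                           max_c = stats$max, min_c = stats$min,
                           error_c = err, u_raw = ps$u,
                           power_pct = 100 * fraction,
                           safety_cut = safety_cut)

    if (k < length(times))
      field <- advance_heat(field, unit_map * fraction, phantom,
                            gains$t_sample)
  }

  records <- do.call(rbind, rec)
  structure(list(records = records,
                 summary = trace_summary(records, sp),
                 scan_matrix = sm, phantom = phantom, quad = quad,
                 slew = slew, config = cfg, final_field = field),
            class = "session_trace")
}

trace_summary <- function(records, sp) {
  tail_win <- records$time_s > max(records$time_s) - 60
  dev <- abs(records$mean_c - sp$target_c)
  settled <- rev(cumprod(rev(dev <= 1))) == 1
  list(steady_mean_c = mean(records$mean_c[tail_win]),
       peak_mean_c = max(records$mean_c),
       max_cell_c = max(records$max_c),
       overshoot_c = max(records$mean_c) - sp$target_c,
       settling_time_s = if (any(settled)) records$time_s[which(settled)[1]]
       else NA_real_)
}

#' @export
print.session_trace <- function(x, ...) {
  s <- x$summary
  cat("session_trace: ", nrow(x$records), " control steps over ",
      max(x$records$time_s), " s\n",
      sprintf("  steady-state mean ROI temperature (last 60 s): %.2f degC\n",
              s$steady_mean_c),
      sprintf("  peak ROI temperature: %.2f degC (limit %.0f)\n",
              s$peak_mean_c, x$config$sp$limit_c),
      sprintf("  peak single-cell temperature: %.2f degC\n", s$max_cell_c),
      sprintf("  settling time (within 1 degC): %s s\n",
              format(s$settling_time_s)), sep = "")
  invisible(x)
}

#' Sweep PID gain combinations
#'
#' Runs one session per row of `gain_grid`, holding everything else in
#' the configuration fixed. Used to reproduce the classic manual tuning
#' narrative: a P-only controller oscillates, adding derivative gain
#' damps the oscillation but leaves a steady-state error, and integral
#' gain removes the offset at the cost of overshoot when set too high.
#'
#' @param cfg A [session_config()].
#' @param gain_grid Data frame with columns `kp`, `ki`, `kd`.
#' @return A named list of `session_trace` objects ("kp=..,ki=..,kd=..").
#' @export
tuning_sweep <- function(cfg, gain_grid) {
  stopifnot(nrow(gain_grid) >= 1,
            all(c("kp", "ki", "kd") %in% names(gain_grid)))
  out <- vector("list", nrow(gain_grid))
  for (i in seq_len(nrow(gain_grid))) {
    cfg_i <- cfg
    cfg_i$gains <- pid_gains(kp = gain_grid$kp[i], ki = gain_grid$ki[i],
                             kd = gain_grid$kd[i],
                             t_sample = cfg$gains$t_sample)
    out[[i]] <- run_session(cfg_i)
  }
  names(out) <- sprintf("kp=%g,ki=%g,kd=%g",
                        gain_grid$kp, gain_grid$ki, gain_grid$kd)
  out
}

#' Eight-point calibration pattern around the scan perimeter
#'
#' Computes the four corners and four edge midpoints of the maximum scan
#' area (the outer +/- half-field perimeter), together with the scan
#' angles, command voltages and DAC codes that project them — the
#' luminous square used to align the target with a reference square
#' during setup.
#'
#' @param grid A [grid_spec()].
#' @param cfg A [galvo_config()].
#' @return Data frame with columns `point`, `x_mm`, `y_mm`, `theta_x`,
#'   `theta_y`, `vx`, `vy`, `dac_x`, `dac_y` (8 rows, clockwise from the
#'   top-left corner).
#' @export
calibration_pattern <- function(grid = grid_spec(), cfg = galvo_config()) {
  hx <- grid$n_cols * grid$pitch_mm / 2
  hy <- grid$n_rows * grid$pitch_mm / 2
  pts <- rbind(c(-hx,  hy), c(0,  hy), c(hx,  hy), c(hx, 0),
               c(hx, -hy), c(0, -hy), c(-hx, -hy), c(-hx, 0))
  lab <- c("top-left", "top-mid", "top-right", "right-mid",
           "bottom-right", "bottom-mid", "bottom-left", "left-mid")
  a <- plane_to_angles(plane_point(pts[, 1], pts[, 2]), cfg)
  v <- angle_to_voltage(a, cfg)
  data.frame(point = lab, x_mm = pts[, 1], y_mm = pts[, 2],
             theta_x = a$theta_x, theta_y = a$theta_y,
             vx = v$vx, vy = v$vy,
             dac_x = voltage_to_dac_code(v$vx, cfg),
             dac_y = voltage_to_dac_code(v$vy, cfg))
}

#' Plot a session temperature trace
#'
#' Mean ROI temperature over time with the reference and safety-limit
#' temperatures as dashed red lines.
#'
#' @param trace A `session_trace`.
#' @param ... Passed to [plot()].
#' @return `trace`, invisibly.
#' @export
plot_trace <- function(trace, ...) {
  r <- trace$records; sp <- trace$config$sp
  plot(r$time_s, r$mean_c, type = "l", lwd = 2,
       xlab = "time (s)", ylab = "mean ROI temperature (degC)",
       ylim = range(c(r$mean_c, sp$limit_c + 0.5)), ...)
  graphics::abline(h = c(sp$target_c, sp$limit_c), col = "red", lty = 2)
  invisible(trace)
}

#' Plot the commanded laser power trace
#'
#' @param trace A `session_trace`.
#' @param ... Passed to [plot()].
#' @return `trace`, invisibly.
#' @export
plot_power <- function(trace, ...) {
  r <- trace$records
  plot(r$time_s, r$power_pct, type = "s", lwd = 2,
       xlab = "time (s)", ylab = "laser power (%)", ylim = c(0, 100), ...)
  invisible(trace)
}

#' Export a session trace as CSV
#'
#' @param trace A `session_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace$records, path, row.names = FALSE)
  invisible(path)
}
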