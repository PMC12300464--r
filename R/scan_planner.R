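# Raster scan planning: ScanMatrix -> time-ordered ScanPath -> stepped
# voltage waveform, plus a slew-rate feasibility check for the galvos.

#' Binary scan matrix
#'
#' The n x n treatment mask: 1 marks cells of the 5 x 5 cm field that the
#' laser visits, 0 cells are skipped. Row 1 is the top of the field.
#'
#' @param mask Matrix of 0/1 (logical or numeric).
#' @return An object of class `scan_matrix` (an integer matrix).
#' @export
scan_matrix <- function(mask) {
  m <- as.matrix(mask)
  stopifnot(all(m %in% c(0, 1)))
  structure(matrix(as.integer(m), nrow(m), ncol(m)), class = "scan_matrix")
}

#' @export
print.scan_matrix <- function(x, ...) {
  cat("scan_matrix: ", nrow(x), " x ", ncol(x), ", ",
      sum(x), " active cells\n", sep = "")
  invisible(x)
}

#' Plan a raster scan over a scan matrix
#'
#' Enumerates the selected cells in raster order — line by line, left to
#' right, top to bottom — and attaches the per-point dwell time. Each
#' voltage update moves the beam to the center of the next cell and holds
#' it there for `dt_ms`, so one full cycle over the path takes
#' `k * dt_ms` for k visited cells. Retraces (end of line back to the
#' start of the next, and bottom-right back to top-left) are instantaneous
#' voltage steps; their feasibility is assessed by [check_slew()].
#'
#' @param mask A [scan_matrix()], or any 0/1 matrix.
#' @param dt_ms Time between voltage updates, ms.
#' @param full_grid If `TRUE`, visit every cell of the grid regardless of
#'   the mask (the beam sweeps the whole field; the mask then only gates
#'   which cells count as region of interest downstream).
#' @return An object of class `scan_path`: a list with `visits` (two-column
#'   matrix of 1-based row, col), `dt_ms`, and `cycle_time_ms`.
#' @export
#' @examples
#' p <- plan_raster(scan_matrix(matrix(1, 30, 30)), dt_ms = 1)
#' p$cycle_time_ms  # 900 ms per cycle
plan_raster <- function(mask, dt_ms = 1, full_grid = FALSE) {
  if (!inherits(mask, "scan_matrix")) mask <- scan_matrix(mask)
  stopifnot(dt_ms > 0)
  if (full_grid) {
    idx <- cbind(row = rep(seq_len(nrow(mask)), each = ncol(mask)),
                 col = rep(seq_len(ncol(mask)), nrow(mask)))
  } else {
    sel <- which(unclass(mask) == 1L, arr.ind = TRUE)
    if (nrow(sel) == 0) stop("nothing to scan: the mask selects no cells")
    idx <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
    colnames(idx) <- c("row", "col")
  }
  rownames(idx) <- NULL
  structure(list(visits = idx, dt_ms = dt_ms,
                 cycle_time_ms = nrow(idx) * dt_ms,
                 n_grid = c(nrow(mask), ncol(mask))),
            class = "scan_path")
}

#' @export
print.scan_path <- function(x, ...) {
  cat("scan_path: ", nrow(x$visits), " visits, dt = ", x$dt_ms,
      " ms, cycle time = ", x$cycle_time_ms, " ms\n", sep = "")
  invisible(x)
}

#' Convert a scan path into the stepped command waveform
#'
#' Composes the geometry chain cell -> plane point -> optical angles ->
#' command voltages -> DAC codes for every visit and lays the values out
#' as a zero-order-hold staircase: each voltage pair is held for `dt_ms`.
#' The horizontal (x) channel steps once per visit while the vertical (y)
#' channel steps once per scan line, which is why the horizontal signal
#' has the higher fundamental frequency.
#'
#' @param path A [scan_path()].
#' @param grid A [grid_spec()]; its dimensions must match the path's grid.
#' @param cfg A [galvo_config()].
#' @return A data frame of class `scan_waveform` with columns `time_ms`,
#'   `row`, `col`, `x_mm`, `y_mm`, `theta_x`, `theta_y`, `vx`, `vy`,
#'   `dac_x`, `dac_y`; one row per visit.
#' @export
path_to_waveform <- function(path, grid = grid_spec(), cfg = galvo_config()) {
  stopifnot(inherits(path, "scan_path"), inherits(grid, "grid_spec"),
            inherits(cfg, "galvo_config"))
  stopifnot(grid$n_rows == path$n_grid[1], grid$n_cols == path$n_grid[2])
  p <- grid_to_plane(path$visits[, "row"], path$visits[, "col"], grid)
  a <- plane_to_angles(p, cfg)
  v <- angle_to_voltage(a, cfg)
  wf <- data.frame(
    time_ms = (seq_len(nrow(path$visits)) - 1) * path$dt_ms,
    row = path$visits[, "row"], col = path$visits[, "col"],
    x_mm = p$x, y_mm = p$y,
    theta_x = a$theta_x, theta_y = a$theta_y,
    vx = v$vx, vy = v$vy,
    dac_x = voltage_to_dac_code(v$vx, cfg),
    dac_y = voltage_to_dac_code(v$vy, cfg))
  class(wf) <- c("scan_waveform", "data.frame")
  wf
}

#' Check a scan path against the galvo slew-rate limit
#'
#' For every transition between consecutive visits (including the cyclic
#' retrace from the last visit back to the first) the required optical
#' angle change per update interval is compared with the mirror's maximum
#' step rate. The horizontal retrace at the end of each line is normally
#' the fastest transition; when the update interval is too short the
#' mirrors cannot complete it and the drawn pattern distorts.
#'
#' @param path A [scan_path()].
#' @param grid A [grid_spec()].
#' @param cfg A [galvo_config()]; `max_step_rate` is the limit in optical
#'   degrees per ms.
#' @return A list of class `slew_report`: `feasible` (logical),
#'   `max_rate` (worst observed deg/ms), `limit`, `worst_transition`
#'   (from/to cells of the worst step), and `n_violations`.
#' @export
check_slew <- function(path, grid = grid_spec(), cfg = galvo_config()) {
  stopifnot(inherits(path, "scan_path"))
  wf <- path_to_waveform(path, grid, cfg)
  n <- nrow(wf)
  nxt <- c(seq_len(n)[-1], 1L)  # cyclic: include the vertical retrace
  dth <- pmax(abs(wf$theta_x[nxt] - wf$theta_x),
              abs(wf$theta_y[nxt] - wf$theta_y))
  rate <- dth / path$dt_ms
  worst <- which.max(rate)
  structure(list(
    feasible = all(rate <= cfg$max_step_rate),
    max_rate = rate[worst],
    limit = cfg$max_step_rate,
    worst_transition = list(from = unlist(wf[worst, c("row", "col")]),
                            to = unlist(wf[nxt[worst], c("row", "col")])),
    n_violations = sum(rate > cfg$max_step_rate)),
    class = "slew_report")
}

#' @export
print.slew_report <- function(x, ...) {
  cat("slew check: ", if (x$feasible) "feasible" else "INFEASIBLE",
      " (max ", format(x$max_rate, digits = 4), " deg/ms vs limit ",
      x$limit, "; ", x$n_violations, " violation(s))\n", sep = "")
  invisible(x)
}

#' Read and write scan matrices
#'
#' Two plain-text interchange formats are supported: a whitespace-
#' separated 0/1 grid (one matrix row per line) and JSON (an array of
#' arrays), the format in which the matrix is handed to the scanning
#' controller.
#'
#' @param x A [scan_matrix()].
#' @param path File path.
#' @param format `"txt"` or `"json"`; inferred from the extension by
#'   default.
#' @return `read_scan_matrix()` returns a [scan_matrix()];
#'   `write_scan_matrix()` returns `path` invisibly.
#' @export
write_scan_matrix <- function(x, path, format = c("auto", "txt", "json")) {
  if (!inherits(x, "scan_matrix")) x <- scan_matrix(x)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "txt"
  if (format == "json") {
    jsonlite::write_json(apply(unclass(x), 1, identity, simplify = FALSE)
                         |> lapply(as.integer), path)
  } else {
    writeLines(apply(unclass(x), 1, paste, collapse = " "), path)
  }
  invisible(path)
}

#' @rdname write_scan_matrix
#' @export
read_scan_matrix <- function(path, format = c("auto", "txt", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "txt"
  if (format == "json") {
    rows <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- if (is.list(rows)) do.call(rbind, rows) else rows
  } else {
    m <- as.matrix(utils::read.table(path))
  }
  dimnames(m) <- NULL
  scan_matrix(m)
}

#' Export a waveform as CSV
#'
#' @param wf A `scan_waveform` from [path_to_waveform()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(inherits(wf, "scan_waveform"))
  utils::write.csv(wf[, c("time_ms", "vx", "vy", "dac_x", "dac_y")],
                   path, row.names = FALSE)
  invisible(path)
}
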