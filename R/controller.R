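# Discrete PID control of laser power from the ROI temperature error.

#' PID gains and sampling period
#'
#' Defaults are the tuned values used for mild-hyperthermia regulation:
#' Kp = 25, Ki = 0.3, Kd = 20 with a 5 s sampling period (the thermal
#' feedback arrives in discrete 5 s intervals).
#'
#' @param kp,ki,kd Proportional, integral and derivative gains.
#' @param t_sample Sampling period, s.
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(kp = 25, ki = 0.3, kd = 20, t_sample = 5) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, t_sample > 0)
  structure(list(kp = kp, ki = ki, kd = kd, t_sample = t_sample),
            class = "pid_gains")
}

#' Temperature setpoint and safety limit
#'
#' @param target_c Target ROI temperature, deg C (42 deg C is the
#'   mild-hyperthermia regime).
#' @param limit_c Hard safety cap, deg C; the session must never exceed
#'   it (46 deg C guards against thermal damage).
#' @param duration_s Session duration, s.
#' @return An object of class `setpoint`.
#' @export
setpoint <- function(target_c = 42, limit_c = 46, duration_s = 300) {
  stopifnot(limit_c > target_c, duration_s > 0)
  structure(list(target_c = target_c, limit_c = limit_c,
                 duration_s = duration_s),
            class = "setpoint")
}

#' Fresh controller state
#'
#' Holds the running error sum (in samples; multiplied by `Ki * T` when
#' the output is formed), the previous error for the derivative term, and
#' the last commanded power fraction.
#'
#' @return An object of class `controller_state`.
#' @export
controller_state <- function() {
  structure(list(error_sum = 0, error_sum_prev = 0, prev_error = 0,
                 n_steps = 0L, last_output = 0),
            class = "controller_state")
}

#' One discrete PID update
#'
#' Computes the raw controller output
#' `u[n] = Kp e[n] + Ki T sum(e[0..n]) + Kd (e[n] - e[n-1]) / T`.
#' The running sum includes the current error; on the first step the
#' previous error is taken as 0, so the derivative term starts at
#' `Kd e[0] / T` only if the initial error is nonzero — the first-sample
#' derivative is therefore defined as 0 by seeding `prev_error` with the
#' first error (see Details).
#'
#' @details The derivative acts on the error signal. To avoid a spurious
#' derivative kick at start-up, the very first call uses
#' `e[n] - e[n-1] = 0`.
#'
#' @param state A [controller_state()].
#' @param error Current setpoint error, deg C.
#' @param gains A [pid_gains()].
#' @return A list with the updated `state` and the raw output `u`
#'   (unclamped; feed it to [to_power_fraction()]).
#' @export
pid_step <- function(state, error, gains) {
  stopifnot(inherits(state, "controller_state"), inherits(gains, "pid_gains"))
  if (!is.finite(error)) stop("non-finite controller error")
  prev <- if (state$n_steps == 0L) error else state$prev_error
  state$error_sum_prev <- state$error_sum
  state$error_sum <- state$error_sum + error
  u <- gains$kp * error +
    gains$ki * gains$t_sample * state$error_sum +
    gains$kd * (error - prev) / gains$t_sample
  state$prev_error <- error
  state$n_steps <- state$n_steps + 1L
  list(state = state, u = u)
}

#' Map raw controller output to a laser power fraction
#'
#' The raw output `u` is in "percent of full power" units; it is divided
#' by `u_scale` (default 100) and clamped to `[0, 1]`. While the command
#' is saturated and the current error keeps pushing it further into the
#' bound, the integral contribution of that error is rolled back
#' (conditional-integration anti-windup), so the accumulator stays
#' bounded during the initial full-power ramp.
#'
#' @param u Raw output from [pid_step()].
#' @param state The [controller_state()] returned by the same
#'   [pid_step()] call.
#' @param gains A [pid_gains()].
#' @param u_scale Raw-output value that corresponds to full power.
#' @param anti_windup Set `FALSE` to observe integrator windup.
#' @return A list with the final `state` and `fraction` in `[0, 1]`.
#' @export
to_power_fraction <- function(u, state, gains, u_scale = 100,
                              anti_windup = TRUE) {
  stopifnot(u_scale > 0)
  fraction <- min(1, max(0, u / u_scale))
  saturated_hi <- u / u_scale > 1
  saturated_lo <- u / u_scale < 0
  e_n <- state$prev_error  # the error just accumulated by pid_step
  if (anti_windup &&
      ((saturated_hi && e_n > 0) || (saturated_lo && e_n < 0))) {
    state$error_sum <- state$error_sum_prev
  }
  state$last_output <- fraction
  list(state = state, fraction = fraction)
}

#' Setpoint error from ROI statistics
#'
#' The controller's process variable is the mean temperature over the
#' region of interest; the error is `target - mean`.
#'
#' @param stats An [roi_stats()] result.
#' @param sp A [setpoint()].
#' @return Error in deg C.
#' @export
error_from_thermogram <- function(stats, sp) {
  stopifnot(inherits(sp, "setpoint"))
  if (is.null(stats$mean) || !is.finite(stats$mean))
    stop("invalid ROI statistics: no finite mean temperature")
  sp$target_c - stats$mean
}
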