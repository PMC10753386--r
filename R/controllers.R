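#' Setpoint action potential
#'
#' One pacing cycle of reference membrane-potential values, one per 1-ms
#' control tick. Setpoints are produced by logging and averaging beats
#' ([log_setpoint()]), by loading a model waveform from file
#' ([load_model_ap()]), or by a generator ([triangular_model()],
#' [record_drug_model()]).
#'
#' @param values Numeric vector of membrane potentials, mV; one per tick.
#' @param dt Control step, ms. Fixed at 1.
#' @param origin One of `"logged"`, `"file"`, `"generator"`.
#' @return An object of class `apqr_setpoint`.
#' @export
setpoint_ap <- function(values, dt = 1, origin = c("logged", "file",
                                                   "generator")) {
  origin <- match.arg(origin)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a setpoint needs at least 2 samples")
  if (any(!is.finite(values))) stop("setpoint values must all be finite")
  if (dt != 1) stop("the control step is fixed at 1 ms")
  structure(list(values = values, dt = dt, origin = origin),
            class = "apqr_setpoint")
}

#' @export
print.apqr_setpoint <- function(x, ...) {
  cat(sprintf("Setpoint AP (%s): %d ticks, %.1f .. %.1f mV\n",
              x$origin, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Average logged beats into a setpoint
#'
#' Element-wise mean of `lognum` aligned single-beat membrane-potential
#' traces, producing the reference trajectory the controllers track.
#'
#' @param beats List of numeric vectors (one per logged beat, equal length,
#'   aligned to the pacing stimulus tick).
#' @param lognum Number of beats that must be present.
#' @return An `apqr_setpoint` with origin `"logged"`.
#' @export
log_setpoint <- function(beats, lognum = length(beats)) {
  if (length(beats) != lognum)
    stop("expected ", lognum, " logged beats, got ", length(beats))
  len <- unique(vapply(beats, length, integer(1)))
  if (length(len) != 1L) stop("logged beats have mismatched lengths")
  m <- do.call(rbind, beats)
  setpoint_ap(colMeans(m), origin = "logged")
}

#' Gains of the adaptive proportional controller
#'
#' The proportional gain is the heuristic ratio `K_P = C_m / R_m`, with `R_m`
#' adapted multiplicatively every tick: an overshoot of the setpoint
#' multiplies `R_m` by `R_m_corr_up` (lowering the gain) and a same-sign
#' growth of the error divides it by `R_m_corr_down` (raising the gain).
#' `C_m` is in pF and `R_m` in arbitrary gain units: the ratio is a numeric
#' gain, not a dimensional current law, and `scale` maps the controller
#' output to an injected current density or a normalized irradiance.
#'
#' @param C_m Cell capacitance, pF.
#' @param R_m Initial adaptive denominator.
#' @param R_m_corr_up,R_m_corr_down Multiplicative correction factors, > 1.
#' @param lognum Number of beats averaged into the setpoint.
#' @param scale Output scale (actuation units per controller-output unit).
#' @return An object of class `apqr_apqr_gains`.
#' @export
apqr_gains <- function(C_m = 100, R_m = 100, R_m_corr_up = 1.1,
                       R_m_corr_down = 1.01, lognum = 5, scale = 1) {
  if (R_m <= 0) stop("R_m must be > 0")
  if (R_m_corr_up <= 1 || R_m_corr_down <= 1)
    stop("correction factors must be > 1")
  if (lognum < 1) stop("lognum must be a positive integer")
  structure(list(C_m = C_m, R_m = R_m, R_m_corr_up = R_m_corr_up,
                 R_m_corr_down = R_m_corr_down, lognum = as.integer(lognum),
                 scale = scale),
            class = "apqr_apqr_gains")
}

#' Gains of the PID controller
#'
#' Proportional-integral-derivative gains with a regression-based derivative:
#' the derivative term is the least-squares slope of the last `l` error
#' samples. `V_plateau` is the apparent reversal of the blue actuator; blue
#' output is only permitted while the measured potential is more negative
#' than `V_plateau`. `scale` and `scale_blue` map the PID value to normalized
#' irradiance of the red and blue channels (the two actuators differ greatly
#' in small-signal authority, so each channel carries its own mapping).
#'
#' @param K_P,K_I,K_D Non-negative gains.
#' @param l Derivative regression window length in ticks (>= 2).
#' @param dt Control step, ms (fixed 1).
#' @param V_plateau Blue-output gating bound, mV.
#' @param lognum Number of beats averaged into a logged setpoint.
#' @param scale Red-channel (or injected-current) output scale.
#' @param scale_blue Blue-channel output scale.
#' @return An object of class `apqr_pid_gains`.
#' @export
pid_gains <- function(K_P = 80, K_I = 3, K_D = 50, l = 10, dt = 1,
                      V_plateau = -11.2, lognum = 5,
                      scale = 2e-3, scale_blue = 2e-4) {
  if (l < 2) stop("the regression window l must hold at least 2 samples")
  if (any(c(K_P, K_I, K_D) < 0)) stop("gains must be >= 0")
  if (dt != 1) stop("the control step is fixed at 1 ms")
  structure(list(K_P = K_P, K_I = K_I, K_D = K_D, l = as.integer(l), dt = dt,
                 V_plateau = V_plateau, lognum = as.integer(lognum),
                 scale = scale, scale_blue = scale_blue),
            class = "apqr_pid_gains")
}

#' Running controller state
#'
#' Mutable memory of a controller between ticks: the phase of the experiment,
#' the tick index within the pacing cycle, the previous error, the integral
#' accumulator, the derivative window, and the adaptive gain denominator.
#'
#' @param phase One of `"LOGGING"`, `"PAUSED"`, `"CORRECTING"`.
#' @param i Tick index within the cycle (1-based).
#' @param R_m Initial adaptive denominator (adaptive controller only).
#' @param l Derivative window capacity.
#' @return An object of class `apqr_controller_state`.
#' @export
controller_state <- function(phase = c("CORRECTING", "LOGGING", "PAUSED"),
                             i = 1L, R_m = 100, l = 10L) {
  phase <- match.arg(phase)
  structure(list(phase = phase, i = as.integer(i),
                 e = 0, e_prev = NA_real_,
                 e_sum = 0, e_sum_prev = 0,
                 e_window = numeric(0), l = as.integer(l),
                 R_m_current = R_m, logged_beats = 0L,
                 correcting = FALSE, V_prev = NA_real_),
            class = "apqr_controller_state")
}

#' One tick of the adaptive proportional controller
#'
#' Computes the membrane-potential error `e = V_m - setpoint[i]`, the output
#' `I_out = (C_m / R_m) * e`, and then updates the adaptive denominator:
#' if the error changed sign since the previous tick (overshoot) `R_m` is
#' multiplied by `R_m_corr_up`; if it grew in magnitude with unchanged sign
#' (moving away) `R_m` is divided by `R_m_corr_down`. The predicates are
#' mutually exclusive; otherwise `R_m` is unchanged. The cycle index then
#' advances modulo the setpoint length.
#'
#' @param V_m Measured membrane potential, mV.
#' @param state Controller state (phase must be `"CORRECTING"`).
#' @param setpoint An `apqr_setpoint`.
#' @param gains An `apqr_apqr_gains`.
#' @return `list(I_out = <output>, state = <updated state>)`.
#' @export
apqr_tick <- function(V_m, state, setpoint, gains) {
  if (state$phase != "CORRECTING")
    stop("apqr_tick requires phase CORRECTING")
  n <- length(setpoint$values)
  if (state$i < 1L || state$i > n) stop("cycle index out of range")
  e <- V_m - setpoint$values[state$i]
  I_out <- gains$C_m / state$R_m_current * e
  ep <- state$e_prev
  if (!is.na(ep)) {
    overshoot <- (sign(e) != sign(ep)) && abs(ep) > 0
    away <- !overshoot && abs(e) > abs(ep) && sign(e) == sign(ep)
    if (overshoot) state$R_m_current <- state$R_m_current * gains$R_m_corr_up
    else if (away) state$R_m_current <- state$R_m_current / gains$R_m_corr_down
  }
  if (!is.finite(state$R_m_current) || state$R_m_current <= 0)
    stop("adaptive R_m left the positive domain")
  state$e <- e
  state$e_prev <- e
  state$i <- if (state$i == n) 1L else state$i + 1L
  list(I_out = I_out, state = state)
}

#' Least-squares slope of an error window
#'
#' Slope of the straight line fitted by least squares to the `l` most recent
#' error samples against time, with samples supplied in chronological order
#' (oldest first). A rising error yields a positive slope.
#'
#' @param e_window Numeric vector of errors, oldest first (length >= 2).
#' @param dt Sample spacing, ms.
#' @return Slope in mV/ms.
#' @examples
#' regress_slope(3 * (0:9), dt = 1)  # exactly 3
#' @export
regress_slope <- function(e_window, dt = 1) {
  l <- length(e_window)
  if (l < 2L) stop("the regression window must hold at least 2 samples")
  if (any(!is.finite(e_window))) stop("error window contains non-finite values")
  x <- (seq_len(l) - 1) * dt
  xc <- x - mean(x)
  sum(xc * e_window) / sum(xc * xc)
}

#' One tick of the PID controller
#'
#' Computes the error against the setpoint, accumulates the integral term
#' (`e_sum`), estimates the derivative term as the regression slope of the
#' last `l` errors (0 until the window is full), and returns
#' `PID = K_P * e + K_I * e_sum + K_D * e_derivative`. The previous value of
#' the accumulator is retained in the state so the caller can freeze the
#' integral (anti-windup) on ticks where the routed output saturates; see
#' [pid_freeze_integral()].
#'
#' @param V_m Measured membrane potential, mV.
#' @param state Controller state (phase must be `"CORRECTING"`).
#' @param setpoint An `apqr_setpoint` (logged, file or generated).
#' @param gains An `apqr_pid_gains`.
#' @return `list(PID = <value>, e = <error>, state = <updated state>)`.
#' @export
pid_tick <- function(V_m, state, setpoint, gains) {
  if (state$phase != "CORRECTING")
    stop("pid_tick requires phase CORRECTING")
  n <- length(setpoint$values)
  if (state$i < 1L || state$i > n) stop("cycle index out of range")
  e <- V_m - setpoint$values[state$i]
  state$e_sum_prev <- state$e_sum
  state$e_sum <- state$e_sum + e
  w <- c(state$e_window, e)
  if (length(w) > gains$l) w <- w[(length(w) - gains$l + 1L):length(w)]
  state$e_window <- w
  ed <- if (length(w) < gains$l) 0 else regress_slope(w, gains$dt)
  pid <- gains$K_P * e + gains$K_I * state$e_sum + gains$K_D * ed
  if (!is.finite(pid)) stop("PID output is non-finite")
  state$e <- e
  state$e_prev <- e
  state$i <- if (state$i == n) 1L else state$i + 1L
  list(PID = pid, e = e, e_derivative = ed, state = state)
}

#' Freeze the integral accumulator for the current tick
#'
#' Anti-windup: reverts the integral accumulator to its value before the
#' last [pid_tick()], to be called when the routed output of that tick was
#' saturated (clipped at 1, or gated to 0 while a correction was demanded).
#'
#' @param state Controller state returned by [pid_tick()].
#' @return The state with `e_sum` reverted.
#' @export
pid_freeze_integral <- function(state) {
  state$e_sum <- state$e_sum_prev
  state
}

#' Route a controller output to the two light channels
#'
#' A positive output drives the red (hyperpolarizing) LED and a negative
#' output drives the blue (depolarizing) LED with its absolute value. Blue
#' output is only permitted while the measured membrane potential is more
#' negative than the blue actuator's plateau potential; otherwise the demand
#' is dropped. At most one channel is nonzero on any tick.
#'
#' @param PID Controller output.
#' @param V_m Measured membrane potential, mV.
#' @param V_plateau Gating bound for blue output, mV.
#' @param scale Red-channel scale (normalized irradiance per output unit).
#' @param scale_blue Blue-channel scale; defaults to `scale`.
#' @param stall_mV Authority-stall margin for the blue channel, mV: a blue
#'   demand issued while the measured potential lies within this margin of
#'   `V_plateau` is flagged as saturated (the conductance has essentially no
#'   driving force left), so the caller can freeze the integral term.
#' @return `list(blue =, red =, saturated = <logical>)`; `saturated` is TRUE
#'   when the commanded drive was clipped at 1, gated to 0, or stalled
#'   against the blue actuator's reversal.
#' @export
route_output <- function(PID, V_m, V_plateau, scale = 1,
                         scale_blue = scale, stall_mV = 1) {
  blue <- 0; red <- 0; saturated <- FALSE
  if (PID > 0) {
    red <- scale * PID
    if (red >= 1) { red <- 1; saturated <- TRUE }
  } else if (PID < 0) {
    if (V_m < V_plateau) {
      blue <- scale_blue * -PID
      if (blue >= 1) { blue <- 1; saturated <- TRUE }
      if (V_m >= V_plateau - stall_mV) saturated <- TRUE
    } else saturated <- TRUE  # demand gated to zero
  }
  list(blue = blue, red = red, saturated = saturated)
}

#' One tick of the waveform-enforcement controller
#'
#' Identical to the PID controller except that the setpoint is a model
#' waveform held on the computer and that the controller itself paces the
#' preparation: during the first `pace_ms` of every cycle a blue pacing pulse
#' is emitted (superseding corrective output). Corrective PID output starts
#' once an action-potential upstroke has been detected (first tick after the
#' pacing pulse whose 1-ms voltage increment exceeds `upstroke_dvdt`), and
#' from then on runs on every non-pacing tick, which also enforces the
#' model's resting potential between action potentials.
#'
#' @param t Absolute time of the tick, ms.
#' @param V_m Measured membrane potential, mV.
#' @param state Controller state.
#' @param model An `apqr_setpoint` of origin `"file"` or `"generator"`,
#'   at least one pacing cycle long.
#' @param gains An `apqr_pid_gains`.
#' @param period Pacing cycle length, ms.
#' @param pace_ms Pacing pulse duration, ms.
#' @param pace_level Normalized blue irradiance of the pacing pulse.
#' @param upstroke_dvdt Upstroke detection threshold, mV/ms.
#' @return `list(blue =, red =, PID =, e =, state =)`.
#' @export
le_tick <- function(t, V_m, state, model, gains, period = 1000,
                    pace_ms = 10, pace_level = 1 / 3, upstroke_dvdt = 2) {
  if (!model$origin %in% c("file", "generator"))
    stop("enforcement requires a model setpoint loaded from file or generated")
  if (length(model$values) < period)
    stop("model AP is shorter than the pacing cycle")
  pos <- t %% period
  state$i <- as.integer(pos) + 1L
  dvdt <- if (is.na(state$V_prev)) 0 else V_m - state$V_prev
  state$V_prev <- V_m
  if (!state$correcting && dvdt > upstroke_dvdt) state$correcting <- TRUE
  if (pos < pace_ms) {
    # pacing window: emit the pulse, freeze the corrective state
    return(list(blue = pace_level, red = 0, PID = NA_real_, e = NA_real_,
                state = state))
  }
  if (!state$correcting)
    return(list(blue = 0, red = 0, PID = NA_real_, e = NA_real_,
                state = state))
  idx <- state$i
  res <- pid_tick(V_m, state, model, gains)
  out <- route_output(res$PID, V_m, gains$V_plateau, gains$scale,
                      gains$scale_blue)
  st <- res$state
  # a blue demand toward a setpoint at or above the actuator's reversal is
  # unreachable; integrating it would only wind up the accumulator
  unreachable <- res$PID < 0 && model$values[idx] >= gains$V_plateau - 0.5
  if (out$saturated || unreachable) st <- pid_freeze_integral(st)
  list(blue = out$blue, red = out$red, PID = res$PID, e = res$e, state = st)
}
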