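#' Experiment protocol
#'
#' Describes pacing, optional light disturbance, optional drug-like
#' perturbation, and the beat counts of the logging / paused / correcting
#' phases of a restoration experiment.
#'
#' @param pacing List with `mode` (`"electrical"` or `"optical"`), `period`
#'   (ms), `pulse_ms` (pulse duration) and `pulse_level` (current density in
#'   mV/ms for electrical pacing, normalized irradiance for optical pacing).
#' @param disturbance `NULL`, or a list with `every_n` (perturb every n-th
#'   correcting beat), `delay_ms`, `duration_ms` and `blue_level`
#'   (normalized irradiance) describing the preprogrammed blue pulse.
#' @param drug List with `label` (`"none"`, `"fourAP"`, `"carbachol"`) and
#'   `onset_beat` (first beat with the drug active; default: the first beat
#'   after the logging phase).
#' @param phases List with beat counts `logging`, `paused`, `correcting`.
#' @return An object of class `apqr_protocol`.
#' @export
protocol <- function(pacing = list(), disturbance = NULL, drug = list(),
                     phases = list()) {
  user <- names(pacing)
  pacing <- utils::modifyList(
    list(mode = "electrical", period = 1000, pulse_ms = 5, pulse_level = 15),
    pacing)
  if (!pacing$mode %in% c("electrical", "optical"))
    stop("pacing mode must be 'electrical' or 'optical'")
  if (pacing$mode == "optical") {
    # optical pacing defaults: 10-ms pulse at a third of maximal irradiance
    if (!"pulse_ms" %in% user) pacing$pulse_ms <- 10
    if (!"pulse_level" %in% user) pacing$pulse_level <- 1 / 3
  }
  if (pacing$period <= pacing$pulse_ms)
    stop("pacing period must exceed the pulse duration")
  if (!is.null(disturbance)) {
    disturbance <- utils::modifyList(
      list(every_n = 5, delay_ms = 200, duration_ms = 200,
           blue_level = 0.1 / 1.5), disturbance)
    if (disturbance$delay_ms + disturbance$duration_ms >= pacing$period)
      stop("disturbance must end within the pacing cycle")
  }
  drug <- utils::modifyList(list(label = "none", onset_beat = NULL), drug)
  phases <- utils::modifyList(
    list(logging = 5, paused = 0, correcting = 10), phases)
  structure(list(pacing = pacing, disturbance = disturbance, drug = drug,
                 phases = phases), class = "apqr_protocol")
}

#' Controller specification for the loop engine
#'
#' Binds a control algorithm to gains and an actuation mode. The adaptive
#' proportional controller (`"apqr"`) drives a single output channel
#' (injected current or the red LED); the PID controller (`"apqr_pid"`)
#' drives the two antagonistic LEDs through the sign-based router.
#'
#' @param algorithm `"apqr"` or `"apqr_pid"`.
#' @param gains An `apqr_apqr_gains` or `apqr_pid_gains` object matching the
#'   algorithm.
#' @param actuation `"current"`, `"single_optical"` (red LED only) or
#'   `"dual_optical"`.
#' @return An object of class `apqr_controller_spec`.
#' @export
controller_spec <- function(algorithm = c("apqr", "apqr_pid"),
                            gains = NULL,
                            actuation = c("current", "single_optical",
                                          "dual_optical")) {
  algorithm <- match.arg(algorithm)
  actuation <- match.arg(actuation)
  if (is.null(gains))
    gains <- if (algorithm == "apqr") apqr_gains() else pid_gains()
  ok <- (algorithm == "apqr" && actuation %in% c("current", "single_optical") &&
           inherits(gains, "apqr_apqr_gains")) ||
        (algorithm == "apqr_pid" && actuation %in% c("dual_optical",
                                                     "current") &&
           inherits(gains, "apqr_pid_gains"))
  if (!ok)
    stop("controller/actuation mismatch: apqr drives one channel ",
         "(current or single_optical), apqr_pid drives dual_optical")
  structure(list(algorithm = algorithm, gains = gains,
                 actuation = actuation), class = "apqr_controller_spec")
}

## deterministic per-tick measurement noise stream
.noise_stream <- function(n, sd, seed) {
  if (sd <= 0) return(numeric(n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Run an AP-shape restoration experiment
#'
#' Executes the full closed-loop protocol at the fixed 1-ms control step:
#' drug-free logging beats (averaged into the setpoint), optional paused
#' beats during which a drug-like perturbation develops, then correcting
#' beats with live control. The measured potential at the start of each tick
#' drives the controller; the resulting actuation is held for the whole tick
#' (zero-order hold) while the plant integrates 20 substeps of 0.05 ms.
#'
#' @param plant Plant parameters from [plant_params()].
#' @param controller A [controller_spec()].
#' @param prot A [protocol()].
#' @param control If `FALSE`, the correcting phase runs with outputs forced
#'   to zero (the control-OFF comparison run).
#' @return A `data.frame` log of class `apqr_loop_log`, one row per tick,
#'   with the setpoint attached as attribute `"setpoint"`.
#' @export
run_restoration <- function(plant, controller, prot = protocol(),
                            control = TRUE) {
  stopifnot(inherits(plant, "apqr_plant_params"),
            inherits(controller, "apqr_controller_spec"),
            inherits(prot, "apqr_protocol"))
  g <- controller$gains
  ph <- prot$phases
  if (ph$logging != g$lognum)
    stop("protocol logging phase (", ph$logging,
         " beats) does not match controller lognum (", g$lognum, ")")
  period <- prot$pacing$period
  beats_total <- ph$logging + ph$paused + ph$correcting
  n <- beats_total * period
  phase_of_beat <- rep(c("LOGGING", "PAUSED", "CORRECTING"),
                       c(ph$logging, ph$paused, ph$correcting))
  onset <- prot$drug$onset_beat
  if (is.null(onset)) onset <- ph$logging + 1L
  pc_base <- .plant_pack(plant)
  pc_drug <- .plant_pack(apply_pharmacology(plant, prot$drug$label))
  noise <- .noise_stream(n, plant$noise_sd, plant$seed)

  st <- c(plant$V_rest_target, 1, 0, 0)
  setpoint <- NULL
  beat_buf <- vector("list", ph$logging)
  cur_beat <- numeric(period)
  is_pid <- controller$algorithm == "apqr_pid"
  state <- controller_state(phase = "CORRECTING",
                            R_m = if (is_pid) 100 else g$R_m,
                            l = if (is_pid) g$l else 10L)
  L_V <- L_set <- L_e <- L_esum <- L_ederiv <- L_out <- L_blue <- L_red <-
    L_pace <- L_dist <- L_inj <- numeric(n)
  L_phase <- character(n)
  elec <- prot$pacing$mode == "electrical"
  dist <- prot$disturbance

  for (i in seq_len(n)) {
    beat <- (i - 1L) %/% period + 1L
    pos <- (i - 1L) %% period
    bphase <- phase_of_beat[beat]
    pc <- if (prot$drug$label != "none" && beat >= onset) pc_drug else pc_base
    V_meas <- st[[1L]] + noise[i]

    pace_I <- 0; pace_blue <- 0
    if (pos < prot$pacing$pulse_ms) {
      if (elec) pace_I <- prot$pacing$pulse_level
      else pace_blue <- prot$pacing$pulse_level
    }
    dist_blue <- 0
    if (!is.null(dist) && bphase == "CORRECTING") {
      k <- beat - ph$logging - ph$paused
      if (k %% dist$every_n == 0L &&
          pos >= dist$delay_ms && pos < dist$delay_ms + dist$duration_ms)
        dist_blue <- dist$blue_level
    }

    out <- 0; blue_c <- 0; red_c <- 0; I_ctrl <- 0
    e <- NA_real_; esum <- NA_real_; ederiv <- NA_real_
    if (bphase == "CORRECTING") {
      if (is.null(setpoint)) stop("correction phase reached with no setpoint")
      e <- V_meas - setpoint$values[pos + 1L]
      if (control) {
        state$i <- pos + 1L
        if (is_pid) {
          res <- pid_tick(V_meas, state, setpoint, g)
          out <- res$PID
          esum <- res$state$e_sum
          ederiv <- res$e_derivative
          if (controller$actuation == "dual_optical") {
            r <- route_output(out, V_meas, g$V_plateau, g$scale, g$scale_blue)
            blue_c <- r$blue; red_c <- r$red
            state <- if (r$saturated) pid_freeze_integral(res$state)
                     else res$state
          } else {            # PID by direct current injection
            I_ctrl <- -g$scale * out
            state <- res$state
          }
        } else {
          res <- apqr_tick(V_meas, state, setpoint, g)
          out <- res$I_out
          state <- res$state
          if (controller$actuation == "current") {
            I_ctrl <- -g$scale * out
          } else {            # single red actuator
            red_c <- min(max(g$scale * out, 0), 1)
          }
        }
      }
    } else if (!is.null(setpoint)) {
      e <- V_meas - setpoint$values[pos + 1L]
    }

    L_phase[i] <- bphase
    L_V[i] <- V_meas
    L_set[i] <- if (is.null(setpoint)) NA_real_ else setpoint$values[pos + 1L]
    L_e[i] <- e
    L_esum[i] <- esum
    L_ederiv[i] <- ederiv
    L_out[i] <- out
    L_blue[i] <- blue_c
    L_red[i] <- red_c
    L_pace[i] <- if (elec) pace_I else pace_blue
    L_dist[i] <- dist_blue
    L_inj[i] <- I_ctrl

    blue_tot <- min(blue_c + pace_blue + dist_blue, 1)
    st <- .plant_tick(st, pc, blue_tot, red_c, pace_I + I_ctrl)

    if (bphase == "LOGGING") {
      cur_beat[pos + 1L] <- V_meas
      if (pos == period - 1L) {
        beat_buf[[beat]] <- cur_beat
        if (beat == ph$logging)
          setpoint <- log_setpoint(beat_buf, g$lognum)
      }
    }
  }
  log <- data.frame(t = seq_len(n) - 1,
                    beat = (seq_len(n) - 1L) %/% period + 1L,
                    phase = L_phase, V_m = L_V, setpoint = L_set, e = L_e,
                    e_sum = L_esum, e_derivative = L_ederiv, out = L_out,
                    blue = L_blue, red = L_red, pace = L_pace,
                    dist_blue = L_dist, I_inj = L_inj)
  structure(log, class = c("apqr_loop_log", "data.frame"),
            setpoint = setpoint, period = period)
}

#' Run a waveform-enforcement experiment
#'
#' First paces the plant electrically with the controller off to register
#' endogenous (control) action potentials, then switches to the enforcement
#' controller: optical pacing pulses at 1 Hz trigger action potentials, and
#' once an upstroke is detected the PID core corrects the measured potential
#' toward the model waveform on every non-pacing tick.
#'
#' @param plant Plant parameters.
#' @param gains An `apqr_pid_gains`.
#' @param model Model waveform (`apqr_setpoint`, origin file or generator).
#' @param n_beats Number of enforced beats.
#' @param ctl_beats Initial uncontrolled, electrically paced beats.
#' @param period Pacing cycle, ms.
#' @param pace_ms,pace_level Optical pacing pulse duration and level.
#' @return An `apqr_loop_log`; enforced beats carry phase `"CORRECTING"`,
#'   the initial segment phase `"CTL"`.
#' @export
run_enforcement <- function(plant, gains, model, n_beats = 8, ctl_beats = 3,
                            period = 1000, pace_ms = 10, pace_level = 1 / 3) {
  stopifnot(inherits(plant, "apqr_plant_params"),
            inherits(gains, "apqr_pid_gains"),
            inherits(model, "apqr_setpoint"))
  if (length(model$values) < period)
    stop("model AP is shorter than the pacing cycle")
  pc <- .plant_pack(plant)
  n <- (ctl_beats + n_beats) * period
  noise <- .noise_stream(n, plant$noise_sd, plant$seed)
  st <- c(plant$V_rest_target, 1, 0, 0)
  state <- controller_state(phase = "CORRECTING", l = gains$l)
  L_V <- L_e <- L_esum <- L_out <- L_blue <- L_red <- L_pace <- numeric(n)
  L_phase <- character(n)
  for (i in seq_len(n)) {
    beat <- (i - 1L) %/% period + 1L
    pos <- (i - 1L) %% period
    ctl <- beat <= ctl_beats
    V_meas <- st[[1L]] + noise[i]
    pace_I <- 0; blue <- 0; red <- 0
    out <- NA_real_; e <- NA_real_
    if (ctl) {
      if (pos < 5) pace_I <- 15
    } else {
      t_le <- (beat - ctl_beats - 1L) * period + pos
      res <- le_tick(t_le, V_meas, state, model, gains, period = period,
                     pace_ms = pace_ms, pace_level = pace_level)
      state <- res$state
      blue <- res$blue; red <- res$red
      out <- res$PID; e <- res$e
    }
    L_phase[i] <- if (ctl) "CTL" else "CORRECTING"
    L_V[i] <- V_meas
    L_e[i] <- e
    L_esum[i] <- state$e_sum
    L_out[i] <- out
    L_blue[i] <- if (!ctl && pos < pace_ms) 0 else blue
    L_red[i] <- red
    L_pace[i] <- if (ctl) pace_I else if (pos < pace_ms) blue else 0
    st <- .plant_tick(st, pc, blue, red, pace_I)
  }
  ticks <- seq_len(n)
  log <- data.frame(t = ticks - 1, beat = (ticks - 1L) %/% period + 1L,
                    phase = L_phase, V_m = L_V,
                    setpoint = rep_len(model$values[seq_len(period)], n),
                    e = L_e, e_sum = L_esum, e_derivative = NA_real_,
                    out = L_out, blue = L_blue, red = L_red, pace = L_pace,
                    dist_blue = 0, I_inj = 0)
  structure(log, class = c("apqr_loop_log", "data.frame"),
            setpoint = model, period = period)
}

#' Pace the plant without control
#'
#' Convenience open-loop run used for calibration checks and model
#' recording: fixed-rate pacing, no controller.
#'
#' @param plant Plant parameters.
#' @param n_beats Number of beats.
#' @param pacing `"electrical"` or `"optical"`.
#' @param period Pacing cycle, ms.
#' @return Data frame with columns `t`, `beat`, `V_m`.
#' @export
run_paced <- function(plant, n_beats = 6, pacing = c("electrical", "optical"),
                      period = 1000) {
  pacing <- match.arg(pacing)
  pc <- .plant_pack(plant)
  st <- c(plant$V_rest_target, 1, 0, 0)
  n <- n_beats * period
  V <- numeric(n)
  for (i in seq_len(n)) {
    pos <- (i - 1L) %% period
    blue <- if (pacing == "optical" && pos < 10) 1 / 3 else 0
    I <- if (pacing == "electrical" && pos < 5) 15 else 0
    st <- .plant_tick(st, pc, blue, 0, I)
    V[i] <- st[[1L]]
  }
  data.frame(t = seq_len(n) - 1, beat = (seq_len(n) - 1L) %/% period + 1L,
             V_m = V)
}

#' Write / read a loop log
#'
#' Per-tick logs are exchanged as plain CSV with a fixed column order; a
#' written log reads back equal to the original.
#'
#' @param log An `apqr_loop_log`.
#' @param path File path.
#' @return [read_log()] returns the log; [write_log()] invisibly returns
#'   `path`.
#' @export
write_log <- function(log, path) {
  utils::write.csv(format(as.data.frame(log), digits = 15, trim = TRUE),
                   path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  d <- utils::read.csv(path, header = TRUE)
  d$phase <- as.character(d$phase)
  for (cn in setdiff(names(d), "phase")) d[[cn]] <- as.numeric(d[[cn]])
  d$beat <- as.integer(d$beat)
  structure(d, class = c("apqr_loop_log", "data.frame"))
}
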