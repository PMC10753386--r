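#' Per-beat membrane-potential traces of a log
#'
#' @param log An `apqr_loop_log`.
#' @param beats Beat numbers to extract; default all complete beats.
#' @return Matrix (beats x ticks) of membrane potential, rownames = beat.
#' @export
beat_traces <- function(log, beats = NULL) {
  period <- attr(log, "period")
  if (is.null(period)) period <- sum(log$beat == log$beat[1])
  if (is.null(beats)) beats <- unique(log$beat)
  m <- t(vapply(beats, function(b) log$V_m[log$beat == b], numeric(period)))
  rownames(m) <- beats
  m
}

## windowed error samples of one beat: measured minus reference over the
## dV/dt_max -> 90%-repolarization window of the measured beat. The beat
## trace is extended by `pre` samples from the preceding beat so that the
## resting potential can be measured pre-stimulus.
.beat_window_errors <- function(V, b0, period, reference, pre = 50L) {
  ext <- V[(b0 - pre + 1L):(b0 + period)]
  m <- ap_metrics(ext, stim_tick = pre + 1L, rest_window = pre)
  t90 <- m$t_repol[["0.9"]]
  if (is.na(t90)) stop("APD_90 undefined for a beat; window unavailable")
  err <- ext[(pre + 1L):(pre + period)] - reference
  tt <- (pre:(pre + period - 1L))     # times of the beat samples within ext
  err[tt >= m$t_dvdt_max & tt <= t90]
}

#' Control quality of a restoration run
#'
#' Pools membrane-potential error samples of the correcting beats over the
#' per-beat analysis window (the interval between the moment of maximal
#' upstroke velocity and the moment of 90% repolarization of the measured
#' beat) and summarizes them with [error_stats()]. The first correcting
#' beats can be excluded as controller settling time.
#'
#' @param log An `apqr_loop_log` from [run_restoration()].
#' @param setpoint Reference setpoint; defaults to the one attached to the
#'   log.
#' @param skip_beats Correcting beats to drop from the start (default 1).
#' @return An `apqr_error_stats` (see [error_stats()]); the pooled samples
#'   are attached as attribute `"errors"`.
#' @export
restoration_quality <- function(log, setpoint = NULL, skip_beats = 1L) {
  if (is.null(setpoint)) setpoint <- attr(log, "setpoint")
  period <- attr(log, "period")
  beats <- unique(log$beat[log$phase == "CORRECTING"])
  beats <- beats[-seq_len(min(skip_beats, length(beats) - 1L))]
  errs <- unlist(lapply(beats, function(b)
    .beat_window_errors(log$V_m, (b - 1L) * period, period,
                        setpoint$values)))
  s <- error_stats(errs)
  attr(s, "errors") <- errs
  s
}

#' Control quality of an enforcement run
#'
#' Pools the membrane-potential error over all ticks of the enforced beats
#' (the entire cycle is under control during enforcement, including the
#' diastolic interval where the model's resting potential is imposed) and
#' summarizes it with [error_stats()].
#'
#' @param log An `apqr_loop_log` from [run_enforcement()].
#' @param model Model waveform; defaults to the one attached to the log.
#' @param skip_beats Enforced beats dropped from the start as settling
#'   (default 2).
#' @return An `apqr_error_stats` with the pooled samples attached as
#'   attribute `"errors"`.
#' @export
enforcement_quality <- function(log, model = NULL, skip_beats = 2L) {
  if (is.null(model)) model <- attr(log, "setpoint")
  period <- attr(log, "period")
  beats <- unique(log$beat[log$phase == "CORRECTING"])
  beats <- beats[-seq_len(min(skip_beats, length(beats) - 1L))]
  errs <- unlist(lapply(beats, function(b) {
    idx <- which(log$beat == b)
    log$V_m[idx] - model$values[seq_len(period)]
  }))
  s <- error_stats(errs)
  attr(s, "errors") <- errs
  s
}

#' Action-potential metrics of every beat in a log
#'
#' @param log An `apqr_loop_log`.
#' @param phase Restrict to beats of this phase (`NULL` for all).
#' @param skip_beats Beats of the selected phase dropped from the start.
#' @return Data frame with one row per beat: beat number, phase, `V_peak`,
#'   `V_rest`, `dvdt_max` and APD at 20/30/50/90% repolarization.
#' @export
log_ap_metrics <- function(log, phase = NULL, skip_beats = 0L) {
  period <- attr(log, "period")
  beats <- unique(if (is.null(phase)) log$beat
                  else log$beat[log$phase == phase])
  beats <- beats[beats > 1L]                # need a preceding beat for V_rest
  if (skip_beats > 0L) beats <- beats[-seq_len(min(skip_beats,
                                                   length(beats) - 1L))]
  rows <- lapply(beats, function(b) {
    ext <- log$V_m[((b - 1L) * period - 49L):(b * period)]
    m <- ap_metrics(ext, stim_tick = 51L)
    data.frame(beat = b, phase = log$phase[(b - 1L) * period + 1L],
               V_peak = m$V_peak, V_rest = m$V_rest, dvdt_max = m$dvdt_max,
               APD20 = m$APD[["0.2"]], APD30 = m$APD[["0.3"]],
               APD50 = m$APD[["0.5"]], APD90 = m$APD[["0.9"]])
  })
  do.call(rbind, rows)
}
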