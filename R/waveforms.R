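#' Triangular model action potential specification
#'
#' Two-phase piecewise-linear model waveforms: a linear upstroke from
#' `V_start` to `V_peak` at `upstroke_rate`, then a linear repolarization at
#' `repol_rate` back to `V_start`, where the waveform is clamped for the rest
#' of the cycle. The four standard repolarization rates 1.3, 0.9, 0.5 and
#' 0.1 mV/ms define the models t13, t09, t05 and t01.
#'
#' @param repol_rate Repolarization rate, mV/ms (> 0).
#' @param V_start Resting/start potential, mV.
#' @param upstroke_rate Upstroke rate, mV/ms.
#' @param V_peak Peak potential, mV.
#' @param cycle_ms Pacing cycle length, ms.
#' @param onset_ms Time of the upstroke foot within the cycle, ms.
#' @return An object of class `apqr_triangular_spec`.
#' @export
triangular_spec <- function(repol_rate, V_start = -68, upstroke_rate = 20,
                            V_peak = 12, cycle_ms = 1000, onset_ms = 10) {
  if (V_peak <= V_start) stop("V_peak must exceed V_start")
  if (repol_rate <= 0 || upstroke_rate <= 0) stop("rates must be > 0")
  structure(list(repol_rate = repol_rate, V_start = V_start,
                 upstroke_rate = upstroke_rate, V_peak = V_peak,
                 cycle_ms = as.integer(cycle_ms),
                 onset_ms = as.integer(onset_ms)),
            class = "apqr_triangular_spec")
}

#' Generate a triangular model action potential
#'
#' Samples a [triangular_spec()] at the 1-ms control step. The peak sample is
#' placed at the analytic peak time rounded to the nearest tick and the
#' waveform is clamped at `V_start` once repolarization completes.
#'
#' @param spec A `apqr_triangular_spec`, or a repolarization rate in mV/ms.
#' @return An `apqr_setpoint` of origin `"generator"`.
#' @examples
#' t13 <- triangular_model(1.3)
#' max(t13$values)  # 12 mV
#' @export
triangular_model <- function(spec) {
  if (is.numeric(spec)) spec <- triangular_spec(spec)
  amp <- spec$V_peak - spec$V_start
  t_up <- amp / spec$upstroke_rate
  t_down <- amp / spec$repol_rate
  t_peak <- spec$onset_ms + t_up
  if (t_peak + t_down >= spec$cycle_ms)
    stop("repolarization does not complete within the pacing cycle")
  tt <- seq_len(spec$cycle_ms) - 1
  v <- ifelse(tt < spec$onset_ms, spec$V_start,
       ifelse(tt < t_peak, spec$V_start + spec$upstroke_rate *
                (tt - spec$onset_ms),
       pmax(spec$V_peak - spec$repol_rate * (tt - t_peak), spec$V_start)))
  # place the peak sample exactly at the rounded analytic peak time
  v[round(t_peak) + 1L] <- spec$V_peak
  setpoint_ap(v, origin = "generator")
}

#' The four standard triangular models
#'
#' Convenience generator for the t13, t09, t05 and t01 model waveforms
#' (repolarization rates 1.3, 0.9, 0.5 and 0.1 mV/ms).
#'
#' @return Named list of `apqr_setpoint`s.
#' @export
triangular_models <- function() {
  rates <- c(t13 = 1.3, t09 = 0.9, t05 = 0.5, t01 = 0.1)
  lapply(rates, triangular_model)
}

#' Read / write model action potentials
#'
#' Model waveforms are exchanged as two-column CSV files
#' (`t_ms,Vm_mV`, header required) with strictly 1-ms spacing starting at 0.
#' The loader validates spacing and finiteness and reports the offending row
#' on failure; a written file loads back to the identical setpoint.
#'
#' @param path File path.
#' @return [load_model_ap()] returns an `apqr_setpoint` of origin `"file"`;
#'   [save_model_ap()] invisibly returns `path`.
#' @export
load_model_ap <- function(path) {
  d <- utils::read.csv(path, header = TRUE)
  if (!identical(names(d)[1:2], c("t_ms", "Vm_mV")))
    stop("model AP file must have header 't_ms,Vm_mV'")
  if (nrow(d) < 2L) stop("model AP file holds fewer than 2 samples")
  dt <- diff(d$t_ms)
  bad <- which(abs(dt - 1) > 1e-9)
  if (length(bad))
    stop("non-uniform sampling (expected 1 ms) at row ", bad[1] + 1L)
  nf <- which(!is.finite(d$Vm_mV))
  if (length(nf)) stop("non-finite membrane potential at row ", nf[1])
  setpoint_ap(d$Vm_mV, origin = "file")
}

#' @param setpoint An `apqr_setpoint` to write.
#' @rdname load_model_ap
#' @export
save_model_ap <- function(setpoint, path) {
  d <- data.frame(t_ms = seq_along(setpoint$values) - 1,
                  Vm_mV = setpoint$values)
  utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Record a drug-perturbed model action potential from the plant
#'
#' Paces the plant to periodic steady state under a drug-like perturbation
#' and packages the final cycle as a model waveform for enforcement
#' experiments. Optical pacing (the enforcement controller's own trigger) is
#' the default so that recorded models are tick-aligned with enforcement.
#'
#' @param params Plant parameters.
#' @param drug One of `"none"`, `"fourAP"`, `"carbachol"`.
#' @param pacing `"optical"` or `"electrical"`.
#' @param period Pacing cycle, ms.
#' @param max_beats Beats to pace before giving up on stationarity.
#' @param tol_mV Sample-wise stationarity tolerance between the last two
#'   beats, mV.
#' @return An `apqr_setpoint` of origin `"generator"`.
#' @export
record_drug_model <- function(params, drug = "none", pacing = c("optical",
                              "electrical"), period = 1000, max_beats = 20,
                              tol_mV = 0.5) {
  pacing <- match.arg(pacing)
  p <- apply_pharmacology(params, drug)
  pc <- .plant_pack(p)
  st <- c(p$V_rest_target, 1, 0, 0)
  prev <- NULL
  for (b in seq_len(max_beats)) {
    cur <- numeric(period)
    for (k in seq_len(period)) {
      blue <- if (pacing == "optical" && k <= 10) 1 / 3 else 0
      I <- if (pacing == "electrical" && k <= 5) 15 else 0
      st <- .plant_tick(st, pc, blue, 0, I)
      cur[k] <- st[[1L]]
    }
    if (!is.null(prev) && max(abs(cur - prev)) < tol_mV)
      return(setpoint_ap(cur, origin = "generator"))
    prev <- cur
  }
  stop("plant failed to reach a periodic steady state within ", max_beats,
       " beats")
}
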