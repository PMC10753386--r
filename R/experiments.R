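#' Canned experiment: AP restoration by direct current injection
#'
#' Single-cell arrangement: the adaptive proportional controller corrects a
#' repolarization-slowing (4AP-like) perturbation by injecting current
#' through the recording electrode. Runs the full protocol (logging, pause
#' while the drug effect develops, correction) once with control on and once
#' with control off, and quantifies both runs over the per-beat
#' dV/dt_max -> APD_90 window.
#'
#' @param plant Plant parameters (default [plant_params()]).
#' @param correcting Number of correcting beats.
#' @return List with `log_on`, `log_off`, `quality_on`, `quality_off`
#'   (see [restoration_quality()]) and the `controller` and `prot` used.
#' @export
scenario_current_injection <- function(plant = plant_params(),
                                       correcting = 10) {
  ctrl <- controller_spec("apqr", apqr_gains(), "current")
  prot <- protocol(drug = list(label = "fourAP"),
                   phases = list(logging = 5, paused = 10,
                                 correcting = correcting))
  .run_scenario(plant, ctrl, prot)
}

#' Canned experiment: AP restoration by a single optogenetic actuator
#'
#' The adaptive proportional controller drives only the red
#' (hyperpolarizing) LED against a 4AP-like perturbation.
#'
#' @inheritParams scenario_current_injection
#' @return As [scenario_current_injection()].
#' @export
scenario_single_actuator <- function(plant = plant_params(),
                                     correcting = 10) {
  ctrl <- controller_spec("apqr", apqr_gains(scale = 0.06), "single_optical")
  prot <- protocol(drug = list(label = "fourAP"),
                   phases = list(logging = 5, paused = 10,
                                 correcting = correcting))
  .run_scenario(plant, ctrl, prot)
}

#' Canned experiment: dual-actuator restoration under a light disturbance
#'
#' Optically paced monolayer arrangement: every 5th correcting beat is
#' perturbed by a preprogrammed 200-ms blue pulse (0.1 of 1.5 mW/mm^2,
#' 200 ms after the pacing stimulus); the PID controller autonomously
#' activates the red LED to neutralize it.
#'
#' @inheritParams scenario_current_injection
#' @return As [scenario_current_injection()].
#' @export
scenario_light_disturbance <- function(plant = plant_params(),
                                       correcting = 10) {
  ctrl <- controller_spec("apqr_pid", pid_gains(), "dual_optical")
  prot <- protocol(pacing = list(mode = "optical"),
                   disturbance = list(),
                   phases = list(logging = 5, paused = 0,
                                 correcting = correcting))
  .run_scenario(plant, ctrl, prot)
}

#' Canned experiment: dual-actuator restoration of a 4AP-like perturbation
#'
#' The PID controller corrects drug-induced APD prolongation with the two
#' antagonistic LEDs (predominantly red output).
#'
#' @inheritParams scenario_current_injection
#' @return As [scenario_current_injection()].
#' @export
scenario_dual_fourap <- function(plant = plant_params(), correcting = 10) {
  ctrl <- controller_spec("apqr_pid", pid_gains(), "dual_optical")
  prot <- protocol(drug = list(label = "fourAP"),
                   phases = list(logging = 5, paused = 10,
                                 correcting = correcting))
  .run_scenario(plant, ctrl, prot)
}

.run_scenario <- function(plant, ctrl, prot) {
  log_on <- run_restoration(plant, ctrl, prot)
  log_off <- run_restoration(plant, ctrl, prot, control = FALSE)
  list(log_on = log_on, log_off = log_off,
       quality_on = restoration_quality(log_on),
       quality_off = restoration_quality(log_off),
       controller = ctrl, prot = prot)
}

#' Canned experiment: enforcement of a drug-model waveform
#'
#' Records the drug-perturbed AP of the plant as a model waveform, then
#' enforces it on the unperturbed plant with the waveform-enforcement
#' controller (optical pacing, PID correction).
#'
#' @param plant Plant parameters.
#' @param drug `"carbachol"` or `"fourAP"`.
#' @param n_beats Enforced beats.
#' @param gains PID gains.
#' @return List with `model`, `log`, `quality` (see
#'   [enforcement_quality()]).
#' @export
scenario_enforce_drug <- function(plant = plant_params(),
                                  drug = "carbachol", n_beats = 8,
                                  gains = pid_gains()) {
  model <- record_drug_model(plant, drug)
  log <- run_enforcement(plant, gains, model, n_beats = n_beats,
                         ctl_beats = 3)
  list(model = model, log = log, quality = enforcement_quality(log))
}

#' Canned experiment: enforcement of the triangular model sequence
#'
#' Enforces the triangular models in the standard consecutive order
#' (t13, t09, t05, t01, t05, t09, t13). The runs are deterministic, so each
#' distinct model is simulated once and its pooled error samples are
#' weighted by the number of times it appears in the sequence.
#'
#' @param plant Plant parameters.
#' @param order Character vector of model names from
#'   [triangular_models()].
#' @param n_beats Enforced beats per segment.
#' @param gains PID gains.
#' @return List with `per_model` (error-stat list per distinct model),
#'   `quality` (combined, sequence-weighted [error_stats()]), `logs`.
#' @export
scenario_enforce_triangular <- function(plant = plant_params(),
                                        order = c("t13", "t09", "t05", "t01",
                                                  "t05", "t09", "t13"),
                                        n_beats = 6,
                                        gains = pid_gains()) {
  models <- triangular_models()
  if (!all(order %in% names(models))) stop("unknown triangular model name")
  uniq <- unique(order)
  logs <- lapply(models[uniq], function(m)
    run_enforcement(plant, gains, m, n_beats = n_beats, ctl_beats = 2))
  per_model <- lapply(logs, enforcement_quality)
  w <- table(factor(order, levels = uniq))
  pooled <- unlist(lapply(uniq, function(nm)
    rep(attr(per_model[[nm]], "errors"), w[[nm]])))
  list(per_model = per_model, quality = error_stats(pooled), logs = logs)
}

#' Actuator plateau calibration report
#'
#' Runs the light-response calibration (1-s pulse per channel at maximal
#' intensity from the dark-adapted state) and reports the plateau potential
#' of each channel together with the resting potential in the dark.
#'
#' @param plant Plant parameters.
#' @return Data frame with one row per condition.
#' @export
calibration_report <- function(plant = plant_params()) {
  data.frame(
    condition = c("dark", "blue_max", "red_max"),
    irradiance = c(0, 1, 1),
    V_plateau_mV = c(plateau_response(plant),
                     plateau_response(plant, blue = 1),
                     plateau_response(plant, red = 1)))
}

#' Read an experiment configuration file
#'
#' One human-readable YAML document per experiment with optional blocks
#' `plant`, `controller`, `protocol`, `enforce` and top-level fields `mode`
#' (`calibrate`, `restore` or `enforce`) and `seed`. Omitted keys take the
#' package defaults; all protocol constants (1-Hz pacing, 10-ms optical
#' pulse, the 200-ms disturbance at 200-ms delay on every 5th beat) live in
#' those defaults rather than in code.
#'
#' @param path Path to the YAML file.
#' @return A validated list of class `apqr_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  experiment_config(cfg)
}

#' @param cfg A raw configuration list (as parsed from YAML).
#' @rdname read_experiment_config
#' @export
experiment_config <- function(cfg) {
  if (is.null(cfg$mode)) cfg$mode <- "restore"
  if (!cfg$mode %in% c("calibrate", "restore", "enforce"))
    stop("mode must be calibrate, restore or enforce")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$plant_params <- do.call(plant_params,
                              utils::modifyList(list(seed = cfg$seed),
                                                as.list(cfg$plant)))
  if (cfg$mode == "restore") {
    cc <- utils::modifyList(list(algorithm = "apqr", actuation = "current",
                                 gains = NULL), as.list(cfg$controller))
    gfun <- if (cc$algorithm == "apqr") apqr_gains else pid_gains
    cc$gains <- do.call(gfun, as.list(cc$gains))
    cfg$controller_spec <- controller_spec(cc$algorithm, cc$gains,
                                           cc$actuation)
    pr <- as.list(cfg$protocol)
    cfg$protocol_obj <- protocol(
      pacing = as.list(pr$pacing),
      disturbance = if (is.null(pr$disturbance)) NULL
                    else as.list(pr$disturbance),
      drug = as.list(pr$drug), phases = as.list(pr$phases))
    ph <- cfg$protocol_obj$phases
    if (ph$logging != cfg$controller_spec$gains$lognum)
      stop("config cross-check: logging beats must equal lognum")
  }
  if (cfg$mode == "enforce") {
    en <- utils::modifyList(
      list(model = "t13", model_file = NULL, n_beats = 6, gains = NULL),
      as.list(cfg$enforce))
    en$gains <- do.call(pid_gains, as.list(en$gains))
    cfg$enforce_opts <- en
  }
  class(cfg) <- c("apqr_experiment_config", "list")
  cfg
}

#' Run a configured experiment
#'
#' Dispatches on the configuration's `mode`: `calibrate` returns the plateau
#' report, `restore` the restoration scenario results (control on and off),
#' `enforce` the enforcement results for a named triangular model, a drug
#' model (`"carbachol"`, `"fourAP"`), or a model-AP CSV given as
#' `model_file`.
#'
#' @param cfg An `apqr_experiment_config` (or a path to one).
#' @return Mode-dependent result list; see the scenario functions.
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  stopifnot(inherits(cfg, "apqr_experiment_config"))
  p <- cfg$plant_params
  switch(cfg$mode,
    calibrate = calibration_report(p),
    restore = .run_scenario(p, cfg$controller_spec, cfg$protocol_obj),
    enforce = {
      en <- cfg$enforce_opts
      model <- if (!is.null(en$model_file)) load_model_ap(en$model_file)
        else if (en$model %in% c("t13", "t09", "t05", "t01"))
          triangular_models()[[en$model]]
        else record_drug_model(p, en$model)
      log <- run_enforcement(p, en$gains, model, n_beats = en$n_beats)
      list(model = model, log = log, quality = enforcement_quality(log))
    })
}

#' Figure-style summary of a loop log
#'
#' Pure function of a saved log: APD table per beat, pooled error
#' distribution of the correcting beats, and the within +/-2.5 mV fraction.
#' Regenerating the report from a written-and-reread log is idempotent.
#'
#' @param log An `apqr_loop_log` (or a path to a log CSV).
#' @param setpoint Reference setpoint; taken from the log attribute when
#'   present. For logs read back from CSV the per-tick `setpoint` column is
#'   used.
#' @param enforcement If `TRUE` summarize with [enforcement_quality()]
#'   (whole enforced cycles), otherwise with [restoration_quality()].
#' @return List with `apd` (data frame), `stats` (`apqr_error_stats`) and
#'   `histogram`.
#' @export
report_log <- function(log, setpoint = NULL, enforcement = FALSE) {
  if (is.character(log)) log <- read_log(log)
  if (is.null(attr(log, "period")))
    attr(log, "period") <- sum(log$beat == log$beat[1L])
  if (is.null(setpoint)) setpoint <- attr(log, "setpoint")
  if (is.null(setpoint)) {
    period <- attr(log, "period")
    idx <- which(log$phase == "CORRECTING")[seq_len(period)]
    setpoint <- setpoint_ap(log$setpoint[idx], origin = "generator")
  }
  stats <- if (enforcement) enforcement_quality(log, model = setpoint)
           else restoration_quality(log, setpoint = setpoint)
  list(apd = log_ap_metrics(log), stats = stats,
       histogram = stats$histogram)
}
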