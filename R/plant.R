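#' Synthetic optogenetic cardiomyocyte plant: parameters
#'
#' Builds the parameter set of the synthetic cardiomyocyte monolayer used as
#' the controlled plant. The membrane model is a phenomenological two-current
#' excitable model expressed in physical millivolts,
#' \eqn{V = V_{rest} + A \cdot u}: a gated inward excitation current
#' \eqn{J_{in} = h\,u^2(1-u)/\tau_{in}} whose gate \eqn{h} inactivates with
#' \eqn{\tau_{inact}} during the action potential and recovers with
#' \eqn{\tau_{open}} at rest, and an ungated repolarizing leak
#' \eqn{J_{leak} = -u\,g(u)} whose conductance is inward-rectifier-like:
#' strong (\eqn{1/\tau_{out}}) below and near the resting potential, weak
#' (\eqn{1/\tau_{close}}) during the plateau. Two optogenetic actuators act on
#' the membrane: a blue-light gated conductance shunting the voltage toward
#' its apparent reversal `E_blue` (CheRiff-like) and a red-light driven,
#' voltage-independent hyperpolarizing pump current (Jaws-like). Drug-like
#' perturbations scale `tau_close`: `f_4AP` (>= 1) slows repolarization,
#' `f_cch` (<= 1, carbachol-like) accelerates it.
#'
#' All currents are expressed as per-capacitance densities (mV/ms), so no
#' absolute cell size enters the dynamics; `C_m` is carried only as the
#' numerator of the adaptive proportional gain heuristic.
#'
#' @param V_rest_target Resting potential, mV.
#' @param amplitude Action-potential amplitude scale `A`, mV.
#' @param tau_in Excitation time constant, ms.
#' @param tau_out Sub-rest / background leak time constant, ms (strong
#'   rest conductance; sets the red-actuator calibration).
#' @param tau_open Gate recovery time constant at rest, ms.
#' @param tau_close Supra-rest repolarization leak time constant, ms; the
#'   main determinant of action-potential duration.
#' @param tau_inact Gate inactivation time constant during the action
#'   potential, ms.
#' @param u_gate Normalized voltage threshold separating gate recovery from
#'   gate inactivation.
#' @param u_leak,leak_width Centre and width (normalized voltage) of the
#'   rectifier transition of the leak conductance.
#' @param g_blue Maximal blue-light gated conductance, ms^-1.
#' @param E_blue Apparent reversal of the blue actuator, mV. The plateau
#'   reached under sustained maximal blue light equals `E_blue` to within
#'   1 mV.
#' @param I_red_max Maximal red-light driven hyperpolarizing current density,
#'   mV/ms. If `NULL` (default) it is calibrated so that the steady state
#'   under sustained maximal red light equals `red_plateau_target`.
#' @param red_plateau_target Target steady-state potential under maximal red
#'   light, mV.
#' @param tau_act_blue,tau_act_red First-order actuator activation time
#'   constants, ms.
#' @param f_4AP Multiplier (>= 1) applied to `tau_close` by
#'   [apply_pharmacology()] for the repolarization-slowing perturbation.
#' @param f_cch Multiplier (<= 1) applied to `tau_close` for the
#'   APD-shortening perturbation.
#' @param C_m Cell capacitance, pF.
#' @param noise_sd Standard deviation of optional Gaussian measurement noise
#'   added to the controller-visible membrane potential, mV. Default 0 keeps
#'   every simulation deterministic.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An object of class `apqr_plant_params` (a named list).
#' @seealso [plant_state()], [step_plant()], [apply_pharmacology()]
#' @export
plant_params <- function(V_rest_target = -75,
                         amplitude = 90,
                         tau_in = 0.9,
                         tau_out = 2,
                         tau_open = 100,
                         tau_close = 180,
                         tau_inact = 15,
                         u_gate = 0.15,
                         u_leak = 0.12,
                         leak_width = 0.03,
                         g_blue = 0.8,
                         E_blue = -11.2,
                         I_red_max = NULL,
                         red_plateau_target = -82,
                         tau_act_blue = 5,
                         tau_act_red = 5,
                         f_4AP = 1.55,
                         f_cch = 0.195,
                         C_m = 100,
                         noise_sd = 0,
                         seed = 1L) {
  p <- list(
    V_rest_target = V_rest_target, amplitude = amplitude,
    tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
    tau_close = tau_close, tau_inact = tau_inact,
    u_gate = u_gate, u_leak = u_leak, leak_width = leak_width,
    g_blue = g_blue, E_blue = E_blue,
    I_red_max = I_red_max, red_plateau_target = red_plateau_target,
    tau_act_blue = tau_act_blue, tau_act_red = tau_act_red,
    f_4AP = f_4AP, f_cch = f_cch, C_m = C_m,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  taus <- c(tau_in, tau_out, tau_open, tau_close, tau_inact,
            tau_act_blue, tau_act_red)
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("all time constants must be finite and > 0")
  if (!(f_cch > 0 && f_cch <= 1 && f_4AP >= 1))
    stop("pharmacology factors must satisfy 0 < f_cch <= 1 <= f_4AP")
  if (!(E_blue > V_rest_target))
    stop("E_blue must exceed V_rest_target (depolarizing actuator)")
  if (amplitude <= 0 || g_blue < 0 || C_m <= 0 || noise_sd < 0)
    stop("amplitude and C_m must be > 0; g_blue and noise_sd must be >= 0")
  if (is.null(p$I_red_max)) p$I_red_max <- calibrate_red_current(p)
  if (p$I_red_max < 0) stop("I_red_max must be >= 0")
  class(p) <- "apqr_plant_params"
  p
}

#' @export
print.apqr_plant_params <- function(x, ...) {
  cat("Synthetic cardiomyocyte plant parameters\n")
  cat(sprintf("  rest %g mV, amplitude %g mV, tau_close %g ms\n",
              x$V_rest_target, x$amplitude, x$tau_close))
  cat(sprintf("  blue: g = %g /ms, E = %g mV;  red: I_max = %.4g mV/ms\n",
              x$g_blue, x$E_blue, x$I_red_max))
  invisible(x)
}

#' Calibrate the red-actuator current amplitude
#'
#' Closed-form calibration of the maximal hyperpolarizing pump current from
#' the steady-state condition under sustained maximal red light: below the
#' resting potential the excitation current is silent, so the fixed point
#' satisfies \eqn{A\,u^* g(u^*) = -I_{red,max}} with
#' \eqn{u^* = (V_{target} - V_{rest})/A}.
#'
#' @param params Plant parameter list (the `I_red_max` field is ignored).
#' @param target Desired steady-state potential under maximal red drive, mV;
#'   defaults to the parameter set's `red_plateau_target`.
#' @return Current density in mV/ms.
#' @export
calibrate_red_current <- function(params, target = NULL) {
  if (is.null(target)) target <- params$red_plateau_target
  if (target >= params$V_rest_target)
    stop("red plateau target must lie below the resting potential")
  u <- (target - params$V_rest_target) / params$amplitude
  -params$amplitude * u * .leak_g(u, params)
}

## rectifier leak conductance g(u), per ms
.leak_g <- function(u, p) {
  sig <- 1 / (1 + exp((u - p$u_leak) / p$leak_width))
  1 / p$tau_close + (1 / p$tau_out - 1 / p$tau_close) * sig
}

#' Initial plant state
#'
#' State vector of the synthetic cell: membrane potential `V` (mV), gate `h`,
#' actuator activations `a_blue` and `a_red` (all dimensionless in
#' \[0, 1\]), and elapsed time `t` (ms). The default is the dark-adapted
#' resting state, which is an exact fixed point of the unforced dynamics.
#'
#' @param params Plant parameters from [plant_params()].
#' @param V,h,a_blue,a_red,t Optional overrides of the individual fields.
#' @return An object of class `apqr_plant_state`.
#' @export
plant_state <- function(params, V = params$V_rest_target, h = 1,
                        a_blue = 0, a_red = 0, t = 0) {
  s <- list(V = V, h = h, a_blue = a_blue, a_red = a_red, t = t)
  class(s) <- "apqr_plant_state"
  s
}

#' Normalized light command
#'
#' Pair of normalized irradiances for the two actuators; 1.0 corresponds to
#' the maximal intensity used during calibration (1.5 mW/mm^2).
#'
#' @param blue,red Normalized irradiance in \[0, 1\].
#' @return A named list of class `apqr_light_command`.
#' @export
light_command <- function(blue = 0, red = 0) {
  if (!is.finite(blue) || !is.finite(red) ||
      blue < 0 || blue > 1 || red < 0 || red > 1)
    stop("light command components must be finite and within [0, 1]")
  structure(list(blue = blue, red = red), class = "apqr_light_command")
}

#' Blue-actuator (light-gated conductance) current
#'
#' Ohmic photocurrent of the depolarizing actuator,
#' `g_blue * a_blue * (V - E_blue)` (mV/ms). By the inward-negative
#' convention the current is negative (depolarizing) whenever `V < E_blue`;
#' it vanishes at the reversal potential and for zero activation.
#'
#' @param V Membrane potential, mV.
#' @param a_blue Activation in \[0, 1\].
#' @param g_blue Maximal conductance, ms^-1.
#' @param E_blue Apparent reversal potential, mV.
#' @return Current density, mV/ms.
#' @export
blue_current <- function(V, a_blue, g_blue, E_blue) {
  stopifnot(a_blue >= 0, a_blue <= 1)
  g_blue * a_blue * (V - E_blue)
}

#' Red-actuator (light-driven pump) current
#'
#' Voltage-independent hyperpolarizing pump current,
#' `I_red_max * a_red` (mV/ms, outward-positive).
#'
#' @param a_red Activation in \[0, 1\].
#' @param I_red_max Maximal pump current density, mV/ms.
#' @return Current density, mV/ms.
#' @export
red_current <- function(a_red, I_red_max) {
  stopifnot(a_red >= 0, a_red <= 1)
  I_red_max * a_red
}

#' Apply a drug-like perturbation to the plant
#'
#' Returns a parameter set with the repolarization time constant scaled:
#' `"fourAP"` multiplies `tau_close` by `f_4AP` (slows repolarization,
#' prolonging the action potential), `"carbachol"` multiplies it by `f_cch`
#' (shortens the action potential). `"none"` returns the baseline unchanged.
#'
#' @param params Plant parameters.
#' @param drug One of `"none"`, `"fourAP"`, `"carbachol"`.
#' @return Modified `apqr_plant_params`.
#' @export
apply_pharmacology <- function(params, drug = c("none", "fourAP", "carbachol")) {
  drug <- match.arg(drug)
  if (drug == "fourAP") params$tau_close <- params$tau_close * params$f_4AP
  if (drug == "carbachol") params$tau_close <- params$tau_close * params$f_cch
  params
}

## Flatten parameters into a plain double vector for the inner loop.
.plant_pack <- function(p) {
  c(vr = p$V_rest_target, A = p$amplitude,
    inv_in = 1 / p$tau_in, inv_out = 1 / p$tau_out,
    inv_open = 1 / p$tau_open, inv_close = 1 / p$tau_close,
    inv_inact = 1 / p$tau_inact,
    u_gate = p$u_gate, u_leak = p$u_leak, inv_w = 1 / p$leak_width,
    g_blue = p$g_blue, E_blue = p$E_blue, I_red = p$I_red_max,
    inv_ab = 1 / p$tau_act_blue, inv_ar = 1 / p$tau_act_red)
}

## One tick (n_sub explicit Euler substeps of dt_sub ms) with zero-order hold
## of the light command and injected current. st = c(V, h, a_blue, a_red).
.plant_tick <- function(st, pc, blue, red, I_inj, dt_sub = 0.05,
                        n_sub = 20L) {
  V <- st[[1L]]; h <- st[[2L]]; ab <- st[[3L]]; ar <- st[[4L]]
  vr <- pc[[1L]]; A <- pc[[2L]]; inv_in <- pc[[3L]]; inv_out <- pc[[4L]]
  inv_open <- pc[[5L]]; inv_close <- pc[[6L]]; inv_inact <- pc[[7L]]
  u_gate <- pc[[8L]]; u_leak <- pc[[9L]]; inv_w <- pc[[10L]]
  g_blue <- pc[[11L]]; E_blue <- pc[[12L]]; I_red <- pc[[13L]]
  inv_ab <- pc[[14L]]; inv_ar <- pc[[15L]]
  dgl <- inv_out - inv_close
  for (k in seq_len(n_sub)) {
    u <- (V - vr) / A
    h <- if (u < u_gate) h + (1 - h) * inv_open * dt_sub
         else h - h * inv_inact * dt_sub
    g <- inv_close + dgl / (1 + exp((u - u_leak) * inv_w))
    up <- if (u > 0) u else 0
    dV <- A * (h * up * up * (1 - u) * inv_in - u * g) -
      g_blue * ab * (V - E_blue) - I_red * ar + I_inj
    V <- V + dV * dt_sub
    ab <- ab + (blue - ab) * inv_ab * dt_sub
    ar <- ar + (red - ar) * inv_ar * dt_sub
  }
  if (!is.finite(V)) stop("plant state diverged: V is non-finite")
  if (!is.finite(h)) stop("plant state diverged: h is non-finite")
  c(V, h, ab, ar)
}

#' Advance the plant by one integration substep
#'
#' Explicit fixed-step (Euler) integration of the plant over a single substep
#' `dt_sub` with the light command and injected current held constant. The
#' closed-loop engine holds these inputs over each 1-ms control tick
#' (zero-order hold) and takes `1/dt_sub` substeps per tick.
#'
#' @param state Plant state from [plant_state()].
#' @param params Plant parameters from [plant_params()].
#' @param light Light command from [light_command()].
#' @param I_inj Injected current density, mV/ms (positive depolarizes).
#' @param dt_sub Substep, ms; must be <= 0.1.
#' @return The advanced `apqr_plant_state`.
#' @examples
#' p <- plant_params()
#' s <- plant_state(p)
#' s <- step_plant(s, p, light_command(0, 0))
#' @export
step_plant <- function(state, params, light = light_command(),
                       I_inj = 0, dt_sub = 0.05) {
  if (dt_sub <= 0 || dt_sub > 0.1)
    stop("dt_sub must be positive and <= 0.1 ms")
  for (f in c("V", "h", "a_blue", "a_red"))
    if (!is.finite(state[[f]]))
      stop("plant state is non-finite in field ", f)
  st <- .plant_tick(c(state$V, state$h, state$a_blue, state$a_red),
                    .plant_pack(params), light$blue, light$red, I_inj,
                    dt_sub = dt_sub, n_sub = 1L)
  plant_state(params, V = st[[1L]],
              h = min(max(st[[2L]], 0), 1),
              a_blue = min(max(st[[3L]], 0), 1),
              a_red = min(max(st[[4L]], 0), 1),
              t = state$t + dt_sub)
}

#' Steady-state light response of the plant
#'
#' Simulates the calibration protocol used to characterize the actuators:
#' a sustained light pulse from the dark-adapted resting state, returning the
#' membrane potential at the end of the pulse (the plateau potential).
#'
#' @param params Plant parameters.
#' @param blue,red Normalized irradiance of each channel during the pulse.
#' @param duration_ms Pulse duration, ms (default 1000, the 1-s calibration
#'   pulse).
#' @param dt_sub Integration substep, ms.
#' @return Plateau potential in mV.
#' @export
plateau_response <- function(params, blue = 0, red = 0, duration_ms = 1000,
                             dt_sub = 0.05) {
  pc <- .plant_pack(params)
  st <- c(params$V_rest_target, 1, 0, 0)
  n_ticks <- as.integer(round(duration_ms))
  for (i in seq_len(n_ticks))
    st <- .plant_tick(st, pc, blue, red, 0, dt_sub = dt_sub,
                      n_sub = as.integer(round(1 / dt_sub)))
  st[[1L]]
}
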