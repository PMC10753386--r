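# Closed-loop scenario runs are deterministic but take seconds each; they are
# shared across test files through this memoising cache.
.scenario_cache <- new.env(parent = emptyenv())

cached <- function(name, fun) {
  if (!exists(name, envir = .scenario_cache))
    assign(name, fun(), envir = .scenario_cache)
  get(name, envir = .scenario_cache)
}

sc_current <- function() cached("current", function()
  scenario_current_injection(plant_params()))
sc_single <- function() cached("single", function()
  scenario_single_actuator(plant_params()))
sc_disturb <- function() cached("disturb", function()
  scenario_light_disturbance(plant_params()))
sc_dual4ap <- function() cached("dual4ap", function()
  scenario_dual_fourap(plant_params()))
sc_carb <- function() cached("carb", function()
  scenario_enforce_drug(plant_params(), "carbachol"))
sc_tri <- function() cached("tri", function()
  scenario_enforce_triangular(plant_params()))

all_restoration_scenarios <- function()
  list(current = sc_current(), single = sc_single(),
       disturb = sc_disturb(), dual4ap = sc_dual4ap())

# brute-force PID recomputation (independent oracle for the tick functions):
# plain cumulative sum for the integral and stats::lm for the derivative
oracle_pid_trace <- function(errors, K_P, K_I, K_D, l, dt = 1) {
  n <- length(errors)
  out <- numeric(n)
  esum <- 0
  for (k in seq_len(n)) {
    esum <- esum + errors[k]
    ed <- 0
    if (k >= l) {
      w <- errors[(k - l + 1):k]
      x <- (seq_len(l) - 1) * dt
      ed <- unname(stats::coef(stats::lm(w ~ x))[2])
    }
    out[k] <- K_P * errors[k] + K_I * esum + K_D * ed
  }
  out
}
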