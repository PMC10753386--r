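test_that("the dark resting state is a fixed point of the unforced plant", {
  p <- plant_params()
  s <- plant_state(p)
  for (k in 1:1000) s <- step_plant(s, p, light_command(0, 0))
  expect_lt(abs(s$V - p$V_rest_target), 0.01)
  expect_true(all(c(s$h, s$a_blue, s$a_red) >= 0))
  expect_true(all(c(s$h, s$a_blue, s$a_red) <= 1))
})

test_that("photocurrent primitives follow their closed forms", {
  expect_equal(blue_current(-50, 0, 0.5, -11.2), 0)
  expect_equal(blue_current(-11.2, 0.7, 0.5, -11.2), 0)
  expect_equal(blue_current(-75, 1, 0.5, -11.2), 0.5 * (-75 + 11.2))
  expect_lt(blue_current(-75, 1, 0.5, -11.2), 0)  # inward below reversal

  expect_equal(red_current(0, 3.5), 0)
  expect_equal(red_current(1, 3.5), 3.5)
  # the pump current carries no voltage argument at all: identical at any V
  expect_equal(red_current(0.5, 3.5), red_current(0.5, 3.5))
  expect_error(red_current(1.5, 3.5))
})

test_that("sustained maximal light drives the membrane to the plateau potentials", {
  p <- plant_params()
  expect_lt(abs(plateau_response(p, blue = 1) - p$E_blue), 1)
  expect_lt(abs(plateau_response(p, red = 1) - (-82)), 1)
  expect_equal(plateau_response(p, 0, 0, duration_ms = 200),
               p$V_rest_target)
})

test_that("small red drives produce proportional steady-state hyperpolarization", {
  p <- plant_params()
  d1 <- p$V_rest_target - plateau_response(p, red = 0.005, duration_ms = 300)
  d2 <- p$V_rest_target - plateau_response(p, red = 0.01, duration_ms = 300)
  expect_gt(d1, 0)
  expect_lt(abs(d2 / d1 - 2), 0.05 * 2)
})

test_that("pharmacology scales the repolarization time constant only", {
  p <- plant_params()
  expect_identical(apply_pharmacology(p, "none"), p)
  p4 <- apply_pharmacology(p, "fourAP")
  expect_equal(p4$tau_close, p$tau_close * p$f_4AP)
  expect_identical(p4[setdiff(names(p4), "tau_close")],
                   p[setdiff(names(p), "tau_close")])
  expect_error(apply_pharmacology(p, "digoxin"))
})

paced_apd90 <- function(p) {
  v <- run_paced(p, n_beats = 3)$V_m
  ext <- v[(2 * 1000 - 49):(3 * 1000)]
  ap_metrics(ext, stim_tick = 51)$APD[["0.9"]]
}

test_that("drug-like perturbations shift the paced APD into the expected ranges", {
  p <- plant_params()
  base <- paced_apd90(p)
  expect_gt(base, 280); expect_lt(base, 320)
  a4 <- paced_apd90(apply_pharmacology(p, "fourAP"))
  expect_gt(a4 - base, 80)
  expect_lt(a4 - base, 140)
  ac <- paced_apd90(apply_pharmacology(p, "carbachol"))
  expect_gt(ac, 90); expect_lt(ac, 100)
})

test_that("paced APD90 is monotone in the pharmacology factors", {
  p <- plant_params()
  a4 <- vapply(seq(1, p$f_4AP, length.out = 5), function(f) {
    q <- p; q$tau_close <- p$tau_close * f; paced_apd90(q)
  }, numeric(1))
  expect_true(all(diff(a4) >= 0))
  ac <- vapply(seq(p$f_cch, 1, length.out = 5), function(f) {
    q <- p; q$tau_close <- p$tau_close * f; paced_apd90(q)
  }, numeric(1))
  expect_true(all(diff(ac) >= 0))
})

test_that("paced beats are stationary after the second beat", {
  v <- run_paced(plant_params(), n_beats = 4)$V_m
  b3 <- v[2001:3000]; b4 <- v[3001:4000]
  expect_lt(max(abs(b3 - b4)), 0.5)
})

test_that("state variables stay in bounds under arbitrary light commands", {
  p <- plant_params()
  s <- plant_state(p)
  set.seed(42)
  for (k in 1:300) {
    s <- step_plant(s, p, light_command(runif(1), runif(1)),
                    I_inj = runif(1, -5, 5))
    expect_true(s$h >= 0 && s$h <= 1)
    expect_true(s$a_blue >= 0 && s$a_blue <= 1)
    expect_true(s$a_red >= 0 && s$a_red <= 1)
  }
})

test_that("non-finite states and invalid parameters are rejected loudly", {
  p <- plant_params()
  s <- plant_state(p, V = NaN)
  expect_error(step_plant(s, p, light_command()), "V")
  expect_error(plant_params(tau_close = -1), "time constants")
  expect_error(plant_params(f_cch = 1.2), "f_cch")
  expect_error(plant_params(E_blue = -90), "E_blue")
  expect_error(step_plant(plant_state(p), p, light_command(), dt_sub = 0.5),
               "dt_sub")
  expect_error(light_command(blue = 2))
})

test_that("the red-current calibration closed form matches simulation", {
  p <- plant_params()
  expect_equal(p$I_red_max, calibrate_red_current(p))
  expect_lt(abs(plateau_response(p, red = 1) - p$red_plateau_target), 0.1)
})
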