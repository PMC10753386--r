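small_prot <- function(...) {
  protocol(drug = list(label = "fourAP"),
           phases = list(logging = 2, paused = 2, correcting = 3), ...)
}
small_ctrl <- function() controller_spec("apqr", apqr_gains(lognum = 2),
                                         "current")

test_that("identical configurations yield bit-identical logs", {
  p <- plant_params()
  a <- run_restoration(p, small_ctrl(), small_prot())
  b <- run_restoration(p, small_ctrl(), small_prot())
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("logs keep a strictly uniform 1-ms time base with one record per tick", {
  p <- plant_params()
  log <- run_restoration(p, small_ctrl(), small_prot())
  expect_equal(nrow(log), 7 * 1000)
  expect_equal(diff(log$t), rep(1, nrow(log) - 1))
  expect_equal(ncol(log), 14)
})

test_that("logs round-trip losslessly through CSV", {
  p <- plant_params()
  log <- run_restoration(p, small_ctrl(), small_prot())
  f <- withr::local_tempfile(fileext = ".csv")
  write_log(log, f)
  back <- read_log(f)
  expect_equal(ncol(back), ncol(log))
  expect_equal(nrow(back), nrow(log))
  for (cn in setdiff(names(log), "beat"))
    expect_equal(back[[cn]], log[[cn]], tolerance = 1e-12, label = cn)
  expect_equal(back$beat, log$beat)
})

test_that("a controller tracking its own setpoint emits almost no output", {
  p <- plant_params()
  prot <- protocol(phases = list(logging = 2, paused = 0, correcting = 3))
  log <- run_restoration(p, small_ctrl(), prot)
  corr <- log[log$phase == "CORRECTING", ]
  expect_lt(max(abs(corr$I_inj)), 0.01 * 1)   # < 1% of the output scale
})

test_that("controller work per tick is bounded by the window length", {
  sp <- setpoint_ap(rep(0, 50), origin = "logged")
  g <- pid_gains(l = 10)
  st <- controller_state(l = g$l)
  sizes <- integer(200)
  for (k in 1:200) {
    st <- pid_tick(rnorm(1), st, sp, g)$state
    sizes[k] <- length(st$e_window)
  }
  expect_true(all(sizes <= g$l))
  expect_equal(length(st), length(controller_state()))  # no growing fields
})

test_that("dual-actuator correction of the 4AP perturbation is predominantly red", {
  sc <- sc_dual4ap()
  corr <- sc$log_on[sc$log_on$phase == "CORRECTING", ]
  expect_gt(sum(corr$red), 10 * sum(corr$blue))
  expect_true(all(corr$blue * corr$red == 0))
})

test_that("red output activates autonomously during disturbed beats only", {
  sc <- sc_disturb()
  corr <- sc$log_on[sc$log_on$phase == "CORRECTING", ]
  disturbed <- unique(corr$beat[corr$dist_blue > 0])
  expect_length(disturbed, 2)     # every 5th of 10 correcting beats
  red_dist <- sum(corr$red[corr$beat %in% disturbed])
  red_quiet <- sum(corr$red[!corr$beat %in% disturbed])
  expect_gt(red_dist, 50 * max(red_quiet, 1e-6))
})

test_that("the uncorrected 4AP run reproduces the perturbed morphology", {
  sc <- sc_current()
  apd_off <- log_ap_metrics(sc$log_off, phase = "CORRECTING")$APD90
  apd_on <- log_ap_metrics(sc$log_on, phase = "CORRECTING",
                           skip_beats = 1)$APD90
  expect_gt(mean(apd_off), mean(apd_on) + 80)   # drug prolongs, control restores
  expect_lt(abs(mean(apd_on) - 302), 20)
})

test_that("enforcing the plant's own AP needs almost no corrective light", {
  p <- plant_params()
  model <- record_drug_model(p, "none")
  log <- run_enforcement(p, pid_gains(), model, n_beats = 4, ctl_beats = 2)
  late <- log[log$phase == "CORRECTING" & log$beat > 4, ]
  expect_lt(max(late$blue + late$red), 0.02)
})

test_that("triangular enforcement imposes the model's timing and resting level", {
  sc <- sc_tri()
  # resting potential of the enforced t01 cycle within 0.7 mV of the model
  log01 <- sc$logs$t01
  last <- log01[log01$beat == max(log01$beat), ]
  expect_lt(abs(mean(last$V_m[951:1000]) - (-68)), 0.7)
  # APD90 of forced beats within 15 ms of the model APD90
  apd_model <- ap_metrics(triangular_model(0.1)$values)$APD[["0.9"]]
  apd_forced <- log_ap_metrics(log01, phase = "CORRECTING",
                               skip_beats = 2)$APD90
  expect_true(all(abs(apd_forced - apd_model) < 15))
})

test_that("configuration mismatches are rejected", {
  expect_error(controller_spec("apqr", apqr_gains(), "dual_optical"),
               "mismatch")
  expect_error(controller_spec("apqr_pid", pid_gains(), "single_optical"),
               "mismatch")
  expect_error(
    run_restoration(plant_params(),
                    controller_spec("apqr", apqr_gains(lognum = 3),
                                    "current"),
                    small_prot()),
    "lognum")
  expect_error(protocol(pacing = list(period = 100, pulse_ms = 200)),
               "exceed")
  expect_error(protocol(disturbance = list(delay_ms = 900,
                                           duration_ms = 200)),
               "within the pacing cycle")
})
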