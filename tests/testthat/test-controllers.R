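test_that("setpoint logging averages beats element-wise", {
  b <- list(c(-75, 10, -40), c(-75, 10, -40))
  expect_equal(log_setpoint(b, 2)$values, c(-75, 10, -40))
  expect_equal(log_setpoint(list(c(0, 10), c(2, 12)), 2)$values, c(1, 11))
  set.seed(7)
  beats <- replicate(5, rnorm(40, -40, 25), simplify = FALSE)
  sp <- log_setpoint(beats, 5)
  # brute-force per-index mean oracle
  oracle <- vapply(seq_len(40), function(i)
    mean(vapply(beats, `[`, numeric(1), i)), numeric(1))
  expect_equal(sp$values, oracle, tolerance = 1e-12)
  expect_error(log_setpoint(beats, 4), "expected 4")
  expect_error(log_setpoint(list(1:3, 1:4), 2), "mismatched")
})

test_that("the logged setpoint is invariant to beat ordering", {
  set.seed(11)
  beats <- replicate(5, rnorm(30), simplify = FALSE)
  expect_equal(log_setpoint(beats, 5)$values,
               log_setpoint(rev(beats), 5)$values)
})

test_that("the adaptive proportional tick follows its closed form", {
  sp <- setpoint_ap(rep(-75, 10), origin = "logged")
  g <- apqr_gains(C_m = 100, R_m = 100)
  st <- controller_state(R_m = g$R_m)
  r <- apqr_tick(-75, st, sp, g)
  expect_equal(r$I_out, 0)
  expect_equal(r$state$R_m_current, 100)

  r <- apqr_tick(-70, controller_state(R_m = 100), sp, g)  # e = 5
  expect_equal(r$I_out, 5)

  # moving-away predicate with R_m_corr_down = 2 doubles the gain next tick
  g2 <- apqr_gains(R_m = 100, R_m_corr_up = 1.5, R_m_corr_down = 2)
  st <- controller_state(R_m = 100)
  r1 <- apqr_tick(-73, st, sp, g2)            # e = +2, no previous error
  r2 <- apqr_tick(-70, r1$state, sp, g2)      # e = +5: same sign, grown
  expect_equal(r2$state$R_m_current, 50)
  r3 <- apqr_tick(-71, r2$state, sp, g2)
  expect_equal(r3$I_out, 100 / 50 * 4)        # K_P doubled from 1 to 2
})

test_that("the adaptation predicates move the gain in the documented directions", {
  sp <- setpoint_ap(rep(0, 4), origin = "logged")
  g <- apqr_gains(R_m = 100, R_m_corr_up = 1.3, R_m_corr_down = 1.2)
  set.seed(3)
  for (trial in 1:50) {
    e <- rnorm(2, sd = 4)
    st <- controller_state(R_m = 100)
    st <- apqr_tick(e[1], st, sp, g)$state
    rm1 <- st$R_m_current
    st <- apqr_tick(e[2], st, sp, g)$state
    overshoot <- sign(e[2]) != sign(e[1])
    away <- !overshoot && abs(e[2]) > abs(e[1])
    if (overshoot) expect_gte(st$R_m_current, rm1)   # gain never increases
    else if (away) expect_lte(st$R_m_current, rm1)   # gain never decreases
    else expect_equal(st$R_m_current, rm1)
  }
})

test_that("the regression derivative equals a brute-force least-squares fit", {
  expect_equal(regress_slope(rep(4.2, 10)), 0)
  expect_equal(regress_slope(3 * (0:9), dt = 1), 3)
  expect_error(regress_slope(5), "at least 2")
  set.seed(19)
  for (trial in 1:100) {
    l <- sample(2:25, 1)
    dt <- sample(c(0.5, 1, 2), 1)
    w <- rnorm(l, sd = 10)
    x <- (seq_len(l) - 1) * dt
    oracle <- unname(stats::coef(stats::lm(w ~ x))[2])
    expect_equal(regress_slope(w, dt), oracle, tolerance = 1e-9)
  }
})

test_that("the PID tick reproduces a step-by-step recomputation", {
  sp <- setpoint_ap(rep(0, 60), origin = "logged")
  g <- pid_gains(K_P = 80, K_I = 3, K_D = 50, l = 10)
  set.seed(23)
  errors <- rnorm(50, sd = 3)
  st <- controller_state(l = g$l)
  got <- numeric(50)
  for (k in seq_along(errors)) {
    r <- pid_tick(errors[k], st, sp, g)   # setpoint 0: V_m is the error
    got[k] <- r$PID
    st <- r$state
  }
  expect_equal(got, oracle_pid_trace(errors, 80, 3, 50, 10),
               tolerance = 1e-9)
})

test_that("simple PID limiting cases hold", {
  sp <- setpoint_ap(rep(0, 10), origin = "logged")
  r <- pid_tick(3, controller_state(), sp, pid_gains(K_P = 1, K_I = 0,
                                                     K_D = 0))
  expect_equal(r$PID, 3)
  st <- controller_state()
  g0 <- pid_gains(K_P = 0, K_I = 0, K_D = 0)
  for (v in c(5, -40, 13, 2)) {
    r <- pid_tick(v, st, sp, g0); st <- r$state
    expect_equal(r$PID, 0)
  }
})

test_that("the PID response is linear in the error history", {
  sp <- setpoint_ap(rep(0, 40), origin = "logged")
  g <- pid_gains()
  set.seed(5)
  errors <- rnorm(40, sd = 2)
  run <- function(e) {
    st <- controller_state(l = g$l)
    vapply(e, function(v) {
      r <- pid_tick(v, st, sp, g); st <<- r$state; r$PID
    }, numeric(1))
  }
  expect_equal(run(3.7 * errors), 3.7 * run(errors), tolerance = 1e-9)
})

test_that("output routing follows the sign convention and the plateau gate", {
  r <- route_output(0.4, V_m = -60, V_plateau = -11.2, scale = 1)
  expect_equal(c(r$blue, r$red), c(0, 0.4))
  r <- route_output(-0.4, V_m = -60, V_plateau = -11.2, scale = 1)
  expect_equal(c(r$blue, r$red), c(0.4, 0))
  r <- route_output(-0.4, V_m = -5, V_plateau = -11.2, scale = 1)
  expect_equal(c(r$blue, r$red), c(0, 0))
  expect_true(r$saturated)
  expect_equal(route_output(0, -60, -11.2, 1)$red, 0)
  # clipping marks saturation
  expect_true(route_output(5, -60, -11.2, scale = 1)$saturated)

  set.seed(9)
  for (k in 1:200) {
    r <- route_output(rnorm(1, sd = 500), runif(1, -90, 20), -11.2,
                      scale = 2e-3, scale_blue = 2e-4)
    expect_equal(r$blue * r$red, 0)
    expect_true(r$blue >= 0 && r$blue <= 1 && r$red >= 0 && r$red <= 1)
  }
})

test_that("the integral freeze reverts exactly one accumulation", {
  sp <- setpoint_ap(rep(0, 10), origin = "logged")
  st <- controller_state()
  r <- pid_tick(2, st, sp, pid_gains())
  expect_equal(r$state$e_sum, 2)
  expect_equal(pid_freeze_integral(r$state)$e_sum, 0)
})

test_that("the enforcement tick paces during the pulse window and validates its model", {
  g <- pid_gains()
  t13 <- triangular_model(1.3)
  st <- controller_state(l = g$l)
  r <- le_tick(3, -70, st, t13, g)
  expect_equal(r$blue, 1 / 3)
  expect_equal(r$red, 0)
  short <- setpoint_ap(rep(-68, 500), origin = "generator")
  expect_error(le_tick(0, -70, st, short, g), "shorter than")
  logged <- setpoint_ap(rep(-68, 1000), origin = "logged")
  expect_error(le_tick(0, -70, st, logged, g), "file or generated")
})

test_that("proportional control of a leaky-RC plant attains the analytic offset", {
  # dV/dt = -g_leak * V + u with u = -K * e held per 1-ms tick; constant
  # setpoint S. Steady-state error -> S * g_leak / (g_leak + K).
  g_leak <- 0.08; K <- 0.3; S <- 10
  sp <- setpoint_ap(rep(S, 10), origin = "logged")
  gains <- apqr_gains(C_m = 100, R_m = 100 / K,
                      R_m_corr_up = 1 + 1e-12, R_m_corr_down = 1 + 1e-12)
  st <- controller_state(R_m = gains$R_m)
  V <- 0
  for (k in 1:4000) {
    r <- apqr_tick(V, st, sp, gains)
    st <- r$state
    u <- -r$I_out
    for (s in 1:20) V <- V + (-g_leak * V + u) * 0.05
  }
  e_ss <- V - S
  expect_lt(abs(e_ss - (-S * g_leak / (g_leak + K))) /
              abs(S * g_leak / (g_leak + K)), 0.02)
})
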