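test_that("hover trim exists and supports body weight within 5%", {
  cfg <- base_cfg()
  tr <- trimmed()
  expect_gt(tr$Phi_p, 60)
  expect_lt(tr$Phi_p, 150)
  traj <- integrate_flight(cfg, tr$command, 2 / cfg$flap_frequency)
  wb1 <- traj$time_s < 1 / cfg$flap_frequency
  expect_lt(abs(mean(traj$zddot[wb1])), 0.05 * cfg$gravity)
})

test_that("integration is deterministic", {
  cfg <- base_cfg()
  a <- integrate_flight(cfg, trimmed_cmd(), 2 / 26)
  b <- integrate_flight(cfg, trimmed_cmd(), 2 / 26)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("mirrored asymmetric commands produce negated roll trajectories", {
  cfg <- base_cfg()
  base <- trimmed_cmd()
  cmd <- base
  cmd$left$alpha_down <- base$left$alpha_down + 3
  cmd$right$alpha_down <- base$right$alpha_down - 3
  a <- integrate_flight(cfg, cmd, 4 / 26)
  b <- integrate_flight(cfg, mirror_command(cmd), 4 / 26)
  expect_equal(b$beta_deg, -a$beta_deg, tolerance = 1e-8)
  expect_equal(b$y_cm, -a$y_cm, tolerance = 1e-8)
  expect_equal(b$z_cm, a$z_cm, tolerance = 1e-8)
})

test_that("a step pitch asymmetry drives first-order roll that then decays", {
  cfg <- base_cfg()
  base <- trimmed_cmd()
  asym <- base
  asym$left$alpha_down <- base$left$alpha_down + 3
  asym$left$alpha_up <- base$left$alpha_up + 3
  asym$right$alpha_down <- base$right$alpha_down - 3
  asym$right$alpha_up <- base$right$alpha_up - 3
  sch <- list(list(t_start = -Inf, command = base),
              list(t_start = 2 / 26, command = asym),
              list(t_start = 8 / 26, command = base))
  traj <- integrate_flight(cfg, sch, 12 / 26)
  wb <- floor(traj$time_s * 26 + 1e-9)
  v <- tapply(traj$betadot, wb, mean)
  v <- as.numeric(v)[1:12]
  # single-exponential approach to a plateau over the step window
  # (wingbeats 0..7; the step lands at wingbeat 2)
  tt <- (0:7)
  vstep <- v[1:8]
  fit <- stats::nls(vstep ~ A * (1 - exp(-pmax(tt - 1.5, 0) / tau)),
                    start = list(A = max(vstep), tau = 0.5),
                    control = list(warnOnly = TRUE))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((vstep - mean(vstep))^2)
  expect_gt(r2, 0.9)
  # after return to symmetry the roll rate decays toward zero
  expect_lt(abs(v[12]), 0.25 * max(abs(v)))
})

test_that("diverging states abort with a diagnostic", {
  cfg <- base_cfg()
  expect_error(
    integrate_flight(cfg, trimmed_cmd(), 3 / 26,
                     init_state = list(ydot = 5e4)),
    "unstable")
})

test_that("zero amplitudes and zero gravity leave the body force-free", {
  cfg <- sim_config(gravity = 0)
  cmd <- wing_command(Phi_p = 0, theta_p = 0)
  traj <- integrate_flight(cfg, cmd, 2 / 26)
  expect_equal(max(abs(traj$Fy)), 0)
  expect_equal(max(abs(traj$Fz)), 0)
  expect_equal(max(abs(traj$Tx)), 0)
  expect_equal(max(abs(traj$ydot)), 0)
  expect_equal(max(abs(traj$zdot)), 0)
})

test_that("trajectory CSV round trips with the documented schema", {
  traj <- integrate_flight(base_cfg(), trimmed_cmd(), 2 / 26)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_identical(names(back),
                   c("time_s", "y_cm", "z_cm", "ydot", "zdot", "yddot",
                     "zddot", "beta_deg", "betadot", "betaddot", "phi_L",
                     "phi_R", "theta_L", "theta_R", "alpha_L", "alpha_R",
                     "Fy", "Fz", "Tx"))
  expect_equal(back$beta_deg, traj$beta_deg, tolerance = 1e-8)
  unlink(path)
})
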