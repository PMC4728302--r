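# Shared fixtures, computed once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

base_cfg <- function() fixture("cfg", sim_config())

trimmed <- function() fixture("trim", trim_hover(base_cfg()))

trimmed_cmd <- function() trimmed()$command

# a short trial with one commanded roll pulse and recovery
maneuver_traj <- function() fixture("traj", {
  cfg <- base_cfg()
  sch <- sideslip_schedule(trimmed_cmd(), cfg$flap_frequency,
                           direction = 1, strength = 1)
  integrate_flight(cfg, sch$schedule, sch$duration)
})

noiseless_frames <- function() fixture("frames0", {
  landmarks_from_trajectory(maneuver_traj(), noise_sd = 0,
                            missing_p5_rate = 0, seed = 5L)
})

# symmetric hover, no noise
hover_frames <- function() fixture("hover_frames", {
  traj <- integrate_flight(base_cfg(), trimmed_cmd(), 5 / 26)
  landmarks_from_trajectory(traj, noise_sd = 0, missing_p5_rate = 0,
                            seed = 3L)
})

# the full synthetic study used by the acceptance tests
acceptance_run <- function() fixture("accept_run", {
  run_pipeline(pipeline_config(seed = 1L))
})

# a stroke-table-shaped data.frame with directly chosen columns, for
# statistics tests that do not need the simulator
make_toy_table <- function(n, seed = 1, betadot = NULL, betaddot = NULL,
                           alpha_LR = NULL, phi_p_LR = NULL,
                           theta_p_LR = NULL, ydot = NULL) {
  set.seed(seed)
  rn <- function(x, sd = 1) if (is.null(x)) stats::rnorm(n, 0, sd) else x
  tab <- data.frame(
    halfstroke = seq_len(n),
    stroke = rep(c("down", "up"), length.out = n),
    wingbeat = rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)],
    time_s = seq_len(n) / 52,
    moth_id = rep(c("m1", "m2"), length.out = n),
    trial_id = rep(c("t1", "t2", "t3", "t4"), length.out = n),
    maneuver_id = 1L,
    alpha_LR = rn(alpha_LR, 3), phi_p_LR = rn(phi_p_LR, 3),
    theta_p_LR = rn(theta_p_LR, 3),
    phi_LR = stats::rnorm(n, 0, 3), theta_LR = stats::rnorm(n, 0, 3),
    alpha_bar = stats::rnorm(n, 45, 3),
    phi_p_bar = stats::rnorm(n, 115, 5),
    theta_p_bar = stats::rnorm(n, 30, 3),
    beta = stats::rnorm(n, 0, 15),
    ydot = rn(ydot, 20), zdot = stats::rnorm(n, 0, 10),
    yddot = stats::rnorm(n, 0, 50), zddot = stats::rnorm(n, 0, 50),
    betadot = rn(betadot, 80), betaddot = rn(betaddot, 500),
    theta_i = stats::rnorm(n, 10, 3),
    stringsAsFactors = FALSE)
  tab$sgn_beta <- sign(tab$beta)
  tab$drag_i <- sqrt(tab$ydot^2 + tab$zdot^2) * sin(tab$theta_i * pi / 180)
  tab$alpha_c_bar <- tab$alpha_bar - mean(tab$alpha_bar)
  tab$phi_pc_bar <- tab$phi_p_bar - mean(tab$phi_p_bar)
  tab$theta_pc_bar <- tab$theta_p_bar - mean(tab$theta_p_bar)
  class(tab) <- c("stroke_table", "data.frame")
  tab
}

coef_of <- function(fit, term) {
  co <- fit$coefficients
  co$estimate[co$term == term]
}
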