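#' Integrate free-flight dynamics of the flapping moth
#'
#' Fixed-step fourth-order Runge-Kutta integration of the lateral (y),
#' vertical (z) and roll degrees of freedom under quasi-steady
#' blade-element forces. Gravity acts in +z (down). x-translation, yaw
#' and pitch are frozen. The integration is deterministic given the
#' configuration and command schedule.
#'
#' @param cfg a [sim_config()].
#' @param cmd a [wing_command()], or a command schedule: a list of
#'   `list(t_start = <s>, command = <wing_command>)` segments (the first
#'   segment must start at or before `t0`).
#' @param duration simulated time (s); must cover at least 2 wingbeats.
#' @param init_state named list with any of `y`, `z`, `beta` (deg),
#'   `ydot`, `zdot` (cm/s), `betadot` (deg/s); missing entries are 0.
#' @param t0 start time (s); wing waveform phase is global, so a run
#'   started at `t0 > 0` continues the phase of an earlier run.
#' @param lock_axes character subset of `c("lateral", "vertical",
#'   "roll")`: axes whose accelerations are zeroed, freezing that
#'   degree of freedom (used to isolate single-axis damping).
#' @return a `trajectory`: a data.frame with one row per timestep and
#'   columns `time_s`, `y_cm`, `z_cm`, `ydot`, `zdot`, `yddot`, `zddot`,
#'   `beta_deg`, `betadot`, `betaddot`, `phi_L`, `phi_R`, `theta_L`,
#'   `theta_R`, `alpha_L`, `alpha_R`, `Fy`, `Fz`, `Tx`, plus the
#'   configuration and schedule as attributes.
#' @export
integrate_flight <- function(cfg, cmd, duration, init_state = list(), t0 = 0,
                             lock_axes = character()) {
  stopifnot(inherits(cfg, "sim_config"))
  f <- cfg$flap_frequency
  if (duration < 2 / f) stop("'duration' must cover at least 2 wingbeats")
  sched <- as_schedule(cmd, t0)
  dt <- cfg$timestep
  nstep <- ceiling(duration / dt)
  st <- full_state(init_state)
  # state vector in radians internally
  s <- c(st$y, st$z, deg2rad(st$beta), st$ydot, st$zdot, deg2rad(st$betadot))

  m <- cfg$body_mass
  Ix <- cfg$roll_inertia
  g <- cfg$gravity

  lock <- c(lateral = "lateral" %in% lock_axes,
            vertical = "vertical" %in% lock_axes,
            roll = "roll" %in% lock_axes)
  deriv <- function(t, s) {
    cm <- schedule_lookup(sched, t)
    wv <- wing_kinematics_waveform(cm, t, f)
    fr <- qs_forces_raw(wv, list(y = s[1], z = s[2], beta = rad2deg(s[3]),
                                 ydot = s[4], zdot = s[5],
                                 betadot = rad2deg(s[6])), cfg)
    acc <- c(if (lock[["lateral"]]) 0 else fr$F_grf[2] / m,
             if (lock[["vertical"]]) 0 else fr$F_grf[3] / m + g,
             if (lock[["roll"]]) 0 else fr$torque_x / Ix)
    list(ds = c(s[4], s[5], s[6], acc), forces = fr)
  }

  out <- matrix(NA_real_, nrow = nstep + 1, ncol = 19)
  times <- t0 + (0:nstep) * dt
  for (i in 0:nstep) {
    t <- times[i + 1]
    k1 <- deriv(t, s)
    cm <- schedule_lookup(sched, t)
    wv <- wing_kinematics_waveform(cm, t, f)
    out[i + 1, ] <- c(t, s[1], s[2], s[4], s[5], k1$ds[4], k1$ds[5],
                      rad2deg(s[3]), rad2deg(s[6]), rad2deg(k1$ds[6]),
                      wv$left$Phi, wv$right$Phi, wv$left$theta, wv$right$theta,
                      wv$left$alpha, wv$right$alpha,
                      k1$forces$F_grf[2], k1$forces$F_grf[3], k1$forces$torque_x)
    if (i == nstep) break
    k2 <- deriv(t + dt / 2, s + dt / 2 * k1$ds)
    k3 <- deriv(t + dt / 2, s + dt / 2 * k2$ds)
    k4 <- deriv(t + dt, s + dt * k3$ds)
    s <- s + dt / 6 * (k1$ds + 2 * k2$ds + 2 * k3$ds + k4$ds)
    if (any(!is.finite(s)) || abs(s[4]) > 3e4 || abs(s[5]) > 3e4 ||
        abs(s[6]) > deg2rad(1e5)) {
      stop(sprintf("simulation unstable at t = %.4f s (state out of bounds)",
                   t + dt))
    }
  }
  traj <- as.data.frame(out)
  names(traj) <- c("time_s", "y_cm", "z_cm", "ydot", "zdot", "yddot", "zddot",
                   "beta_deg", "betadot", "betaddot",
                   "phi_L", "phi_R", "theta_L", "theta_R",
                   "alpha_L", "alpha_R", "Fy", "Fz", "Tx")
  attr(traj, "config") <- cfg
  attr(traj, "schedule") <- sched
  class(traj) <- c("trajectory", "data.frame")
  traj
}

as_schedule <- function(cmd, t0 = 0) {
  if (inherits(cmd, "wing_command")) {
    sched <- list(list(t_start = -Inf, command = cmd))
  } else if (is.list(cmd) && all(vapply(cmd, function(x)
    is.list(x) && inherits(x$command, "wing_command"), logical(1)))) {
    sched <- cmd[order(vapply(cmd, function(x) x$t_start, numeric(1)))]
    if (sched[[1]]$t_start > t0) {
      stop("the first schedule segment must start at or before t0")
    }
  } else {
    stop("'cmd' must be a wing_command or a list of (t_start, command) segments")
  }
  sched
}

schedule_lookup <- function(sched, t) {
  i <- 1L
  for (j in seq_along(sched)) {
    if (sched[[j]]$t_start <= t + 1e-12) i <- j else break
  }
  sched[[i]]$command
}

#' Wingbeat-averaged vertical acceleration at rest
#'
#' Average of the instantaneous vertical acceleration (force/mass plus
#' gravity) over one wingbeat with the body held at rest. Zero means
#' exact weight support.
#'
#' @param cfg a [sim_config()].
#' @param cmd a [wing_command()].
#' @param n_samples samples per wingbeat.
#' @return mean vertical acceleration (cm/s^2, positive = sinking).
#' @export
mean_vertical_accel <- function(cfg, cmd, n_samples = cfg$steps_per_wingbeat) {
  f <- cfg$flap_frequency
  ts <- (seq_len(n_samples) - 0.5) / (f * n_samples)
  acc <- vapply(ts, function(t) {
    fr <- quasi_steady_forces(cmd, cfg, t)
    fr$F_grf[3] / cfg$body_mass + cfg$gravity
  }, numeric(1))
  mean(acc)
}

#' Find the hover-trim sweep amplitude
#'
#' Searches the bilateral sweep amplitude for weight support: the
#' peak-to-peak `Phi_p` at which the wingbeat-averaged vertical force
#' equals body weight with the body at rest.
#'
#' @param cfg a [sim_config()].
#' @param cmd template [wing_command()]; its `Phi_p` is replaced.
#' @param interval search interval for `Phi_p` (deg).
#' @return list with `Phi_p` (deg), the trimmed `command`, and
#'   `residual_accel` (cm/s^2).
#' @export
trim_hover <- function(cfg, cmd = wing_command(), interval = c(60, 150)) {
  obj <- function(phi_p) {
    cm <- cmd
    cm$left$Phi_p <- phi_p
    cm$right$Phi_p <- phi_p
    mean_vertical_accel(cfg, cm)
  }
  lo <- obj(interval[1]); hi <- obj(interval[2])
  if (sign(lo) == sign(hi)) {
    stop("no hover trim in the given Phi_p interval; adjust aero constants")
  }
  root <- stats::uniroot(obj, interval, tol = 1e-4)
  cm <- cmd
  cm$left$Phi_p <- root$root
  cm$right$Phi_p <- root$root
  list(Phi_p = root$root, command = cm, residual_accel = root$f.root)
}

#' Passive damping probe
#'
#' Applies an impulsive velocity perturbation on one axis of a
#' symmetrically hovering moth and fits an exponential decay to the
#' wingbeat-averaged velocity, returning the decay time constant and
#' half-life. The fit regresses the wingbeat-to-wingbeat velocity
#' derivative on velocity (slope `lambda`, time constant `-1/lambda`),
#' which tolerates a nonzero equilibrium velocity.
#'
#' @param cfg a [sim_config()].
#' @param axis one of "roll", "lateral", "vertical".
#' @param cmd trimmed symmetric [wing_command()]; if `NULL`, hover trim
#'   is searched with [trim_hover()].
#' @param perturbation impulse magnitude (deg/s for roll, cm/s otherwise).
#' @param settle_wingbeats wingbeats of undisturbed flapping before the
#'   impulse.
#' @param probe_wingbeats wingbeats observed after the impulse.
#' @param isolate freeze the other two degrees of freedom during the
#'   probe so the decay reflects only the probed axis (no cross-axis
#'   coupling).
#' @return list with `time_constant` (s), `half_life` (s), `lambda`
#'   (1/s), and `velocity` (wingbeat-averaged velocity series). A
#'   non-decaying response yields non-finite values with a warning.
#' @export
damping_probe <- function(cfg, axis = c("roll", "lateral", "vertical"),
                          cmd = NULL, perturbation = NULL,
                          settle_wingbeats = 4, probe_wingbeats = 16,
                          isolate = FALSE) {
  axis <- match.arg(axis)
  if (is.null(cmd)) cmd <- trim_hover(cfg)$command
  if (is.null(perturbation)) {
    perturbation <- switch(axis, roll = 400, lateral = 40, vertical = 40)
  }
  f <- cfg$flap_frequency
  t1 <- settle_wingbeats / f
  settle <- integrate_flight(cfg, cmd, t1)
  end <- settle[nrow(settle), ]
  init <- list(y = end$y_cm, z = end$z_cm, beta = end$beta_deg,
               ydot = end$ydot, zdot = end$zdot, betadot = end$betadot)
  vfield <- switch(axis, roll = "betadot", lateral = "ydot", vertical = "zdot")
  init[[vfield]] <- init[[vfield]] + perturbation
  lock <- if (isolate) setdiff(c("lateral", "vertical", "roll"), axis)
          else character()
  probe <- integrate_flight(cfg, cmd, probe_wingbeats / f, init, t0 = t1,
                            lock_axes = lock)

  wb <- floor((probe$time_s - t1) * f + 1e-9)
  v <- tapply(probe[[vfield]], wb, mean)
  v <- as.numeric(v[order(as.numeric(names(v)))])
  nv <- length(v)
  if (nv < 5) stop("probe too short to fit a decay")
  Tw <- 1 / f
  dv <- (v[3:nv] - v[1:(nv - 2)]) / (2 * Tw)
  vm <- v[2:(nv - 1)]
  fit <- stats::lm(dv ~ vm)
  lambda <- unname(stats::coef(fit)[2])
  if (!is.finite(lambda) || lambda >= 0) {
    warning("no decay detected on axis '", axis,
            "'; returning non-finite time constant")
    return(list(time_constant = Inf, half_life = Inf, lambda = lambda,
                velocity = v))
  }
  tau <- -1 / lambda
  list(time_constant = tau, half_life = log(2) * tau, lambda = lambda,
       velocity = v)
}

#' Write / read a trajectory CSV
#'
#' @param traj a trajectory from [integrate_flight()].
#' @param path output file path.
#' @return `path`, invisibly (writer); a data.frame (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path)
}
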