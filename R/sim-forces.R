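#' Quasi-steady blade-element forces and roll torque
#'
#' Computes instantaneous aerodynamic forces on both wings and the net
#' roll torque about the body x-axis, given the body state and the
#' commanded wing kinematics at time `t`. The relative air velocity at
#' each blade element combines the flapping velocity, the body
#' translational velocity and the roll-rate-induced velocity at that
#' span station; the roll-rate coupling is what produces flapping
#' counter-torque. Three quasi-steady terms are summed per element:
#' translational lift/drag with `CL = A_L*sin(2*a)` and
#' `CD = C_D0 + B_D*(1-cos(2*a))` of the signed effective angle of
#' attack `a`, a rotational (Kramer) force proportional to the pitch
#' rate about the spanwise axis, and a cylinder added-mass reaction to
#' the flapping acceleration normal to the wing surface.
#'
#' @param cmd a [wing_command()].
#' @param cfg a [sim_config()].
#' @param t time (s), scalar.
#' @param state named list or vector with `y`, `z` (cm), `beta` (deg),
#'   `ydot`, `zdot` (cm/s), `betadot` (deg/s). Missing entries default
#'   to 0.
#' @return list with `F_brf` and `F_grf` (length-3 net force vectors,
#'   dyn), `torque_x` (dyn cm, about the body x-axis), and `per_wing`
#'   (2x3 matrix of net body-frame force per wing).
#' @export
quasi_steady_forces <- function(cmd, cfg, t, state = list()) {
  stopifnot(inherits(cmd, "wing_command"), inherits(cfg, "sim_config"))
  st <- full_state(state)
  wv <- wing_kinematics_waveform(cmd, t, cfg$flap_frequency)
  qs_forces_raw(wv, st, cfg)
}

full_state <- function(state) {
  st <- list(y = 0, z = 0, beta = 0, ydot = 0, zdot = 0, betadot = 0)
  for (nm in names(state)) st[[nm]] <- as.numeric(state[[nm]])
  st
}

# internal force kernel; state angles in degrees, waveforms as returned by
# wing_kinematics_waveform() at a scalar time
qs_forces_raw <- function(wv, st, cfg) {
  n <- cfg$n_blade_elements
  w <- c(rep(-1, n), rep(1, n))          # left, right
  r <- rep(cfg$stations_r, 2)
  ch <- rep(cfg$chord_profile, 2)
  dr <- cfg$stations_dr

  per_row <- function(f) c(rep(wv$left[[f]][1], n), rep(wv$right[[f]][1], n))
  Phi <- deg2rad(per_row("Phi"))
  dPhi <- deg2rad(per_row("dPhi"))
  ddPhi <- deg2rad(per_row("ddPhi"))
  th <- deg2rad(per_row("theta"))
  dth <- deg2rad(per_row("dtheta"))
  ddth <- deg2rad(per_row("ddtheta"))
  xi <- deg2rad(per_row("xi"))
  dxi <- deg2rad(per_row("dxi"))

  cT <- cos(th); sT <- sin(th); cP <- cos(Phi); sP <- sin(Phi)
  s <- cbind(cT * sP, w * cT * cP, -sT)
  ds_dPhi <- cbind(cT * cP, -w * cT * sP, 0)
  ds_dth <- cbind(-sT * sP, -w * sT * cP, -cT)
  d2s_dPhi2 <- cbind(-cT * sP, -w * cT * cP, 0)
  d2s_dPhidth <- cbind(-sT * cP, w * sT * sP, 0)
  sdot <- ds_dPhi * dPhi + ds_dth * dth
  sddot <- ds_dPhi * ddPhi + ds_dth * ddth +
    d2s_dPhi2 * dPhi^2 + 2 * d2s_dPhidth * (dPhi * dth) - s * dth^2

  a_hat <- cbind(cP, -w * sP, 0)
  up <- w * cross3m(s, a_hat)
  c_hat <- cos(xi) * a_hat + sin(xi) * up
  n_hat <- cross3m(s, c_hat)

  beta <- deg2rad(st$beta)
  bdot <- deg2rad(st$betadot)
  vb <- c(0,
          st$ydot * cos(beta) + st$zdot * sin(beta),
          -st$ydot * sin(beta) + st$zdot * cos(beta))
  b_off <- cbind(cfg$wing_base_offset[1],
                 w * cfg$wing_base_offset[2],
                 cfg$wing_base_offset[3])
  p <- b_off + r * s
  v_el <- r * sdot +
    cbind(vb[1], vb[2] - bdot * p[, 3], vb[3] + bdot * p[, 2])

  u_rel <- -v_el
  u_par <- rowSums(u_rel * s)
  u_n <- u_rel - u_par * s
  U <- sqrt(rowSums(u_n^2))
  ok <- U > 1e-10
  Us <- ifelse(ok, U, 1)
  d_hat <- u_n / Us
  v_dir <- -d_hat
  a_sgn <- atan2(rowSums(cross3m(v_dir, c_hat) * s), rowSums(v_dir * c_hat))

  CL <- cfg$A_L * sin(2 * a_sgn)
  CD <- cfg$C_D0 + cfg$B_D * (1 - cos(2 * a_sgn))
  q <- 0.5 * cfg$air_density * U^2 * ch * dr
  l_hat <- cross3m(d_hat, s)
  F_tr <- q * (CL * l_hat + CD * d_hat)
  F_tr[!ok, ] <- 0

  omega_s <- w * dxi
  F_rot <- (cfg$air_density * cfg$C_rot * ch^2 * omega_s * dr) * cross3m(u_n, s)

  a_n <- rowSums((r * sddot) * n_hat)
  F_am <- -(cfg$air_density * pi * ch^2 / 4) * a_n * dr * n_hat

  F <- F_tr + F_rot + F_am
  torque_x <- sum(p[, 2] * F[, 3] - p[, 3] * F[, 2])
  F_brf <- colSums(F)
  F_grf <- as.numeric(rot_x(beta) %*% F_brf)
  per_wing <- rbind(left = colSums(F[seq_len(n), , drop = FALSE]),
                    right = colSums(F[n + seq_len(n), , drop = FALSE]))
  list(F_brf = F_brf, F_grf = F_grf, torque_x = torque_x, per_wing = per_wing)
}
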