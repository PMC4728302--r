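#' Evaluate commanded wing kinematic waveforms
#'
#' Returns the commanded sweep, elevation and wing-pitch path angles and
#' their analytic time derivatives for both wings at the requested times.
#'
#' The pitch path variable `xi` is the signed angle of the wing chord
#' (trailing edge to leading edge) from the instantaneous forward
#' direction in the stroke plane: it equals `alpha_down` during
#' downstroke and `180 - alpha_up` during upstroke, transitioning through
#' a cosine-smoothed square wave at stroke reversal. The conventional
#' wing pitch angle `alpha` (measured from the forward axis during
#' downstroke and from the backward axis during upstroke, so that both
#' midstroke values are positive) is also returned.
#'
#' @param cmd a [wing_command()].
#' @param t numeric vector of times (s), >= 0.
#' @param freq wingbeat frequency (Hz).
#' @return list with elements `left` and `right`; each is a list of
#'   numeric vectors `Phi`, `dPhi`, `ddPhi`, `theta`, `dtheta`,
#'   `ddtheta` (deg, deg/s, deg/s^2), `xi`, `dxi`, `alpha`, and
#'   `halfstroke` (character, "down"/"up").
#' @export
wing_kinematics_waveform <- function(cmd, t, freq) {
  stopifnot(inherits(cmd, "wing_command"))
  if (any(t < 0)) stop("'t' must be >= 0")
  lapply(
    stats::setNames(c("left", "right"), c("left", "right")),
    function(side) waveform_one(cmd[[side]], cmd$reversal_fraction, t, freq)
  )
}

waveform_one <- function(p, rev_frac, t, freq) {
  w <- 2 * pi * freq
  phP <- deg2rad(p$phase_Phi)
  phT <- deg2rad(p$phase_Phi + p$phase_theta)
  Phi <- p$Phi0 + (p$Phi_p / 2) * cos(w * t + phP)
  dPhi <- -(p$Phi_p / 2) * w * sin(w * t + phP)
  ddPhi <- -(p$Phi_p / 2) * w^2 * cos(w * t + phP)
  theta <- p$theta0 + (p$theta_p / 2) * cos(w * t + phT)
  dtheta <- -(p$theta_p / 2) * w * sin(w * t + phT)
  ddtheta <- -(p$theta_p / 2) * w^2 * cos(w * t + phT)

  # cycle fraction: tau = 0 at end-downstroke (sweep maximum)
  tau <- (freq * t + p$phase_Phi / 360) %% 1
  sq <- smoothed_square(tau, rev_frac / 2)
  span <- 180 - p$alpha_up - p$alpha_down
  xi <- p$alpha_down + span * sq$S
  dxi <- span * sq$dS * freq          # deg/s
  down <- tau >= 0.5
  alpha <- ifelse(down, xi, 180 - xi)
  list(Phi = Phi, dPhi = dPhi, ddPhi = ddPhi,
       theta = theta, dtheta = dtheta, ddtheta = ddtheta,
       xi = xi, dxi = dxi, alpha = alpha,
       halfstroke = ifelse(down, "down", "up"))
}

# Smoothed square wave on cycle fraction tau in [0,1):
# 1 on the upstroke (tau in (h, 0.5-h)), 0 on the downstroke
# (tau in (0.5+h, 1-h)), cosine ramps of half-width h at tau = 0, 0.5.
# Returns S and dS/dtau.
smoothed_square <- function(tau, h) {
  S <- numeric(length(tau))
  dS <- numeric(length(tau))
  # distance from the two reversal points, wrapped to [-0.5, 0.5)
  u0 <- ((tau + 0.5) %% 1) - 0.5       # near tau = 0: rising 0 -> 1
  u5 <- ((tau - 0.5 + 0.5) %% 1) - 0.5 # near tau = 0.5: falling 1 -> 0
  in0 <- abs(u0) < h
  in5 <- abs(u5) < h
  up <- !in0 & !in5 & (tau > 0 & tau < 0.5)
  S[up] <- 1
  a0 <- pi * (u0[in0] + h) / (2 * h)
  S[in0] <- 0.5 * (1 - cos(a0))
  dS[in0] <- 0.5 * sin(a0) * pi / (2 * h)
  a5 <- pi * (u5[in5] + h) / (2 * h)
  S[in5] <- 0.5 * (1 + cos(a5))
  dS[in5] <- -0.5 * sin(a5) * pi / (2 * h)
  list(S = S, dS = dS)
}
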