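#' Simulator configuration
#'
#' Morphology, aerodynamic constants and numerical settings for the
#' blade-element flapping-flight simulator. Units are CGS throughout
#' (cm, g, s) with angles in degrees at the interface; the global z-axis
#' points down (parallel with gravity) and +y is the moth's right.
#'
#' The default morphology is a 2 g hawkmoth with 5 cm wings flapping at
#' 26 Hz. The aerodynamic constants follow the standard quasi-steady
#' decomposition: a translational lift curve `CL = A_L * sin(2 * alpha)`,
#' a drag curve `CD = C_D0 + B_D * (1 - cos(2 * alpha))`, a rotational
#' force coefficient `C_rot = pi * (0.75 - x0_hat)` where `x0_hat` is the
#' chord fraction of the pitch axis, and a cylinder added-mass term
#' `m_a = rho * pi * c^2 / 4` per unit span. Defaults are calibrated so
#' that hover trim occurs near a 110-120 degree sweep amplitude.
#'
#' @param body_mass body mass (g).
#' @param wing_length wing length, base to tip (cm).
#' @param mean_chord mean wing chord (cm); used to build the default
#'   elliptic `chord_profile`.
#' @param chord_profile optional vector of per-blade-station chord lengths
#'   (cm), length `n_blade_elements`. Overrides `mean_chord` if given.
#' @param roll_inertia moment of inertia about the body x (roll) axis
#'   (g cm^2).
#' @param flap_frequency wingbeat frequency (Hz).
#' @param air_density air density (g/cm^3).
#' @param gravity gravitational acceleration (cm/s^2).
#' @param A_L lift-curve amplitude.
#' @param C_D0 minimum drag coefficient.
#' @param B_D drag-curve amplitude.
#' @param x0_hat pitch-axis location as a chord fraction.
#' @param C_rot rotational force coefficient; default `pi * (0.75 - x0_hat)`.
#' @param n_blade_elements number of blade elements per wing (>= 4).
#' @param steps_per_wingbeat integration steps per wingbeat (>= 50).
#' @param wing_base_offset numeric length-3: position of the right wing
#'   base in the body frame (cm); the left base is mirrored in y. A
#'   negative z places the wing bases dorsal to (above) the center of
#'   mass, which is what couples lateral velocity into roll torque.
#' @param seed integer seed recorded with the configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(body_mass = 2,
                       wing_length = 5,
                       mean_chord = 1.8,
                       chord_profile = NULL,
                       roll_inertia = 1.0,
                       flap_frequency = 26,
                       air_density = 0.0012,
                       gravity = 980.665,
                       A_L = 1.8,
                       C_D0 = 0.1,
                       B_D = 1.7,
                       x0_hat = 0.25,
                       C_rot = pi * (0.75 - x0_hat),
                       n_blade_elements = 8,
                       steps_per_wingbeat = 64,
                       wing_base_offset = c(0, 0.55, -1.2),
                       seed = 1L) {
  stopifnot_positive(body_mass, "body_mass")
  stopifnot_positive(wing_length, "wing_length")
  stopifnot_positive(roll_inertia, "roll_inertia")
  stopifnot_positive(flap_frequency, "flap_frequency")
  if (gravity < 0) stop("'gravity' must be >= 0")
  if (air_density < 0) stop("'air_density' must be >= 0")
  if (n_blade_elements < 4) stop("'n_blade_elements' must be >= 4")
  if (steps_per_wingbeat < 50) {
    stop("'steps_per_wingbeat' must be >= 50 (timestep <= 1/(50*flap_frequency))")
  }
  if (length(wing_base_offset) != 3) stop("'wing_base_offset' must have length 3")

  n <- as.integer(n_blade_elements)
  # blade station midpoints and widths
  dr <- wing_length / n
  r <- (seq_len(n) - 0.5) * dr
  if (is.null(chord_profile)) {
    # elliptic planform with the requested mean chord
    s <- r / wing_length
    chord_profile <- mean_chord * (4 / pi) * sqrt(pmax(0, 1 - (2 * s - 1)^2))
  }
  if (length(chord_profile) != n) {
    stop("'chord_profile' must have one chord per blade element")
  }
  stopifnot_positive(chord_profile, "chord_profile")

  cfg <- list(
    body_mass = body_mass,
    wing_length = wing_length,
    chord_profile = chord_profile,
    roll_inertia = roll_inertia,
    flap_frequency = flap_frequency,
    air_density = air_density,
    gravity = gravity,
    A_L = A_L, C_D0 = C_D0, B_D = B_D, x0_hat = x0_hat, C_rot = C_rot,
    n_blade_elements = n,
    steps_per_wingbeat = as.integer(steps_per_wingbeat),
    timestep = 1 / (flap_frequency * steps_per_wingbeat),
    wing_base_offset = as.numeric(wing_base_offset),
    seed = as.integer(seed),
    stations_r = r,
    stations_dr = dr
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  body_mass: %.3g g, wing_length: %.3g cm, roll_inertia: %.3g g cm^2\n",
              x$body_mass, x$wing_length, x$roll_inertia))
  cat(sprintf("  flap_frequency: %.3g Hz, air_density: %.4g g/cm^3, g: %.4f cm/s^2\n",
              x$flap_frequency, x$air_density, x$gravity))
  cat(sprintf("  aero: A_L=%.3g C_D0=%.3g B_D=%.3g x0_hat=%.3g C_rot=%.3g\n",
              x$A_L, x$C_D0, x$B_D, x$x0_hat, x$C_rot))
  cat(sprintf("  %d blade elements, %d steps/wingbeat (dt=%.3g s)\n",
              x$n_blade_elements, x$steps_per_wingbeat, x$timestep))
  invisible(x)
}

#' Wing kinematic command
#'
#' Commanded flapping kinematics for the left and right wing pairs. The
#' sweep angle follows `Phi(t) = Phi0 + (Phi_p/2) * cos(2*pi*f*t + phase)`,
#' elevation follows the analogous cosine, and the wing pitch command
#' transitions between its downstroke and upstroke values through a
#' smoothed square wave with a configurable reversal fraction.
#'
#' Each parameter may be a single value (applied to both wings) or a
#' length-2 vector `c(left, right)`.
#'
#' @param Phi0 mean sweep angle (deg); 0 means the wing points straight
#'   laterally at midstroke.
#' @param Phi_p peak-to-peak sweep amplitude (deg), in (0, 180).
#' @param theta0 mean elevation angle (deg).
#' @param theta_p peak-to-peak elevation amplitude (deg), in [0, 90).
#' @param alpha_down midstroke wing pitch during downstroke (deg), in (0, 90).
#' @param alpha_up midstroke wing pitch during upstroke (deg), in (0, 90).
#' @param phase_Phi sweep phase offset (deg).
#' @param phase_theta elevation phase offset (deg) relative to sweep.
#' @param reversal_fraction fraction of the halfstroke spent reversing
#'   wing pitch (smoothed square-wave ramp width).
#' @return an object of class `wing_command`: a list with `left` and
#'   `right` per-wing parameter sets.
#' @export
wing_command <- function(Phi0 = 0, Phi_p = 115,
                         theta0 = 16, theta_p = 15,
                         alpha_down = 40, alpha_up = 40,
                         phase_Phi = 0, phase_theta = 0,
                         reversal_fraction = 0.1) {
  two <- function(x, name) {
    if (length(x) == 1) x <- c(x, x)
    if (length(x) != 2) stop(sprintf("'%s' must have length 1 or 2", name))
    as.numeric(x)
  }
  Phi0 <- two(Phi0, "Phi0"); Phi_p <- two(Phi_p, "Phi_p")
  theta0 <- two(theta0, "theta0"); theta_p <- two(theta_p, "theta_p")
  alpha_down <- two(alpha_down, "alpha_down"); alpha_up <- two(alpha_up, "alpha_up")
  phase_Phi <- two(phase_Phi, "phase_Phi"); phase_theta <- two(phase_theta, "phase_theta")
  if (any(Phi_p < 0 | Phi_p >= 180)) stop("'Phi_p' must be in [0, 180)")
  if (any(theta_p < 0 | theta_p >= 90)) stop("'theta_p' must be in [0, 90)")
  if (any(alpha_down <= 0 | alpha_down >= 90)) stop("'alpha_down' must be in (0, 90)")
  if (any(alpha_up <= 0 | alpha_up >= 90)) stop("'alpha_up' must be in (0, 90)")
  if (reversal_fraction <= 0 || reversal_fraction > 0.5) {
    stop("'reversal_fraction' must be in (0, 0.5]")
  }
  mk <- function(i) list(Phi0 = Phi0[i], Phi_p = Phi_p[i],
                         theta0 = theta0[i], theta_p = theta_p[i],
                         alpha_down = alpha_down[i], alpha_up = alpha_up[i],
                         phase_Phi = phase_Phi[i], phase_theta = phase_theta[i])
  cmd <- list(left = mk(1), right = mk(2), reversal_fraction = reversal_fraction)
  class(cmd) <- "wing_command"
  cmd
}

#' Swap the left and right wing commands
#'
#' @param cmd a [wing_command()].
#' @return the mirrored `wing_command`.
#' @export
mirror_command <- function(cmd) {
  stopifnot(inherits(cmd, "wing_command"))
  out <- cmd
  out$left <- cmd$right
  out$right <- cmd$left
  out
}

#' @export
print.wing_command <- function(x, ...) {
  cat("<wing_command>\n")
  for (side in c("left", "right")) {
    p <- x[[side]]
    cat(sprintf("  %-5s Phi0=%g Phi_p=%g theta0=%g theta_p=%g a_down=%g a_up=%g\n",
                side, p$Phi0, p$Phi_p, p$theta0, p$theta_p, p$alpha_down, p$alpha_up))
  }
  cat(sprintf("  reversal_fraction=%g\n", x$reversal_fraction))
  invisible(x)
}

#' Read simulator configuration and wing commands from a YAML-like file
#'
#' Reads a plain structured text (YAML) config with optional `sim` and
#' `command` blocks whose keys are the arguments of [sim_config()] and
#' [wing_command()].
#'
#' @param path file path.
#' @return list with elements `config` and `command`.
#' @export
read_sim_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vals <- parse_simple_yaml(txt)
  cfg <- do.call(sim_config, vals$sim %||% list())
  cmd <- do.call(wing_command, vals$command %||% list())
  list(config = cfg, command = cmd)
}

# minimal two-level "key: value" parser (numbers and numeric vectors only)
parse_simple_yaml <- function(lines) {
  out <- list()
  block <- NULL
  for (ln in lines) {
    if (grepl("^\\s*(#|$)", ln)) next
    if (grepl("^[A-Za-z_][A-Za-z0-9_]*:\\s*$", ln)) {
      block <- sub(":\\s*$", "", trimws(ln))
      out[[block]] <- list()
    } else if (grepl("^\\s+[A-Za-z_]", ln) && !is.null(block)) {
      kv <- strsplit(trimws(ln), ":", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      val <- gsub("\\[|\\]", "", val)
      out[[block]][[key]] <- as.numeric(strsplit(val, ",")[[1]])
    }
  }
  out
}
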