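#' Body Euler angles from digitized landmarks
#'
#' Computes yaw, pitch and roll from the scutum, abdomen tip and wing
#' base points of one frame. The body x-axis runs from the abdomen tip
#' to the centroid of scutum and wing bases; the y-axis is the wing
#' base line orthonormalized against it (Gram-Schmidt); z completes a
#' right-handed triad. Angles are the intrinsic z-y-x (yaw, pitch,
#' roll) decomposition, so roll is measured absolute to the global
#' horizontal plane. The modified global reference frame (MGRF) is the
#' global frame rotated in yaw only, keeping z vertical.
#'
#' @param frame one row of a `landmark_frames` data.frame (or any list
#'   with `p1_x`..`p3R_z` entries).
#' @return list with `yaw`, `pitch`, `roll` (deg), `R_body` (3x3 BRF to
#'   GRF rotation) and `yaw_R` (3x3 MGRF to GRF rotation).
#' @export
body_euler <- function(frame) {
  gp <- function(nm) as.numeric(c(frame[[paste0(nm, "_x")]],
                                  frame[[paste0(nm, "_y")]],
                                  frame[[paste0(nm, "_z")]]))
  p1 <- gp("p1"); p2 <- gp("p2"); p3L <- gp("p3L"); p3R <- gp("p3R")
  if (any(!is.finite(c(p1, p2, p3L, p3R)))) {
    stop("body points p1, p2, p3L, p3R must all be present")
  }
  ctr <- (p1 + p3L + p3R) / 3
  xb <- ctr - p2
  nx <- sqrt(sum(xb^2))
  if (nx < 1e-9) stop("degenerate body axis: abdomen tip coincides with centroid")
  xb <- xb / nx
  yraw <- p3R - p3L
  yb <- yraw - sum(yraw * xb) * xb
  ny <- sqrt(sum(yb^2))
  if (ny < 1e-9) {
    stop(sprintf("collinear landmarks in frame %s: wing base line parallel to body axis",
                 frame[["frame"]] %||% "?"))
  }
  yb <- yb / ny
  zb <- cross3(xb, yb)
  R <- cbind(xb, yb, zb)
  e <- euler_zyx(R)
  yawR <- rot_zyx(e["yaw"], 0, 0)
  list(yaw = rad2deg(unname(e["yaw"])), pitch = rad2deg(unname(e["pitch"])),
       roll = rad2deg(unname(e["roll"])), R_body = R, yaw_R = yawR)
}

#' Wing angles from one landmark frame
#'
#' Computes per-wing sweep, elevation and wing pitch from the
#' body-frame wing vectors. Sweep is the angle of the base-to-forewing
#' tip vector projected onto the body x/y plane (0 = straight lateral,
#' positive forward); elevation is its angle above the body horizontal;
#' wing pitch is the angle of the chord vector (hindwing tip to
#' forewing tip) projected onto the body x/z plane, measured from the
#' +x axis for downstroke frames and from the -x axis for upstroke
#' frames (positive above horizontal). When the hindwing tip is missing
#' the pitch falls back to the forewing-vector normal in the x/z plane
#' and is flagged.
#'
#' @param frame one row of a `landmark_frames` data.frame.
#' @param pose the [body_euler()] result for that frame; computed if
#'   omitted.
#' @param chord_tol minimum body x/z-plane chord projection length (cm)
#'   below which the pitch is reported missing.
#' @return data.frame with one row per side: `side`, `Phi`, `theta`,
#'   `alpha` (deg), `alpha_src` ("chord", "fallback" or "missing").
#' @export
wing_angles <- function(frame, pose = body_euler(frame), chord_tol = 0.05) {
  down <- grepl("down", frame[["phase"]] %||% "mid_down")
  Rt <- t(pose$R_body)
  gp <- function(nm) as.numeric(c(frame[[paste0(nm, "_x")]],
                                  frame[[paste0(nm, "_y")]],
                                  frame[[paste0(nm, "_z")]]))
  out <- lapply(c(L = -1, R = 1), function(w) {
    side <- if (w < 0) "L" else "R"
    base <- gp(paste0("p3", side)); tip <- gp(paste0("p4", side))
    hw <- gp(paste0("p5", side))
    fw <- as.numeric(Rt %*% (tip - base))
    if (sqrt(sum(fw^2)) < 1e-9) stop("zero-length forewing vector")
    Phi <- rad2deg(atan2(fw[1], w * fw[2]))
    theta <- rad2deg(atan2(-fw[3], sqrt(fw[1]^2 + fw[2]^2)))
    if (all(is.finite(hw))) {
      ch <- as.numeric(Rt %*% (tip - hw))
      if (sqrt(ch[1]^2 + ch[3]^2) < chord_tol) {
        alpha <- NA_real_; src <- "missing"
      } else {
        alpha <- chord_pitch(ch, down)
        src <- "chord"
      }
    } else {
      # hindwing tip absent: use the forewing-vector normal in the x/z plane
      nrm <- c(-fw[3], 0, fw[1])
      if (sqrt(sum(nrm^2)) < 1e-9) {
        alpha <- NA_real_; src <- "missing"
      } else {
        alpha <- chord_pitch(nrm, down)
        if (alpha < 0) alpha <- alpha + 180
        src <- "fallback"
      }
    }
    data.frame(side = side, Phi = Phi, theta = theta, alpha = alpha,
               alpha_src = src, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# pitch of a body-frame chord vector projected on the x/z plane;
# measured from +x (downstroke) or -x (upstroke), positive above horizontal
chord_pitch <- function(ch_brf, down) {
  x <- ch_brf[1]; zup <- -ch_brf[3]
  if (down) rad2deg(atan2(zup, x)) else rad2deg(atan2(zup, -x))
}

#' Halfstroke amplitudes from two consecutive endstroke frames
#'
#' The angular stroke amplitude is the 3D angle between the body-frame
#' forewing vectors at the two ends of a halfstroke; the sweep and
#' elevation amplitudes are the angles between their projections onto
#' the body x/y and x/z planes.
#'
#' @param fw1,fw2 body-frame forewing vectors (base to tip) at the two
#'   endstrokes.
#' @param type1,type2 endstroke phase labels; must be one "end_down"
#'   and one "end_up".
#' @return list with `Psi_p`, `Phi_p`, `theta_p` (deg).
#' @export
stroke_amplitudes <- function(fw1, fw2, type1 = "end_up", type2 = "end_down") {
  if (type1 == type2) {
    stop("consecutive endstrokes of the same type: sequencing error")
  }
  ang <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) return(NA_real_)
    rad2deg(acos(max(-1, min(1, sum(a * b) / (na * nb)))))
  }
  list(Psi_p = ang(fw1, fw2),
       Phi_p = ang(c(fw1[1], fw1[2]), c(fw2[1], fw2[2])),
       theta_p = ang(c(fw1[1], fw1[3]), c(fw2[1], fw2[3])))
}

#' Stroke-plane roll from forewing tips
#'
#' Signed angle of the line between the two forewing tips relative to
#' the global horizontal plane, positive when the right tip is lower.
#' Used as a net-force-direction proxy for body roll.
#'
#' @param frame one row of a `landmark_frames` data.frame (or a list
#'   with `p4L_x`.. `p4R_z`).
#' @return angle in degrees.
#' @export
stroke_plane_roll <- function(frame) {
  d <- c(frame[["p4R_x"]] - frame[["p4L_x"]],
         frame[["p4R_y"]] - frame[["p4L_y"]],
         frame[["p4R_z"]] - frame[["p4L_z"]])
  d <- as.numeric(d)
  h <- sqrt(d[1]^2 + d[2]^2)
  if (sqrt(sum(d^2)) < 1e-9) stop("coincident forewing tips")
  rad2deg(atan2(d[3], h))
}

#' Wingbeat-to-wingbeat derivatives of a phase-sampled series
#'
#' First derivatives are central differences between like-phase samples
#' one wingbeat apart divided by the wingbeat period (forward/backward
#' at the series ends); this filters out any signal with period exactly
#' one wingbeat. The four phase-specific estimates are averaged per
#' wingbeat; second derivatives apply the same scheme to the first
#' derivatives.
#'
#' @param wingbeat integer wingbeat index per sample.
#' @param phase phase label per sample.
#' @param value numeric series.
#' @param period wingbeat period (s).
#' @return list with per-sample `d1`, `d2` (slot-wise estimates) and
#'   per-wingbeat `wb` data.frame (`wingbeat`, `d1`, `d2`: averages of
#'   the phase-specific estimates).
#' @export
wingbeat_derivatives <- function(wingbeat, phase, value, period) {
  ph_levels <- unique(phase)
  wbs <- sort(unique(wingbeat))
  wb_index <- match(wingbeat, wbs)
  M <- matrix(NA_real_, nrow = length(wbs), ncol = length(ph_levels),
              dimnames = list(NULL, ph_levels))
  M[cbind(wb_index, match(phase, ph_levels))] <- value
  diff_cols <- function(M) {
    D <- M * NA_real_
    n <- nrow(M)
    if (n >= 2) {
      for (j in seq_len(ncol(M))) {
        x <- M[, j]
        d <- rep(NA_real_, n)
        if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * period)
        d[1] <- (x[2] - x[1]) / period
        d[n] <- (x[n] - x[n - 1]) / period
        D[, j] <- d
      }
    }
    D
  }
  D1 <- diff_cols(M)
  D2 <- diff_cols(D1)
  idx <- cbind(wb_index, match(phase, ph_levels))
  list(d1 = D1[idx], d2 = D2[idx],
       wb = data.frame(wingbeat = wbs,
                       d1 = rowMeans(D1, na.rm = TRUE),
                       d2 = rowMeans(D2, na.rm = TRUE)))
}

#' Segment sustained lateral maneuvers
#'
#' Labels maximal runs of constant-sign lateral acceleration lasting at
#' least `min_duration` seconds as maneuvers; shorter runs are left
#' unlabeled.
#'
#' @param time sample times (s).
#' @param yddot lateral acceleration series.
#' @param min_duration minimum sustained duration (s); the default is
#'   about two wingbeat cycles at 26 Hz.
#' @return data.frame with one row per maneuver: `start`, `end`,
#'   `duration`, `sign`.
#' @export
segment_maneuvers <- function(time, yddot, min_duration = 0.077) {
  ok <- is.finite(yddot) & yddot != 0
  sgn <- ifelse(ok, sign(yddot), 0)
  out <- list()
  i <- 1L
  n <- length(sgn)
  while (i <= n) {
    if (sgn[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < n && sgn[j + 1] == sgn[i]) j <- j + 1L
    dur <- time[j] - time[i]
    if (dur >= min_duration) {
      out[[length(out) + 1]] <- data.frame(start = time[i], end = time[j],
                                           duration = dur, sign = sgn[i])
    }
    i <- j + 1L
  }
  if (length(out) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), sign = numeric(0)))
  }
  do.call(rbind, out)
}
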