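# build a landmark row from template points posed by a known rotation
posed_frame <- function(yaw = 0, pitch = 0, roll = 0, pos = c(0, 0, 0),
                        phase = "mid_down") {
  m <- morphology_template()
  R <- mothslip:::rot_zyx(yaw * pi / 180, pitch * pi / 180, roll * pi / 180)
  pts <- list(p1 = m$p1_scutum, p2 = m$p2_abdomen,
              p3L = m$p3L_base, p3R = m$p3R_base,
              p4L = m$p3L_base + c(0, -5, 0), p4R = m$p3R_base + c(0, 5, 0),
              p5L = m$p3L_base + c(-2, -5, 0), p5R = m$p3R_base + c(-2, 5, 0))
  row <- list(frame = 1L, phase = phase)
  for (nm in names(pts)) {
    p <- pos + as.numeric(R %*% pts[[nm]])
    row[[paste0(nm, "_x")]] <- p[1]
    row[[paste0(nm, "_y")]] <- p[2]
    row[[paste0(nm, "_z")]] <- p[3]
  }
  row
}

test_that("body Euler angles recover known rotations", {
  p0 <- body_euler(posed_frame())
  expect_equal(c(p0$yaw, p0$pitch, p0$roll), c(0, 0, 0), tolerance = 1e-9)
  py <- body_euler(posed_frame(yaw = 25))
  expect_equal(c(py$yaw, py$pitch, py$roll), c(25, 0, 0), tolerance = 1e-9)
  pc <- body_euler(posed_frame(yaw = 20, pitch = -10, roll = 15))
  expect_equal(c(pc$yaw, pc$pitch, pc$roll), c(20, -10, 15),
               tolerance = 1e-9)
})

test_that("degenerate body landmarks raise errors", {
  fr <- posed_frame()
  for (ax in c("_x", "_y", "_z")) fr[[paste0("p3R", ax)]] <- fr[[paste0("p3L", ax)]]
  # wing bases coincide -> y-axis degenerate after Gram-Schmidt
  expect_error(body_euler(fr), "collinear|degenerate")
  fr2 <- posed_frame()
  fr2$p1_x <- NA_real_
  expect_error(body_euler(fr2), "present")
})

test_that("wing pitch follows the chord projection conventions", {
  mkchord <- function(chord_brf, phase) {
    fr <- posed_frame(phase = phase)
    # right wing lateral; chord = p4 - p5
    for (i in 1:3) {
      fr[[paste0("p5R", c("_x", "_y", "_z")[i])]] <-
        fr[[paste0("p4R", c("_x", "_y", "_z")[i])]] - chord_brf[i] * 2
    }
    wa <- wing_angles(fr)
    wa$alpha[wa$side == "R"]
  }
  # chord in the body x/y plane -> 0 pitch
  expect_equal(mkchord(c(1, 0.2, 0), "mid_down"), 0, tolerance = 1e-9)
  # vertical chord at mid-downstroke -> 90
  expect_equal(mkchord(c(0, 0, -1), "mid_down"), 90, tolerance = 1e-9)
  # forward-up 45-degree chord: 45 from +x in downstroke,
  # 135 when measured from -x in upstroke
  ch <- c(1, 0, -1) / sqrt(2)
  expect_equal(mkchord(ch, "mid_down"), 45, tolerance = 1e-9)
  expect_equal(mkchord(ch, "mid_up"), 135, tolerance = 1e-9)
})

test_that("halfstroke amplitudes match spherical trigonometry", {
  none <- stroke_amplitudes(c(1, 2, 0.5), c(1, 2, 0.5))
  expect_equal(none$Psi_p, 0, tolerance = 1e-5)
  expect_equal(none$Phi_p, 0, tolerance = 1e-5)
  # planar stroke in the body x/y plane
  v1 <- c(cos(50 * pi / 180), sin(50 * pi / 180), 0)
  v2 <- c(cos(50 * pi / 180), -sin(50 * pi / 180), 0)
  pl <- stroke_amplitudes(v1, v2)
  expect_equal(pl$Psi_p, 100, tolerance = 1e-9)
  expect_equal(pl$Phi_p, 100, tolerance = 1e-9)
  expect_equal(pl$theta_p, 0, tolerance = 1e-9)
  # 100-degree sweep in a plane inclined 20 degrees about x
  inc <- 20 * pi / 180
  w1 <- c(cos(50 * pi / 180), sin(50 * pi / 180) * cos(inc),
          sin(50 * pi / 180) * sin(inc))
  w2 <- c(cos(50 * pi / 180), -sin(50 * pi / 180) * cos(inc),
          -sin(50 * pi / 180) * sin(inc))
  am <- stroke_amplitudes(w1, w2)
  expect_equal(am$Psi_p, 100, tolerance = 1e-9)
  # closed-form projections of the inclined sweep
  expect_equal(am$Phi_p, 2 * atan(tan(50 * pi / 180) * cos(inc)) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(am$theta_p, 2 * atan(tan(50 * pi / 180) * sin(inc)) * 180 / pi,
               tolerance = 1e-9)
  expect_error(stroke_amplitudes(v1, v2, "end_up", "end_up"), "sequencing")
})

test_that("like-phase differencing filters within-wingbeat signals", {
  Tw <- 1 / 26
  wb <- rep(0:9, each = 4)
  phase <- rep(c("end_down", "mid_up", "end_up", "mid_down"), 10)
  t <- wb * Tw + rep(c(0, 0.25, 0.5, 0.75), 10) * Tw
  # constant
  d <- wingbeat_derivatives(wb, phase, rep(3, 40), Tw)
  expect_equal(max(abs(d$d1)), 0)
  expect_equal(max(abs(d$d2), na.rm = TRUE), 0)
  # linear motion
  d <- wingbeat_derivatives(wb, phase, 12 * t, Tw)
  expect_equal(d$d1, rep(12, 40), tolerance = 1e-9)
  expect_equal(max(abs(d$wb$d2)), 0, tolerance = 1e-6)
  # pure within-wingbeat oscillation vanishes under like-phase differencing
  d <- wingbeat_derivatives(wb, phase, 2 * sin(2 * pi * 26 * t), Tw)
  expect_lt(max(abs(d$d1)), 1e-9)
  # second derivatives equal the scheme applied twice
  x <- stats::rnorm(40)
  d <- wingbeat_derivatives(wb, phase, x, Tw)
  d1_again <- wingbeat_derivatives(wb, phase, d$d1, Tw)
  expect_equal(d$d2, d1_again$d1, tolerance = 1e-12)
})

test_that("maneuver segmentation applies the sustained-sign rule", {
  t <- seq(0, 1, by = 0.02)
  acc <- rep(0, length(t))
  acc[t >= 0.1 & t <= 0.18] <- 50    # 0.08 s run
  m <- segment_maneuvers(t, acc)
  expect_identical(nrow(m), 1L)
  expect_gte(m$duration, 0.077)
  acc2 <- rep(0, length(t))
  acc2[t >= 0.3 & t < 0.35] <- -40   # 0.04 s run
  expect_identical(nrow(segment_maneuvers(t, acc2)), 0L)
  acc3 <- rep(c(30, -30), length.out = length(t))  # alternating signs
  expect_identical(nrow(segment_maneuvers(t, acc3)), 0L)
})

test_that("stroke-plane roll is the tip-line angle from horizontal", {
  fr <- posed_frame()
  expect_equal(stroke_plane_roll(fr), 0, tolerance = 1e-9)
  fr$p4R_z <- fr$p4R_z + 2    # right tip lower (z down)
  dy <- fr$p4R_y - fr$p4L_y
  expect_equal(stroke_plane_roll(fr), atan2(2, dy) * 180 / pi,
               tolerance = 1e-9)
  fr2 <- posed_frame()
  for (ax in c("_x", "_y", "_z")) fr2[[paste0("p4R", ax)]] <- fr2[[paste0("p4L", ax)]]
  expect_error(stroke_plane_roll(fr2), "coincident")
})

test_that("rotating a trial about the vertical leaves MGRF measures unchanged", {
  fr <- noiseless_frames()
  kin0 <- frame_kinematics(fr)
  ang <- 37 * pi / 180
  rot <- fr
  for (p in c("p1", "p2", "p3L", "p3R", "p4L", "p4R", "p5L", "p5R")) {
    x <- fr[[paste0(p, "_x")]]; y <- fr[[paste0(p, "_y")]]
    rot[[paste0(p, "_x")]] <- cos(ang) * x - sin(ang) * y
    rot[[paste0(p, "_y")]] <- sin(ang) * x + cos(ang) * y
  }
  kin1 <- frame_kinematics(rot)
  expect_equal(kin1$yaw, kin0$yaw + 37, tolerance = 1e-6)
  expect_equal(kin1$Phi_L, kin0$Phi_L, tolerance = 1e-6)
  expect_equal(kin1$alpha_R, kin0$alpha_R, tolerance = 1e-6)
  expect_equal(kin1$y_m, kin0$y_m, tolerance = 1e-6)
  expect_equal(kin1$z_m, kin0$z_m, tolerance = 1e-9)
})

test_that("MGRF z equals GRF z", {
  fr <- noiseless_frames()
  kin <- frame_kinematics(fr)
  zg <- (fr$p1_z + fr$p3L_z + fr$p3R_z) / 3
  expect_equal(kin$z_m, zg, tolerance = 1e-12)
})
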