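test_that("noiseless landmarks recover the commanded pose and wing angles", {
  fr <- noiseless_frames()
  tru <- attr(fr, "truth")
  kin <- frame_kinematics(fr)
  expect_lt(max(abs(kin$roll - tru$beta)), 1e-9)
  expect_lt(max(abs(kin$yaw)), 1e-6)
  expect_lt(max(abs(kin$pitch)), 1e-6)
  expect_lt(max(abs(kin$Phi_L - tru$Phi_L)), 1e-6)
  expect_lt(max(abs(kin$Phi_R - tru$Phi_R)), 1e-6)
  expect_lt(max(abs(kin$theta_L - tru$theta_L)), 1e-6)
  expect_lt(max(abs(kin$theta_R - tru$theta_R)), 1e-6)
  expect_lt(max(abs(kin$alpha_L - tru$alpha_L)), 1e-6)
  expect_lt(max(abs(kin$alpha_R - tru$alpha_R)), 1e-6)
  expect_lt(max(abs(kin$y_m - tru$y)), 1e-9)
})

test_that("all-missing hindwing tips still yield flagged wing pitch", {
  traj <- maneuver_traj()
  fr <- landmarks_from_trajectory(traj, noise_sd = 0, missing_p5_rate = 1,
                                  seed = 2L)
  expect_true(all(is.na(fr$p5L_x)))
  expect_true(all(is.na(fr$p5R_x)))
  kin <- frame_kinematics(fr)
  expect_true(all(is.finite(kin$alpha_L)))
  expect_true(all(kin$alpha_src_L == "fallback"))
})

test_that("a commanded roll ramp is recovered through landmark noise", {
  traj <- maneuver_traj()
  fr <- landmarks_from_trajectory(traj, noise_sd = 0.05,
                                  missing_p5_rate = 0, seed = 9L)
  tru <- attr(fr, "truth")
  kin <- frame_kinematics(fr)
  sl <- stats::coef(stats::lm(kin$roll ~ tru$beta))[2]
  expect_gt(sl, 0.9)
  expect_lt(sl, 1.1)
  expect_lt(stats::sd(kin$roll - tru$beta), 4 * 5)
})

test_that("landmark generation is deterministic in the seed", {
  traj <- maneuver_traj()
  a <- landmarks_from_trajectory(traj, noise_sd = 0.05, seed = 17L)
  b <- landmarks_from_trajectory(traj, noise_sd = 0.05, seed = 17L)
  cc <- landmarks_from_trajectory(traj, noise_sd = 0.05, seed = 18L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$p1_x, cc$p1_x))
})

test_that("inconsistent morphology is rejected", {
  expect_error(
    landmarks_from_trajectory(maneuver_traj(),
                              morphology_template(wing_length = 4)),
    "inconsistent")
})

test_that("landmark CSV round trips including missing cells", {
  fr <- landmarks_from_trajectory(maneuver_traj(), noise_sd = 0.02,
                                  missing_p5_rate = 0.5, seed = 4L)
  path <- tempfile(fileext = ".csv")
  write_landmark_csv(fr, path)
  back <- read_landmark_csv(path)
  expect_equal(back$p4R_x, fr$p4R_x, tolerance = 1e-9)
  expect_identical(is.na(back$p5L_x), is.na(fr$p5L_x))
  expect_identical(back$phase, fr$phase)
  unlink(path)
})

test_that("angle errors scale with landmark noise", {
  traj <- maneuver_traj()
  err <- vapply(c(0.05, 0.2), function(ns) {
    e <- c()
    for (s in 1:4) {
      fr <- landmarks_from_trajectory(traj, noise_sd = ns, seed = 20L + s,
                                      missing_p5_rate = 0)
      kin <- frame_kinematics(fr)
      e <- c(e, kin$roll - attr(fr, "truth")$beta)
    }
    stats::sd(e)
  }, numeric(1))
  expect_gt(err[2], 2.5 * err[1])
  expect_lt(err[2], 6.5 * err[1])
})

test_that("phases cycle in the fixed stroke order", {
  fr <- hover_frames()
  ph <- fr$phase
  i <- which(ph == "end_up")[1]
  expect_identical(ph[i + 0:3], c("end_up", "mid_down", "end_down", "mid_up"))
})
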