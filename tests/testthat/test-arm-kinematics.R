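# Forward kinematics, angle extraction and inverse kinematics of the
# seven-DoF arm model.

# independent oracle: compose homogeneous transforms matrix by matrix,
# written directly from the declared convention (and separately from the
# package's FK implementation)
oracle_fk <- function(q, geometry, shoulder = geometry$shoulder_home) {
  d <- pi / 180
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a),
                             cos(a)), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0,
                             cos(a)), 3, 3)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0,
                             1), 3, 3)
  H <- function(R, p) rbind(cbind(R, p), c(0, 0, 0, 1))
  Tsh <- H(diag(3), shoulder)
  Tu <- Tsh %*% H(Ry(-q[1] * d) %*% Rx(-q[2] * d) %*% Rz(q[3] * d),
                  c(0, 0, 0))
  Te <- Tu %*% H(diag(3), c(0, 0, -geometry$lengths[["upper"]]))
  Tf <- Te %*% H(Ry(-q[4] * d) %*% Rz(q[5] * d), c(0, 0, 0))
  Tw <- Tf %*% H(diag(3), c(0, 0, -geometry$lengths[["fore"]]))
  Th <- Tw %*% H(Ry(-q[7] * d) %*% Rx(-q[6] * d), c(0, 0, 0))
  Tc <- Th %*% H(diag(3), c(0, 0, -geometry$lengths[["hand"]]))
  list(hand = Tc[1:3, 4], axis = Th[1:3, 3], elbow = Te[1:3, 4])
}

test_that("neutral posture places the hand straight below the shoulder", {
  fk <- forward_kinematics(joint_posture(), geo)
  expect_equal(fk$hand$center, c(0, 0, -geo$reach), tolerance = 1e-12)
  expect_equal(fk$hand$axis, c(0, 0, 1), tolerance = 1e-12)
})

test_that("elbow flexion displaces the distal chain forward, matching the
          homogeneous-transform oracle", {
  q <- joint_posture(el_flex = 90)
  fk <- forward_kinematics(q, geo)
  expect_equal(fk$frames$elbow, c(0, 0, -geo$lengths[["upper"]]),
               tolerance = 1e-12)
  expect_equal(fk$hand$center,
               c(geo$lengths[["fore"]] + geo$lengths[["hand"]], 0,
                 -geo$lengths[["upper"]]),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:25) {
    q <- random_posture()
    fk <- forward_kinematics(q, geo, check_limits = FALSE)
    or <- oracle_fk(q, geo)
    expect_equal(fk$hand$center, unname(or$hand), tolerance = 1e-10)
    expect_equal(fk$hand$axis, unname(or$axis), tolerance = 1e-10)
    expect_equal(fk$frames$elbow, unname(or$elbow), tolerance = 1e-10)
  }
})

test_that("FK preserves segment lengths and the reach triangle inequality", {
  set.seed(11)
  for (i in 1:200) {
    fk <- forward_kinematics(random_posture(), geo, check_limits = FALSE)
    expect_equal(sqrt(sum((fk$frames$elbow - fk$frames$shoulder)^2)),
                 unname(geo$lengths[["upper"]]), tolerance = 1e-12)
    expect_equal(sqrt(sum((fk$frames$wrist - fk$frames$elbow)^2)),
                 unname(geo$lengths[["fore"]]), tolerance = 1e-12)
    expect_equal(sqrt(sum((fk$frames$hand_center - fk$frames$wrist)^2)),
                 unname(geo$lengths[["hand"]]), tolerance = 1e-12)
    expect_lte(sqrt(sum(fk$hand$center^2)), geo$reach + 1e-12)
  }
})

test_that("angle extraction inverts FK on the declared branch", {
  expect_equal(angles_from_segment_orientations(
    list(upper = diag(3), fore = diag(3), hand = diag(3))),
    joint_posture(), tolerance = 1e-12)
  q0 <- joint_posture(10, 20, -15, 45, 30, 5, -10)
  expect_equal(angles_from_segment_orientations(
    forward_kinematics(q0, geo)), q0, tolerance = 1e-6)
  set.seed(7)
  maxerr <- 0
  for (i in 1:1000) {
    q <- random_posture()
    q2 <- angles_from_segment_orientations(forward_kinematics(
      q, geo, check_limits = FALSE))
    maxerr <- max(maxerr, max(abs(q2 - q)))
  }
  expect_lt(maxerr, 1e-6)
})

test_that("gimbal-singular orientations resolve by the documented
          tie-break", {
  # at |sh_abd| = 90 the axial freedom folds into flexion; the extracted
  # posture has hum_rot = 0, |sh_abd| <= 90, and reproduces the frames
  q <- joint_posture(sh_flex = 20, sh_abd = 90, hum_rot = 30, el_flex = 40)
  fr <- forward_kinematics(q, geo)$frames
  qe <- angles_from_segment_orientations(fr)
  expect_equal(unname(qe["hum_rot"]), 0)
  expect_lte(abs(qe["sh_abd"]), 90)
  fr2 <- forward_kinematics(qe, geo, check_limits = FALSE)$frames
  expect_equal(fr2$upper, fr$upper, tolerance = 1e-9)
  expect_equal(fr2$hand, fr$hand, tolerance = 1e-9)
})

test_that("axis_from_tilt spans the frontal plane with the declared sign", {
  expect_equal(axis_from_tilt(0), c(0, 0, 1))
  expect_equal(axis_from_tilt(90), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(axis_from_tilt(22.5),
               c(0, sin(22.5 * pi / 180), cos(22.5 * pi / 180)),
               tolerance = 1e-12)
})

test_that("posture limit violations name the offending DoF", {
  expect_error(forward_kinematics(joint_posture(el_flex = 170), geo),
               "el_flex")
})

test_that("IK returns the attractor at its own FK image and flags
          unreachable goals", {
  goal <- forward_kinematics(comfort, geo)$hand
  r <- solve_ik(goal, geo, init = comfort)
  expect_true(r$converged)
  expect_equal(r$posture, comfort, tolerance = 1e-9)
  far <- hand_pose(geo$shoulder_home + c(geo$reach * 1.01, 0, 0),
                   c(0, 0, 1))
  expect_false(solve_ik(far, geo, init = comfort)$reachable)
})

test_that("FK o IK closure holds on random reachable goals", {
  set.seed(3)
  for (i in 1:60) {
    goal <- random_reachable_goal()
    r <- solve_ik(goal, geo, init = comfort, attractor = comfort)
    expect_true(r$converged)
    fk <- forward_kinematics(r$posture, geo)
    expect_lte(sqrt(sum((fk$hand$center - goal$center)^2)), 0.001 + 1e-9)
    expect_lte(axis_angle_deg(fk$hand$axis, goal$axis), 0.5 + 1e-9)
  }
})

test_that("IK is deterministic: identical inputs give identical postures", {
  goal <- hand_pose(c(0.28, 0.05, 0.1), axis_from_tilt(22.5))
  r1 <- solve_ik(goal, geo, init = comfort, tilt_hint = 22.5)
  r2 <- solve_ik(goal, geo, init = comfort, tilt_hint = 22.5)
  expect_identical(r1$posture, r2$posture)
})
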