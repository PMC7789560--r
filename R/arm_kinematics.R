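# Seven-DoF arm kinematic model: three rigid segments (upper arm, forearm,
# hand) linked by ideal rotational joints. Three DoFs at the shoulder
# (flexion-extension, abduction-adduction, humeral axial rotation), elbow
# flexion-extension, forearm pronation-supination, and two wrist DoFs
# (radial-ulnar deviation, flexion-extension).
#
# World frame: right-handed, x anterior, y left, z up; the subject faces +x.
# In the neutral posture (all angles 0) every segment frame equals the world
# frame, each segment extends along its local -z, and the hand grasp axis is
# the hand-frame +z (world-vertical at neutral).
#
# Rotation conventions (intrinsic, right-multiplied; angles in degrees):
#   R_upper = Ry(-sh_flex) %*% Rx(-sh_abd) %*% Rz(hum_rot)
#   R_fore  = R_upper %*% Ry(-el_flex) %*% Rz(for_sup)
#   R_hand  = R_fore  %*% Ry(-wr_ext)  %*% Rx(-wr_dev)
# Signs are chosen so that positive flexion carries the limb anteriorly (+x)
# and positive abduction carries the (right) arm away from the trunk (-y).
# The Euler singularity of the shoulder triplet sits at |sh_abd| = 90 deg.

DOF_NAMES <- c("sh_flex", "sh_abd", "hum_rot", "el_flex", "for_sup",
               "wr_dev", "wr_ext")

#' Default anatomical joint limits
#'
#' Standard anatomical ranges of motion for the seven modelled DoFs, in
#' degrees. Rows are named after the DoFs, columns are `lower` and `upper`.
#'
#' @return A 7 x 2 numeric matrix of limits in degrees.
#' @export
default_joint_limits <- function() {
  m <- matrix(c(-60, 170,   # sh_flex
                -30, 120,   # sh_abd
                -90,  90,   # hum_rot
                  0, 150,   # el_flex
                -85,  85,   # for_sup
                -30,  20,   # wr_dev
                -70,  70),  # wr_ext
              ncol = 2, byrow = TRUE,
              dimnames = list(DOF_NAMES, c("lower", "upper")))
  m
}

#' Arm geometry
#'
#' Segment lengths of the three-segment arm model and the resting position of
#' the shoulder center in the world frame.
#'
#' @param upper_arm_length Upper-arm (shoulder-to-elbow) length in metres.
#' @param forearm_length Forearm (elbow-to-wrist) length in metres.
#' @param hand_length Wrist-to-hand-center offset in metres.
#' @param shoulder_home 3-vector, shoulder-center position (m) with the trunk
#'   at rest.
#' @param limits 7 x 2 matrix of joint limits in degrees
#'   (see [default_joint_limits()]).
#' @return An object of class `arm_geometry`.
#' @export
arm_geometry <- function(upper_arm_length = 0.30, forearm_length = 0.25,
                         hand_length = 0.08, shoulder_home = c(0, 0, 0),
                         limits = default_joint_limits()) {
  lengths <- c(upper = upper_arm_length, fore = forearm_length,
               hand = hand_length)
  if (any(lengths <= 0)) stop("all segment lengths must be strictly positive")
  stopifnot(length(shoulder_home) == 3, is.matrix(limits),
            nrow(limits) == 7, ncol(limits) == 2)
  structure(list(lengths = lengths,
                 reach = sum(lengths),
                 shoulder_home = as.numeric(shoulder_home),
                 limits = limits),
            class = "arm_geometry")
}

#' Construct a joint posture
#'
#' A posture is a named numeric vector of the seven joint angles in degrees:
#' `sh_flex`, `sh_abd`, `hum_rot`, `el_flex`, `for_sup`, `wr_dev`, `wr_ext`.
#'
#' @param sh_flex,sh_abd,hum_rot Shoulder flexion, abduction and humeral
#'   axial rotation (degrees).
#' @param el_flex Elbow flexion (degrees).
#' @param for_sup Forearm supination (degrees).
#' @param wr_dev,wr_ext Wrist radial-ulnar deviation and extension (degrees).
#' @return Named numeric vector of length 7.
#' @export
joint_posture <- function(sh_flex = 0, sh_abd = 0, hum_rot = 0, el_flex = 0,
                          for_sup = 0, wr_dev = 0, wr_ext = 0) {
  c(sh_flex = sh_flex, sh_abd = sh_abd, hum_rot = hum_rot, el_flex = el_flex,
    for_sup = for_sup, wr_dev = wr_dev, wr_ext = wr_ext)
}

as_posture <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 7) stop("a posture has exactly 7 joint angles")
  names(q) <- DOF_NAMES
  q
}

check_joint_limits <- function(posture, geometry, tol = 1e-9) {
  q <- as_posture(posture)
  lim <- geometry$limits
  bad <- which(q < lim[, "lower"] - tol | q > lim[, "upper"] + tol)
  if (length(bad)) {
    stop(sprintf("joint limit violated for %s (value %.2f deg, limits [%g, %g])",
                 DOF_NAMES[bad[1]], q[bad[1]],
                 lim[bad[1], "lower"], lim[bad[1], "upper"]))
  }
  invisible(q)
}

clamp_to_limits <- function(posture, geometry) {
  q <- as_posture(posture)
  pmin(pmax(q, geometry$limits[, "lower"]), geometry$limits[, "upper"])
}

# elementary rotation matrices, angle in radians
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

segment_rotations <- function(posture) {
  q <- deg2rad(as_posture(posture))
  R_upper <- rot_y(-q[["sh_flex"]]) %*% rot_x(-q[["sh_abd"]]) %*%
    rot_z(q[["hum_rot"]])
  R_fore <- R_upper %*% rot_y(-q[["el_flex"]]) %*% rot_z(q[["for_sup"]])
  R_hand <- R_fore %*% rot_y(-q[["wr_ext"]]) %*% rot_x(-q[["wr_dev"]])
  list(upper = R_upper, fore = R_fore, hand = R_hand)
}

#' Forward kinematics
#'
#' Maps a joint posture to the segment frames and the 6-D hand pose (hand
#' center plus unit grasp axis).
#'
#' @param posture Joint posture (degrees), see [joint_posture()].
#' @param geometry An [arm_geometry()].
#' @param shoulder_position 3-vector, current shoulder-center position (m);
#'   defaults to the geometry's home position.
#' @param check_limits Check the posture against the joint limits
#'   (default `TRUE`).
#' @return A list with `frames` (rotations `upper`, `fore`, `hand` and
#'   positions `shoulder`, `elbow`, `wrist`, `hand_center`) and `hand` (a
#'   hand pose: `center`, unit `axis`).
#' @export
forward_kinematics <- function(posture, geometry,
                               shoulder_position = geometry$shoulder_home,
                               check_limits = TRUE) {
  if (check_limits) check_joint_limits(posture, geometry)
  R <- segment_rotations(posture)
  down <- c(0, 0, -1)
  sh <- as.numeric(shoulder_position)
  elbow <- sh + geometry$lengths[["upper"]] * as.numeric(R$upper %*% down)
  wrist <- elbow + geometry$lengths[["fore"]] * as.numeric(R$fore %*% down)
  hand <- wrist + geometry$lengths[["hand"]] * as.numeric(R$hand %*% down)
  axis <- as.numeric(R$hand[, 3])
  list(frames = list(upper = R$upper, fore = R$fore, hand = R$hand,
                     shoulder = sh, elbow = elbow, wrist = wrist,
                     hand_center = hand),
       hand = hand_pose(hand, axis))
}

#' Construct a hand pose
#'
#' @param center 3-vector hand-center position (m).
#' @param axis 3-vector grasp axis; normalised to unit length.
#' @return A list of class `hand_pose` with `center` and unit `axis`.
#' @export
hand_pose <- function(center, axis) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("hand axis must be non-zero")
  structure(list(center = as.numeric(center), axis = as.numeric(axis) / n),
            class = "hand_pose")
}

# wrap to (-180, 180]
wrap_deg <- function(a) ((a + 180) %% 360) - 180

#' Joint angles from segment orientations
#'
#' Inverts the forward-kinematic orientation map: recovers the seven joint
#' angles from the three segment rotation matrices under the package's Euler
#' conventions. At the shoulder gimbal singularity (|sh_abd| = 90 deg) the
#' decomposition is degenerate; the tie-break assigns the full axial freedom
#' to shoulder flexion and sets `hum_rot = 0`, keeping |sh_abd| <= 90 deg
#' (the anatomical branch).
#'
#' @param frames Segment frames as returned by [forward_kinematics()] (only
#'   the rotations `upper`, `fore`, `hand` are used).
#' @return A joint posture (named numeric, degrees).
#' @export
angles_from_segment_orientations <- function(frames) {
  if (is.list(frames) && !is.null(frames$frames)) frames <- frames$frames
  Ru <- frames$upper; Rf <- frames$fore; Rh <- frames$hand
  # shoulder triplet: Ru = Ry(a) Rx(b) Rz(g), a = -sh_flex, b = -sh_abd,
  # g = hum_rot
  cb <- sqrt(Ru[2, 1]^2 + Ru[2, 2]^2)
  if (cb > 1e-9) {
    b <- atan2(-Ru[2, 3], cb)
    g <- atan2(Ru[2, 1], Ru[2, 2])
    a <- atan2(Ru[1, 3], Ru[3, 3])
  } else {
    # gimbal: fold axial rotation into flexion, hum_rot := 0
    b <- if (Ru[2, 3] < 0) pi / 2 else -pi / 2
    g <- 0
    a <- atan2(-Ru[3, 1], Ru[1, 1])
  }
  # elbow/forearm: Ru' Rf = Ry(-el_flex) Rz(for_sup)
  M <- t(Ru) %*% Rf
  sup <- atan2(M[2, 1], M[2, 2])
  el <- -atan2(M[1, 3], M[3, 3])
  # wrist: Rf' Rh = Ry(-wr_ext) Rx(-wr_dev)
  W <- t(Rf) %*% Rh
  wdev <- -atan2(-W[2, 3], W[2, 2])
  wext <- -atan2(-W[3, 1], W[1, 1])
  as_posture(wrap_deg(rad2deg(c(-a, -b, g, el, sup, wdev, wext))))
}

#' Target axis from a frontal-plane tilt
#'
#' The target (bottle) axis is the world vertical rotated by `tilt` degrees
#' in the frontal (y-z) plane; positive tilts lean toward the subject's left
#' (counterclockwise as seen by the subject).
#'
#' @param tilt Tilt angle in degrees, in `[-90, 90]`.
#' @return Unit 3-vector.
#' @export
axis_from_tilt <- function(tilt) {
  stopifnot(tilt >= -90, tilt <= 90)
  t <- deg2rad(tilt)
  c(0, sin(t), cos(t))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# unsigned angle between axes in degrees (a bottle is symmetric under flip)
axis_angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

# Geometric Jacobian of the hand pose w.r.t. the 7 joint angles (radians).
# Rows 1:3 -> hand-center velocity, rows 4:6 -> grasp-axis velocity
# (omega x axis). Columns ordered as DOF_NAMES.
arm_jacobian <- function(posture, geometry,
                         shoulder_position = geometry$shoulder_home) {
  q <- deg2rad(as_posture(posture))
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  R1 <- rot_y(-q[["sh_flex"]])
  R2 <- R1 %*% rot_x(-q[["sh_abd"]])
  Ru <- R2 %*% rot_z(q[["hum_rot"]])
  R4 <- Ru %*% rot_y(-q[["el_flex"]])
  Rf <- R4 %*% rot_z(q[["for_sup"]])
  R6 <- Rf %*% rot_y(-q[["wr_ext"]])
  Rh <- R6 %*% rot_x(-q[["wr_dev"]])
  down <- c(0, 0, -1)
  sh <- as.numeric(shoulder_position)
  elbow <- sh + geometry$lengths[["upper"]] * as.numeric(Ru %*% down)
  wrist <- elbow + geometry$lengths[["fore"]] * as.numeric(Rf %*% down)
  hand <- wrist + geometry$lengths[["hand"]] * as.numeric(Rh %*% down)
  axis <- as.numeric(Rh[, 3])
  axes <- list(-ey,                       # sh_flex
               as.numeric(R1 %*% (-ex)),  # sh_abd
               as.numeric(R2 %*% ez),     # hum_rot
               as.numeric(Ru %*% (-ey)),  # el_flex
               as.numeric(R4 %*% ez),     # for_sup
               as.numeric(R6 %*% (-ex)),  # wr_dev
               as.numeric(Rf %*% (-ey)))  # wr_ext
  centers <- list(sh, sh, sh, elbow, elbow, wrist, wrist)
  J <- matrix(0, 6, 7, dimnames = list(NULL, DOF_NAMES))
  for (i in 1:7) {
    w <- axes[[i]]
    J[1:3, i] <- cross3(w, hand - centers[[i]])
    J[4:6, i] <- cross3(w, axis)
  }
  list(J = J, hand = hand, axis = axis)
}
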