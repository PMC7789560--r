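# Synthetic subject: generates naturalistic full-arm reaching recordings
# (standing in for the human acquisition and baseline phases) and a
# closed-loop compensating user model for the hybrid-control test phases.
#
# Redundancy injection: the subject resolves each reach toward an attractor
# posture (its comfort posture plus a target-dependent bias). The
# context_coupling knob reallocates how the target's frontal-plane tilt is
# resolved: at 0 the tilt is absorbed by a fixed humeral-rotation
# coordination (visible in the shoulder angles a predictor receives), at 1
# by smooth tilt- and position-dependent biases of the four distal joints
# (invisible to a shoulder-only predictor). This is what makes target
# context informative for distal-joint prediction.

#' Synthetic subject parameters
#'
#' @param comfort_posture Posture (deg) toward which redundancy is resolved.
#' @param posture_cost_weights Positive 7-vector weighting the posture cost.
#' @param motor_noise_sd SD (deg) of per-sample joint angle noise before
#'   low-pass filtering (2nd-order Butterworth, 5 Hz).
#' @param movement_speed_gain Movement duration per unit hand travel (s/m).
#' @param context_coupling In `[0, 1]`: strength of target-dependent distal
#'   redundancy resolution.
#' @param trunk_gain Trunk translation rate (m per unit normalised residual
#'   per sample) of the compensating user model.
#' @param sway_sd SD (m) of the slow natural shoulder-center sway
#'   (scapular/postural motion present in all phases).
#' @param seed Integer seed namespacing this subject's random streams.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(comfort_posture = joint_posture(25, 15, 0, 60,
                                                           0, 0, 0),
                           posture_cost_weights = rep(1, 7),
                           motor_noise_sd = 1.0,
                           movement_speed_gain = 2.8,
                           context_coupling = 1.0,
                           trunk_gain = 0.0008,
                           sway_sd = 0.0075,
                           seed = 1L) {
  stopifnot(motor_noise_sd >= 0, context_coupling >= 0, context_coupling <= 1)
  structure(list(comfort_posture = as_posture(comfort_posture),
                 posture_cost_weights = posture_cost_weights,
                 motor_noise_sd = motor_noise_sd,
                 movement_speed_gain = movement_speed_gain,
                 context_coupling = context_coupling,
                 trunk_gain = trunk_gain,
                 sway_sd = sway_sd,
                 seed = as.integer(seed)),
            class = "subject_params")
}

#' Context-dependent distal attractor bias
#'
#' Smooth deterministic bias (deg) of the redundancy-resolution attractor as
#' a function of the target's tilt and its position within the grid, scaled
#' by `context_coupling`. At coupling 0 the bias is identically zero for the
#' four distal DoFs and the tilt is instead coordinated proximally through
#' humeral rotation; at coupling 1 the proximal coordination vanishes and
#' the distal bias reaches up to ~15 deg.
#'
#' @param target Target (list with `x`, `y`, `z`, `tilt`).
#' @param subject A [subject_params()].
#' @param grid_center 3-vector, center of the target grid (m).
#' @return Named 7-vector of attractor offsets in degrees.
#' @export
distal_bias <- function(target, subject, grid_center) {
  cc <- subject$context_coupling
  u <- target$tilt / 45
  p <- (target_position(target) - grid_center) / 0.20
  b <- joint_posture()
  b["hum_rot"] <- (1 - cc) * 25 * u
  b["el_flex"] <- cc * (5 * u + 5 * p[1])
  b["for_sup"] <- cc * (12 * u + 3 * p[2])
  b["wr_dev"] <- cc * (-4 * u + 3 * p[3])
  b["wr_ext"] <- cc * (6 * u - 4 * p[2])
  b
}

reach_attractor <- function(target, subject, geometry, grid_center) {
  clamp_to_limits(subject$comfort_posture +
                    distal_bias(target, subject, grid_center), geometry)
}

# goal posture for a natural reach: IK toward the target pose with the
# context-biased attractor resolving the redundancy. Canonical init (the
# attractor itself) keeps the resolution target-dependent but
# trajectory-independent.
natural_goal_posture <- function(target, subject, geometry, grid_center,
                                 shoulder_position = geometry$shoulder_home) {
  attr <- reach_attractor(target, subject, geometry, grid_center)
  goal <- hand_pose(target_position(target), axis_from_tilt(target$tilt))
  ik <- solve_ik(goal, geometry, shoulder_position, init = attr,
                 attractor = attr, weights = subject$posture_cost_weights,
                 tilt_hint = target$tilt)
  if (!ik$reachable) stop("target beyond reach radius")
  ik$posture
}

# minimum-jerk time scaling s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5
min_jerk_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# second-order low-pass (Butterworth, cutoff_hz) applied forward-backward;
# used to smooth white motor noise into plausible jitter
lowpass_noise <- function(n, ncol, sd, rate = SAMPLE_RATE_HZ,
                          cutoff_hz = 5) {
  if (sd <= 0 || n == 0) return(matrix(0, n, ncol))
  raw <- matrix(stats::rnorm(n * ncol, 0, sd), n, ncol)
  if (n < 24) return(raw)  # too short to filter stably
  bf <- signal::butter(2, cutoff_hz / (rate / 2))
  apply(raw, 2, function(col) signal::filtfilt(bf, col))
}

# slow AR(1) shoulder sway; state carries across trials within a phase
sway_step <- function(state, subject, n, rate = SAMPLE_RATE_HZ) {
  rho <- exp(-1 / (rate * 2))   # ~2 s time constant
  sd_innov <- subject$sway_sd * sqrt(1 - rho^2)
  out <- matrix(0, n, 3)
  x <- state
  for (i in seq_len(n)) {
    x <- rho * x + stats::rnorm(3, 0, sd_innov)
    out[i, ] <- x
  }
  list(sway = out, state = x)
}

#' Generate a natural reach trajectory
#'
#' Minimum-jerk joint-space interpolation from `start` to the IK goal
#' posture for `target` (redundancy resolved toward the context-biased
#' attractor), followed by a terminal dwell, with low-pass-filtered Gaussian
#' motor noise added to all joints. The shoulder center drifts with the
#' subject's natural sway.
#'
#' @param start Starting posture (deg).
#' @param target Target (list with `x`, `y`, `z`, `tilt`).
#' @param subject A [subject_params()].
#' @param geometry An [arm_geometry()].
#' @param grid_center 3-vector, grid center (m).
#' @param dwell_s Terminal dwell duration (s).
#' @param sway_state Carried AR(1) sway state (3-vector).
#' @return List: `q` (n x 7 posture matrix, deg), `shoulder` (n x 3, m),
#'   `goal_posture`, `duration_s`, `sway_state`.
#' @export
natural_reach <- function(start, target, subject, geometry = arm_geometry(),
                          grid_center = NULL, dwell_s = 1.3,
                          sway_state = c(0, 0, 0)) {
  if (is.null(grid_center)) {
    gc_ <- build_target_grid(geometry)
    grid_center <- c(mean(gc_$x), mean(gc_$y), mean(gc_$z))
  }
  goal_q <- natural_goal_posture(target, subject, geometry, grid_center)
  start <- as_posture(start)
  f0 <- forward_kinematics(start, geometry, check_limits = FALSE)
  dist <- sqrt(sum((f0$hand$center - target_position(target))^2))
  duration <- max(0.4, subject$movement_speed_gain * dist)
  n_move <- max(2L, as.integer(round(duration * SAMPLE_RATE_HZ)))
  n_dwell <- as.integer(round(dwell_s * SAMPLE_RATE_HZ))
  n <- n_move + n_dwell
  s <- c(min_jerk_s(seq_len(n_move) / n_move), rep(1, n_dwell))
  q <- outer(rep(1, n), start) + outer(s, goal_q - start)
  q <- q + lowpass_noise(n, 7, subject$motor_noise_sd)
  colnames(q) <- DOF_NAMES
  for (j in 1:7) {
    q[, j] <- pmin(pmax(q[, j], geometry$limits[j, 1]),
                   geometry$limits[j, 2])
  }
  sw <- sway_step(sway_state, subject, n)
  shoulder <- outer(rep(1, n), geometry$shoulder_home) + sw$sway
  list(q = q, shoulder = shoulder, goal_posture = goal_q,
       duration_s = duration, sway_state = sw$state)
}

# batch FK: hand centers and axes for a posture matrix + shoulder matrix
fk_batch <- function(q, shoulder, geometry) {
  n <- nrow(q)
  centers <- matrix(0, n, 3)
  axes <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    f <- forward_kinematics(q[i, ], geometry, shoulder[i, ],
                            check_limits = FALSE)
    centers[i, ] <- f$hand$center
    axes[i, ] <- f$hand$axis
  }
  list(centers = centers, axes = axes)
}

empty_recording_rows <- function() {
  as.data.frame(matrix(numeric(0), 0, 12,
                       dimnames = list(NULL, c("t", "trial_id", DOF_NAMES,
                                               "shx", "shy", "shz"))))
}

make_recording <- function(rows, trials, phase, subject_id = 1L,
                           rate = SAMPLE_RATE_HZ) {
  structure(list(data = rows, trials = trials, phase = phase,
                 subject_id = subject_id, rate = rate),
            class = "motion_recording")
}

#' Simulate a natural-control phase
#'
#' Runs the trial lifecycle over chained natural reaches (each trial starts
#' from the hand's location at the end of the previous one; the arm is
#' never reset). Used for the acquisition phase (whole-set order, strict
#' tolerance) and the baseline phase (subset order, test tolerance).
#'
#' @param order A [generate_target_order()] result.
#' @param tol A [tolerance()].
#' @param subject A [subject_params()].
#' @param geometry An [arm_geometry()].
#' @param phase Phase label stored in the recording.
#' @param seed Integer seed for this phase's random streams.
#' @return A `motion_recording`: `data` (per-sample rows with `t`,
#'   `trial_id`, seven angles, shoulder position, `in_zone`), `trials`
#'   (per-trial targets and outcomes), `phase`.
#' @export
simulate_phase_natural <- function(order, tol, subject,
                                   geometry = arm_geometry(),
                                   phase = "acquisition",
                                   seed = subject$seed) {
  set.seed(seed)
  grid <- build_target_grid(geometry)
  grid_center <- c(mean(grid$x), mean(grid$y), mean(grid$z))
  tg <- order$sequence
  cur_q <- subject$comfort_posture
  sway_state <- c(0, 0, 0)
  t_offset <- 0
  rows <- vector("list", nrow(tg))
  trials <- vector("list", nrow(tg))
  for (k in seq_len(nrow(tg))) {
    target <- target_row(tg, k)
    tr <- natural_reach(cur_q, target, subject, geometry, grid_center,
                        sway_state = sway_state)
    fk <- fk_batch(tr$q, tr$shoulder, geometry)
    z <- in_target_zone_vec(fk$centers, fk$axes, target, tol)
    life <- trial_from_inzone(z)
    n_keep <- life$end_idx
    idx <- seq_len(n_keep)
    rows[[k]] <- data.frame(
      t = t_offset + (idx - 1) / SAMPLE_RATE_HZ,
      trial_id = k,
      tr$q[idx, , drop = FALSE],
      shx = tr$shoulder[idx, 1], shy = tr$shoulder[idx, 2],
      shz = tr$shoulder[idx, 3],
      in_zone = z[idx])
    trials[[k]] <- data.frame(
      trial_id = k, role = target$role,
      col = target$col, row = target$row, depth = target$depth,
      x = target$x, y = target$y, z = target$z, tilt = target$tilt,
      success = life$success, zone_entered = life$zone_entered,
      approach_time = if (life$zone_entered)
        (life$first_in - 1) / SAMPLE_RATE_HZ else NA_real_,
      end_time = (n_keep - 1) / SAMPLE_RATE_HZ,
      start_dist = sqrt(sum((fk$centers[1, ] -
                               target_position(target))^2)),
      hold_start = life$hold_start, hold_end = life$hold_end)
    cur_q <- as_posture(tr$q[n_keep, ])
    sway_state <- tr$sway_state
    t_offset <- t_offset + n_keep / SAMPLE_RATE_HZ
  }
  make_recording(do.call(rbind, rows), do.call(rbind, trials), phase)
}
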