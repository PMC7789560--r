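# Closed-loop hybrid control: the virtual shoulder follows the synthetic
# subject's commanded shoulder angles while the four distal joints follow
# the predictor. The user model steers its three shoulder angles by damped
# least-squares steps on the 6-D hand-pose error computed through the
# composite map FK o [shoulder -> (shoulder, predict(shoulder[, context]))],
# and recruits compensatory trunk translation only when shoulder-only
# progress has plateaued (the seated subject keeps the trunk against the
# backrest unless the task demands otherwise).

# user-model constants, calibrated once against the study's phenomenology
# (natural control fastest, hybrid C+ intermediate, hybrid C- slowest and
# trunk-compensating) and frozen
USER_GAIN <- 0.06       # damped gradient step per sample
USER_REACT_S <- 0.25    # reaction latency at each trial start (s)
USER_STEP_CAP_DEG <- 1.2  # max shoulder step per sample
TRUNK_BOUND <- 0.12     # max trunk excursion (m), seated subject

#' Initial state of the compensating user model
#'
#' @param shoulder Commanded shoulder angles (deg, 3).
#' @return A list of class `user_state`: commanded `shoulder` angles,
#'   `trunk` offset (m), `best_score` memory, `frozen` flag, `score0`.
#' @export
user_state <- function(shoulder = c(25, 15, 0)) {
  structure(list(shoulder = as.numeric(shoulder), trunk = c(0, 0, 0),
                 best_hist = numeric(0), frozen = FALSE,
                 score0 = NA_real_),
            class = "user_state")
}

# task error of a displayed posture against a target; score combines
# position (m) and axis error (rad, scaled) like the IK
hybrid_task_error <- function(jac, target) {
  g <- axis_from_tilt(target$tilt)
  if (sum(g * jac$axis) < 0) g <- -g
  e_pos <- target_position(target) - jac$hand
  ca <- pmin(1, pmax(-1, sum(jac$axis * g)))
  e_axis <- g - ca * jac$axis
  list(e = c(e_pos, AXIS_ERR_SCALE * e_axis),
       pos_err = sqrt(sum(e_pos^2)),
       axis_err = rad2deg(acos(ca)),
       score = sqrt(sum(e_pos^2)) + AXIS_ERR_SCALE * acos(ca))
}

#' One 90 Hz step of the hybrid-control loop
#'
#' Computes the displayed posture (commanded shoulder + predicted distal
#' angles), then updates the user state: a damped gradient step of the
#' shoulder command on the composite hand-pose error, trunk translation at
#' rate `subject$trunk_gain` when progress has plateaued (error improvement
#' below 1% over the last 0.5 s) while outside the zone, and a divergence
#' guard freezing the trunk if the error grows tenfold from trial start.
#'
#' @param state A [user_state()].
#' @param model An `mlp_model` (or a function mapping the input row to 4
#'   distal angles, for stubs).
#' @param target Target (list with `x`, `y`, `z`, `tilt`).
#' @param subject A [subject_params()].
#' @param geometry An [arm_geometry()].
#' @param sway Natural shoulder sway offset this sample (m, 3).
#' @param tol A [tolerance()] (used for residual normalisation and the
#'   plateau gate).
#' @param jac_cache Optional cached composite Jacobian (recomputed when
#'   `NULL`).
#' @param react When `FALSE` (the user's reaction latency at trial start),
#'   the displayed posture and error are computed but the command is not
#'   updated.
#' @return List: `state` (updated), `displayed` posture (7), `shoulder_pos`
#'   (m), `pos_err`, `axis_err`, `in_zone`, `jac_cache`.
#' @export
hybrid_step <- function(state, model, target, subject,
                        geometry = arm_geometry(), sway = c(0, 0, 0),
                        tol = tolerance_test(), jac_cache = NULL,
                        react = TRUE) {
  shoulder_pos <- geometry$shoulder_home + sway + state$trunk
  qs <- state$shoulder
  input <- if (is.function(model)) NULL else if (model$net$dims[1] == 7) {
    c(qs, make_context(shoulder_pos, target))
  } else qs
  distal <- if (is.function(model)) model(qs, shoulder_pos, target) else
    as.numeric(predict(model, input))
  displayed <- clamp_to_limits(as_posture(c(qs, distal)), geometry)
  jac <- arm_jacobian(displayed, geometry, shoulder_pos)
  err <- hybrid_task_error(jac, target)
  in_zone <- err$pos_err <= tol$spatial && err$axis_err <= tol$angular
  if (is.na(state$score0)) state$score0 <- err$score
  # composite Jacobian w.r.t. the 3 commanded shoulder angles
  if (is.null(jac_cache)) {
    Jp <- if (is.function(model)) matrix(0, 4, 3) else
      predict_jacobian(model, input)[, 1:3, drop = FALSE]
    Jc <- jac$J[, 1:3, drop = FALSE] +
      jac$J[, 4:7, drop = FALSE] %*% Jp
    Jc[4:6, ] <- AXIS_ERR_SCALE * Jc[4:6, ]
    jac_cache <- Jc
  }
  if (!react) {
    return(list(state = state, displayed = displayed,
                shoulder_pos = shoulder_pos, pos_err = err$pos_err,
                axis_err = err$axis_err, in_zone = in_zone,
                jac_cache = jac_cache))
  }
  Jc <- jac_cache
  dqs <- as.numeric(t(Jc) %*% solve(Jc %*% t(Jc) + diag(0.05^2, 6)) %*%
                      err$e)
  dqs <- pmin(pmax(USER_GAIN * dqs, -deg2rad(USER_STEP_CAP_DEG)), deg2rad(USER_STEP_CAP_DEG))
  lim <- geometry$limits[SHOULDER_DOFS, , drop = FALSE]
  state$shoulder <- pmin(pmax(qs + rad2deg(dqs), lim[, 1]), lim[, 2])
  # plateau detection over the last 0.5 s (45 samples)
  state$best_hist <- c(state$best_hist, err$score)
  nh <- length(state$best_hist)
  plateau <- FALSE
  if (nh > 45) {
    state$best_hist <- state$best_hist[(nh - 45):nh]
    prev <- min(state$best_hist[1:23])
    now <- min(state$best_hist)
    plateau <- (prev - now) < 0.01 * prev
  }
  if (err$score > 10 * state$score0) state$frozen <- TRUE
  if (plateau && !in_zone && !state$frozen && err$pos_err > 1e-6) {
    resid <- min(err$pos_err / tol$spatial, 5)
    step_tr <- subject$trunk_gain * resid *
      (target_position(target) - jac$hand) / err$pos_err
    tr <- state$trunk + step_tr
    trn <- sqrt(sum(tr^2))
    if (trn > TRUNK_BOUND) tr <- tr * (TRUNK_BOUND / trn)
    state$trunk <- tr
  }
  list(state = state, displayed = displayed, shoulder_pos = shoulder_pos,
       pos_err = err$pos_err, axis_err = err$axis_err, in_zone = in_zone,
       jac_cache = jac_cache)
}

#' Simulate a hybrid-control test phase
#'
#' Runs the closed-loop user model against a predictor over a target order
#' with the test tolerance, recording both the displayed stream and the
#' parallel mimicked stream (the distal trajectory natural control would
#' have produced for the same targets, sharing the commanded shoulder
#' angles sample by sample).
#'
#' @param order A [generate_target_order()] result.
#' @param model An `mlp_model` (or stub function).
#' @param tol A [tolerance()] (test value: 4 cm, 10 deg).
#' @param subject A [subject_params()].
#' @param geometry An [arm_geometry()].
#' @param phase Phase label (`"testC+"` or `"testC-"`).
#' @param seed Integer seed for this phase's random streams.
#' @param hold_s,timeout_s Trial lifecycle parameters (s).
#' @return A `motion_recording` whose `data` carries the displayed angles
#'   plus mimicked distal columns `m_el_flex`, `m_for_sup`, `m_wr_dev`,
#'   `m_wr_ext`.
#' @export
simulate_phase_hybrid <- function(order, model, tol = tolerance_test(),
                                  subject = subject_params(),
                                  geometry = arm_geometry(),
                                  phase = "testC+", seed = subject$seed,
                                  hold_s = 1.0, timeout_s = 15.0) {
  set.seed(seed)
  grid <- build_target_grid(geometry)
  grid_center <- c(mean(grid$x), mean(grid$y), mean(grid$z))
  tg <- order$sequence
  n_hold <- as.integer(round(hold_s * SAMPLE_RATE_HZ)) + 1L
  n_max <- as.integer(round(timeout_s * SAMPLE_RATE_HZ)) + 1L
  state <- user_state(subject$comfort_posture[SHOULDER_DOFS])
  m_distal <- subject$comfort_posture[DISTAL_DOFS]
  sway_state <- c(0, 0, 0)
  noise_state <- c(0, 0, 0)
  rho_noise <- exp(-1 / (SAMPLE_RATE_HZ * 0.2))
  t_offset <- 0
  rows <- vector("list", nrow(tg))
  trials <- vector("list", nrow(tg))
  for (k in seq_len(nrow(tg))) {
    target <- target_row(tg, k)
    goal_q <- natural_goal_posture(target, subject, geometry, grid_center)
    # mimicked natural distal time course for this trial
    f0 <- forward_kinematics(as_posture(c(state$shoulder, m_distal)),
                             geometry, check_limits = FALSE)
    dist0 <- sqrt(sum((f0$hand$center - target_position(target))^2))
    dur <- max(0.4, subject$movement_speed_gain * dist0)
    n_move <- max(2L, as.integer(round(dur * SAMPLE_RATE_HZ)))
    state$best_hist <- numeric(0); state$frozen <- FALSE
    state$score0 <- NA_real_
    buf_q <- matrix(0, n_max, 7)
    buf_m <- matrix(0, n_max, 4)
    buf_sh <- matrix(0, n_max, 3)
    buf_z <- logical(n_max)
    run <- 0L; first_in <- NA_integer_; n_used <- n_max
    jc <- NULL
    m_start <- m_distal
    for (i in seq_len(n_max)) {
      sw <- sway_step(sway_state, subject, 1)
      sway_state <- sw$state
      noise_prev <- noise_state
      noise_state <- rho_noise * noise_state +
        stats::rnorm(3, 0, subject$motor_noise_sd * 0.3 *
                       sqrt(1 - rho_noise^2))
      if (i %% 5 == 1) jc <- NULL
      st <- hybrid_step(state, model, target, subject, geometry,
                        sw$sway[1, ], tol, jac_cache = jc,
                        react = i > USER_REACT_S * SAMPLE_RATE_HZ)
      jc <- st$jac_cache
      state <- st$state
      # smoothed motor jitter rides on the commanded shoulder angles
      state$shoulder <- state$shoulder + (noise_state - noise_prev)
      s_mj <- min_jerk_s(min(i, n_move) / n_move)
      m_distal <- m_start + s_mj * (goal_q[DISTAL_DOFS] - m_start)
      buf_q[i, ] <- st$displayed
      buf_m[i, ] <- m_distal
      buf_sh[i, ] <- st$shoulder_pos
      buf_z[i] <- st$in_zone
      if (st$in_zone) {
        if (is.na(first_in)) first_in <- i
        run <- run + 1L
        if (run >= n_hold) { n_used <- i; break }
      } else run <- 0L
    }
    idx <- seq_len(n_used)
    life <- trial_from_inzone(buf_z[idx], hold_s = hold_s,
                              timeout_s = timeout_s)
    colnames(buf_q) <- DOF_NAMES
    rows[[k]] <- data.frame(
      t = t_offset + (idx - 1) / SAMPLE_RATE_HZ,
      trial_id = k,
      buf_q[idx, , drop = FALSE],
      shx = buf_sh[idx, 1], shy = buf_sh[idx, 2], shz = buf_sh[idx, 3],
      in_zone = buf_z[idx],
      m_el_flex = buf_m[idx, 1], m_for_sup = buf_m[idx, 2],
      m_wr_dev = buf_m[idx, 3], m_wr_ext = buf_m[idx, 4])
    trials[[k]] <- data.frame(
      trial_id = k, role = target$role,
      col = target$col, row = target$row, depth = target$depth,
      x = target$x, y = target$y, z = target$z, tilt = target$tilt,
      success = life$success, zone_entered = life$zone_entered,
      approach_time = if (life$zone_entered)
        (life$first_in - 1) / SAMPLE_RATE_HZ else NA_real_,
      end_time = (n_used - 1) / SAMPLE_RATE_HZ,
      start_dist = dist0,
      hold_start = life$hold_start, hold_end = life$hold_end)
    m_distal <- buf_m[n_used, ]
    names(m_distal) <- DISTAL_DOFS
    t_offset <- t_offset + n_used / SAMPLE_RATE_HZ
  }
  make_recording(do.call(rbind, rows), do.call(rbind, trials), phase)
}
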