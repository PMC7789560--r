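# shared fixtures: default geometry, a comfort posture, random in-limit
# postures on the non-singular Euler branch, and a memoised scaled-down
# multi-subject experiment run reused by the directional tests.

geo <- arm_geometry()
comfort <- joint_posture(25, 15, 0, 60, 0, 0, 0)

# random posture within limits, restricted to |sh_abd| <= 85 deg (the
# declared extraction branch, away from the gimbal singularity)
random_posture <- function() {
  lim <- geo$limits
  lo <- lim[, 1]; hi <- lim[, 2]
  lo["sh_abd"] <- max(lo["sh_abd"], -85)
  hi["sh_abd"] <- min(hi["sh_abd"], 85)
  as_posture(stats::runif(7, lo, hi))
}

# a random reachable goal: the FK image of a posture drawn from a
# realistic reaching envelope (guaranteed feasible within the joint
# limits, spanning a wide anterior workspace)
REACH_ENVELOPE <- cbind(lower = c(0, -20, -60, 10, -80, -28, -65),
                        upper = c(110, 80, 60, 140, 80, 18, 65))
random_reachable_goal <- function() {
  q <- stats::runif(7, REACH_ENVELOPE[, 1], REACH_ENVELOPE[, 2])
  forward_kinematics(as_posture(q), geo, check_limits = FALSE)$hand
}

.directional_cache <- new.env(parent = emptyenv())

# scaled-down five-subject study run (context_coupling = 1); order minimums
# and epochs reduced from the study values to desk scale, memoised across
# test files
directional_run <- function() {
  if (is.null(.directional_cache$manifest)) {
    cfg <- experiment_config(
      n_subjects = 5, min_whole = 60, min_subset = 30,
      max_whole = 60, max_subset = 30,
      hyper = predictor_hyper(max_epochs = 30, patience = 8),
      context_coupling = 1.0, master_seed = 20260924L)
    .directional_cache$manifest <- run_experiment(cfg)
  }
  .directional_cache$manifest
}

# tiny single-subject natural recording (noise-free optional), memoised
small_natural_recording <- function(noise = TRUE) {
  key <- paste0("nat_", noise)
  if (is.null(.directional_cache[[key]])) {
    subj <- subject_params(motor_noise_sd = if (noise) 1 else 0,
                           seed = 42L)
    grid <- build_target_grid(geo)
    subset <- build_target_set(grid, "subset")
    ord <- generate_target_order(subset, 12, seed = 5L, max_length = 12)
    .directional_cache[[key]] <- simulate_phase_natural(
      ord, tolerance_acquisition(), subj, geo, phase = "acquisition",
      seed = 99L)
  }
  .directional_cache[[key]]
}
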