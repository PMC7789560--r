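# Online performance metrics: approach time and speed, shoulder-spread
# ellipsoid volume (SV), average reaching postures and their variability.

#' Approach speed of a trial
#'
#' Distance from the hand center at trial start to the target center,
#' divided by the approach time (time to first zone entry), in cm/s.
#' Defined only for trials where the zone was entered; the approach time is
#' floored at one sample period.
#'
#' @param start_dist Start-to-target distance (m).
#' @param approach_time Approach time (s).
#' @param rate Sampling rate (Hz).
#' @return Approach speed (cm/s).
#' @export
approach_speed <- function(start_dist, approach_time,
                           rate = SAMPLE_RATE_HZ) {
  if (is.na(approach_time)) return(NA_real_)
  at <- max(approach_time, 1 / rate)
  100 * start_dist / at
}

#' Shoulder-position spread volume (SV)
#'
#' Volume of the dispersion ellipsoid of the recorded shoulder positions:
#' the covariance matrix of the 3-D coordinates is eigendecomposed and the
#' ellipsoid semi-axes are set to three standard deviations along each
#' eigenvector, giving volume 36*pi*s1*s2*s3. For multivariate normal data
#' this ellipsoid contains ~97% of the positions. Invariant under rigid
#' rotation and translation of the cloud.
#'
#' @param positions n x 3 matrix of shoulder positions (m).
#' @return A list of class `sv_report`: `volume_cm3`, `volume_dm3`,
#'   `coverage` (fraction of samples inside the ellipsoid), `sd_axes` (m),
#'   `degenerate` flag.
#' @export
shoulder_spread_volume <- function(positions) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 positions")
  C <- stats::cov(positions)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  degenerate <- any(ev < 1e-12 * max(ev, 1e-30)) || all(ev == 0)
  sds <- sqrt(ev)
  vol_m3 <- if (degenerate) 0 else 36 * pi * prod(sds)
  ctr <- colMeans(positions)
  coverage <- if (degenerate) NA_real_ else {
    X <- sweep(positions, 2, ctr)
    # Mahalanobis distance in the eigenframe; inside iff <= 3 SD
    Y <- X %*% eg$vectors
    mean((Y[, 1] / sds[1])^2 + (Y[, 2] / sds[2])^2 +
           (Y[, 3] / sds[3])^2 <= 9)
  }
  structure(list(volume_cm3 = vol_m3 * 1e6, volume_dm3 = vol_m3 * 1e3,
                 coverage = coverage, sd_axes = sds,
                 degenerate = degenerate),
            class = "sv_report")
}

#' Average reaching postures over holding periods
#'
#' For each trial where the target zone was entered, averages the seven
#' joint angles over the last contiguous in-zone run (the one-second holding
#' period when the trial succeeded), yielding one posture per trial. For
#' hybrid recordings, `group` labels the displayed arm (`"C+"`/`"C-"`) and
#' the parallel mimicked stream can be extracted with `mimicked = TRUE`
#' (groups MC+/MC-), whose shoulder angles are identical to the displayed
#' ones by construction.
#'
#' @param recording A `motion_recording`.
#' @param group Group label stored with each posture.
#' @param mimicked Use the mimicked distal columns (`m_*`) instead of the
#'   displayed ones.
#' @return Data frame: `trial_id`, `group`, one column per DoF.
#' @export
average_reaching_postures <- function(recording, group,
                                      mimicked = FALSE) {
  d <- recording$data
  tr <- recording$trials
  cols <- DOF_NAMES
  if (mimicked) {
    mcols <- paste0("m_", DISTAL_DOFS)
    if (!all(mcols %in% names(d))) {
      stop("recording has no mimicked stream")
    }
    cols <- c(SHOULDER_DOFS, mcols)
  }
  keep <- which(tr$zone_entered & !is.na(tr$hold_start))
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    sel <- which(d$trial_id == tr$trial_id[k])
    sel <- sel[tr$hold_start[k]:tr$hold_end[k]]
    m <- colMeans(d[sel, cols, drop = FALSE])
    names(m) <- DOF_NAMES
    out[[i]] <- data.frame(trial_id = tr$trial_id[k], group = group,
                           as.list(m))
  }
  do.call(rbind, out)
}

#' Across-trial standard deviation of reaching postures
#'
#' Sample SD (n-1 denominator) of each joint angle across the average
#' reaching postures of one phase/group.
#'
#' @param postures Data frame from [average_reaching_postures()].
#' @return Named 7-vector of SDs (deg).
#' @export
posture_sd <- function(postures) {
  if (nrow(postures) < 2) stop("need at least 2 postures")
  vapply(postures[, DOF_NAMES], stats::sd, numeric(1))
}

#' Summary metrics for one recorded phase
#'
#' @param recording A `motion_recording` with trial outcomes.
#' @return A list of class `phase_metrics`: per-trial `approach_time` and
#'   `approach_speed`, their means, `success_rate`, `sv` (an `sv_report`).
#' @export
phase_metrics <- function(recording) {
  tr <- recording$trials
  at <- tr$approach_time[tr$zone_entered]
  as_ <- mapply(approach_speed, tr$start_dist[tr$zone_entered],
                tr$approach_time[tr$zone_entered])
  sv <- shoulder_spread_volume(
    as.matrix(recording$data[, c("shx", "shy", "shz")]))
  structure(list(phase = recording$phase,
                 approach_time = at, approach_speed = as_,
                 mean_at = mean(at), mean_as = mean(as_),
                 success_rate = mean(tr$success),
                 n_trials = nrow(tr), sv = sv),
            class = "phase_metrics")
}
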