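# Turns motion recordings into supervised datasets: in-zone filtering,
# contextual-feature construction, and the C+/C- input schemas.
# C- inputs: the 3 shoulder angles. C+ inputs: the 3 shoulder angles plus
# 4 contextual features (shoulder-to-target vector in the egocentric frame,
# in metres, and the target tilt in degrees). Outputs: the 4 distal angles
# of the same sample. Angles stay in degrees and distances in metres;
# standardization happens inside the predictor, not here.

SHOULDER_DOFS <- c("sh_flex", "sh_abd", "hum_rot")
CONTEXT_FEATURES <- c("dx", "dy", "dz", "tilt")

#' Contextual features for one sample
#'
#' The shoulder-to-target-center vector expressed in the egocentric frame
#' (axes parallel to the world frame, origin at the instantaneous shoulder
#' center) plus the target's frontal-plane tilt.
#'
#' @param shoulder_position 3-vector (m).
#' @param target Target (list with `x`, `y`, `z`, `tilt`).
#' @return Named 4-vector: `dx`, `dy`, `dz` (m), `tilt` (deg).
#' @export
make_context <- function(shoulder_position, target) {
  d <- target_position(target) - as.numeric(shoulder_position)
  c(dx = d[1], dy = d[2], dz = d[3], tilt = target$tilt)
}

# recompute per-sample in-zone flags from poses + per-trial targets
recompute_in_zone <- function(recording, tol, geometry = arm_geometry()) {
  d <- recording$data
  tr <- recording$trials
  q <- as.matrix(d[, DOF_NAMES])
  sh <- as.matrix(d[, c("shx", "shy", "shz")])
  fk <- fk_batch(q, sh, geometry)
  z <- logical(nrow(d))
  for (k in seq_len(nrow(tr))) {
    sel <- which(d$trial_id == tr$trial_id[k])
    z[sel] <- in_target_zone_vec(fk$centers[sel, , drop = FALSE],
                                 fk$axes[sel, , drop = FALSE],
                                 target_row(tr, k), tol)
  }
  z
}

#' Filter a recording to in-zone samples
#'
#' Keeps exactly the samples flagged inside the target zone (the stored
#' flags; they can be recomputed from the poses and trial targets with the
#' internal recompute path, which must agree).
#'
#' @param recording A `motion_recording`.
#' @return The row subset of `recording$data` (with a `row_index` column
#'   recording provenance). Warns if no sample is in zone.
#' @export
filter_in_zone <- function(recording) {
  if (is.null(recording$trials) || !nrow(recording$trials)) {
    stop("recording has no attached targets")
  }
  d <- recording$data
  d$row_index <- seq_len(nrow(d))
  out <- d[d$in_zone, , drop = FALSE]
  if (!nrow(out)) warning("no in-zone samples in recording")
  out
}

#' Build a supervised training dataset from a recording
#'
#' @param recording A `motion_recording` (natural-control phase: the distal
#'   angles are the subject's own).
#' @param mode `"C+"` (with context) or `"C-"` (shoulder angles only).
#' @return A list of class `training_dataset`: `mode`, `inputs` (n x 3 or
#'   n x 7 matrix), `outputs` (n x 4 matrix of distal angles), `provenance`
#'   (source row indices).
#' @export
build_dataset <- function(recording, mode = c("C+", "C-")) {
  mode <- match.arg(mode)
  rows <- filter_in_zone(recording)
  X <- as.matrix(rows[, SHOULDER_DOFS])
  if (mode == "C+") {
    tr <- recording$trials
    ctx <- matrix(0, nrow(rows), 4,
                  dimnames = list(NULL, CONTEXT_FEATURES))
    tmap <- match(rows$trial_id, tr$trial_id)
    for (i in seq_len(nrow(rows))) {
      ctx[i, ] <- make_context(c(rows$shx[i], rows$shy[i], rows$shz[i]),
                               target_row(tr, tmap[i]))
    }
    X <- cbind(X, ctx)
  }
  Y <- as.matrix(rows[, DISTAL_DOFS])
  structure(list(mode = mode, inputs = X, outputs = Y,
                 provenance = rows$row_index),
            class = "training_dataset")
}
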