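# Task environment: the 5 x 5 x 2 target grid (8 cm pitch), whole/subset
# target sets, constrained random target orders, the 6-D target-zone test
# and the trial lifecycle (hold-to-complete within a timeout).

TILT_SET <- c(-45, -22.5, 0, 22.5, 45)
SAMPLE_RATE_HZ <- 90

#' Grid configuration
#'
#' Placement of the 5-wide x 5-high x 2-deep target lattice relative to the
#' shoulder's home position. The grid center is laterally and
#' antero-posteriorly referenced to the shoulder; `center_rise` lifts the
#' grid center above the shoulder so that every target pose (position +
#' frontal-plane tilt) is achievable within the anatomical joint limits.
#'
#' @param spacing Lattice pitch in metres.
#' @param anterior_offset Distance (m) from the shoulder to the near grid
#'   face along +x.
#' @param center_rise Height (m) of the grid center above the shoulder.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(spacing = 0.08, anterior_offset = 0.24,
                        center_rise = 0.08) {
  structure(list(spacing = spacing, anterior_offset = anterior_offset,
                 center_rise = center_rise),
            class = "grid_config")
}

#' Build the target position grid
#'
#' Lays out the 50 lattice positions: 5 columns (left-right, index `col`),
#' 5 rows (bottom-top, index `row`), 2 depths (near-far, index `depth`),
#' 8 cm pitch by default. Errors if any lattice point lies beyond the arm's
#' reach radius.
#'
#' @param geometry An [arm_geometry()].
#' @param config A [grid_config()].
#' @return A data.frame with columns `col`, `row`, `depth` (0-based indices)
#'   and `x`, `y`, `z` (m, world frame).
#' @export
build_target_grid <- function(geometry = arm_geometry(),
                              config = grid_config()) {
  s <- config$spacing
  sh <- geometry$shoulder_home
  g <- expand.grid(col = 0:4, row = 0:4, depth = 0:1)
  g$x <- sh[1] + config$anterior_offset + s * g$depth
  g$y <- sh[2] + s * (g$col - 2)
  g$z <- sh[3] + config$center_rise + s * (g$row - 2)
  d <- sqrt((g$x - sh[1])^2 + (g$y - sh[2])^2 + (g$z - sh[3])^2)
  if (any(d > geometry$reach)) {
    bad <- which(d > geometry$reach)
    stop("grid positions beyond reach radius at indices: ",
         paste(sprintf("(%d,%d,%d)", g$col[bad], g$row[bad], g$depth[bad]),
               collapse = ", "))
  }
  g
}

#' Build a target set
#'
#' The whole set combines all 50 grid positions with the five frontal-plane
#' tilts (250 targets); the subset keeps the 24 positions obtained by
#' excluding the leftmost column, the rightmost column and the lowest row
#' (120 targets).
#'
#' @param grid Output of [build_target_grid()].
#' @param which `"whole"` or `"subset"`.
#' @return A list of class `target_set` with `name` and `targets`
#'   (a data.frame: grid indices, position, `tilt`).
#' @export
build_target_set <- function(grid, which = c("whole", "subset")) {
  which <- match.arg(which)
  pos <- grid
  if (which == "subset") {
    pos <- pos[pos$col != 0 & pos$col != 4 & pos$row != 0, , drop = FALSE]
  }
  targets <- merge(pos, data.frame(tilt = TILT_SET))
  targets <- targets[order(targets$depth, targets$row, targets$col,
                           targets$tilt), ]
  rownames(targets) <- NULL
  structure(list(name = which, targets = targets), class = "target_set")
}

target_row <- function(set_or_df, i) {
  df <- if (inherits(set_or_df, "target_set")) set_or_df$targets else
    set_or_df
  as.list(df[i, , drop = FALSE])
}

target_position <- function(target) c(target$x, target$y, target$z)

#' Generate a constrained random target order
#'
#' Draws targets without replacement, alternating pick/place roles, such
#' that no two consecutive targets sit at neighbouring grid positions
#' (Chebyshev index distance < 2, i.e. the 26-neighbourhood including the
#' same position). Drawing stops when no admissible target remains; if the
#' sequence is then shorter than `min_length` the draw restarts with the
#' next seed. Deterministic given `seed`.
#'
#' @param set A [build_target_set()] result.
#' @param min_length Minimum order length (study values: 200 for the whole
#'   set, 100 for the subset).
#' @param seed Integer RNG seed.
#' @param max_length Optional truncation of the drawn order (the full draw
#'   runs to a dead end); useful for scaled-down runs.
#' @return A list of class `target_order`: `sequence` (targets data.frame
#'   with a `role` column alternating `"pick"`/`"place"`), `seed`,
#'   `set_name`.
#' @export
generate_target_order <- function(set,
                                  min_length = if (set$name == "whole")
                                    200L else 100L,
                                  seed = 1L, max_length = Inf) {
  stopifnot(min_length >= 2)
  tg <- set$targets
  for (attempt_seed in seq.int(seed, seed + 1000L)) {
    drawn <- local({
      set.seed(attempt_seed)
      avail <- rep(TRUE, nrow(tg))
      idx <- integer(0)
      repeat {
        cand <- which(avail)
        if (length(idx)) {
          last <- tg[idx[length(idx)], ]
          ok <- abs(tg$col[cand] - last$col) >= 2 |
            abs(tg$row[cand] - last$row) >= 2 |
            abs(tg$depth[cand] - last$depth) >= 2
          cand <- cand[ok]
        }
        if (!length(cand)) break
        pick <- if (length(cand) == 1) cand else cand[sample.int(
          length(cand), 1)]
        idx <- c(idx, pick)
        avail[pick] <- FALSE
      }
      idx
    })
    if (length(drawn) >= min_length) {
      if (is.finite(max_length)) drawn <- drawn[seq_len(min(
        length(drawn), max_length))]
      out <- tg[drawn, , drop = FALSE]
      out$role <- rep(c("pick", "place"), length.out = nrow(out))
      rownames(out) <- NULL
      return(structure(list(sequence = out, seed = attempt_seed,
                            set_name = set$name),
                       class = "target_order"))
    }
  }
  stop("could not draw an order of length >= ", min_length,
       " from set '", set$name, "'")
}

#' Zone tolerances
#'
#' @param spatial Maximum hand-center-to-target-center distance (m).
#' @param angular Maximum hand-axis-to-target-axis angle (deg, unsigned).
#' @return A list of class `tolerance`.
#' @export
tolerance <- function(spatial, angular) {
  stopifnot(spatial > 0, angular > 0)
  structure(list(spatial = spatial, angular = angular), class = "tolerance")
}

#' Acquisition-phase zone tolerance: 2 cm, 5 degrees
#' @rdname tolerance
#' @export
tolerance_acquisition <- function() tolerance(0.02, 5)

#' Test/baseline-phase zone tolerance: 4 cm, 10 degrees
#' @rdname tolerance
#' @export
tolerance_test <- function() tolerance(0.04, 10)

#' Test whether a hand pose is inside a target zone
#'
#' True iff the hand center is within the spatial tolerance of the target
#' center and the unsigned angle between the hand axis and the target axis
#' (from [axis_from_tilt()]) is within the angular tolerance. Both
#' boundaries are closed.
#'
#' @param hand A [hand_pose()].
#' @param target A target (one row of a target set, as a list with `x`,
#'   `y`, `z`, `tilt`).
#' @param tol A [tolerance()].
#' @return Logical scalar.
#' @export
in_target_zone <- function(hand, target, tol) {
  d <- sqrt(sum((hand$center - target_position(target))^2))
  d <= tol$spatial &&
    axis_angle_deg(hand$axis, axis_from_tilt(target$tilt)) <= tol$angular
}

# vectorised zone test over matrices of hand centers (n x 3) and axes
# (n x 3, unit rows)
in_target_zone_vec <- function(centers, axes, target, tol) {
  p <- target_position(target)
  d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 +
    (centers[, 3] - p[3])^2
  ta <- axis_from_tilt(target$tilt)
  ca <- abs(axes[, 1] * ta[1] + axes[, 2] * ta[2] + axes[, 3] * ta[3])
  ang <- rad2deg(acos(pmin(1, ca)))
  d2 <= tol$spatial^2 & ang <= tol$angular
}

# Core hold/timeout logic on a per-sample in-zone logical vector sampled at
# `rate` Hz with t = t0 + (0:(n-1))/rate. Success when an in-zone run SPANS
# `hold_s` seconds (hold_s * rate + 1 consecutive samples); the trial ends
# at the sample completing the hold, or at `timeout_s`, whichever is first.
# Returns indices relative to the vector (NA when absent) plus the last
# contiguous in-zone run within the trial (the holding period used for
# posture averaging).
trial_from_inzone <- function(inzone, rate = SAMPLE_RATE_HZ, hold_s = 1.0,
                              timeout_s = 15.0) {
  if (!length(inzone)) stop("empty sample stream")
  n_hold <- as.integer(round(hold_s * rate)) + 1L
  n_max <- min(length(inzone), as.integer(round(timeout_s * rate)) + 1L)
  z <- inzone[seq_len(n_max)]
  first_in <- if (any(z)) which(z)[1] else NA_integer_
  success <- FALSE
  end_idx <- n_max
  if (!is.na(first_in)) {
    r <- rle(z)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= n_hold)
    if (length(ok)) {
      success <- TRUE
      end_idx <- starts[ok[1]] + n_hold - 1L
    }
  }
  hold <- c(NA_integer_, NA_integer_)
  if (!is.na(first_in)) {
    zz <- z[seq_len(end_idx)]
    r <- rle(zz)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    last <- runs[length(runs)]
    hold <- c(starts[last], ends[last])
  }
  list(success = success,
       zone_entered = !is.na(first_in),
       first_in = first_in,
       end_idx = end_idx,
       hold_start = hold[1], hold_end = hold[2])
}

#' Run the trial lifecycle over a stream of hand poses
#'
#' Applies the hold-to-complete rule: the trial succeeds when the hand stays
#' inside the target zone for an interval spanning `hold_s` seconds, and
#' ends at that moment or at `timeout_s`, whichever comes first. The
#' approach time is the time from trial start to the first in-zone sample.
#'
#' @param poses List of [hand_pose()] sampled at `rate` Hz (first element at
#'   trial time 0).
#' @param target Target (list with `x`, `y`, `z`, `tilt`).
#' @param tol A [tolerance()].
#' @param hold_s Required hold duration (s).
#' @param timeout_s Trial timeout (s).
#' @param rate Sampling rate (Hz).
#' @return A list of class `trial_outcome`: `success`, `zone_entered`,
#'   `approach_time` (s, `NA` if the zone was never entered), `end_time`
#'   (s), `hold_start`, `hold_end` (sample indices of the last in-zone run),
#'   `start_hand_pose`.
#' @export
run_trial_lifecycle <- function(poses, target, tol, hold_s = 1.0,
                                timeout_s = 15.0, rate = SAMPLE_RATE_HZ) {
  if (!length(poses)) stop("empty sample stream")
  centers <- t(vapply(poses, function(p) p$center, numeric(3)))
  axes <- t(vapply(poses, function(p) p$axis, numeric(3)))
  z <- in_target_zone_vec(centers, axes, target, tol)
  res <- trial_from_inzone(z, rate, hold_s, timeout_s)
  structure(list(success = res$success,
                 zone_entered = res$zone_entered,
                 approach_time = if (res$zone_entered)
                   (res$first_in - 1) / rate else NA_real_,
                 end_time = (res$end_idx - 1) / rate,
                 hold_start = res$hold_start, hold_end = res$hold_end,
                 start_hand_pose = poses[[1]]),
            class = "trial_outcome")
}
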