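# Inverse kinematics for the redundant 7-DoF arm.
#
# Two stages, both deterministic:
#  1. a smooth box-constrained minimisation (L-BFGS-B, analytic gradient) of
#     squared position error + squared axis misalignment (1 - (a.g)^2, which
#     treats the grasp axis as unsigned) + a light posture cost pulling
#     toward the attractor posture, restarted from a fixed ordered library of
#     initial postures (comfort-like, lateral, overhand, underhand grasps)
#     until the polish stage succeeds;
#  2. a damped-least-squares polish on the 6-D task error (3 position +
#     axis tangent displacement) with null-space descent of the weighted
#     squared deviation from the attractor, masking the columns of joints
#     pinned at a limit. This drives the residual below the hard tolerance.
#
# The attractor (comfort posture, possibly biased by target context) resolves
# the arm's redundancy consistently but target-dependently.

AXIS_ERR_SCALE <- 0.15   # m per rad: balances axis error against position

# fixed ordered init library; tl = target tilt (deg) selects mirror variants
ik_init_library <- function(init, tl = 0) {
  s <- sign(tl + 1e-9)
  list(init,
       joint_posture(35, 10, -20 * s, 45, 30 * s, 0, -40),
       joint_posture(100, 5, 0, 60, 0, 0, -45),
       joint_posture(20, 10, 0, 120, 0, 0, 60),
       joint_posture(45, 40, -30, 110, 30, 0, 50),
       joint_posture(10, 40, 0, 90, 0, 0, -50),
       joint_posture(60, 0, 30, 100, -40, 0, 40))
}

# deterministic coarse restart lattice used when the ordered library fails
# (goals far from the task workspace, e.g. behind or above the head)
ik_fallback_library <- function() {
  g <- expand.grid(sh_flex = c(-40, 30, 90, 150),
                   sh_abd = c(0, 60, 110),
                   hum_rot = c(-60, 0, 60),
                   el_flex = c(20, 80, 140))
  lapply(seq_len(nrow(g)), function(i) {
    joint_posture(g$sh_flex[i], g$sh_abd[i], g$hum_rot[i], g$el_flex[i],
                  0, 0, 0)
  })
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(NULL)
  v / n
}

# analytic candidate configurations reconstructed from the goal pose:
# wrist placed along either signed axis branch, elbow on the two-link
# circle at a few swivel angles, segment frames built by minimal twist and
# decomposed into joint angles. Near-exact except where the clamp to
# anatomical limits bites; the polish stage finishes the job.
ik_analytic_inits <- function(goal, geometry, shoulder_position) {
  sh <- as.numeric(shoulder_position)
  Lu <- geometry$lengths[["upper"]]
  Lf <- geometry$lengths[["fore"]]
  Lh <- geometry$lengths[["hand"]]
  out <- list()
  for (sgn in c(1, -1)) {
    a <- sgn * goal$axis
    w <- goal$center + Lh * a          # wrist: hand segment along -a
    v <- w - sh
    r <- sqrt(sum(v^2))
    r <- min(max(r, abs(Lu - Lf) + 1e-6), Lu + Lf - 1e-6)
    n <- unit3(v)
    if (is.null(n)) next
    d1 <- (Lu^2 + r^2 - Lf^2) / (2 * r)
    h2 <- Lu^2 - d1^2
    if (h2 < 0) next
    h <- sqrt(h2)
    # sweep the flexion-plane normal (well-conditioned at any elbow
    # angle, including the near-straight arm); both segment directions
    # are exactly orthogonal to it by construction
    ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    b1 <- unit3(cross3(n, ref)); b2 <- cross3(n, b1)
    for (psi in seq(-pi, pi - pi / 6, by = pi / 6)) {
      yu <- cos(psi) * b1 + sin(psi) * b2
      cdir <- unit3(cross3(yu, n))
      if (is.null(cdir)) next
      elbow <- sh + d1 * n + h * cdir
      u <- unit3(elbow - sh); f <- unit3(w - elbow)
      if (is.null(u) || is.null(f)) next
      Ru <- cbind(cross3(yu, -u), yu, -u)
      Rf0 <- cbind(cross3(yu, -f), yu, -f)
      # supination candidates; the two wrist angles then follow in closed
      # form from the axis expressed in the forearm frame
      for (gam in deg2rad(seq(-80, 80, by = 20))) {
        Rf <- Rf0 %*% rot_z(gam)
        af <- as.numeric(t(Rf) %*% a)
        wdev <- asin(pmin(1, pmax(-1, af[2])))
        wext <- -atan2(af[1], af[3])
        Rh <- Rf %*% rot_y(-wext) %*% rot_x(-wdev)
        q <- tryCatch(angles_from_segment_orientations(
          list(upper = Ru, fore = Rf, hand = Rh)), error = function(e)
            NULL)
        if (!is.null(q)) out[[length(out) + 1]] <- q
      }
    }
  }
  out
}

ik_coarse <- function(goal, geometry, shoulder_position, init, attractor,
                      weights, w_axis = 8) {
  lim <- geometry$limits
  g <- goal$axis
  fn <- function(q) {
    jac <- arm_jacobian(as_posture(q), geometry, shoulder_position)
    ep <- goal$center - jac$hand
    sum(ep^2) * 400 + w_axis * (1 - sum(jac$axis * g)^2) +
      1e-4 * sum(weights * deg2rad(q - attractor)^2)
  }
  gr <- function(q) {
    jac <- arm_jacobian(as_posture(q), geometry, shoulder_position)
    ep <- goal$center - jac$hand
    ag <- sum(jac$axis * g)
    gpos <- -800 * as.numeric(t(jac$J[1:3, ]) %*% ep)
    gax <- -2 * w_axis * ag * as.numeric(t(jac$J[4:6, ]) %*% g)
    (gpos + gax + 2e-4 * weights * deg2rad(q - attractor)) * pi / 180
  }
  o <- stats::optim(init, fn, gr, method = "L-BFGS-B",
                    lower = lim[, "lower"], upper = lim[, "upper"],
                    control = list(maxit = 600, factr = 1e5))
  as_posture(o$par)
}

ik_polish <- function(goal, geometry, shoulder_position, q, attractor,
                      weights, tol, lambda, max_iter, k_null = 0.2) {
  lim <- geometry$limits
  qa <- deg2rad(as_posture(attractor))
  best <- list(pe = Inf, ae = Inf, q = q)
  for (it in seq_len(max_iter)) {
    jac <- arm_jacobian(q, geometry, shoulder_position)
    g <- goal$axis
    if (sum(g * jac$axis) < 0) g <- -g       # unsigned axis
    ep <- goal$center - jac$hand
    ca <- pmin(1, pmax(-1, sum(jac$axis * g)))
    ea <- g - ca * jac$axis                  # tangential axis displacement
    pe <- sqrt(sum(ep^2))
    ae <- rad2deg(acos(ca))
    if (pe + AXIS_ERR_SCALE * deg2rad(ae) <
        best$pe + AXIS_ERR_SCALE * deg2rad(best$ae)) {
      best <- list(pe = pe, ae = ae, q = q)
    }
    if (pe <= tol$position && ae <= tol$axis) {
      return(list(q = q, pe = pe, ae = ae, ok = TRUE, iterations = it))
    }
    e <- c(ep, AXIS_ERR_SCALE * ea)
    en <- sqrt(sum(e^2))
    if (en > 0.02) e <- e * (0.02 / en)      # stay in the linear regime
    J <- jac$J
    J[4:6, ] <- AXIS_ERR_SCALE * J[4:6, ]
    solve_dls <- function(J) {
      Jinv <- t(J) %*% solve(J %*% t(J) + diag(lambda^2, 6))
      dq <- as.numeric(Jinv %*% e)
      N <- diag(7) - Jinv %*% J
      dq + as.numeric(N %*% (-k_null * weights * (deg2rad(q) - qa)))
    }
    dq <- solve_dls(J)
    # joints pinned at a limit and pushed outward contribute nothing
    pin <- (q <= lim[, "lower"] + 1e-9 & dq < 0) |
      (q >= lim[, "upper"] - 1e-9 & dq > 0)
    if (any(pin)) {
      J[, pin] <- 0
      dq <- solve_dls(J)
    }
    q <- clamp_to_limits(q + rad2deg(pmin(pmax(dq, -0.1), 0.1)), geometry)
  }
  list(q = best$q, pe = best$pe, ae = best$ae, ok = FALSE,
       iterations = max_iter)
}

#' Inverse kinematics for the 7-DoF arm
#'
#' Finds a joint posture whose forward kinematics matches a 6-D hand-pose
#' goal (center + unsigned grasp axis) within tolerance, while locally
#' minimising the weighted squared deviation from `attractor` among
#' tolerance-satisfying postures (null-space redundancy resolution).
#' Deterministic given its inputs: the solver restarts from a fixed, ordered
#' library of initial postures and takes the first tolerance-satisfying
#' solution.
#'
#' @param goal A [hand_pose()]; the axis is treated as unsigned (a bottle is
#'   symmetric under axis flip).
#' @param geometry An [arm_geometry()].
#' @param shoulder_position 3-vector shoulder-center position (m).
#' @param init Initial posture (degrees), tried before the canonical library.
#' @param attractor Posture toward which the redundancy resolution pulls;
#'   defaults to `init`.
#' @param weights Positive 7-vector of posture-cost weights.
#' @param tol List with `position` (m) and `axis` (deg) tolerances.
#' @param lambda Damping factor of the least-squares polish.
#' @param max_iter Maximum polish iterations per restart.
#' @param tilt_hint Target tilt in degrees; orients the mirror-image members
#'   of the restart library.
#' @return A list of class `hr_ik`: `posture`, `reachable`, `converged`,
#'   `pos_err` (m), `axis_err` (deg), `iterations`. A goal beyond the reach
#'   radius gives `reachable = FALSE` and a `NULL` posture. Non-convergence
#'   raises an error carrying the best residual.
#' @export
solve_ik <- function(goal, geometry,
                     shoulder_position = geometry$shoulder_home,
                     init, attractor = init, weights = rep(1, 7),
                     tol = list(position = 0.001, axis = 0.5),
                     lambda = 0.02, max_iter = 200L, tilt_hint = 0) {
  stopifnot(inherits(goal, "hand_pose"), length(weights) == 7,
            all(weights > 0))
  sh <- as.numeric(shoulder_position)
  if (sqrt(sum((goal$center - sh)^2)) > geometry$reach) {
    return(structure(list(posture = NULL, reachable = FALSE,
                          converged = FALSE, pos_err = NA_real_,
                          axis_err = NA_real_, iterations = 0L),
                     class = "hr_ik"))
  }
  init <- clamp_to_limits(as_posture(init), geometry)
  attractor <- as_posture(attractor)
  best <- list(pe = Inf, ae = Inf)
  total_it <- 0L
  done <- function(pol) {
    structure(list(posture = pol$q, reachable = TRUE, converged = TRUE,
                   pos_err = pol$pe, axis_err = pol$ae,
                   iterations = total_it),
              class = "hr_ik")
  }
  note_best <- function(pol) {
    if (pol$pe + AXIS_ERR_SCALE * deg2rad(pol$ae) <
        best$pe + AXIS_ERR_SCALE * deg2rad(best$ae)) best <<- pol
  }
  # pass 1: task-workspace library through the smooth stage + polish
  for (ini in ik_init_library(init, tilt_hint)) {
    q0 <- ik_coarse(goal, geometry, sh, clamp_to_limits(ini, geometry),
                    attractor, weights)
    pol <- ik_polish(goal, geometry, sh, q0, attractor, weights, tol,
                     lambda, max_iter)
    total_it <- total_it + pol$iterations
    if (pol$ok) return(done(pol))
    note_best(pol)
  }
  # pass 2: analytic pose reconstructions, polish only (they are exact up
  # to the limit clamp); least-clamped candidates first
  ana <- ik_analytic_inits(goal, geometry, sh)
  if (length(ana)) {
    lim <- geometry$limits
    viol <- vapply(ana, function(q) {
      sum(pmax(0, q - lim[, "upper"]) + pmax(0, lim[, "lower"] - q))
    }, numeric(1))
    for (ini in ana[order(viol)]) {
      pol <- ik_polish(goal, geometry, sh, clamp_to_limits(ini, geometry),
                       attractor, weights, tol, lambda, max_iter)
      total_it <- total_it + pol$iterations
      if (pol$ok) return(done(pol))
      note_best(pol)
    }
  }
  # pass 3: coarse restart lattice for anything still unresolved
  for (ini in ik_fallback_library()) {
    q0 <- ik_coarse(goal, geometry, sh, ini, attractor, weights)
    pol <- ik_polish(goal, geometry, sh, q0, attractor, weights, tol,
                     lambda, max_iter)
    total_it <- total_it + pol$iterations
    if (pol$ok) return(done(pol))
    note_best(pol)
  }
  stop(sprintf(paste0("inverse kinematics did not converge ",
                      "(best residual: %.4f m position, %.2f deg axis)"),
               best$pe, best$ae))
}
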