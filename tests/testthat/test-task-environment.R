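# Target grid, target sets, constrained orders, zone test and trial
# lifecycle.

test_that("grid and target-set combinatorics are exact", {
  grid <- build_target_grid(geo)
  expect_equal(nrow(grid), 50L)
  # lattice pitch: minimal pairwise distance equals the spacing
  d <- as.matrix(dist(grid[, c("x", "y", "z")]))
  expect_equal(min(d[d > 0]), 0.08, tolerance = 1e-12)
  expect_true(max(sqrt((grid$x - geo$shoulder_home[1])^2 +
                         (grid$y - geo$shoulder_home[2])^2 +
                         (grid$z - geo$shoulder_home[3])^2)) < geo$reach)
  whole <- build_target_set(grid, "whole")
  subset <- build_target_set(grid, "subset")
  expect_equal(nrow(whole$targets), 250L)
  expect_equal(nrow(subset$targets), 120L)
  pos <- unique(subset$targets[, c("col", "row", "depth")])
  expect_equal(nrow(pos), 24L)
  # brute-force set subtraction over the lattice
  keep <- grid$col != 0 & grid$col != 4 & grid$row != 0
  expect_equal(nrow(pos), sum(keep))
  expect_true(all(pos$col %in% 1:3) && all(pos$row %in% 1:4))
})

test_that("unreachable lattice points are rejected with their indices", {
  small <- arm_geometry(0.1, 0.1, 0.05)
  expect_error(build_target_grid(small), "beyond reach")
})

test_that("orders alternate roles, respect the adjacency constraint and
          the minimum length, and are seed-deterministic", {
  grid <- build_target_grid(geo)
  whole <- build_target_set(grid, "whole")
  subset <- build_target_set(grid, "subset")
  for (s in 1:15) {
    o <- generate_target_order(subset, 100, seed = s)
    tg <- o$sequence
    expect_gte(nrow(tg), 100)
    expect_identical(tg$role,
                     rep(c("pick", "place"), length.out = nrow(tg)))
    cheb <- pmax(abs(diff(tg$col)), abs(diff(tg$row)),
                 abs(diff(tg$depth)))
    expect_true(all(cheb >= 2))
  }
  ow <- generate_target_order(whole, 200, seed = 3)
  expect_gte(nrow(ow$sequence), 200)
  o1 <- generate_target_order(subset, 100, seed = 42)
  o2 <- generate_target_order(subset, 100, seed = 42)
  expect_identical(o1$sequence, o2$sequence)
})

test_that("the target zone test uses closed boundaries and unsigned axes,
          and is monotone in tolerance", {
  target <- list(x = 0.3, y = 0, z = 0, tilt = 0)
  at_center <- hand_pose(c(0.3, 0, 0), c(0, 0, 1))
  expect_true(in_target_zone(at_center, target, tolerance(0.04, 10)))
  expect_false(in_target_zone(hand_pose(c(0.341, 0, 0), c(0, 0, 1)),
                              target, tolerance(0.04, 10)))
  tilted <- hand_pose(c(0.3, 0, 0), axis_from_tilt(10))
  expect_true(in_target_zone(tilted, target, tolerance(0.04, 10)))
  # axis flip symmetry: an inverted axis is the same grasp
  expect_true(in_target_zone(hand_pose(c(0.3, 0, 0), c(0, 0, -1)),
                             target, tolerance(0.04, 10)))
  set.seed(9)
  for (i in 1:100) {
    hp <- hand_pose(c(0.3, 0, 0) + rnorm(3, 0, 0.03),
                    axis_from_tilt(runif(1, -60, 60)))
    small <- in_target_zone(hp, target, tolerance(0.02, 5))
    big <- in_target_zone(hp, target, tolerance(0.04, 10))
    expect_true(!small || big)
  }
})

# brute-force oracle: success iff some window of hold_s*rate + 1
# consecutive in-zone samples fits before the timeout
oracle_lifecycle <- function(z, rate = 90, hold_s = 1, timeout_s = 15) {
  n_hold <- round(hold_s * rate) + 1
  z <- z[seq_len(min(length(z), round(timeout_s * rate) + 1))]
  if (length(z) < n_hold) return(list(success = FALSE, end = length(z)))
  for (s in seq_len(length(z) - n_hold + 1)) {
    if (all(z[s:(s + n_hold - 1)])) {
      return(list(success = TRUE, end = s + n_hold - 1))
    }
  }
  list(success = FALSE, end = length(z))
}

test_that("trial lifecycle matches its worked examples", {
  rate <- 90
  t_of <- function(i) (i - 1) / rate
  # permanently in zone: success exactly at t = 1.0 s, approach time 0
  z <- rep(TRUE, 3 * rate)
  r <- trial_from_inzone(z, rate)
  expect_true(r$success)
  expect_equal(t_of(r$first_in), 0)
  expect_equal(t_of(r$end_idx), 1.0)
  # never in zone: failure at the 15 s timeout
  r <- trial_from_inzone(rep(FALSE, 20 * rate), rate)
  expect_false(r$success)
  expect_true(is.na(r$first_in))
  expect_equal(t_of(r$end_idx), 15)
  # in zone during [0.5, 1.3] then [2.0, 3.1]: approach at 0.5 s, the
  # first run is too short, success at 3.0 s, holding period [2.0, 3.0]
  tt <- t_of(seq_len(16 * rate))
  z <- (tt >= 0.5 & tt <= 1.3) | (tt >= 2.0 & tt <= 3.1)
  r <- trial_from_inzone(z, rate)
  expect_true(r$success)
  expect_equal(t_of(r$first_in), 0.5)
  expect_equal(t_of(r$end_idx), 3.0)
  expect_equal(t_of(r$hold_start), 2.0)
  expect_equal(t_of(r$hold_end), 3.0)
  expect_error(trial_from_inzone(logical(0)), "empty")
})

test_that("trial lifecycle agrees with a brute-force oracle on random
          streams", {
  set.seed(4)
  for (i in 1:300) {
    n <- sample.int(1600, 1) + 50
    z <- runif(n) < runif(1, 0.3, 0.95)
    r <- trial_from_inzone(z)
    o <- oracle_lifecycle(z)
    expect_identical(r$success, o$success)
    expect_identical(r$end_idx, as.integer(o$end))
  }
})

test_that("run_trial_lifecycle wraps pose streams", {
  target <- list(x = 0.3, y = 0, z = 0, tilt = 0)
  inpose <- hand_pose(c(0.3, 0, 0), c(0, 0, 1))
  poses <- rep(list(inpose), 200)
  out <- run_trial_lifecycle(poses, target, tolerance(0.04, 10))
  expect_true(out$success)
  expect_equal(out$approach_time, 0)
  expect_equal(out$end_time, 1.0)
  expect_identical(out$start_hand_pose, inpose)
})
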