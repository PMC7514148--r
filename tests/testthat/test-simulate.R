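test_that("zero noise and zero gains give straight constant-velocity flight", {
  cfg <- sim_config(noise = 0, corridor_gain = 0, coupling_mode = "none",
                    seed = 1)
  traj <- simulate_pair(cfg)
  d1 <- traj[traj$agent == 1, ]
  # displacement direction is constant
  steps <- as.matrix(d1[, c("x", "y", "z")])
  dirs <- diff(steps)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_lt(max(abs(sweep(dirs, 2, dirs[1, ]))), 1e-9)
  # curvature is zero downstream
  kin <- fit_spline_and_resample(d1, 180)
  expect_lt(max(kin$curvature, na.rm = TRUE), 1e-6)
})

test_that("identical seed and config reproduce identical trajectories", {
  cfg <- sim_config(coupling_mode = "bidirectional", seed = 42)
  expect_identical(simulate_pair(cfg), simulate_pair(cfg))
  g1 <- simulate_group(sim_config(), n_pairs = 3, seed = 7)
  g2 <- simulate_group(sim_config(), n_pairs = 3, seed = 7)
  expect_identical(g1, g2)
})

test_that("speed is conserved along each simulated path", {
  traj <- simulate_pair(sim_config(coupling_mode = "rear_to_front",
                                   seed = 3))
  for (ag in 1:2) {
    d <- traj[traj$agent == ag, ]
    sp <- sqrt(rowSums(diff(as.matrix(d[, c("x", "y", "z")]))^2)) *
      180  # chord speed per native step
    # chords of a constant-speed curved path are shorter than the arc by
    # O((kappa v dt)^2): equality holds to ~1e-4 at these curvatures
    expect_lt(max(abs(sp - 3)) / 3, 1e-3)
    expect_lt(stats::sd(sp) / mean(sp), 1e-3)
  }
})

test_that("agent 1 enters the volume before agent 2", {
  traj <- simulate_pair(sim_config(seed = 5))
  expect_lt(min(traj$t[traj$agent == 1]), min(traj$t[traj$agent == 2]))
})

test_that("groups use distinct per-pair seeds and jittered durations", {
  g <- simulate_group(sim_config(), n_pairs = 10, seed = 11)
  gt <- attr(g, "ground_truth")
  expect_equal(nrow(gt), 10)
  expect_equal(length(unique(gt$seed)), 10)
  durs <- purrr::map_dbl(split(g$t, paste(g$pair_id, g$agent)),
                         ~ diff(range(.x)))
  expect_true(all(durs >= 1.3 * 0.8 - 1e-6 & durs <= 1.3 * 1.2 + 1e-6))
  expect_gt(length(unique(round(durs, 4))), 3)

  # total concatenated overlap length ~ n_pairs * (duration - entry) * rate
  kin <- extract_overlap(compute_kinematics(g, 180))
  n_overlap <- sum(kin$agent == 1)
  expected <- 10 * (1.3 - 0.55) * 180
  expect_gt(n_overlap, expected * 0.75)
  expect_lt(n_overlap, expected * 1.3)
})

test_that("shared corridor forcing induces within-pair curvature similarity", {
  # strong shared environment, zero direct coupling
  cors <- purrr::map_dbl(1:60, function(i) {
    traj <- simulate_pair(sim_config(coupling_mode = "none",
                                     corridor_gain = 2, seed = 9000 + i))
    kin <- extract_overlap(compute_kinematics(traj, 180))
    cor(kin$curvature[kin$agent == 1], kin$curvature[kin$agent == 2])
  })
  # positively correlated on average (shared forcing, no interaction)
  expect_gt(mean(cors) / (sd(cors) / sqrt(length(cors))), 2)
})

test_that("swapping agent labels with reversed coupling is exchangeable", {
  # distribution of the driven agent's curvature must not depend on
  # whether it is labelled front or rear
  summ <- function(mode, agent) {
    purrr::map_dbl(1:25, function(i) {
      traj <- simulate_pair(sim_config(coupling_mode = mode,
                                       seed = 3000 + i))
      kin <- extract_overlap(compute_kinematics(traj, 180))
      mean(kin$curvature[kin$agent == agent])
    })
  }
  follower_when_rear_drives <- summ("rear_to_front", 1)
  follower_when_front_drives <- summ("front_to_rear", 2)
  p <- stats::t.test(follower_when_rear_drives,
                     follower_when_front_drives)$p.value
  expect_gt(p, 0.01)
})

test_that("coupled groups show the configured information-flow direction", {
  hits <- 0
  for (w in 1:6) {
    traj <- simulate_group(sim_config(coupling_mode = "rear_to_front"),
                           n_pairs = 8, seed = 600 + w)
    kin <- extract_overlap(compute_kinematics(traj, 180))
    ens <- build_ensemble(kin, "curvature")
    b <- attr(ens, "segment_bounds")
    t21 <- transfer_entropy_ksg(ensemble_series(ens, 2),
                                ensemble_series(ens, 1), k = 8,
                                bounds = b)$value
    t12 <- transfer_entropy_ksg(ensemble_series(ens, 1),
                                ensemble_series(ens, 2), k = 8,
                                bounds = b)$value
    if (t21 > t12) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("mean coupled-direction TE is nondecreasing in the gain", {
  mean_te <- function(gain) {
    mean(purrr::map_dbl(1:8, function(w) {
      traj <- simulate_group(sim_config(coupling_mode = "rear_to_front",
                                        gain = gain),
                             n_pairs = 6, seed = 700 + w)
      kin <- extract_overlap(compute_kinematics(traj, 180))
      ens <- build_ensemble(kin, "curvature")
      transfer_entropy_ksg(ensemble_series(ens, 2),
                           ensemble_series(ens, 1), k = 8,
                           bounds = attr(ens, "segment_bounds"))$value
    }))
  }
  te_by_gain <- c(mean_te(0), mean_te(10), mean_te(35))
  expect_true(all(diff(te_by_gain) > -0.01))
  expect_gt(te_by_gain[3], te_by_gain[1])
})

test_that("trajectory files round-trip losslessly in the CSV dialect", {
  g <- simulate_group(sim_config(), n_pairs = 10, seed = 13)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectories(g, f1)
  expect_identical(readLines(f1)[1], "pair_id,agent,t,x,y,z,behavior")
  back <- read_trajectories(f1)
  expect_equal(nrow(back), nrow(g))
  expect_lt(max(abs(back$x - g$x)), 1e-12)
  expect_equal(nrow(dplyr::distinct(back, pair_id, agent)), 20)
  write_trajectories(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(read_trajectories(tempfile()), "no such")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(delay = 2), "shorter than")
  expect_error(sim_config(duration = 0.1, sample_rate = 100), "at least 50")
  expect_error(sim_config(noise = -1))
  expect_s3_class(sim_config(), "sim_config")
})
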