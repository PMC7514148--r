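test_that("cubic trajectories are reproduced exactly, derivatives included", {
  tt <- seq(0, 1, by = 1 / 60)
  tr <- tibble::tibble(t = tt,
                       x = 1 + 2 * tt - 0.5 * tt^2 + 0.25 * tt^3,
                       y = -3 * tt + tt^3,
                       z = 2 - tt^2)
  kin <- fit_spline_and_resample(tr, 180)
  g <- kin$t
  expect_equal(kin$x, 1 + 2 * g - 0.5 * g^2 + 0.25 * g^3, tolerance = 1e-9)
  expect_equal(kin$vx, 2 - g + 0.75 * g^2, tolerance = 1e-9)
  expect_equal(kin$ax, -1 + 1.5 * g, tolerance = 1e-9)
  expect_equal(kin$vy, -3 + 3 * g^2, tolerance = 1e-9)
  expect_equal(kin$az, rep(-2, length(g)), tolerance = 1e-9)
})

test_that("uniform circular motion gives the closed-form speed and curvature", {
  kin <- fit_spline_and_resample(circle_trajectory(R = 1, omega = 2 * pi), 180)
  interior <- kin$t > 0.1 & kin$t < 0.9
  expect_lt(max(abs(kin$speed[interior] - 2 * pi)) / (2 * pi), 1e-3)
  expect_lt(max(abs(kin$curvature[interior] - 1)), 1e-2)
})

test_that("resampling grid spans the input at the target rate", {
  tr <- circle_trajectory(rate = 60, t_end = 1)  # 61 samples over 1 s
  kin <- fit_spline_and_resample(tr, 180)
  expect_equal(nrow(kin), 181)
  expect_equal(diff(range(diff(kin$t))), 0, tolerance = 1e-9)
  # a series already on the target grid is reproduced at the knots
  kin2 <- fit_spline_and_resample(kin[, c("t", "x", "y", "z")], 180)
  expect_equal(kin2$x, kin$x, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  tr <- circle_trajectory()
  expect_error(fit_spline_and_resample(tr[1:3, ]), "at least 4")
  bad <- tr; bad$t[5] <- bad$t[4]
  expect_error(fit_spline_and_resample(bad), "increasing")
  bad2 <- tr; bad2$x[2] <- Inf
  expect_error(fit_spline_and_resample(bad2), "finite")
})

test_that("curvature matches closed forms: circle, line, helix", {
  # circle of radius 2: rho = 1/R = 0.5
  kin <- fit_spline_and_resample(circle_trajectory(R = 2, omega = pi,
                                                   rate = 120, t_end = 2), 180)
  interior <- kin$t > 0.2 & kin$t < 1.8
  expect_lt(max(abs(kin$curvature[interior] - 0.5)) / 0.5, 1e-3)

  # straight line: rho = 0 (computed directly from exact derivatives)
  v <- matrix(rep(c(1, 2, 3), each = 50), ncol = 3)
  a <- matrix(0, 50, 3)
  cv <- compute_curvature(v, a)
  expect_equal(cv$curvature, rep(0, 50))

  # helix x = cos t, y = sin t, z = t: rho = 1/(1 + 1) = 0.5, exactly,
  # from the analytic derivatives
  tt <- seq(0, 2, length.out = 40)
  vh <- cbind(-sin(tt), cos(tt), 1)
  ah <- cbind(-cos(tt), -sin(tt), 0)
  cvh <- compute_curvature(vh, ah)
  expect_equal(cvh$curvature, rep(0.5, 40), tolerance = 1e-6)
})

test_that("curvature decomposition is orthogonal and reconstructs a", {
  set.seed(4)
  v <- matrix(rnorm(60), ncol = 3)
  a <- matrix(rnorm(60), ncol = 3)
  cv <- compute_curvature(v, a)
  expect_equal(cv$tangential + cv$normal, a, tolerance = 1e-9)
  expect_lt(max(abs(rowSums(cv$normal * v))) / max(abs(a)), 1e-9)
  expect_true(all(cv$curvature >= 0))
})

test_that("sub-floor speeds are flagged invalid, not divided through", {
  v <- matrix(c(1e-9, 0, 0, 1, 0, 0), byrow = TRUE, ncol = 3)
  a <- matrix(1, 2, 3)
  cv <- compute_curvature(v, a)
  expect_false(cv$valid[1])
  expect_true(is.na(cv$curvature[1]))
  expect_true(cv$valid[2])
})

test_that("curvature is invariant under rigid motions and scales as 1/s", {
  set.seed(11)
  tr <- helix_trajectory(rate = 60, t_end = 2)
  base <- fit_spline_and_resample(tr, 120)$curvature
  for (i in 1:3) {
    Q <- random_rotation()
    shift <- rnorm(3)
    rot <- as.matrix(tr[, c("x", "y", "z")]) %*% t(Q)
    tr_rot <- tibble::tibble(t = tr$t, x = rot[, 1] + shift[1],
                             y = rot[, 2] + shift[2], z = rot[, 3] + shift[3])
    expect_equal(fit_spline_and_resample(tr_rot, 120)$curvature, base,
                 tolerance = 1e-9)
  }
  # time shift: identical curvature; spatial scaling by s: curvature / s
  tr_shift <- dplyr::mutate(tr, t = t + 5)
  expect_equal(fit_spline_and_resample(tr_shift, 120)$curvature, base,
               tolerance = 1e-9)
  s <- 3.7
  tr_scaled <- dplyr::mutate(tr, x = s * x, y = s * y, z = s * z)
  expect_equal(fit_spline_and_resample(tr_scaled, 120)$curvature, base / s,
               tolerance = 1e-9)
})

test_that("overlap extraction trims to the co-presence window", {
  mk <- function(pid, agent, t0, t1) {
    tt <- seq(t0, t1, by = 1 / 60)
    tibble::tibble(pair_id = pid, agent = agent, t = tt,
                   x = cos(tt), y = sin(tt), z = tt, behavior = "NM")
  }
  traj <- dplyr::bind_rows(mk("A", 1L, 0, 1.5), mk("A", 2L, 0.3, 2.0))
  kin <- extract_overlap(compute_kinematics(traj, 180))
  d1 <- kin[kin$agent == 1, ]; d2 <- kin[kin$agent == 2, ]
  expect_equal(nrow(d1), nrow(d2))
  expect_gte(min(kin$t), 0.3 - 1e-9)
  expect_lte(max(kin$t), 1.5 + 1e-9)
  expect_equal(d1$t, d2$t)

  # idempotence
  kin2 <- extract_overlap(kin)
  expect_equal(nrow(kin2), nrow(kin))
  expect_equal(kin2$t, kin$t)

  # identical spans: unchanged lengths
  traj_same <- dplyr::bind_rows(mk("B", 1L, 0, 1), mk("B", 2L, 0, 1))
  kin_same <- compute_kinematics(traj_same, 180)
  expect_equal(nrow(extract_overlap(kin_same)), nrow(kin_same))

  # disjoint spans: pair excluded with a logged reason
  traj_disj <- dplyr::bind_rows(mk("C", 1L, 0, 0.5), mk("C", 2L, 1, 2))
  expect_error(suppressWarnings(compute_kinematics(traj_disj, 180)),
               "no analyzable")
  expect_warning(try(compute_kinematics(traj_disj, 180), silent = TRUE),
                 "do not overlap")
})

test_that("ensembles concatenate with correct bounds and normalize", {
  mk <- function(pid, n) {
    tt <- seq(0, (n - 1) / 180, by = 1 / 180)
    dplyr::bind_rows(lapply(1:2, function(ag) {
      tibble::tibble(pair_id = pid, agent = ag, behavior = "NM", t = tt,
                     x = cos(tt + ag), y = sin(tt + ag), z = tt,
                     vx = 1, vy = 1, vz = 1, ax = 0, ay = 0, az = 0,
                     speed = sqrt(3),
                     curvature = abs(sin(tt + ag * pid_num(pid))) + 0.1,
                     curvature_valid = TRUE)
    }))
  }
  pid_num <- function(p) match(p, c("P1", "P2", "P3"))
  kin <- dplyr::bind_rows(mk("P1", 100), mk("P2", 50), mk("P3", 70))
  attr(kin, "resample_rate") <- 180
  ens <- build_ensemble(kin, "curvature", normalize = "none")
  expect_equal(sum(ens$agent == 1), 220)
  expect_equal(attr(ens, "segment_bounds"), c(0L, 100L, 150L))
  expect_equal(attr(ens, "segment_bounds"),
               attr(build_ensemble(kin, "curvature"), "segment_bounds"))

  # single pair: the ensemble is the series itself
  kin1 <- mk("P1", 60); attr(kin1, "resample_rate") <- 180
  ens1 <- build_ensemble(kin1, "curvature", normalize = "none")
  expect_equal(ensemble_series(ens1, 1),
               kin1$curvature[kin1$agent == 1],
               ignore_attr = TRUE)

  # global normalization: mean 0, sample variance 1 per agent
  ensn <- normalize_ensemble(ens)
  for (ag in 1:2) {
    v <- ensemble_series(ensn, ag)
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(stats::var(v), 1, tolerance = 1e-9)
  }
  # idempotence of standardization
  ensn2 <- normalize_ensemble(ensn)
  expect_equal(ensemble_series(ensn2, 1), ensemble_series(ensn, 1),
               tolerance = 1e-12)
  # per-segment scope
  ps <- normalize_ensemble(ens, scope = "per_segment")
  seg1 <- ps$value[ps$agent == 1 & ps$segment == 2]
  expect_equal(mean(seg1), 0, tolerance = 1e-9)
  expect_equal(stats::var(seg1), 1, tolerance = 1e-9)
})

test_that("normalization rejects constant scopes by name", {
  tt <- seq(0, 0.3, by = 1 / 180)
  kin <- dplyr::bind_rows(lapply(1:2, function(ag)
    tibble::tibble(pair_id = "P1", agent = ag, behavior = "NM", t = tt,
                   x = tt, y = 0, z = 0, vx = 1, vy = 0, vz = 0,
                   ax = 0, ay = 0, az = 0, speed = 1,
                   curvature = 1, curvature_valid = TRUE)))
  attr(kin, "resample_rate") <- 180
  expect_error(build_ensemble(kin, "curvature"), "zero variance")
})

test_that("normalized [1,2,3] has sample variance one", {
  # direct check of the standardization convention on a minimal ensemble
  tt <- (0:2) / 180
  kin <- dplyr::bind_rows(lapply(1:2, function(ag)
    tibble::tibble(pair_id = "P1", agent = ag, behavior = "NM", t = tt,
                   x = tt, y = 0, z = 0, vx = 1, vy = 0, vz = 0,
                   ax = 0, ay = 0, az = 0, speed = 1,
                   curvature = c(1, 2, 3), curvature_valid = TRUE)))
  attr(kin, "resample_rate") <- 180
  v <- ensemble_series(build_ensemble(kin, "curvature"), 1)
  expect_equal(as.numeric(v), c(-1, 0, 1))
})
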