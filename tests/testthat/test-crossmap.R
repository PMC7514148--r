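test_that("shadow manifolds count points and respect segment boundaries", {
  x <- rnorm(100)
  mf <- build_shadow_manifold(x, E = 3, tau = 1)
  expect_equal(nrow(mf$points), 98)
  expect_equal(mf$time_index, 3:100)
  # E = 1: the series itself
  mf1 <- build_shadow_manifold(x, E = 1)
  expect_equal(as.numeric(mf1$points), x)
  # two segments of 50: two points lost per segment
  mf2 <- build_shadow_manifold(x, E = 3, bounds = c(0L, 50L))
  expect_equal(nrow(mf2$points), 96)
  expect_false(any(mf2$time_index %in% 51:52))
  expect_error(build_shadow_manifold(rnorm(5), E = 6), "too short")
})

test_that("lag ordering follows the delay-vector convention", {
  x <- 1:20
  mf <- build_shadow_manifold(x, E = 3, tau = 2)
  # point at time t is (x(t), x(t-2), x(t-4))
  expect_equal(mf$points[1, ], c(5, 3, 1))
  expect_equal(mf$time_index[1], 5)
})

test_that("simplex projection selects a workable embedding dimension", {
  set.seed(2)
  x <- logistic_series(500)
  sel <- select_embedding_dim(x, E_grid = 1:6)
  expect_true(sel$E %in% 1:3)
  expect_gt(max(sel$skills$skill), 0.95)

  # planar limit cycle embeds in 2D
  s <- sin(2 * pi * (1:400) / 20)
  sel_s <- select_embedding_dim(s, E_grid = 1:5)
  expect_gt(sel_s$skills$skill[sel_s$skills$E == 2], 0.99)

  # unforecastable noise: still returns an argmax, with low skill
  set.seed(3)
  expect_message(sel_n <- select_embedding_dim(rnorm(400), E_grid = 1:4),
                 "low forecast skill")
  expect_lt(max(sel_n$skills$skill), 0.4)

  # too-short series names the feasible limit
  expect_error(select_embedding_dim(rnorm(25), E_grid = 1:10),
               "maximum feasible E")
})

test_that("self-cross-mapping of a chaotic series approaches skill one", {
  set.seed(5)
  x <- logistic_series(500)
  mf <- build_shadow_manifold(x, E = 2)
  expect_gte(as.numeric(cross_map_skill(mf, x)), 0.99)
})

test_that("negative raw correlations are clipped to zero", {
  # unrelated noise series: the raw cross-map correlation straddles zero,
  # and any negative value must be reported as exactly zero skill
  set.seed(1)
  a <- rnorm(200); b <- rnorm(200)
  sk <- cross_map_skill(build_shadow_manifold(b, 2), a)
  expect_lt(attr(sk, "raw_correlation"), -0.1)
  expect_identical(as.numeric(sk), 0)
  # clipping is also sign-stable: negating the target flips neither the
  # estimate-vs-target correlation nor the clipped skill
  set.seed(6)
  x <- logistic_series(500)
  mf <- build_shadow_manifold(x, E = 2)
  expect_equal(as.numeric(cross_map_skill(mf, -x)),
               as.numeric(cross_map_skill(mf, x)), tolerance = 1e-9)
  # independent noise: clipped skill equals zero in most seeded runs
  zeros <- sum(replicate(10, {
    a2 <- rnorm(300); b2 <- rnorm(300)
    as.numeric(cross_map_skill(build_shadow_manifold(b2, 2), a2)) == 0
  }))
  expect_gte(zeros, 5)
})

test_that("skill is invariant under separate affine rescaling", {
  set.seed(8)
  p <- logistic_pair(400)
  mf <- build_shadow_manifold(p$y, E = 2)
  base <- as.numeric(cross_map_skill(mf, p$x))
  mf_s <- build_shadow_manifold(5 * p$y - 2, E = 2)
  expect_equal(as.numeric(cross_map_skill(mf_s, -3 * p$x + 1)), base,
               tolerance = 1e-9)
})

test_that("library smaller than E + 2 is refused", {
  x <- rnorm(50)
  mf <- build_shadow_manifold(x, E = 3)
  expect_error(cross_map_skill(mf, x, lib = 1:4), "insufficient")
})

test_that("library sweep counts windows and degenerates to one full window", {
  set.seed(10)
  p <- logistic_pair(100)
  r <- ccm_sweep(p$x, p$y, E_a = 2, E_b = 2, lib_sizes = c(10, 50, 100),
                 window_cap = 1000)
  expect_equal(r$a_to_b$n_windows, c(91L, 51L, 1L))
  # L = full length: single window equals one direct cross-map call
  mf_y <- build_shadow_manifold(p$y, E = 2)
  direct <- as.numeric(cross_map_skill(mf_y, p$x))
  expect_equal(r$a_to_b$skills[3], direct, tolerance = 1e-9)
  expect_true(all(tidy(r)$skill >= 0 & tidy(r)$skill <= 1))
})

test_that("cross mapping recovers the direction of a unidirectional pair", {
  hits <- 0
  for (s in 1:20) {
    p <- logistic_pair(1000, seed = 100 + s)
    Ex <- select_embedding_dim(p$x, 1:5)$E
    Ey <- select_embedding_dim(p$y, 1:5)$E
    # x drives y: x is recoverable from y's manifold
    c_xy <- as.numeric(cross_map_skill(build_shadow_manifold(p$y, Ey), p$x))
    c_yx <- as.numeric(cross_map_skill(build_shadow_manifold(p$x, Ex), p$y))
    if (c_xy > c_yx) hits <- hits + 1
  }
  expect_gte(hits, 17)
})

test_that("direction recovery holds across embedding dimensions 2 to 4", {
  for (E in 2:4) {
    hits <- 0
    for (s in 1:8) {
      p <- logistic_pair(800, seed = 500 + 10 * E + s)
      c_xy <- as.numeric(cross_map_skill(build_shadow_manifold(p$y, E), p$x))
      c_yx <- as.numeric(cross_map_skill(build_shadow_manifold(p$x, E), p$y))
      if (c_xy > c_yx) hits <- hits + 1
    }
    expect_gte(hits, 6)
  }
})

test_that("convergence classification follows the tolerance rules", {
  expect_equal(assess_convergence(c(0.2, 0.6, 0.74, 0.75)), "converged")
  expect_equal(assess_convergence(c(0.2, 0.4, 0.6, 0.75)), "increasing")
  expect_equal(assess_convergence(c(0, 0, 0, 0)), "converged")
  expect_equal(assess_convergence(c(0.2, 0.6, 0.4, 0.41)), "flat")
  expect_true(is.na(assess_convergence(c(0.1, 0.2))))
})

test_that("self-cross-map skill grows with library size on the logistic map", {
  set.seed(12)
  x <- logistic_series(600)
  r <- ccm_sweep(x, x, E_a = 2, E_b = 2, lib_sizes = c(30, 100, 300, 600),
                 window_cap = 30)
  sk <- r$a_to_b$skills
  expect_true(all(diff(sk) > -0.02))
  expect_gt(sk[length(sk)], 0.95)
})
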