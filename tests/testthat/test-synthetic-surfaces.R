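test_that("random_surface is uniform, reproducible and validates input", {
  expect_equal(nrow(random_surface(0)$stomata), 0)
  expect_error(random_surface(-1), "non-negative")
  a <- random_surface(500, window = c(1, 1), seed = 11)
  b <- random_surface(500, window = c(1, 1), seed = 11)
  expect_identical(a$stomata, b$stomata)
  # KS test of x-coordinates against uniform rarely rejects at alpha = 0.01
  pass <- vapply(1:60, function(s) {
    s <- random_surface(500, window = c(1, 1), seed = 1000 + s)
    suppressWarnings(stats::ks.test(s$stomata$x, "punif")$p.value) > 0.01
  }, TRUE)
  expect_gte(sum(pass), 57)
})

test_that("conditioned triangular grids hit the exact count with lattice geometry", {
  for (n in c(13, 50, 120)) {
    g <- triangular_grid_surface(grid_sim_config(n, seed = n))
    expect_equal(nrow(g$stomata), n)
  }
  g <- triangular_grid_surface(grid_sim_config(200, window = c(1, 1),
                                               seed = 7))
  s <- attr(g, "spacing")
  # interior stomata sit at exactly one lattice constant from their nearest
  # neighbour
  nn <- amphistom:::cpp_nn_dists(g$stomata$x, g$stomata$y)
  interior <- g$stomata$x > s & g$stomata$x < 1 - s &
    g$stomata$y > s & g$stomata$y < 1 - s
  expect_true(any(interior))
  expect_lt(max(abs(nn[interior] - s)), 1e-9)
  # NNI approaches the triangular-lattice maximum 2*sqrt(2/sqrt(3))
  expect_equal(nni(g)$nni, 2 * sqrt(2 / sqrt(3)), tolerance = 0.05)
  # determinism
  g2 <- triangular_grid_surface(grid_sim_config(200, window = c(1, 1),
                                                seed = 7))
  expect_identical(g$stomata, g2$stomata)
})

test_that("lattice scan-line counting agrees with direct enumeration", {
  # fixed-orientation C++ scan vs an independent R enumeration
  set.seed(42)
  for (i in 1:20) {
    s <- runif(1, 0.05, 0.3); dy <- s * sqrt(3) / 2
    tx <- runif(1, 0, 2 * s); ty <- runif(1, 0, dy)
    got <- amphistom:::cpp_lattice_points(s, 0, tx, ty, 1, 1)
    jr <- 0:floor((1 - ty) / dy)
    exp_n <- sum(vapply(jr, function(j) {
      ox <- tx + j * s / 2
      max(0, floor((1 - ox) / s) - ceiling(-ox / s) + 1)
    }, 0))
    expect_length(got$x, exp_n)
    expect_true(all(got$x >= 0 & got$x <= 1 & got$y >= 0 & got$y <= 1))
  }
  # rotated lattice points keep the lattice constant as nearest distance
  pts <- amphistom:::cpp_lattice_points(0.1, 0.4, 0.03, 0.05, 1, 1)
  nn <- amphistom:::cpp_nn_dists(pts$x, pts$y)
  interior <- pts$x > 0.12 & pts$x < 0.88 & pts$y > 0.12 & pts$y < 0.88
  expect_lt(max(abs(nn[interior] - 0.1)), 1e-9)
})

test_that("ideal grid spacing and density are exact inverses", {
  expect_equal(ideal_grid_spacing(10.107), 338, tolerance = 1e-3)
  expect_equal(round(spacing_to_density(338)), 10)
  d <- c(0.5, 10, 129.5, 600)
  expect_equal(spacing_to_density(ideal_grid_spacing(d)), d,
               tolerance = 1e-9)
  expect_equal(ideal_grid_spacing(4 * d), ideal_grid_spacing(d) / 2)
  expect_error(ideal_grid_spacing(0), "positive")
  expect_error(spacing_to_density(-1), "positive")
})

test_that("hard-core surfaces respect the inhibition distance", {
  for (s in 1:10) {
    h <- hardcore_surface(60, r_min = 0.03, seed = s)
    expect_gte(amphistom:::cpp_min_pairwise_dist(h$stomata$x, h$stomata$y),
               0.03)
  }
  expect_error(hardcore_surface(100, window = c(0.1, 0.1), r_min = 0.05,
                                max_tries = 1e4),
               "infeasible")
  # r_min = 0 degenerates to the same count and window as the random model
  h0 <- hardcore_surface(40, r_min = 0, seed = 1)
  expect_equal(nrow(h0$stomata), 40)
})

test_that("moderate inhibition yields dispersion strictly between random and ideal", {
  di <- vapply(1:100, function(s) {
    h <- hardcore_surface(50, r_min = 0.5 * expected_nn_distance(0.386, 50),
                          seed = 2000 + s)
    dispersion_analysis(h, n_sim = 199, seed = 3000 + s)$dispersion_index
  }, 0)
  expect_gt(median(di), 0.05)
  expect_lt(median(di), 0.95)
})

test_that("simulate_pair produces the three coordination regimes", {
  al <- simulate_pair(pair_sim_config(30, mode = "aligned", seed = 5))
  expect_identical(al$abaxial$stomata$x, al$adaxial$stomata$x)
  expect_identical(al$abaxial$stomata$y, al$adaxial$stomata$y)

  ind <- simulate_pair(pair_sim_config(30, 20, mode = "independent",
                                       seed = 5))
  expect_equal(nrow(ind$abaxial$stomata), 30)
  expect_equal(nrow(ind$adaxial$stomata), 20)

  # independent pairs: mean NSD correlation is small but systematically
  # POSITIVE, because both rasters share the deterministic edge structure
  # (pixels near window corners are far from stomata on either surface).
  # The Monte-Carlo coordination test is calibrated against a null that
  # carries the same bias (see the calibration test), so this does not
  # compromise inference.
  r_ind <- vapply(1:300, function(s) {
    nsd_correlation(simulate_pair(pair_sim_config(50, mode = "independent",
                                                  seed = 4000 + s)), 64)
  }, 0)
  expect_gt(mean(r_ind), 0)
  expect_lt(mean(r_ind), 0.1)

  # offset-coordinated dense pairs: negative correlation almost surely
  r_off <- vapply(1:40, function(s) {
    nsd_correlation(simulate_pair(pair_sim_config(
      60, mode = "offset_coordinated", seed = 5000 + s)), 64)
  }, 0)
  expect_gte(mean(r_off < 0), 0.95)
})

test_that("attach_lengths plants an exact affine signal when noiseless", {
  r <- random_surface(40, seed = 9)
  z <- voronoi_zones(r)
  r0 <- attach_lengths(r, alpha = 18, beta = 1.5, sigma = 0, seed = 1)
  expect_equal(r0$stomata$length, 18 + 1.5 * z$areas, tolerance = 1e-12)
  # beta = 0: no association with zone area on average
  cors <- vapply(1:50, function(s) {
    rr <- attach_lengths(random_surface(40, seed = 6000 + s), beta = 0,
                         sigma = 2, seed = 7000 + s)
    zz <- voronoi_zones(rr)
    cor(rr$stomata$length, zz$areas)
  }, 0)
  expect_lt(abs(mean(cors)), 0.1)
})
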