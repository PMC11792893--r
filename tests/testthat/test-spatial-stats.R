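test_that("expected and observed nearest-neighbour distances match closed forms", {
  expect_equal(expected_nn_distance(1, 4), 0.25)
  expect_equal(expected_nn_distance(0.386, 100), 0.5 * sqrt(0.00386))
  expect_error(expected_nn_distance(1, 0), ">= 1")
  expect_error(expected_nn_distance(0, 5), "positive")

  two <- surface_record(c(0.1, 0.4), c(0.2, 0.2), window = c(1, 1))
  expect_equal(observed_mean_nn_distance(two), 0.3)
  corners <- surface_record(c(0, 1, 1, 0), c(0, 0, 1, 1), window = c(1, 1))
  expect_equal(observed_mean_nn_distance(corners), 1.0)
  expect_error(observed_mean_nn_distance(surface_record(0.5, 0.5)),
               "at least 2")
})

test_that("nearest-neighbour search equals the brute-force oracle", {
  for (s in 1:10) {
    r <- random_surface(sample(5:80, 1), seed = 100 + s)
    expect_equal(observed_mean_nn_distance(r),
                 oracle_mean_nn(r$stomata$x, r$stomata$y),
                 tolerance = 1e-12)
  }
})

test_that("NNI anchors: square corners give 4, random surfaces give about 1", {
  corners <- surface_record(c(0, 1, 1, 0), c(0, 0, 1, 1), window = c(1, 1))
  expect_equal(nni(corners)$nni, 4.0)
  r <- nni(random_surface(2000, window = c(1, 1), seed = 2))
  expect_equal(r$nni, 1, tolerance = 0.1)  # slight positive edge bias
})

test_that("dispersion index is the affine rescaling between the two nulls", {
  rand <- c(0.9, 1.0, 1.1)
  ideal <- c(2.0, 2.1, 2.2)
  expect_equal(dispersion_index(1.0, rand, ideal), 0)
  expect_equal(dispersion_index(2.1, rand, ideal), 1)
  expect_equal(dispersion_index(1.55, rand, ideal), 0.5)
  expect_error(dispersion_index(1, rand, rand), "degenerate")
  expect_error(dispersion_index(1, numeric(), ideal), "non-empty")
})

test_that("add-one Monte-Carlo p-value handles extremes and ties", {
  null <- seq_len(1000) / 1000
  expect_equal(mc_p_greater(2, null), 1 / 1001)
  expect_equal(mc_p_greater(-1, null), 1)
  expect_equal(mc_p_greater(0.5, rep(0.5, 99)), 1)
  expect_error(mc_p_greater(1, numeric()), "non-empty")
})

test_that("BH adjustment reproduces the hand-worked step-up and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  set.seed(1)
  for (i in 1:5) {
    p <- runif(20)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("dispersion_analysis is reproducible and calibrated at the extremes", {
  r <- random_surface(60, seed = 31)
  a <- dispersion_analysis(r, n_sim = 300, seed = 8)
  b <- dispersion_analysis(r, n_sim = 300, seed = 8)
  expect_identical(a, b)

  g <- triangular_grid_surface(grid_sim_config(100, seed = 15))
  dg <- dispersion_analysis(g, n_sim = 500, seed = 16)
  # an ideal grid beats every random null draw: p attains its minimum
  expect_equal(dg$p_raw, 1 / 501)
  expect_equal(dg$dispersion_index, 1, tolerance = 0.15)
  expect_error(dispersion_analysis(surface_record(0.5, 0.5)), "at least 2")
})

test_that("dispersion_batch adjusts across the whole family", {
  recs <- lapply(1:6, function(i) random_surface(30, seed = 40 + i))
  d <- dispersion_batch(recs, n_sim = 99, seed = 3)
  expect_equal(nrow(d), 6)
  expect_equal(d$p_adjusted, bh_adjust(d$p_raw))
})

test_that("two-way ANOVA matches hand-computed sums of squares on a balanced design", {
  # 2x2 with 2 replicates per cell
  y <- c(10, 12, 20, 22, 15, 17, 31, 33)
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(rep(c("b1", "b2"), each = 2), 2)
  tab <- two_way_anova(y, A, B)
  # hand computation (balanced: Type II equals the classical decomposition)
  gm <- mean(y)
  ssa <- 4 * sum((tapply(y, A, mean) - gm)^2)
  ssb <- 4 * sum((tapply(y, B, mean) - gm)^2)
  cell <- tapply(y, interaction(A, B), mean)
  ssab <- 2 * sum((cell - rep(tapply(y, A, mean), 2) -
                     rep(tapply(y, B, mean), each = 2) + gm)^2)
  sse <- sum((y - cell[interaction(A, B)])^2)
  f_hand <- c(ssa, ssb, ssab) / (sse / 4)
  expect_equal(tab$sum_sq, c(ssa, ssb, ssab), tolerance = 1e-10)
  expect_equal(tab$f, f_hand, tolerance = 1e-10)
  expect_equal(tab$p, stats::pf(f_hand, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)
  # independent cross-check on an unbalanced layout
  y2 <- c(y, 14, 26)
  A2 <- c(A, "a1", "a2"); B2 <- c(B, "b1", "b1")
  tab2 <- two_way_anova(y2, A2, B2)
  ref <- car::Anova(stats::lm(y2 ~ factor(A2) * factor(B2)), type = 2)
  expect_equal(tab2$sum_sq, ref$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(tab2$f, ref$`F value`[1:3], tolerance = 1e-10)
})

test_that("purely additive cell-constant data carry no interaction sum of squares", {
  A <- rep(c("a1", "a2"), each = 6)
  B <- rep(rep(c("b1", "b2", "b3"), each = 2), 2)
  y <- ifelse(A == "a2", 5, 0) + c(b1 = 0, b2 = 3, b3 = 7)[B]
  tab <- two_way_anova(y, A, B)
  expect_lt(abs(tab$sum_sq[tab$effect == "A:B"]), 1e-18)
})

test_that("ANOVA p-values are uniform under label permutation", {
  set.seed(99)
  y <- rnorm(48)
  A <- rep(c("a1", "a2"), 24)
  B <- rep(c("b1", "b2", "b3"), each = 16)
  ps <- vapply(1:200, function(i) {
    two_way_anova(y, sample(A), sample(B))$p[1]
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})
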