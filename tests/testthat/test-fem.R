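test_that("mesh construction counts nodes, covers the domain and refines", {
  m <- build_mesh(100, 300, nx = 4, ny = 4)
  expect_equal(nrow(m$nodes), 25)
  expect_equal(nrow(m$tri), 32)
  tri_area <- function(mesh) {
    tr <- mesh$tri; x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
    sum(abs((x[tr[, 2]] - x[tr[, 1]]) * (y[tr[, 3]] - y[tr[, 1]]) -
              (x[tr[, 3]] - x[tr[, 1]]) * (y[tr[, 2]] - y[tr[, 1]])) / 2)
  }
  expect_equal(tri_area(m), m$W * m$H, tolerance = 1e-12)

  edge_len <- function(mesh) {
    tr <- mesh$tri; nd <- mesh$nodes
    e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
    max(sqrt(rowSums((nd[e[, 1], ] - nd[e[, 2], ])^2)))
  }
  m1 <- build_mesh(100, 300, nx = 8, ny = 8)
  m2 <- build_mesh(100, 300, nx = 16, ny = 16)
  expect_equal(edge_len(m1) / edge_len(m2), 2, tolerance = 1e-12)
  # graded mesh still covers the domain exactly and resolves the pore
  mg <- build_mesh(338, 300, nx = 64, ny = 16, pore_halfwidth = 10)
  expect_equal(tri_area(mg), mg$W * mg$H, tolerance = 1e-12)
  xb <- sort(unique(mg$nodes[, 1]))
  expect_gte(sum(xb <= 10e-6 + 1e-12), 5)  # >= 4 edges across the pore
  expect_error(build_mesh(338, 300, nx = 8, ny = 8, pore_halfwidth = 10),
               "increase nx")
})

test_that("effective diffusivity follows the porosity/tortuosity scaling", {
  expect_equal(effective_diffusivity(1.6e-5, 0.2, 1.57), 1.6e-5 * 0.2 / 1.57)
  expect_equal(effective_diffusivity(1.6e-5, 0.2, 1.57), 2.038e-6,
               tolerance = 1e-3)
  expect_equal(effective_diffusivity(1.54e-5, 1, 1), 1.54e-5)
  expect_gt(effective_diffusivity(1e-5, 0.3, 1.5),
            effective_diffusivity(1e-5, 0.2, 1.5))
  expect_lt(effective_diffusivity(1e-5, 0.2, 2),
            effective_diffusivity(1e-5, 0.2, 1.5))
})

test_that("volumetric demand honours its biochemical limits", {
  p <- leaf_model_params()
  # at the compensation point the net rate is exactly -Rd
  expect_equal(demand(p$Gamma_star, c(0, 150, 301), p),
               rep(-p$Rd_vol, 3))
  # darkness: no electron transport, pure respiration
  pdark <- leaf_model_params(I0 = 1e-300)
  expect_equal(demand(c(0.001, 0.0163, 1), 100, pdark),
               rep(-pdark$Rd_vol, 3), tolerance = 1e-6)
  # CO2 saturation under saturating light: Rubisco-limited asymptote
  psat <- leaf_model_params(I0 = 1e5, Jmax_vol = 8 * 0.3, k_abs = 1e-9)
  expect_equal(demand(1e3, 150, psat), psat$Vcmax_vol - psat$Rd_vol,
               tolerance = 1e-3)
  # monotone non-decreasing in c
  cs <- seq(1e-4, 0.05, length.out = 50)
  expect_true(all(diff(demand(cs, 100, p)) >= 0))
})

test_that("zero reaction with uniform Dirichlet reproduces the constant field", {
  mesh <- build_mesh(100, 300, nx = 8, ny = 8)
  dir <- which(mesh$nodes[, 2] == 0)
  sol <- fem_solve(mesh, 2e-6, function(c) rep(0, length(c)),
                   function(c) rep(0, length(c)), dir, 0.0163)
  expect_equal(sol$c, rep(0.0163, nrow(mesh$nodes)), tolerance = 1e-12)
  expect_equal(sol$consumption, 0)
})

test_that("linear-reaction solution matches the 1-D cosh closed form", {
  # Dirichlet on the entire top and bottom boundaries makes the problem 1-D
  L <- 300e-6
  D <- 2e-6
  k <- 150       # s^-1, gives a marked but resolvable profile
  c0 <- 0.0163
  mesh <- build_mesh(200, 300, nx = 64, ny = 64)
  dir <- which(mesh$nodes[, 2] < 1e-12 | mesh$nodes[, 2] > L - 1e-12)
  sol <- fem_solve(mesh, D, function(c) k * c, function(c) rep(k, length(c)),
                   dir, c0, tol = 1e-10)
  q <- sqrt(k / D)
  y <- mesh$nodes[, 2]
  analytic <- c0 * cosh(q * (y - L / 2)) / cosh(q * L / 2)
  expect_lt(max(abs(sol$c - analytic)) / c0, 0.005)
})

test_that("converged leaf solves conserve mass and respond monotonically", {
  sol <- solve_leaf(leaf_model_params(), nx = 48, ny = 48)
  expect_lt(sol$mass_balance_error, 1e-3)
  expect_true(all(sol$c_field >= -1e-10))
  expect_gt(sol$A_total, 0)

  A_I <- vapply(c(50, 500, 1000), function(i0) {
    solve_leaf(leaf_model_params(I0 = i0), nx = 32, ny = 32)$A_total
  }, 0)
  expect_true(all(diff(A_I) > 0))
  A_c <- vapply(c(0.010, 0.0163, 0.025), function(cp) {
    solve_leaf(leaf_model_params(c_pore = cp), nx = 32, ny = 32)$A_total
  }, 0)
  expect_true(all(diff(A_c) > 0))
})

test_that("identical pore geometries give zero coordination advantage", {
  p <- leaf_model_params(arrangement = "aligned")
  a1 <- solve_leaf(p, nx = 32, ny = 32)$A_total
  a2 <- solve_leaf(p, nx = 32, ny = 32)$A_total
  expect_identical(log(a1 / a2), 0)
})

test_that("nearly contiguous stomata leave nothing to gain from offsetting", {
  # U close to the pore width: pores cover most of both surfaces
  p <- leaf_model_params(U = 34, T_leaf = 201, pore_halfwidth = 10)
  adv <- coordination_advantage(p, nx = 48, ny = 48)
  expect_lt(abs(as.numeric(adv)), 1e-4)
})

test_that("the advantage is mesh-converged at the reference resolution", {
  # evaluated on the thin-sparse cell, where the advantage is largest and
  # discretisation error is most visible
  p <- leaf_model_params(T_leaf = 101, U = 338, phi_pal = 0.1, I0 = 1000)
  a64 <- as.numeric(coordination_advantage(p, nx = 64, ny = 64))
  a128 <- as.numeric(coordination_advantage(p, nx = 128, ny = 128))
  expect_lt(abs(a64 - a128) / abs(a128), 0.05)
})

test_that("parameter sweep enumerates the grid and tolerates cell failures", {
  sw <- parameter_sweep(T_leaf = c(101, 301), U = c(34, 169),
                        phi_pal = c(0.1, 0.3), I0 = c(50, 1000),
                        nx = 24, ny = 24)
  expect_equal(nrow(sw), 16)
  expect_true(all(is.finite(sw$advantage)))
  # offsetting never hurts in the homogeneous model (numerical tolerance)
  expect_true(all(sw$advantage > -1e-8))
})
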