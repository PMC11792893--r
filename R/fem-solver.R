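# --- mesh -------------------------------------------------------------------

# x-breakpoints for nx edges on [0, W] with pore segments of length ph at
# both ends resolved by >= 4 edges. Uniform spacing already suffices when
# W/nx <= ph/4; otherwise the pore zones are refined and the interior keeps
# the remaining edges.
graded_breaks <- function(W, nx, ph) {
  if (is.null(ph) || W / nx <= ph / 4) return(seq(0, W, length.out = nx + 1))
  if (2 * ph >= 0.9 * W) {
    stopf("pore under-resolved: increase nx to >= %d", ceiling(4 * W / ph))
  }
  n_p <- max(4L, ceiling(nx * ph / W))
  nm <- nx - 2L * n_p
  if (nm < 2) {
    stopf("pore under-resolved: increase nx to >= %d",
          max(2L * n_p + 2L, ceiling(4 * W / ph)))
  }
  c(seq(0, ph, length.out = n_p + 1),
    seq(ph, W - ph, length.out = nm + 1)[-1],
    seq(W - ph, W, length.out = n_p + 1)[-1])
}

#' Build a structured triangular mesh of the leaf cross-section
#'
#' Triangulates the rectangle `[0, U/2] x [0, T_leaf]` with `(nx+1)(ny+1)`
#' nodes and `2*nx*ny` right triangles (each grid cell split along one
#' diagonal). When `pore_halfwidth` is given, the x-spacing is graded so
#' that each pore segment at the domain edges is resolved by at least four
#' boundary edges.
#'
#' @param U Full interstomatal distance (um); the domain spans `U/2`.
#' @param T_leaf Leaf thickness (um).
#' @param nx,ny Edge counts in x and y (>= 4).
#' @param pore_halfwidth Optional pore half-width (um) used for grading and
#'   the resolution check.
#' @return List of class `leaf_mesh`: `nodes` (matrix, metres), `tri`
#'   (3-column index matrix), `nx`, `ny`, `W`, `H` (metres).
#' @export
build_mesh <- function(U, T_leaf, nx = 64, ny = 64, pore_halfwidth = NULL) {
  if (nx < 4 || ny < 4) stopf("nx and ny must be >= 4")
  W <- U / 2 * 1e-6
  H <- T_leaf * 1e-6
  ph <- if (is.null(pore_halfwidth)) NULL else pore_halfwidth * 1e-6
  xb <- graded_breaks(W, nx, ph)
  yb <- seq(0, H, length.out = ny + 1)
  nodes <- cbind(x = rep(xb, times = ny + 1), y = rep(yb, each = nx + 1))
  # cell (i, j) -> nodes n00, n10, n01, n11; split along the n00-n11 diagonal
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  n00 <- (j - 1) * (nx + 1) + i
  n10 <- n00 + 1L
  n01 <- n00 + (nx + 1L)
  n11 <- n01 + 1L
  tri <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
  structure(list(nodes = nodes, tri = tri, nx = nx, ny = ny, W = W, H = H),
            class = "leaf_mesh")
}

#' @export
print.leaf_mesh <- function(x, ...) {
  cat(sprintf("<leaf_mesh> %g x %g um, %d nodes, %d triangles\n",
              x$W * 1e6, x$H * 1e6, nrow(x$nodes), nrow(x$tri)))
  invisible(x)
}

# Assemble the unit-diffusivity P1 stiffness matrix and lumped mass vector.
assemble_fem <- function(mesh) {
  tr <- mesh$tri
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  x1 <- x[tr[, 1]]; x2 <- x[tr[, 2]]; x3 <- x[tr[, 3]]
  y1 <- y[tr[, 1]]; y2 <- y[tr[, 2]]; y3 <- y[tr[, 3]]
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)  # 2A, > 0 (ccw)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (d in 1:3) {
    k <- k + 1L
    ii[[k]] <- tr[, a]; jj[[k]] <- tr[, d]
    vv[[k]] <- (b[, a] * b[, d] + cc[, a] * cc[, d]) / (2 * area2)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(vv),
                            dims = rep(nrow(mesh$nodes), 2L))
  m <- as.vector(Matrix::sparseMatrix(
    i = as.vector(tr), j = rep(1L, length(tr)),
    x = rep(area2 / 6, 3L), dims = c(nrow(mesh$nodes), 1L)))
  list(K = K, m = m)
}

# --- nonlinear solve --------------------------------------------------------

#' Solve a steady reaction-diffusion problem on a leaf mesh
#'
#' Solves `div(D grad c) = a(c)` with Dirichlet values on the given nodes
#' and zero flux elsewhere, using linear triangular elements and Newton
#' iteration on the reaction term (the reaction is linearised about the
#' current iterate with its analytic slope, which must be non-negative; the
#' resulting systems stay symmetric positive definite). Iterates until the
#' relative change of the concentration field falls below `tol`.
#'
#' @param mesh A [build_mesh()] result.
#' @param D_eff Effective diffusivity (m^2 s^-1).
#' @param reaction Function of the node concentration vector returning the
#'   volumetric sink `a(c)` per node (mol m^-3 s^-1).
#' @param reaction_slope Function returning `da/dc >= 0` per node; `NULL`
#'   uses a forward difference.
#' @param dirichlet_nodes Integer node indices held at `dirichlet_value`.
#' @param dirichlet_value Concentration at those nodes (mol m^-3).
#' @param tol Relative convergence tolerance (default 1e-8).
#' @param max_iter Iteration budget (default 200).
#' @param damping Step damping in (0, 1]; 1 is the full Newton step.
#' @return List: `c` (node concentrations), `iterations`, `residual`
#'   (last relative change), `consumption` (integral of `a(c)` over the
#'   domain, mol m^-1 s^-1 per unit depth), `flux_in` (total influx through
#'   the Dirichlet boundary, same units), `K`, `m`.
#' @export
fem_solve <- function(mesh, D_eff, reaction, reaction_slope = NULL,
                      dirichlet_nodes, dirichlet_value, tol = 1e-8,
                      max_iter = 200, damping = 1) {
  stopifnot(inherits(mesh, "leaf_mesh"))
  if (length(dirichlet_nodes) < 1) stopf("no Dirichlet nodes")
  asm <- assemble_fem(mesh)
  K <- D_eff * asm$K
  m <- asm$m
  nn <- nrow(mesh$nodes)
  dir <- sort(unique(as.integer(dirichlet_nodes)))
  free <- setdiff(seq_len(nn), dir)
  if (is.null(reaction_slope)) {
    h <- 1e-7 * max(abs(dirichlet_value), 1e-12)
    reaction_slope <- function(c) {
      pmax((reaction(c + h) - reaction(c)) / h, 0)
    }
  }
  K_ff <- K[free, free]
  K_fd <- K[free, dir]
  cvec <- rep(dirichlet_value, nn)
  bc <- as.vector(K_fd %*% rep(dirichlet_value, length(dir)))
  iter <- 0L
  rel <- Inf
  scale <- max(abs(dirichlet_value), 1e-300)
  while (iter < max_iter && rel > tol) {
    iter <- iter + 1L
    a <- reaction(cvec)
    s <- pmax(reaction_slope(cvec), 0)
    A <- K_ff + Matrix::Diagonal(x = m[free] * s[free])
    rhs <- -bc - m[free] * (a[free] - s[free] * cvec[free])
    cf <- as.vector(Matrix::solve(A, rhs))
    cnew <- cvec
    cnew[free] <- (1 - damping) * cvec[free] + damping * cf
    rel <- max(abs(cnew - cvec)) / max(max(abs(cnew)), scale)
    cvec <- cnew
  }
  if (rel > tol) {
    stopf("FEM solve did not converge: relative change %.3g after %d iterations",
          rel, max_iter)
  }
  if (min(cvec) < -1e-8 * scale) {
    warning(sprintf("negative concentrations at convergence (min %.3g)",
                    min(cvec)), call. = FALSE)
  }
  a <- reaction(cvec)
  resid <- as.vector(K %*% cvec) + m * a
  list(c = cvec, iterations = iter, residual = rel,
       consumption = sum(m * a), flux_in = sum(resid[dir]),
       K = K, m = m)
}

# --- leaf-level wrapper -----------------------------------------------------

pore_nodes <- function(mesh, ph_m, arrangement) {
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  eps <- 1e-9 * mesh$W
  top <- y < eps           # adaxial surface, y = 0
  bot <- y > mesh$H - eps  # abaxial surface, y = T_leaf
  adax <- which(top & x <= ph_m + eps)
  abax <- if (arrangement == "offset") {
    which(bot & x >= mesh$W - ph_m - eps)
  } else {
    which(bot & x <= ph_m + eps)
  }
  c(adax, abax)
}

#' Solve the leaf CO2 transport model
#'
#' Assembles and solves the porous-medium reaction-diffusion model for the
#' given parameters: Dirichlet pore concentration on the pore segments (the
#' adaxial pore at the `x = 0` corner; the abaxial pore at `x = U/2` for the
#' offset arrangement or at `x = 0` for aligned), zero flux elsewhere, and
#' the Farquhar demand of [demand()] as the volumetric sink.
#'
#' @param params A [leaf_model_params()].
#' @param nx,ny Mesh resolution (default 64 x 64).
#' @param tol,max_iter,damping Passed to [fem_solve()].
#' @return List of class `fem_solution`: `mesh`, `c_field` (mol m^-3 per
#'   node), `A_total` and `flux_in` (mol m^-2 s^-1, per unit projected leaf
#'   area), `mass_balance_error` (relative), `iterations`, `residual`,
#'   `params`.
#' @export
solve_leaf <- function(params, nx = 64, ny = 64, tol = 1e-8,
                       max_iter = 200, damping = 1) {
  stopifnot(inherits(params, "leaf_model_params"))
  mesh <- build_mesh(params$U, params$T_leaf, nx, ny,
                     pore_halfwidth = params$pore_halfwidth)
  solve_leaf_on_mesh(params, mesh, tol, max_iter, damping)
}

# variant taking a prebuilt mesh so sweeps can reuse geometry
solve_leaf_on_mesh <- function(params, mesh, tol = 1e-8, max_iter = 200,
                               damping = 1) {
  D_eff <- effective_diffusivity(params$D_air, params$phi_pal, params$tau)
  y_um <- mesh$nodes[, 2] * 1e6
  I <- params$I0 * exp(-params$k_abs * y_um / params$T_leaf)
  J <- electron_transport(I, params$Jmax_vol, params$alpha_light,
                          params$theta_J)
  reaction <- function(c) demand_given_J(c, J, params)
  slope <- function(c) demand_slope_given_J(c, J, params)
  dir <- pore_nodes(mesh, params$pore_halfwidth * 1e-6, params$arrangement)
  sol <- fem_solve(mesh, D_eff, reaction, slope, dir, params$c_pore,
                   tol = tol, max_iter = max_iter, damping = damping)
  A_total <- sol$consumption / mesh$W
  flux_in <- sol$flux_in / mesh$W
  mb <- if (flux_in != 0) abs(A_total - flux_in) / abs(flux_in) else 0
  structure(list(mesh = mesh, c_field = sol$c, A_total = A_total,
                 flux_in = flux_in, mass_balance_error = mb,
                 iterations = sol$iterations, residual = sol$residual,
                 params = params),
            class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf(
    paste0("<fem_solution> A = %.3f umol m^-2 s^-1, %d iterations, ",
           "mass balance %.2g\n"),
    x$A_total * 1e6, x$iterations, x$mass_balance_error))
  invisible(x)
}

#' Photosynthetic advantage of offset stomatal arrangement
#'
#' Solves the leaf model with the abaxial stomate offset (`x = U/2`) and
#' aligned (`x = 0`) and returns the log response ratio
#' `ln(A_offset / A_aligned)` — the coordination advantage. A value of 0.01
#' corresponds to about a 1 % gain. The raw ratio and both assimilation
#' rates are attached as attributes.
#'
#' @param params_base A [leaf_model_params()]; its `arrangement` field is
#'   overridden for each solve.
#' @param nx,ny,tol Passed to [solve_leaf()].
#' @return Numeric scalar (log response ratio) with attributes `ratio`,
#'   `A_offset`, `A_aligned`.
#' @export
coordination_advantage <- function(params_base, nx = 64, ny = 64,
                                   tol = 1e-8) {
  stopifnot(inherits(params_base, "leaf_model_params"))
  mesh <- build_mesh(params_base$U, params_base$T_leaf, nx, ny,
                     pore_halfwidth = params_base$pore_halfwidth)
  p_off <- params_base; p_off$arrangement <- "offset"
  p_al <- params_base; p_al$arrangement <- "aligned"
  A_off <- solve_leaf_on_mesh(p_off, mesh, tol = tol)$A_total
  A_al <- solve_leaf_on_mesh(p_al, mesh, tol = tol)$A_total
  if (A_al <= 0) stopf("aligned assimilation is non-positive (%.3g)", A_al)
  structure(log(A_off / A_al), ratio = A_off / A_al,
            A_offset = A_off, A_aligned = A_al)
}

#' Sweep the coordination advantage over a parameter grid
#'
#' Evaluates [coordination_advantage()] over the Cartesian product of the
#' supplied parameter levels. Failures in individual cells are logged and
#' reported as `NA` rows, not fatal.
#'
#' @param T_leaf,U,phi_pal,I0 Numeric vectors of levels (um, um,
#'   dimensionless, umol m^-2 s^-1).
#' @param params_base Base [leaf_model_params()] supplying all remaining
#'   parameters.
#' @param nx,ny,tol Passed to the solver.
#' @param verbose Print one line per cell.
#' @return data.frame with columns `T_leaf`, `U`, `phi_pal`, `I0`,
#'   `advantage` (log response ratio), `A_offset`, `A_aligned` (mol m^-2
#'   s^-1).
#' @export
parameter_sweep <- function(T_leaf = c(101, 201, 301, 401, 501),
                            U = c(17, 55, 93, 131, 169) * 2,
                            phi_pal = c(0.1, 0.2, 0.3),
                            I0 = c(50, 525, 1000),
                            params_base = leaf_model_params(),
                            nx = 64, ny = 64, tol = 1e-8, verbose = FALSE) {
  grid <- expand.grid(phi_pal = phi_pal, I0 = I0, T_leaf = T_leaf, U = U,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("T_leaf", "U", "phi_pal", "I0")]
  out <- grid
  out$advantage <- out$A_offset <- out$A_aligned <- NA_real_
  mesh_cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(grid))) {
    p <- params_base
    p$T_leaf <- grid$T_leaf[r]; p$U <- grid$U[r]
    p$phi_pal <- grid$phi_pal[r]; p$I0 <- grid$I0[r]
    res <- tryCatch({
      key <- paste(p$U, p$T_leaf)
      if (is.null(mesh_cache[[key]])) {
        mesh_cache[[key]] <- build_mesh(p$U, p$T_leaf, nx, ny,
                                        pore_halfwidth = p$pore_halfwidth)
      }
      mesh <- mesh_cache[[key]]
      p$arrangement <- "offset"
      A_off <- solve_leaf_on_mesh(p, mesh, tol = tol)$A_total
      p$arrangement <- "aligned"
      A_al <- solve_leaf_on_mesh(p, mesh, tol = tol)$A_total
      if (A_al <= 0) stopf("aligned assimilation non-positive")
      c(log(A_off / A_al), A_off, A_al)
    }, error = function(e) {
      message(sprintf("sweep cell %d (T=%g, U=%g, phi=%g, I0=%g) failed: %s",
                      r, grid$T_leaf[r], grid$U[r], grid$phi_pal[r],
                      grid$I0[r], conditionMessage(e)))
      rep(NA_real_, 3)
    })
    out$advantage[r] <- res[1]; out$A_offset[r] <- res[2]
    out$A_aligned[r] <- res[3]
    if (verbose) {
      message(sprintf("T=%g U=%g phi=%g I0=%g -> advantage %.5f",
                      grid$T_leaf[r], grid$U[r], grid$phi_pal[r],
                      grid$I0[r], res[1]))
    }
  }
  out[, c("T_leaf", "U", "phi_pal", "I0", "advantage", "A_offset",
          "A_aligned")]
}
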