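#' Simulate a completely random leaf surface
#'
#' `n` stomata placed i.i.d. uniformly over the window — the null model for
#' all dispersion tests.
#'
#' @param n Number of stomata (>= 0).
#' @param window Length-2 numeric, window width/height in mm.
#' @param seed Optional integer seed; the caller's RNG stream is untouched
#'   when a seed is given.
#' @param ... Metadata passed to [surface_record()].
#' @return A [surface_record()].
#' @export
random_surface <- function(n, window = default_window(), seed = NULL, ...) {
  if (!is_scalar_number(n) || n < 0) stopf("`n` must be a non-negative count")
  with_seed(seed, {
    surface_record(x = runif(n, 0, window[1]), y = runif(n, 0, window[2]),
                   window = window, ...)
  })
}

#' Spacing of the ideal equilateral-triangular grid at a given density
#'
#' For an equilateral triangular lattice with point density `density`
#' (mm^-2), the lattice constant is `U = sqrt(2 / (sqrt(3) * density))`.
#' A density of about 10 mm^-2 corresponds to U = 338 um.
#'
#' @param density Stomatal density (mm^-2), positive.
#' @return Interstomatal distance U in micrometres.
#' @seealso [spacing_to_density()]
#' @export
ideal_grid_spacing <- function(density) {
  if (any(!is.finite(density)) || any(density <= 0)) {
    stopf("`density` must be positive")
  }
  1000 * sqrt(2 / (sqrt(3) * density))
}

#' Density of the ideal equilateral-triangular grid at a given spacing
#'
#' Inverse of [ideal_grid_spacing()]: `density = 2 / (sqrt(3) * U^2)`.
#' @param spacing Interstomatal distance U in micrometres, positive.
#' @return Density in mm^-2.
#' @export
spacing_to_density <- function(spacing) {
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("`spacing` must be positive")
  }
  2 / (sqrt(3) * (spacing / 1000)^2)
}

#' Configuration for the conditioned triangular-grid simulator
#'
#' @param n_target Exact number of in-window stomata to condition on.
#' @param window Window dimensions (mm).
#' @param max_rejections Rejection budget for the conditioning loop.
#' @param randomize_rotation Rotate the lattice uniformly in `[0, 60)`
#'   degrees in addition to the random translation (default `TRUE`).
#'   Translation-only randomisation (`FALSE`) keeps rows parallel to x, but
#'   then the in-window count moves in whole-row jumps and exact-count
#'   conditioning can be infeasible on square windows except at small
#'   counts.
#' @param seed Optional integer seed.
#' @return A list of class `grid_sim_config`.
#' @export
grid_sim_config <- function(n_target, window = default_window(),
                            max_rejections = 100000L,
                            randomize_rotation = TRUE, seed = NULL) {
  if (!is_scalar_number(n_target) || n_target < 1) {
    stopf("`n_target` must be a positive count")
  }
  if (!is_scalar_number(max_rejections) || max_rejections < 1) {
    stopf("`max_rejections` must be >= 1")
  }
  structure(list(n_target = as.integer(n_target), window = window,
                 max_rejections = as.integer(max_rejections),
                 randomize_rotation = isTRUE(randomize_rotation),
                 seed = seed),
            class = "grid_sim_config")
}

# All in-window points of the triangular lattice with constant `s` and
# translation (tx, ty): points (tx + i*s + j*s/2, ty + j*dy), dy = s*sqrt3/2.
lattice_in_window <- function(s, window, tx, ty) {
  dy <- s * sqrt(3) / 2
  xs <- numeric(); ys <- numeric()
  jlo <- ceiling(-ty / dy); jhi <- floor((window[2] - ty) / dy)
  if (jhi >= jlo) {
    for (j in jlo:jhi) {
      ox <- tx + j * s / 2
      ilo <- ceiling(-ox / s); ihi <- floor((window[1] - ox) / s)
      if (ihi < ilo) next
      xs <- c(xs, ox + (ilo:ihi) * s)
      ys <- c(ys, rep(ty + j * dy, ihi - ilo + 1L))
    }
  }
  list(x = xs, y = ys)
}

#' Simulate an ideally dispersed surface conditioned on its stomatal count
#'
#' Draws a plausible density (`lambda ~ Gamma(n, 1)`, then a Poisson count —
#' the posterior of the rate under a flat prior), lays down an equilateral
#' triangular lattice at that density with a uniformly random translation
#' (and optional rotation), and accepts the draw only when the window
#' contains exactly `n_target` points. This integrates over density
#' uncertainty while matching the observed count, and is the "ideal"
#' reference of the dispersion index.
#'
#' @param config A [grid_sim_config()].
#' @return A [surface_record()] with exactly `n_target` stomata. The
#'   attributes `tries` (rejection count) and `spacing` (accepted lattice
#'   constant, mm) report the conditioning diagnostics.
#' @export
triangular_grid_surface <- function(config) {
  stopifnot(inherits(config, "grid_sim_config"))
  n <- config$n_target
  w <- config$window
  with_seed(config$seed, {
    res <- cpp_tri_grid_conditioned(n, w[1], w[2], config$max_rejections,
                                    config$randomize_rotation)
    if (is.null(res$x)) {
      stopf(paste0("triangular grid conditioning failed: 0 acceptances in ",
                   "%d tries (acceptance rate < %.2g)"),
            config$max_rejections, 1 / config$max_rejections)
    }
    rec <- surface_record(res$x, res$y, window = w)
    attr(rec, "tries") <- res$tries
    attr(rec, "spacing") <- res$spacing
    attr(rec, "translation") <- c(res$tx, res$ty)
    attr(rec, "theta") <- res$theta
    rec
  })
}

#' Simulate an overdispersed (hard-core) surface
#'
#' Sequential dart throwing: uniform candidates are accepted when at least
#' `r_min` away from all previously accepted stomata. With `r_min = 0` this
#' is identical in distribution to [random_surface()]; moderate `r_min`
#' yields the "overdispersed but far from ideal" patterns seen on real
#' leaves.
#'
#' @param n Number of stomata.
#' @param window Window dimensions (mm).
#' @param r_min Inhibition distance (mm), >= 0.
#' @param seed Optional integer seed.
#' @param max_tries Total candidate budget (default `1e4 * n`).
#' @param ... Metadata passed to [surface_record()].
#' @return A [surface_record()].
#' @export
hardcore_surface <- function(n, window = default_window(), r_min = 0,
                             seed = NULL, max_tries = 1e4 * n, ...) {
  if (!is_scalar_number(n) || n < 0) stopf("`n` must be a non-negative count")
  if (r_min < 0) stopf("`r_min` must be >= 0")
  with_seed(seed, {
    res <- cpp_hardcore(n, window[1], window[2], r_min, max_tries)
    if (is.null(res$x)) {
      stopf("hard-core packing infeasible: placed %d of %d points in %g tries",
            res$placed, n, res$tries)
    }
    surface_record(res$x, res$y, window = window, ...)
  })
}

#' Configuration for paired-surface simulation
#'
#' @param n_ab,n_ad Stomatal counts on the abaxial and adaxial surface.
#' @param window Window dimensions (mm).
#' @param mode `"independent"` (two independent random surfaces — the null of
#'   the coordination test), `"aligned"` (identical coordinates on both
#'   surfaces), or `"offset_coordinated"` (both surfaces on the same
#'   triangular lattice, the adaxial copy translated by half the lattice
#'   vector `a1 + a2` — the idealised coordinated pattern).
#' @param seed Optional integer seed.
#' @return A list of class `pair_sim_config`.
#' @export
pair_sim_config <- function(n_ab, n_ad = n_ab, window = default_window(),
                            mode = c("independent", "offset_coordinated",
                                     "aligned"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (n_ab < 0 || n_ad < 0) stopf("counts must be >= 0")
  structure(list(n_ab = as.integer(n_ab), n_ad = as.integer(n_ad),
                 window = window, mode = mode, seed = seed),
            class = "pair_sim_config")
}

#' Simulate a pair of leaf surfaces
#'
#' See [pair_sim_config()] for the three generation modes. In
#' `offset_coordinated` mode the abaxial surface is a conditioned triangular
#' grid with exactly `n_ab` stomata and the adaxial surface is the same
#' lattice translated by `(a1 + a2) / 2 = (3s/4, dy/2)`; its in-window count
#' is whatever the translated lattice yields (close to `n_ab`), so `n_ad` is
#' ignored in that mode.
#'
#' @param config A [pair_sim_config()].
#' @return A [paired_surfaces()].
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "pair_sim_config"))
  w <- config$window
  with_seed(config$seed, {
    if (config$mode == "independent") {
      ab <- random_surface(config$n_ab, w, surface = "abaxial")
      ad <- random_surface(config$n_ad, w, surface = "adaxial")
    } else if (config$mode == "aligned") {
      ab <- random_surface(config$n_ab, w, surface = "abaxial")
      ad <- surface_record(ab$stomata$x, ab$stomata$y, window = w,
                           surface = "adaxial")
    } else {
      ab <- triangular_grid_surface(grid_sim_config(config$n_ab, w))
      s <- attr(ab, "spacing")
      dy <- s * sqrt(3) / 2
      tr <- attr(ab, "translation")
      # regenerate the full lattice shifted (in the lattice frame) by
      # (a1 + a2)/2 = (3s/4, dy/2)
      pts <- cpp_lattice_points(s, attr(ab, "theta"), tr[1] + 3 * s / 4,
                                tr[2] + dy / 2, w[1], w[2])
      ad <- surface_record(pts$x, pts$y, window = w, surface = "adaxial")
    }
    ab$surface <- "abaxial"; ab$surface_id <- "L1_abaxial"
    paired_surfaces(ab, ad)
  })
}

#' Attach synthetic guard-cell lengths with a planted zone-area association
#'
#' Generates `length_i = alpha + beta * zone_area_i + Normal(0, sigma)`,
#' where `zone_area_i` is the Voronoi supply-zone area of stomate i (from
#' [voronoi_zones()]). Used to test recovery of the stomatal length /
#' supply-zone association with a known ground truth. Lengths are truncated
#' below at 0.1 um to stay positive.
#'
#' @param record A [surface_record()] with at least one stomate.
#' @param alpha Intercept (um). Default 20 um, a typical guard-cell length.
#' @param beta Slope (um per mm^2 of zone area).
#' @param sigma Residual standard deviation (um).
#' @param seed Optional integer seed.
#' @return The record with the `length` column filled in.
#' @export
attach_lengths <- function(record, alpha = 20, beta = 800, sigma = 3,
                           seed = NULL) {
  stopifnot(inherits(record, "surface_record"))
  if (n_stomata(record) < 1) stopf("record has no stomata")
  zones <- voronoi_zones(record)
  with_seed(seed, {
    len <- alpha + beta * zones$areas +
      rnorm(n_stomata(record), 0, sigma)
    record$stomata$length <- pmax(len, 0.1)
    record
  })
}
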