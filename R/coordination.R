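#' Nearest-stomatal-distance (NSD) raster
#'
#' For each pixel centre of a regular raster over the window, the squared
#' Euclidean distance (mm^2) to the nearest stomatal centroid. No
#' wrap-around; distances are to centroids, ignoring pore extent.
#'
#' @param record A [surface_record()] with >= 1 stomate.
#' @param resolution Integer pixel counts `(nx, ny)`; a scalar is recycled.
#'   Default 64 x 64 (about 9.7 um pixels on the default window).
#' @param squared Return squared distance (default, matching the definition
#'   of NSD used in the coordination test) or plain distance.
#' @return Object of class `nsd_map`: list with `values` (matrix, `ny` rows
#'   by `nx` columns; rows indexed by y from the bottom), `pixel_size`,
#'   `resolution`, `window`.
#' @export
nsd_map <- function(record, resolution = 64, squared = TRUE) {
  stopifnot(inherits(record, "surface_record"))
  if (n_stomata(record) < 1) stopf("need at least 1 stomate")
  if (length(resolution) == 1L) resolution <- rep(resolution, 2L)
  nx <- as.integer(resolution[1]); ny <- as.integer(resolution[2])
  if (nx < 1 || ny < 1) stopf("resolution must be positive")
  w <- record$window
  px_size <- c(w[1] / nx, w[2] / ny)
  cx <- (seq_len(nx) - 0.5) * px_size[1]
  cy <- (seq_len(ny) - 0.5) * px_size[2]
  grid_x <- rep(cx, times = ny)
  grid_y <- rep(cy, each = nx)
  v <- cpp_nsd_sq(grid_x, grid_y, record$stomata$x, record$stomata$y)
  if (!squared) v <- sqrt(v)
  structure(list(values = matrix(v, nrow = ny, ncol = nx, byrow = TRUE),
                 resolution = c(nx, ny), pixel_size = px_size,
                 window = w, squared = squared),
            class = "nsd_map")
}

#' @export
print.nsd_map <- function(x, ...) {
  cat(sprintf("<nsd_map> %d x %d pixels (%.2f x %.2f um), %s distance\n",
              x$resolution[1], x$resolution[2], 1000 * x$pixel_size[1],
              1000 * x$pixel_size[2],
              if (x$squared) "squared" else "plain"))
  invisible(x)
}

#' Pixel-wise correlation of paired NSD rasters
#'
#' Pearson correlation between the flattened NSD-squared rasters of the two
#' surfaces of a leaf. Coordinated (offset) surfaces give negative values: a
#' pixel far from any stomate on one surface is close to one on the other.
#'
#' @param pair A [paired_surfaces()]; both surfaces non-empty.
#' @param resolution Raster resolution, as in [nsd_map()].
#' @param squared Correlate squared (default) or plain distances.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
nsd_correlation <- function(pair, resolution = 64, squared = TRUE) {
  stopifnot(inherits(pair, "paired_surfaces"))
  a <- nsd_map(pair$abaxial, resolution, squared = squared)$values
  b <- nsd_map(pair$adaxial, resolution, squared = squared)$values
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stopf("zero variance in an NSD raster")
  }
  cor(as.vector(a), as.vector(b))
}

#' Monte-Carlo test for abaxial-adaxial coordination
#'
#' Compares the observed NSD correlation of a leaf pair against a null
#' distribution from `n_sim` synthetic pairs of independent random-uniform
#' surfaces with the observed per-surface stomatal counts. The alternative
#' is *negative* correlation (coordination), so the one-tailed add-one
#' p-value is `p = (1 + #{null_r <= r_obs}) / (1 + n_sim)`. The opposite
#' tail (alignment, positive correlation) is available via
#' `alternative = "positive"`.
#'
#' @param pair A [paired_surfaces()].
#' @param n_sim Number of synthetic pairs (default 1000).
#' @param resolution Raster resolution, as in [nsd_map()].
#' @param seed Optional integer seed.
#' @param alternative `"negative"` (default) or `"positive"`.
#' @return List of class `coordination_result`: `leaf_id`, `r_observed`,
#'   `null_r`, `p_raw`, `p_adjusted` (`NA` until batch adjustment), `n_sim`.
#' @export
coordination_test <- function(pair, n_sim = 1000, resolution = 64,
                              seed = NULL,
                              alternative = c("negative", "positive")) {
  stopifnot(inherits(pair, "paired_surfaces"))
  alternative <- match.arg(alternative)
  r_obs <- nsd_correlation(pair, resolution)
  n_ab <- n_stomata(pair$abaxial)
  n_ad <- n_stomata(pair$adaxial)
  w <- pair$abaxial$window
  with_seed(seed, {
    null_r <- vapply(seq_len(n_sim), function(i) {
      sim <- simulate_pair(pair_sim_config(n_ab, n_ad, window = w,
                                           mode = "independent"))
      nsd_correlation(sim, resolution)
    }, 0)
    p <- if (alternative == "negative") {
      (1 + sum(null_r <= r_obs)) / (1 + n_sim)
    } else {
      mc_p_greater(r_obs, null_r)
    }
    structure(list(leaf_id = pair$leaf_id, r_observed = r_obs,
                   null_r = null_r, p_raw = p, p_adjusted = NA_real_,
                   n_sim = as.integer(n_sim), alternative = alternative),
              class = "coordination_result")
  })
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf(
    "<coordination_result> leaf %s: r = %.3f, p = %.4g (%s tail, n_sim %d)\n",
    x$leaf_id, x$r_observed, x$p_raw, x$alternative, x$n_sim))
  invisible(x)
}

#' Coordination tests for a batch of leaf pairs with FDR control
#'
#' Runs [coordination_test()] on every pair; all pair tests form one
#' Benjamini-Hochberg adjustment family.
#'
#' @param pairs List of [paired_surfaces()].
#' @param n_sim,resolution,alternative Passed to [coordination_test()].
#' @param seed Optional master seed; per-pair seeds are derived from it.
#' @return data.frame with one row per leaf pair.
#' @export
coordination_batch <- function(pairs, n_sim = 1000, resolution = 64,
                               seed = NULL, alternative = "negative") {
  res <- lapply(seq_along(pairs), function(i) {
    coordination_test(pairs[[i]], n_sim = n_sim, resolution = resolution,
                      seed = derive_seed(seed, i),
                      alternative = alternative)
  })
  out <- do.call(rbind, lapply(res, function(r) {
    data.frame(leaf_id = r$leaf_id, r_observed = r$r_observed,
               null_r_mean = mean(r$null_r), p_raw = r$p_raw,
               n_sim = r$n_sim)
  }))
  out$p_adjusted <- bh_adjust(out$p_raw)
  out
}
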