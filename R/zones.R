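# Clip a convex polygon (matrix with columns x, y, vertices in order) by the
# half-plane a1*x + a2*y <= b (Sutherland-Hodgman, convex case).
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  side <- poly %*% a - b
  if (all(side <= 0)) return(poly)
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    si <- side[i]; sj <- side[j]
    if (si <= 0) {
      keep_x <- c(keep_x, poly[i, 1]); keep_y <- c(keep_y, poly[i, 2])
    }
    if ((si < 0 && sj > 0) || (si > 0 && sj < 0)) {
      t <- si / (si - sj)
      keep_x <- c(keep_x, poly[i, 1] + t * (poly[j, 1] - poly[i, 1]))
      keep_y <- c(keep_y, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
    }
  }
  cbind(keep_x, keep_y, deparse.level = 0)
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Voronoi stomatal zones clipped to the window
#'
#' The stomatal zone of stomate i is the part of the leaf surface closer to
#' it than to any other stomate — its Voronoi cell, clipped to the
#' rectangular image window (cells of boundary stomata are closed by the
#' clip, not discarded). Cells are computed by intersecting the window with
#' the perpendicular-bisector half-planes of each neighbour; neighbours
#' farther than twice the cell's current maximal extent cannot cut and are
#' skipped.
#'
#' @param record A [surface_record()] with >= 1 stomate and no duplicated
#'   centroids.
#' @return Object of class `zone_set`: `surface_id`, `polygons` (list of
#'   two-column vertex matrices, mm), `areas` (mm^2, aligned with the
#'   stomata ordering).
#' @export
voronoi_zones <- function(record) {
  stopifnot(inherits(record, "surface_record"))
  n <- n_stomata(record)
  if (n < 1) stopf("need at least 1 stomate")
  pts <- as.matrix(record$stomata[, c("x", "y")])
  dup <- duplicated(pts)
  if (any(dup)) {
    stopf("exactly duplicated centroids at row(s): %s",
          paste(which(dup), collapse = ", "))
  }
  w <- record$window
  window_poly <- cbind(c(0, w[1], w[1], 0), c(0, 0, w[2], w[2]))
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    if (n == 1) { polys[[i]] <- window_poly; next }
    d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
    ord <- order(d2)[-1]
    poly <- window_poly
    for (j in ord) {
      # prune: bisector at distance d/2 cannot cut a cell contained in a
      # disc of radius < d/2 around p
      r2max <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
      if (d2[j] >= 4 * r2max) break
      q <- pts[j, ]
      a <- q - p                     # a . x <= a . (p+q)/2
      poly <- clip_halfplane(poly, a, sum(a * (p + q) / 2))
    }
    polys[[i]] <- poly
  }
  structure(list(surface_id = record$surface_id, polygons = polys,
                 areas = vapply(polys, polygon_area, 0)),
            class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %s: %d zones, total area %.4f mm^2\n",
              x$surface_id, length(x$polygons), sum(x$areas)))
  invisible(x)
}

# Stomata-level table across records: one row per stomate with metadata,
# guard-cell length and Voronoi zone area. Stomata without lengths dropped.
zone_table <- function(records) {
  rows <- lapply(records, function(r) {
    if (n_stomata(r) < 1) return(NULL)
    z <- voronoi_zones(r)
    data.frame(plant_id = r$plant_id, leaf_id = r$leaf_id,
               surface = r$surface, treatment = r$treatment,
               length = r$stomata$length, zone_area = z$areas)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$length), , drop = FALSE]
}

fit_slope <- function(tab, direction) {
  if (direction == "area_on_length") {
    if (stats::var(tab$length) == 0) stopf("degenerate predictor variance")
    unname(coef(lm(zone_area ~ length, data = tab))[2])
  } else {
    if (stats::var(tab$zone_area) == 0) stopf("degenerate predictor variance")
    unname(coef(lm(length ~ zone_area, data = tab))[2])
  }
}

#' Stomatal length / supply-zone association with hierarchical bootstrap
#'
#' Within each (treatment, surface) group, fits an ordinary least-squares
#' regression between guard-cell length and Voronoi zone area and attaches a
#' 95 % percentile confidence interval from a hierarchical bootstrap that
#' respects the sampling design: plants are resampled with replacement,
#' then leaves within each sampled plant, and the regression is refit on the
#' pooled stomata.
#'
#' The default direction regresses zone area on length (slope in mm^2 per
#' um); `direction = "length_on_area"` reverses it (um per mm^2), which is
#' the unbiased direction when lengths are generated from zone areas as in
#' [attach_lengths()].
#'
#' @param records List of [surface_record()]s with measured lengths.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param direction `"area_on_length"` (default) or `"length_on_area"`.
#' @param conf Interval coverage (default 0.95).
#' @return data.frame with one row per (treatment, surface) group: `slope`,
#'   `ci_low`, `ci_high`, `n_stomata`, `n_leaves`, `n_plants`, `n_boot`.
#' @export
zone_length_slope <- function(records, n_boot = 1000, seed = NULL,
                              direction = c("area_on_length",
                                            "length_on_area"),
                              conf = 0.95) {
  direction <- match.arg(direction)
  tab <- zone_table(records)
  if (is.null(tab) || nrow(tab) == 0) stopf("no stomata with lengths")
  groups <- split(tab, list(tab$treatment, tab$surface), drop = TRUE)
  with_seed(seed, {
    out <- lapply(groups, function(g) {
      if (nrow(g) < 3) stopf("fewer than 3 measured stomata in a group")
      plants <- unique(g$plant_id)
      if (length(plants) < 2) {
        stopf("need >= 2 plants per group for the hierarchical bootstrap")
      }
      slope <- fit_slope(g, direction)
      boot <- vapply(seq_len(n_boot), function(b) {
        ps <- sample(plants, replace = TRUE)
        pieces <- lapply(ps, function(p) {
          gp <- g[g$plant_id == p, , drop = FALSE]
          lv <- unique(gp$leaf_id)
          lsel <- if (length(lv) > 1) sample(lv, replace = TRUE) else lv
          do.call(rbind, lapply(lsel, function(l) {
            gp[gp$leaf_id == l, , drop = FALSE]
          }))
        })
        gb <- do.call(rbind, pieces)
        if (stats::var(gb$length) == 0 || stats::var(gb$zone_area) == 0) {
          return(NA_real_)
        }
        fit_slope(gb, direction)
      }, 0)
      boot <- boot[is.finite(boot)]
      qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                     names = FALSE)
      data.frame(treatment = g$treatment[1], surface = g$surface[1],
                 slope = slope, ci_low = qs[1], ci_high = qs[2],
                 n_stomata = nrow(g), n_leaves = length(unique(g$leaf_id)),
                 n_plants = length(plants), n_boot = length(boot))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}
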