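#' Generate a complete synthetic study
#'
#' Emits a synthetic data set mirroring the design scale of the motivating
#' study: `n_pairs` leaves split evenly across three light treatments, each
#' leaf contributing an abaxial and an adaxial surface on the standard
#' 0.386 mm^2 window. Surfaces are hard-core (overdispersed) point patterns
#' whose densities differ by treatment, the adaxial density is a fixed
#' fraction of the abaxial one, and guard-cell lengths are generated with a
#' planted positive association to the Voronoi zone area
#' (see [attach_lengths()]).
#'
#' @param n_pairs Number of leaves (default 66, i.e. 132 surfaces).
#' @param treatments Treatment labels cycled over leaves.
#' @param density_ab Named abaxial densities per treatment (mm^-2).
#' @param ad_ratio Adaxial/abaxial density ratio (default 0.44).
#' @param plants_per_treatment Leaves are assigned round-robin to this many
#'   plants within each treatment.
#' @param r_min_factor Hard-core inhibition distance as a multiple of the
#'   expected nearest-neighbour distance at the surface's density.
#' @param window Window dimensions (mm).
#' @param seed Master seed; all per-surface seeds derive from it, so equal
#'   seeds give byte-identical output files.
#' @param out_dir Optional directory: writes `surfaces.csv` and
#'   `manifest.json` (seed and generator parameters).
#' @return List with `records` (all surfaces), `pairs`, `unpaired`,
#'   invisibly when `out_dir` is given.
#' @export
run_fixture <- function(n_pairs = 66,
                        treatments = c("low", "medium", "high"),
                        density_ab = c(low = 150, medium = 200, high = 400),
                        ad_ratio = 0.44, plants_per_treatment = 4,
                        r_min_factor = 0.7, window = default_window(),
                        seed = 1, out_dir = NULL) {
  if (n_pairs == 0) {
    warning("empty study: n_pairs = 0", call. = FALSE)
    return(list(records = list(), pairs = list(), unpaired = character()))
  }
  area <- window[1] * window[2]
  trt <- rep_len(treatments, n_pairs)
  plant <- paste0(trt, "_p",
                  (stats::ave(seq_len(n_pairs), trt, FUN = seq_along) - 1) %%
                    plants_per_treatment + 1)
  records <- list()
  k <- 0L
  for (i in seq_len(n_pairs)) {
    leaf <- sprintf("leaf%02d", i)
    for (side in c("abaxial", "adaxial")) {
      k <- k + 1L
      s_seed <- derive_seed(seed, k)
      dens <- density_ab[[trt[i]]] * if (side == "adaxial") ad_ratio else 1
      n <- max(2L, with_seed(s_seed, rpois(1, dens * area)))
      r_min <- r_min_factor * expected_nn_distance(area, n)
      rec <- hardcore_surface(n, window, r_min = r_min,
                              seed = derive_seed(seed, k + 10000L),
                              surface = side, plant_id = plant[i],
                              leaf_id = leaf, treatment = trt[i])
      rec <- attach_lengths(rec, seed = derive_seed(seed, k + 20000L))
      records[[k]] <- rec
    }
  }
  paired <- pair_surfaces(records)
  out <- list(records = records, pairs = paired$pairs,
              unpaired = paired$unpaired)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_surfaces(records, file.path(out_dir, "surfaces.csv"))
    manifest <- list(seed = seed, n_pairs = n_pairs,
                     treatments = treatments,
                     density_ab = as.list(density_ab), ad_ratio = ad_ratio,
                     plants_per_treatment = plants_per_treatment,
                     r_min_factor = r_min_factor, window = window)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on a set of surfaces: per-surface dispersion
#' analysis with Benjamini-Hochberg adjustment across all surfaces (one
#' family), per-pair coordination tests with adjustment across all pairs (a
#' second family), the stomatal length / zone-area association per
#' (treatment, surface) group, two-way ANOVAs of density and dispersion
#' index on light x surface, and (optionally) the FEM coordination-advantage
#' sweep.
#'
#' @param records List of [surface_record()]s (e.g. from [run_fixture()] or
#'   [read_surfaces()]).
#' @param n_sim Monte-Carlo simulations per dispersion/coordination test.
#' @param resolution NSD raster resolution.
#' @param n_boot Bootstrap replicates for the zone-length slopes.
#' @param fem_levels Levels per FEM sweep dimension (`NULL` skips the
#'   sweep); level grids are evenly spaced over T_leaf 101-501 um,
#'   U 34-338 um, phi 0.1-0.3, I0 50-1000.
#' @param nx,ny FEM mesh resolution.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional directory for CSV outputs and the run manifest.
#' @return List with `dispersion`, `coordination`, `zone_slopes`,
#'   `anova_density`, `anova_di`, `fem_sweep` (or `NULL`).
#' @export
run_all <- function(records, n_sim = 1000, resolution = 64, n_boot = 1000,
                    fem_levels = NULL, nx = 64, ny = 64, seed = 1,
                    out_dir = NULL) {
  paired <- pair_surfaces(records)
  stages <- list()
  fail <- character()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      message(sprintf("stage %s failed: %s", name, conditionMessage(e)))
      fail <<- c(fail, name)
      NULL
    })
  }
  disp <- run_stage("dispersion", {
    d <- dispersion_batch(records, n_sim = n_sim,
                          seed = derive_seed(seed, 1))
    meta <- do.call(rbind, lapply(records, function(r) {
      data.frame(surface_id = r$surface_id, treatment = r$treatment,
                 surface = r$surface, density = stomatal_density(r))
    }))
    merge(meta, d, by = "surface_id", sort = FALSE)
  })
  coord <- run_stage("coordination", {
    coordination_batch(paired$pairs, n_sim = n_sim,
                       resolution = resolution,
                       seed = derive_seed(seed, 2))
  })
  slopes <- run_stage("zones", {
    zone_length_slope(records, n_boot = n_boot,
                      seed = derive_seed(seed, 3))
  })
  anova_density <- run_stage("anova_density", {
    two_way_anova(disp$density, disp$treatment, disp$surface,
                  names_ab = c("treatment", "surface"))
  })
  anova_di <- run_stage("anova_di", {
    two_way_anova(disp$dispersion_index, disp$treatment, disp$surface,
                  names_ab = c("treatment", "surface"))
  })
  fem <- if (!is.null(fem_levels)) {
    run_stage("fem_sweep", {
      lv <- function(lo, hi) seq(lo, hi, length.out = fem_levels)
      parameter_sweep(T_leaf = lv(101, 501), U = lv(34, 338),
                      phi_pal = lv(0.1, 0.3), I0 = lv(50, 1000),
                      nx = nx, ny = ny)
    })
  } else NULL
  out <- list(dispersion = disp, coordination = coord,
              zone_slopes = slopes, anova_density = anova_density,
              anova_di = anova_di, fem_sweep = fem,
              failed_stages = fail)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("dispersion", "coordination", "zone_slopes",
                 "anova_density", "anova_di", "fem_sweep")) {
      if (!is.null(out[[nm]])) {
        write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                  row.names = FALSE)
      }
    }
    manifest <- list(seed = seed, n_sim = n_sim, resolution = resolution,
                     n_boot = n_boot, fem_levels = fem_levels,
                     n_surfaces = length(records),
                     n_pairs = length(paired$pairs),
                     unpaired = paired$unpaired, failed_stages = fail)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
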