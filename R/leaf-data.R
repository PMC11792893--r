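#' Construct a leaf-surface record
#'
#' A `surface_record` holds everything measured on one imaged (or simulated)
#' leaf surface: the rectangular observation window and the stomatal
#' centroids, plus optional guard-cell lengths and study metadata. All
#' coordinates are in mm with the origin at the lower-left window corner
#' (x rightward, y upward); guard-cell lengths are in micrometres.
#'
#' @param x,y Numeric vectors of stomatal centroid coordinates (mm).
#' @param window Numeric length-2 vector, window width and height in mm.
#'   Default is the square imaging field of 0.386 mm^2 (side 0.6213 mm).
#' @param length Optional numeric vector of guard-cell lengths (um); may
#'   contain `NA` for unmeasured stomata.
#' @param surface `"abaxial"` or `"adaxial"`.
#' @param surface_id,plant_id,leaf_id,treatment Free-text metadata labels.
#' @return An object of class `surface_record`.
#' @examples
#' s <- surface_record(x = c(0.1, 0.3), y = c(0.2, 0.5))
#' stomatal_density(s)
#' @export
surface_record <- function(x, y, window = default_window(),
                           length = NULL, surface = "abaxial",
                           surface_id = NULL, plant_id = "P1",
                           leaf_id = "L1", treatment = "medium") {
  stopifnot(length(x) == length(y))
  if (!is.numeric(window) || length(window) != 2L || any(window <= 0)) {
    stopf("`window` must be two positive lengths (mm)")
  }
  surface <- match.arg(surface, c("abaxial", "adaxial"))
  if (length(x) > 0) {
    bad <- which(x < 0 | x > window[1] | y < 0 | y > window[2] |
                   !is.finite(x) | !is.finite(y))
    if (length(bad) > 0) {
      stopf("stomata outside the window or non-finite at position(s) %s",
            paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  if (is.null(length)) length <- rep(NA_real_, length(x))
  stopifnot(length(length) == length(x))
  if (any(!is.na(length) & length <= 0)) {
    stopf("guard-cell lengths must be positive")
  }
  if (is.null(surface_id)) surface_id <- paste(leaf_id, surface, sep = "_")
  structure(
    list(surface_id = as.character(surface_id),
         plant_id = as.character(plant_id),
         leaf_id = as.character(leaf_id),
         surface = surface,
         treatment = as.character(treatment),
         window = as.numeric(window),
         stomata = data.frame(x = as.numeric(x), y = as.numeric(y),
                              length = as.numeric(length))),
    class = "surface_record")
}

#' Default observation window
#'
#' The square imaging field used throughout: area 0.386 mm^2, i.e. side
#' sqrt(0.386) = 0.6213 mm.
#' @return Numeric length-2 vector (mm).
#' @export
default_window <- function() rep(sqrt(0.386), 2L)

#' @export
print.surface_record <- function(x, ...) {
  cat(sprintf("<surface_record> %s (%s, %s light)\n", x$surface_id,
              x$surface, x$treatment))
  cat(sprintf("  window %.4f x %.4f mm, %d stomata (density %.1f mm^-2)\n",
              x$window[1], x$window[2], nrow(x$stomata),
              stomatal_density(x)))
  invisible(x)
}

n_stomata <- function(record) nrow(record$stomata)

window_area <- function(record) record$window[1] * record$window[2]

#' Stomatal density of a surface
#'
#' Count of stomata divided by the window area.
#' @param record A [surface_record()].
#' @return Density in stomata per mm^2.
#' @export
stomatal_density <- function(record) {
  stopifnot(inherits(record, "surface_record"))
  n_stomata(record) / window_area(record)
}

#' Pair the two surfaces of one leaf
#'
#' @param abaxial,adaxial `surface_record`s of the same leaf. Windows must
#'   have identical dimensions (both surfaces are expressed in one shared
#'   coordinate frame).
#' @param mirror_abaxial_x Flip the abaxial x-coordinates (`x <- width - x`)
#'   before pairing, for data digitised in a mirrored frame. Default `FALSE`:
#'   no registration convention is imposed.
#' @return An object of class `paired_surfaces`.
#' @export
paired_surfaces <- function(abaxial, adaxial, mirror_abaxial_x = FALSE) {
  stopifnot(inherits(abaxial, "surface_record"),
            inherits(adaxial, "surface_record"))
  if (abaxial$surface != "abaxial" || adaxial$surface != "adaxial") {
    stopf("surfaces must be labelled abaxial and adaxial respectively")
  }
  if (!isTRUE(all.equal(abaxial$window, adaxial$window))) {
    stopf("leaf %s: abaxial and adaxial windows differ", abaxial$leaf_id)
  }
  if (isTRUE(mirror_abaxial_x)) {
    abaxial$stomata$x <- abaxial$window[1] - abaxial$stomata$x
  }
  structure(list(leaf_id = abaxial$leaf_id, abaxial = abaxial,
                 adaxial = adaxial),
            class = "paired_surfaces")
}

#' @export
print.paired_surfaces <- function(x, ...) {
  cat(sprintf("<paired_surfaces> leaf %s: %d abaxial / %d adaxial stomata\n",
              x$leaf_id, n_stomata(x$abaxial), n_stomata(x$adaxial)))
  invisible(x)
}

#' Match abaxial and adaxial records into leaf pairs
#'
#' Every leaf id with exactly one abaxial and one adaxial record becomes a
#' [paired_surfaces()]; leaves missing one surface are reported in the
#' `unpaired` element. Pairing is order-invariant (pairs are sorted by leaf
#' id).
#'
#' @param records List of [surface_record()]s.
#' @param mirror_abaxial_x Passed to [paired_surfaces()].
#' @return List with elements `pairs` (list of `paired_surfaces`) and
#'   `unpaired` (character vector of leaf ids).
#' @export
pair_surfaces <- function(records, mirror_abaxial_x = FALSE) {
  stopifnot(all(vapply(records, inherits, TRUE, "surface_record")))
  keys <- vapply(records, function(r) paste(r$leaf_id, r$surface), "")
  if (anyDuplicated(keys)) {
    stopf("duplicate (leaf_id, surface) records: %s",
          paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  leaves <- sort(unique(vapply(records, `[[`, "", "leaf_id")))
  pairs <- list(); unpaired <- character()
  for (lf in leaves) {
    recs <- records[vapply(records, `[[`, "", "leaf_id") == lf]
    sides <- vapply(recs, `[[`, "", "surface")
    if (all(c("abaxial", "adaxial") %in% sides)) {
      pairs[[lf]] <- paired_surfaces(recs[[which(sides == "abaxial")]],
                                     recs[[which(sides == "adaxial")]],
                                     mirror_abaxial_x = mirror_abaxial_x)
    } else {
      unpaired <- c(unpaired, lf)
    }
  }
  list(pairs = unname(pairs), unpaired = unpaired)
}

default_schema <- function() {
  list(plant_id = "plant_id", leaf_id = "leaf_id", surface = "surface",
       treatment = "treatment", x = "x_mm", y = "y_mm",
       length = "length_um", window_width = "window_width_mm",
       window_height = "window_height_mm")
}

#' Read leaf-surface tables from CSV
#'
#' The expected layout is long format: one row per stomate, with columns for
#' plant, leaf, surface, treatment, coordinates, guard-cell length and window
#' dimensions (see `amphistom:::default_schema()` for the default column
#' names). A surface with zero stomata is encoded as a single row with `NA`
#' coordinates.
#'
#' @param path CSV file path.
#' @param schema Named list mapping the fields above to column names in the
#'   file; defaults are used for omitted entries.
#' @param coord_unit Unit of the coordinate columns, `"mm"` (default) or
#'   `"um"`; micrometre input is converted to mm.
#' @return List of [surface_record()]s, one per (leaf, surface).
#' @export
read_surfaces <- function(path, schema = list(), coord_unit = c("mm", "um")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  coord_unit <- match.arg(coord_unit)
  sc <- utils::modifyList(default_schema(), schema)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(sc[c("plant_id", "leaf_id", "surface", "x", "y",
                      "window_width", "window_height")], use.names = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stopf("schema error: missing column(s) %s",
          paste(missing_cols, collapse = ", "))
  }
  scale <- if (coord_unit == "um") 1e-3 else 1
  key <- paste(df[[sc$leaf_id]], df[[sc$surface]])
  out <- lapply(split(seq_len(nrow(df)), factor(key, unique(key))),
                function(idx) {
    sub <- df[idx, , drop = FALSE]
    empty <- all(is.na(sub[[sc$x]]))
    if (empty && nrow(sub) > 1) {
      stopf("surface %s: multiple rows but no coordinates", key[idx[1]])
    }
    lengths <- if (sc$length %in% names(sub)) sub[[sc$length]] else NULL
    treatment <- if (sc$treatment %in% names(sub)) {
      sub[[sc$treatment]][1]
    } else "unknown"
    rec <- tryCatch(
      surface_record(
        x = if (empty) numeric() else sub[[sc$x]] * scale,
        y = if (empty) numeric() else sub[[sc$y]] * scale,
        window = c(sub[[sc$window_width]][1], sub[[sc$window_height]][1]) *
          scale,
        length = if (empty || is.null(lengths)) NULL else lengths,
        surface = sub[[sc$surface]][1],
        plant_id = sub[[sc$plant_id]][1],
        leaf_id = sub[[sc$leaf_id]][1],
        treatment = treatment),
      error = function(e) {
        stopf("validation error in rows %s-%s of %s: %s",
              min(idx), max(idx), basename(path), conditionMessage(e))
      })
    if (empty) message("surface ", rec$surface_id, " has zero stomata")
    rec
  })
  unname(out)
}

#' Write leaf-surface records to CSV
#'
#' Inverse of [read_surfaces()] under the default schema; an empty surface is
#' written as a single row with `NA` coordinates so it survives the
#' round-trip.
#'
#' @param records List of [surface_record()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surfaces <- function(records, path) {
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  rows <- lapply(records, function(r) {
    n <- max(1L, n_stomata(r))
    data.frame(
      plant_id = r$plant_id, leaf_id = r$leaf_id, surface = r$surface,
      treatment = r$treatment,
      x_mm = if (n_stomata(r)) num(r$stomata$x) else "NA",
      y_mm = if (n_stomata(r)) num(r$stomata$y) else "NA",
      length_um = if (n_stomata(r)) num(r$stomata$length) else "NA",
      window_width_mm = rep(num(r$window[1]), n),
      window_height_mm = rep(num(r$window[2]), n))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
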