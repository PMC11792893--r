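#' Expected mean nearest-neighbour distance under complete randomness
#'
#' For `n` points placed uniformly at random on an area `A`, the expected
#' distance from a point to its nearest neighbour is `0.5 * sqrt(A / n)`
#' (Clark-Evans expectation, no edge correction).
#'
#' @param area Window area (mm^2), positive.
#' @param n Number of points, >= 1.
#' @return Expected nearest-neighbour distance (mm).
#' @export
expected_nn_distance <- function(area, n) {
  if (!is_scalar_number(area) || area <= 0) stopf("`area` must be positive")
  if (!is_scalar_number(n) || n < 1) stopf("`n` must be >= 1")
  0.5 * sqrt(area / n)
}

#' Observed mean nearest-neighbour distance
#'
#' Mean over all stomata of the Euclidean distance to the nearest other
#' stomate. No edge correction is applied: boundary bias is cancelled by
#' comparing against synthetic surfaces generated on the same window.
#'
#' @param record A [surface_record()] with >= 2 stomata.
#' @return Mean nearest-neighbour distance (mm).
#' @export
observed_mean_nn_distance <- function(record) {
  stopifnot(inherits(record, "surface_record"))
  if (n_stomata(record) < 2) stopf("need at least 2 stomata")
  cpp_mean_nn_dist(record$stomata$x, record$stomata$y)
}

#' Nearest-neighbour index of a surface
#'
#' Ratio of observed to expected mean nearest-neighbour distance. NNI near 1
#' indicates random spacing, values above 1 overdispersion; the equilateral
#' triangular lattice attains the maximum, about 2.149.
#'
#' @param record A [surface_record()] with >= 2 stomata.
#' @return List of class `nni_result` with `d_obs_mean`, `d_exp_mean`, `nni`.
#' @export
nni <- function(record) {
  d_obs <- observed_mean_nn_distance(record)
  d_exp <- expected_nn_distance(window_area(record), n_stomata(record))
  structure(list(d_obs_mean = d_obs, d_exp_mean = d_exp,
                 nni = d_obs / d_exp),
            class = "nni_result")
}

#' Dispersion index
#'
#' Rescales an observed NNI so that the median NNI of the random null maps
#' to 0 and the median NNI of the ideal triangular-grid reference maps to 1:
#' `DI = (NNI - median(random)) / (median(ideal) - median(random))`.
#' Observed surfaces can fall slightly outside `[0, 1]`.
#'
#' @param nni_obs Observed NNI (scalar).
#' @param nni_random Sample of NNI values from the random null.
#' @param nni_ideal Sample of NNI values from the ideal-grid reference.
#' @return Dispersion index (dimensionless).
#' @export
dispersion_index <- function(nni_obs, nni_random, nni_ideal) {
  if (length(nni_random) < 1 || length(nni_ideal) < 1) {
    stopf("both reference samples must be non-empty")
  }
  denom <- median(nni_ideal) - median(nni_random)
  if (!is.finite(denom) || denom == 0) {
    stopf("degenerate dispersion index: median(ideal) == median(random)")
  }
  (nni_obs - median(nni_random)) / denom
}

#' One-tailed Monte-Carlo p-value (observed greater than synthetic)
#'
#' Add-one Monte-Carlo rule: `p = (1 + #{synthetic >= observed}) / (1 + N)`.
#' Ties count against the observation, and p is never exactly zero, which
#' keeps the Monte-Carlo test valid at any simulation size.
#'
#' @param observed Observed statistic (scalar).
#' @param synthetic Vector of statistics simulated under the null.
#' @return p-value in `(0, 1]`.
#' @export
mc_p_greater <- function(observed, synthetic) {
  if (length(synthetic) < 1) stopf("`synthetic` must be non-empty")
  (1 + sum(synthetic >= observed)) / (1 + length(synthetic))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (via [stats::p.adjust()]), with
#' input validation: raw p-values must lie in (0, 1]. Output is order-aligned
#' with the input, monotone over the sorted p-values, never smaller than the
#' raw value, and capped at 1.
#'
#' @param p_values Vector of raw p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Full dispersion analysis of one surface
#'
#' Simulates `n_sim` random surfaces and `n_sim` conditioned triangular
#' grids, both matched to the record's window and stomatal count; computes
#' the observed NNI, the two reference NNI medians, the dispersion index and
#' the one-tailed Monte-Carlo p-value for overdispersion (against the random
#' null). The same simulation set feeds both the p-value and the dispersion
#' index. `p_adjusted` is `NA` here; it is filled in across a batch of
#' surfaces by [dispersion_batch()].
#'
#' @param record A [surface_record()] with >= 2 stomata.
#' @param n_sim Number of synthetic surfaces per reference (default 1000).
#' @param seed Optional integer seed (bitwise-reproducible results).
#' @param ideal Simulate the ideal-grid reference too (default `TRUE`).
#'   With `FALSE` only the random null is run and the dispersion index is
#'   `NA` — cheaper when only the overdispersion test is needed.
#' @return List of class `dispersion_result`.
#' @export
dispersion_analysis <- function(record, n_sim = 1000, seed = NULL,
                                ideal = TRUE) {
  stopifnot(inherits(record, "surface_record"))
  if (n_stomata(record) < 2) stopf("need at least 2 stomata")
  if (n_sim < 1) stopf("`n_sim` must be >= 1")
  n <- n_stomata(record)
  w <- record$window
  obs <- nni(record)
  with_seed(seed, {
    nni_rand <- vapply(seq_len(n_sim), function(i) {
      cpp_mean_nn_dist(runif(n, 0, w[1]), runif(n, 0, w[2]))
    }, 0) / obs$d_exp_mean
    if (ideal) {
      tries <- 0L
      nni_ideal <- vapply(seq_len(n_sim), function(i) {
        g <- cpp_tri_grid_conditioned(n, w[1], w[2], 100000L)
        if (is.null(g$x)) stopf("ideal-grid conditioning failed (n = %d)", n)
        tries <<- tries + g$tries
        cpp_mean_nn_dist(g$x, g$y)
      }, 0) / obs$d_exp_mean
      di <- dispersion_index(obs$nni, nni_rand, nni_ideal)
      accept <- n_sim / tries
    } else {
      nni_ideal <- numeric()
      di <- NA_real_
      accept <- NA_real_
    }
    structure(
      list(surface_id = record$surface_id,
           nni_observed = obs$nni,
           nni_random_median = median(nni_rand),
           nni_ideal_median = if (ideal) median(nni_ideal) else NA_real_,
           dispersion_index = di,
           p_raw = mc_p_greater(obs$nni, nni_rand),
           p_adjusted = NA_real_,
           n_sim = as.integer(n_sim),
           acceptance_rate = accept),
      class = "dispersion_result")
  })
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf(
    "<dispersion_result> %s: NNI %.3f, DI %.3f, p %.4g (n_sim %d)\n",
    x$surface_id, x$nni_observed, x$dispersion_index, x$p_raw, x$n_sim))
  invisible(x)
}

#' Dispersion analysis of a batch of surfaces with FDR control
#'
#' Runs [dispersion_analysis()] on every record and applies the
#' Benjamini-Hochberg adjustment across the whole batch (all single-surface
#' tests form one adjustment family).
#'
#' @param records List of [surface_record()]s.
#' @param n_sim Simulations per surface.
#' @param seed Optional master seed; per-surface seeds are derived from it.
#' @param ideal Passed to [dispersion_analysis()].
#' @return A data.frame with one row per surface.
#' @export
dispersion_batch <- function(records, n_sim = 1000, seed = NULL,
                             ideal = TRUE) {
  res <- lapply(seq_along(records), function(i) {
    dispersion_analysis(records[[i]], n_sim = n_sim,
                        seed = derive_seed(seed, i), ideal = ideal)
  })
  out <- do.call(rbind, lapply(res, function(r) {
    data.frame(surface_id = r$surface_id, nni_observed = r$nni_observed,
               nni_random_median = r$nni_random_median,
               nni_ideal_median = r$nni_ideal_median,
               dispersion_index = r$dispersion_index, p_raw = r$p_raw,
               n_sim = r$n_sim)
  }))
  out$p_adjusted <- bh_adjust(out$p_raw)
  out
}

#' Two-way analysis of variance
#'
#' Fits `values ~ A * B` and reports Type-II sums of squares, F ratios and
#' p-values for the two main effects and their interaction. Type II (each
#' main effect adjusted for the other, the interaction adjusted for both)
#' handles the unbalanced layouts that arise when leaves are lost, and
#' coincides with the textbook decomposition for balanced data. The sums of
#' squares are obtained by comparing nested [stats::lm()] fits, so
#' degenerate designs with zero residual variance still yield valid sums of
#' squares (their F ratios are `NaN`).
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factor labels, same length as `values`.
#' @param names_ab Optional names for the two factors in the output.
#' @return data.frame with columns `effect`, `sum_sq`, `df`,
#'   `df_residual`, `f`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          names_ab = c("A", "B")) {
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  d <- data.frame(y = values, A = factor(factor_a), B = factor(factor_b))
  full <- lm(y ~ A * B, data = d)
  if (full$df.residual < 1) stopf("no residual degrees of freedom")
  if (any(is.na(coef(full)))) stopf("rank-deficient design")
  rss <- function(f) sum(stats::residuals(f)^2)
  fit_ab <- lm(y ~ A + B, data = d)
  fit_a <- lm(y ~ A, data = d)
  fit_b <- lm(y ~ B, data = d)
  ss <- c(rss(fit_b) - rss(fit_ab),    # SS(A | B)
          rss(fit_a) - rss(fit_ab),    # SS(B | A)
          rss(fit_ab) - rss(full))     # SS(A:B | A, B)
  df <- c(nlevels(d$A) - 1L, nlevels(d$B) - 1L,
          (nlevels(d$A) - 1L) * (nlevels(d$B) - 1L))
  mse <- rss(full) / full$df.residual
  f <- (ss / df) / mse
  data.frame(effect = c(names_ab, paste(names_ab, collapse = ":")),
             sum_sq = ss, df = df, df_residual = full$df.residual,
             f = f, p = pf(f, df, full$df.residual, lower.tail = FALSE))
}
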