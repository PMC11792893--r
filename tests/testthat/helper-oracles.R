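# Brute-force oracles, written independently of the package internals
# (plain double loops), used to pin the fast C++ paths.

oracle_mean_nn <- function(x, y) {
  n <- length(x)
  total <- 0
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    total <- total + best
  }
  total / n
}

oracle_nsd_sq <- function(px, py, sx, sy) {
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    best <- Inf
    for (j in seq_along(sx)) {
      d2 <- (px[i] - sx[j])^2 + (py[i] - sy[j])^2
      if (d2 < best) best <- d2
    }
    out[i] <- best
  }
  out
}

# is p inside the convex polygon (vertices in order), with tolerance?
oracle_in_convex <- function(poly, p, tol = 1e-9) {
  n <- nrow(poly)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (p[2] - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (p[1] - poly[i, 1])
    if (cr > tol) { if (sgn < 0) return(FALSE); sgn <- 1 }
    if (cr < -tol) { if (sgn > 0) return(FALSE); sgn <- -1 }
  }
  TRUE
}

# small synthetic study with lengths, for the zone-slope machinery:
# `plants` plants x `leaves_per_plant` leaves, one treatment/surface group
make_length_study <- function(plants = 4, leaves_per_plant = 2, n = 45,
                              alpha = 20, beta = 800, sigma = 3,
                              seed = 1) {
  recs <- list()
  k <- 0
  for (p in seq_len(plants)) {
    for (l in seq_len(leaves_per_plant)) {
      k <- k + 1
      rec <- random_surface(n, seed = seed + 100 * k,
                            plant_id = paste0("p", p),
                            leaf_id = paste0("p", p, "_l", l))
      recs[[k]] <- attach_lengths(rec, alpha = alpha, beta = beta,
                                  sigma = sigma, seed = seed + 100 * k + 1)
    }
  }
  recs
}
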