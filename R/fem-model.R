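#' Parameters of the 2-D porous-medium leaf photosynthesis model
#'
#' The leaf cross-section is the rectangle from `x = 0` to `x = U/2`
#' (symmetry-reduced: one adaxial and one abaxial stomate represent the
#' periodic row) and from the adaxial surface at `y = 0` down to the abaxial
#' surface at `y = T_leaf`. CO2 enters through Dirichlet pore segments and
#' diffuses through the mesophyll, treated as a homogeneous porous medium
#' with effective diffusivity `D_air * phi_pal / tau`, while a Farquhar-type
#' volumetric demand consumes it. Light enters the adaxial face and decays
#' exponentially with depth (Beer-Lambert).
#'
#' Geometry is given in micrometres, concentrations in mol m^-3 and
#' volumetric rates in mol m^-3 s^-1 (the solver works in strict SI). The
#' biochemical defaults give leaf-level assimilation of roughly 10-20
#' umol m^-2 s^-1 at `I0 = 1000` and a 400 ppm pore concentration; the
#' offset-vs-aligned comparison is a geometry-driven ratio and is
#' insensitive to the absolute kinetic scale.
#'
#' @param T_leaf Leaf thickness (um).
#' @param U Full interstomatal distance along the surface (um); the model
#'   domain spans `U/2`.
#' @param phi_pal Mesophyll porosity (m^3 airspace per m^3 leaf), in (0, 1).
#' @param tau Tortuosity of the airspace (dimensionless), default 1.57.
#' @param I0 Incident PPFD on the adaxial surface (umol m^-2 s^-1).
#' @param pore_halfwidth Half-width of a stomatal pore (um); each pore sits
#'   at a symmetry edge and contributes this length of Dirichlet boundary.
#' @param c_pore CO2 concentration at the pore (mol m^-3); default 0.0163,
#'   about 400 ppm at 25 C.
#' @param D_air CO2 diffusivity in air (m^2 s^-1).
#' @param Vcmax_vol,Km_eff,Gamma_star,Rd_vol,Jmax_vol Volumetric Farquhar
#'   parameters: Rubisco capacity (mol m^-3 s^-1), effective Michaelis
#'   constant (mol m^-3), CO2 compensation point without day respiration
#'   (mol m^-3), day respiration (mol m^-3 s^-1) and maximum electron
#'   transport (mol m^-3 s^-1).
#' @param alpha_light Conversion from incident PPFD to volumetric potential
#'   electron transport (mol e- m^-3 s^-1 per umol photon m^-2 s^-1).
#' @param theta_J Curvature of the non-rectangular hyperbola light response,
#'   in (0, 1].
#' @param k_abs Light extinction over the leaf thickness (dimensionless;
#'   0 gives uniform light).
#' @param arrangement `"offset"` (abaxial stomate at `x = U/2`) or
#'   `"aligned"` (abaxial stomate below the adaxial one at `x = 0`).
#' @return List of class `leaf_model_params`.
#' @export
leaf_model_params <- function(T_leaf = 301, U = 101, phi_pal = 0.2,
                              tau = 1.57, I0 = 1000, pore_halfwidth = 10,
                              c_pore = 0.0163, D_air = 1.54e-5,
                              Vcmax_vol = 0.30, Km_eff = 0.027,
                              Gamma_star = 0.0018, Rd_vol = 0.003,
                              Jmax_vol = 0.60, alpha_light = 1e-3,
                              theta_J = 0.9, k_abs = 1.0,
                              arrangement = c("offset", "aligned")) {
  arrangement <- match.arg(arrangement)
  pos <- c(T_leaf = T_leaf, U = U, tau = tau, pore_halfwidth =
             pore_halfwidth, c_pore = c_pore, D_air = D_air,
           Vcmax_vol = Vcmax_vol, Km_eff = Km_eff,
           Gamma_star = Gamma_star, Rd_vol = Rd_vol, Jmax_vol = Jmax_vol,
           alpha_light = alpha_light, theta_J = theta_J)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad) > 0) stopf("parameter(s) must be > 0: %s",
                             paste(bad, collapse = ", "))
  if (I0 < 0) stopf("I0 must be >= 0")
  if (k_abs < 0) stopf("k_abs must be >= 0")
  if (phi_pal <= 0 || phi_pal >= 1) stopf("phi_pal must be in (0, 1)")
  if (theta_J > 1) stopf("theta_J must be in (0, 1]")
  if (pore_halfwidth >= U / 2) stopf("pore_halfwidth must be < U/2")
  structure(list(T_leaf = T_leaf, U = U, phi_pal = phi_pal, tau = tau,
                 I0 = I0, pore_halfwidth = pore_halfwidth, c_pore = c_pore,
                 D_air = D_air, Vcmax_vol = Vcmax_vol, Km_eff = Km_eff,
                 Gamma_star = Gamma_star, Rd_vol = Rd_vol,
                 Jmax_vol = Jmax_vol, alpha_light = alpha_light,
                 theta_J = theta_J, k_abs = k_abs,
                 arrangement = arrangement),
            class = "leaf_model_params")
}

#' @export
print.leaf_model_params <- function(x, ...) {
  cat(sprintf(
    "<leaf_model_params> T_leaf %g um, U %g um, phi %g, I0 %g, %s pores\n",
    x$T_leaf, x$U, x$phi_pal, x$I0, x$arrangement))
  invisible(x)
}

#' Effective CO2 diffusivity of the porous mesophyll
#'
#' `D_eff = D_air * phi / tau`: the free-air diffusivity reduced by the
#' airspace volume fraction and path tortuosity.
#'
#' @param D_air Diffusivity in air (m^2 s^-1).
#' @param phi Porosity (0-1).
#' @param tau Tortuosity (>= 1 typically).
#' @return Effective diffusivity (m^2 s^-1).
#' @export
effective_diffusivity <- function(D_air, phi, tau) {
  if (any(c(D_air, phi, tau) <= 0)) stopf("inputs must be positive")
  D_air * phi / tau
}

# Smaller root of theta*J^2 - (aI + Jmax)*J + aI*Jmax = 0: the
# non-rectangular hyperbola light response of electron transport.
# Vectorised over I.
electron_transport <- function(I, Jmax, alpha, theta) {
  aI <- alpha * I
  b <- aI + Jmax
  disc <- pmax(b^2 - 4 * theta * aI * Jmax, 0)
  (b - sqrt(disc)) / (2 * theta)
}

#' Volumetric net CO2 demand
#'
#' Farquhar-type net assimilation per unit leaf volume at CO2 concentration
#' `c` and depth `y` below the adaxial surface:
#' `a(c, y) = (1 - Gamma*/c) * min(Wc, Wj) - Rd`, with the Rubisco-limited
#' rate `Wc = Vcmax * c / (c + Km)`, the RuBP-limited rate
#' `Wj = (J(y)/4) * c / (c + 2 Gamma*)`, and `J(y)` the non-rectangular
#' hyperbola response to the Beer-Lambert light profile
#' `I(y) = I0 * exp(-k_abs * y / T_leaf)`. At `c = Gamma*` the net rate is
#' exactly `-Rd`; non-positive `c` (outside the physical domain) returns
#' `-Rd` as the defined limit.
#'
#' @param c CO2 concentration (mol m^-3), vectorised.
#' @param y Depth below the adaxial surface (um), vectorised.
#' @param params A [leaf_model_params()].
#' @return Net volumetric assimilation (mol m^-3 s^-1).
#' @export
demand <- function(c, y, params) {
  stopifnot(inherits(params, "leaf_model_params"))
  I <- params$I0 * exp(-params$k_abs * y / params$T_leaf)
  J <- electron_transport(I, params$Jmax_vol, params$alpha_light,
                          params$theta_J)
  demand_given_J(c, J, params)
}

# demand with the light response pre-evaluated (J per location)
demand_given_J <- function(c, J, params) {
  G <- params$Gamma_star
  m <- max(length(c), length(J))
  cc <- rep_len(pmax(c, 0), m)
  J <- rep_len(J, m)
  Wc <- params$Vcmax_vol * cc / (cc + params$Km_eff)
  Wj <- (J / 4) * cc / (cc + 2 * G)
  W <- pmin(Wc, Wj)
  gross <- numeric(m)
  pos <- cc > 0
  gross[pos] <- (1 - G / cc[pos]) * W[pos]
  gross - params$Rd_vol
}

# analytic d(demand)/dc, clamped at a small positive concentration to avoid
# the 1/c^2 blow-up; always >= 0 (demand is non-decreasing in c)
demand_slope_given_J <- function(c, J, params) {
  G <- params$Gamma_star
  floor_c <- 1e-3 * G
  cc <- pmax(c, floor_c)
  Wc <- params$Vcmax_vol * cc / (cc + params$Km_eff)
  Wj <- (J / 4) * cc / (cc + 2 * G)
  use_c <- Wc <= Wj
  W <- ifelse(use_c, Wc, Wj)
  Wp <- ifelse(use_c,
               params$Vcmax_vol * params$Km_eff / (cc + params$Km_eff)^2,
               (J / 4) * 2 * G / (cc + 2 * G)^2)
  pmax(Wp * (1 - G / cc) + W * G / cc^2, 0)
}
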