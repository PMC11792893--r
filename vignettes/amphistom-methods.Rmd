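---
title: "Methods: stomatal patterning statistics and the leaf CO2 transport model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stomatal patterning statistics and the leaf CO2 transport model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`amphistom` quantifies how stomata are arranged on the two epidermes of
amphistomatous leaves and what that arrangement is worth photosynthetically.
This vignette is the package's own account of its methods: the statistics,
the generators behind every null distribution, the biophysical model, the
numerical choices, and the limits of what the synthetic tests can show.

## 1. Single-surface dispersion

Each imaged surface is a planar point pattern of stomatal centroids on a
rectangular window (the default window is the square 0.386 mm² imaging
field, side 0.6213 mm). Spacing is summarised by the nearest-neighbour
index

$$\mathrm{NNI} = \bar D_O / \bar D_E, \qquad
  \bar D_E = 0.5\sqrt{A/n},$$

where $\bar D_O$ is the mean distance from each stomate to its nearest
neighbour and $\bar D_E$ the expectation under complete spatial randomness
for $n$ points on area $A$. NNI ≈ 1 indicates random spacing; the
equilateral triangular lattice — the arrangement that maximises spacing at
fixed density, and therefore minimises the mean distance from mesophyll to
the nearest stomate — attains the maximum, $2\sqrt{2/\sqrt3} \approx
2.149$. No edge correction is applied to $\bar D_O$: every observed
surface is compared against synthetic surfaces generated on the *same*
window with the *same* count, so boundary bias cancels by construction.

Because NNI itself is hard to interpret between those two poles, the
dispersion index rescales it against two simulated references matched to
each surface:

$$\mathrm{DI} = \frac{\mathrm{NNI} - \mathrm{median}(\mathrm{NNI}_{\rm random})}
  {\mathrm{median}(\mathrm{NNI}_{\rm ideal}) - \mathrm{median}(\mathrm{NNI}_{\rm random})},$$

so DI ≈ 0 means "as random" and DI ≈ 1 means "as evenly spaced as the
ideal grid". One simulation set (default $10^3$ of each reference) feeds
both the DI and the overdispersion p-value; this is cheaper than two
independent sets and keeps the two quantities mutually consistent.

The overdispersion test is one-tailed Monte Carlo with the add-one rule,
$p = (1 + \#\{\mathrm{NNI}_{\rm null} \ge \mathrm{NNI}_{\rm obs}\}) /
(1 + N)$: ties count against the observation and $p$ is never exactly
zero, which keeps the test valid at any simulation size. Across a batch of
surfaces, all single-surface tests form one Benjamini–Hochberg adjustment
family; all paired-surface tests (below) form a second.

### The ideal-grid reference and its conditioning

The ideal reference for a surface with $n$ stomata is an equilateral
triangular lattice *conditioned to contain exactly $n$ points in the
window*, while integrating over the uncertainty in the underlying density:
a rate $\lambda \sim \Gamma(n, 1)$ (the posterior of a Poisson rate under
a flat prior), a count $m \sim \mathrm{Poisson}(\lambda)$, a lattice of
density $m/A$, a uniformly random translation over the fundamental cell —
and the draw is accepted only when exactly $n$ points land in the window.

One design choice here was forced by geometry. With the lattice rows held
parallel to the window edges, the in-window count changes in whole-row
jumps as the lattice translates, and on a square window the attainable
counts *skip* most integers: at $n = 50$ on the default window, $10^6$
translation-only draws never once contained exactly 50 points (attainable
counts nearby were 45, 46, 48, 49, 52, 56). The generator therefore also
rotates the lattice uniformly over $[0°, 60°)$ (the lattice symmetry
group) by default, which makes the count vary finely and yields acceptance
rates of roughly 1–5 % across realistic densities; rejection sampling then
conditions exactly. Rotation randomisation also removes any artefact of
aligning lattice rows with the window. Translation-only behaviour remains
available (`randomize_rotation = FALSE`) for small counts.

## 2. Abaxial–adaxial coordination

If the two surfaces cooperated to shorten CO₂ diffusion paths, stomata on
one surface would sit opposite the gaps of the other. The test statistic
is the pixel-wise Pearson correlation of the *nearest-stomatal-distance
squared* (NSD²) rasters of the two surfaces, on a common 64 × 64 grid
(≈ 9.7 µm pixels on the default window; the NSD field is smooth at
interstomatal scales and 32–256 px give the same inference, which the
resolution argument exposes). Coordination makes the correlation negative.
The null distribution is simulated: $10^3$ pairs of independent
random-uniform surfaces with the observed per-surface counts, and the
one-tailed add-one p-value for the *negative* tail,
$p = (1 + \#\{r_{\rm null} \le r_{\rm obs}\})/(1 + N)$. The direction
follows from the hypothesis (coordination ⇒ negative $r$); the positive
tail — alignment — is available as an option.

Two facts discovered during testing are worth recording:

* **The null mean of $r$ is not zero.** Independent surfaces give a small
  *positive* mean correlation (≈ +0.06 at 130 mm⁻², ≈ +0.035 at
  520 mm⁻²), because both rasters share the deterministic edge structure
  of the window — corner pixels are far from stomata on *any* surface.
  The Monte-Carlo test is unaffected (its null carries the same bias; the
  type-I error calibrates at 5 % ± 2 % in the test suite), but raw
  correlations should not be read against zero. Weak positive observed
  correlations are exactly what this artefact produces on real image
  pairs.
* Squared distance is the statistic; plain distance is available as a
  sensitivity switch and changes nothing qualitatively.

Both surfaces of a pair are assumed co-registered in one coordinate frame;
no mirroring is applied when overlaying them, and a `mirror_abaxial_x`
flag exists for data digitised in a mirrored frame.

## 3. Stomatal zones and the size–supply relation

The *stomatal zone* of a stomate is the part of the leaf surface closer to
it than to any other stomate — its Voronoi cell clipped to the window — and
is the natural proxy for the mesophyll volume that stomate supplies. Cells
are computed by intersecting the window rectangle with the
perpendicular-bisector half-planes of each neighbour (Sutherland–Hodgman
clipping, nearest-first with a pruning bound); boundary stomata keep their
clipped, finite cells rather than being discarded. The tessellation is
validated two ways in the test suite: the cells tile the window to
$10^{-9}$ relative area, and cell membership agrees with brute-force
nearest-stomate classification of $10^4$ random points.

The association between guard-cell length and zone area is estimated per
(light treatment, surface) group by ordinary least squares, with a 95 %
percentile interval from a *hierarchical bootstrap* that mirrors the
sampling design: resample plants with replacement, then leaves within each
sampled plant, then refit on the pooled stomata. This replaces a Bayesian
mixed-effects formulation deliberately: the estimand — the marginal slope
per group — is delivered by the bootstrap without a general-purpose
posterior sampler, and grouped resampling carries the within-plant and
within-leaf dependence that a naive i.i.d. bootstrap would ignore. The
regression direction is configurable: zone area on length (the reported
direction, mm² µm⁻¹) or length on zone area, which is the unbiased
direction when lengths are *generated* from zone areas as the synthetic
generator does.

## 4. Synthetic surfaces: what the generators emulate

All inference above is calibrated against generators that live in the
package, not in test fixtures:

* `random_surface()` — complete spatial randomness, the null everywhere.
* `triangular_grid_surface()` — the conditioned ideal grid (§1).
* `hardcore_surface()` — sequential dart throwing with an inhibition
  radius `r_min`; the simplest process producing the "overdispersed but
  far from ideal" patterns real leaves show. With `r_min = 0` it *is* the
  random model.
* `simulate_pair()` — independent, aligned, or offset-coordinated pairs;
  the offset mode places both surfaces on one triangular lattice with the
  adaxial copy translated by half a lattice vector, the idealised
  coordinated arrangement.
* `attach_lengths()` — guard-cell lengths affine in zone area plus
  Gaussian noise, for parameter-recovery tests with known ground truth.

The bundled study generator (`run_fixture()`) emits 66 leaf pairs across
three light treatments with abaxial densities of 150/200/400 mm⁻²
(low/medium/high), an adaxial:abaxial density ratio of 0.44, hard-core
patterning with `r_min` at 0.7 times the random-expectation
nearest-neighbour distance (which yields median DI ≈ 0.19, inside the
range real leaves show), and lengths around 20 µm with a planted positive
length–zone slope. These are generator choices for a realistic synthetic
study at the design scale of the motivating experiment, not measured
values.

What the generators do *not* emulate — and what passing tests therefore
cannot certify about real leaves: developmental spacing rules (one-cell
spacing, lineage effects) beyond a bare inhibition radius; within-leaf
density gradients; measurement error in centroid placement; non-rectangular
or differently-sized imaging fields per leaf; and any real registration
error between paired images.

## 5. The CO₂ transport model

The photosynthetic value of inter-surface coordination is computed with a
two-dimensional steady reaction–diffusion model of CO₂ in a leaf
cross-section, treating the mesophyll as a homogeneous porous medium:

$$\nabla \cdot (D_{\rm eff}\, \nabla c) = a(c, y), \qquad
  D_{\rm eff} = D_{\rm air}\, \varphi_{\rm pal} / \tau.$$

Stomata repeat along the surface with interstomatal distance $U$, so by
symmetry the domain is $[0, U/2] \times [0, T_{\rm leaf}]$ with one
adaxial stomate (at $x = 0$, $y = 0$) and one abaxial stomate at
$y = T_{\rm leaf}$, either *offset* ($x = U/2$) or *aligned* ($x = 0$).
Pores are Dirichlet segments at the pore CO₂ concentration `c_pore`
(default 0.0163 mol m⁻³ ≈ 400 ppm at 25 °C); all other boundary is
zero-flux. The volumetric demand is Farquhar-type,

$$a(c, y) = \left(1 - \Gamma^*/c\right)\min(W_c, W_j) - R_d,$$

with $W_c = V_{\rm cmax} c/(c + K_m)$, $W_j = (J(y)/4)\, c/(c +
2\Gamma^*)$, and $J(y)$ the smaller root of the non-rectangular hyperbola
driven by a Beer–Lambert light profile $I(y) = I_0 e^{-k_{\rm abs} y /
T_{\rm leaf}}$ from the adaxial face. At the compensation point the net
rate is exactly $-R_d$; for non-positive $c$ (outside the physical domain)
the demand is defined as $-R_d$. The *coordination advantage* is the log
response ratio $\ln(A_{\rm offset}/A_{\rm aligned})$ of area-integrated
net assimilation per unit leaf area; 0.01 on this scale is ≈ 1 %. The raw
ratio is attached alongside.

### Parameterisation

Geometry and environment are swept (thickness 101–501 µm, $U$ 34–338 µm —
full interstomatal distance, so the model half-domain spans up to 169 µm;
porosity 0.1–0.3; PPFD 50–1000 µmol m⁻² s⁻¹). The biochemistry is a fixed
volumetric default chosen so that leaf-level assimilation lands in the
ordinary 10–20 µmol m⁻² s⁻¹ range at saturating light and 400 ppm:
$V_{\rm cmax} = 0.30$, $J_{\rm max} = 0.60$, $R_d = 0.003$ mol m⁻³ s⁻¹,
$K_m = 0.027$, $\Gamma^* = 0.0018$ mol m⁻³, $\alpha = 10^{-3}$ mol e⁻ m⁻³
s⁻¹ per unit PPFD, $\theta_J = 0.9$, $k_{\rm abs} = 1$, $\tau = 1.57$,
pore half-width 10 µm. The advantage is a geometry-driven *ratio* of two
solves that share every kinetic constant, so it is insensitive to the
absolute kinetic scale; the sweep bound (advantage < 0.01 off the
thin-sparse corner) is robust across these defaults. All constants are
arguments of `leaf_model_params()`. Volumetric rates mean that a thicker
leaf carries proportionally more photosynthetic machinery, consistent with
the homogeneous-tissue assumption. $R_d$ is set low enough that net
assimilation stays positive at the dimmest corner of the sweep (50 µmol
m⁻² s⁻¹), where a leaf-level dark respiration of ≈ 0.9 µmol m⁻² s⁻¹
results.

### Numerics

Linear triangular elements on a structured mesh, default 64 × 64 edges
(≈ 4 × 10³ nodes). When a pore would be resolved by fewer than four
boundary edges at uniform spacing, the x-grid is graded: at least four
edges across each pore segment, uniform interior. The nonlinear reaction
is handled by Newton linearisation: each iterate solves $(K + M\,
a'(c_k))\,c = M(a'(c_k)c_k - a(c_k))$ with the analytic, non-negative
demand slope, so every system is symmetric positive definite and
convergence to the $10^{-8}$ relative tolerance typically takes 3–5
iterations. (Undamped fixed-point iteration on the right-hand side — the
obvious simpler scheme — diverges for thick, low-porosity leaves, where
the reaction-to-diffusion spectral ratio exceeds 1; damping rescues it but
needs > 100 iterations, so the linearised scheme is both the fast and the
robust choice.) Mass balance — boundary influx versus volumetric
consumption — closes to better than $10^{-3}$ relative at convergence, and
the discrete solution matches the one-dimensional $\cosh$ closed form of
the linear-reaction limit within 0.5 % at the default mesh. Mesh
convergence is checked where it is hardest, on the thin-sparse cell with
the largest advantage: 64² vs 128² changes the advantage by < 5 %.

What the model omits, deliberately: substomatal cavity geometry, stomatal
and boundary-layer resistance (which cancel to first order in the
offset/aligned ratio), palisade/spongy porosity contrast, anisotropic
tortuosity, 3-D airspace structure, and any temporal dynamics. Several of
these (lateral tortuosity, layered porosity) would plausibly *increase*
the advantage of offsetting somewhat; none are expected to overturn the
conclusion that the benefit is far below 1 % except for thin leaves with
very sparse stomata, where lateral diffusion dominates.

## 6. Problem sizes used by the test suite

The suite regenerates everything from code under fixed seeds: dispersion
calibration on 500 random surfaces of 100 stomata (199 null simulations
each); coordination calibration on 500 independent pairs of 50 stomata
(99 simulations, 32² rasters — the type-I error of a Monte-Carlo test does
not depend on raster resolution); DI anchors on 200 + 200 surfaces of 50
stomata with $10^3$ simulations each; slope recovery over 100 synthetic
studies of 4 plants × 2 leaves × 45 stomata with 200 bootstrap
replicates; and a 3 × 3 × 2 × 2 FEM sweep at 64². These sizes make the
anchors and error rates sharp enough to detect miscalibration of a
percentage point or two while keeping the whole suite in minutes.

## 7. Known limitations

* The Voronoi clipping assumes convex windows (rectangles); arbitrary
  imaging masks are out of scope.
* The hierarchical bootstrap requires at least two plants per group and
  quantifies uncertainty in the marginal slope only — it does not estimate
  variance components.
* NSD correlation assumes the two images of a pair share a coordinate
  frame; there is no registration machinery.
* The FEM is 2-D and homogeneous; its output should be read as the order
  of magnitude of the coordination advantage, not a leaf-specific
  prediction.
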