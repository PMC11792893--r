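# amphistom

Spatial statistics and biophysical modelling of stomatal patterning in
**amphistomatous leaves** — leaves that carry stomata on both the abaxial
(lower) and adaxial (upper) epidermis. Amphistomy roughly halves the CO₂
diffusion path from pore to chloroplast, and theory predicts that an
"optimal" amphistomatous leaf would (i) space the stomata of each surface
on an equilateral triangular grid and (ii) offset the two surfaces so each
stomate faces the gaps of the other. `amphistom` provides the machinery to
test how far real (or simulated) leaves sit from that optimum, and what
the optimum would actually be worth:

* **Dispersion.** The nearest-neighbour index
  `NNI = D̄_O / D̄_E` with `D̄_E = 0.5·√(A/n)`, and a dispersion index

  ```
  DI = (NNI − median NNI_random) / (median NNI_ideal − median NNI_random)
  ```

  that rescales each surface between its own simulated random null
  (DI = 0) and an ideal triangular-grid reference conditioned on the
  observed stomatal count (DI = 1), with one-tailed add-one Monte-Carlo
  p-values and Benjamini–Hochberg control across surfaces.
* **Coordination.** Pixel-wise Pearson correlation of the
  nearest-stomatal-distance-squared (NSD²) rasters of paired surfaces;
  coordinated (offset) surfaces give negative correlation. Tested against
  simulated pairs of independent random surfaces.
* **Stomatal zones.** Voronoi supply zones clipped to the image window,
  and the association between guard-cell length and zone area per
  treatment × surface group (OLS with a hierarchical plant→leaf
  bootstrap interval).
* **Photosynthesis model.** A 2-D porous-medium reaction–diffusion model
  of leaf CO₂ transport (finite elements, Farquhar-type volumetric
  demand, Beer–Lambert light profile) that prices the **coordination
  advantage** `ln(A_offset / A_aligned)` of offsetting stomata between
  surfaces, swept over leaf thickness, interstomatal distance, porosity
  and irradiance.
* **Synthetic surfaces.** Generators for every reference pattern —
  random-uniform, exact-count conditioned triangular grids, hard-core
  (inhibition) patterns, and independent/aligned/offset surface pairs —
  plus a full synthetic-study generator (`run_fixture()`).

Audience: plant ecophysiologists and quantitative biologists working on
stomatal anatomy, gas exchange, or spatial point patterns on bounded
windows.

## Worked example

```r
library(amphistom)

## a synthetic study: 6 leaves, both surfaces, three light treatments
study <- run_fixture(n_pairs = 6, seed = 1)
rec <- study$records[[1]]
rec
#> <surface_record> leaf01_abaxial (abaxial, low light)
#>   window 0.6213 x 0.6213 mm, 64 stomata (density 165.8 mm^-2)

## is this surface overdispersed, and how close to the ideal grid?
dispersion_analysis(rec, n_sim = 1000, seed = 2)
#> <dispersion_result> leaf01_abaxial: NNI 1.137, DI 0.075, p 0.1339 (n_sim 1000)

## are the two surfaces of leaf 1 spatially coordinated?
coordination_test(study$pairs[[1]], n_sim = 1000, seed = 3)
#> <coordination_result> leaf leaf01: r = -0.005, p = 0.3616 (negative tail, n_sim 1000)

## stomatal length vs Voronoi supply-zone area, per group (mm^2 per um)
zone_length_slope(study$records, n_boot = 500, seed = 4)[, 1:5]
#>   treatment surface    slope   ci_low  ci_high
#> 1      high abaxial 0.000115 0.000108 0.000128
#> 2       low abaxial 0.000393 0.000378 0.000410
#> 3    medium abaxial 0.000260 0.000228 0.000300
#> 4      high adaxial 0.000487 0.000481 0.000506
#> 5       low adaxial 0.000941 0.000897 0.000941
#> 6    medium adaxial 0.000870 0.000624 0.000978

## what would perfect inter-surface coordination buy a thin, sparse leaf?
adv <- coordination_advantage(leaf_model_params(T_leaf = 101, U = 338,
                                                phi_pal = 0.1, I0 = 1000))
sprintf("advantage = %.5f (ratio %.5f)", adv, attr(adv, "ratio"))
#> "advantage = 0.00625 (ratio 1.00626)"
```

Reading the output: the example surface has NNI 1.137 — spacing 14 %
wider than random — but a dispersion index of only 0.075, i.e. nowhere
near the ideal grid, and the Monte-Carlo test does not reject randomness
for this single surface (p = 0.13). The NSD² correlation between its two
surfaces is ≈ 0: no inter-surface coordination. Guard-cell length and
supply-zone area are positively associated in every group (the generator
plants that association; the intervals recover it). And even in the most
favourable geometry of the whole parameter space — a 101 µm leaf with
stomata 338 µm apart — offsetting the two surfaces raises assimilation by
only 0.6 %; everywhere else the model puts the benefit far below 1 %.

`run_all()` chains every stage (dispersion with batch FDR, coordination,
zone slopes, ANOVAs of density and DI on light × surface, optional FEM
sweep) and writes CSV tables plus a seed-bearing manifest.

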