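# erfront

Endoplasmic reticulum (ER) morphometrics and cell-front mechanics at curved
epithelial wound edges.

Epithelial gaps close by two orthogonal migration modes: lamellipodial
crawling at **convex** wound edges (signed curvature κ > 0, the edge bulges
into the gap) and purse-string contraction at **concave** edges (κ < 0). The
ER reorganizes with edge curvature — thin tubules dominate the cell front at
convex edges, dense sheets at concave edges — and this reorganization tracks
the forces of protrusion and contraction. `erfront` provides both halves of
the computational story:

- **Quantification** of fluorescence images: signed edge curvature at cell
  and tissue scale (algebraic circle fits; smoothing-spline curvature
  κ(s) = (x′y″ − y′x″)/(x′² + y′²)^{3/2}), the strict >20%
  perimeter-contact inclusion filter, trainable three-class pixel
  segmentation of ER tubules / sheets / background with the classical
  multi-scale filter bank (Gaussian, Sobel, Hessian eigenvalues, difference
  of Gaussians, membrane projections) and a seeded random forest, the front
  tubule fraction f_tubule = A_tubule / (A_tubule + A_sheet), the mean
  distribution from the edge (MDE = Σ p(x)·d(x, edge), lower = edge
  polarized), front intensity fractions, the shape index P/√A,
  Fourier-spectrum orientation histograms (6 bins 0–90° for focal
  adhesions; 10 bins 0–180° for microtubules), focal-adhesion detection
  with the 0–18° parallel / 72–90° perpendicular angular classes, FA–ER
  contact association, and kymograph flow-direction calls
  (anterograde/retrograde).
- **Mechanics**: a plane-stress finite-element model of the cell front —
  cytoplasm, actin cortex and ER as three regions, the leading edge an arc
  of prescribed signed curvature — that compares the strain-energy density

  U = (1/V) · ½ ∫ Σ : ε dV

  of three equal-area ER layouts (edge-normal "perpendicular" tubules, an
  edge-parallel tubule cluster, one dense sheet) under protrusive traction
  or purse-string (tangential cortex eigenstress) contraction, across edge
  curvatures κ ∈ ±[0.01, 0.08] µm⁻¹.
- A **seeded synthetic-scene generator** (curved-edge cells, ER with a
  prescribed front tubule fraction, von Mises-oriented focal adhesions,
  drifting time-lapse stacks, PSF + Poisson + read noise) with full ground
  truth, so the entire pipeline runs and is validated with no external
  data.

## Worked example

Render a convex-edge scene at the tubule-dominated operating point, train
the segmenter on disjoint seeded scenes, and quantify:

```r
library(erfront)

spec  <- synth_preset("convex-default", seed = 42)   # kappa = +0.05, f_true = 0.64
scene <- render_er(spec)

tset  <- make_training_set(list(synth_spec(seed = 101, f_true = 0.2),
                                synth_spec(seed = 102, f_true = 0.5),
                                synth_spec(seed = 103, f_true = 0.8)), seed = 1)
model <- train_on_synthetic(tset, seed = 1)
model
#> <er_classifier> 100 trees, OOB accuracy 0.906, features 5e872218

mask <- classify(model, scene$image)
tubule_fraction(mask, scene$truth$front_roi)
#> <fraction_result> f_tubule = 0.653 (tubule 17.58 um^2, sheet 9.33 um^2)
scene$truth$f_realized                       # generator ground truth
#> [1] 0.6425888

mde(mask, scene$truth$cell_mask, scene$truth$wound_edge, component = "tubule")
#> <mde_result> MDE = 4.424 um (tubule)

fit_circle(scene$truth$wound_edge$vertices)  # recover the edge curvature
#> <circle_fit> center (8.320, 24.086), radius 20.000 um, |kappa| 0.05 um^-1
```

The estimated front tubule fraction (0.653) recovers the ground truth
(0.643) to ~0.01; the wound-edge circle fit returns exactly the requested
20 µm radius.

Ask the mechanical model which ER layout a protruding convex front prefers:

```r
dom <- build_domain(0.05, er_layout("perpendicular"))
solve_front(dom, load = load_case("protrusion"))
#> <fe_solution> protrusion: U = 0.0055469 kPa, tip 1.269 um, residual 1.2e-11

solve_front(build_domain(0.05, er_layout("sheet")), load = load_case("protrusion"))
#> <fe_solution> protrusion: U = 0.0072723 kPa, tip 1.673 um, residual 1.7e-11
```

Edge-normal tubules store ~24% less strain energy than an equal-area sheet
under the same protrusive load — the protruding convex front "prefers"
perpendicular tubules. `curvature_sweep()` runs the full factorial
(curvature × layout × load mode) with normalized energies, and
`ordering_report()` ranks layouts per case; under contraction the ordering
reverses (sheet < parallel < perpendicular).

A command-line surface wraps the same functions (`synth`, `train`,
`segment`, `quantify`, `curvature`, `orient`, `kymo`, `mech-solve`,
`mech-sweep`, `report`):

```sh
Rscript inst/cli/erfront.R synth --preset convex-default --seed 42 --out-dir scene/
Rscript inst/cli/erfront.R mech-solve --kappa 0.05 --layout sheet --mode protrusion --out sol.json
```

See `vignettes/er-curvature-methods.Rmd` for the model assumptions,
parameter defaults, estimator design, and known limitations.

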