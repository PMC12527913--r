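---
title: "Methods: ER morphometrics and cell-front mechanics at curved wound edges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ER morphometrics and cell-front mechanics at curved wound edges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(erfront)
```

# The scientific problem

Epithelial monolayers close gaps by two orthogonal migration modes:
lamellipodial crawling at convex wound edges (the edge bulges into the
cell-free gap, signed curvature $\kappa > 0$) and purse-string-like
contraction at concave edges ($\kappa < 0$). The endoplasmic reticulum (ER)
reorganizes with edge curvature — thin tubules dominate the front of cells
at convex edges, dense Climp63/p180-positive sheets dominate at concave
edges — and this reorganization couples to focal-adhesion orientation and
hence to the migration mode itself.

`erfront` implements the two computational halves of this problem:

1. **Image morphometrics** — quantifying ER organization, edge curvature,
   focal-adhesion orientation and ER flow from fluorescence microscopy; and
2. **A mechanical model** — a finite-element (FE) calculation asking which
   idealized ER layout (edge-normal tubules, edge-parallel tubules, or a
   dense sheet) minimizes the strain-energy density of the cell front under
   protrusive or contractile loading at a given edge curvature.

Because the microscopy data behind such analyses are rarely public, the
package includes a first-class seeded synthetic-scene generator that
produces ground-truthed images with the statistical structure the
estimators assume. Every estimator in the package is validated against that
generator.

# Geometry: signed curvature and the inclusion filter

Curvature is measured at two scales. At the **cell scale**, an arc of the
cell's wound-facing boundary is fit with Taubin's algebraic circle fit
(`fit_circle()`), which is stable on short arcs (< 180°); collinear input
is returned as the zero-curvature limit rather than an error. At the
**tissue scale**, `spline_curvature()` fits smoothing splines $x(t), y(t)$
against chordal arclength and evaluates
$\kappa = (x'y'' - y'x'')/(x'^2+y'^2)^{3/2}$, resampled at uniform
arclength. The smoothing level defaults to generalized cross-validation and
is exposed because the appropriate level depends on tracing density; with
fewer than roughly 100 vertices on a strongly curved arc, spline end
effects can distort endpoint curvatures, so arcs should be traced densely.

The sign convention is resolved with a probe point known to lie in the
cell-free gap (`assign_sign()`): curvature is positive when the edge bulges
into the gap (the osculating center lies on the monolayer side), negative
when it indents into the monolayer.

Cells whose geometry is dominated by neighbours rather than by the wound
are excluded with the perimeter-contact filter
(`perimeter_contact_fraction()`): a cell enters curvature analyses only if
strictly more than 20% of its boundary arclength lies within a contact
tolerance of the wound edge. The tolerance defaults to one pixel
equivalent, since the underlying contact criterion of manual analyses is
never sharper than the pixel grid. The boundary case (exactly 20%) is
excluded, following the strict reading of "more than 20%".

The **front ROI** (`front_roi()`) is the intersection of the cell polygon
with the band extending `d_front` (default 10 µm) inward from the wound
edge. Rather than exact polygon clipping, the ROI boundary is extracted as
the zero level set of $\max(d_{\text{edge}} - d_{\text{front}},
\,\mathrm{sd}_{\text{cell}})$ on a fine grid, which handles curved edges
and non-convex cells uniformly; the grid resolution (default 400 across
the bounding box) keeps area errors well under 2%.

# ER segmentation and the fraction metrics

Segmentation follows the trainable-pixel-classification paradigm: a
multi-scale filter bank (`compute_features()`) feeds a random-forest
ensemble (`train_classifier()`, 100 trees, $\sqrt{p}$ features per split,
seeded and single-threaded for determinism) that labels each pixel as
**tubule**, **sheet**, or **background**. The feature bank comprises, per
scale in {1, 2, 4, 8} px: Gaussian smoothing, Sobel gradient magnitude,
both Hessian eigenvalues, and a difference of Gaussians (scale vs twice
the scale); plus membrane projections — six aggregations (sum, mean, max,
min, median, s.d.) over the responses of a 1-px-wide, 19-px-long line
kernel rotated through 30 orientations. These are the classical defaults
of interactive trainable-segmentation tools, which typically expose the
feature names but not their parameters; the values here are therefore
stated explicitly and kept configurable. Images are normalized by their
maximum before
feature computation, making classification invariant to uniform intensity
rescaling. Ties in the per-pixel argmax are broken by the fixed class
order tubule < sheet < background.

**Training emphasis matters more than training size.** A fluorescence
image blurs a 2-px tubule into a ~5-px ridge; if training samples the
three classes evenly, the learned boundary sits at the blurred halo and
tubule areas inflate by a factor approaching two, biasing the tubule
fraction upward by ~0.13 at mid fractions. `make_training_set()` therefore
samples the background class at four times the rate of the ER classes,
with 60% of background samples drawn from the halo within 7 px of an ER
structure — the synthetic counterpart of iteratively retraining an
interactive classifier "until the segmentation matches the image". With
this protocol the front tubule-fraction error against generator truth has
mean absolute error ≈ 0.006 across fractions 0.2–0.8 and both edge signs.

The fraction and polarity metrics built on the mask are:

- `tubule_fraction()`: tubular ER area / (tubule + sheet) area within an
  ROI. Unclassified (background) pixels never enter the denominator.
- `front_intensity_fraction()`: background-subtracted summed intensity in
  the front ROI over the whole cell (the Climp63 front-enrichment
  readout); background is the median extracellular intensity.
- `mde()`: the mean distribution from the edge — signal within the cell
  normalized to a probability density, MDE = $\sum_x p(x)\,d(x)$ with $d$
  the Euclidean distance (µm) to the wound-edge polyline. Distances are
  absolute micrometres (not normalized by cell length); and the reference
  is the migrating wound edge, not the full cell outline. A lower MDE
  means edge polarization.
- `shape_index()`: perimeter / √area of the cell polygon.
- `validate_fractions()`: Pearson correlation of estimated vs reference
  fractions — the package's headline validation, run on 30 synthetic
  scenes spanning true fractions 0.1–0.9 in `scripts/acceptance.R`.

# Orientation, focal adhesions, and flow

`directionality_fourier()` reimplements the Fourier-components
orientation histogram: the ROI is Hann-windowed (to suppress spectral
leakage from the image border — the plugin description leaves windowing
unstated), Fourier-transformed, and spectral power is binned by frequency
angle, with structure orientation = spectral angle + 90°. Focal-adhesion
analyses use 6 bins on [0°, 90°] relative to the local edge tangent;
microtubule analyses use 10 bins on [0°, 180°].

`detect_fa()` segments paxillin-like punctae (median-background
subtraction, Otsu threshold by default, minimum area 0.1 µm²) and measures
each object's orientation from its second central moments; the angle to
the local edge tangent is folded to [0°, 90°]. `classify_fa()` applies the
field's angular classes: 0–18° **parallel** to the wound, 72–90°
**perpendicular**, everything else excluded. Both thresholds are
inclusive; the boundary membership is unstated in the source convention,
and the inclusive choice keeps the three classes an exact partition of
[0°, 90°]. `fa_er_association()` assigns each FA the majority ER class
within a contact radius (default 0.3 µm ≈ 3 px) of its centroid.

`kymograph()` samples intensity along a line (bilinear interpolation,
averaged over a perpendicular width) per frame; the convention is that the
line's second endpoint faces the wound edge, so increasing space index
means "toward the edge". `flow_direction()` finds the dominant slope by a
Radon-style shear search: each candidate velocity shears the
column-mean-subtracted kymograph, and the velocity maximizing the variance
of the time-averaged profile wins, with parabolic sub-grid refinement. Two
numerical details are load-bearing: the shear is taken about the *middle*
frame, and only trajectories visible in *every* frame are scored — these
make the estimator exactly antisymmetric under time reversal. Speeds below
0.05 µm/min are reported as "none"; the source analyses make only
qualitative anterograde/retrograde calls, so this floor is a package
choice.

# The cell-front mechanical model

## Model structure

The model asks a comparative question: at fixed edge curvature, ER volume
and load, which ER layout yields the lowest strain-energy density

$$U \;=\; \frac{1}{V}\,\frac{1}{2}\int_V \Sigma : \epsilon \; dV$$

The domain is the front of one cell — width $W = 20$ µm, depth
$D = 15$ µm, out-of-plane thickness constant — whose leading edge is a
circular arc of signed curvature $\kappa$. Three regions partition the
domain: cytoplasm, ER, and a cortex band of thickness $t_c = 0.2$ µm along
the leading edge. Cytoplasm and ER are linear elastic; the cortex is an
elastic band carrying the active load in the quasi-static limit. The
nucleus is not modeled (the front of a migrating cell excludes it), and
microtubules are not explicitly modeled.

The reduction to 2D plane stress is deliberate: every model output used
scientifically — energy *orderings* between layouts, tip displacement
contrasts, bending-vs-axial dominance — is an in-plane comparison, and the
orderings are the acceptance surface. The rate dependence of the cortex
law drops out in the quasi-static limit used here.

Defaults (all config): $E_{\text{cyt}} = 1$ kPa, $E_{\text{ER}} = 10$ kPa,
$E_c = 100$ kPa, all $\nu = 0.45$; ER area fraction $\phi = 0.15$; tubule
width $w_t = 0.3$ µm; load magnitude 0.1 kPa. Because the constitutive
parameters of the original simulations are not published, every reported
ordering is re-checked across a 4× range of $E_{\text{ER}}/E_{\text{cyt}}$
and a 2× range of $\phi$ — the claims must be (and are) parameter-robust,
not single-point results.

## Loads and boundary conditions

**Protrusion** is an outward normal traction on the leading edge — the
lamellipodial push. **Contraction** is a contractile eigenstress in the
cortex acting *along the edge tangent* — the purse-string cable shortening
along its length. The tangential (rather than isotropic) eigenstress is a
deliberate modeling choice: a purse string is a tangential cable, and only
tangential contraction produces the observed phenomenology in which the ER
carries high bending moments under contraction but predominantly axial
load under protrusion.

The rear edge (monolayer side) is clamped. The lateral edges are free.
Lateral mirror symmetry was considered and rejected: with a tangential
eigenstress, symmetry conditions on both lateral edges prevent the cortex
from shortening at all at $\kappa = 0$, collapsing the contraction case
into a degenerate near-zero-deformation state in which layout comparisons
are meaningless. With free lateral edges the cortex contracts against the
elastic front band, and all flat-edge and curved-edge orderings emerge.

## ER layouts at equal area

At fixed $(\kappa, \phi)$ the three layouts realize the same ER area
within far less than 1% (the "constant ER volume" constraint), by growing
each region element-by-element in a deterministic priority order until the
area target is met:

- **perpendicular**: 20 tubules of width $w_t$, exactly normal to the
  local edge (the mesh is annular near the front, so tube axes follow the
  edge normal by construction), grown in depth;
- **parallel**: a cluster of edge-tangential tubules stacked behind the
  cortex (8 bands nominally; on concave domains, which flare outward and
  so carry a larger area target, extra bands are stacked deeper until the
  target is reachable), grown from the midline outward;
- **sheet**: one simply connected slab behind the cortex, grown in depth
  (realized depth ≈ 2.3 µm at defaults).

## Discretization and verification

The mesh is a structured grid in edge-following coordinates $(s, d)$
(arclength along the edge; depth behind it), mapped annularly near the
front and blended to a flat rear — a pure annular sector is impossible for
convex $1/\kappa < D$. Elements are bilinear quadrilaterals under plane
stress with selective reduced integration (2×2 Gauss points for normal
strains, the center point for shear), which removes parasitic shear
locking in bending-dominated states while keeping the patch test exact.
The default element size 0.1 µm resolves the tubule width and cortex with
≥ 2 elements (preconditioned; coarser meshes error). The linear system
(~60k unknowns at defaults) is solved by sparse Cholesky factorization;
within a curvature sweep the stiffness matrix of each (curvature, layout)
cell is factorized once and reused across load modes.

Three closed-form verification problems guard the solver and run in
seconds: the patch test reproduces a prescribed uniform-strain state to
~1e-17 on a distorted mesh; a uniaxial bar matches $U = \sigma^2/2E$ to
~1e-13; a slenderness-10 cantilever matches Euler–Bernoulli tip deflection
to 0.4%.

## Energy split and diagnostics

`energy_split()` decomposes the ER strain energy into membrane (stretch)
and bending contributions along each tubule/sheet mid-axis: per
cross-section (a tube's element columns at one depth, or a sheet's element
column at one arclength), the area-mean axial strain carries the membrane
energy, and the residual axial variation plus axial-transverse shear is
bending. On fabricated closed-form states this recovers pure extension as
~100% membrane and an antisymmetric (beam-bending) axial field as ~100%
bending. For the sheet, whose "axis" is ambiguous, the edge-tangent frame
is used, and this convention is applied uniformly.

At defaults the model reproduces, as *emergent* results (none of these is
imposed): sheets beat perpendicular tubules under flat-edge contraction
and the reverse under protrusion; under convex protrusion, perpendicular
tubules are best at every curvature with a sheet–perpendicular gap that
grows monotonically; under concave contraction, sheet < parallel <
perpendicular at every curvature with a perpendicular–sheet gap that
shrinks with increasing |κ|; protrusion tip displacement is higher with
sheet ER, contraction edge displacement higher with perpendicular ER; and
the ER bending-energy fraction under contraction (~0.34) dwarfs that under
protrusion (~0.003) at matched load magnitude. The sweep tests assert the
orderings and monotonicity, not particular energy values, because the
absolute scale depends on the unpublished constitutive parameters.

Sweeps are reported both raw and normalized by the flat-edge
perpendicular-layout energy of the same load mode; the original
normalization reference is unstated, and this choice makes the flat
perpendicular case the unit for both modes.

# The synthetic-scene generator

`synth_spec()` fixes the study conditions: 256×256 px at 0.065 µm/px
(typical spinning-disk sampling), Gaussian PSF σ = 1.5 px, Poisson noise
at 2 counts per intensity unit plus Gaussian read noise (σ = 1.5),
tubules as persistent random-walk strokes 2 px wide, sheets as a
thresholded smooth random field in a 3-µm band behind the edge, and a
10-µm-deep cell abutting an edge arc of prescribed κ. The presets
`convex-default` (κ = +0.05 µm⁻¹, front tubule fraction 0.64) and
`concave-default` (κ = −0.05 µm⁻¹, fraction 0.35) encode the observed
initial operating points of cells at the two edge types, so the
generator's convex/concave contrast is the structure the estimators must
recover. Stroke addition is steered by area accounting so the realized
front-ROI fraction lands within 0.02 of the request (the final stroke is
truncated pixel-wise). Ground-truth masks are defined pre-noise: estimator
error is measured against geometry, not against a noise realization.

Focal adhesions are rendered as non-overlapping ellipses (1.1 × 0.35 µm)
whose axis angles to the local edge tangent follow an axial von Mises
distribution (Best–Fisher sampling; concentration 0 gives uniform). The
minimum center separation (1.6 × the semi-major axis) reflects that real
adhesions are discrete objects; without it, merged punctae corrupt
moment-based orientation estimates. Time-lapse stacks translate the
pre-noise scene along the edge normal at a signed velocity (positive =
anterograde) with per-frame noise redrawn; the default frame interval is
30 s so that typical speeds (±0.5 µm/min) stay in frame over 10–12 frames.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: three-dimensional ER structure and defocus,
spatially varying background, organelle crowding and exclusion (nucleus,
mitochondria), true reticular network topology (strokes cross but are not
junction-resolved), photobleaching, and drift. The validation
demonstrates that the estimators are correct *given* the imaging model,
not that the imaging model is complete.

# Numerical choices and degenerate inputs

- Coordinates are continuous micrometres, y-down image convention; pixel
  (i, j) maps to its center ((i−0.5)·px, (j−0.5)·px).
- Collinear circle-fit input → degenerate zero-curvature result, not an
  error; probe on the edge → error.
- Blank images classify as all background; empty ER in an ROI errors
  ("empty ER in ROI"); a frame with empty ER in a time series is flagged,
  not fatal.
- Constant kymographs → direction "none", speed 0.
- Classifier determinism: fixed seed, single-threaded ranger; serialized
  models round-trip bit-identically.
- All TIFF/CSV/JSON writers are deterministic, so write→read→write is
  byte-identical; float TIFFs store intensities scaled to [0, 1] with the
  scale in a JSON sidecar.

# Problem sizes used in validation

The shipped test-suite and acceptance-script problem sizes are the
package's chosen validation scale: 256² px scenes; 30 scenes for the
segmentation validation; 5 fractions × 5 seeds for fraction recovery; the
full ±{0.01…0.08} µm⁻¹ curvature sweeps at the default 0.1-µm mesh
(~30,000 elements per case); and the robustness grid at 5 parameter
points. These sizes give stable results at desk scale; all are config
parameters and scale up unchanged.

# Known limitations

- The mechanics is linear and quasi-static: no buckling, no active
  remodeling of ER during loading, no cortex rate dependence (an extension
  hook — a single-parameter viscous update — is the natural next step).
- The 2D plane-stress section cannot report out-of-plane sheet bending;
  conclusions are restricted to in-plane orderings.
- The classifier is trained per imaging model; applying a model trained on
  the synthetic conditions to real micrographs requires retraining on
  labeled regions of those micrographs (the workflow exists:
  `train_classifier()` on a label matrix).
- MDE is reported in absolute micrometres; comparisons across cells of
  very different depth may warrant a normalized variant.
- Spline curvature endpoints are unreliable on sparsely traced arcs
  (< ~100 vertices over a strongly curved arc).
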