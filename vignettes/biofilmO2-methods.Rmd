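---
title: "Patch-scale biofilm O2 transport and metabolism: models and methods"
author: "biofilmO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-scale biofilm O2 transport and metabolism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmO2)
```

# The scientific problem

Phototrophic stream biofilms organize into patches of distinct
composition and architecture: a cyanobacteria-dominated base layer
(CDB), diatom-dominated patches (DDP), and tall filamentous
Klebsormidiophyceae-dominated patches (KDP). Their metabolism (net
photosynthesis NP in light, respiration R in darkness) both shapes and
is shaped by oxygen transport: O2 must cross the diffusive boundary
layer above the biofilm, and within the porous biofilm matrix it moves
both by diffusion (reduced relative to water) and by advection through
the pore space. `biofilmO2` implements the full analysis chain that
connects structural imaging, microsensor chemistry, and physics-based
modelling of these patches:

1. **Imaging** — biofilm surface topology (digital elevation models,
   DEMs) and internal porosity from optical coherence tomography (OCT)
   intensity volumes; patch-type maps from colour segmentation of
   macrophotographs; patch geometry statistics.
2. **Microprofiles** — calibration, drift correction, surface
   alignment, and 2D gradient analysis of O2 microsensor depth
   profiles.
3. **Hydrodynamics and transport** — a steady 2D coupled free-flow /
   porous-biofilm solver for velocity, pressure, and O2
   advection-diffusion-reaction.
4. **Inverse modelling** — Nelder-Mead estimation of transport and
   metabolic parameters from measured O2 transects.
5. **Upscaling** — volume-weighted aggregation of patch metabolic
   rates into landscape O2 budgets.
6. **Synthetic data** — generators that emulate the flume study design
   so every stage is testable without instrument data.

# Flow model

The water column above the biofilm is modelled as steady, incompressible
and turbulent with a constant-eddy-viscosity Reynolds-averaged closure:
the effective kinematic viscosity in the free-flow region is
$\nu + \nu_t$. Inside the biofilm, treated as a water-saturated porous
medium, a Brinkman-type momentum balance combines a Darcy drag
$(\nu/K)\,\bar u$ with a viscous term scaled by $1/\epsilon$. This
formulation couples naturally to free flow (velocity and stress are
continuous at the interface) and recovers the Darcy limit for small
permeability, which supplies one of our closed-form oracles. The
effective-viscosity convention in the Brinkman term ($\mu/\epsilon$
rather than $\mu$) is not observable at the permeabilities of interest;
a regression test verifies insensitivity at $K \le 2\times10^{-10}$ m².

Boundary conditions reproduce a flume working section: a Dirichlet
velocity profile at the inlet (a quadratic fit of velocimetry points
over the lowest 5 mm of the water column), zero static pressure at the
outlet, no-slip at the substrate and a slip (zero-shear) lid at the
top, which stands in for the remaining water column. The inlet profile
is imposed across the biofilm inlet cells as well; this over-predicts
velocities in the porous matrix near the inlet and equilibrates within
roughly a millimetre downstream. Statistics of the interior flow
therefore exclude an entrance margin (default 1.5 mm) — without it a
flat base-layer domain is dominated by the artificial entrance
through-flow and comparisons between geometries are meaningless.

Turbulence does not penetrate the porous matrix at these scales, so
eddy viscosity and eddy diffusivity apply only in the free-flow
region; inside the biofilm the O2 diffusivity is $C\,D_{aq}$ alone.

# Transport model

Steady O2 transport solves
$-D\nabla^2 c + \bar u \cdot \nabla c = R$ with $D = D_{aq} + D_t$ in
water ($D_t = \nu_t / P_{rt}$) and $D = C\,D_{aq}$ in the biofilm, and
a uniform volumetric reaction rate $R$ in the biofilm region — negative
for dark respiration, positive for net photosynthesis. Boundary
conditions: Dirichlet concentration profile at the inlet, advective
outflow (zero diffusive flux) at the outlet, zero flux at top and
bottom. Concentrations that turn negative beyond 1% of the field scale
raise a "consumption exceeds supply" warning and are reported
unclipped: this is a physically meaningful diagnostic, not a numerical
artifact to be hidden.

The ratio of advective to diffusive flux magnitudes,
$J_c/J_d = |\bar u\, c| / |D_{\mathrm{eff}} \nabla c|$, is computed per
cell; values above 1 mark advection-dominated transport. Cells with
vanishing diffusive flux report an infinite ratio and are excluded
from region means.

# Discretization

Both equations are discretized with a structured finite-volume scheme
on a tensor-product grid: a staggered (MAC) arrangement for momentum
and continuity (velocities on faces, pressure at cell centres),
cell-centred for the scalar. The vertical grid is uniformly fine in a
band covering the biofilm interface (55% of cells by default) and
geometrically stretched above; typical runs use 40 x 44 to 60 x 60
cells, and a refinement test verifies that halving the cell size moves
the biofilm-mean concentration by less than 1%.

Convection is implicit first-order upwind. For the scalar a
deferred-correction central scheme is iterated to a fixed point
(default up to 8 sweeps, tolerance 1e-10 on the relative change, with
the factorized matrix reused), restoring second-order accuracy while
remaining stable at cell Peclet numbers above 2. Momentum advection is
retained through Picard iteration (under-relaxation 0.7, relative
tolerance 1e-6, first iteration unrelaxed) without a deferred
correction: the momentum oracles are advection-free, the fit operates
in either mode, and the first-order momentum truncation error is
dominated by the eddy-viscosity model error in the free stream. A
Stokes-Brinkman mode (advection off) solves the saddle-point system in
a single sparse LU factorization and underlies the closed-form checks:
half-Poiseuille channel flow (no-slip bottom, slip top), the Darcy
slab, and the 1D reaction-diffusion parabola, each matched to well
under 1% on 64-cell grids.

Because the discretization is conservative, the steady scalar balance
$\int_{biofilm} R\,dV = $ net boundary flux holds to round-off; it is
checked with the binary-indicator biofilm area (the region the solver
actually applies the source in). The geometric biofilm area reported
to users accounts for partial cell coverage, matching the trapezoid
integral of the elevation profile; the binary indicator carries an
O(dz/2) staircase bias on flat profile sections that would otherwise
contaminate geometry checks.

Wall shear over the biofilm surface is evaluated with the molecular
viscosity from the first water cell above the interface: the derived
quantities ($u^* = \sqrt{\tau/\rho}$, $\delta = \nu/u^*$,
$\mathrm{DBL} = \delta/\sqrt{Sc}$) are viscous-sublayer properties to
which the constant-eddy-viscosity closure does not apply. With
flume-like settings this yields $\delta$ of a few hundredths of a
millimetre and DBL scales of a few micrometres.

# Imaging conventions

Rasters are row-major with the origin at the upstream-left corner,
heights in millimetres, and pixel sizes carried as metadata;
half-open pixel intervals. The DEM of a volume is the highest voxel
above an intensity threshold per column, referenced to the substrate
plane (auto-detected as the brightest z slice in the lowest quartile of
the volume), followed by a size-4 median filter; columns with no
signal report zero height and are counted. Tiles acquired in a mosaic
with fractional overlap are stitched by translation with averaging in
the overlaps.

Porosity is defined as the void fraction — void voxels over total
voxels in the top layer of each column. Two gray thresholds (120, 130)
and two layer depths (0.1, 0.2 mm) span the estimation uncertainty;
the per-type estimate is the median over columns for each setting,
reported with the min-max band over the four settings. Void/total
(rather than biomass/total) is the reading under which the loosely
packed filamentous patch type has the *higher* porosity, which is the
physically meaningful orientation. Columns protruding beyond the
reliable imaging depth (1.2 mm) are excluded, and the layer is sampled
strictly below the surface voxel, which delimits the biofilm rather
than sampling its interior.

Patch segmentation thresholds default to Otsu's criterion on the
feature images (red/green ratio for DDP; green channel averaged with a
local mean filter for KDP), a reproducible parameter-free choice since
no canonical threshold values exist; all are overridable. Small
objects and holes below 25 px are removed, and the KDP mask is dilated
5 px by default to capture the diffuse filament fringe of real
photographs. Ground-truth recovery tests run without dilation: the
synthetic images have no fringe, so dilation only adds a border that
is absent from the generating mask.

# Microprofile conventions

Calibration is the affine map through the anoxic and air-saturated
readings; drift is compensated by linear interpolation of repeated
bulk-water readings (samples are rescaled so the interpolated bulk
maps to the reference bulk). Surface alignment refines the OCT height
by the inflection point of the O2 profiles, implemented as the maximum
summed absolute second difference of the light and dark profiles
within ±0.3 mm of the OCT height. Two estimator details matter: the
per-condition curvature magnitudes are summed rather than averaging
the profiles first, because light and dark deficits cancel in the mean
when NP and |R| are comparable; and pre-smoothing is off by default
because a 3-point running mean displaces the curvature maximum of a
sharp interface by about one sensor step (0.05 mm), defeating the
one-step accuracy the estimator should deliver on clean data. Flat or
out-of-window profiles fall back to the OCT height with a warning.

Transect gradient fields are built by triangulating the sample points.
Profiles at x stations with fixed 50 µm vertical steps form a
structured grid, so the triangulation splits each grid quad into two
triangles; gradients come from the exact plane through each triangle's
vertices (exact for affine fields) and node gradients are area-weighted
over incident triangles. The angle convention reports the direction of
transport down the gradient ($-\nabla c$): 0° points downstream, 90°
toward the substrate. A dark, diffusion-dominated slab yields a median
angle of 90°; with strong internal advection the against-flow bending
(angles above 90°) appears downstream of the internal concentration
minimum, where depletion creates a back-gradient — a whole-patch
transect has its median tilted below 90° toward the minimum, so tests
of the bending sample the rear flank of the patch.

# Parameter estimation

The objective is the sum of squared differences between measured
transect concentrations and the modelled field interpolated bilinearly
at the sensor coordinates. Free parameters (any subset of R, K,
$\epsilon$, C, $P_{rt}$, $\nu_t$) are optimized by Nelder-Mead over a
smooth bound transform — log10 scale for K and $\nu_t$, then a logit
onto the bounds for all — so the simplex roams an unconstrained space
and bounds act without penalty walls. Default bounds bracket plausible
fitted values for these biofilms ($\epsilon \in [0.2, 0.95]$,
$C \in [0.4, 1]$, $K \in [10^{-11}, 5\times10^{-10}]$ m²,
$|R| \le 6\times10^{-3}$ mol m⁻³ s⁻¹). The stopping rule is the
optimizer's relative objective tolerance (default 1e-4) or the
evaluation budget; random restarts (jittered starts, best objective
wins) mitigate entrapment in local optima. Solver failures return a
large finite sentinel so the simplex retreats rather than aborting.
Eddy viscosity is initialized from the mixing-length estimate
$\nu_t \approx 0.07\,h\,u^*$ with $P_{rt} = 1$.

Identifiability, quantified by the packaged recovery study
(`recoveryStudy()`): R and C are strongly informed (profile depth and
curvature; typically recovered within a few percent at realistic
sensor noise), K is informed through internal advection on protruding
geometries (tens of percent), and $\epsilon$ enters only the momentum
equations and is weakly identified — tolerances of 15% (R, C) and 50%
($\epsilon$, K) reflect this structure. The recovery experiments run
in Stokes-Brinkman mode on a 36 x 40 grid with five profiles at 50 µm
steps and noise SD 2e-3 mol m⁻³: the generator and the fitter share
the physics exactly, isolating the estimation question from model
error.

# Upscaling

Patch volumetric rates convert to fluxes across the projected planar
area by multiplication with mean thickness, volume/area carried in
millimetres — the only convention under which the published patch and
landscape budget tables are internally consistent, reproduced here
with the printed unit label and this documented caveat. Landscape
volumetric rates are biovolume-weighted means of patch rates
(a convex combination, invariant to splitting a patch at equal rate),
and landscape areal fluxes multiply by total volume over total area.
Net ecosystem production is NEP = NP + R with R negative. Spatial
arrangement and between-patch interactions are not considered.

# Synthetic-data generator

The generator defines the study conditions for every test:

* **Landscape**: DDP and KDP patches are Gaussian-smoothed thresholded
  noise blobs (1 mm correlation length) on a CDB base; KDP is placed
  first and takes precedence, and DDP thresholds are taken among the
  remaining pixels so realized coverages are exact at pixel
  resolution. Per-type heights are spatially correlated fields
  standardized to the target mean and SD (clipped at 0.01 mm).
  Defaults are the slow-flow landscape statistics: heights
  0.39/0.58/1.09 mm (SD 0.15/0.15/0.24), coverages 0.70/0.20/0.098,
  porosities 0.36/0.47/0.58 for CDB/DDP/KDP. No biological
  realism is claimed for blob shapes — they provide controllable
  coverage and correlation structure only.
* **OCT volumes**: a bright substrate plane, sub-surface voxels drawn
  as biomass (gray > 130) or void (gray < 120) with void probability
  equal to the target porosity, the surface voxel pinned to biomass,
  low-intensity noise above the surface, and a gentle depth decay of
  biomass intensity. The defaults use a 0.01 mm axial voxel (the
  instrument's nominal 2.18 µm would make test volumes needlessly
  large); gray-level conventions deliberately exercise the
  two-threshold uncertainty band of the porosity estimator.
* **Macrophotographs**: patch-specific coloration (elevated red/green
  ratio for DDP, elevated green for KDP) with additive Gaussian
  channel noise (SD 0.03) and mild height shading.
* **Inlet velocimetry**: points from a quadratic profile vanishing at
  the wall over the lowest 5 mm (14 points by default).
* **O2 transects**: forward-model fields sampled at 50 µm steps with
  additive Gaussian sensor noise; the true parameters are recorded in
  the transect metadata for recovery experiments.

What the generator does **not** emulate — OCT speckle statistics and
realistic attenuation, shadows and illumination gradients in
photographs, sensor response-time dynamics, 3D flow steering around
patches, biological morphogenesis — bounds what passing tests show:
they certify the pipeline's internal consistency and its numerical
claims, not robustness to every artifact of real instrument data.

# Degenerate inputs and edge policies

Empty masks, zero-coverage classes, all-background images,
zero-length series and zero flow all have defined behaviour (errors
with messages where the quantity is undefined, zeros or warnings where
a benign default exists); these paths are unit-tested. Ties in the
surface estimator resolve to the lowest z in the window;
interpolation outside the cell-centre lattice clamps to the boundary
cell; labels always partition the raster with KDP taking precedence
over DDP.

# Known limitations

The model is 2D: flow crosses protruding patches entirely over their
tops, which inflates dynamic pressure differences and hence internal
advection relative to a 3D reality; fitted permeabilities absorb part
of this bias. The constant eddy viscosity has no wall damping, so the
modelled boundary layer is sharper than reality just above the
interface. The reaction rate is uniform within a patch (no light
attenuation with depth, no substrate limitation). Fitted parameters
carry no formal uncertainty quantification — the recovery study
characterizes the estimator, not the posterior. Landscape upscaling
ignores spatial covariance between patches.
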