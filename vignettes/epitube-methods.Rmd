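---
title: "Models and methods behind epitube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epitube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

epitube collects the computational machinery needed to study how embryonic
epithelial tubes (mouse lung bronchi, kidney collecting ducts) elongate with
a directional bias: why tubes lengthen about twice as much as they widen,
whether mechanically forced tube collapse could provide the directional cue,
whether luminal fluid shear is strong enough for cells to sense, and how a
longitudinally biased force acting on an epithelial sheet translates into
biased cell shapes, division orientations, and tissue outgrowth. This
vignette describes each model, its assumptions, its tunable parameters, and
the numerical choices made, in the package's own terms.

## 1. The proliferating vertex model

The apical surface of the tube epithelium is represented as a planar
tessellation: each cell is a polygon of shared vertices, and the
configuration energy is

$$U = \sum_k \lambda\,(A_k - A_{0,k})^2 \;+\; \sum_k \beta\,(C_k - C_{0,k})^2
      \;+\; \sum_{\text{edges}} \gamma\,\ell,$$

with per-cell area $A_k$ and perimeter $C_k$, area elasticity $\lambda$,
perimeter (cortical contractility) elasticity $\beta$, and line tension
$\gamma$ per edge, distinguishing cell–cell contacts from the free tissue
boundary. Vertices follow overdamped dynamics
$\dot{x} = -\nabla U/\xi$ plus external forces. All quantities are in model
units (a.u.); the initial cell area sets the length scale.

Defaults: $\lambda = 100$, $\beta = 10$, $\gamma_{cc} = 1$,
$\gamma_{boundary} = 10$, drag $\xi = 1$ — the canonical coefficient set of
the vertex-model literature. The target-shape index $c_0 = C_0/\sqrt{A_0} =
3.55$ sits below the regular hexagon's 3.72, i.e. a mildly contractile
cortex.

**Growth and division.** Cells grow by linear target-area inflation over
their cycle, $A_{0}( \tau ) = A_0 (1 + \tau/T)$, reaching twice the base
target at the nominal cycle end and continuing linearly if division is
delayed. A cell divides when its age exceeds its sampled cycle duration
*and* its area exceeds its sampled division threshold; both are resampled
per daughter from truncated Gaussians. Division follows Hertwig's rule: the
cell is split through its area centroid along the shortest principal axis of
the polygon's second-moment tensor (that is, perpendicular to its longest
axis). Exactly degenerate axes (a regular polygon) draw a uniformly random
axis; a split that fails to produce two simple polygons is retried with
±5° jitter. An optional mode (`hertwig_aspect_threshold = 1.53`, off by
default) switches to a random axis below the aspect ratio at which real
lung epithelial cells stop orienting their spindle; the default is always
shortest-axis, per the simulation protocol the package reproduces.

**Topology.** Interior edges shorter than the T1 threshold (1% of the
initial mean edge length) undergo a neighbour exchange, with the new edge
opened perpendicular at 1.5× the threshold; triangular cells below 1% of
the mean area are removed (T2). Both are enabled by default. The integration
step is adaptive: the base step `dt = 0.002` is shortened whenever the
largest vertex displacement would exceed a quarter of the T1 threshold
(edge lengths are checked against the threshold after every step), so
rearrangement events cannot be stepped over.

**Differentiated boundary rows and the elongation force.** Cells of the
top-most and bottom-most rows of the initial honeycomb (fixed at
initialization by centroid rank) are differentiated: they never divide, and
their vertices carry the external longitudinal force — $+f\hat{y}$ on the
top row, $-f\hat{y}$ on the bottom — emulating the pull that apical shear
stress (or the cells' active response to it) exerts along the tube axis.
The tissue boundary is otherwise free. The model makes no attempt to equate
$f$ with a physical shear-stress level; it is an abstract longitudinal
force, and the simulated force axis is anchored by one calibrated scalar
(`force_unit`) chosen so that `boundary_force = 1` a.u. reproduces the
2-fold outgrowth bias measured for embryonic lung tubes between E10.5 and
E11.5. This re-anchoring is a pure relabelling of the force axis.

**Calibration of the stochastic parameters.** Apical area variability and
the neighbour-count spectrum of the simulated tissue are controlled by the
cycle-duration and division-threshold Gaussians. A sweep over these four
parameters selected `cycle_mean = 10`, `cycle_sd = 5`, `div_area_mean = 4`,
`div_area_sd = 3` (truncations at 0.5 and 0.2), which reproduce the target
statistics of the E11.5 lung apical surface — area coefficient of variation
0.6 ± 0.1 and ~30% hexagons — in the unforced simulation, while a 100-cell
tissue grows to ~250–300 cells over the standard duration of 48 a.u. The
division threshold must exceed the doubled base target: it is the
heavy-tailed waiting for large thresholds, superimposed on cycle-length
dispersion, that widens the area distribution to a CV of 0.6.

**Burn-in and residual lattice anisotropy.** The honeycomb generator trims
an integer row/column layout to the requested cell count and then applies a
small area-preserving anisotropic rescale (about 8% for 100 cells) to hit
the requested bounding-box aspect exactly. The simulation relaxes the
tissue force-free for 2 a.u. before taking the reference snapshot;
otherwise that relaxation would contaminate the outgrowth-bias measurement
(without it, an unforced tissue reports a spurious bias of ~0.93). The
pre-strain leaves a trace: unforced division angles carry a weak axial
orientation signal (about 1.5x between the extreme 15-degree bins over
~700 divisions) that only large samples resolve — at 200 divisions the
distribution is statistically uniform. The forced operating point's
strong axial mode is an order of magnitude above this residual.

**Read-outs.** `compute_outgrowth_bias()` reports
$(L_f/L_0)/(W_f/W_0)$ from the bounding box of cell centroids (vertex
bounding boxes are noisier: a single protruding boundary cell moves them).
`shape_statistics()` uses the population SD in the area CV and counts a
cell's neighbours as the cells sharing at least one edge, boundary cells
included but flagged. `displacement_profile()` tracks each initial cell's
descendants by averaging their centroids.

## 2. Tube collapse as a stretch-and-bend ring

Collapse of a tube cross-section is modelled on the tissue midline: a
closed ring of straight segments with constant thickness $t$, elastic
energy

$$U = \frac{E^* t}{2}\oint \varepsilon^2\,ds +
      \frac{E^* t^3}{24}\oint \kappa^2\,ds, \qquad E^* = \frac{E}{1-\nu^2},$$

with hoop Cauchy strain $\varepsilon$ per segment and curvature $\kappa$
from the turning angle at each node over the mean adjacent segment length.
The tissue is intrinsically uncurved: a stress-free configuration would be
flat, so even the initial circle stores bending energy. This is a
geometrically nonlinear Euler–Bernoulli (stretch + bend) discretization;
transverse shear deformation is deliberately omitted — the observables
reproduced here (collapsed shapes, localization of hoop stress and
curvature) do not depend on it at the qualitative level, and $\nu$ enters
only through $E^*$. The energy quadrature uses the material (rest) arc
measure so pure stretching does not change bending energy; reported
profiles use current geometry.

Dynamics are $M\ddot{x} + D\dot{x} = f(x)$ with lumped masses
$m_i = \rho\,t\,s_i$, damping $D = M/\tau$, integrated by an explicit
second-order Newmark scheme in predictor–corrector form
($\beta = 0, \gamma = 1/2$). The stable step is estimated from the
stiffest stretch/bend/contact mode and re-estimated every 50 steps because
segments shorten as the tube folds. Defaults: $E = 1$, $\nu = 0.49$
(nearly incompressible tissue), $\rho = 1$, $\tau = 1$, $R = 1$,
$t = 0.5R$, 100 segments.

Three load scenarios: (i) a net pressure difference applied along the
current inward normals (a follower load), ramped linearly until the
enclosed area has collapsed and then held; (ii) two rigid horizontal
clamps approaching at constant speed until they are 2.5 tissue thicknesses
apart; (iii) linear drainage of the enclosed area, imposed through a stiff
quadratic penalty (stiffness $2000\,E^*t/R^2$, keeping the volume error
below 0.5% — a Lagrange multiplier would enforce it exactly but the penalty
keeps the explicit integrator simple and the error bound is the stated
contract). Contact — between opposite tube walls and with the clamps — is
penalty-based with stiffness $40\,E^*t$ per unit length, activated at
surface separation (midline distance below $t$, accounting for the
half-thickness on each side); interpenetration stays below 5% of $t$.

Because a perfect circle is a (metastable) equilibrium of both the pressure
and the drainage load, those two scenarios seed a deterministic mode-2
radial perturbation (amplitude $10^{-4}R$ by default); $\cos 2\theta$ is
mirror-symmetric about both axes, so symmetric equilibria remain available.
Equilibrium is declared when the maximum nodal speed falls below
$10^{-5} R/\tau$ and the residual force below $10^{-5} E t$; the stricter
$10^{-8}$ is attainable but costs hundreds of $\tau$ of damped ringing for
no visible change in the configurations, so $10^{-5}$ is the shipped
default (configurable in `collapse_control()`).

`buckling_pressure()` estimates the critical pressure from a slow ramp as
the pressure at the turning point of the ring's radial deviation: below
threshold the seeded non-circularity decays, above it grows, so the
minimum of the deviation trace marks the onset. On a thin ring
($t/R = 0.1$, where the classical formula applies) this lands within a few
percent of $P_{cr} = 3E^*I/R^3$, $I = t^3/12$. At the default $t/R = 0.5$
the same machinery produces the collapsed dumbbell shapes with hoop stress
concentrated at the two extremal-curvature points. One caveat worth
stating: draining a thick-walled tube to 20% of its lumen forces the
midline perimeter to shorten, so deep-drainage equilibria carry a large
near-uniform compressive hoop stress on top of the localized bending
signal; stress localization is therefore sharpest in the clamp scenario
and at moderate drainage, while curvature localization survives deep
drainage.

## 3. Wall shear stress in the lumen

For steady laminar flow along a tube of constant cross-section the axial
velocity solves a Poisson problem on the section, $-\nabla^2 u = G/\mu$,
with no-slip walls — the fully developed limit of Stokes flow. Two solvers
are provided.

*Closed form on ellipses* (`ellipse_wall_shear()`): the velocity is the
exact paraboloid $u = u_{max}(1 - y^2/a^2 - z^2/b^2)$ with
$u_{max} = 2\bar{u}$ and $\dot{V} = \pi a b \bar{u}$; the wall shear
magnitude is
$\tau(\theta) = 2\mu u_{max}\sqrt{\cos^2\theta/a^2 + \sin^2\theta/b^2}$,
maximal at the minor-axis co-vertices (the flat side of a collapsed lumen)
and minimal at the strongly curved major-axis tips. The reported mean is
the arc-length-weighted boundary average by adaptive quadrature. With the
measured inputs — viscosity 0.016 Pa·s (ten times water), mean velocity
0.364 µm/s (half the fastest-bead speed 0.73 µm/s, the lower-bound
read-out of a parabolic profile) — a collapsed lumen of 2 µm opening
yields mean wall shear in the 0.01–0.1 Pa range, within the reported
sensitivity of renal epithelial cells, while a 20 µm opening yields only
~10⁻³ Pa.

*Arbitrary polygons* (`solve_cross_section_flow()`): a masked
finite-difference discretization on a regular grid (default 400 cells
across the major extent) with Shortley–Weller boundary stencils, so the
no-slip condition acts at the exact wall location; the sparse system is
solved directly (Matrix). Linearity makes the rescaling of $G$ to the
requested mean velocity or flow rate exact. Wall shear is the one-sided
normal derivative at the wall, obtained per boundary sample by a
least-squares fit of $u \approx \alpha d + \beta d^2$ over interior nodes
within ~2.4 grid cells, $d$ being the exact distance to the polygon — a
quadratic extrapolation robust to the staircase of the grid. Boundary
samples shorter than a grid cell are excluded from the shear statistics.
On ellipses the numerical mean shear agrees with the closed form to better
than 2% across aspect ratios 1–50; the momentum identity
$\bar{\tau} P = G A$ provides an implementation-independent cross-check.
The solver requires at least 20 interior samples across the narrowest
opening and refuses coarser resolutions.

`mean_velocity_from_tracks()` implements the bead read-out: per-track speed
is the maximum consecutive-displacement speed (no smoothing by default;
3-point smoothing available for noisy tracks), the fastest track bounds the
peak velocity from below, and $\bar{u} = u_{max}/2$ under the parabolic
profile. The generator `make_bead_tracks()` seeds beads uniformly in an
elliptical section and advects them at the local Poiseuille speed, so the
lower-bound property and the $n \to \infty$ convergence are exact by
construction.

## 4. Branch morphometrics of 2D explant movies

The pipeline mirrors the skeleton-based quantification of epifluorescence
explant time series: contrast-limited adaptive histogram equalization,
background subtraction by grayscale opening with a disc (the package's
rolling-ball-style estimate), global Otsu thresholding, Gaussian boundary
smoothing with re-thresholding at 0.5, and selection of the dominant
foreground component. The preprocessing parameters (CLAHE tiling,
background radius 25 px, blur σ = 2 px) are package defaults — the
operation chain, not the parameter values, is what the pipeline fixes —
and all are exposed and logged.

Skeletonization is Guo–Hall thinning (two-subiteration, topology
preserving, 1 px wide; implemented in the package since no installed
package provides 2D thinning), followed by pruning of spurs shorter than
the local width read from the distance transform, which suppresses the
width-scale artifacts that blunt tube ends otherwise produce. Branch
graphs take junctions as 8-connected clusters of skeleton pixels with ≥3
neighbours (merged at their centroid), endpoints as pixels with one.
Branch length sums pixel steps (1 axial, √2 diagonal, including the
connecting step into each junction cluster) × pixel size, measured on a
stride-3 simplification of the pixel chain: raw 8-connected step sums
overestimate digitized curves by up to ~6% (staircase effect); with the
simplification, synthetic curved tubes of known centerline length are
recovered within ~1%. Branch width is twice the Euclidean distance
transform averaged along the branch, excluding pixels within one local
radius of a junction. Coordinates in all public outputs are 0-based
(row, col), y-down; lengths are in µm.

Branch lineages across frames use overlap-after-dilation matching: each
old branch is dilated by its half-width, overlaps with the new branches
are counted, and a greedy one-to-one assignment by overlap (ties broken by
centroid distance) continues lineages; unmatched new branches become
children of their best-overlapping (else nearest) predecessor lineage.
Relative length/width series are normalized to each branch's first
appearance — branches appear at different times, so normalizing to the
movie's first frame would be undefined for later branches. The 2D
elongation bias of a lineage is its final relative length over relative
width.

## 5. Synthetic data and what passing tests mean

Every module is exercised end-to-end on generated inputs with exact ground
truth: honeycomb tissues, elliptical and dumbbell lumen polygons, bead
tracks with a known Poiseuille profile, and growing-tube mask/image series
rendered by exact point-to-polyline distance thresholded at the half-width
(sub-pixel unbiased, so measured widths are not systematically offset).
All generators are deterministic under a mandatory seed.

These generators emulate geometry and kinematics, not microscopy: no
photon noise model, no uneven illumination, no segmentation ambiguity at
tissue contacts, no out-of-plane motion. Tests passing on them validate
the measurement and simulation machinery — length/width recovery,
tracking, flow physics, mechanics — on clean inputs with known answers;
they do not certify segmentation performance on real fluorescence movies,
where the preprocessing parameters would need tuning per dataset.

## 6. Problem sizes and reproducibility

The shipped test-suite and acceptance-script configurations use the study
conditions directly: 100-cell tissues run for 48 a.u. (5 seeds for all
tissue statistics), 100-element rings, 2–5-frame image series, and
closed-form shear evaluations; property checks that only need an ordering
(bias vs force, tension antagonism) use half-length runs (24 a.u., 2
seeds), where the ordering is already established. Single runs complete in
tens of seconds; every stochastic path takes an explicit integer seed and
identical seeds give bitwise-identical results. Configurations round-trip
through YAML/JSON (`sim_config()`), and run manifests record parameters,
seed and package version next to every CLI output.
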