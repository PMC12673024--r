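---
title: "Personalizing ventricular tissue conductivity from QRS duration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalizing ventricular tissue conductivity from QRS duration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cardiotwin builds desk-scale digital twins of the human ventricles and
estimates two tissue properties — the myocyte radius $R$ and an
extracellular conductivity factor $ECF$ — from a single clinical
measurement, the QRS duration. This vignette explains the models behind
each stage, the tunable parameters and their defaults, the numerical
choices, and what the synthetic validation can and cannot show about real
data.

## The tissue model

Ventricular tissue is treated as a continuum of cylindrical myocytes of
radius $R$ (µm) embedded in an extracellular space that occupies the volume
fraction $ECV$. Conduction is monodomain: per axis $a$ (fiber, transverse,
sheet-normal) the intra- and extracellular conductivities combine
harmonically,

$$\sigma^{e}_{a} = \sigma^{e,0}_{a}\,\frac{ECV}{ECV_{ref}}\,(1 - ECF),
\qquad
\sigma^{mono}_{a} = \frac{\sigma^{i}_{a}\,\sigma^{e}_{a}}
                         {\sigma^{i}_{a} + \sigma^{e}_{a}},
\qquad
D_a = \frac{\sigma^{mono}_{a}}{\beta\,C_m},\qquad \beta = \frac{2}{R}.$$

Three consequences drive the whole method. A larger cell radius lowers the
surface-to-volume ratio $\beta$ and accelerates conduction ($D \propto R$);
a larger $ECV$ raises extracellular conductivity and also accelerates
conduction; a larger $ECF$ — the proxy for fibrotic occupancy of the
extracellular space — depresses it, down to a non-conducting tissue at
$ECF = 1$ (handled as a flagged degenerate state, not an error). $ECV$ is
measured by imaging and is an input; $R$ and $ECF$ are the free parameters
the inverse method estimates.

The exact functional form of the $ECF$ scaling is a package design choice:
we scale all extracellular axes linearly and uniformly, keep the
intracellular conductivities untouched, and normalize $ECV$ so that the
reference state ($R = 15.45$ µm, $ECV = 25.8\%$, $ECF = 0$) reproduces the
baseline conductivities identically. The mapping sits behind a single
function (`effective_conductivity()`), so an alternative law can be swapped
in without touching anything downstream.

Baseline per-axis conductivities live in a versioned YAML file
(`inst/extdata/baseline_conductivities.yaml`). They are chosen in the upper
part of the experimentally reported range so that reference tissue conducts
at ≈75 cm/s along the fiber (≈28 cm/s across it). This is deliberate:
physiological activation is mimicked by simultaneously pacing five
endocardial sites rather than by an explicit His–Purkinje network, and
without a fast endocardial layer the tissue itself must carry realistic
total activation times. With these defaults the reference biventricular
model produces a QRS surrogate of ~80–85 ms and septal conduction
velocities of ~50–60 cm/s under apical pacing — inside the clinically
expected range for QRS ≤ 110 ms patients.

## Membrane kinetics

The reaction term is the ten Tusscher–Panfilov 2006 human ventricular
myocyte model (19 states), integrated with Rush–Larsen exponential updates
for the gates and forward updates for the potential and concentrations.
The epicardial parameter set is the tissue default; endocardial and
mid-myocardial variants are available for single-cell work. Default steps:
0.02 ms in tissue, refined automatically whenever explicit diffusion
stability requires it; single-cell reference oracles use 0.001–0.01 ms.
Stimuli are transmembrane current injections (2 ms, ~2× diastolic
threshold; 40–50 pA/pF).

## Forward activation: two engines, one contract

**Monodomain reference.** Linear P1 finite elements on tetrahedra with mass
lumping, reaction–diffusion operator splitting (diffusion sub-step 0.1 ms,
automatically reduced if a Gershgorin bound detects instability). The
protocol is 1000 ms of quiescence — integrated as a single cell and
broadcast, which is exact for uniform resting tissue — followed by S1
pacing at 600 ms cycle length; activation is the first upward crossing of
0 mV on the last beat. "Until steady state" defaults to 3 beats; strand
calibrations propagate a single front, which at this cycle length differs
negligibly from the steady-state front. The solver refuses meshes coarser
than 1 mm edges: full-ionic accuracy is not defensible there.

**Calibrated eikonal.** Biventricular runs use an anisotropic eikonal
solver: per-element slowness metrics from the fiber field and the per-axis
conduction velocities, first-arrival times from the stimulus sites. The
velocities are *calibrated*, not assumed: a fine 1-D monodomain strand is
run at the direction's diffusivity and its measured CV feeds the metric.
Calibration strands adapt their spacing with $\sqrt{D}$ so the wavefront is
equally resolved across the whole parameter range, and results are cached.
When the eikonal is compared against a *coarse* monodomain run (as in the
cross-engine checks), calibration is instead performed at the target mesh
resolution, which cancels the discrete dispersion bias of the coarse grid.

The default local solver is a fast-iterative method with the closed-form
piecewise-linear update, robust on the strongly non-convex biventricular
anatomy. A source-factored variant is also provided: it represents the
solution as (analytic straight-line time) × (mesh-solved correction) and is
exact on convex homogeneous regions independent of resolution, but the
straight-line factor can cut across unmeshed cavities, so it is reserved
for convex domains (validation cubes, slabs, strand-like geometries).

**QRS surrogate.** The model's QRS duration is the total activation time —
latest activation minus earliest stimulus onset — which is insensitive to
QRS morphology and needs no extracellular potential recovery.

**Radius sweeps at one solve.** Within the personalization loops the
activation *order* is independent of $R$: changing $R$ rescales all
diffusivities by the same factor, so both axis velocities scale together
and times scale as $1/CV_{fiber}(R)$. The engine therefore caches one
normalized map per (mesh, pacing, $ECV$, $ECF$) — computed at unit fiber
speed with the anisotropy ratio calibrated at the reference radius — and
rescales it. The neglected drift of the calibrated anisotropy ratio across
the admissible radius range measures below 0.1%. This makes a full radius
bisection as cheap as one eikonal solve and keeps $QRS(R)$ exactly
monotone, which the fitting assumes and asserts.

## Idealized anatomy

Patient meshes are out of scope; the anatomy module builds an idealized
stand-in. The LV is a thick-walled truncated ellipsoidal shell; the RV is a
thin-walled crescent extruded outward from a rotational sector of the LV
epicardium, with the cavity gap pinching to exact attachment along both
insertion lines and at an apical ring — so the free wall is electrically
continuous with the septum where real anatomy attaches it. The wall
midsurface is triangulated with rings graded to the target edge length
(including near the apex pole), extruded transmurally into prisms, and
split into tetrahedra with a minimum-vertex diagonal rule that guarantees a
conforming mesh. Construction is fully deterministic. The default
desk-scale edge length is 1.5 mm for single models and 3.0 mm for cohort
work; wall thickness may vary with apicobasal position.

Ventricular coordinates: transmural is a Laplace (harmonic) field, 0 on the
endocardium and 1 on the epicardium, with the RV-facing septal surface
counting as the septum's outer boundary; apicobasal is the normalized
geodesic position between apex and base, $d_{apex}/(d_{apex}+d_{base})$ —
a pure Laplace solve is unusable here because the apex boundary set is
point-like in 3-D and the harmonic field hugs 1 almost everywhere;
rotational is the angle about the long axis with origin at the anterior
LV–RV junction. Fibers are rule-based: the helix angle interpolates
linearly in the transmural coordinate from +60° (endo) to −60° (epi) in a
frame built from the coordinate gradients. AHA segmentation uses the
apicobasal cuts 0.12/0.41/0.70 and the standard 6/6/4+apex rotational
sectors; wall thickness per segment is the area-weighted endo-to-nearest-
outer-surface distance, whose weighted mean reproduces the LV average
identically.

Landmarks: five early activation sites (defaults: LV septal mid and basal,
LV anterior paraseptal, LV inferior free wall, RV anterior free wall — all
endocardial, simultaneous onset, configurable via `eas_spec`); an RV apical
pacing site at the most apical free-wall endocardium near mid-sector, so
the paced wave enters the septum at its apical end; and a CV probe pair on
the RV-facing septal endocardium ~20 mm apart (geodesic along the septal
surface) in the apicobasal direction. The default RV site deviates from a
septal placement deliberately: with a line-attached idealized free wall, a
septal-only RV site delays free-wall activation by tens of milliseconds,
which no physiological activation map shows.

## The two-step inverse method

For each patient, the pre/post wall thicknesses and ECVs fix the radius
ratio
$$\rho = \sqrt{\frac{WT_{post}\,(1-ECV_{post})}
                    {WT_{pre}\,(1-ECV_{pre})}},$$
the conservation form implied by a constant number and length of
cylindrical myocytes (total myocyte volume ∝ wall thickness × (1−ECV)).
The formula is pluggable; everything downstream depends only on $\rho$.

**Step 1 — radius.** Find the smallest $R_{pre}$ (bisection to 0.05 µm,
both radii constrained to 9.6–17.8 µm) such that *both* models, at
$ECF = 0$ and with $R_{post} = \rho R_{pre}$, produce a QRS no longer than
their patient's. Monotonicity of $QRS(R)$ makes the feasible set an
interval; infeasibility at the upper bound is flagged and the ECF stage
skipped for that model. When the two timepoints disagree, the binding
(larger) minimal radius wins — the only reading under which "shorter than
or equal to" holds for each model.

**Step 2 — ECF.** Per timepoint, walk $ECF$ upward on the 5% grid while
the absolute QRS mismatch improves; monotonicity of $QRS(ECF)$ makes the
first worsening step terminal, and ties break toward smaller $ECF$.

Once personalized, each model is paced from the RV apex and the septal CV
is measured as geodesic probe separation over activation-time difference.

**Identifiability.** A single QRS number cannot pin down $(R, ECF)$
jointly: pairs trading a smaller radius against less fibrosis produce
identical activation times. The two-step convention resolves the
degeneracy canonically — the smallest admissible radius, then the smallest
ECF consistent with it; with two coupled timepoints, one timepoint is
binding (its ECF is forced to 0 unless the radius bound binds) and the
other absorbs the residual in ECF. Any synthetic ground truth must respect
this manifold for parameter recovery to be a meaningful test, which is why
the cohort generator draws truth in canonical form (below).

## The synthetic cohort

Real patient data are not available, so the cohort module generates paired
pre/post records that emulate the *structure* of a small surgical
aortic-valve-replacement cohort: 12 patients by default, half female;
pre-surgical ECV centred on 24.2% rising by ~4 points after surgery; wall
thickness centred on 10.3 mm (female) / 12.7 mm (male) shrinking by ~21% /
~8% respectively (the sex effect enters only through the wall-thickness
reduction); true radii drawn inside the histological 9.6–17.8 µm range and
within the window the ratio constraint allows; true ECF on the 5% grid with
half the patients fibrosis-free. All continuous draws are truncated
normals sampled by inversion (generation cannot fail); one timepoint per
patient, drawn at random, is binding and carries $ECF = 0$. "Patient" QRS
durations are produced by running the forward model at the true parameters
(optional measurement noise, default 0, as a recovery experiment demands),
and the ground-truth $\rho$ is computed from the generated thicknesses and
ECVs with the same conservation formula the inverse method uses, closing
the bookkeeping loop exactly.

Cohort models use an 18/36 mm ellipsoid at 3.0 mm edges: small enough that
a 20-patient generation-plus-recovery cycle completes in a few minutes,
large enough that QRS surrogates stay in the 75–105 ms band of the
inclusion criterion. These sizes, like every default above, were fixed
once as the package's study conditions.

**What passing recovery does and does not show.** Noise-free recovery on
this cohort demonstrates that the implementation inverts its own forward
model on the prescribed grids — an internal-consistency property, and the
right first test of an inverse method. It does not demonstrate robustness
to QRS measurement noise (available via `qrs_noise_sd_ms`), to
model-anatomy mismatch (every twin here uses the same idealized geometry
family), to EAS placement error, or to departures of real tissue from the
cylindrical-myocyte continuum. Those are the caveats that separate these
synthetic results from a clinical validation.

## Statistics

The analysis toolkit mirrors what a paired-cohort study needs: Wilcoxon
matched-pairs signed rank (exact by enumeration — implemented as dynamic
programming over doubled mid-ranks, identical to summing over all $2^n$
sign assignments — for n ≤ 25), Mann-Whitney (exact by enumerating all
group assignments for combined n ≤ 16), and Spearman correlation (exact by
full permutation enumeration for n ≤ 8). Larger samples use the standard
tie-corrected approximations, always flagged. All tests are two-sided with
no multiplicity correction; summaries are median and IQR with type-7
(linear-interpolation) quantiles.

## Numerical choices and limitations

* Explicit diffusion is guarded by stability checks (strand: $D\,dt/h^2
  \le 0.3$; FEM: Gershgorin bound) that shrink the step rather than fail.
* Activation threshold 0 mV, upward crossing, linear sub-step
  interpolation; configurable.
* The eikonal solver is first-order; absolute activation times carry a few
  percent discretization error at 3 mm edges. Personalization is
  insensitive to this: generation and fitting share the engine, and the
  method only compares model QRS values with one another.
* Calibrated CVs inherit the dispersion of the calibration strand
  (sub-2% upon halving the already-fine default spacing).
* The idealized RV attaches to the septum along lines rather than across a
  junction area; activation crossing the attachment is slightly delayed
  relative to continuous anatomy.
* Monodomain only; no extracellular potentials, no ECG morphology, no
  bidomain. Changes in sodium channels, gap junctions or other active
  membrane properties between timepoints are explicitly out of scope.
* Wall thickness is measured on the one (end-diastolic) geometry the mesh
  represents.

## Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates
every headline quantity from scratch: the cable-theory $\sqrt{2}$ ratio,
the monotonicity fractions, the cross-engine slab agreement, and the full
12-patient synthetic cohort with recovery errors, fitted radii, septal CVs
and the paired statistics. The test suite (`testthat`) additionally runs a
20-patient recovery and the brute-force oracle comparisons.
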