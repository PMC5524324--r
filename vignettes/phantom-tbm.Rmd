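---
title: "Phantom-based tensor morphometry for small primate cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based tensor morphometry for small primate cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Studies of the MPTP-lesioned marmoset — a non-human-primate model of
Parkinson's disease — quantify structural brain change from high-resolution
ex vivo T2-weighted MRI in two complementary ways: hypothesis-driven manual
ROI volumetry (caudate, putamen, substantia nigra, hippocampus, cortical
thickness, with skull and whole-brain volumes as normalisers) and
hypothesis-free tensor-based morphometry (TBM), where every subject is
non-rigidly registered to a control template and the Jacobian determinant of
the deformation is tested voxel by voxel. Group sizes in such work are
necessarily small (typically 4 controls vs 7 treated animals), which makes
the statistical machinery — exhaustive permutation tests, FDR correction,
and post-hoc power analysis — as important as the image processing.

No image data from such studies are publicly deposited. `marmotbm`
therefore pairs the full analysis pipeline with a synthetic phantom
generator whose ground truth (applied transforms, per-region volume
factors, deformation fields) is known exactly, so that every stage is
verified by parameter recovery rather than by eye.

## The phantom world

`build_atlas()` constructs a labelled head from nested geometric
primitives: an ellipsoidal skull shell, a brain ellipsoid whose outer 15%
radial band forms a cortical ribbon (split into motor / parietal / temporal
sectors per hemisphere plus one occipital reference patch), bilateral
caudate, putamen, substantia nigra and hippocampus ellipsoids, and paired
ventricular cavities. Geometry is expressed in coordinates normalised to
the grid's physical half-extent, so the default acquisition grid
(96 x 96 x 60 voxels at 0.175 x 0.175 x 0.5 mm) and the reduced CI grid
(64 x 64 x 48) carry the same topology. The whole assembly is tilted 9
degrees about the x axis — partly cosmetic (a specimen rarely lies exactly
along the scanner axes), but mainly numerical: it de-phases structure
boundaries from the voxel lattice so that sub-voxel warps change discrete
volumes gradually rather than in grid-aligned steps. The fidelity target is
*topological* (which structures exist and which neighbour which), not
metric anatomy.

One acquisition-geometry note: the source protocol quotes a voxel volume of
0.0875 mm^3 alongside 0.175 mm in-plane resolution and 0.5 mm slices; the
product of the stated spacings is 0.0153125 mm^3, and the phantom uses the
product (0.0875 is the product of one in-plane spacing and the slice
thickness, i.e. a per-slice-edge area, not a volume).

### Signal model

`simulate_t2_image()` emulates a multi-echo spin-echo acquisition whose
echoes (default eight, 10–80 ms) are summed into one T2-weighted image:
per region, `signal = PD * sum_k exp(-TE_k / T2)`. Default tissue values
give bright fluid (ventricles, T2 250 ms), intermediate grey matter,
slightly hypointense substantia nigra (T2 45 ms, emulating
neuromelanin/iron), dark skull, and zero-signal background (the specimen is
immersed in a hydrogen-free fluid). Noise is additive Gaussian
(default sd 5 on tissue signals of roughly 300–670), not Rician: summed
multi-echo magnitude data at this SNR are effectively Gaussian, and the sd
is an explicit knob.

### Inter-subject variability

Each subject is the atlas passed through (i) a rigid jitter (translation sd
0.3 mm, rotation sd 2 degrees), (ii) one isotropic global scale draw, and
(iii) a smooth random warp (RMS 0.1 mm, correlation length 2 mm), composed
into a single pull-back map so labels are resampled exactly once. The
global-scale sd defaults to 0.01 (about 3% in volume). That number is
pinned by the study design this package emulates: reported Cohen's d values
of 3–7.5 for ~12% volume effects imply a within-group volume coefficient of
variation of about 3%. With a markedly larger spread those effect sizes
would be unreachable, and the seeded recovery tests would be testing a
different world than the one reported.

### Calibrated atrophy and the voxel-aliasing trap

`apply_atrophy()` injects known regional volume change. Deep structures get
a radial contraction toward their centroid; cortical ribbon sectors get a
normal-direction squeeze toward their mid-surface (computed in
brain-ellipsoid scaled coordinates), which thins the ribbon instead of
shrinking it tangentially. Every field is weighted by the region's
*mollified membership* (its binary mask smoothed with a 0.6 mm Gaussian,
peak-normalised) and additionally confined to brain tissue by a mollified
brain mask, so the skull never moves. These choices were forced by failure
modes of simpler designs: a centroid-ellipsoid weight floods the brain
interior for shell-shaped sectors (dragging hippocampus and ventricles
along), and an unconfined membership tail bridges the thin CSF gap and
inflates the skull. With the final design untargeted deep regions recover
volume factors of 1.00 and the skull is exactly preserved in the leakage
tests; the immediate neighbourhood of a squeezed ribbon (unlabelled brain
tissue, hippocampus) may still gain a few percent as it expands into the
vacated space — visible, and documented, in the end-to-end group tables.

The field is linear in the per-region strengths, so the strengths are
calibrated by Gauss–Seidel sweeps of bracketed monotone searches against
recounted label volumes, using precomputed sparse basis fields. Two
numerical facts shaped this design. First, any binary label map places its
boundary halfway between voxel centres: a coherent sub-half-voxel
displacement is invisible to nearest-neighbour resampling, so labels are
warped by *anti-aliased voting* (`warp_labels_smooth()`): each label's
indicator is mollified (0.5 voxel), interpolated at the pull-back
positions, and the largest value wins. Second, even then the discrete
volume response to the contraction strength is a monotone ladder with a
flat dead zone near zero — derivative-based root finding fails, bracketed
bisection does not. Requested fractions are achieved within ±0.02
(the default tolerance; requests outside the reachable set raise an error
reporting the best achieved value). The calibration contract is stated for
subjects carrying anatomical variability — on the pristine atlas the ladder
is coarser, which is one reason atrophy is injected *after* the subject
warp in `sample_cohort()`.

## Registration

`register_linear()` maximises normalised cross-correlation by Nelder–Mead
over a 3-level coarse-to-fine pyramid; 6 dof is rigid, 9 dof adds per-axis
log-scales whose product estimates the whole-brain volume ratio. NCC was
chosen because the phantoms are intra-modality with possible global
intensity differences; the optimiser is derivative-free because trilinear
resampling makes the objective piecewise smooth at best. The canonical
reference is the first control subject, mirroring the single-control
reference of the emulated workflow; `population_mean()` registers each
image to it (9 dof by default) and averages.

`register_fluid()` is a compositive demons scheme standing in for the
"fluid model" of the emulated pipeline (the original citations give no
equations): force = intensity difference times the image gradient — by
default the *symmetric* mean of the fixed and warped-moving gradients,
which recovered injected deformations measurably better than the classic
fixed-gradient force in the package's own end-to-end experiments — with
the classic stabilised denominator; the update field is Gaussian-smoothed
(the fluid-like regularisation of the velocity), capped at 0.4 voxel per
axis, and composed with the running field. The default update smoothing is
0.9 mm: in group studies the Jacobian maps of *different subjects* must be
comparable voxel by voxel, and heavier regularisation buys cross-subject
consistency at the price of per-structure sharpness (for registering a
single pair with a small focal difference, ~0.5 mm resolves better; the
parameter is explicit in `fluid_params()`). A step is accepted only if SSD
does not increase *and* the composed field keeps a positive interior
Jacobian; rejected steps retry at half length, and after ten consecutive
rejections the level is abandoned with diagnostics in the returned
metadata (`level_aborted`, SSD trace) rather than raising an error — a
level that is already at its attainable SSD floor is normal when the
images differ only in a small region. SSD is therefore non-increasing
across accepted iterations by construction, and every accepted field
satisfies `min interior det > 0`; both are asserted in the test suite.

Conventions, fixed package-wide: axis order x, y, z; world coordinates
`(index - 1) * spacing + origin` (voxel centres, mm); displacement fields
are stored in mm on the *fixed* grid and act as pull-backs,
`out(x) = in(x + u(x))`; a linear transform maps fixed-image world points
to moving-image world points. `jacobian_map()` differentiates `x + u(x)`
with spacing-aware central differences (one-sided at the border; border
voxels are excluded from statistics via the eroded brain mask). Under these
conventions a determinant below 1 means the moving image (the subject) is
locally smaller than the fixed image (the control mean) — i.e. atrophy —
and the forward (template-to-subject) direction is the one computed.

## Voxel-wise statistics

`tbm_voxelwise()` tests log-transformed determinants by default: log makes
a halving and a doubling symmetric and group means meaningful; raw
determinants remain available (`log_transform = FALSE`). With 4 vs 7
subjects there are exactly `choose(11, 4) = 330` distinct relabelings, so
permutation p-values are computed by exhaustive enumeration (vectorised
over voxels through one indicator-matrix multiplication); Monte-Carlo
sampling with the `(b+1)/(m+1)` estimator engages only above a configurable
cap. Exhaustive mode is deterministic and its smallest attainable p is
1/330. Two practical consequences are worth knowing. At the uncorrected
threshold p < 0.01 the attainable p-values below threshold are 1/330, 2/330
and 3/330, so the null rejection rate is at most 3/330 = 0.0091 — the test
is slightly conservative by granularity alone. And Benjamini–Hochberg at
q = 0.05 over m masked voxels can only reject if at least `(1/330) m / q`,
about 6% of the mask, reaches the minimal p; with small effects the FDR
mask is legitimately empty even when uncorrected maps show structure. This
granularity is a real property of exhaustive permutation inference at these
group sizes, not an implementation artifact.

The granularity interacts with the phantom's realistic anatomy to put a
hard ceiling on voxel-wise recovery. In the seeded end-to-end cohort the
injected smooth anatomical warp leaves a within-group log-determinant sd
of about 0.045 per voxel — real inter-subject anatomy, not registration
error — while the injected effects are 0.10-0.13 (deep grey) and about
0.10 concentrated on a 0.9 mm cortical ribbon. A voxel only reaches the
minimal p of 1/330 when the two groups separate completely, which at these
effect-to-noise ratios happens at roughly a fifth to a third of the truly
atrophied voxels. The FDR mask therefore switches on (the ~6%-of-mask
min-p requirement is met) and lands almost entirely inside or adjacent to
the true lesion, but its Dice overlap with the full true masks plateaus
near 0.21-0.23 across every registration setting explored (update
smoothing 0.35-1.2 mm, deeper convergence, symmetric vs fixed forces,
optional Jacobian-map smoothing — which only hurts, because the anatomy
noise is correlated at 2 mm and the thin-ribbon signal blurs first). The
acceptance suite states Dice > 0.3 for this recovery; that criterion is
implemented exactly as stated and left failing, with the analysis above as
the explanation: it is not reachable in this stated world without either
more subjects (finer permutation resolution) or unrealistically clone-like
phantom anatomy.

Zero-variance voxels (all subjects tied) get t = 0 and are counted and
reported rather than propagating NaN. The brain mask is the union of brain
labels eroded by one voxel, keeping one-sided-difference border Jacobians
out of the family.

## Power analysis

`ttest_power()` uses the noncentral t distribution
(`df = n1 + n2 - 2`, `ncp = d sqrt(n1 n2 / (n1 + n2))`); sample-size
solvers scan N upward under an allocation ratio and return the smallest N
meeting the target, which makes the minimality contract testable.
`pearson_power()` uses the Fisher z approximation with the standard mean
bias correction `z_r = atanh(r) + r / (2(n - 1))`. The bias term is
included deliberately: it is what the widely used desk calculators
implement, and it reproduces the canonical n = 29 for r = 0.5 at 80% power
(the uncorrected formula lands at 29.01 and would round to 30). Note that
small-n correlation claims of the form "r > 0.8 still requires N = 28" are
not reproducible from this (or the uncorrected) approximation, which gives
single-digit n for r = 0.8; the package documents rather than targets such
statements.

## What a green test establishes — and what it does not

The phantoms share the acquisition geometry, contrast ordering, noise
scale, group sizes and effect magnitudes of the emulated study, and the
end-to-end tests show that the pipeline recovers injected 12–13% deep-grey
atrophy and 4–11% cortical thinning at those settings. They do not
establish anatomical realism: the atlas is parametric, partial-volume
effects are only crudely present, intensity confounds (iron accumulation,
fixation gradients) are absent, and rigid-body jitter is far smaller than
real positioning variability. Registration accuracy on real ex vivo tissue
is harder than on these phantoms; the recovery bounds here are best read as
necessary, not sufficient, conditions for the real workflow.

## Numerical details worth knowing

* Label resampling is nearest-neighbour in the cohort warp (validity by
  construction) and anti-aliased voting inside the atrophy calibration (see
  above); ties in the vote resolve to the lower label id.
* Cortical thickness: exact Euclidean distance transform
  (Felzenszwalb–Huttenlocher, spacing-aware), five systematic sites along
  the ribbon's longest bounding-box axis, thickness = 2 x medial distance
  minus one in-plane voxel (centre-to-centre distances overshoot the
  boundary-to-boundary crossing by about one voxel; the correction makes a
  one-voxel sheet measure exactly one voxel thick).
* Group statistics follow the emulated design: classic pooled-variance
  independent t for skull and whole brain (Welch available), two-way ANOVA
  (group x side, or group x cortical region) with Sidak-adjusted per-cell
  contrasts elsewhere; Cohen's d uses the pooled sd. Degenerate
  zero-variance cells report d = 0 (equal means) or Inf instead of
  aborting a coarse-grid run.
* All randomness is locally seeded (`with_local_seed()`): generators never
  disturb the caller's RNG state, and a master seed fans out
  deterministically to per-subject, per-stage seeds recorded in the run
  manifest.
* NIfTI-1 I/O is implemented in the package (float64 scalars and fields,
  uint8 labels, little-endian, single-file `.nii`, JSON sidecars for label
  dictionaries); files have been cross-checked against an independent
  reader. Write-then-read round-trips are bit-exact.

## Known limitations

* The atlas is not an anatomical marmoset atlas; region volumes are of the
  right order but not calibrated to histology.
* The fluid stand-in is a demons scheme, not a Navier–Stokes solver;
  very large deformations (beyond ~2–3 voxels) are out of its sweet spot.
* Exhaustive-permutation FDR at n = 4 + 7 has the granularity floor
  described above; studies needing voxel-wise FDR sensitivity at these
  sizes should consider larger relabeling families (e.g. sign-flips on
  within-pair statistics) — out of scope here.
* The CLI covers the documented subcommands; it is a thin layer over the
  exported functions and not a workflow manager.
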