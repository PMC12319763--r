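---
title: "Simulating and analysing fMRI of adjacent somatosensory nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing fMRI of adjacent somatosensory nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Somatosensory input from the hands and face is relayed through a chain of
small, adjacent nuclei: the cuneate nucleus of the dorsal medulla (hand), the
spinal trigeminal nucleus directly lateral to it (face), the ventroposterior
lateral and medial thalamus, and finally the hand and face regions of primary
somatosensory cortex (S1). The brainstem nuclei measure only a few
millimetres, so at typical 3T resolutions (1.8 mm isotropic here) each
nucleus spans a handful of voxels, neighbouring nuclei share voxels through
partial-volume effects and smoothing, and cardiac and respiratory pulsation
contribute noise comparable to the signal itself. Under these conditions
univariate contrasts between hand and face movement can fail to separate the
nuclei even when their multivoxel activity patterns remain discriminable.

`somatopipe` builds a fully synthetic, seeded model of this situation and
runs the complete analysis chain on it. Everything is generated in code: no
template images, no acquired data. The purpose is twofold — to provide a
working reference implementation of each analysis component (physiological
regression, block-design GLM, nonparametric group inference with TFCE,
across-subject decoding, searchlight cluster correction), and to verify by
simulation that each component delivers what its statistics promise
(calibrated nulls, controlled familywise error, recovery of injected
effects).

# The phantom

`build_phantom_atlas()` lays out three region slabs stacked along z —
brainstem, thalamus, S1 — and ten nuclei inside them: bilateral cuneate and
spinal trigeminal nuclei (face-adjacent neighbours at the midline of the
brainstem slab, mirror-symmetric across x), bilateral VPL with a midline VPM,
and bilateral S1 hand areas with a midline S1 face area. Default nucleus
boxes are 2 × 2 × 3 voxels (3.6 × 3.6 × 5.4 mm at 1.8 mm voxels), matching
the few-millimetre scale of the real structures. Geometry is validated at
construction: nuclei must be nonempty, inside their parent region, pairwise
disjoint, the cuneate pair exactly mirror-symmetric, and each cuneate
face-adjacent to its ipsilateral trigeminal neighbour (no gap — the
adjacency that makes the decoding problem hard).

Laterality follows the anatomy of the dorsal-column and trigeminal pathways:
hand movement drives the **ipsilateral** cuneate analogue and the
**contralateral** VPL and S1-hand analogues; face movement drives the
trigeminal, VPM, and S1-face analogues **bilaterally**. The wiring table is
stored on the atlas and can be overridden.

# Effect structure and its calibration

`effect_spec()` holds the four scalars that define the study conditions:

| parameter             | default | units  | meaning |
|-----------------------|---------|--------|---------|
| `snr["s1"]`           | 2       | —      | response amplitude / thermal noise sd in S1 |
| `snr["thalamus"]`     | 0.4     | —      | same, thalamus |
| `snr["brainstem"]`    | 0.15    | —      | same, brainstem |
| `amplitude`           | 2       | % PSC  | plateau response of an active voxel |
| `pattern_overlap`     | 0.5     | [0, 1] | fraction of a nucleus's voxels shared with the neighbouring condition's pattern |
| `subject_variability` | 0.6     | sd     | per-voxel multiplicative and additive perturbation of the shared template |

Condition templates carry heterogeneous per-voxel weights (log-normal, sd
0.5 on the log scale, unit mean per nucleus), drawn once from a fixed
template seed. Templates therefore depend only on the atlas and effect spec,
while the cohort seed drives subject-level perturbations — this separation
makes across-subject decoding possible (subjects share group-level pattern
structure) while keeping every cohort a pure function of its seed.
`pattern_overlap` controls the adjacency confound: at 1, hand and face
patterns occupy identical voxels in the cuneate/trigeminal pair with equal
mean amplitude, so mean contrasts are null while pattern geometry still
separates the conditions.

The SNR values are calibration knobs, not empirical claims. They were set
once, by a three-configuration sweep on a reduced cohort, to the realistic
regime the package is meant to exercise: near-ceiling decoding in S1,
intermediate accuracy in thalamus, and brainstem accuracy well above the
33.3% chance level but far below ceiling. They were then frozen; the test
suite asserts the ordering, not any particular accuracy value. Per-voxel
contrast-to-noise of 0.1–0.3 in deep structures and ~1–2 in cortex at 3T is
the regime these defaults encode.

# Simulation

A run is simulated as

```
Y(v, t) = baseline
        + Σ_c G_c(v) · x_c(t)                      (condition responses)
        + a_v · lin(t) + b_v · cos(2π t / T)       (drift)
        + α_v sin φ_c(t) + β_v cos φ_c(t)          (cardiac, in-brain)
        + γ_v sin φ_r(t) + δ_v cos φ_r(t)          (respiratory, in-brain)
        + σ(v) ε(v, t)                             (thermal noise)
```

with baseline 100 (so one intensity unit is one percent signal change),
`x_c` the condition boxcar convolved with the canonical HRF — the *same*
regressor the design module builds, so a noiseless simulation is recovered
by the GLM to machine precision — and `σ(v) = amplitude / SNR(region)`
inside the labelled regions. Per-voxel drift and physiological coefficients
are Gaussian with configurable scale; physiological components are exact
first-order functions of the instantaneous phase, which makes the RETROICOR
regressors consequential by construction (the regression-efficacy test
verifies that including them strictly reduces residual variance). Thermal
noise is white by default; an AR(1) flag exists but is off, matching the
OLS-without-prewhitening analysis. Head motion is summarised as one
log-normal mean-absolute-displacement scalar per run (median ≈ 0.3 mm,
occasionally exceeding the 1 mm exclusion threshold); image-space motion is
not simulated, because only the exclusion rule consumes it.

Physiological recordings are simulated directly: cardiac peak times at
jittered inter-beat intervals around 1 Hz (per-subject rates drawn around
1.0 ± 0.1 Hz) and a frequency- and amplitude-jittered respiratory sinusoid
around 0.3 Hz sampled at 496 Hz.

What the phantom deliberately does **not** emulate: slice timing and
slicewise physiological phase (phases are assigned at mid-volume times), EPI
distortion and k-space artefacts, image-space motion and registration,
resampling between acquisition and analysis grids, spatially correlated
thermal noise, and surface geometry. Passing tests therefore demonstrate
correctness of the analysis logic under the stated noise model — not
robustness to artefacts the phantom does not contain.

# Design and first-level model

`make_block_schedule()` draws a pseudo-random order of 24 movement blocks
(8 per condition) under two constraints: no condition three times in a row,
and every condition present in each ordinal quarter of the run (a concrete
counterbalancing rule; the quarter constraint is enforced only when there
are at least four blocks per condition, below which it is unsatisfiable).
Runs drawn from one seed get distinct orders. A lead-in rest pads the 432 s
task structure to the 447.5 s of 179 volumes at TR 2.5 s.

`nominal_volume_counts()` implements the bookkeeping convention in which
each 12 s block contributes `ceiling(12 / 2.5) = 5` volumes, so four default
runs give 160 volumes per movement condition and 236 rest volumes. This is a
counting convention kept separate from simulation-time sampling, where block
edges need not align with the volume grid.

The HRF basis is the canonical double-gamma (response gamma shape 6, scale
1; undershoot gamma shape 16, weighted 1/6; peak near 5 s) with its
finite-difference temporal derivative and a numerical dispersion derivative,
each normalised to unit peak absolute value and sampled from a 16×
oversampled grid. Task regressors are scaled by the plateau response of a
single reference block, so a regression weight of 1 means "the plateau
percent-signal-change of one block" — this is what makes recovered betas
directly comparable to injected amplitudes. High-pass filtering is a
discrete-cosine drift block (`floor(2T / 90 s)` cosines plus intercept),
chosen over a running-line filter for exact testability. Inference uses only
canonical-column weights; nonzero weights on derivative columns are a
contract violation and raise an error. The movement-versus-all contrast uses
+1 on the target and −1/2 on each other condition. Rest is the implicit
baseline. The GLM is OLS with degrees-of-freedom-corrected residual
variance; no prewhitening, consistent with the simulator's white noise.

Run exclusion (>1 mm, strictly greater) applies to the within-subject
fixed-effects combination only; every run still yields beta maps, so the
decoding table of a complete default cohort always has 20 × 4 × 3 = 240
rows. Fixed effects combine runs by inverse-variance weighting, with the
combined z taken against a normal reference.

# Physiological regressors

Cardiac phase advances linearly between recorded peaks,
`φ = 2π (t − t_k)/(t_{k+1} − t_k)`; times outside the peak span extend the
nearest interval periodically and are flagged. Respiratory phase is
histogram-equalised: with `F` the empirical amplitude CDF, inhalation maps
to `π F(b)` and exhalation to `2π − π F(b)`. The regressor set is
`sin/cos(k φ_c)` for k ≤ cardiac order, likewise respiratory, and
`sin/cos(m φ_c ± n φ_r)` for every pair m, n up to the interaction order —
four columns per (m, n) pair, which is the only convention consistent with a
34-column model at orders 4/4/2 plus heart rate and respiration volume. The
column-count law is `K = 2c + 2r + 4i² + |extras|`. Heart rate is the
smoothed inverse inter-beat interval; respiration volume per time is breath
amplitude over breath period from peak-segmented breaths; heart-rate
variability is a 6-beat moving sd of inter-beat intervals — all interpolated
to mid-volume times, uncolvolved (the slow regressors enter raw).

# Group inference

The one-sample group test computes a pseudo-t (subject mean over
variance smoothed with a 5 mm FWHM Gaussian), enhances it with TFCE
(`Σ_h extent(h)^0.5 · h² · dh`, 26-connected components, `dh` = observed
max / 100, reused for all permutations), and builds the familywise null from
the maximum enhanced value under random sign flips of the subject maps.
Corrected p values are proportions of the null at or above the observed
value, floored at 1/n_perm. Smoothing uses half-sample-symmetric reflection,
the boundary rule under which a normalised symmetric kernel preserves the
image sum exactly. Component labelling crops to the suprathreshold bounding
box and exploits the nesting of TFCE threshold sets (equal suprathreshold
count ⇒ identical set) to avoid redundant labelling passes.

# ROI statistics

Per-ROI subject × condition tables of mean z are tested with a gated
procedure: the ±2.5 sd outlier rule first (single pass; mean and sd from the
full cell — note that a single extreme value inflates the cell sd enough to
mask itself, which is a property of the rule, not a bug), Shapiro–Wilk per
cell, then repeated-measures ANOVA (via `aov` with an `Error(subject/
condition)` stratum) with partial η², Mauchly's test, and a
Greenhouse–Geisser-corrected p when sphericity fails — or, if any cell
violates normality, Friedman's test with Kendall's W and Dunn's rank-based
post-hoc z tests. Planned contrasts compare the ROI's target condition (the
condition whose afferents the nucleus relays) against each non-target, with
Bonferroni (or Dunn) correction within ROI. A table with no within-subject
variation short-circuits to F = 0, p = 1.

# Decoding

Features are canonical-HRF betas at mask voxels, all voxels retained
regardless of intensity. The classifier is a linear multiclass SVM at C = 1
(libsvm's one-vs-one reduction; the standard linear multiclass reductions
are equivalent for this purpose, and no tuning is done anywhere). One
numerical choice: features are divided by a single scalar — the standard
deviation of the training fold's feature matrix — before fitting. A global
scalar rescaling keeps libsvm's optimiser in a well-conditioned regime
without per-feature renormalisation, and the scalar is derived from the
training fold only, so cross-validation hygiene is preserved. Folds are
subjects (leave-one-subject-out); accuracy is the pooled accuracy from the
unnormalised confusion matrix.

The permutation null shuffles labels within subject — the exchangeable unit
for subject-level folds — and refits the full LOSO pipeline per shuffle; the
empirical p is the proportion of null accuracies at or above the observed,
floored at 1/n_perm. The searchlight decodes sphere ∩ mask features at every
mask voxel (offsets with `‖v ⊙ voxel size‖ ≤ r`, 123 offsets at 3 mm / 1 mm,
7 at 1.8 mm voxels); permutation maps reuse one within-subject shuffle per
map across all centres. Cluster correction pools all voxels of all
permutation maps for the voxelwise accuracy cutoff (95th percentile by
default), thresholds observed and permutation maps at that cutoff (values at
or above pass), takes the 95th percentile of per-map maximum cluster sizes
as the size cutoff, and keeps observed clusters **strictly larger** than it
— the strict inequality makes the procedure exactly null-safe when the
observed map is exchangeable with the permutation maps.

# Problem sizes and reproducibility

Every stochastic operation is a pure function of its inputs and an integer
seed (via `withr::with_seed`, leaving the global RNG untouched); cohorts,
pipeline runs, and permutation distributions are bit-reproducible. The test
suite and the acceptance script run the full logic at reduced sizes chosen
as the package's verification scale: a 14 × 10 × 9 phantom (180-voxel
brainstem) for cohort-level end-to-end checks, a 20 × 20 × 18 phantom for
the accuracy-gradient checks, 10–20 subjects with 2–4 runs, and 20–200
permutations depending on the statistic. The full-scale defaults (20
subjects × 4 runs, 5000 sign-flip permutations, 1000 label permutations)
remain the `default_pipeline_config()` settings.

# Known limitations

* The noise model is stylised: white thermal noise, sinusoidal physiology,
  scalar motion. Robustness to realistic artefacts is out of scope.
* Friedman's test and Dunn's z use mid-rank ties without continuity
  correction; with the simulated continuous data ties do not occur.
* The searchlight is volumetric only; no surface analysis is provided (the
  cortical analogue is handled by the same volumetric machinery on the S1
  mask).
* `rvt` breath segmentation assumes breaths slower than ~1 Hz; pathological
  waveforms (apnoea, double peaks) are not handled.
* At very low SNR the pooled-null voxel cutoff of the searchlight correction
  can sit close to chance, making cluster recall sensitive to the number of
  permutation maps; at least 100 maps are recommended (fewer triggers a
  warning).
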