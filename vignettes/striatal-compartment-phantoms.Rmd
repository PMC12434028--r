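---
title: "Connectivity-based striatal compartment parcellation on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based striatal compartment parcellation on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The striatum is built from two interdigitated tissue compartments. The
*striosome* is a minority web of thin tubules — roughly 15% of striatal
volume, with branches no wider than about 1.25 mm — embedded in the
contiguous *matrix* that makes up the remaining 85%. The two compartments
sit in segregated structural networks: a set of cortical and subcortical
regions projects preferentially to the matrix (inferior frontal gyrus pars
opercularis, primary motor and somatosensory cortex, supplementary motor
area, superior parietal cortex) and another set to the striosome (posterior
orbitofrontal cortex, anterior insula, basolateral amygdala, basal
operculum, posterior temporal fusiform cortex). Because the compartments can
only be identified directly by histochemical staining of post-mortem
tissue, *connectivity-based parcellation* is used in vivo instead: seed
probabilistic tractography at every striatal voxel, use composite
matrix-favoring and striosome-favoring "bait" masks as targets, and call a
voxel matrix-like or striosome-like according to the share of its
streamlines reaching each composite.

This package implements that full analysis pipeline — tracking,
classification, high-bias mask construction, leave-one-bait-out
somatotopy, and group-level inference — together with a synthetic phantom
generator that provides ground truth for every stage. Group-level results
on clinical cohorts depend on restricted human data; the phantoms make the
pipeline itself testable end-to-end, from streamline propagation to
family-wise error control.

## The phantom

`build_phantom()` constructs a 1 mm isotropic grid (default 40 x 48 x 40,
about 3,000 striatal voxels) holding:

* **Nuclei.** Mirror-symmetric ellipsoidal caudate and putamen per
  hemisphere, in right-anterior-superior axis order ("rostral" is +y,
  "ventral" is -z), with an explicit affine.
* **Ground-truth compartments.** Striosomes are grown as unbranched
  random-walk tubules, one voxel thick, 26-separated from one another, with
  a rostro-ventral placement bias normalized within each nucleus; growth
  stops when the striosome fraction reaches its 15% target (tolerance
  ±2 percentage points). One-voxel thickness makes the tubule
  cross-section exactly the 1 mm voxel edge, inside the 1.25 mm diameter
  cap reported for human striosome branches; the validator enforces this
  as "no fully-striosome 2x2 in-plane block". Unbranched chains (rather
  than branching walkers) were chosen because branching adds parameters
  without being needed for any invariant — island count, abundance and the
  diameter cap are all expressible on chains, where the thickness check is
  exact.
* **Bait regions.** Ten box-shaped masks: five somatotopic y-bands in a
  dorsal slab (matrix-favoring) and five in a ventral slab
  (striosome-favoring), each slab one voxel away from the striatal surface.
  The bands' y-cuts are striatal y-quantiles, so ground-truth somatotopic
  zones are similar in size.
* **Orientation field.** Each voxel carries a categorical mixture over
  attractor points. A striatal voxel routes `1 - leakage` (default 0.85)
  of its probability toward bait attractors of its own compartment's
  affinity — concentrated on its own somatotopic band's region by
  `zone_weight` (default 0.6) — and `leakage` toward the opposite
  affinity. Attractor points sit far beyond their slab on a vertical axis
  through each band, so drawn directions are near-vertical (dorsal for
  matrix, ventral for striosome). This geometry is deliberate: the tracker
  re-samples a direction at every step from the *local* voxel's mixture,
  so a streamline's destination must be decided by its seed voxel's first
  draw and then preserved. Because the two composite routes are antipodal
  and the tracker flips sign-ambiguous directions toward the current
  heading, draws from traversed tissue wired the other way are folded back
  into the streamline's own heading rather than diverting it. With
  lateral (non-antipodal) target layouts the per-step mixture averaging
  washes out the seed's identity entirely — a property we verified
  empirically before settling on this wiring.
* **Tensor eigenvalues and covariates.** A gray-matter-like eigenvalue
  triple (1.0, 0.6, 0.5) x 10^-3 mm^2/s with ±5% voxel noise supplies
  radial diffusivity; eTIV defaults to 1.438 x 10^6 mm^3.

What the phantom does *not* emulate: raw diffusion signal or scanner
noise, crossing-fiber anatomy, registration error, partial-volume mixing at
compartment borders, or anatomically realistic cortical geometry. Passing
tests therefore demonstrate that the pipeline's logic is correct under its
own assumptions, not that compartment-like voxels in real data coincide
with histological compartments.

## Tracking

`track_classification()` follows the standard probabilistic tractography
settings: curvature threshold 0.2 (minimum cosine between successive unit
steps), 0.5 mm steps, up to 2,000 steps per sample, 5,000 samples per seed
voxel, per-hemisphere tracking with a contra-hemispheric exclusion mask.
Design choices where the convention needed pinning down:

* direction draws are categorical over the voxel's (direction, weight)
  pairs with antipodal symmetrization (orientation is sign-ambiguous);
  a curvature-violating draw is re-drawn once, then the streamline is
  discarded;
* nearest-voxel field lookup, no trilinear interpolation — phantom fields
  are piecewise constant, a documented deviation from real-data trackers;
* first-touch target crediting with immediate termination
  (classification-targets semantics);
* `track_streamline_mode()` adds waypoint/avoid masks and normalizes the
  region-to-region count by the seed volume in mm^3.

On a 1D chain field the tracker (with symmetrization off and curvature
unconstrained) is exactly a biased ±1 random walk; its absorption
frequencies are tested against the gambler's-ruin closed form. One phantom
limitation worth stating: with bait regions as *seeds*, every route into
the striatum crosses the dorsal or ventral striatal surface, which is
mostly matrix, so bait-seeded first-touch counts against whole-compartment
targets cannot discriminate compartments in the phantom (real anatomy
routes these streams through white matter). The matched-versus-mismatched
connectivity property is therefore asserted with compartment voxels as
seeds; the reverse direction is supported and tested mechanically.

## Parcellation

`compute_bias_probabilities()` turns counts into the two superimposable
probability maps (their sum is one on every seeded voxel). The field's
published constants are defaults: bias threshold P ≥ 0.55 (inclusive), indeterminate
band [0.45, 0.55), high-bias mask target 13% of striatal volume with the
larger mask truncated to match the smaller. Choices the sources leave
open, fixed here:

* a classification floor of 10 total streamlines per voxel (avoids 0/0 and
  unstable ratios; configurable);
* high-bias ties at the selection boundary break by (bias descending, flat
  voxel index ascending) for cross-platform determinism;
* cluster connectivity defaults to 26 (the convention of the usual
  volumetric clustering tools);
* normalized volume is the plain ratio raw/eTIV; raw and normalized are
  always reported side by side;
* high-bias locations are reported relative to the centroid of each
  voxel's *nucleus of origin* (caudate or putamen, per hemisphere), which
  isolates within-nucleus location bias from the nuclei's different
  positions.

## Somatotopy

`n_minus_one_parcellation()` re-runs the identical pipeline with one bait
region removed from its composite and the same per-hemisphere seed
streams; the signed influence map is `full p_matrix − N-1 p_matrix` (one
signed map suffices because the two maps are complementary).
`derive_zones()` assigns every voxel with at least one influence above a
per-map floor (default: the map's 95th percentile of absolute influence)
to the region of maximal absolute influence — argmax assignment guarantees
disjointness — then truncates zones to a largest:smallest size ratio of at
most 4 (both parameters configurable; the sources do not state their
thresholding rule). The zone statistic is the signed normalized ratio
(Vdom − Vnon)/(Vdom + Vnon) of compartment-like volumes at P ≥ 0.55, with
the region's favored compartment as dominant; an empty zone is reported as
missing, never as 0.

## Cohorts and inference

`simulate_cohort()` draws healthy controls as jittered copies of one base
phantom (lognormal volume and eTIV noise, σ = 0.03, realized as
mirror-paired boundary erosion/dilation so nucleus geometry stays
symmetric). MDD subjects additionally receive, as study conditions:

* a putamen volume scale of 0.917 (raw putamen volume 8.3% smaller);
* an eTIV scale of 0.960;
* a connectivity-bias shift implemented as a fixed rostral-putamen voxel
  set whose orientation-field bias flips toward striosome-favoring
  targets, sized so striosome-like volume rises 15%, plus an
  indeterminate-band set completing an 8.2% matrix-like reduction — both
  applied per subject with membership probability 0.9 (the shift is a
  change in connectivity, not a relabeling of ground-truth tissue, because
  the measured quantity is connectivity-defined volume);
* a severity gradient that flips 10% of caudate striosome-bias voxels per
  severity category step toward matrix bias, emulating the reported
  caudate shift with severity. Severity scores are binned with the
  published scale tables; shared bin boundaries (Achenbach 85, RCADS 27)
  are resolved half-open to the upper bin.

`group_compare()` is the covariate-adjusted ANOVA (study, scanner, age as
covariates of no interest) with Benjamini–Hochberg correction inside
pre-declared families. The sources describe Benjamini–Hochberg as a
family-wise error method; it is in fact a false-discovery-rate procedure,
and this package implements exactly the cited step-up procedure and labels
its output `bh_adjusted` rather than silently substituting a different
correction.

`permutation_test()` reproduces nonparametric voxelwise inference:
Freedman–Lane residualization of nuisance covariates (permute
reduced-model residuals, add back the reduced fit), a per-permutation
t-map whose variance image is Gaussian-smoothed with σ = 2 mm (the
convention of the tool whose flag takes sigma in mm; switchable), TFCE with
H = 2, E = 0.5, 100 integration steps and 26-connectivity (the published
defaults of that tool; the sources state none), and family-wise correction
by the max-statistic null distribution with the identity permutation
included — so corrected p-values are bounded below by 1/n_perm and
significance is declared at p ≤ α (the exact-calibration convention for
discrete permutation p-values). Negative statistics are enhanced on the
negated map separately. Hemispheres are combined into a single test;
severity analyses run within the MDD subset only.

## Numerical choices and problem sizes

Deterministic behavior is part of the contract: every stage takes an
integer seed, one global seed spawns per-stage substreams, and identical
seeds give bit-identical phantoms, counts and maps. The test suite and the
acceptance script scale problem sizes to what the analysis needs rather
than to the full published settings: the default phantom (~3,000 striatal
voxels) is parcellated with 500–2,000 samples per seed voxel (the
test-retest check uses 2,000), cohort analyses use 20 + 20 subjects on a
reduced 34 x 40 x 34 grid with 300 samples per voxel and 500 permutations,
and the null error-control study uses 200 replicate cohorts of smooth
noise maps on a small mask with 500 permutations each. At these sizes the
classification contrast is far from the 0.55 threshold, so sampling noise
does not move voxel labels; results at the full published settings differ
only in Monte-Carlo error.

## Known limitations

* Compartment-like labels are connectivity constructs; nothing here should
  be read as histological identity.
* The phantom's orientation field is piecewise constant and its bait
  geometry abstract; tracker behaviors that depend on curvature-limited
  propagation through realistic fiber fields are exercised only in
  stylized form.
* Bait-seeded (inverse) tractography cannot discriminate compartments in
  this phantom (see above).
* The F-test degrees of freedom reported by `group_compare()` are
  model-derived; no attempt is made to reproduce non-standard degrees of
  freedom conventions from other software.
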