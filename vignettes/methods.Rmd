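---
title: "Coarse-grained chromatin simulation and FISH distance analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained chromatin simulation and FISH distance analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

chromdist models a chromatin region at nucleosome resolution, samples its
equilibrium 3D configurations by replica-exchange Metropolis Monte Carlo,
and compares the resulting marker-pair distance distributions with
two-color FISH distance measurements at the ~5-kb / ~100-nm scale. This
vignette is the package's own account of the models, the numerical choices
behind them, and what the accompanying tests do and do not demonstrate.
The repository is organized as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions and
write their tables under `results/`; all computation lives in the package
so the test suite and `scripts/acceptance.R` exercise exactly the same
code paths.

## The chain model

A region is described by a `nucleosome_set`: non-overlapping 147-bp
footprints with occupancy scores on a 0-based half-open genomic interval.
`build_chain()` converts it into a chain of segments:

* **Linker DNA** between footprints is converted at 0.34 nm/bp and split
  into at least 2 segments; linkers longer than 20 nm get
  `ceiling(length / 10 nm)` equal segments, so production segments are at
  most 10 nm (~1/5 of the DNA persistence length). Touching footprints
  produce a 0.34-nm stub so the chain stays well defined.
* **Each nucleosome** contributes one stem segment. The nucleosome body (a
  spherocylinder, diameter 11 nm, height 5.5 nm) is placed rigidly relative
  to the stem's local frame by a distance `d` and six angles: the rest kink
  at the two flanking joints (the entry/exit linker geometry), two angles
  for the direction of the center displacement, and three Euler angles for
  the body orientation. Linker histone H1 acts purely through a second
  angle set: its stronger kink (default 1.27 vs 0.83 rad) folds the
  entering and exiting linkers back toward each other (stem formation),
  which compacts the fiber. The exact values of `d` and the angle sets are
  deliberately configuration inputs with documented defaults
  (`nucleosome_geometry()`), not constants: they parameterize a geometry
  family rather than encode one structure, and both sets are replaceable.

Every joint keeps its genomic coordinate, so any bp position maps to a
chain position (`anchor_to_joint()`); marker anchors are probe-set
midpoints mapped to the nearest joint.

A configuration stores joint positions plus one frame vector per segment;
the frame tangent is recomputed from positions, and `f = u x v`
orthonormalizes by construction. Frames are re-orthonormalized at every
sampling point; `validate_configuration()` checks the invariants at 1e-9.

## Energy terms

All energies are in kT at the reference temperature; replica temperatures
are dimensionless multipliers.

**Elastic.** Stretching, bending and torsion are harmonic per segment or
joint. The bending constant is *discretization-corrected*:
`bend_stiffness(Lp, l)` solves `<cos theta> = exp(-l / Lp)` under the
`sin(theta)` measure of the discrete chain, rather than using the naive
`Lp / l`. The naive constant yields an effective persistence length a few
percent above `Lp` at 10-nm segments (a ~+3-4% bias in the end-to-end
statistics of a 300-nm naked chain), which the corrected constant removes;
the worm-like-chain validation below then passes with the bias at ~0.5%
instead of consuming most of its tolerance. Torsional stiffness is
`C / l` with `C = 75` nm; twist is measured after parallel transport of
the frame across the joint.

**Screened electrostatics.** Linker segments carry discrete charge points
(Manning-condensed density 1.41 e/nm, one point per `charge_spacing` nm,
default 2 nm) interacting by Debye-Hueckel repulsion (Debye length 0.96 nm,
100 mM monovalent salt) between non-adjacent segments, truncated at 10
Debye lengths. The unit test for this term integrates the same screened
kernel as a continuous double integral over two parallel rods and requires
2% agreement at fine charge spacing — this is why the spacing is a
parameter rather than the cheaper one-point-per-segment discretization,
which cannot meet that bound.

**Internucleosomal attraction.** An anisotropic pair potential between
nucleosome bodies with a 12-6 radial profile in the surface separation:
the contact distance interpolates between face-to-face (5.5 nm) and
side-by-side (11 nm) from the axis orientations, and the depth anisotropy
is `(0.55 + 0.45 s)^2` with `s` the mean squared alignment of the two axes
and the center line. The depth function has a substantial isotropic floor,
and the well width defaults to 3.5 nm: a purely stacking-selective, narrow
well makes typical encounter orientations feel almost nothing, the contact
coordination number stays near 2, and the fiber then never condenses
beyond local zig-zag stacking at physiological well depths. With the floor
and width above, a 48-nucleosome fiber stays open at 4 kT (a handful of
contacts) and condenses cooperatively at 6 kT — the qualitative 4-vs-6-kT
contrast documented for this model family, with mean 5-kb marker distances
in the same ranges reported at full scale. The potential is normalized so its global minimum is exactly
`-E_max` at coaxial face-to-face stacking, is tapered smoothly to exactly
0 at the 20-nm cutoff, and is identically 0 when `E_max = 0`. `E_max` is
the biological handle: 4 kT for the active region (histone modifications
weaken stacking), 6 kT for the unmodified inactive region.

**Excluded volume.** A capped quartic overlap penalty
(`min(1000, 4000 * overlap^4)` kT) for DNA-DNA (segment-segment minimum
distance vs 2.4 nm), DNA-nucleosome (4 + 1.2 nm, a compromise between the
face and side radii of the body), and nucleosome-nucleosome (the
orientation-dependent contact distance). A finite cap keeps every proposal
energy finite so the Metropolis rule, not a hard rejection, decides —
detailed balance stays clean, and acceptance tends to 1 in the
high-temperature limit as it should.

## Sampling

One MC step is one attempted elementary move: crankshaft rotations of short
interior stretches (span <= 8 joints) about their chord, pivot rotations of
a chain end about a random axis, and frame twists about the segment axis
(70/10/20% mixture). Move amplitudes are auto-tuned toward ~40% acceptance
during simulated-annealing pre-relaxation and then frozen for production
(fixed amplitudes are a detailed-balance requirement). Energy differences
are evaluated incrementally over the affected segment pairs; a paranoid
mode compares the incrementally accumulated energy against full
recomputation and the test suite requires agreement within 1e-6 kT.

Replica exchange runs one replica per ladder temperature (default: 8
replicas, geometric in [1.0, 2.5]) with adjacent-pair swap attempts every
5000 steps using `min(1, exp(-(beta_i - beta_j)(E_j - E_i)))`. Each replica
owns a counter-based RNG substream derived from the master seed, so
results are bit-reproducible and independent of how chunks interleave; a
single-temperature ladder degenerates exactly to a plain Metropolis run.
`optimize_ladder()` implements the feedback-optimized placement: the
fraction of "up-flowing" replicas per temperature is measured, monotonized,
and the ladder re-placed at equal flow quantiles (endpoints fixed), which
concentrates temperatures where the flow gradient is steep; with no
measured flow it falls back to geometric spacing with a warning.

Equilibration is detected automatically (`equilibration_cut()`): the first
index from which the running means of both monitored observables — total
energy and end-to-end distance — stay within 1.5 late-run standard
deviations over two consecutive windows; an explicit override is honored
verbatim. The integrated autocorrelation time uses Sokal windowing
(`tau = 1 + 2 sum rho_k`, window `5 tau`), and trajectories are thinned at
`ceiling(tau)` of the *slower* of the two observables before any distance
analysis.

## Distance analysis

Marker distances are Euclidean distances between the chain joints nearest
the two probe-set midpoints, in 3D (as for the 3D microscopy comparison).
Distances above the beads-on-a-string bound `span_bp * 0.34 / 7` nm
(~243 nm for 5 kb) are excluded as unphysical, mirroring the treatment of
measured data (250-nm cutoff at 5 kb). Histograms are density-normalized
at a 10-nm default bin width over `[0, max_extension]`; the bin width for
the deconvolution is not prescribed anywhere authoritative, so it is an
exposed parameter, and identical binning between compared histograms is
enforced structurally (operations error on mismatched breaks rather than
trusting convention).

`fit_mixture()` solves the constrained least-squares problem — weights
non-negative and summing to one — as a quadratic program (Goldfarb-Idnani
dual method via quadprog, with a 1e-10 ridge so collinear components keep
the QP strictly convex), and reports the bin-wise RMSE of the fitted
mixture. The test suite checks it against an exhaustive 0.01-resolution
grid search on the simplex and against end-to-end weight recovery from
sampled histograms (L-infinity error below 0.05 at n = 1e4 per component).
Comparisons of location between datasets use the two-sided Wilcoxon
rank-sum test with midrank tie correction; 2D microscopy-style data can be
emulated either by omitting z from coordinate pairs or by isotropic random
projection (`distance * sin(theta)`, theta from the uniform-sphere polar
density), and projected outputs are labeled as such.

## Spot localization

Synthetic two-channel 3D stacks carry one Gaussian-PSF spot per channel
(STED-like widths, default sigma 75/40/40 nm in z/y/x at 30-nm voxels)
with Poisson photon noise over a constant background.
`detect_brightest_spot()` scans a scale-normalized Laplacian-of-Gaussian
response and reports the maximizing voxel with a deterministic (lowest
z, y, x) tie-break and a robust noise floor; `fit_gaussian_3d()` refines to
sub-voxel precision by Levenberg-Marquardt least squares of a 3D Gaussian
plus constant background over a +-3-sigma window, with anisotropic z width
(the axial PSF differs). Quality control here is threshold-based (noise
floor, convergence, bounds checks) — a deliberate simplification of the
supervised stack-classification step used with real microscope data, whose
features and labels are instrument-specific. Chromatic offset and
refractive-index scaling would enter as per-axis affine calibration inputs
and are not computed. At 500 photons per spot the pairwise 3D distance RMS
error lands in the single-digit nanometer range, consistent with
STED-class localization precision (~7.5 nm).

## Synthetic data: what it emulates, and what it does not

Every generator is seed-deterministic and returns its ground truth:

* `gen_positions()` places footprints sequentially with truncated-normal
  spacing (default mean 183 bp — the chromosome-scale NRL average — sd 25
  bp). The truncation at 148 bp models steric exclusion. The generator
  does not emulate the long positioning gaps of real population maps, so
  its NRL standard deviation is deliberately smaller than the ~66 bp of
  chromosome-scale estimates, most of which comes from such gaps.
* `gen_occupancy_track()` sums Gaussian-smoothed, jittered, score-weighted
  footprints with Poisson sampling — enough structure for occupancy
  ranking (Spearman > 0.8 against generating weights at default depth),
  not a sequencing-bias model.
* `gen_distance_dataset()` draws from a log-normal mixture (right-tailed,
  positive support; families for single-cell distance data are not settled,
  and log-normal is the simplest right-tailed choice) and adds isotropic
  localization error per spot so the pairwise RMS matches the stated
  precision (7.5 nm default).
* `gen_image_stack()` produces the Gaussian-PSF/Poisson stacks described
  above.

Passing tests on these inputs demonstrate that the estimators and the
sampling machinery are correct under their stated models. They do not
demonstrate that real MNase tracks obey the occupancy model, nor that
measured distance distributions are log-normal mixtures, nor that the
default geometry reproduces any particular measured fiber — those are
exactly the questions the real-data workflow (with measured distance
tables read via `read_distance_table()`) would address.

## Scaled-down study design

Desk-scale runs use 8 replicas, 2e5 steps per replica and ~10 flanking
nucleosomes per side of the studied interval; cluster-scale settings
(16-60 replicas, 1e7-9e7 steps, ~110-nucleosome flanks) are the same code
with larger control parameters. The direction-of-effect suite
(`direction_suite()`) runs one fixed ~48-nucleosome synthetic region (a
~5-kb studied interval of 28 nucleosomes plus flanks, generated once under
its own constant seed — the experiments perturb a single region, so the
region is an input, not a random variable of the suite), pools three
independent replica-exchange runs per variant — independent repeats
average over slow condensation kinetics far more effectively than one
longer run — and gives the 6-kT variant twice the steps, the same
asymmetry used at full scale where deeper wells needed several-fold more
sampling. Removal candidates
are ranked within the studied interval only, as in the original removal
experiments. Directions of all three perturbations (removal extends;
6 kT compacts; H1 compacts) are asserted with percentile-bootstrap 95%
confidence intervals over the pooled thinned samples.

## Known limitations

* The nucleosome is rigid: no unwrapping/breathing, no sequence-dependent
  DNA mechanics, and H1 is not an explicit particle (angle sets only).
* The geometry defaults are a plausible crossed-linker parameterization,
  not a fitted structure; quantitative distance scales shift with `d`, the
  angle sets and `E_max`, which is why the validation targets directions
  and analytic oracles rather than measured medians.
* Excluded volume treats the nucleosome as a point-centered body against
  DNA; grazing DNA-nucleosome contacts are approximated by a single
  effective radius.
* The equilibration heuristic assumes the run reaches stationarity within
  the monitored window; glassy low-temperature runs without replica
  exchange can fool any such rule — the error message recommends longer
  runs rather than guessing. Inside the experiment driver a run that never
  passes the strict rule (typical of a slowly condensing 6-kT system at
  desk scale) falls back, with a warning, to discarding the first half of
  its samples — the classic conservative burn-in choice.
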