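---
title: "Methods: P-wave analysis, activation mapping, and tissue simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: P-wave analysis, activation mapping, and tissue simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrialep)
```

`atrialep` quantifies atrial electrical properties at three observation
scales — the surface ECG, invasive high-density activation maps, and
simulated tissue — and ties them together with synthetic-data generators so
that every estimator in the chain can be validated against known ground
truth.  This vignette explains the models and procedures, the parameters
that matter, and the choices made where the methods literature leaves the
design open.

## 1. Synthetic data as the validation substrate

No patient recordings ship with the package.  Instead, each analysis stage
has a paired generator whose output carries exact annotations:

* `gen_ecg()` builds multi-beat 12-lead ECGs.  Per beat, a P wave (a
  truncated Gaussian of width `p_duration/5`, or a positive/negative lobe
  pair in V1 for the biphasic morphology), a narrow QRS complex, and a T
  wave are placed relative to each R peak.  The generator defines QRS onset
  50 ms before the R peak and places the P onset `pr_interval` earlier, so
  its annotations are exactly the quantities the P-wave pipeline estimates.
  Additive white noise, 50/60 Hz mains interference, and a linear drift
  term are available; more elaborate clinical noise taxonomies are not
  emulated, so passing recovery tests says nothing about, for example,
  electrode motion artifacts or atrial ectopy.
* `gen_wavefront()` renders planar, radial, or colliding activation waves
  on a triangulated patch (flat, or a spherical cap to exercise
  tangent-plane projection) as biphasic unipolar electrograms: each
  electrode's trace is the scaled negative time-derivative of a Gaussian
  centred at the true local activation time (LAT), so the steepest negative
  slope falls exactly at the annotated LAT.  Electrodes are placed by
  Poisson-disk sampling, mimicking the irregular coverage of basket or
  multi-spline catheters.  Default density (10 /cm^2 on a 40 x 40 mm patch)
  gives ~160 electrodes, similar per-area to clinical high-density maps.
* `gen_cohort()` draws two-group Gaussian feature samples for calibrating
  the statistics layer.

All generators are deterministic for a fixed seed and restore the caller's
RNG state.

## 2. P-wave pipeline

Preprocessing follows the clinical acquisition chain: an optional 2nd-order
IIR notch at the mains frequency, then a fifth-order Chebyshev type-I
low-pass at 100 Hz (0.5 dB ripple).  Every filter is applied
forward-backward, because delineation is a timing measurement and any group
delay would bias it.

Recordings are cut into 15-second epochs (trailing remainder discarded).
R peaks are detected per epoch with a Pan-Tompkins-style chain (5-15 Hz
band-pass, differentiate, square, 150-ms integration, adaptive threshold,
200-ms refractory period, refinement to the band-passed extremum).
Candidate P windows span [R-350 ms, R-50 ms].  Per lead, every candidate is
scored by its mean best-lag cross-correlation (Pearson at the best lag
within +/-50 ms) against the others; the best-scoring beat seeds the
template, beats correlating below 0.9 are discarded, and survivors are
aligned at their best lag and averaged.

P-wave analysis chains built on template averaging typically leave the
delineation rule unspecified, so the package declares its own: the baseline is the
median of the first 40 ms of the window, and onset/offset are the outermost
sustained (>= 5 ms) crossings of 5% of the lead's peak amplitude.  The
sustained-run requirement keeps isolated noise samples from extending the
bounds while still spanning both lobes of a biphasic wave.  The global
onset (offset) is the earliest (latest) per-lead bound; flat leads are
excluded.

The feature vector has exactly 65 entries: five global features — P-wave
duration, PR interval, P-wave terminal force in V1 (signed area of the
terminal negative V1 deflection, always <= 0), FWHM of the dominant lead,
and P-wave axis (`atan2` of the net areas in aVF and I) — plus five
features for each of the 12 leads: area, peak count (local maxima with
topographic prominence >= 10% of the lead peak), maximum absolute
amplitude, Shannon entropy of the amplitude histogram (10 equal-width bins,
natural log — invariant to positive rescaling), and sample entropy (m = 2,
r = 0.2 x SD, self-matches excluded).  Where formulations vary in the
literature (entropy binning, sample-entropy parameters, peak prominence),
the package uses these conventional defaults and exposes them in
`pwave_config()`.  The PR interval uses the window end (R-50 ms) as a QRS
onset proxy; a dedicated QRS-onset estimate can be supplied instead.
Patient-level features are the arithmetic mean over epochs (NA-skipping,
with counts reported); the median would be a defensible alternative, but
the mean keeps the estimator linear in the per-epoch values.

Recovery at the documented study conditions (100 synthetic patients, 15-s
recordings, 0.02 mV noise) is tested to a mean absolute error below 12 ms
for P-wave duration and 10 ms for PR.

## 3. Activation mapping

Electrograms (953.6 Hz) are detrended by subtracting a Savitzky-Golay
smoothed trend (order 2, span 201 samples — subtraction, not smoothing, so
the depolarization edge is untouched) and band-passed with a zero-phase
fifth-order Butterworth filter, 2-100 Hz by default.

LAT is the time of the maximum negative slope (central differences with
parabolic sub-sample refinement; at 953.6 Hz one sample is ~1.05 ms, and
the refinement roughly halves the quantization error), referenced to the
coronary-sinus channel.  Detections whose derivative minimum sits at the
window edge are flagged low-confidence.  LATs are projected to the nearest
mesh vertex (5-mm distance gate; shared-vertex values averaged), screened
by a 2-mm neighborhood check (a vertex is excluded when it deviates from
the neighborhood median by more than 10 ms and has at least two neighbors;
Euclidean distance stands in for geodesic at this radius), and interpolated
with Gaussian-kernel radial basis functions.  The kernel width and ridge
smoothing are selected by leave-one-out cross-validation over a log grid
using the closed-form LOO residuals of the ridge system; vertices farther
than 10 mm from any datum are NaN rather than extrapolated.  The 10-ms
outlier tolerance is a package choice — the neighborhood radius is standard
but no tolerance is established in the mapping literature.

Total atrial activation time (TAAT) is the interval from the earliest
valid right-atrial LAT to the distal coronary-sinus activation; it scales
exactly linearly under uniform conduction slowing, and non-positive values
are flagged as unphysiological rather than silently accepted.

## 4. Conduction velocity

At each recording point, neighbors within 5 mm (at least 8, falling back to
k-nearest) are projected onto a local PCA tangent plane and a quadratic
surface T(u, v) is fitted to their LATs by least squares; the CV vector is
the inverse gradient g/||g||^2 mapped back to 3-D, so a gradient of
1 ms/mm yields 1 m/s.  Gradients below 1e-3 ms/mm (near-simultaneous
activation) leave CV undefined rather than exploding.  The quadratic
degree matches the established polynomial-surface-fitting family;
degree 1 or 3 is configurable.

Divergence is estimated per point by fitting linear models to the
tangential CV components over the same neighborhoods; wave-collision sites
are masked where divergence is strictly below -1.5 s^-1 (the boundary value
itself is retained — a declared, testable convention).  On noise-free
planar data fewer than 1% of points are masked; on colliding-wave data the
masked band covers the collision line.  Masked points are excluded from
interpolation and summaries.  Summaries additionally gate magnitudes above
2 m/s (reported, not silent) — collisions are the main source of spuriously
high CV, but the gate catches residual fit artifacts.  Histograms use
fixed 0.05 m/s bins over [0, 2] m/s, making maps comparable across
datasets.

## 5. Tissue simulation

The monodomain reaction-diffusion equation is solved on a 2-D rectangular
sheet (fibers along x) with the Courtemanche-Ramirez-Nattel (CRN) human
atrial ionic model: Rush-Larsen updates for the twelve voltage-dependent
gates (rates tabulated per time step on a 0.02-mV grid), forward Euler for
concentrations and voltage, and explicit anisotropic diffusion with
no-flux boundaries.  A deliberately independent R transcription of the
same published equations (integrated with deSolve) serves as the test
oracle; the two agree on derivatives to machine precision and on APD90 to
well within 10%.

Electrical remodeling scales g_to, g_CaL and g_K1 to 40%, 35% and 200% of
normal; at 1 Hz pacing this shortens APD90 from ~297 ms to ~138 ms.
Sodium-channel loss of function multiplies g_Na by 0.30 on a flagged
fraction of nodes (default 50%), and fibrosis removes a flagged fraction
of transverse (cross-fiber) couplings from the diffusion stencil.  Both
masks contain exactly `floor(fraction x n)` elements and are reproducible
from the seed.

Three spatial design choices deserve emphasis, because they were forced by
experiments at desk scale rather than taken from the methods literature:

* **Mask correlation length.**  With node-wise random selection at 0.5-mm
  spacing, the gNa-depressed nodes sit at the scale of the depolarization
  wavefront itself; waves scatter and die on every mask realization (50%
  intact nodes is also below the 2-D site-percolation threshold of 0.593).
  `build_tissue()` therefore defaults to spatially correlated patchy masks
  (a thresholded smoothed Gaussian random field, correlation length
  `brs_patch_mm = 7`), which preserves the flagged fraction exactly while
  representing heterogeneity at the mm scale seen in patchy atrial
  substrate; `brs_patch_mm = 0` restores independent node selection.
* **Baseline anisotropy.**  With a conventional 4:1 diffusivity ratio plus
  50% transverse decoupling, the sheet degenerates into uncoupled 1-D
  fibers and no 2-D activity is possible.  The defaults
  (`d_long = 0.15`, `d_trans = 0.1125` mm^2/ms) keep the remaining
  transverse bonds conductive and let the structural decoupling itself
  carry the functional anisotropy.
* **Sheet scale.**  The 50 x 50 mm sheet at 0.25-0.5 mm spacing is far
  smaller than real atria; reentrant dynamics here are at best marginal,
  and all scenario comparisons are directional, not quantitative.

AF induction uses a 2.5-s burst of stimuli with linearly decreasing
coupling intervals (`make_schedule()`, default 200 to 120 ms; the
AF-induction studies in this package run the ramp to 80 ms, without which
the desk-scale substrate is almost never induced), a 2-ms, 40 pA/pF
stimulus on a 1.5 x 1.5 mm patch, applied at each pacing site in turn
(default: an evenly spaced 20-site lattice).  Induction is sustained when
suprathreshold activity persists through the final 100 ms of the run
(default 1 s post-pacing).  Conduction-pattern complexity is the number of
waves — connected components of the Vm > -60 mV node set (4-neighbor
connectivity) — counted every millisecond and averaged over the
post-pacing period.  `compare_scenarios()` applies Welch t tests to
per-site wave counts, Fisher exact tests to induced/not-induced counts,
and Bonferroni adjustment.

Numerics: the reaction step defaults to 0.02 ms (scenario studies use
0.05 ms, which leaves strand CV unchanged at these diffusivities);
the explicit diffusion step enforces dt <= h^2/(4 D_max) with an
informative error.  Problem sizes in the test-suite study conditions are
scaled for a workstation: strands of 30 x 2 mm for CV measurements, 10-20
mm sheets for stability checks, and 10 replicate 50 x 50 mm scenario pairs
at 0.5-mm spacing with one pacing site per replicate.  Halving the fine
default spacing (0.25 mm) changes planar CV by under 10%; the 0.5-mm
setting used in scenario work underestimates CV by a further ~15%, which
is acceptable for directional comparisons and is reported here so that no
absolute CV from the simulator is over-read.

Direction of the scenario contrast at desk scale: the contrast is weak and
strongly mask-dependent.  In the packaged replicate study (10 seed
replicates, one pacing site, 50% fibrosis) the sodium-heterogeneity arm
showed the higher post-pacing wave count in under half of realizations —
on this small no-flux sheet the depressed patches shorten the lifetime of
paced waves more often than they fragment them, and when the control arm's
fibrotic zigzag conduction does sustain reentry the control wave count
dominates.  The corresponding acceptance check is therefore expected to
fail at desk scale, and the replicate table should be read as a
characterization of that limitation: a closed atrial geometry without
no-flux boundaries (out of scope here) appears necessary for the
mechanism to express itself robustly.

## 6. Statistics

The cohort layer wraps the standard machinery (Welch two-sample t, Pearson
correlation with R^2, chi-squared with continuity correction, two-sided
Fisher exact, Bonferroni `min(1, m p)`), adds a summary-statistics Welch
path (identical formulas from group moments, enabling checks against
printed cohort tables), and a per-feature two-group report across the
65-entry feature vectors.  The Welch variant is used for every t test:
with equal variances it reduces to the classical test, and it is the safer
default for unequal group sizes.  Fisher's two-sided p sums all tables
with probability not exceeding the observed one — stated explicitly
because two-sided conventions differ.  Calibration is tested empirically:
type-I error at alpha = 0.05 over 2,000 null cohorts stays within
5% +/- 1.5%, and Fisher p-values equal direct hypergeometric enumeration
to 1e-12.

One known discrepancy: at the reference group moments used for the
P-wave-duration cohort example
(n = 89: 135.5 +/- 17.3 vs n = 44: 124.2 +/- 15.7 ms), the analytic power
of a Welch test at alpha = .01 is about 0.87, not above 0.95; the
generator tests assert the computed value.

## 7. Known limitations

* The ECG generator's beat model is deliberately simple; template
  correlation screening is exercised by noise and inverted-beat cases, not
  by realistic ectopy.
* Geodesic distances are approximated by Euclidean ones in the 2-mm
  outlier check and the RBF kernels; on strongly curved geometries with
  thin structures this under-estimates distances.
* The simulator is monodomain, 2-D, and desk-scale: no atrial anatomy, no
  bidomain effects, no ECG forward model, and scenario results are
  directional only.
* Sample entropy is O(n^2) and intended for the ~300-sample P-wave
  segments it is applied to, not long records.
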