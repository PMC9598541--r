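---
title: "Mapping cortico-striatal-thalamic circuits from ASL perfusion and polygraphic EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cortico-striatal-thalamic circuits from ASL perfusion and polygraphic EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cstflow)
```

## The analysis problem

Periodic EEG discharges and epileptic spasms are thought to engage loops
linking cortex (C), striatum (S) and thalamus (T). Arterial spin labeling
(ASL) MRI quantifies cerebral blood flow (CBF, ml/100 g/min) without
contrast and can localise ictal and inter-ictal perfusion changes. The
question this package operationalises is circuit-level: when a patient's
perfusion deviates from age-matched norms, do the deviations line up across
the *corresponding* functional territories of cortex, striatum and
thalamus?

`cstflow` takes spatially normalised, co-registered CBF volumes and atlas
label volumes as input (acquisition, CBF quantification and spatial
normalisation are upstream and out of scope) and provides the full analysis
chain downstream of them, plus a polygraphic EEG/EMG module for the
electrophysiological side of the same phenomenon, and a synthetic-data
module that generates every input with ground truth.

## The compartment model

All statistics operate on **compartments**: triples of

* structure — cortex, striatum, thalamus (donut rings, outside to inside),
* functional subdivision — prefrontal, rostral motor, caudal motor,
  parietal, occipital, temporal (donut sectors, clockwise from the top),
* hemisphere — left, right.

That gives 3 × 6 × 2 = 36 compartments per examination, so a group of 14
examinations has 504 compartments, a group of 8 has 288, and a group of 4
has 144 — the denominators of all report percentages.

Connectivity-based striatal and thalamic atlases come with seven source
subregions per structure. `apply_merge_rules()` maps them onto the six
shared subdivisions: for the striatum, limbic and executive merge into
prefrontal; for the thalamus, premotor maps to rostral motor, primary motor
to caudal motor, and sensory plus posterior parietal merge into parietal.
Merging is purely a relabelling — voxel membership is conserved, which the
test suite checks by brute-force voxel counting. A cortical parcellation is
regrouped to the same six subdivisions; because no canonical lobar grouping
is mandated anywhere, `default_cortical_grouping()` is a documented,
configurable choice and the fixture atlases bypass it by being generated
directly in the six subdivisions.

Probabilistic 4D atlases are reduced to max-probability label images with a
25% floor (voxels whose best probability is lower become background), ties
going to the lowest label id for determinism. Hemisphere labels come from
the label table when present; otherwise labels are split at the world
x = 0 plane (RAS+), with voxels exactly on the midline assigned to
background, since a voxel on the midplane belongs to neither hemisphere.
All inter-volume operations happen in voxel space after an affine-equality
check (tolerance 1e-4 elementwise); nothing is ever resampled silently.

## CBF measures

For each compartment, `build_cbf_table()` reports

* **A-CBF** — the arithmetic mean of CBF over the compartment's voxels, and
* **R-CBF** — A-CBF divided by the whole-brain-cortex mean.

The whole-cortex denominator is the voxel-weighted mean over the union of
all twelve cortical compartments, not a mean of compartment means; the
distinction matters whenever compartment sizes differ. By construction
`r_cbf * whole_cortex_mean == a_cbf` to floating-point precision, R-CBF is
invariant to global rescaling of the volume, and voxels outside all
compartments can never influence any output — all three are enforced as
tests.

Negative voxel values occur in ASL as noise; they are included in means by
default (and counted in the volume metadata), with an optional
`exclude_nonpositive` switch. No smoothing and no partial-volume correction
are applied. Whole-image artifact QC is an upstream visual decision carried
as a metadata flag, not an automated detector.

`subtraction_map()` produces ictal − inter-ictal difference volumes for
paired examinations of one subject, refusing mismatched subjects or grids.

## Single-case normative statistics

Each patient examination is compared against a cohort of controls matched
on scanner and sedation status exactly, and on age within a window that
starts at ±25% of the patient's age and doubles until at least 10 controls
are found (capped at the whole scanner/sedation-matched pool). The minimum
of 10 keeps the control standard deviation, which anchors the test, from
being estimated on too few degrees of freedom. The window policy is a
design choice of this package; matching is deterministic given the pool.

With one value per ROI per subject, comparing a single patient with a
control sample is the pooled-variance two-sample t-test with a singleton
first sample, which reduces to the Crawford–Howell single-case form

$$ t = \frac{x - \bar{m}}{s\sqrt{1 + 1/n}}, \qquad df = n - 1 $$

with two-sided p. The suite verifies exact equivalence (to 1e-10) with a
general pooled t-test run on ({x}, controls). Each of the 72
(compartment, measure) pairs is classified **increase** (p < α and patient
above the control mean), **decrease** (p < α, below), or **normal**, at
α = 0.05 with no multiple-comparison correction by default — matching the
plain significance rule the analysis is built around; a Benjamini–Hochberg
option exists but is off by default. Testing is two-sided because both
directions of change are scientifically meaningful.

Calibration is verified by simulation: patients drawn from the control
model itself are classified against freshly drawn cohorts, and the fraction
of non-normal calls per compartment must sit in [0.03, 0.07] at α = 0.05.
One subtlety the simulation respects: conditioning on a *single* control
cohort makes the type-I error fluctuate with that cohort's realised
standard deviation (a cohort whose 30 controls happen to be tight is
anti-conservative for every patient tested against it), so the null
simulation redraws the cohort across replicates (25 cohorts × 40 patients)
to estimate the unconditional rate. The calibration and recovery studies
hold age fixed (12 months for all subjects) so patient and controls are
exchangeable draws; the age-window matcher is exercised separately.

## Circuit coincidences, group summaries and donut charts

A **circuit pattern** is a set of at least two structures whose
compartments share subdivision, hemisphere, measure and direction of
significant change; the maximal such subset is emitted once and labelled
C-S-T, C-S, C-T or S-T. "Corresponding" deliberately requires all four
attributes to align; structures changing in opposite directions within a
stratum are not a circuit. Bilateral homologous changes count once per
hemisphere. `detect_circuits()` is tested against exhaustive enumeration
over all strata and structure subsets.

`summarize_group()` aggregates one measure across a group's examinations:
the 36-per-exam denominator, changed counts by direction and structure, and
circuit-pattern counts, with exact fractions retained and percentages
rounded to integers for reporting. `fisher_contrast()` provides the exact
two-sided Fisher test for group contrasts, summing hypergeometric
point probabilities not exceeding the observed table's (with a 1e-7
relative tie tolerance); it is checked against full enumeration for every
2×2 table with margins up to 12, and against `stats::fisher.test()`.

`build_donut()` turns one examination's statuses into the three-ring,
six-sector donut model (red = increase, blue = decrease, green = normal;
18 cells per hemisphere), and `plot_donut()` renders it; the model, not the
image, is the tested surface, and the cell colours re-derive losslessly
from the status table.

## Jerk-locked back-averaging

The EEG module characterises periodic discharges with motor accompaniment.
`detect_emg_onsets()` finds jerk onsets on a surface EMG channel:
high-pass at 20 Hz, rectification, double moving-average smoothing (13 ms),
threshold at baseline median + 5·MAD, 30 ms minimum supra-threshold
duration and a 500 ms refractory period. Each onset is then refined by
fitting the rising envelope with a folded-normal hinge,
$m(t) = \sqrt{b^2 + (k\,\max(0, t - t_0))^2}$, where $b$ is the rectified
noise floor; the fit is located by a grid search over candidate onsets with
parabolic interpolation of the residual sum of squares. This form is
unbiased for ramp-like ("diamond") burst envelopes, where a naive
threshold crossing is systematically late and a straight-line extrapolation
is systematically early. When a burst rises faster than the smoother can
resolve (noise-free rectangular test bursts), the first raw
supra-threshold sample is used instead. Timing precision is
information-limited by the envelope slope relative to the rectified noise;
the onset-accuracy test therefore samples EMG at a clinical 2 kHz rate,
where the detector recovers ≥95% of diamond-burst onsets within ±5 ms at
an amplitude-to-noise ratio of 10.

`back_average()` re-references EEG to the common average (configurable),
extracts epochs in a −500..+500 ms window around each onset, subtracts the
per-epoch baseline mean (−500..−300 ms), drops epochs that do not fit the
recording, and averages. The per-channel peak is the signed extremum of
largest magnitude in the −200..0 ms pre-motor window; its latency (ms,
negative = EEG precedes EMG) is the premotor lead of the cortical
transient. The peak-search and baseline windows are design choices
consistent with a premotor sharp wave leading the jerk by a few tens of
milliseconds. `interdischarge_intervals()` summarises complex-to-complex
periodicity (median, IQR, range).

## The synthetic-data generators

The generators define the study conditions for every simulation-based
guarantee:

* **Fixture atlases** (`make_fixture_atlas()`): deterministic
  contiguous-block label volumes on a cubic grid (default 32³; the test
  simulations use 16³ for speed, which leaves every compartment with
  roughly 100–500 voxels) — 7 striatal + 7 thalamic source subregions and
  6 cortical subdivisions per hemisphere, hemispheres split at x = 0.
* **Control cohorts** (`generate_control_cohort()`): each subject's
  cortical mean follows an age curve
  $c(a) = 60 - 30\,e^{-a/24\,\text{mo}}$ (ml/100 g/min) times a log-normal
  between-subject factor (CV 0.12; log-normal for positivity); subcortical
  compartments are the cortical mean times the ratio curve
  $r(a) = 1 + 0.5\,e^{-(a/72\,\text{mo})^2}$, which stays ≈1.5 through the
  first year of life and decays to ≈1.0 by adolescence, reflecting the
  later maturation of cortical perfusion relative to thalamus and
  striatum; Gaussian voxel noise (sd 5) is added on top. The default
  cohort size is 232. Curve shapes and dispersions are parametric choices
  constrained by those qualitative facts; all are exposed in
  `cohort_spec()`.
* **Patients** (`generate_patient()`): a control-model draw whose targeted
  compartments are multiplied by effect factors, with the full ground
  truth retained. The recovery study injects a +60% C-S-T effect —
  about five between-subject standard deviations, comfortably above the
  three-sd floor at which recovery is promised — and requires the correct
  pattern, direction, subdivision and hemisphere in ≥95% of 500 simulated
  patients run through the complete pipeline (matching included).
* **Polygraphy** (`generate_polygraphy()`): depressed slow background
  (band-limited 1–4 Hz noise, sd 20 µV), stereotyped periodic complexes —
  a negative central-parietal sharp wave (90 µV, zero-mean topography with
  positive frontal phase reversal so the common-average reference
  preserves the amplitude) followed by a slow wave — and diamond-shaped
  EMG bursts (triangular envelope, deterministic 80 Hz carrier, 200 ms)
  starting a fixed 20–60 ms latency (default 40 ms) after each complex
  peak. Presets encode early SSPE periodicity (5–7 s), late SSPE (2–3 s),
  lateralized discharges, spasm clusters, and a null background. The
  default sampling rate is 256 Hz (≈4 ms latency resolution, typical for
  clinical EEG).

What the generators deliberately do *not* emulate: real anatomy and
registration error, partial-volume mixtures at compartment borders,
scanner-specific CBF biases, hypsarrhythmia, or the stochastic
interference-pattern character of real surface EMG (the deterministic
carrier makes burst onsets identifiable, which real EMG makes strictly
harder). Passing the recovery tests therefore demonstrates that the
pipeline's logic and statistics are correct under the stated model, not
that any particular clinical dataset would yield particular findings.

## Numerical and degenerate-input choices

* Max-probability ties go to the lowest label id; voxels on the x = 0
  midplane go to background.
* Zero control variance and sub-minimum cohorts are classified errors, not
  silent NAs; within `classify_compartments()` a degenerate compartment is
  flagged in the `note` column while the other 71 tests proceed.
* The Fisher two-sided rule uses the standard point-probability convention
  with a 1e-7 relative tie tolerance; odds ratios use the sample
  cross-product with 0/∞ conventions (`NaN` when both products vanish).
* A flat EMG yields an empty onset list, not an error; back-averaging with
  no usable epoch is an error.
* All generators are strictly seed-deterministic, and every writer has a
  reader that round-trips (TSV tables to 1e-6, NIfTI volumes bit-for-bit
  up to float storage).

## Problem sizes in the shipped test suite

The suite runs the statistical guarantees at sizes chosen to be decisive
yet quick: the null calibration uses 25 cohorts × 40 patients (1000
replicates, 72 tests each), the circuit recovery 10 cohorts × 50 patients
(500 replicates), the back-averaging checks 100-jerk recordings, the
Fisher sweep all margins ≤ 12, and the latency-recovery scan 40 simulated
recordings spanning the 20–60 ms range. The full suite completes in about
a minute on a single core.

## Known limitations

* The cortical grouping table is a convention, not an anatomical ground
  truth; users with their own cortical atlases should review it.
* R-CBF control variance in the synthetic model is voxel-noise-driven
  (the subject factor cancels in the ratio), so R-CBF significance in
  simulations is more sensitive than A-CBF — real ratio data carry
  additional physiological variance the generator does not model.
* The single-case test assumes approximate normality of control values;
  heavy-tailed cohorts would need the robust/BH options.
* EDF input is not implemented; polygraphy interchange is TSV
  (time column + one channel per column).
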