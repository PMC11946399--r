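---
title: "IMU gait indices and their test-retest reliability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IMU gait indices and their test-retest reliability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitrel)
```

## The measurement problem

People recovering from severe traumatic brain injury walk slowly and
asymmetrically, and clinicians need instrumented measures of gait *stability*,
*symmetry* and *smoothness* that are reliable enough, over a short 10 m bout,
to distinguish real change from measurement noise. `gaitrel` implements a
complete pipeline for this setting: five body-worn inertial sensors (head,
sternum, pelvis at L4/L5, both shanks) record tri-axial acceleration and
angular velocity at 128 Hz while the subject stands quietly for a few seconds
and then walks a 14 m path (10 m core plus 2 m acceleration and deceleration
sections). Each trial is repeated, and the paired index tables feed a
reliability analysis (ICC, SEM, MDC).

## Preprocessing

Each sensor is calibrated from the quiet-standing window (default the first
3 s), always on the raw signals, in a fixed order:

1. **Gyroscope bias**: the static mean angular velocity is subtracted from the
   whole stream.
2. **Gravity alignment**: the static mean acceleration defines the craniocaudal
   (CC) axis. The rotation taking the sensor frame to the anatomical
   (AP, ML, CC) frame needs a second axis; the gravity direction alone leaves a
   free yaw. We complete the frame with the horizontal projection of a per-site
   *forward axis* (default: the sensor x-axis, i.e. sensors are mounted facing
   forward), and ML = CC x AP. This completion is a declared convention — any
   pipeline must pick one — and it is configurable per site.
3. **Gravity removal**: the static-window mean of the rotated CC acceleration
   is subtracted from the CC column (more robust to residual misalignment than
   subtracting 9.81), leaving AP and ML untouched.
4. **Filtering**: second-order Butterworth low-pass, 10 Hz for accelerations
   and 6 Hz for angular velocities, applied forward-backward (zero phase).
   Per-stride indices are phase-sensitive, which is why zero-phase filtering is
   the norm in gait work; a single causal pass is available via
   `gait_config(zero_phase = FALSE)`. Our zero-phase implementation uses
   odd-reflection padding with steady-state initial conditions, so constants
   (and the static window) pass through transient-free.

## Stride segmentation

Strides are cut from the shank sagittal-plane (ML) angular velocity: mid-swing
appears as a tall positive peak. Peaks with prominence of at least 1 rad/s and
separation of at least 0.6 s are kept, each stride boundary is the signal
minimum preceding a peak (a terminal-contact proxy), and consecutive
boundaries delimit strides; durations outside 0.6–2.5 s are discarded as
implausible. The first and last stride of the bout are flagged non-steady
(the 2 m auxiliary sections correspond to roughly one stride at the typical
0.79 m/s walking speed of this population), and a trial needs at least three
steady-state strides to be usable. Upper-body indices are windowed on the
left-leg stride grid by default (`anchor_leg` configures this; the choice is a
convention, since the bout is too short to average the two grids).

## The three index families

For each steady-state stride the pipeline computes, then averages across
strides (mean by default, median via `gait_config(aggregate = "median")`):

**Normalized RMS (stability).** Per stride,
$\mathrm{nRMS} = \mathrm{RMS}(x)/\mathrm{RMS}(y)$ where $x$ is the AP or ML
acceleration and $y$ the CC acceleration of the same site (pelvis, trunk,
head). Dividing by CC absorbs between-subject differences in overall
acceleration magnitude due to walking speed; higher values mean larger
horizontal accelerations relative to vertical, i.e. reduced stability. CC
itself has no nRMS — it is the normalizer.

**Improved harmonic ratio (symmetry), pelvis only.** Each demeaned stride is
decomposed into stride-frequency harmonics. A stride spans two steps, so a
perfectly symmetric AP or CC signal repeats every half stride and carries its
power at *even* harmonics, while ML alternates sign between steps and carries
it at *odd* harmonics. With $P_{I,i}$ and $P_{E,i}$ the powers of the first
$K = 20$ intrinsic and extrinsic harmonics,
$$\mathrm{iHR} = 100 \times \frac{\sum_{i=1}^{K} P_{I,i}}
{\sum_{i=1}^{K} P_{I,i} + P_{E,i}},$$
so 100% is perfect symmetry and 0% complete asymmetry. The parity map is
configurable but defaults to the convention above.

**Log dimensionless jerk (smoothness), pelvis only.** Per axis and stride,
$$\mathrm{LDLJ} = -\ln\!\left(\frac{(t_2-t_1)^3}{\max s^2}
\int_{t_1}^{t_2} \left(\tfrac{ds}{dt}\right)^2 dt\right),$$
applied to accelerations (LDLJa) and angular velocities (LDLJw). The formula
is duration- and amplitude-normalized, hence invariant to uniform scaling of
$s$. By this expression a rougher signal (more derivative energy) gives a more
negative value; published interpretations of the sign direction differ, so the
formula is applied literally and reports should state the direction used.

### Numerical choices

* iHR: each stride (which covers exactly one period, boundary samples
  included) is resampled to 256 points by periodic cubic spline so that stride
  harmonics fall exactly on DFT bins — no leakage correction is needed. The
  two boundary samples sit at the same stride phase and are tied to their
  average before resampling. If a short resample length cannot support
  $2K$ harmonics, the available ones are used and a warning logged.
* LDLJ: derivative by central differences (one-sided at segment ends),
  integral by the trapezoidal rule. At 128 Hz with gait-band signals the
  discretization bias of this scheme is a few parts in a thousand of the
  index value.
* Everything is deterministic: the same aligned trial yields bit-identical
  indices.

## Reliability analysis

For every index, `reliability_table()` computes session means with t-based
95% CIs, the mean absolute test-retest difference, a Shapiro–Wilk gate on the
paired differences choosing between the paired t-test and the Wilcoxon
signed-rank test, Cohen's $d = \bar{\Delta}/s_\Delta$ with a t-based CI, and
the reliability surface:

* **ICC**, single measure, from the two-way mean squares. Both the
  absolute-agreement form (default; charges systematic session shifts against
  reliability) and the classical consistency form ICC(3,1) are available, with
  F-based 95% CIs (Satterthwaite df for the agreement form). The estimator was
  cross-validated against an independent implementation and a direct
  variance-components oracle.
* **SEM** $= \mathrm{SD}\sqrt{1-\mathrm{ICC}}$. Which dispersion enters is a
  convention; the default is the pooled SD of test and retest values, with the
  test-session SD and the SD of differences selectable
  (`gait_config(sd_convention = )`), because reported usage varies and the
  choice cannot be recovered from rounded published tables.
* **MDC**: two multiplier conventions are exposed —
  `"printed_2"` ($\mathrm{SEM} \times 1.96 \times 2$, the default) and
  `"sqrt2"` ($\mathrm{SEM} \times 1.96 \times \sqrt{2}$, the conventional
  MDC95). Published tables in this literature are not always internally
  consistent about which multiplier was used, so the convention is recorded in
  every output row.
* SEM and MDC intervals are obtained by propagating the ICC CI endpoints
  through the formulas, which keeps them nonnegative and consistent with the
  ICC interval.
* Subgroup effects on reliability (e.g. age or sex) are assessed by a
  two-sided Mann–Whitney test on per-subject absolute test-retest differences
  (`subgroup_compare()`). $\alpha = 0.05$ throughout; no multiplicity
  correction is applied.

## The synthetic cohort generator

No public recordings exist for this population, so validation rests on a
generator whose ground truth is analytic:

* Upper-body accelerations are finite sums of the first six stride-frequency
  harmonics. Under this model the symmetry index is exact by construction
  (`harmonic_amplitudes()` splits power between parity sets to hit a target
  fraction), per-axis RMS follows from Parseval, and LDLJ is computable by
  high-resolution quadrature — so every pipeline stage can be checked against
  closed forms (`analytic_truth()`), including the pipeline's own filter,
  whose exact per-harmonic gain is applied to the truth.
* Shank angular velocity carries one template swing peak per cycle with a
  boundary trough at 55% of the cycle, giving known event times.
* Sensors are tilted by a known rotation (default 20°) about a random
  horizontal axis, with the x-axis forward — consistent with the alignment
  convention, so the anatomical frame is fully recoverable and the
  gravity-alignment step is genuinely exercised.
* Test-retest structure: each index target has a subject-level random effect
  plus session noise with variance split so the true ICC per index family is
  exactly the specified value (defaults: nRMS 0.95, iHR 0.90, LDLJ 0.65,
  matching the reliability ranges reported for this population). Marginal
  means and SDs default to values typical of a severe-TBI cohort on a 10 m
  walk (e.g. symmetry 71–78%, stride time ≈ 1.27 s ≈ 1 m strides at
  0.79 m/s). The default stride time is 163/128 s so a stride is an integer
  number of samples at 128 Hz, keeping the harmonic model exactly commensurate
  with the grid.
* Stride-to-stride duration jitter (CV 2%) exercises segmentation robustness;
  it and the sensor noise are disabled for analytic-truth tests.

What the generator does **not** emulate: cross-axis correlation of real trunk
accelerations, turning, double-support fine structure, soft-tissue artefact,
or pathological phenotypes beyond what the index targets encode. Passing the
recovery tests therefore shows the pipeline computes its defined quantities
correctly — not that those quantities capture every aspect of disordered gait.

```{r example, fig.width = 6, fig.height = 4}
spec <- cohort_spec(n_subjects = 6, seed = 42)
cohort <- generate_cohort(spec)
run <- run_pipeline(cohort$trials)
run$reliability[1:5, c("index", "icc", "icc_lo", "icc_hi", "sem", "mdc")]
```

## Validation problem sizes

The shipped tests validate: filter response against its analytic Butterworth
magnitude; alignment on randomly tilted static frames; segmentation on
template trains with known event times (boundary error under 23 ms at
128 Hz); index closed forms (sinusoid LDLJ to 1e-3, symmetry bounds to 1e-9);
ICC against a direct mean-squares oracle (1e-10) with CI coverage checked over
200 simulated 49-subject cohorts per reliability level; and end-to-end
recovery of generator truths from noiseless rotated 8-stride trials (symmetry
within 1 percentage point, nRMS within 2%, LDLJ within 0.01). These sizes keep
the whole suite near ten seconds while leaving each check statistically
meaningful.

## Known limitations

* The AP/ML completion assumes a roughly forward-facing sensor mounting; a
  grossly rotated mounting needs a per-site `forward_axis` hint.
* Stride detection assumes positive mid-swing peaks in the ML shank channel;
  mounting conventions that flip the sign require negating the channel.
* The harmonic signal model makes symmetry exact but cannot represent
  within-stride transients (e.g. spasticity-related jerks) except through
  their harmonic footprint.
* With only two sessions the agreement ICC's session mean square is estimated
  on one degree of freedom; its CI is accordingly wide at small n.
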