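---
title: "Measuring motor segmentation from isometric force recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring motor segmentation from isometric force recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forceseg)
```

## The measurement problem

Healthy adults produce a rapid isometric contraction with one brief,
high-amplitude burst of neuromuscular excitation; the force trace rises
smoothly to its peak. In a subset of people with Parkinson's disease the
excitation is interrupted by transient reductions, and force rises in
several *segments* separated by *slowing periods* — plateaus where the
rate of force development (RFD) collapses before the next burst.
`forceseg` quantifies this from a single normalized force channel. Each
acceleration lobe of the force signal corresponds to one excitation
burst, so counting sign changes of the second derivative F″(t) between
pulse onset and peak force counts segments:

> segments = ceiling((zero crossings of F″ + 1) / 2)

The ceiling resolves the half-integer case the bare formula produces when
an interval ends mid-acceleration (an even crossing count): the segment
that is still in progress — in particular the one delivering 90% of peak
force when counting "segments to F90" — is counted. On a pattern like
`+ − + − + −` between onset and peak (three bursts), there are 5
crossings and (5+1)/2 = 3 segments.

## Pipeline stages and their parameters

**Normalization.** All analysis operates in %MVC units (100 · F / MVC,
with MVC the greatest of the subject's maximal-contraction trials, via
`best_mvc()`). Operations refuse raw-unit recordings rather than rescale
silently, so unit errors surface immediately.

**Derivative estimation** (`compute_derivatives()`). RFD and F″ are
windowed least-squares slopes, applied twice, with a 50 ms window
(`window_ms = 50`). The window is `round(window_ms · fs / 1000)` samples,
forced odd by rounding up — 11 samples at 200 Hz, spanning exactly 50 ms
of sampling intervals, as a centered window needs odd length. At the
edges the full-width window is shifted to stay in bounds; because a
fitted line's slope does not depend on where in the window it is read,
the shifted window's slope is reported at the off-center sample, giving
full-length output. No smoothing beyond the two slope passes is applied:
the 50 Hz low-pass is a property of the acquisition chain (and of the
simulator), not of the analysis.

The window trades noise suppression against bandwidth. The slope filter's
gain at 5 Hz is about 0.93, i.e. a ~7% attenuation of derivative
amplitude relative to the true derivative (a central difference at 200 Hz
attenuates by < 1%). Below about 2.5 Hz the two estimators agree within
2% of the peak derivative, which the test suite verifies; segmentation
itself depends on the *sign* pattern of F″, which the attenuation does
not disturb for the 5–12 Hz burst alternation seen in segmented pulses.

**Pulse detection** (`detect_pulses()`). Candidate peaks are local force
maxima of at least `min_peak = 10` %MVC separated by at least
`min_separation = 1` s (taller peaks suppress smaller neighbours); these
two gates replace the investigator's visual screen and are deliberately
permissive — eligibility for analysis is decided later by the 20–60 %MVC
amplitude window. Onset and offset use the `rfd_threshold = 20` %MVC/s
rule. The onset scan runs backward from the peak and accepts a
sub-threshold-RFD sample as "pre-onset" only if force there is also near
baseline (`onset_force_max = 10` %MVC). The force guard is essential for
the signals this package exists to measure: during a slowing period RFD
routinely dips below 20 %MVC/s while force is high, and a bare backward
threshold scan would truncate every segmented pulse at its last slowing
period. Ties are broken toward the peak (the onset is the sample
immediately after the last qualifying pre-onset sample). The offset scan
arms once RFD has fallen below −20 %MVC/s and closes when it rises back
above it. Scans that collide with a neighbouring pulse flag the pulse
`merged`; a manual-override CSV (`apply_overrides()`) can drop or
reinstate individual pulses, standing in for visual confirmation.

**Zero crossings and boundaries** (`zero_crossings()`,
`extract_boundaries()`). Crossings are strict sign changes between
consecutive non-zero-sign samples; samples exactly at zero inherit the
previous non-zero sign, so plateaus at zero are bridged and never
double-counted. Because piecewise-linear force makes F″ *numerically*
tiny rather than exactly zero between corners, F″ values below 1e-9 of
the series maximum are snapped to zero before crossing detection. A
crossing's position is the first sample of the new sign. Segment k ends
at the F″ minimum between crossings 2k−1 and 2k and begins (k ≥ 2) at the
F″ maximum between crossings 2k−2 and 2k−1; missing right bounds fall
back to the peak sample, and an in-progress segment ends at the peak.
Segments and slowing periods therefore interleave and exactly tile the
span from onset to the last segment end, which the tests assert
structurally on every simulated pulse.

**Timing metrics.** t_F90 is the time from onset to the first *sample* at
or above 0.9 × peak force — no interpolation, so the worst-case bias at
200 Hz is 5 ms, below the group differences of interest, and the rule is
deterministic. The RFD peak takes the earliest sample on exact ties; if
it falls inside a slowing period (a degenerate case, since the RFD
maximum sits at a +→− F″ crossing inside a segment), it is assigned to
the nearer adjacent segment, the earlier one on an exact tie.

**Subject aggregation** (`select_pulses()`, `summarize_subject()`).
Pulses with peaks in [20, 60] %MVC that are not QC-flagged are eligible;
`k = 41` are drawn uniformly without replacement. The odd default keeps
medians of integer segment counts integral ("half segments" are not
observations). Subjects with fewer than 41 eligible pulses contribute all
of them, with a warning — the fallback a practical analyst would use.
Selection is keyed on pulses in onset order and seeded per subject by a
stable hash of (master seed, subject id), so results are independent of
subject processing order and of how pulses were stored. Ordinal duration
medians (segment j, slowing period j, j = 1..5) use only pulses
possessing that ordinal, so per-ordinal n shrinks for higher ordinals
exactly as it does in real cohorts. A PD subject is classified PD_Seg
when the median segments-to-F90 is ≥ 2 (inclusive).

## The inference layer

- **Prevalence** (`prevalence_test()`): exact binomial test of k
  segmented among n PD subjects against p₀ = 0.5. The two-sided p doubles
  the smaller tail — `min(1, 2·min(P(X ≤ k), P(X ≥ k)))` — which is the
  convention that reproduces a doubled-tail p of 0.008 at 39/57; the
  minimum-likelihood rule used by `binom.test()` is available via
  `method = "minlik"`. Clopper-Pearson bounds are the inverse-beta closed
  form, with the degenerate k = 0 / k = n endpoints fixed at 0 and 1.
- **Omnibus** (`kruskal_wallis()`): `stats::kruskal.test` (midranks,
  tie-corrected H, chi-square reference); an all-identical pooled sample
  returns H = 0, p = 1 by convention.
- **Pairwise** (`dunn_pairwise_bonferroni()`): Dunn's z on pooled
  midranks with tie correction — the standard follow-up to
  Kruskal-Wallis in mainstream statistical software, implemented here
  because no post-hoc package ships with the environment's R stack.
  p-values are Bonferroni-adjusted with m = g(g−1)/2 contrasts per
  measure (one family per measure), and every contrast carries
  r = |z|/√(n_i + n_j). The `n_pair` used for r is reported explicitly.
- **Two-sample** (`mann_whitney()`): U from midranks, tie-corrected
  normal z, and an exact two-sided p by enumerating all group labelings
  when n₁ + n₂ ≤ 12.
- **Repeated measures** (`friedman_stepdown()`): Friedman chi-square in
  Conover's tie-corrected form, `(k−1)·Σ(R_j − n(k+1)/2)² / (Σr² −
  nk(k+1)²/4)`, which reduces to the classical statistic without ties;
  `stats::friedman.test` is used as a cross-check on tie-free data in the
  tests but does not apply the tie correction itself. Rows with missing
  ordinals are dropped and counted. Homogeneous subsets are the maximal
  runs of conditions, ordered by mean rank, whose restricted Friedman
  test has p > α, discarding runs nested in an earlier one. This is a
  deterministic, documented stand-in for the step-down procedure of
  proprietary software; it can produce overlapping subsets (e.g.
  conditions 2–4 and 3–5), which a literal "restart after the breaking
  condition" rule cannot.
- **Descriptives** (`descriptives()`): median, IQR with the
  linear-interpolation (type 7) quantile convention, CV = 100·sd/mean
  with the n−1 denominator, computed across PD_Seg subjects' per-subject
  medians.

## The synthetic cohort generator

No recordings are deposited with segmentation studies of this kind, so
the package carries a generative model whose defaults are the study
conditions: 200 Hz sampling, 50 Hz low-pass character, pulses cued 3–5 s
apart, peak targets ~N(40, 3.5²) %MVC, and archetype-dependent burst
structure. Each pulse is a train of rectangular bursts of neural drive;
the drive sets the *rate* of force through a critically damped
second-order twitch kernel (time constant 25 ms, unit gain), and force is
the running integral of that rate. This is the simplest mechanism that
reproduces the observed force topology — ramps separated by plateaus —
because with a rate-drive the force holds its level between bursts
instead of decaying. After the last burst the model switches to an
exponential relaxation (time constant 120 ms) 2.5 twitch time constants
past the final burst, approximating the excitation-to-relaxation
transition; only the rising phase is analyzed. The 25 ms twitch constant
is a calibration constant placing noiseless single-burst RFD peaks in the
several-hundred %MVC/s range typical of healthy rapid contractions; it is
configurable.

Burst/gap parameters: first, second and later segment duration means of
86 / 65 / 52.5 ms and gap means of 80 / 60 / 50 ms with CVs of ~16–26%,
drawn truncated-normal at ±3 SD so times stay positive. Bursts after the
first have relative drive amplitude ~N(1.3, 0.3²) (floored at 0.2), so
the RFD peak most often lands in the second segment of a multi-burst
pulse, as observed in segmented patients. Archetypes: OA and PD_NoSeg
pulses are single-burst with a 5% multi-burst admixture; PD_Seg subjects
draw a per-subject multi-burst probability uniformly from [0.80, 0.95]
(mean 0.875, consistent with the ~82% multi-segment pulse share reported
in segmented patients; the lower bound keeps the noiseless-limit
classification recovery exact for any seed). Multi-burst pulses carry
2–6 bursts with probabilities 0.35/0.30/0.20/0.10/0.05, so 5th-ordinal
segment and slowing durations occur in a realistic minority of subjects.
Noise (SD 0.3 %MVC) is added after filtering, so the analysis-side
derivative pipeline faces broadband noise at 200 Hz as a real DAQ would
deliver.

What the simulator does *not* emulate: tremor oscillations, drift or
fatigue across a session, amplitude-dependent noise, EMG, and any
within-pulse variability beyond the burst train (e.g. partial rather
than complete drive silencing during slowing periods). Passing recovery
tests therefore demonstrate that the pipeline's geometry and counting
rules are correct and robust to broadband noise at realistic amplitude —
not that the simulator's cohort statistics match any real cohort beyond
the descriptive targets built into its defaults.

## Verification strategy and problem sizes

The test suite validates every stage against independent oracles:
per-window normal-equation slope fits, a sign-carrying brute-force
crossing scan, direct-formula Dunn z, full enumeration for small-sample
Mann-Whitney and binomial tails, and hand-computed rank statistics
(H = 7.2 on three consecutive rank triples; Friedman χ² = 10 on 5×3
concordant rows; the (B−A)²/n sign-test equivalence at k = 2). Recovery
tests run the whole pipeline on simulated ground truth: 1,000 random
pulses for oracle equivalence and noise robustness, a 39/18/22-subject
cohort (45 pulses each) for classification recovery at default noise and
in the noiseless limit, and a 10,000-replicate null simulation (3 groups
of 15 normal draws) for Kruskal-Wallis type-I calibration. These sizes
keep the default suite under a few minutes on one CPU while leaving the
statistical margins (≥ 95% recovery thresholds, ±1 percentage point on
the 5% rejection rate) comfortably testable.

## Known limitations

- The 50 ms slope window attenuates derivative amplitude above a few Hz
  (~7% at 5 Hz); RFD peaks are therefore mildly conservative. Crossing
  *counts* are unaffected until bursts alternate faster than the window
  can resolve (< ~25 ms gaps, well below the 40 ms robustness floor).
- The onset definition needs near-baseline force; contractions initiated
  from a sustained pre-load would require raising `onset_force_max`.
- The step-down homogeneous-subset rule is a documented reconstruction,
  not a replication of any proprietary implementation.
- Only the rising phase of each pulse is analyzed; the offset threshold
  bounds the pulse but relaxation-phase structure is not profiled.
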