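---
title: "Methods: from annotated beat streams to cohort-level HRV statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from annotated beat streams to cohort-level HRV statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`holterhrv` analyses *annotated* beat streams from long ambulatory ECG
(Holter) recordings — typically overnight, 12-hour recordings derived from a
500 Hz waveform — of the kind produced when an operator builds a waveform
library in a commercial Holter platform and exports R-peak times, beat
labels and wave fiducials. The package deliberately starts *after* waveform
processing: R-peak detection, wave delineation and any visual morphology
call (e.g. fragmented QRS) are inputs, not algorithms, here.

A recording is a `beat_series`: R-peak times in ms from recording start,
one label per beat (`N` normal, `V` ventricular, `S` supraventricular,
`A` artifact; unknown labels are conservatively remapped to `A`), an
optional integer morphology class for `V` beats, and optional fiducials
(P onset, QRS onset/offset, T end) which must satisfy
`p_on < qrs_on < qrs_off < t_end` and bracket the R peak. Times are 0-based
ms floats; at 500 Hz source resolution no sub-ms rounding is ever needed.

## NN cleaning

All HRV mathematics runs on the `nn_series` produced by `clean_to_nn()`.
The rule: of the `n - 1` consecutive-beat intervals, keep an interval iff
**both** flanking beats are labelled `N`. This is equivalent to excluding
the RR intervals preceding and following every arrhythmic beat, and is
strictly conservative — artifact-adjacent intervals are dropped too, so
only intervals between normal complexes survive. A physiologic guard
additionally removes kept intervals outside `[200, 3000]` ms (configurable):
telemetry dropouts otherwise masquerade as giant RR intervals and corrupt
every downstream index. Both exclusion counts are reported separately, and
`kept + excluded + guarded = n - 1` always holds.

Successive-difference statistics (RMSSD, pNN50, Poincaré pairs) use only
*contiguous* pairs — two kept intervals with no excluded interval between
them. Differences spanning a cleaning gap are artifacts of exclusion
(post-extrasystolic dynamics, dropouts), not sinus physiology.

# Intervals and rate-corrected QT

`summarize_intervals()` averages over the whole trace: HR is
`60000 / mean(NN)` (the mean-of-intervals convention, so alternating
500/1500 ms intervals give 60 bpm), PR is `qrs_on - p_on` and QT is
`t_end - qrs_on` over normal beats carrying those fiducials. Beats lacking
fiducials are skipped and counted; a trace with none gets explicit `NA`,
never zero.

Four QT corrections are provided, the set in common canine use:

| formula | form | identity point |
|---|---|---|
| Bazett (B) | QT / sqrt(RR_s) | RR = 1 s |
| Fridericia (F) | QT / RR_s^(1/3) | RR = 1 s |
| Van de Water (V) | QT − 87·(RR_s − 1) | RR = 1 s |
| Matsunaga (M) | QT·ln(600)/ln(RR_ms) | RR = 600 ms |

A note on Matsunaga: the canine form is normalised to a *reference interval
of 600 ms* (HR 100 bpm, a typical dog), not to 1 s. It is therefore the
identity at RR = 600 ms and **not** at RR = 1 s; treating all four formulas
as 1-s identities would silently misstate M. The package asserts B/F/V at
1 s and M at its own reference point.

QTc is computed **per beat** from that beat's own preceding RR and then
averaged (default). Per-beat correction is standard Holter practice and is
what makes a per-trace correlation of QTc against HR meaningful; correcting
the trace-mean QT by the trace-mean RR is also exposed
(`qtc_mode = "trace-mean"`). The RR used is the interval *ending* at the
beat, and beats following a non-normal beat are skipped (post-extrasystolic
RR would bias the correction).

`select_qtc()` implements the data-driven formula choice: for each formula,
Pearson's r of QTc against HR and the OLS slope of QTc on HR are computed
on healthy-subject observations, with a Shapiro–Wilk screen reported per
formula. The selected formula minimises `|r|`; ties break on smaller
`|slope|` (the published procedure reports both quantities but states no
explicit combination rule; `|r|`-primary is the natural reading of
"best at decorrelating"). Whether observations are pooled beats or
per-subject trace means is the caller's choice — both pooling levels are
legitimate and the reference procedure is ambiguous on this point.

# Ventricular ectopy and Lown grading

`find_runs()` enumerates maximal runs of consecutive `V` beats: doublet = 2,
triplet = 3, and a run of **4 or more** is a ventricular-tachycardia salvo —
"more than 3 consecutive" read literally, so triplets stay in class 4a.
Bigeminy is a sustained stretch of at least 4 consecutive `N,V` pairs
(configurable). R-on-T is judged from fiducials when available (a `V` beat's
R-peak time precedes the previous beat's T end); without a T end, a coupling
interval below half the mean NN is used as a fallback and flagged as
heuristic.

`grade_lown()` assigns the highest applicable class in the order
`5 > 4b > 4a > 3b > 3a > 2 > 1 > 0`. Classes 1 and 2 split isolated-PVB
rates at 30/hr; the published wording ("< 30/hr" vs "> 30/hr") leaves
exactly 30/hr unassigned, and the package classes the boundary as 2
(frequent). Polymorphism is judged from the input `morph_id` labels
(≥ 2 distinct nonzero ids); if all `V` beats carry the unassigned id 0 the
trace is treated as monomorphic with a caveat flag — morphology clustering
from waveforms is out of scope. Ectopy burden is reported both per hour and
as a percentage of total beats, since both conventions appear in practice.

# Time-domain and Poincaré indices

All SDs here are population (divide-by-`n`) SDs. The reference methods are
silent on the convention; on multi-hour traces the difference is
negligible, and the population convention makes the Poincaré–RMSSD identity
below *exact*, which is worth more to a test suite than an `n/(n-1)` factor.

Indices: SDNN; CV(RR) = SDNN/meanNN; RMSSD over contiguous pairs; pNN50
(strictly greater than 50 ms) and the rate-adaptive pNN10%(meanRR)
(threshold 10% of the trace's mean NN); and the HRV triangular index —
total NN count divided by the modal bin count of the NN histogram at bin
width 1000/128 ≈ 7.8125 ms (the bin width implied by a 128 Hz discretisation
of the interval axis), bins anchored at 0. Whether the reference
implementation anchors bins at the minimum NN instead is unknowable from
its description; anchor-at-0 is fixed here and documented. The index is
bounded by `[1, n]` by construction.

For the Poincaré plot each NN is plotted against the previous one
(contiguous pairs only). LTV (SD2) is the population SD of
`(x + y)/sqrt(2)` — dispersion along the identity line about the mean
point. STV (SD1) is the RMS of `(x − y)/sqrt(2)` — dispersion about the
identity line itself. Two conventions exist for STV: deviation about the
*line* (second moment of `x − y` about zero) and deviation about the *mean
difference*. They coincide when the mean successive difference is zero and
differ by `mean(d)^2/2` otherwise. The about-the-line convention is used
because (a) it is what "SD of the points along a perpendicular crossing the
line of identity" literally describes, and (b) it makes
`STV = RMSSD/sqrt(2)` hold to machine precision on the same pair set,
which the suite asserts at 1e-9 relative. The rotation identity then takes
the exact form `STV² + LTV² = Var(x) + Var(y) + mean(x−y)²/2`, and is
tested in that form.

# Spectral analysis

`spectral_summary()` epochises the recording into contiguous 15-minute
windows from time 0; an epoch is used iff kept-NN time covers at least 80%
of it (both parameters configurable; the trailing partial window is always
rejected). Per epoch, `band_power()`:

1. resamples the NN tachogram (value = RR at each interval's end time) to
   an even 2 Hz grid by **cubic-spline** interpolation, bridging cleaning
   gaps up to 5 s — samples affected by longer gaps are invalidated so no
   low-frequency power is fabricated across dropouts;
2. splits the grid into 512-sample segments at 50% overlap, removes each
   segment's mean, applies a rectangular window (i.e. none), and scales
   periodograms so the integrated power over (0, Nyquist] equals the
   segment variance in ms² (Parseval, exact for the rectangular window);
3. averages periodograms over fully valid segments (Welch) and sums bins
   whose *center* frequency falls in each half-open band:
   VLF [0.003, 0.04), LF [0.04, 0.15), HF [0.15, 0.4) Hz. The total is
   literally `VLF + LF + HF`, mirroring how such tables are printed.

Two deliberate deviations from the reference description deserve emphasis.

**FFT geometry.** "512 points on a 15-min epoch" implies an effective
sampling near 0.57 Hz, whose Nyquist (0.28 Hz) cannot reach the stated HF
band edge of 0.4 Hz. The band edges are treated as authoritative over the
implied geometry: the tachogram is resampled at 2 Hz (Nyquist 1 Hz) and
512-point rectangular segments are Welch-averaged within the epoch
(6 segments per full epoch).

**Interpolation.** Linear interpolation between knots spaced at the beat
period acts as a sinc² low-pass at the beat rate: at RR ≈ 870 ms the
0.25 Hz respiratory component loses ≈ 38% of its power
(sinc⁴ interpolation loss × the IPFM averaging loss below — verified both
analytically and empirically during development). Cubic-spline
interpolation, the default of mainstream HRV toolchains, has an essentially
flat passband through 0.4 Hz at canine rates and is used instead. Spline
overshoot at gap edges is clamped to the local data range.

A physical limit remains and is *not* corrected for: any beat-mediated
measurement of a modulation at frequency `f` is low-passed by the
integral-averaging of the heart period over each interval, an attenuation
of `sinc²(f · RR)` in power. At RR = 500 ms (young dog, HR 120) this is
−5% at 0.25 Hz; at RR = 880 ms (adult) it reaches −15%. Spectral-recovery
tests therefore plant their sinusoids at the young-dog rate, where the
estimator's own error budget (±10%) is meaningful; this is a property of
beat-sampled tachograms, not of this implementation. VLF estimability is
flagged whenever fewer than 3 cycles of the lowest VLF frequency fit in an
epoch (a 900 s epoch holds only 2.7 cycles of 0.003 Hz, so the flag is on
at the defaults — absolute VLF values from 15-min epochs are indicative,
not definitive). HF n.u. = 100·HF/(LF+HF) and LF/HF are computed per epoch
and then averaged across used epochs, as are the band powers.

Because the reference platform's exact spectral dialect (span of its 512
points, interpolation, overlap) is unpublished, absolute ms² values are
dialect-dependent; only arithmetic identities of printed tables (band
additivity) and parameter-recovery properties are asserted, never absolute
published powers.

# Cohort statistics

`lsd_compare()` contrasts the two groups at each shared age with the
Fisher-LSD construction: the error mean square is pooled over all
group × age cells of the variable (cells with fewer than 2 values
contribute nothing), and the per-age statistic is
`t = (m1 − m2)/sqrt(MSE·(1/n1 + 1/n2))` on the pooled error df. With a
single timepoint this reduces exactly to the pooled two-sample t-test (the
suite asserts agreement with `t.test(var.equal = TRUE)` to 1e-12). The full
mixed-model / repeated-measures omnibus machinery is deliberately not
reproduced — its random-effects structure is not recoverable from the
reference description and its p-values are not acceptance surfaces; the
within-group age effect reported alongside is a plain one-way ANOVA across
ages, for orientation only.

`spearman_cor()` computes rho on tie-averaged ranks; for n ≤ 9 the
two-sided p is an exact enumeration over all permutations of one margin
(valid under ties — relevant because the outcome screens of interest run at
n = 8), otherwise the usual t approximation. `early_late_screen()`
correlates early predictors (variable at a given age) with a late outcome
(e.g. fractional shortening at 24 months) per subject, restricted by
default to the affected group. Reported p-values are deliberately
unadjusted, matching the screening procedure the package mirrors; a
Benjamini–Hochberg column is emitted alongside so the user sees both — an
unadjusted screen over many indices at n = 8 carries an obvious risk of
biased correlations, and the output should make that visible rather than
hide it.

# The synthetic world

`gen_beats()` realises a stated generative world by integral pulse
frequency modulation: the instantaneous heart period
`m(t) = base_rr + Σ aᵢ·sin(2πfᵢt + φᵢ)` (ms) drives an emitter that fires a
beat each time `∫ dt/m(t)` accrues one unit. IPFM is chosen over direct
tachogram sampling so that modulator frequencies are defined in real time
(Hz) — exactly the axis the band analysis integrates over. Integration uses
a 50 ms trapezoid grid with linear crossing interpolation; unmodulated, the
emitted intervals are exact to sub-µs and the beat count is
`⌊T/base_rr⌋ ± 1`.

Defaults state an overnight canine recording: 12 h duration, adult resting
RR 880 ms, VLF/LF sinusoids (60 ms at 0.01 Hz, 55 ms at 0.08 Hz) plus a
pronounced 90 ms respiratory sinus arrhythmia at 0.25 Hz — dogs are strongly
vagally modulated, which is what produces the branched Poincaré morphology.
Fiducials follow linear rate laws with small Gaussian noise
(PR = 55 + 0.05·RR ms; QT = 230 + 87·(RR_s − 1) ms, the Van de Water
inverse law, so QTcV recovers the 230 ms intercept and the selection
procedure must prefer V). Ectopy is an explicit grammar: events per hour,
coupling at 0.6 of the local NN, fully compensatory pauses (factor 2.0 —
the sinus clock is untouched), a run-length distribution, optional
bigeminal stretches and an R-on-T toggle that shortens the first event's
coupling below the preceding T end. Every generated stream passes the
package's own reader validation, and a ground-truth event log accompanies
injected ectopy.

`gen_cohort()` layers a cohort on top: group sizes (8/8 by default),
timepoints 2–24 months, an age law for resting HR interpolating
133 → 68 bpm from 2 to 24 months (the trajectory of growing dogs), a
GRMD heart-rate excess of +20 bpm, multiplicative VLF suppression (0.6 on
amplitude), a QTc drift and ectopy escalation with age in the affected
group, per-subject random effects (HR SD 3 bpm; VLF amplitude uniform
20–80 ms — a several-fold between-subject spread comparable to what young
dogs show), and the outcome law
`lvfs_24m = 20 + 0.02·VLF_true(4 mo) + ε`, ε SD 0.5. The outcome
coefficients are chosen once so the deterministic span (≈ 5 percentage
points of fractional shortening across the VLF range) dominates the noise —
the stated construction is "planted law, small noise", i.e. a world in
which the screen *should* succeed; the test then verifies that the
pipeline's measurement chain does not destroy it.

What the generator does **not** emulate — and hence what a green suite does
not establish: circadian architecture beyond the stated modulators,
non-stationary or broadband (1/f) RR dynamics, waveform-level morphology,
annotation error, or the correlational structure of real dystrophic
remodelling beyond the planted laws. Recovery tests certify the estimators
against a known truth; they are not evidence about any real cohort.

# Numerical choices and scaled-down studies

* Band edges half-open `[low, high)`; bin assignment by bin-center
  frequency; per-segment mean removal only (no detrending).
* Triangular-index bins anchored at 0; width exactly `1000/128` ms.
* NN guard `[200, 3000]` ms, configurable; guard exclusions counted
  separately from label exclusions.
* Exactly 30 isolated PVBs/hr grades as Lown 2.
* Population SDs throughout the time-domain/Poincaré indices.
* Derived seeds stay below 2³¹; every generator records its seed in the
  output metadata, and `run_trace()` stamps the package version and an MD5
  configuration hash into every row.

The 100-seed cohort recovery studies in the acceptance suite run at reduced
recording length — one full 15-minute spectral epoch (16 min) for the VLF
screen, 6 minutes for the heart-rate contrast — so they complete on one CPU
in minutes. The planted effect sizes are those of the stated world;
shortening the recordings only widens measurement error, i.e. makes the
tests harder, not easier.

# Known limitations

* Absolute spectral powers are dialect-dependent (resampling rate,
  interpolation, windowing); cross-software comparisons should be made on
  identities and trends, not raw ms².
* VLF from 15-minute epochs is estimability-limited by construction.
* The LSD contrast assumes homoscedastic cells; with strongly heteroscedastic
  variables (raw band powers, typically log-normal) a transform before
  `lsd_compare()` is advisable.
* Supraventricular ectopy is cleaned around but not sub-typed; conduction
  defects are out of scope.
* The heuristic R-on-T fallback (coupling < 0.5·meanNN) is a screen, not a
  diagnosis; it is flagged as heuristic wherever used.
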