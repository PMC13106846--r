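---
title: "Complexity-based screening of normal-sinus-rhythm ECGs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity-based screening of normal-sinus-rhythm ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgcomplexity)
```

## The problem and the model

Hearts that produce ectopic beats under exercise load are believed to
carry diffuse myocardial alterations that leave faint, rate-dependent
traces in the normal-sinus-rhythm surface ECG. This package quantifies
those traces as the *disorderliness* of symbolised 60-s ECG strips and
turns per-subject averages of heart-rate-corrected disorderliness into a
screening score. Everything downstream of the raw voltage trace — strip
selection, coarse graining, the six complexity estimators, the
correction and the evaluation — is deterministic, so any two runs on the
same data agree exactly.

The pipeline assumes a single-lead recording with a dominant R
deflection, normal sinus rhythm in the analysed band, and a sampling
rate of at least 125 Hz (the analysis rate; higher-rate input is
down-sampled). It does not model multi-lead geometry, atrial
fibrillation, or exercise rates above 120 bpm.

## Strip selection

R peaks are detected with a band-pass (5–40 Hz, zero-phase Butterworth),
differentiate-square-integrate energy transform and an adaptive
threshold, followed by refinement on the raw signal and a 0.3 s
refractory rule consistent with rates up to 200 bpm. A greedy
left-to-right scan then accepts non-overlapping 60-s windows anchored at
R peaks; a window is accepted iff every RR interval inside deviates
less than 30% from the window's own mean RR and the window's mean rate
lies in the configured band. The "window-local mean RR" reading of the
30% rule, the beat-anchored windows, and the one-beat advance after a
rejection are deliberate determinism choices where several readings were
possible; they make acceptance decisions independent of anything outside
the window.

The 30% rule is the only artefact/ectopy gate. It tolerates respiratory
sinus arrhythmia (a few percent RR modulation) but rejects any window
holding a premature beat at ≥ 35% prematurity, the floor the synthetic
generator enforces for its ectopics — that is what makes the
"no ectopic inside an accepted strip" guarantee provable rather than
statistical. A beat missed by the detector inside a window widens one RR
by ~100% and likewise forces rejection.

Baseline wander is removed by subtracting a natural cubic spline through
knots at the middle of each RR interval, each knot valued at the local
median voltage in a ±40 ms window; with fewer than two knots the strip
median is subtracted instead. The spline degree and the knot statistic
are package choices (the originating procedure is described only as "a
polynomial spline at the middle of R-R intervals").

## Fiducial annotation

Six markers are located per beat, searching windows scaled by the local
RR: Q peak (extremum opposite R within 0.12 RR before R), Q onset (last
sample before Q peak with |v| below 5% of the beat's peak-to-peak
range), QRS end (first such sample after the S extremum), T peak
(largest deflection in (QRS end + 50 ms, QRS end + 0.45 RR)) and T end
(first sample after T peak below 5% of the T amplitude). All searches
run on a 30 Hz zero-phase low-passed copy with a per-beat local-offset
estimate from the pre-Q isoelectric window, because the 5% crossings
otherwise sit below the noise floor of realistic recordings. Beats in
which any search fails, the T deflection is indistinguishable from the
QRS residue, or the marker ordering is violated are flagged and
excluded; a strip with no annotatable beat is excluded entirely.

Two readings in the source material were settled here: the `'J'`/`'L'`
symbols mark the **T**-wave peak and termination (the alternative — the
R wave — is inconsistent with the rest of the feature list, which
already assigns `'A'` to the R peak), and T end is located by the same
5%-amplitude decay rule the synthetic ground truth uses rather than a
tangent construction, so the generator and the annotator share a single
documented definition. No separate beat-detection scheme exists: it is
the FD subset containing only the R marker.

## Complexity estimators

* **LZ'76** counts components of the exhaustive-history decomposition
  (Kaspar–Schuster scan); the final, possibly incomplete, component
  counts as one.
* **LZ'78** counts incremental-dictionary phrases; a trailing
  already-known fragment counts as one.
* **Titchener T-complexity** sums `log2(k_i + 1)` over the greedy
  right-anchored T-decomposition `p_m^{k_m} … p_1^{k_1} α`. Worth
  stating plainly: this quantity is *not* monotone under appending a
  single character — the decomposition is anchored at the final literal,
  and an appended symbol can reorganise the parse into fewer or
  lower-exponent steps (e.g. `bababbbab` → 5 taug but `bababbbaba` →
  4 taug). Complexity still grows on average with length and random
  strings dominate sorted ones by a wide margin; the property tests
  check those statistical versions.
* **Shannon entropy** is order-1 (single-symbol frequencies); no block
  length is defined for it here.
* **ApEn/SampEn** run on the raw voltage strip with Chebyshev distance,
  embedding m = 2 and tolerance r = 0.2·sd — the field-standard defaults,
  adopted because none are stated in the source description. A
  zero-variance series degenerates the relative tolerance; a 1e-10
  absolute floor is applied and logged.

Normalisation to bit/sample: LZ'76 by n/log2(n), LZ'78 by n; the
entropies pass through. For the T-complexity the per-sample rate C_T/n
is used — the available description ("average entropy values") does not
distinguish the linearised T-information rate from the per-sample
complexity, and the per-sample rate keeps every symbolic estimator on
the same footing; since the heart-rate correction subtracts a fitted
trend per estimator anyway, any fixed monotone rescaling would not
change group comparisons or ranks.

All string kernels are compiled (Rcpp), mirroring how nonlinear
time-series packages treat their inner loops; independent naive
quadratic R parsers live in the test helpers and agree exactly on 10⁴
random strings.

## Heart-rate correction

Complexity depends strongly and non-linearly on heart rate, so per
estimator × mask the strip values are averaged within 5-bpm bins (both
the bin mean rate and mean value are used), polynomials of degree 2–4
are fitted by least squares, and AIC = n·ln(RSS/n) + 2k selects the
degree with ties to the lower degree; essentially-exact fits are floored
so the parameter penalty breaks the tie. The fitted curve is subtracted
from each strip's value and the per-subject mean of the residuals is the
score. Bin-averaging before fitting is the adopted reading of "averaged
complexity data values"; the bin width is configurable.

Two honest caveats, both inherited from the procedure being modelled:
the polynomial is fitted on the full cohort (no leave-one-subject-out),
so a small optimistic bias leaks into the evaluation; and when a sweep
band is so narrow that all strips fall into fewer than three bins, the
pipeline falls back to mean-centring (a degree-0 trend) and logs it —
within a 5-bpm-wide band there is no rate trend left to remove.

## The synthetic generator

Each beat is a sum of five Gaussian bumps (amplitude mV, centre offset
from R in s, width s); defaults imitate a base-apex-style equine lead
with R dominant (1.0 mV, σ 16 ms), T at +0.22 s (0.35 mV, σ 50 ms) and P
at −0.26 s. The T centre shifts with the nominal RR (0.25 s/s around a
0.8 s reference, i.e. QT shortens at speed) and the P offset scales with
RR within [0.75, 1.3]× — without this rate adaptation the T and the next
P collide above ~90 bpm and no annotator could (or should) find a T end.
Beat schedules follow a constant or piecewise-linear heart-rate
trajectory (validated to 25–200 bpm) with multiplicative Gaussian RR
jitter (default sd 4%, a typical resting respiratory arrhythmia depth).
Measurement noise (0.02 mV sd), sinusoidal wander (0.15 mV at 0.25 Hz)
and the native 500 Hz rate (so the 125 Hz path is always exercised) are
defaults chosen once as realistic Holter-export conditions.

Ground truth is computed per beat by a brute-force scan of the clean
beat waveform with the same 5% threshold definitions the annotator uses,
so noiseless agreement is exact by construction and the tests measure
only the detector's noise robustness.

**The case/control knob.** Per beat, wave centres are jittered
(default sd 20 ms for P and T; a quarter of that for Q and S, since
intra-QRS timing is tightly coupled — full QRS jitter produced
unphysiological S-on-R collisions) and amplitudes by 5%. Cases receive
an additive change to the timing-jitter sd; the default strong effect of
−15 ms (20 → 5 ms) quarters beat-to-beat waveform variability, which
lowers symbolic complexity — matching the observed direction (cases
score lower) without claiming any mechanistic model of *why* diseased
myocardium would do this. The knob can be gated to beats above a heart
rate threshold, which is how the band-sweep demonstration injects an
effect only above 60 bpm. Ectopics are premature (≥ 35% of RR) beats
with no P wave, broadened QRS, a large R (1.6×, so the detector cannot
miss them in a refractory contest with a neighbouring sinus beat) and an
inverted T.

What passing tests on this generator shows — and does not. It shows the
pipeline recovers injected group differences at realistic SNR, respects
its own exclusion guarantees, and is chance-level under a null. It does
not show that real equine cohorts separate: the generator's effect is a
stand-in for an unknown generative mechanism, its waveforms are smooth
bumps without P/QRS micro-structure, electrode artefacts or
non-stationary noise, and its subjects are exchangeable.

## Problem sizes used in the checks

The shipped checks run a null cohort of 30 + 30 subjects (80-s
recordings, LZ'76 over the 63 masks), a strong-effect cohort of 20 + 20
(150-s recordings, LZ'76 + Titchener), a band sweep on 8 + 8 subjects
with 240-s ramped-rate recordings, segmentation properties over 1000
(test) / 300 (acceptance script) random recordings, and oracle
agreement over 10⁴ random strings of up to 64 symbols — sizes chosen so
the full suite completes in a few minutes on one CPU while keeping the
statistical assertions comfortably powered (the effect-cohort
separation margin is orders of magnitude, not percent).

## Numerical details and degenerate inputs

* Down-sampling: zero-phase 6th-order Butterworth at 80% of the target
  Nyquist, then exact decimation (integer ratios) or spline
  interpolation. Zero-phase filtering keeps fiducial indices aligned
  across rates; a polyphase FIR resampler was rejected after showing
  ~0.17 mV passband/delay error on a 1 Hz sine against the ~10⁻¹³ of
  this design.
* Ties: TC symbolisation maps values equal to the median to `'1'`
  ("the rest"); ranking breaks equal p by higher AUC, then lower mask
  code; the k-NN vote falls back k → k−2 → … → 1.
* Flat signals: R detection returns an empty index set; a flat beat
  template reports "no beat"; both-variances-zero group comparisons and
  B = 0 sample entropy raise errors rather than returning numbers.
* Wald intervals are clipped to [0, 100]%; an undefined PPV (no
  positive predictions) is reported as such, never as 0.
* All indices are 1-based (R convention) with strip windows
  `[start, start + 7500)`; symbol strings are length-preserving
  transforms of the 7500-sample strip.

## Known limitations

Single-lead only; the correction is cohort-internal (see above); the
restitution module is demonstrated on synthetic data only, where its
interval conventions (QT from Q onset; TQ from T end to the next Q
onset, so QT + TQ exactly tiles the Q-to-Q interval) are exact by
construction; and above ~110 bpm the annotator increasingly flags beats
as T and P merge — consistent with the method's own preference for
sub-maximal rates.
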