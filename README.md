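# ecgcomplexity

Non-linear disorderliness analysis of normal-sinus-rhythm ECGs for
screening subjects — athletic horses in the motivating application — that
are prone to ectopic beats during exercise, using only resting or
low-intensity-exercise single-lead recordings.

The premise: pathophysiological changes that predispose a heart to
ectopy subtly alter the beat-to-beat regularity of the surface ECG even
while the rhythm is normal. Those alterations are quantified by symbolic
complexity estimators applied to coarse-grained 60-s ECG strips, after
removing the strong dependence of every estimator on heart rate.

## Method

For each recording:

1. **Strip extraction** — down-sample to 125 Hz, detect R peaks
   (Pan–Tompkins-style band-pass/derivative/energy detector, 0.3 s
   refractory), and scan greedily for non-overlapping 60-s windows
   (7500 samples) in which every RR interval deviates < 30% from the
   window's mean RR and the mean heart rate lies in a configurable band
   (default 30–120 bpm). Baseline wander is removed by subtracting a
   natural cubic spline through mid-RR knots.
2. **Coarse graining** — each strip becomes symbol strings:
   *TC* (threshold crossing): `v_i >= median(v)` → `1`, else `0`;
   *XD*: the six fiducial markers per beat (Q onset `6`, Q peak `7`,
   R peak `A`, QRS end `G`, T peak `J`, T end `L`) on a background of
   `0`; *FD*: the 63 binary projections of the XD string, one per
   non-empty subset of the six markers (mask codes 1–63, bit order
   Qon=1, Qpk=2, R=4, QRSend=8, Tpk=16, Tend=32).
3. **Disorderliness estimation** — Lempel–Ziv '76 exhaustive-history
   component count c76, Lempel–Ziv '78 dictionary phrase count c78,
   Titchener T-complexity C_T = Σ log2(k_i + 1) over the greedy
   T-decomposition, order-1 Shannon entropy, and approximate/sample
   entropy ApEn(m, r·σ) / SampEn(m, r·σ) on the raw voltage strip
   (defaults m = 2, r = 0.2). Length normalisation: c76·log2(n)/n,
   c78/n, C_T/n; the entropies are already rates.
4. **Heart-rate correction** — per estimator × mask, complexity is
   averaged in 5-bpm bins and an AIC-selected polynomial of degree 2–4
   (AIC = n·ln(RSS/n) + 2k, ties to the lower degree) is fitted and
   subtracted. The per-subject mean corrected complexity (bit/sample) is
   the diagnostic score; cases are expected to score *lower*.
5. **Evaluation** — Welch two-sided t-tests and rank AUC
   (P(control > case) + ½P(tie)) per estimator × mask × heart-rate
   band; a band-limit sweep; ranking by ascending p, then descending
   AUC; sensitivity/specificity/PPV/NPV with 95% Wald intervals and
   clinical utility indices (CUI± = Se·PPV, Sp·NPV) at a score
   threshold.

A restitution module extracts per-beat RR, QT (Q onset → T end),
TQ (T end → next Q onset) and QRS-width series and ships a
(TQ, QT, RR)-triplet k-NN classifier.

Because no public recordings accompany the method, the package includes
a parameterised synthetic single-lead ECG generator (sum-of-Gaussian
P-QRS-T bumps, RR jitter, premature ectopic beats, baseline wander,
noise) with exact ground-truth fiducials, and a labelled cohort
generator whose "case" effect is a tunable reduction of beat-to-beat
fiducial-timing jitter. The whole pipeline is testable end to end
without clinical data.

## Worked example

```r
library(ecgcomplexity)
cfg <- pipeline_config(n_cases = 5, n_controls = 10, effect = -0.015,
                       duration_s = 120, seed = 42)
rep <- run_pipeline(cfg)
head(rank_algorithms(rep$comparisons), 3)
```

```
  estimator scheme mask mean_case mean_control        p auc
1      LZ76     FD   55  -0.01610     0.009519 2.86e-07   1
2      LZ76     FD   58  -0.01097     0.006357 3.56e-07   1
3 Titchener     FD   37  -0.00093     0.000536 5.97e-07   1
```

The top algorithm (LZ'76 on FD mask 55 = Q onset, Q peak, R peak,
T peak, T end) separates the simulated cases (mean corrected complexity
−0.016 bit/sample) from controls (+0.010 bit/sample) with p ≈ 3·10⁻⁷
and AUC 1.0 — cases score lower, as the method presumes. Thresholding
the per-subject scores midway between the group means and passing the
confusion counts to `diagnostic_metrics()` prints:

```
Diagnostic performance (95% Wald CI):
  sensitivity 100.0% (100.0-100.0%)
  specificity 100.0% (100.0-100.0%)
  ...
```

(This simulated cohort is perfectly separable; real cohorts are not.)

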