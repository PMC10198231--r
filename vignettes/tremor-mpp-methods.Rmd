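---
title: "Quantifying harmaline tremor suppression with tremorMPP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying harmaline tremor suppression with tremorMPP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorMPP)
```

## The measurement problem

Systemic harmaline induces a 9–16 Hz action tremor in mice, a widely used
pharmacological model of essential tremor. On a load-sensor platform the
tremor appears as a motion-power peak in that band, superimposed on broadband
locomotion. Because absolute motion power confounds tremor with overall
activity, the tremor statistic is a band-power *ratio*, the **motion power
percentage**:

$$\mathrm{MPP} = 100 \times
\frac{\int_{9}^{16} S(f)\,df}{\int_{0.25}^{32} S(f)\,df},$$

where $S(f)$ is the one-sided power spectral density of a 15-minute epoch
sampled at 128 Hz. MPP is invariant to amplitude scaling and bounded in
$[0, 100]$ because the numerator band nests inside the denominator band.

A session records seven epochs per animal: baseline (B), two post-harmaline
pre-treatment epochs (H1, H2), then four post-treatment epochs (E1–E4) after
injection of drug or vehicle. Drug effects are tested per genotype as
dose-versus-vehicle contrasts at each post-treatment epoch under a
repeated-measures mixed ANOVA, with knockout (KO) littermates lacking the
targeted receptor subunit serving as a built-in null: they tremble normally
but do not respond to the drug.

## Spectral estimation

The acquisition software's FFT settings are not part of the public record, so
the estimator is a design choice:

* **Welch averaging** with 8-s (1024-sample) Hann windows at 50% overlap and
  per-window mean removal. The 0.125 Hz resolution resolves the 0.25 Hz lower
  band edge with a factor-of-two margin, and a 15-minute epoch yields ~220
  averaged segments, giving a per-epoch MPP standard error well under one
  percentage point.
* **Band-edge rule**: a bin belongs to a band when its centre frequency lies
  in the closed interval. Both edges of the nested band count toward both
  bands, which keeps MPP ≤ 100 and makes disjoint bin-aligned sub-bands
  exactly additive.
* **Scaling** satisfies Parseval: the PSD integrates to the signal variance
  (within ~2% Hann/mean-removal bias), which the tests check against white
  noise and sinusoid oracles, and the Welch MPP is cross-checked against an
  independent full-length periodogram (agreement within 1.5 points on
  15-minute synthetic epochs).
* **Degenerate input**: an all-zero epoch has an undefined ratio; the package
  raises an error rather than returning 0, since silent zeros would bias
  group means.
* One MPP is computed per full epoch (a single PSD over the epoch), not by
  averaging sub-epoch MPPs; whether the original analysis subdivided epochs
  is unknown, and this is the reading consistent with "motion power assessed
  during a 15-minute epoch".

## The synthetic cohort generator

No raw traces are publicly deposited, so the package ships a generator whose
defaults *are* the stated world implied by the published design and summary
numbers. It is first-class, tested code — the distributional assumptions the
inference relies on are exactly the ones it implements.

### Background and tremor spectra

Baseline motion is stationary Gaussian noise with a two-component spectrum: a
flat component spanning 0.25–32 Hz plus a band-limited 9–16 Hz component. A
purely flat spectrum would put the chance fraction
$(16-9)/(32-0.25) \approx 0.2205$ of its power in the tremor band, whereas
baseline MPP is reported at 30–35%; the mixing weight is solved so the
expected in-band fraction equals `in_band_fraction` (default **0.32**, the
midpoint of that range). This is the minimal model matching the only printed
baseline constraint.

Tremor is band-limited Gaussian noise (default support 9.5–14.5 Hz, centre
12 Hz — the true centre frequency within 9–16 Hz is not printed, so 12 Hz is
a choice, not a datum) with variance `variance_ratio` × background variance.
The closed-form expectation
$E[\mathrm{MPP}] \approx 100\,(fB + T)/(B + T)$ with $f = 0.32$ inverted at
the 79% midpoint of the reported 75–83% harmaline range gives the default
**`variance_ratio = 2.24`**. Gaussian band noise rather than a sinusoid
reflects the cycle-to-cycle frequency variability of harmaline tremor; the
published record defines it only by its bandwidth.

Both components are synthesised in the frequency domain (complex Gaussian
coefficients on in-band FFT bins), so realised tremor power is confined to
its band by construction and calibrations are exact in expectation.

### Between-animal heterogeneity

With every animal an identical copy of the model, the only MPP variation
would be Welch estimation noise (~0.4 points at 900 s), and any microscopic
dose effect would reach significance — contradicting the published nulls.
Real cohorts vary. The defaults are derived once, a priori, from the printed
ranges read as spreads of group means over groups of $n \approx 11$:

* harmaline MPP 75–83% across eight groups → group-mean SD ≈ 2 points →
  per-animal SD ≈ $2\sqrt{11.5} \approx 7$ points → by the delta method on
  $\mathrm{MPP}(R) = 100(f+R)/(1+R)$, a lognormal SD of **0.5** on the tremor
  variance ratio (median preserved at 2.24);
* baseline MPP 30–35% → logit-normal SD **0.25** on the in-band fraction
  (per-animal baseline SD ≈ 5 points);
* a within-animal, between-epoch lognormal jitter of **0.15** on tremor
  variance, so repeated epochs of one animal correlate strongly (≈ 0.9) but
  not perfectly — the compound-symmetry structure the mixed model assumes.

The animal draw happens once per session from the per-animal seed; the logit
draw is truncated just above the chance fraction so the mixture weight stays
valid (affects ~2% of animals in the tail).

### Pharmacodynamics

Dose maps to fractional suppression of tremor variance through an Emax/Hill
curve gated by epoch and genotype: zero before treatment, zero outside the
drug's active epochs (alcohol: E1 only, reflecting rapid clearance;
ganaxolone: E1–E4), zero in KO animals. Published results give per-epoch
significance patterns, not dose–response parameters, so the defaults are
chosen to reproduce the qualitative pattern:

| drug | emax | ed50 | hill | active |
|---|---|---|---|---|
| alcohol | 0.8 | 0.46 g/kg | 12 | E1 |
| ganaxolone | 0.8 | 5 mg/kg | 8 | E1–E4 |

The alcohol Hill coefficient deserves a note. With hill = 8 the lowest tested
dose (0.40 g/kg) receives suppression 0.197 — a ~3.4-point true MPP effect
that, against the ~7-point between-animal SD above, would be detected in
roughly a quarter of $n = 12$ experiments, too often for the reported clean
null at that dose. A closed-form power calculation (done before any
acceptance run) led to **hill = 12**, which puts 0.40 g/kg at suppression
0.126 (≈ 2-point effect, detected ~10% of the time) while leaving 0.50 and
0.575 g/kg strongly active (suppression 0.59 and 0.75). The steepness is
itself plausible for a threshold-like behavioural response over a 1.4-fold
dose range. All parameters are user-configurable.

### Scheduling, seeding, hardware

Default schedule: seven 900-s epochs with 300-s rests and a 600-s
injection-to-E1 gap (gaps are bookkeeping only; nothing is simulated in
them). Per-animal seeds derive from the master seed and a position counter,
so regeneration is bit-identical and one group's traces do not depend on
another group's size. The acquisition amplifier's 1–70 Hz passband can be
emulated with a 2nd-order Butterworth filter but is **off by default**: the
analysis band extends below the 1 Hz hardware high-pass, how much real power
lay below 1 Hz is unknowable from the published record, and the clean
generative path keeps calibrations exact. (At 128 Hz sampling only the
high-pass edge is realisable; 70 Hz exceeds Nyquist.)

## Inference

`fit_rm_anova()` fits, per genotype,

$$y_{ijk} = \mu + \alpha_j + \beta_k + (\alpha\beta)_{jk} + a_i +
\varepsilon_{ijk},$$

with dose $j$, epoch $k$, and a random intercept $a_i$ per animal — the
compound-symmetry covariance that "repeated-measures mixed ANOVA" most
commonly denotes, and the minimal structure supporting pooled SEs — fitted by
REML (`lme4`). Factors use sum-to-zero coding so the Wald F for each term is
the marginal (type III) test; on the balanced designs used here these
coincide with classical ANOVA F ratios. Model-based cell means and pooled
SEs come from the fixed-effect estimates and their covariance; in balanced
data they equal raw cell means, but the model-based route also covers the
unequal group sizes of the published cohorts.

**Fisher LSD, protected.** Dose-versus-vehicle contrasts at each
post-treatment epoch are t-type tests on model-based means with the model's
pooled SE and split-plot ("between-within") degrees of freedom: dose
contrasts compare disjoint groups of animals, so they take the
between-subject error df ($N_{\text{animals}} - n_{\text{doses}}$), while
within-animal terms (epoch, dose × epoch) keep the residual df — the
partitioning classical split-plot ANOVA and mixed-model software defaults
use. Unprotected LSD over
four dose groups cannot bound the familywise error, so a contrast is
*flagged* only at the end of the classical omnibus → simple-effects →
pairwise chain: (1) the omnibus dose × epoch interaction F, (2) the
dose-within-epoch simple-effect F at the compared epoch (the joint test of
all dose contrasts there), and (3) the pairwise p must all clear
$\alpha = 0.05$. The interaction — not the dose main effect — is the first
gate because any real treatment pattern here is an interaction by design
(dose effects are impossible pre-injection) and because the between-animal
main-effect F runs liberal under the df convention below. The within-epoch
layer matters for a subtler reason: per-animal baseline in-band fraction
shifts baseline MPP strongly but tremor-epoch MPP hardly at all, an
animal × epoch component that compound symmetry does not absorb and that
inflates the global interaction F under the null; the simple-effect F is
built only from the compared epoch's cells and is free of it. Real effects
open both gates trivially, so the chain costs essentially no power.
Single-epoch fits, which have no interaction, gate on the dose F.
Unprotected p-values are always reported alongside the flag. No further multiplicity adjustment
is applied, matching the original analysis.

Two caveats are deliberate and documented rather than hidden:

* An earlier draft used the residual df for *all* contrasts (one common
  reading of "pooled"); simulation against the trace-level null generator
  showed that convention runs measurably liberal for the between-animal
  dose contrasts (≈ 0.07 per comparison instead of 0.05, worse at small
  $n$), which motivated the between-within partitioning above. Even so, the
  lognormal animal heterogeneity leaves mild residual inflation
  (≈ 0.06); the protected flag stays below 0.05. The acceptance suite
  measures both rates against the trace-level null generator.
* Baseline epochs B, H1, H2 enter the model as levels of the repeated factor
  (they stabilise the variance-component estimates); dose comparisons are
  only reported for E1–E4, where effects are possible by design.

Residual normality — the parametric assumption — is checked with a
Shapiro–Wilk test and normal-quantile coordinates (`check_residual_normality()`).
With a single epoch the random intercept is unidentifiable and the fitter
falls back to ordinary least squares, which makes the two-group LSD exactly
the pooled-variance t-test (a tested identity).

**Parameter recovery** is defined on the tremor-band-*power* scale: with
band-power cell means, $(\text{vehicle} - \text{dose})/(\text{vehicle} -
\text{baseline})$ estimates the generator's fractional suppression with
slope 1, because band power is linear in tremor variance. The same quotient
on the MPP scale does *not* have slope 1 — MPP is a saturating ratio — which
is why the recovery test feeds `fit_rm_anova()` the `tremor_band_power`
column rather than `mpp`.

## What a green test establishes — and what it does not

The generator emulates the *statistical skeleton* the analysis assumes:
stationary Gaussian epochs, a band-confined tremor, lognormal animal
heterogeneity, compound-symmetric repeats, Hill-type dose response with
all-or-none genotype gating. It does not emulate nonstationary locomotion
bouts, 1/f-like background slopes, movement artifacts, habituation drift
across epochs, or tremor frequency migration. Green acceptance tests
therefore establish that the pipeline measures and infers correctly in a
world with the published summary statistics — not that the biological claims
are reproduced from raw data, which are not public.

Scaled-down simulations are used where the tested property is invariant to
the scaled dimension: epoch duration for inference-level error rates
(between-animal SD ~7 points dwarfs Welch noise at any duration used), never
group size for type-I error (the residual-df caveat above makes the error
rate n-dependent).

## Numerical and reporting conventions

* Significance stars: \*, \*\*, \*\*\* at p < 0.05, 0.01, 0.001, attached
  only to protected-significant rows. (Published figure legends print these
  thresholds with inverted inequality signs, "P > 0.05" — read here as a
  typographical slip for "<".)
* Config files serialise to JSON and round-trip identically; reports carry a
  provenance block (config hash, master seed, versions).
* A minimum trace duration of 60 s (configurable) guards MPP against
  unstable short-window spectra; traces shorter than one Welch window are a
  hard error.
* Child seeds are kept below $2^{31}$; all randomness descends from one
  master seed.

## Known limitations

* Absolute p-value agreement with the original analysis is out of reach by
  construction (real data and the original covariance software settings are
  unpublished); only the qualitative significance pattern is testable.
* The within-animal covariance is exchangeable; AR(1) or unstructured
  alternatives are not implemented beyond the module boundary that would
  accept them.
* The generator's heterogeneity calibration leans on reading printed ranges
  as group-mean spreads; if they were per-animal ranges, between-animal SDs
  would be ~3× smaller and every power statement sharper.
* On simulated cohorts the Shapiro–Wilk diagnostic frequently *rejects*
  (lognormal animal effects on a saturating percentage scale are mildly
  skewed, and n ≈ 300 residuals give the test power to notice). The
  diagnostic is reported, never used as a gate; the error-rate tests show
  the resulting inference still holds its level at these sample sizes.
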