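---
title: "Quantifying nonlinear dendritic integration with dendsum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nonlinear dendritic integration with dendsum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendsum)
```

## The scientific problem

When several glutamatergic inputs arrive near-synchronously on a short
stretch of dendrite, the somatic depolarization they produce can exceed the
arithmetic sum of the responses to the same inputs delivered one at a time.
This *supralinear integration* is a signature of regenerative dendritic
conductances (NMDA receptors above all) and can be probed directly with
two-photon glutamate uncaging: a dozen spots along a dendrite are stimulated
either *asynchronously* (one 0.5 ms light pulse per location, separated by
100.32 ms gaps, so each unitary uEPSP is recorded in isolation) or
*near-synchronously* (0.32 ms gaps, i.e. 0.82 ms onset-to-onset), with the
number of co-active locations increased cumulatively from 1 to 12 across
sweeps.  Dendritic calcium is monitored in parallel with a two-channel
linescan: a calcium-sensitive green indicator (Fluo-4) and a
calcium-insensitive red reference (Alexa-594).

`dendsum` implements the full quantification chain for such experiments —
from raw voltage sweeps and linescans to per-dendrite nonlinearity indices
and estimation-statistics summaries — together with a synthetic experiment
generator with known ground truth, so that every stage of the pipeline is
testable without access to recorded data.

## The nonlinearity index

For each number of co-active locations $i$, let $M_i$ be the measured
near-synchronous response and $A_i$ the *arithmetic sum*: the expected
linear response, constructed by staggering the $i$ isolated unitary
responses by 0.82 ms (matching the near-synchronous onset spacing) and
summing them.  The per-dendrite index is

$$\%\mathrm{NL} \;=\; \frac{\sum_{i=2}^{n}\left(\dfrac{M_i}{A_i}-1\right)}{n-1}\times 100\%,$$

the mean relative deviation of the observed response from its linear
expectation, in percent.  Positive values are supralinear, negative
sublinear.  The index is computed twice per dendrite: for the peak
amplitude (mV) and for the time integral of the depolarization over 100 ms
(mV·ms), which is more sensitive to plateau-like prolongations.  The $i=1$
term is identically zero and never contributes.  Should an expectation term
be numerically degenerate ($|A_i| \le 10^{-9}$) it is excluded and the
divisor reduced — a guard for synthetic edge cases rather than a situation
arising in practice.

Two properties worth knowing: the index is invariant under a common
rescaling of $M$ and $A$ (so the min–max scaled series exported for
plotting never affect it), and it is *index-paired* — permuting $M$ against
$A$ changes the value.

### Calcium

The calcium channel is quantified as $\Delta F/A$: the peak change of the
(smoothed, artifact-cleaned) green fluorescence from its pre-stimulus
baseline, normalized by the mean red fluorescence.  Because calcium does
not relax to baseline within the 100 ms asynchronous gaps, no arithmetic
sum can be built for it.  The linear expectation is instead interpolated
between the single-location near-synchronous transient and the transient
measured at the end of the asynchronous record (which encompasses all 12
uncaging events):

$$\mathrm{expected}_i = \Delta F/A_{(1)} + \frac{i-1}{n-1}\,
\bigl(\Delta F/A_{\mathrm{async},n} - \Delta F/A_{(1)}\bigr).$$

The same \%NL formula is then applied with $A_i :=$ expected$_i$.

## The synthetic generator

`generate_experiment()` emits complete experiments — cycles of asynchronous
and near-synchronous sweeps, with matching linescans — plus a noiseless
twin from which ground-truth nonlinearity is computed *through the same
measurement code path*.

**Voltage model.** Unitary uEPSPs are difference-of-exponentials kernels
(default rise 1 ms, decay 20 ms), normalized to per-location peak
amplitudes (defaults between 0.6 and 1.5 mV — typical somatic unitary
uEPSP sizes for this preparation; the values are parameters and can be
set freely).  The linear drive for $k$ locations is the staggered sum
$L_k(t)=\sum_{j\le k} u_j(t-(j-1)\cdot 0.82\,\mathrm{ms})$, and the
observed depolarization is

$$V = S\!\left(L + G\,L\,\sigma\!\left(\frac{L-\theta}{\kappa}\right)\right),
\qquad S(x)=v_{\mathrm{sat}}\left(1-e^{-x/v_{\mathrm{sat}}}\right),$$

a sigmoid boost (gain $G$, half-activation $\theta$, slope $\kappa$; a
stand-in for voltage-dependent NMDA-receptor recruitment) composed with an
exponential saturation (a stand-in for the collapse of driving force near
the synaptic reversal potential).  With $G=0$ and $v_{\mathrm{sat}}=\infty$
the transfer is the identity and summation is exactly linear; $G=0$ with a
finite ceiling gives the passive, sublinear regime; large $G$ with a finite
ceiling gives sigmoid observed-vs-expected curves that plateau.  Defaults
($G=2$, $\theta=4$ mV, $\kappa=1.5$ mV, $v_{\mathrm{sat}}=40$ mV) place the
amplitude nonlinearity near +60%, the magnitude scale reported for
dendrite-targeting interneurons.  Gaussian recording noise (default SD
0.1 mV per sample at 20 kHz) and a resting potential of −65 mV are added
last; optionally a stereotyped action-potential contamination (60 mV,
2 ms triangular spike with a 0.5 ms upstroke) is injected with a configurable
per-sweep probability, to exercise the exclusion rule.

Because the transfer is instantaneous, the synthetic integral nonlinearity
is somewhat *smaller* than the amplitude nonlinearity.  Real regenerative
events outlast their drive (plateau potentials), which makes the recorded
integral nonlinearity the larger of the two; reproducing that would require
a kinetic (state-dependent) boost, which is outside the generator's scope.
Tests that pass on synthetic data therefore validate the measurement
pipeline, not the biophysics of plateaus.

**Calcium model.**  A single pool obeys
$\dot c = -c/\tau_{\mathrm{ca}} + \alpha\,\max(V-V_{\mathrm{th}},0)\cdot g(c)$
with $g(c)=\text{store\_gain}$ once $c$ exceeds a store threshold
(calcium-induced calcium release) and 1 otherwise.  Green fluorescence is
$F_g = F_{g,0}(1+k_f\,c)$ plus noise; red is a flat reference.  Uncaging
light artifacts are added to both channels at pulse times and recorded in a
mask.  The defaults place the store threshold (3.5 pool units) between the
noiseless pool peaks attained with 5 and with 6 co-active locations (3.35
and 4.47), so the measured $\Delta F/A$-versus-$k$ curve jumps abruptly
between 5 and 6 locations — the discontinuity position reported for
neurogliaform cells.  The calcium scale is qualitative: the model
reproduces the threshold structure and store amplification, but not the
quantitative $\Delta F/A$ magnitudes of a real indicator (no indicator
saturation, no buffering), so synthetic calcium nonlinearity percentages
are much larger than recorded ones.

## Numerical conventions

A few deliberate choices keep the generator and the measurement pipeline
*numerically consistent*, so that a noiseless linear experiment yields
exactly 0% nonlinearity rather than an interpolation-artifact residue:

* **Timing.**  The stated inter-pulse intervals are treated as gaps, so
  onset-to-onset spacing is 100.82 ms (asynchronous) and 0.82 ms
  (near-synchronous); the 0.82 ms arithmetic-sum stagger equals pulse
  duration (0.5 ms) + gap (0.32 ms).  This is the single timing convention
  used everywhere.
* **Fractional delays.**  0.82 ms is 16.4 samples at 20 kHz.  Both the
  generator (when placing near-synchronous events) and `arithmetic_sum()`
  use the same linear-interpolation shift operator, so the constructed
  arithmetic sum reproduces the noiseless near-synchronous drive exactly.
* **Asynchronous onsets** are snapped to the sample grid, and unitary
  kernels are supported on one asynchronous inter-onset period minus a 5 ms
  guard.  Unitary extraction therefore slices exact segments, and each
  segment is preceded by a true-zero baseline.  The truncation discards
  under 1% of the kernel tail (at the default 20 ms decay).  On real data,
  where tails are not truncated, the per-segment re-baselining treats the
  residual decay of the previous event (≈0.7% of its peak at 100.82 ms
  spacing) as baseline.
* **Filter placement.**  Savitzky–Golay smoothing (default window 2.05 ms
  — 41 samples at 20 kHz — order 3, preserving millisecond-scale rise
  times) is applied *identically to the measured near-synchronous trace and
  to the constructed arithmetic sum*, after summation.  Filtering each raw
  sweep first is available (`filter_sweeps = TRUE`) but is not the default:
  the smoothing window is wider than the 0.5 ms margin between the 100 ms
  measurement horizon and the 100.82 ms inter-onset spacing, so per-sweep
  filtering lets each unitary's filtered tail absorb a little of the next
  event's rise, biasing the arithmetic sum where the observed trace has no
  counterpart.  Applying one common filter to both measured traces removes
  this asymmetry (and makes the filter choice irrelevant in the noiseless
  limit).
* **Measurement windows.**  Peak search and integration both run from the
  first onset over 100 ms (the peak window covers plateau responses);
  integration is trapezoidal on the native grid.
* **Degenerate inputs.**  Constant min–max references raise an error;
  near-zero arithmetic-sum terms are excluded as described above;
  action-potential detection uses inclusive (≥) comparisons at −20 mV and
  80 mV/ms (the simulated regenerative rise stays below ~30 mV/ms while the
  spike upstroke is 120 mV/ms; both thresholds are configurable).
* **Scaling is display-only.**  Min–max scaling normalizes the asynchronous
  (arithmetic-sum) series to [0, 1] and applies the same extrema to the
  near-synchronous series, for cross-dendrite visual comparison.  The
  nonlinearity index is always computed from unscaled measures.

## Estimation statistics

Per-dendrite nonlinearity values (the dendrite is the experimental unit)
are summarized with estimation statistics rather than bare significance
tests:

* **Mean difference with a BCa 95% confidence interval** —
  bias-corrected-and-accelerated bootstrap with 5000 resamples by default;
  $z_0$ from the fraction of bootstrap means below the point estimate,
  acceleration from the jackknife skewness, interpolated (type-7) quantiles
  at the adjusted levels.  Degenerate all-equal samples return a
  zero-width interval.  For unpaired two-group contrasts the same
  construction uses stratified resampling and the combined leave-one-out
  jackknife.
* **Two-sided permutation t-tests.**  One-group ("compared to 0%") and
  paired designs sign-flip the differences; unpaired designs permute group
  labels with the Welch statistic (the t-statistic variant is not uniquely
  determined by convention; Welch is the safer default under unequal
  variances).  Enumeration is exhaustive up to $2^{20}$ permutations,
  otherwise 10 000 Monte-Carlo draws with the observed arrangement included
  in numerator and denominator (so $p > 0$).  Zero-variance data are
  reported as $p = 1$.
* **Designs.**  "Nonlinearity vs 0" is a one-group sign-flip test
  (equivalent to pairing against an identically-zero condition);
  drug wash-in designs pair two condition labels through a shared dendrite
  id.  No hierarchical nesting by cell or animal is attempted — a known
  limitation of treating dendrites as independent units.

The test suite checks the size of the permutation test (type-I error at
$\alpha=0.05$ over 1000 null simulations) and the BCa coverage (500
simulations, $m=10$, 2000 resamples), and cross-checks the BCa endpoints
against an independent transcription of the formulas on shared bootstrap
replicates and against `boot::boot.ci`.

## Problem sizes used for validation

The packaged tests and the acceptance script run entirely on synthetic
data at the native experimental protocol (12 locations, 20 kHz, 3
stimulation cycles): a supralinear cohort of 11 dendrites (7 with
linescans, sample sizes typical of such experiments), a 5-dendrite linear
control cohort, a
5-regime sub-to-supralinear recovery sweep, and the store-threshold
calcium simulation.  These sizes keep a full run in the tens of seconds
while leaving Monte-Carlo margins (recovery errors ≈0.3–1.3 percentage
points against ground truth at 0.1 mV noise) far inside the tolerances
asserted.

## Known limitations

* The transfer function is memoryless; plateau-potential *kinetics* (and
  hence integral nonlinearity exceeding amplitude nonlinearity) are not
  reproduced.
* Recording noise is white Gaussian; real recordings carry 1/f and line
  components that would inflate small-sample variability slightly.
* Calcium magnitudes are qualitative (no indicator saturation or
  buffering); the calcium pipeline is validated on threshold structure,
  interpolation identities and sign, not on absolute percentages.
* The deposited-archive adapter is a boundary only: `read_experiment()`
  documents the directory-of-CSV layout this package writes, and external
  datasets must be mapped into `voltage_sweep`/`linescan` records by a
  source-specific adapter.
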