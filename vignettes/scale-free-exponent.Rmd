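---
title: "Estimating the scale-free spectral exponent: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the scale-free spectral exponent: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specslope)
```

## The model

The aperiodic background of neural field potentials follows, over
restricted frequency ranges, a power law

$$\mathrm{PSD}(f) \;\propto\; \frac{1}{f^{\beta}},$$

a straight line of slope $-\beta$ on log-log axes. `specslope`
estimates $\beta$ separately in two bands where resting intracranial
recordings show clean power-law behaviour: a **low band** (0.5–4 Hz)
and a **high band** (33–80 Hz). The band between them is dominated by
oscillatory peaks (alpha, 8–12 Hz, and neighbours) that are *not* part
of the power law and drag any naive slope fit; the pipeline's central
assumption is therefore that the aperiodic component is well separated
from oscillations once each band is isolated by filtering.

The estimation chain for one channel is

1. zero-phase Butterworth filtering (low-pass 8 Hz for the low band,
   high-pass 33 Hz for the high band; order 7),
2. Welch PSD (Hamming window, `nperseg = nfft = 2048`, 50 % overlap,
   per-segment mean removal),
3. restriction to the band's bins (closed interval on the discrete
   grid, never the DC bin) and division by the applied filter's exact
   power response,
4. least squares on $\log_{10} \mathrm{PSD}$ vs $\log_{10} f$ — unit
   weights for a single channel, inverse-variance weights
   $w_i = 1/\Delta y_i^2$ for a region-average spectrum with
   cross-channel dispersion.

`specslope()` returns $\beta$ with its standard error, intercept,
and $R^2$; `delta_beta()` rescales a set of region exponents to
$\Delta\beta_i = (\beta_i - \beta_{\min})/(\beta_{\max} - \beta_{\min})
\in [0, 1]$ for mapping.

## Parameters that matter

| parameter | default | units | why this value |
|---|---|---|---|
| low band | 0.5–4 | Hz | below delta/theta oscillatory territory; lower edge above the 0.5 Hz high-pass character of typical acquisition |
| high band | 33–80 | Hz | above beta-band peaks; upper edge safely below the 100 Hz Nyquist of 200 Hz recordings |
| low-pass cutoff | 8 | Hz | keeps the full low band in the passband while the alpha peak (8–12 Hz) sits at or beyond −3 dB and falls fast at order 7 |
| high-pass cutoff | 33 | Hz | places the high band in the passband; everything below (including alpha) is crushed |
| filter order | 7 | — | ≈ 42 dB/octave per pass; sharp enough to separate bands only a fraction of an octave from the cutoff |
| `zero_phase` | `TRUE` | — | offline analysis; no phase distortion, squared magnitude response |
| `nperseg = nfft` | 2048 | samples | 10.24 s segments at 200 Hz: resolution 0.098 Hz gives 35 bins in the low band; 10 averaged segments per 60 s channel |
| `overlap` | 0.5 | — | the conventional Welch compromise between variance reduction and segment correlation |
| `detrend` | `"constant"` | — | per-segment mean removal protects the bins adjacent to 0.5 Hz from DC leakage |

The robustness of $\beta$ to these choices is itself part of the
analysis: `robustness_sweep()` re-estimates every region under
cutoffs {4, 8} Hz (low-pass) / {33, 50} Hz (high-pass), orders {5, 7}
and FFT lengths {256, 1024, 2048} — 12 configurations per band — and
reports the maximum pairwise shift per region plus a one-way ANOVA
treating configuration as the factor. On simulated β = 2 cohorts the
shifts stay below 0.2 and the homogeneity test is non-significant
(this is asserted in the test suite). When a high-pass cutoff lies
above the band's lower edge the fitted band starts at the cutoff
(fitting inside a stopband would be meaningless); the symmetric rule
truncates the low band at a low-pass cutoff below its upper edge.

## Why the fitted PSD is compensated for the filter response

A Butterworth filter is only −3 dB *at* its cutoff, and the analysis
bands touch their cutoffs (33 Hz high-pass, 33–80 Hz band). Zero-phase
application squares the magnitude response, so the first bins of the
high band are attenuated by up to 6 dB — enough to tilt an in-band fit
by several tenths. Because the applied response is known exactly (the
digital design's $|H(e^{-i\omega})|^2$ per pass, see `butter_gain()`),
`specslope()` divides it out of the band's PSD before fitting
(`compensate = TRUE`). With compensation, band-matched fits recover
generating exponents across 0–2.5 to within 0.1 and the parameter
sweep above becomes flat; without it, estimates near the cutoff are
biased and different sweep configurations disagree strongly. The
uncompensated path remains available for comparison.

Filtering earns its keep a second way: for steep spectra the dominant
low-frequency power leaks through the spectral window's sidelobes into
the high band and flattens naive estimates. High-pass filtering
removes that leakage source in the time domain *before* the Welch
step, which is what makes high-band fits of steep exponents unbiased.

## What the simulators generate, and what they do not

**Colored noise by spectral synthesis.** `noise_powerlaw()` shapes the
one-sided amplitude spectrum of unit white noise as $f^{-\beta/2}$
with i.i.d. uniform phases and inverse-transforms; the DC term is
zero and the output is rescaled to the requested SD. The expected
spectrum is exact by construction, which keeps recovery oracles
trivial. Fractional-integration generators were deliberately not used.
A two-exponent variant (`beta_high`, break at
$\sqrt{4 \times 33} \approx 11.5$ Hz, the geometric midpoint of the
two bands, amplitude-continuous at the break) produces channels whose
low- and high-band exponents differ — the structure the
region-discrimination analysis is about.

**Oscillatory peaks.** `add_peak()` adds a component whose PSD is an
exact Gaussian bump (FWHM `bandwidth`) scaled to `amplitude` times the
channel's background PSD at the centre frequency, synthesized with
random phases. A Gaussian bump has negligible tails, so the background
outside the peak's neighbourhood is conserved (asserted to < 5 %
band-mean change, in practice ~10⁻⁵). An earlier amplitude-modulated
sinusoid design was rejected: its rectangular-envelope sinc sidelobes
leaked measurably into the 0.5–4 Hz band.

**Cohorts.** `simulate_cohort()` draws subject-level exponents
$\beta_s = \beta_{\text{region}} + N(0, \sigma_b^2)$ and channel-level
$\beta_c = \beta_s + N(0, \sigma_w^2)$, independently per band;
defaults $\sigma_b = 0.3 > \sigma_w = 0.1$ encode the empirical
hierarchy that subjects differ more than channels within a subject.
Negative draws are clipped at 0 with a warning. Channels are
independent given the subject — no spatial correlation model is
imposed. Recordings default to 60 s at 200 Hz (12 000 samples), the
format of open intracranial atlases. Sub-seeds derive
deterministically from the master seed and the (region, subject,
channel) indices, so cohorts are bit-reproducible.

What the simulations do **not** emulate: nonstationarity, non-Gaussian
increments, spatially correlated channels, knee/bend spectra,
multifractality, line noise, artifacts. Passing tests therefore
demonstrate correctness of the estimation machinery under the stated
model, not robustness to everything real recordings contain.

## Reference signals and the Brownian 1.8

White noise ($\beta = 0$) and Brownian noise (integrated white noise,
theoretical $1/f^2$) are the two analytic anchors. A subtlety worth
recording: a *discrete* random walk's true spectrum is
$\propto 1/(4\sin^2(\omega/2))$, which equals $1/\omega^2$ only at low
frequency and flattens toward Nyquist. A full-range Welch log-log fit
of simulated Brownian noise therefore lands just above 1.8, not at
2.0 — reproducibly so (`scripts/acceptance.R` prints it), and the
same mechanism is why cross-checking `noise_powerlaw(beta = 2)`
against `noise_brownian()` is done in the low band, where the two
spectra agree.

## Weighted fitting and aggregation choices

* **Log base.** All fits use $\log_{10}$; $\beta$ is base-invariant
  (asserted), the intercept is reported in $\log_{10}$ units.
* **Weights.** For region fits the per-bin uncertainty is the pooled
  cross-channel, cross-subject SD of the *linear* PSD, propagated to
  log space to first order: $\Delta y_i = \sigma_i/(\mathrm{PSD}_i
  \ln 10)$. Pooling over all channels of all subjects (not
  within-subject first) is the conservative choice: between-subject
  variability dominates, and the pooled SD is the larger uncertainty.
  An unweighted option exists (`weighting = "none"`), and a
  single-channel region falls back to it with a warning rather than
  dividing by zero.
* **Standard errors** come from the weighted normal equations scaled
  by the residual variance (the `lm` convention): they are fitting
  errors, exactly 0 for collinear input.
* **Signed storage.** $\beta$ is stored signed (positive for decaying
  spectra) and printed as $|\beta|$, the field's notation.
* **Boundary bins** are inclusive: a bin at exactly 4.0 Hz would
  belong to the low band. At the default grid (spacing 200/2048 Hz)
  the low band holds bins 6–40, i.e. 35 bins; no bin falls at 4.0
  exactly.
* **Non-positive PSD bins** in a band (conceivable after aggressive
  filtering) raise an error rather than being dropped silently.

One property of the "average the PSDs, then fit" design deserves
emphasis. The arithmetic mean of spectra whose exponents vary is not a
power law with the mean exponent: convexity makes the averaged
spectrum slightly flatter around the frequencies where the channel
spectra cross, and the inverse-variance weights concentrate exactly
there. With realistic between-subject spread ($\sigma_b = 0.3$) the
region-level fit can read ~0.1–0.2 below the mean of per-subject
exponents. This is a property of the estimand (the region-average
spectrum), not an implementation defect; it is shared by any pipeline
that averages before fitting. All discrimination statistics therefore
use **per-subject** fits as the replicate unit, which also avoids
pseudo-replication from correlated channels within a subject.

## Statistics and their calibration

`region_anova()` is a fixed-effects one-way ANOVA of per-subject
exponents by region (regions with a single subject are excluded with a
warning); `tukey_hsd()` performs the studentized-range pairwise
comparisons at $\alpha = 0.05$; `beta_gamma_correlation()` is a
Pearson test between region exponents and unit-total-normalized mean
gamma-band power; `beta_age_regression()` an OLS slope with 95 % CI.

Calibration (type-I error within [0.03, 0.07] at $\alpha = 0.05$,
Tukey family-wise error ≤ 0.07, power ≥ 0.9 for a 0.5 exponent
separation at 20 subjects/region) is verified on cohorts of
subject-level records drawn directly from the two-level Gaussian model
(`simulate_beta_records()`), 500 replicates for the null rates and 200
for power. Drawing records rather than synthesizing 500 × full signal
cohorts is what makes thousands of replicates affordable; the two
routes share the same distributional model, and the signal route's
variance decomposition is checked separately on a full cohort. A
permutation-based ANOVA reference (≥ 95 % decision agreement) guards
the parametric test on small cohorts.

## Problem sizes used in the test suite

Single-channel checks use 12 000-sample signals (the 60 s × 200 Hz
default). Exponent-recovery runs 50 replicates per level over
$\beta \in \{0, 0.5, 1, 1.5, 2, 2.5\}$ in both bands; the sweep runs a
3-region × 4-subject × 2-channel cohort through all 24 configurations;
the end-to-end region-discrimination check uses 5 regions × 6 subjects
× 2 channels with high-band exponents 1.6–3.2 over a constant low-band
exponent. These sizes were chosen as the smallest that leave the
stochastic assertions comfortable margins.

## Known limitations and open choices

* The high band is quoted in the literature both as 33–80 Hz and
  34–80 Hz; the package defaults to 33–80 Hz, matching the 33 Hz
  high-pass cutoff, and both are expressible via `band()`.
* The normalization behind "normalized gamma-band PSD" is not
  standardized; the package uses unit total power over (0, fs/2] per
  recording, with `normalize = "none"` as the alternative.
* Whether single-pass or zero-phase filtering was used by any given
  reference analysis is usually unstated; both are exposed via
  `zero_phase`, and the sweep shows the exponent is insensitive to
  the choice once the response is compensated.
* No knee/bend model: a spectrum with a bend inside a band will be
  fit by a single line, and $R^2$ is the only warning.
* No joint periodic + aperiodic decomposition (FOOOF-style peak
  fitting is deliberately out of scope: oscillations are handled by
  band isolation only).
* EDF support covers continuous 16-bit recordings with uniform
  records — the common case — not EDF+ annotations or discontinuous
  files.
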