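---
title: "Models and methods behind timbrefuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind timbrefuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(timbrefuse)
```

timbrefuse analyses listening experiments on *dyads* — two instrument
tones sounded together in pitch unison or octave — rated on four
perceptual attributes: fusion (the tones heard as one event),
segregation (heard as separate streams), roughness (beating-related
dissonance) and pleasantness. This vignette documents the statistical
models, the synthetic-data generator that stands in for listening-test
data, and the numerical conventions, so that every choice a maintainer
might question is written down in one place.

## The response model and the scaling estimator

The scaling stage assumes the classic Thurstonian category-judgment
process. Stimulus $a_j$ occupies a latent position $f(a_j)$ on the
perceptual continuum; a rating is produced by adding normal
discriminal noise and cutting the result at $m-1$ ordered category
boundaries $t_1 < \dots < t_{m-1}$ ($m = 9$ throughout). Under this
model the probability of a response at or below category $g$ is
$\Phi(t_g - f(a_j))$, so the inverse-normal transform of the observed
cumulative proportion,
$z_{gj} = \Phi^{-1}(P_{gj})$, satisfies the additive layout
$z_{gj} = t_g - f(a_j)$.

`fit_successive_categories()` estimates this layout by column and row
means — for a complete table this *is* the least-squares solution, a
fact the test suite verifies against a brute-force QR solve on small
instances. Only differences are identified, so the scale is anchored
by $\bar f = 0$.

Numerical conventions:

* **Extreme proportions.** $P_{gj} \in \{0, 1\}$ has no finite normal
  deviate. The default clips $P$ into $[1/2N, 1 - 1/2N]$ for $N$
  raters, preserving the complete layout; `clip = "drop"` instead
  removes those cells and solves the incomplete layout by least
  squares. The two agree when no clipping occurs (tested).
* **Real-valued ratings.** After mean imputation, ratings need not be
  integers; "response $\le g$" is interpreted as *value* $< g + 0.5$,
  which reduces to the usual counting on integer data.
* **Stimuli with no interior information** (all responses in one
  extreme category) are flagged in the fit rather than silently
  scaled.
* **Category units.** The z-unit scale is mapped to the familiar 1–9
  axis by the least-squares affine map sending the estimated
  boundaries $t_g$ to their nominal positions $g + 0.5$. The map is
  invariant to positive affine changes of the z scale, so any latent
  shift/stretch the clipping induces cancels.

## Rating QC

Cronbach's alpha treats the raters as items and the stimuli as cases,
one alpha per attribute — the convention that makes "32 raters"
the instrument being assessed. Alpha is undefined when the total
score has zero variance; that is signalled, not patched.

The validity filter removes, per stimulus and attribute, ratings
outside mean ± 1.5 SD across raters (sample SD, single pass — bounds
are *not* recomputed iteratively) and imputes the retained-group mean
so downstream proportions stay complete. Imputed values are kept
real-valued by default because they feed cumulative proportions; a
`round_imputed` flag restores integer categories. With SD = 0 nothing
is removed; a cell whose ratings would all be removed raises an
error, since the filter is then meaningless.

## The statistics battery

One-way ANOVA is the standard between/within decomposition
(`stats::lm`). The two-way envelope × culture analysis uses Type III
sums of squares with sum-to-zero contrasts because the default
518-dyad design is unbalanced (class sizes 226/227/65); on balanced
designs Type I/III coincide, which the suite checks. The interaction
is screened at $\alpha = 0.05$ and, when non-significant, the model
is refit with main effects only.

SNK post-hoc grouping implements the stepwise studentized-range
procedure on ordered group means, with the harmonic mean of group
sizes for unequal $n$, built on `stats::qtukey`. Maximal
non-significant stretches of ordered means become the familiar
homogeneous subsets; identical samples can never be split because
their range statistic is zero.

The preference map is a principal-component decomposition of the
column-standardized stimulus × attribute matrix. Attribute loadings
are correlations between attributes and component scores, so they are
bounded by 1; stimulus points and envelope × culture centroids share
the space. This is a numeric approximation to optimal-scaling
categorical PCA: by the time the map is built the inputs are already
interval-scaled psychological values, so the optimal-scaling
transform would be close to affine. Sign indeterminacy is fixed by
orienting dimension 1 so fusion loads positively and dimension 2 so
segregation loads positively; maps are then reproducible run to run.

## Acoustic descriptors

The STFT front end uses a 23.2 ms Hann window with a 5.8 ms hop at
44.1 kHz (the descriptor-toolbox convention), FFT length the next
power of two. Descriptors follow their standard definitions; the
choices that needed fixing are:

* **Spectral flatness** is computed on the power spectrum averaged
  into 32 equal sub-bands (the MPEG-7 audio-spectrum-flatness style)
  rather than on raw periodogram bins. Raw-bin flatness of white
  noise converges to $e^{-\gamma} \approx 0.56$ — an artefact of the
  exponential distribution of periodogram ordinates — while the
  sub-band form approaches 1 for noise and 0 for tones, which is the
  behaviour a tonality measure should have.
* **Roll-off** is the smallest frequency containing 95% of frame
  energy; it is nondecreasing in the threshold (tested), but no
  ordering against the centroid is assumed.
* **Harmonic vs noise energy.** Dyads have two fundamentals, so a
  single-f0 harmonic sieve is ill-posed; partials are instead strict
  per-frame spectral peaks above 8× the median bin power, each owning
  a ±2-bin neighbourhood (the Hann main lobe). The mean power of the
  non-peak bins estimates the noise floor, which is subtracted inside
  the neighbourhoods — without this, broadband noise sitting under
  the partials biases noisiness low by roughly the covered bin
  fraction. On synthesized dyads the measured noisiness tracks the
  generator's noise fraction to well within ±0.05 across the 0–0.5
  range.
* **Tristimulus** contributes its first component to the 45-feature
  set (one slot per parameter keeps 27 parameters → 45 statistics);
  all three components are exported per frame.
* **Temporal thresholds.** Attack is 10% → 90% of the envelope peak
  (so a linear ramp of length $L$ measures $0.8L$); effective
  duration uses a 40% threshold; release is the last 90% crossing to
  the last 10% crossing. The envelope is the frame RMS over 20 ms
  windows at a 5 ms hop. Amplitude modulation is the relative
  envelope fluctuation in the 4–8 Hz band (FFT band selection);
  frequency modulation is the relative spread of the per-frame
  dominant-frequency track over energetic frames. Temporal centroid
  and zero-crossing rate are also computed per frame so they can
  carry the mean + IQR statistics of the frame-varying family.
* **IQR** uses linear-interpolation (type 7) quartiles; the IQR of
  $1..100$ is exactly 49.5, which the tests pin.
* **Degenerate frames.** Zero-energy frames yield NA descriptors and
  are excluded from summaries with an exclusion count; a frame with
  no detected partials reports zero harmonic energy, noisiness 1, and
  undefined partial ratios.

The screening operation reproduces the 216-statistic battery (8
statistics × 27 parameters), ranks every candidate by $|r|$ against
the fusion target, and applies the rule: keep the mean and IQR
families (54), then drop the IQR of the nine per-note parameters
(attack-family, modulation) whose frame statistics are not
meaningful for melody-length stimuli, leaving 45.

## Fusion models

Features are z-standardized inside `fit_model()` so linear
coefficients share a scale — the $|c| > 4$ equation-extraction rule
is meaningless otherwise. The lasso penalty is chosen by inner
cross-validation on the training folds (no value is prescribed by the
study design); a fixed `lambda` can be supplied. The random forest
uses 10 trees with at most 6 candidate features per split; the MLP is
one hidden layer of 32 rectified-linear units trained by plain
stochastic gradient descent at learning rate 0.001, implemented
directly so the optimizer and seeding are exact. Model quality is the
4-fold cross-validated $R^2 = 1 - SSE/SST$; out of sample this can be
negative, and the identity $R^2 = SSR/SST$ holds only for in-sample
least squares. Whether the reported equation should come from the
lasso itself or an unpenalized refit is genuinely open; the package
reports the lasso coefficients (the refit is a one-liner on the
retained support).

## What the synthetic generator emulates — and what it does not

`build_stimulus_set()` reproduces the experiment geometry: 518 dyads,
259 per culture, envelope classes S+S / S+N / N+N with pooled sizes
226/227/65 (the per-culture split 113/113/33 and 113/114/32 satisfies
both constraints). Voices are additive-synthesis tones (harmonics
$h f_0$, amplitudes $h^{-\text{slope}}$, seeded random phases) in
unison or octave, with sustaining (attack–plateau–release) or
non-sustaining (attack–exponential-decay) envelopes and broadband
noise mixed to an exact energy fraction; Chinese dyads draw somewhat
larger noise fractions, mirroring the noisier attack transients of
plucked and percussive folk instruments. Loudness equalization is RMS
matching — deliberately simpler than gated loudness models, and
sufficient for synthetic fixtures.

`synth_ratings()` plants the latent structure the analysis is meant
to detect. Defaults, chosen once from the distribution statistics
reported for dyad listening studies and kept fixed: fusion class
means 5.97 / 3.98 / 5.51 and roughness 4.96 / 4.42 / 3.54 (category
units, S+S / S+N / N+N), between-stimulus SD 0.8, rater SD 1.2,
boundaries at 1.5 … 8.5. Segregation and pleasantness are mirrored
from fusion and roughness about the scale midpoint with coefficient
−1 and residual SD 0.25, encoding the strong observed
anticorrelations. Rater noise is homoscedastic normal (the Thurstone
assumption), and every rater rates every stimulus — the real
experiment rotated stimulus groups across rater groups, but the
scaling model needs complete proportions, so the generator defaults
to a complete design with `n_raters` exposed.

What passing tests therefore show: the estimators recover structure
*of the kind assumed by the models* at the study's scale. What they
do not show: robustness to heteroscedastic or inattentive raters,
rating drift, real instrument spectra (inharmonicity, formants,
vibrato), room acoustics, or any genuine audio–perception link beyond
the envelope class — in the synthetic world the ratings depend on the
audio only through that class, which caps the achievable model
$R^2$ well below what real perceptual data support.

## Problem sizes and determinism

The test suite and the acceptance script run at deliberately chosen
sizes: scaling recovery at 60 stimuli × 32 raters; alpha checks at
500–600 stimuli; the ANOVA null at 2000 replicates of $n = 60$; SNK
pattern recovery over 40 replicates of 20 stimuli per class;
end-to-end structure recovery at 200 stimuli × 32 raters; lasso sign
recovery over 100 replicates at $n = 518$ with all 45 features.
These sizes make every Monte Carlo margin comfortable while keeping
a full run in tens of seconds. Every stochastic step takes an
explicit integer seed, audio synthesis included, and the pipeline
derives all stage seeds from one master seed, so identical configs
reproduce identical outputs byte for byte.

## Known limitations

* The preference map is plain standardized PCA, not optimal-scaling
  categorical PCA; loadings can differ from an optimal-scaling fit
  when the scale values are far from interval-valid.
* The frequency-modulation descriptor is a coarse dominant-bin track,
  adequate for sustained synthetic tones but not a vibrato analyser.
* Boundary variances of the category cut points are not estimated —
  only locations are used downstream.
* The SNK procedure controls its error rate stepwise; with planted
  near-equal groups the expected two-subset outcome still fails in a
  predictable minority of replicates, which is why pattern checks are
  asserted as modal outcomes over replicates rather than single
  draws.
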