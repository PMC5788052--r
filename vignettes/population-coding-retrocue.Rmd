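---
title: "Modelling retro-cue benefits in working memory with population coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling retro-cue benefits in working memory with population coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retropop)
```

## The scientific problem

In delayed-estimation (continuous report) experiments, observers reproduce a
remembered feature — a colour on a wheel, an orientation, a motion direction —
on an analogue circular scale. A *retro-cue* presented during the retention
interval singles out the item most likely to be probed, and retro-cued items
are recalled more accurately even though the stimuli are long gone. The
question retropop addresses is *which* property of the memory representation
the retro-cue changes.

Descriptive mixture models answer this ambiguously: when recall errors are
decomposed into a von Mises component around the target, a uniform "guess"
component and von Mises components around unprobed items ("swap" errors), a
retro-cue typically shifts all three parameters at once. retropop therefore
implements, alongside that mixture model, a generative neural model —
population coding with Poisson spiking — in which the same behavioural data
are explained by just a tuning-curve *height* (peak rate) and *width*
(FWHM), and asks which of those is affected.

## The population-coding model

A remembered value $\theta$ is encoded by $M$ idealized neurons with von
Mises tuning curves, evenly spaced preferred values $\phi_i$, and
independent Poisson spiking:

$$\lambda_i(\theta) = r_{\max}\, w\, \exp\{\kappa(\cos(\theta-\phi_i)-1)\},
\qquad n_i \sim \text{Poisson}(\lambda_i),$$

where $\kappa$ is related to the full-width at half-maximum by
$\kappa = \ln 2 / (1 - \cos(\mathrm{FWHM}/2))$. Recall is maximum a
posteriori decoding of the spike pattern; for an evenly spaced population
the Poisson penalty term is constant in $\theta$, so the decoder reduces to
the direction of the spike-weighted resultant $\sum_i n_i e^{j\phi_i}$
(`decode_map()`). A pattern with no spikes carries no information: the model
responds uniformly at random. These degenerate trials are the model's
intrinsic "guesses" — no separate guessing process is assumed.

The predicted distribution of decoding errors follows by mixing over the
total spike count $N \sim \text{Poisson}(\Lambda)$, where
$\Lambda = M\, r_{\max} w\, e^{-\kappa} I_0(\kappa)$ is the *population
gain* (expected spikes per decode):

$$p(\varepsilon) = e^{-\Lambda}\frac{1}{2\pi}
 + \sum_{n\ge1} P(N{=}n)\, f_n(\varepsilon),$$

with $f_n$ the density of the resultant direction of $n$ independent von
Mises spike labels (the dense-population limit; the finite-$M$ simulator in
`sample_spikes()`/`decode_map()` exists to validate it, and the two agree to
within a chi-square test at 20,000 trials). Because low counts produce broad
components and high counts sharp ones, the mixture has a sharp peak and long
tails — systematically non-von-Mises, which is exactly what distinguishes it
from the descriptive mixture model.

Swap and guess extensions enter at the trial level
(`popmodel_loglik()`): with probability `pswap` decoding is centred on a
non-target (divided equally among the $m$ non-targets), with probability
`pguess` the response is uniform.

## Units: why `window = 1/n_neurons`

Behaviour identifies only the product $r_{\max} w$ (equivalently the gain
$\Lambda$), not a physical firing rate. retropop fixes the readout-window
scale at $w = 1/M$ by default, so that

$$\Lambda = r_{\max}\, e^{-\kappa} I_0(\kappa)$$

independently of the (arbitrary) population size. This convention is
calibrated against the empirical literature itself: fitted mixture models of
collated retro-cue corpora give $\kappa' \approx 11$–$12$ and guess rates of
6–12%. Under population coding the guess rate is $e^{-\Lambda}$ and the core
concentration is $\approx \Lambda\,\kappa A(\kappa)$, which together imply
$\Lambda \approx 2$–$3$ spikes per recall; with FWHM $\approx 1.25$ that maps
to $r_{\max} \approx 13$–$19$ — the range in which peak rates are indeed
reported. The same calibration matters statistically: at gains an order of
magnitude larger the error distribution is indistinguishable from a single
von Mises, and $(r_{\max}, \mathrm{FWHM})$ become jointly unidentifiable
along the ridge of constant $\Lambda \kappa A(\kappa)$. In the
few-spikes regime both parameters are well identified (the zero/low-count
tail pins the gain, the core width pins the tuning width), which is what the
parameter-recovery studies below verify.

## Numerical evaluation of the error density

The component densities $f_n$ have no elementary closed form. retropop
evaluates them deterministically (`density_settings(method = "quadrature")`):

* $n = 0$: uniform; $n = 1$: the von Mises density itself.
* $n = 2$: exact. Tilting the two-step uniform random walk by
  $e^{\kappa R \cos\varphi}$ shows
  $f_2(\varphi) = (2\pi^2 I_0(\kappa)^2)^{-1}\int_0^\pi
  \exp\{2\kappa\cos(v/2)\cos\varphi\}\,dv$, a smooth one-dimensional
  quadrature.
* $3 \le n \le 40$: a renormalized two-dimensional saddlepoint
  approximation of the summed spike-label vector, integrated radially with
  the substitution $\omega = A^{-1}(r/n)$ (the tilted concentration), which
  keeps the integrand resolved at any $\kappa$. Slices are tabulated once
  per session on a 176-point logarithmic $\kappa$ grid over
  $[\ln 2/2,\,400]$ and interpolated linearly in $\log\kappa$; the table
  costs a few seconds to build and makes one likelihood evaluation ~0.5 ms.
* $n > 40$: the asymptotic limit $VM(0,\, n\kappa A(\kappa))$, whose
  accuracy at that point is well inside the interpolation error.

Each density is renormalized on its $1^\circ$ grid, so the circular
trapezoidal integral is 1 by construction; likelihoods interpolate the grid
linearly. The Poisson sum is truncated at tail mass $10^{-6}$ (a gain so
large that truncation would exceed `n_cap` raises a settings error rather
than silently degrading).

A brute-force per-$n$ Monte Carlo estimator (`method = "mc"`, seeded,
50,000 draws per retained count by default) is retained as the independent
cross-check; the test suite verifies the two paths agree within Monte Carlo
noise, and the deterministic path is what fitting uses — a deterministic
surface is a strictly stronger form of the common-random-numbers device
usually employed to keep simulation noise out of the optimizer.

Numerical guard rails: per-trial densities are floored at $10^{-10}$ to
survive extreme tails; zero-resultant spike patterns are decoded as a
uniform draw with a degeneracy flag; $\kappa'$ is capped at $10^4$ during
mixture fits (fitted values are ~$12$); concentrations are clamped to the
table range during popcode fits.

## Fitting and model comparison

`fit_mle()` maximizes the log likelihood with Nelder-Mead in an
unconstrained space: $\log r_{\max}$, $\log(\kappa - \ln 2/2)$ (popcode),
$\log \kappa'$ (mixture), and an additive log-ratio transform of
$(p_{\text{swap}}, p_{\text{guess}}, \text{remainder})$, which enforces the
probability simplex by construction. Because mixture likelihoods can be
multimodal, the best of `n_starts = 10` Latin-hypercube-dispersed restarts
is kept (ranges: $r_{\max} \in [1, 100]$, FWHM $\in [0.3, 3]$,
$\kappa' \in [1, 50]$, probabilities $\in [0.01, 0.3]$); convergence uses a
relative function tolerance of $10^{-6}$ and at most 5,000 evaluations per
start. Identical data, options and seed reproduce a fit bitwise.

Model comparison uses AIC ($2k - 2\ln L$) per participant, aggregated as
the summed AIC difference across participants, the fraction of participants
favouring each model, and a two-sided exact sign test on the signs of the
per-participant differences (ties dropped). Parameter contrasts between
retro-cue and control conditions use medians with bootstrap standard errors
(1,000 resamples) and Wilcoxon signed-rank tests — fitted parameters are
heavy-tailed across participants, so robust statistics are the default —
while the mean-absolute-error comparison across data sets uses a paired t
test. Cross-experiment parameter correlations z-score each variable across
experiment-by-condition medians, pool both conditions, and report Pearson's
r together with an ANCOVA (`y ~ x + condition`, common slope, partial F on
the condition factor).

## The synthetic-experiment generator

`generate_experiment()` runs the generative models forward: array values
uniform with an optional minimum pairwise separation (rejection sampling —
several source experiments enforce such separations, which is why the
chance-correction procedure exists), item 1 probed, responses decoded from
simulated spikes (popcode) or drawn von Mises (mixture), with swaps
implemented as full-fidelity decodes of a uniformly chosen non-target and
guesses as uniform draws. The default design mirrors a collated corpus at
desk scale — 20 subjects, 300 trials per condition, set size 4, a
360-degree colour wheel — with a gain advantage and reduced swap rate for
the retro-cued item (`rmax` 19 vs 15, equal FWHM 1.25, `pswap` 0.07 vs
0.15), the qualitative structure the real corpus exhibits.

What the generator deliberately does *not* emulate: cue timing and validity
manipulations (only valid retro-cue trials are analysed), presentation
details of individual studies, set-size-dependent gain normalization (each
set size is treated as an independent data set), and any drift or decay
dynamics during retention. Passing recovery tests on synthetic data
therefore show that the estimation machinery is consistent — not that the
model captures every feature of real data.

`chance_corrected_hist()` implements the randomization correction for
non-target deviations: within each subject-by-condition group the
target-to-non-target deviations are permuted across (trial, slot) pairs,
re-added to the targets, and the response deviations from these simulated
non-targets averaged over 1,000 repetitions estimate the chance
distribution, which is subtracted from the observed one. The shuffle unit
(the pooled deviations of a subject-by-condition group, permuted without
replacement) is the closest literal reading of the procedure; the bin count
(36, i.e. 10 degrees of internal angle) is configurable since the
reference analyses do not state one.

## Design choices where the field leaves options open

* **Internal angle convention.** All feature spaces are mapped onto
  $[-\pi, \pi)$ (half-open; $\pi$ wraps to $-\pi$), so orientation data
  (180-degree period) are doubled; summaries are reported back in native
  degrees. One code path serves all feature dimensions.
* **Mean absolute error units.** Reported in native response-space degrees
  per experiment-by-set-size data set, then compared across data sets with
  a paired t test; orientation experiments therefore contribute errors on
  their native 0–90-degree scale.
* **Control-condition choice.** Where an experiment offers several control
  conditions the pipeline keeps one, preferring neutral-cue, then no-cue,
  then post-cue.
* **Aggregation for AIC totals.** Group-level ΔAIC is the sum of
  per-participant differences; sign tests count participants.
* **Recovery-report bias.** `recovery_study()` reports the median estimate
  (robust location) alongside `bias` defined as the *mean* estimation
  error, so the invariant RMSE ≥ |bias| holds exactly.
* **Shared concentration.** Target and non-target (swap) components share a
  single $\kappa'$ in the mixture model, the standard formulation.

## Problem sizes used by the checks

The packaged checks run entirely on synthetic data at desk scale, chosen as
the smallest sizes at which the scientific effects are decisively measurable:
parameter recovery uses 20 subjects at 300 trials; the model-family
identification study uses 2,000 trials per subject (at a realistic gain the
population-coding and mixture models differ by only ~1 AIC point per 300
trials — the same order as in published corpus analyses — so distinguishing
them reliably per subject needs longer sessions); the gain-versus-width
study uses 20 replicate experiments of 40 subjects with 3 restarts per fit;
generator-versus-density agreement uses 20,000 trials. `scripts/acceptance.R`
regenerates a 20-subject corpus at the empirically fitted medians and
re-runs the full five-model pipeline from scratch.

## Known limitations

* The saddlepoint components are approximate at the density shoulders
  (relative error well under 1% in the body, a few percent where the
  density is ~$10^{-3}$); the Monte Carlo method is available where exact
  stochastic evaluation is preferred.
* The dense-population limit ignores decoder quantization at very small
  $M$; with the default $M = 100$ the agreement with the finite simulator
  is statistically indistinguishable at 20,000 trials.
* Gains large enough that $\Lambda \gtrsim 100$ make the model practically
  a von Mises and its two tuning parameters unidentifiable from behaviour;
  fits in that regime will show ridge-like uncertainty (this is a property
  of the model class, not of the optimizer).
* The pipeline treats trials as exchangeable within subject and condition;
  sequential effects, lapses correlated in time, and cue-validity effects
  are out of scope.
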