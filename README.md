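# retropop

Population-coding analysis of retrospective cueing in visual working memory.

`retropop` is for researchers analysing **delayed estimation (continuous
report)** experiments with **retro-cues** — trials where a cue presented
during the retention interval marks the memory item most likely to be
probed. Its purpose is to ask *what the retro-cue changes* in the memory
representation, by fitting two families of trial-level models to circular
recall errors and comparing them:

* **The neural population-coding model.** A remembered feature value θ is
  encoded by M idealized neurons with von Mises tuning curves
  λᵢ(θ) = r_max · w · exp{κ(cos(θ − φᵢ) − 1)}, independent Poisson spiking,
  and maximum a posteriori decoding over a readout window. Its two
  behavioural parameters are the tuning-curve **height** (peak rate r_max)
  and **width** (FWHM = 2·acos(1 − ln2/κ)). Mixing over the Poisson total
  spike count N ~ Poisson(Λ), Λ = M·r_max·w·e^{−κ}I₀(κ), yields sharply
  peaked, long-tailed error distributions; zero-spike trials respond
  uniformly, so "guessing" emerges from the model instead of being assumed.
* **The von Mises + uniform mixture model** (concentration κ′, guess rate
  p_guess), the standard descriptive account.

Both extend with **swap errors** (probability p_swap of reporting a
non-target item). The package provides per-participant maximum-likelihood
fitting (Nelder–Mead with dispersed restarts in a transform that enforces
the probability simplex), AIC model comparison with sign tests,
chance-corrected histograms of deviations around non-target values (the
randomization procedure that removes minimum-separation artefacts),
non-parametric group contrasts with bootstrap standard errors, z-scored
cross-experiment parameter correlations with ANCOVA, a synthetic-experiment
generator interchangeable with real data, and parameter-recovery studies.

Everything is tidyverse-native: trial tables are tibbles in one canonical
schema (`?validate_trials`), fitted objects have `tidy()`/`glance()`
methods, and result types have `autoplot()` methods.

## Worked example

```r
library(retropop)

# simulate a small retro-cue experiment from the population-coding model
design <- experiment_design(
  n_subjects = 8, trials_per_condition = 300, set_size = 4,
  conditions = list(
    retrocue = pop_params(rmax = 19, fwhm = 1.25, pswap = 0.07),
    control  = pop_params(rmax = 15, fwhm = 1.25, pswap = 0.15)),
  seed = 1)
trials <- generate_experiment(design)

# fit the population-coding model with swaps to one subject's retro-cue data
one <- dplyr::filter(trials, subject == "s01", condition == "retrocue")
fit <- fit_mle(one, model_spec("popcode", with_swaps = TRUE), seed = 1)
fit
#> <rc_fit> popcode+swap  loglik=-144.01 AIC=294.02 n=300
#>    rmax    fwhm   pswap
#> 21.4715  1.1593  0.0869

# recover parameters across all subjects and contrast conditions
rec <- recovery_study(design, model_spec("popcode", with_swaps = TRUE),
                      fit_options(n_starts = 5), seed = 2)
rec$contrasts[, c("term", "median_retrocue", "median_control", "p_value")]
#> # A tibble: 3 × 4
#>   term  median_retrocue median_control p_value
#>   <chr>           <dbl>          <dbl>   <dbl>
#> 1 rmax          19.6            15.5   0.00781
#> 2 fwhm           1.20            1.24  0.641
#> 3 pswap          0.0729          0.158 0.00781
```

The single-subject fit recovers the generating parameters (r_max 21.5 vs
truth 19, FWHM 1.16 vs 1.25, p_swap 0.087 vs 0.07); across 8 subjects the
condition contrast shows the signature pattern of retrospective cueing: the
**gain** differs between retro-cue and control (median 19.6 vs 15.5,
Wilcoxon p = 0.008) while the **tuning width does not** (1.20 vs 1.24,
p = 0.64), and the swap rate is lower for cued items (0.073 vs 0.158,
p = 0.008).

For real data, `read_trials("trials.csv", c(exp1 = 360, exp2 = 180))`
loads a delimited table in native degrees (one row per trial: subject,
experiment, condition, control kind, set size, target, non-targets,
response) and converts it to the same internal representation, so the whole
pipeline — `fit_participants()`, `compare_models()`,
`chance_corrected_hist()`, `run_analysis()` — applies unchanged.

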