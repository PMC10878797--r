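# neutralherb

Neutral compound-Poisson models of herbivore damage distributions.

## The problem

Field surveys of herbivory record the proportion of leaf area removed on
each sampled leaf.  The resulting distributions are famously unequal —
most leaves untouched, a few devoured — and that inequality is usually
read as evidence of heterogeneity in plant quality or herbivore
behaviour.  `neutralherb` implements the neutral alternative: identical,
passive plants attacked by herbivores drawn at random from a regional
pool, and asks how much of the observed pattern such pure process
stochasticity already explains.  It is aimed at plant–herbivore ecologists
who want a mechanistic null model, and at methodologists interested in
fitting and testing mixed discrete/continuous proportion distributions.

## The model

The number of feeding events per leaf is Poisson(λ); λ — the attack
rate — is the model's **only free parameter**.  The damage of a single
event, φ, is truncated Pareto on [φ_m, φ_M]:

    P(φ) = (1 − α) φ^(−α) / (φ_M^(1−α) − φ_m^(1−α)),

with α = 14/9 derived from metabolic scaling (consumption ∝ M^(3/4),
density ∝ M^(−3/4), richness ∝ M^(−2/3); `derive_alpha()`).  Cumulative
damage φ_T = Σφ_i, truncated at 1, has a mixed distribution: atoms at
exactly 0 (probability e^(−λ)) and exactly 1, and a continuous density
between, computed by FFT convolution (`damage_distribution()`).  λ is
estimated by interval-censored maximum likelihood at the 0.5% visual
recording resolution (`fit_neutral()`).  For large λ any unitless
inequality index obeys I ≈ √(E[φ²]/λ) / (c·E[φ]) with c = 1 (CV), √π
(Gini), √(2π) (Hoover) — variability declines as 1/√λ.

Around the core model the package provides: plant-scale analysis (bounds
divided by the median leaves per plant L), a closed-form presence/absence
estimator, hurdle-truncated-lognormal and zero-one-inflated-beta
competitors with AICc model selection, Monte-Carlo-averaged KS tests, ten
statistical probes with a constrained (RDA-style) variance partition,
major-axis CV regression, leaf-shuffle permutation nulls, bootstrapped KL
divergence, a synthetic survey generator with controllable non-neutral
contamination, and a command-line front end (`inst/cli/neutralherb`).

## Worked example

```r
library(neutralherb)

ep <- event_params()            # phi_m = 0.005, phi_M = 1, alpha = 14/9
tab <- generate_survey(synth_config(lam = 2, seed = 11))  # 30 plants x 10 leaves
fit <- fit_neutral(tab$prop_damage, ep)
fit
#> Neutral fit: lambda-hat = 1.9842  (loglik = -1202.8731, n = 300, AICc = 2407.7597)

comparison_report(tab$prop_damage, ep, seed = 11)
#> Comparison report (n = 300, lambda-hat = 1.984)
#>   KS: stat 0.074, p 0.425 (1% of 100 replicates p < 0.05)
#>   CV: observed 1.597, predicted 1.591, shuffled -
#>   KL divergence: 0.2397 nats
#>   dAICc (HTLN: neutral) 22.66, (ZOIB: neutral) 112.10
```

The fitted attack rate (1.98) recovers the generating rate (2) within 1%.
The averaged two-sample KS p-value (0.43) and the near-identical observed
and predicted CVs say the survey is statistically indistinguishable from
its neutral fit, and the positive ΔAICc values say the one-parameter
neutral model beats both 3–4 parameter phenomenological competitors after
small-sample correction — as it should on data it generated.

The CLI wraps the same functions:

```sh
inst/cli/neutralherb generate --out surveys.csv --n-surveys 5 --lam 2 --seed 1
inst/cli/neutralherb fit --in surveys.csv --scale plant
inst/cli/neutralherb compare --in surveys.csv --scale leaf --out-csv report.csv
inst/cli/neutralherb sensitivity --in surveys.csv --bounds 0.001:1,0.005:1,0.01:1
```

## Documentation

The methods vignette (`vignettes/neutral-herbivory-model.Rmd`) describes
the model, its numerical representation, the likelihood and design
choices, and what the synthetic generator does and does not emulate.
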