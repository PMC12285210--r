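# sadfit

Compound species abundance distribution models, zero-class richness
extrapolation, and diagnostics for the instability of diversity and
evenness indices.

## For whom, and why

Community ecologists summarise species count inventories with indices —
Shannon's *H*, Simpson's *D*, Hill numbers, Pielou's *J* = *H*/ln *S*, the
logged Hill ratio *H* + ln *D* — and treat the "evenness" they encode as an
ecological property. sadfit takes the complementary, model-based view: an
inventory is one draw from a generative *compound* process (latent
per-species abundances, thinned by a discrete sampling layer), and the
informative quantities are the fitted parameters of that process. The
package provides both toolkits side by side so the indices' behaviour can
be examined against models that actually generate count data.

Two compound models are implemented end to end (PMF, sampler,
zero-truncated maximum-likelihood fit, richness extrapolation):

* **CEGS** — the compound exponential-geometric series: a species' latent
  abundance comes from a Weibull-type quantile transform of an exponential
  variate *E* = −ln *U* with shape γ and scale λ, and its count is
  geometric with stopping probability *p*(*E*) = 1/(abundance + 1), so
  P(*x*) = ∫ e^(−E) (1 − p)^x p dE.
* **PLN** — the Poisson log normal: rates e^Z with Z ~ Normal(μ, σ),
  Poisson counts, P(x) = ∫ Pois(x; e^z) φ(z; μ, σ) dz.

Because a fitted model says how likely a pool species was missed entirely
(its zero class p₀), observed richness extrapolates to the full pool:

```
R̂ = S / (1 − p₀)
```

Around the models sit the classical indices (`diversity_profile()`),
robustness diagnostics (dominant-species removal, bootstrap, reciprocal-sum
pair matching, latitudinal summaries), and vectorised Monte-Carlo
experiments showing that e^H and 1/D jump around across repeated samples of
a *fixed* community while S and the fitted parameters stay put.

## Worked example

```r
library(sadfit)

## classical indices for one inventory
diversity_profile(inventory(c(1, 1, 1, 10), site_id = "demo"))
#>   site S  N      H  expH      D  invD      J      d hill_ratio alpha   x_ls
#> 1 demo 4 13 0.7937 2.212 0.6095 1.641 0.5726 0.7692     0.2986 1.974 0.8682
```

Four species, thirteen individuals: e^H says the inventory behaves like
2.21 equally-abundant species, 1/D like 1.64 — both dragged far below S = 4
by the single dominant count, which holds d = 77% of the individuals.

```r
## fit CEGS to a synthetic inventory with known truth (pool of 1000 species)
fx <- generate_fixture("cegs", cegs_params(2, 1), pool_size = 1000,
                       n_inventories = 1, seed = 42)
cegs_fit(fx[[1]])
#> CEGS zero-truncated ML fit
#>   gamma = 2.2455, lam = 1.1016  (convention: frechet)
#>   log-likelihood = -1050.0157   (290 likelihood evaluations)
#>   p0 = 0.4209   S_obs = 562   extrapolated richness R_hat = 970.5
```

Only 562 of the 1000 species were observed, yet the fitted zero class
recovers a pool estimate within 3% of the truth, with parameter estimates
near the generating (γ = 2, λ = 1).

```r
## index instability under repeated sampling of one fixed community
run_abundance_experiment("pln", pln_params(0, 2), pool_size = 100,
                         n_trials = 10000, seed = 7)
#> PLN sampling experiment: pool = 100 species, 10000 trials
#>   mu = 0, sigma = 2
#>   geometric mean S = 58.6   sd(ln S) = 0.085
#>   sd(ln expH) = 0.465   sd(ln 1/D) = 0.596
```

Nothing varies across trials except sampling noise, yet the log-scale
spread of e^H and 1/D is five to seven times that of S.

## Command-line interface

A thin CLI over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "sadfit.R", package = "sadfit"))')
Rscript $CLI profile counts.csv
Rscript $CLI fit counts.csv --model cegs --out fits.json
Rscript $CLI simulate --model pln --trials 10000 --pool 100 --seed 1
Rscript $CLI diagnose bootstrap counts.csv --metrics expH,invD,J --seed 1
```

Input is long-format CSV/TSV with columns `site`, `species`, `count` and
optional `latitude`, `group`.

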