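# fractalsad

Fitting the one-parameter fractal (Zipf-type) model of the species
abundance distribution to ranked community data, and surveying the fitted
exponent across large collections of samples.

## The model

Rank the species of a community by decreasing abundance. The fractal SAD
model states that the relative abundance of the species of rank *r* is

```
A_r / A_1 = r^(-p),      r = 1, 2, ..., S
```

where *A*₁ is the abundance of the dominant species, *S* the richness and
*p* (the reciprocal of the fractal dimension *d* of the underlying
species-accumulation process) the single free parameter. *p* = 1 is Zipf's
law; *p* = 0 is a perfectly even community; larger *p* means steeper
dominance.

With *F_r* = ln(*A_r*/*A*₁) and *D_r* = ln *r*, minimizing
Σ(−*p D_r* − *F_r*)² gives the closed-form least-squares estimator

```
p-hat = -Σ D_r F_r / Σ D_r²
```

with goodness of fit *R*² measured on the log-transformed variables.

The model plugs directly into diversity theory: the ratio of total to
dominant abundance, *A_T*/*A*₁ = Σ r^(−p), is the Hill effective number of
species of order ∞. At *p* = 1 it is the harmonic number *H_S*, whose gap
to ln *S* decreases to the Euler–Mascheroni constant; for infinite
richness the series converges to the Riemann zeta value ζ(*p*) exactly
when *p* > 1 and diverges otherwise — the boundary that makes Zipf's law
(*p* = 1) the marginal case.

The package provides:

* `estimate_p()`, `r_squared_log()`, `predict_sad()` — the estimator, fit
  quality (centered or uncentered) and the model curve;
* `hill_number()`, `renyi_entropy()`, `diversity_profile()` — Hill
  numbers and Rényi entropy, including the exact order-∞ identity;
* `effective_species_finite()`, `effective_species_infinite()`,
  `harmonic_gap()` — the generalized harmonic series machinery;
* `synthetic_spec()` + `generate_community()` — seeded generators (exact
  power law, multinomial sampling noise, stepwise fractal accumulation
  with K = k^d new species per step) for parameter-recovery validation;
* `read_abundance_table()`, `write_fit_table()` — long-format CSV I/O
  with configurable column dialects;
* `fit_collection()`, `survey_summary()`, `p_histogram()` — the batch
  survey layer producing per-dataset summary tables and third-width
  binned frequency distributions of *p*;
* `inst/cli/fractalsad.R` — a thin command-line front end
  (`simulate` / `fit` / `survey`).

## Worked example

```r
library(fractalsad)

fit <- estimate_p(rank_abundance(c(60, 30, 20, 15, 12, 10),
                                 sample_id = "pond-A"))
fit
#> Fractal SAD fit for 'pond-A':
#>   p = 1   R^2(log) = 1.0000   S = 6   A_T = 147
```

The counts are proportional to 1, 1/2, ..., 1/6 — an exact Zipf
community — so the estimator returns *p* = 1 with a perfect log-scale
fit. Its effective number of species of order ∞ is the harmonic number:

```r
hill_number(c(60, 30, 20, 15, 12, 10), Inf)   # A_T/A_1
#> [1] 2.45
effective_species_finite(1, 6)                # H_6 = 49/20
#> [1] 2.45
```

A parameter-recovery survey over 200 multinomially sampled Zipf
communities (*S* = 100 species, *N* = 100,000 individuals each):

```r
fits <- fit_collection(lapply(1:200, function(s)
  generate_multinomial(synthetic_spec("multinomial_power_law",
                                      p_true = 1, S = 100, N = 1e5,
                                      seed = s))))
survey_summary(fits, "p")[, c("group", "median", "mean", "standard_error", "n_samples")]
#>       group   median     mean standard_error n_samples
#> 1 synthetic 1.000564 1.000746   0.0001731701       200
#> 2     Total 1.000564 1.000746   0.0001731701       200

p_histogram(fits)
#> Frequency distribution of fitted p [synthetic]
#>   [0.000, 0.333): 0
#>   [0.333, 0.667): 0
#>   [0.667, 1.000): 81
#>   [1.000, 1.333): 119
```

The batch mean sits within a tenth of a percent of the true exponent and
the histogram mass concentrates in the two bins around 1, the same
summary statistics and binning used when surveying empirical datasets.

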