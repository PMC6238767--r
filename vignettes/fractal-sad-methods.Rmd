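---
title: "Methods: the fractal rank-abundance model and its estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fractal rank-abundance model and its estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalsad)
```

## The model and its assumptions

A community of `S` species is ranked by decreasing abundance. The fractal
model asserts a single power law on the ranked curve,

$$\frac{A_r}{A_1} = r^{-p}, \qquad r = 1, \dots, S,$$

where $A_1$ is the dominant abundance and $p > 0$ in the model's own
premise (it is the reciprocal of the fractal dimension $d$ of the
accumulation interpretation below). The model assumes (i) strict ranks —
ties are an artefact of finite counts, not of the model — and (ii) that a
single exponent describes the whole curve; it deliberately has no second
shape parameter (contrast the two-parameter Zipf–Mandelbrot family, which
this package does not fit).

`p = 1` is Zipf's law, `p = 0` perfect evenness, `p < 0` an inverted
curve that no ranked data set can produce but that the mathematics
permits.

## The estimator

With $F_r = \ln(A_r/A_1)$ and $D_r = \ln r$, least squares through the
origin on the log-log scale minimizes
$\sum_{r=1}^{S} (-p D_r - F_r)^2$, giving the closed form

$$\hat p = -\frac{\sum_r D_r F_r}{\sum_r D_r^2}.$$

The $r = 1$ term contributes zero to both sums (the model forces the
curve through $(0, 0)$ on the log scale), so at least two ranks are
required; `estimate_p()` rejects samples with `S < 2` and the survey
layer logs and counts such exclusions instead of dropping them silently.
The estimate is returned exactly as computed — zero for flat curves,
negative for inverted ones — because empirical surveys should report what
the estimator yields, not a clamped version of it.

The estimator is scale-invariant (multiplying all abundances by a
constant changes nothing, since only ratios $A_r/A_1$ enter) and is
verified in the test suite against an independent numerical minimization
of the same sum of squares (dense grid plus bracketed golden-section
refinement) on hundreds of noisy samples.

## Goodness of fit on the log scale

Fit quality is $R^2 = 1 - SS_{res}/SS_{tot}$ with
$SS_{res} = \sum_r (F_r + \hat p D_r)^2$. Two conventions for
$SS_{tot}$ exist for through-origin regressions and the package exposes
both:

* **centered** (default): $SS_{tot} = \sum_r (F_r - \bar F)^2$. This is
  the ordinary coefficient of determination, bounded above by 1 and
  comparable across samples; it can be negative when the through-origin
  line fits worse than the mean.
* **uncentered**: $SS_{tot} = \sum_r F_r^2$, natural for a model with no
  intercept and non-negative at the optimum.

The choice is genuinely open — either is defensible for a through-origin
log-log fit — so `estimate_p()`, `fit_collection()` and the CLI accept
`r2_variant`, and batch surveys can be run under both to see whether a
published table used one or the other. A perfectly flat sample fitted at
$p = 0$ has $SS_{tot} = SS_{res} = 0$ and is defined to return
$R^2 = 1$: zero residuals are a perfect fit, and the convention avoids
0/0.

## The diversity bridge

With relative abundances $w_i = A_i/A_T$, the Hill number of order $a$ is
$\left(\sum_i w_i^a\right)^{1/(1-a)}$ and the Rényi entropy its
logarithm. Two orders are handled analytically rather than numerically:
$a = 1$ uses the Shannon limit $\exp(-\sum w_i \ln w_i)$ (no tolerance
knob for "close to 1"), and $a = \infty$ is an explicit sentinel
returning $1/\max_i w_i = A_T/A_1$ exactly. The order-$\infty$ identity
is the bridge between the model and diversity theory: for a fractal
community,

$$\frac{A_T}{A_1} = \sum_{r=1}^{S} r^{-p}$$

is simultaneously the partial generalized harmonic sum and the effective
number of species of order $\infty$. At $p = 1$ it is the harmonic number
$H_S$, and `harmonic_gap(S)` $= H_S - \ln S$ decreases monotonically to
the Euler–Mascheroni constant $\gamma \approx 0.5772157$. For infinite
richness the series converges to $\zeta(p)$ exactly when $p > 1$;
`effective_species_infinite()` treats $p \le 1$ as a *contract*, raising
a condition of class `fractalsad_divergence` rather than returning a
number, because the divergence is the scientifically meaningful answer.

### Numerical evaluation of the convergent series

$\zeta(p)$ is computed as a partial sum of $N$ terms plus the integral
tail $N^{1-p}/(p-1)$ with Euler–Maclaurin correction terms
$-N^{-p}/2 + pN^{-p-1}/12$. The remainder is bounded by
$p(p+1)(p+2)N^{-p-3}/720$, and $N$ is doubled from 64 until that bound
falls below the requested tolerance (default $10^{-12}$). The correction
terms matter: with the bare integral bound alone, exponents near 1 would
need astronomically many terms to reach tight tolerances, whereas the
corrected form stays below a few thousand terms across the whole
parameter range. The implementation is verified in the tests against
frozen arbitrary-precision values of $\zeta(3/2)$ and $\zeta(2) =
\pi^2/6$.

## Synthetic communities

Three seeded generators produce communities with the statistical
structure the analysis assumes; a `synthetic_spec` (including its integer
seed) fully determines the output, and the multinomial generator restores
the caller's RNG state.

* **Exact power law** — the noise-free curve; a round trip through the
  estimator recovers the exponent to machine precision, which anchors all
  other tests.
* **Multinomial sampling** — $N$ individuals drawn from $S$ categories
  with probabilities $\propto r^{-p_{true}}$, zero-count species removed
  and the counts re-ranked. Zero-truncation mirrors real survey tables,
  which record only detected species. The recovery experiments use
  $S = 100$, $N = 10^5$ and $p_{true} = 1$ — a realistic richness and
  census size for the kinds of bird, tree and diatom surveys this model
  is applied to — averaged over 100 seeds, and require the batch mean of
  $\hat p$ within $\pm 0.05$ of truth; smaller censuses ($N = 10^3$) are
  used to demonstrate that recovery bias shrinks as $N$ grows.
* **Fractal accumulation** — the mechanism behind the model: step 0 holds
  one species of abundance 1, and each subsequent step multiplies the
  species total by $K = k^d$ while the new arrivals are $k$ times less
  abundant than the previous step's. The generator reads the hypothesis
  multiplicatively (total richness after step $j$ is $\lceil K^j
  \rceil$), because that reading reproduces $A_r \propto r^{-1/d}$ — the
  curve the model itself asserts — whereas an additive reading ($K$ new
  species per step regardless of $j$) does not. Non-integer $K$ is
  supported by ceiling the richness schedule, with the count added at
  step $j$ being $\lceil K^j\rceil - \lceil K^{j-1}\rceil$; a stated
  rounding rule makes the output exact and testable. Two numerical
  details: $K^j$ is evaluated as $k^{dj}$ (evaluating $(k^d)^j$
  accumulates floating error and can push an exact integer such as
  $(2^{1/2})^2$ above 2, corrupting the schedule), and a $10^{-12}$
  relative guard is applied before the ceiling. The ranked staircase
  output satisfies $r^{-1/d}/k \le A_r/A_1 \le r^{-1/d}\,k$ at every
  rank, and ten doubling steps ($d = 1$, $k = 2$) yield $\hat p$ within
  $\pm 0.1$ of $1/d$.

What the generators do *not* emulate: spatial or temporal autocorrelation
between samples, detection bias that varies with abundance, and
competing SAD families (log-series, lognormal). Passing the recovery
tests therefore shows that the estimator is unbiased under the model's
own sampling assumptions, not that real communities follow the model.

## Data handling rules

Long-format tables (sample, species, abundance) are read under a
configurable column dialect. Duplicate (sample, species) rows are summed
(surveys often split records by subplot or period); zero-abundance rows
are dropped (only detected species carry information and $\ln A_r$ must
exist); negative or unparseable abundances are errors that name the
offending row. Abundances may be non-negative reals, not just counts,
since density and biomass data are common. Ties are ranked stably by
species label so ranks are always the strict sequence $1..S$ and results
are reproducible under row shuffling. Samples reduced to fewer than one
positive abundance at read time, or fewer than two species at fit time,
are omitted *and counted*, so batch totals can be audited.

## Problem sizes and tolerances in the test suite

The suite validates the estimator against the independent minimizer on
500 noisy samples (richness 2–200, log-normal noise) at $10^{-8}$, the
$R^2$ against term-by-term recomputation at $10^{-12}$, Hill numbers
against an independent community-ecology implementation (`vegan::renyi`)
at $10^{-10}$, the order-$\infty$ identity exactly on 200 samples, and
multinomial recovery over 100 seeds at the tolerances quoted above.
These sizes make the full suite run in well under a minute while keeping
the Monte-Carlo standard errors an order of magnitude below the asserted
tolerances.

## Known limitations

* The estimator weights all ranks equally on the log scale; rare-species
  counts (small integers) are the noisiest part of the curve and exert
  the largest leverage through $\ln A_r$. No downweighting is attempted
  because the closed form *is* the method under study.
* $R^2$ on log-transformed rank data is a descriptive fit measure, not a
  basis for model selection among SAD families; the package deliberately
  fits only the one-parameter model.
* The divergence contract means `effective_species_infinite()` cannot be
  used to extrapolate $A_T/A_1$ for $p \le 1$; use the finite sum with an
  explicit richness instead.
* Batch surveys of published datasets depend on per-file column dialects;
  the dialect object absorbs layout variation but the mapping must be
  checked against each file's documentation on first use.
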