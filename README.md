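# clonedist

Exact, time-independent (size-indexed) distributions for clonal dynamics.

When a labelled progenitor cell grows into a clone, most experiments can
count the cells — total, proliferating, mutant — but not date the clone.
clonedist works on the embedded Markov jump chain of the underlying
birth–death process, so every law it computes is indexed by clone or colony
*size* instead of time. It is aimed at quantitative biologists analysing
clonal lineage-tracing or colony-forming assays (epithelial progenitors,
keratinocyte cultures) and at modellers of subclonal mutation data from
growing cell populations.

## What it computes

**Homeostasis (progenitor/differentiated).** A dividing progenitor yields
PP, PD or DD daughters with probabilities *a*, *b*, *c* (*a + b + c* = 1).
The number of proliferating cells is a weighted Motzkin lattice walk
absorbed at 0, giving

- `clone_state_distribution(n, fate)` — P(*k* proliferating cells | clone
  size *n*), via weighted Motzkin numbers *m*ₙ,ₖ with
  *P*ₙ,ₖ = *m*ₙ₋₁,ₖ₋₁;
- `ruin_probabilities(n_max, fate)` — the gambler's-ruin series
  *P*ₙ,₀ = *c·m*ₙ₋₂,₀ = {*c*, *bc*, *c*(*b*² + *ac*), …}, the probability a
  clone freezes (fully differentiates) at size exactly *n*, with an
  independent generating-function route
  *G*(*t*) = (1 − *bt* − √((1 − *bt*)² − 4*ac t*²)) / (2*at*);
- `extinction_probability(fate)` — 1 if *a* ≤ *c*, else *c/a*;
- `estimate_fate_ratio(counts)` — the ratio estimator of (*a*, *b*, *c*)
  from observed counts of small fully differentiated clones
  (*N*₃/*N*₂ → *b*, *N*₄/*N*₃ → (*b*² + *ac*)/*b*, then
  *x*² − (1 − *b*)*x* + *ac* = 0), plus a multinomial MLE extension and a
  bootstrap;
- exact symbolic output: `clone_state_polynomial(5, 3)` returns
  3*a*³*c* + 6*a*²*b*² with exact integer coefficients.

**Growing colonies with mutation.** Mutants arise at non-mutant divisions
with probability *μ*₁ and divide *ρ* times faster than non-mutants:
`neutral_distribution()`, `selection_distribution()` (exact
fluctuation-type mutant-count laws conditional on colony size *k*; the zero
class is *μ*₀^(k−1)), `neutral_moments()`, and the subclone structure —
`mutation_frequency_spectrum()`, `clone_count_distribution()`
(*C* − 1 ~ Bin(*k* − 1, *μ*₁)), `clone_size_distribution()`,
`mutations_per_clone()`.

**Stochastic oracles.** `simulate_homeostasis()` (jump-chain and
continuous-time modes), `simulate_mutation_growth()` (optionally
genotype-tracked with unique Poisson mutation labels) and
`generate_count_fixture()` (synthetic count tables with observational
censoring) reproduce every exact law and power the test suite.

All user-facing functions take and return tibbles, pipe cleanly, have
`ggplot2::autoplot()` methods, and the fate estimator supports broom-style
`tidy()`/`glance()`. A thin command-line wrapper lives at
`inst/cli/clonedist.R` (`fate dist|ruin|estimate`, `ld dist|moments`,
`subclone spectrum|clones|sizes|mutations`, `simulate fate|growth`,
`fixtures counts`).

## Worked example

A 7-day clonal culture yielded 259, 72 and 53 fully differentiated colonies
of two, three and four cells:

```r
library(clonedist)

counts <- tibble::tibble(size = 2:4, count = c(259, 72, 53))
est <- bootstrap_fate(counts, replicates = 2000, seed = 1)
est
#> <fate_estimate>  method: ratio+bootstrap  feasible: TRUE
#>   b_hat = 0.278   ac_hat = 0.1274   (root policy: a_greater)
#>   a = 0.4155   b = 0.278   c = 0.3065
#>   bootstrap CIs over 2000 replicates ( 856 infeasible )

tidy(est)
#> # A tibble: 3 × 4
#>   term  estimate conf.low conf.high
#>   <chr>    <dbl>    <dbl>     <dbl>
#> 1 a        0.416   0.395      0.617
#> 2 b        0.278   0.211      0.363
#> 3 c        0.307   0.0876     0.320
```

The count ratios give *b̂* = 72/259 = 0.278 and *âĉ* = 0.127; solving the
quadratic with the larger root assigned to *a* (proliferating clones were
still present, indicating *a* > *c*) gives (*a*, *b*, *c*) ≈
(0.416, 0.278, 0.307). A third of divisions produce two differentiated
daughters, and a clone started from one such progenitor still fully
differentiates with probability *c/a*:

```r
r <- ruin_probabilities(6, est$fate)
r
#> # A tibble: 5 × 2
#>       n   prob
#> 1     2 0.307
#> 2     3 0.0852
#> 3     4 0.0627
#> 4     5 0.0391
#> 5     6 0.0299
attr(r, "extinction")
#> [1] 0.7376664
```

The many infeasible bootstrap replicates are informative, not a bug: the
quadratic's discriminant is (*a* − *c*)² at the truth, and with only 384
clones the estimate sits close to that identifiability boundary (see the
methods vignette).

On the mutation side, a three-cell colony with *μ*₁ = 0.1 carries 0, 1 or 2
mutant cells with probabilities

```r
neutral_distribution(3, mutation_model(0.1))
#> # A tibble: 3 × 2
#>       m  prob
#> 1     0 0.81
#> 2     1 0.135
#> 3     2 0.055
```

and a randomly chosen mutation in a four-cell colony is carried by 1, 2 or
3 cells with probabilities 2/3, 2/9, 1/9
(`mutation_frequency_spectrum(4)`).

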