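---
title: "Size-indexed clone distributions: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-indexed clone distributions: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedist)
library(dplyr)
```

## The modelling idea: condition on size, not time

Lineage-tracing and clonal culture experiments observe the *composition* of
a clone — how many of its cells still proliferate, or how many carry a
mutation — but rarely its *age*. clonedist works entirely on the embedded
Markov chain (jump chain) of the underlying continuous-time birth–death
process: the state is examined at each cell division, indexed by the total
number of cells, and the exponential holding times between divisions drop
out. Every distribution in the package is therefore a function of clone or
colony size alone. The package's simulators include a continuous-time mode
precisely so this reduction can be checked empirically: the timed process
and the plain jump chain must give statistically indistinguishable state
laws, and the test suite verifies that they do.

Two processes are covered.

**Homeostatic growth (progenitor/differentiated).** A dividing progenitor
cell (P) produces two P daughters with probability $a$, one P and one
differentiated (D) daughter with probability $b$, or two D daughters with
probability $c$, with $a + b + c = 1$. Starting from one P cell, each
division adds one cell, and the number of proliferating cells $k$ performs
a lattice walk — up $a$, flat $b$, down $c$ — absorbed at $k = 0$ (a fully
differentiated clone, frozen forever). This is a gambler's ruin whose law
is governed by Motzkin lattice paths weighted by $(a, b, c)$:

$$P_{n,k} = m_{n-1,k-1}, \qquad
  m_{n,k} = \sum_i \binom{n}{n-k-2i}\, D_{k+2i,\,k}\;
  a^{k+i}\, b^{n-k-2i}\, c^{i},$$

where $D_{n,k}$ counts Dyck-triangle paths
($D_{n,k} = D_{n-1,k-1} + D_{n-1,k+1}$, $D_{2n,0} = C_n$, the Catalan
numbers) and $P_{n,0} = c\, m_{n-2,0}$ is the probability of absorbing at
size exactly $n$ (the walk must pass through the penultimate state with one
proliferating cell and make a final DD division). The probability that a
clone ever fully differentiates evaluates the ruin generating function at
1: it is $1$ when $a \le c$ and $c/a$ when $a > c$.

**Expanding colonies with mutation.** A colony grows by pure birth from a
single non-mutant cell. At each division the dividing cell is chosen
proportionally to its division rate ($\rho = \beta_m/\beta_n$ is the only
way rates enter); a dividing non-mutant produces one mutant daughter with
probability $\mu_1 = 1 - \mu_0$; mutants breed true. Conditioning on colony
size $k$ gives an exact, recurrence-defined analogue of the classical
fluctuation-analysis distribution of mutant counts — the zero class is
exactly $\mu_0^{k-1}$ — together with moments (the expected non-mutant
count has the product form $\prod_{j=1}^{k-1}(j+\mu_0)/j$) and a selection
version ($\rho \ne 1$). At the genotype level, each division carries a
Poisson($\lambda$) number of distinct new mutations with
$\mu_0 = e^{-\lambda}$, every mutation-producing division founds a new
clone (a new mutation combination), and a marked lineage spreads as a
Pólya urn. This yields the mutation frequency spectrum, the shifted-binomial
clone count $C - 1 \sim \mathrm{Bin}(k-1, \mu_1)$, the clone-size law, and
the mutations-per-clone distribution.

## Parameters that matter

| Parameter | Meaning | Range / default |
|---|---|---|
| `a`, `b`, `c` | PP / PD / DD division probabilities (dimensionless, sum to 1) | validated by `fate_probabilities()` |
| `mu1` | per-division probability a non-mutant division yields a mutant daughter | $[0,1]$ |
| `rho` | mutant/non-mutant division-rate ratio | $>0$, default 1 (neutral) |
| `lambda` | mean distinct mutations per division | default $-\log \mu_0$, so a division is mutation-free exactly with probability $\mu_0$ |
| `beta` | division rate per proliferating cell (continuous-time simulation only) | default 1; has no effect on any size-indexed law |

Only `rho`, never the absolute rates, enters the exact distributions; that
is the point of the jump-chain reduction and is verified by simulation.

## Estimating (a, b, c) from small fully differentiated clones

At late observation times every small, non-expanding clone is fully
differentiated, and its frozen size is distributed along the ruin series
$\{c,\, bc,\, c(b^2+ac), \dots\}$. Ratios of observed counts at sizes 2–4
therefore isolate $b = N_3/N_2$ and $ac = b\,(N_4/N_3) - b^2$; with
$a + c = 1 - b$, the pair $\{a, c\}$ solves
$x^2 - (1-b)x + ac = 0$. Three design points deserve emphasis:

* **Root symmetry.** The ruin series is symmetric in $a$ and $c$, so counts
  alone cannot say which root is which. `root_policy` makes the tie-break
  explicit (default `a_greater`, appropriate when persisting proliferative
  clones indicate an expansion bias); the data are agnostic.
* **Identifiability boundary.** The discriminant is $(a-c)^2$ at the truth.
  For balanced fates ($a \approx c$) sampling noise drives it negative in
  roughly half of datasets; `estimate_fate_ratio()` then flags
  `feasible = FALSE` with diagnostics rather than fabricating a root, and
  $\hat b$ remains consistent regardless. Precision of the $\{a, c\}$ split
  degrades continuously as $|a - c| \to 0$; the recovery tests use regimes
  with $|a - c| \ge 0.1$ and a dedicated test documents the boundary.
* **Reporting precision.** Point estimates are carried at full double
  precision. For the worked keratinocyte table (259, 72, 53 clones of sizes
  2–4) the exact larger root is $a = 0.41550$; three-decimal presentations
  of this quantity are sensitive to whether intermediates were rounded
  before solving the quadratic.

`estimate_fate_mle()` extends the ratio idea to all observed sizes
$2..n_{\max}$ by maximising the multinomial likelihood under the
conditional size law $P_{n,0} / \sum_j P_{j,0}$. The conditional likelihood
depends on $(a, c)$ only through $ac$ (the leading factor $c$ cancels in
the normalisation), so the optimiser works on $(b, ac)$ through logit
transforms and the same root policy resolves the pair. It is an extension,
not the published procedure. `bootstrap_fate()` resamples the count vector
multinomially; infeasible replicates are counted, reported, and excluded
from the percentile intervals, with a warning beyond 50%.

## Numerical and arithmetic choices

* **Exact integers and polynomials.** Path counts (`catalan()`,
  `dyck_triangle()`) use exact integer arithmetic, guarded below $2^{53}$
  (where doubles are exact); the guard raises an error rather than losing
  precision. Exactness for weighted quantities is provided symbolically:
  `motzkin_polynomial()` and `clone_state_polynomial()` return the exact
  integer-coefficient monomial expansion in $(a, b, c)$. Identities such as
  probability conservation,
  $\sum_{k\ge1} P_{n,k} + \sum_{j\le n} P_{j,0} = 1$, are verified in the
  suite as exact polynomial identities
  (coefficient-by-coefficient, after multiplying the absorbed terms by
  $(a+b+c)^{n-j}$), which is stronger than checking any particular rational
  parameter value. Numeric evaluation is double precision with 1e-12
  tolerances.
* **Two independent routes everywhere.** The weighted Motzkin numbers are
  computed both by the one-step recurrence
  ($m_{n+1,k} = c\,m_{n,k+1} + b\,m_{n,k} + a\,m_{n,k-1}$, the binding
  definition) and by the Dyck-decomposition closed form; the ruin series
  both via $c\,m_{n-2,0}$ and as Taylor coefficients of
  $G(t) = \bigl(1 - bt - \sqrt{(1-bt)^2 - 4ac\,t^2}\bigr)/(2at)$, expanded
  by a power-series square root in doubles (the Motzkin route is the
  reference; the two agree to 1e-12 relative through $n = 60$). The
  subclone laws likewise: the frequency spectrum and the clone-size
  distribution are separately coded Pólya recursions required to agree
  entry for entry, and an Appendix-style renewal identity
  ($u_n = \sum_r f_r v_{n-r}$, connecting the ruin series to unrestricted
  walk returns) is checked as a diagnostic.
* **Degenerate inputs.** $b = 1$ (the clone neither grows its proliferating
  count nor differentiates) is rejected by `extinction_probability()` and
  accepted everywhere else; $a = 0$ short-circuits the geometric ruin
  series $b^{n-2}c$; $c = 0$ gives an all-zero ruin series and extinction
  probability 0; $\mu_1 \in \{0, 1\}$ collapse the mutant-count law to
  point masses; `mutations_per_clone()` requires $\mu_0 \in (0,1)$ because
  its founding count is a zero-truncated Poisson.
* **Normalisation is asserted, never repaired.** Probability vectors whose
  mass drifts beyond 1e-10 raise an error; nothing is silently
  renormalised. `write_distribution()` refuses unnormalised vectors unless
  the caller acknowledges a partial series (ruin masses).
* **Mutations per clone.** The count for a clone founded at division $i$
  (uniform over $1..k-1$) is $Z + \sum_{r<i} X_r N_r$ with
  $X_r \sim \mathrm{Bernoulli}(1/(r+1))$, $N_r \sim$ Poisson($\lambda$),
  and $Z$ the founding division's own count. $Z$ is taken as
  *zero-truncated* Poisson($\lambda$): a clone exists only if its founding
  division produced at least one mutation. This convention is isolated
  behind the `mode` machinery so an alternative could be swapped in; `pgf`
  mode multiplies the component generating functions by truncated series
  convolution (truncation chosen so the neglected tail is below 1e-13),
  and `sample` mode draws from the same construction.
* **Clone membership.** The clone-size recursion lets clonal cells divide
  without loss to newer mutations, so the simulator validates against the
  *founding-lineage* definition (all descendants of the founding cell,
  `cells_lineage`); the exact-genotype size (`cells_genotype`) is reported
  alongside and agrees only when mutation is rare.
* **"Randomly selected mutation".** The spectrum weights mutation origins
  uniformly over the $k-1$ divisions. An alternative would weight divisions
  by their (possibly multiple) Poisson mutation counts; since those counts
  are i.i.d. across divisions, the two coincide for the pooled empirical
  spectra the simulator produces.

## What the simulators emulate — and what they do not

`simulate_homeostasis()`, `simulate_mutation_growth()` and
`generate_count_fixture()` generate data under exactly the model
assumptions above: Markovian (exponential) cell cycles, fate probabilities
constant across cells and time, no apoptosis, no loss or shedding of
differentiated cells, no back mutation, every mutation unique, and mutants
suffering no extra death risk. Passing tests therefore demonstrate internal
correctness of the exact laws, not fidelity of real tissues to the model.
Real data deviate in known ways — cell-cycle times are closer to gamma than
exponential (harmless for the size-indexed laws only insofar as the
jump-chain outcomes stay i.i.d.), differentiated keratinocytes eventually
shed, recurrent mutation violates uniqueness in small genomes — and none of
these are modelled. The fixture generator censors clones still
proliferating at `max_size` (default 20), mimicking the observational
exclusion of expanding clones, and reports the censored number.

## Problem sizes used by the test suite

The suite fixes every seed and scales simulations to run in about two
minutes total: $10^5$ jump-chain replicates for the proliferating-cell and
extinction checks, $4\times10^5$ colonies for the mutant-count
total-variation comparisons at $k = 100$ (chosen so the TV estimator's
sampling floor lies below the 0.01 acceptance band), $2\times10^4$
genotype-tracked colonies at $k = 50$ for the subclonal laws, and exact
identities through $n = 30$ (polynomial conservation), $n = 60$ (ruin
series routes, spectrum/clone-size equality) and $k = 500$ (normalisation).
The exact recurrences themselves handle $k = 1000$ in under a second.

## Known limitations

* The $\{a, c\}$ ambiguity is structural; only side information resolves it.
* Exact integer guarantees end at $2^{53}$; very long paths (roughly
  $n \gtrsim 60$ for raw counts) fall back on errors, not approximations.
* No apoptosis, shedding, spatial constraint, or non-Markovian cell cycle;
  no time-indexed (age-dependent) distributions at all — size is the only
  index.
* The mutant-count recurrences are $O(k^2)$; they are fast to $k \sim 10^3$
  but are not asymptotic approximations and will not scale to tumour-sized
  populations.
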