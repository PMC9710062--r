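---
title: "Metapopulation dynamics of a transferable gene: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapopulation dynamics of a transferable gene: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metahgt)
```

## The model

`metahgt` simulates the long-run fate of a horizontally transferable gene T
across a collection of spatially segregated microbial host populations — a
metapopulation of "populations of T". Each population carries a character
state `(y, z)` of non-negative integers:

* **indispensability `y`** — the number of dependencies its current host
  has accumulated on T through gene-host coevolution (e.g. by constructive
  neutral evolution). Higher `y` protects against gene loss when the
  environment temporarily stops rewarding the gene's function.
* **connectivity `z`** — the degree to which T's protein product requires
  the specific cellular milieu of its current host. Higher `z` makes
  fixation after horizontal transfer into a naive host less likely.

Time advances in discrete **ancestor–descendant mappings**, each standing
in for billions of microbial generations, long enough for within-host
fixation or loss to complete. Within-host population genetics is deliberately
kept in the background: the model works at the level of whole populations of
T, with three processes per mapping.

**Death by gene loss.** A host is exposed to the neutral environmental state
with probability $\delta$ per mapping; given exposure, the population of T
dies with probability $p_D(y) = e^{-ys}$. The persistence fitness of a
population is therefore $w^p = 1 - \delta\, e^{-ys}$.

**Birth by horizontal transfer.** Each population seeds a Poisson number of
colonization attempts with mean $\beta_N = \beta(1 - N/N_{max})$, where $N$
is the current metapopulation size — colonization opportunity shrinks as
naive hosts are used up. Each attempt fixes with probability
$p_B(z) = e^{-zs}$, so the multiplication fitness is
$w^m = \beta_N\, e^{-zs}$. A newborn population inherits its ancestor's
connectivity but starts at $y = 0$: a naive host has accumulated no
dependencies. Total expected fitness is $w = w^p + w^m$.

**Transmission bias.** In each persisting population, each coordinate
independently moves by $+1$ with probability $P(+1)$, by $-1$ with
probability $P(-1)$, and otherwise stays put. Rates are strongly biased
upward ($P(+1) \gg P(-1)$), encoding the ratchet-like character of
coevolutionary entrenchment. At the boundary $x = 0$ the $-1$ outcome is
unavailable; we remove its mass and renormalize the remaining two outcomes,
giving an upward probability $P(+1)/(1 - P(-1))$ and expected change
$E(\Delta x) = P(+1)/(P(0) + P(+1))$ with $P(0) = 1 - P(+1) - P(-1)$. The
model's boundary expectation is stated without fixing $P(0)$ there; we read
$P(0)$ as the interior no-change probability. The alternative reading
$P(0) = 1 - P(+1)$ differs by about $10^{-8}$ at default rates, far below
every tolerance used here, so the choice is documented rather than
consequential. Newborns are never mutated in the mapping of their birth:
coevolution starts only after fixation.

## Parameters

| name | meaning | default | units |
|---|---|---|---|
| `p_plus` | $P(+1)$ per coordinate | $10^{-3}$ | per mapping |
| `p_minus` | $P(-1)$ per coordinate | $10^{-5}$ | per mapping |
| `delta` | neutral-state exposure | $0.01$ | per mapping |
| `s` | kernel scale in $e^{-ys}$, $e^{-zs}$ | $0.20$ | per character unit |
| `beta` | baseline colonization opportunity | $0.06$ | expected attempts per mapping |
| `n_max` | metapopulation carrying capacity | $10^4$ | populations |

`s = 0.20` gives an e-fold drop in the death (or fixation) probability per
five units of `y` (or `z`). The interesting regime transition happens over
`beta` in `[0.06, 0.08]` at the other defaults: below it the gene survives
by entrenchment (sessile), above it by dispersal (itinerant). `y` and `z`
are unbounded above and must stay so — trajectories routinely pass 20.

## The two engines

`run_expected()` iterates expected class counts. Per class `(y, z)` with
count `n`: survivors `n(1 - delta e^{-ys})` stay put (then spread over the
mutation lattice), and births `n beta_N e^{-zs}` enter `(0, z)`. Two
ordering decisions matter and are fixed as follows: births are computed
from the *full ancestral* counts, not from survivors — a population
eliminated during a mapping may still have colonized first, so death and
birth are independent given the ancestral state — and `beta_N` is evaluated
once per mapping from the ancestral total `N`, ignoring within-mapping
feedback, consistent with the discrete-mapping construction. Counts are
real-valued; extinction is declared when total expected `N` falls below a
threshold of 1 ("fewer than one population expected to remain"), exposed as
an argument. Expected-mode mutation uses the full three-outcome
distribution per coordinate rather than only its mean, keeping mass on the
integer `(y, z)` lattice.

`run_stochastic()` replaces each expectation by a draw: survivors are
Binomial, newborns Poisson, and mutation outcomes multinomial over the nine
`(dy, dz)` combinations (coordinates independent). Three distributional
identities let us sample whole classes at once instead of population by
population — populations within a class are exchangeable, the two-stage
exposure-then-loss Bernoulli collapses to one Bernoulli with success
$\delta p_D(y)$, and Poisson attempts thinned by $p_B(z)$ are
Poisson($\beta_N p_B(z)$). That is what makes $10^4$ populations over
$10^4$ mappings run in seconds. There is no hard cap at `n_max`: `beta_N`
clamps to zero at or above capacity (also guarding against a transiently
negative rate), so `N` can exceed `n_max` only by one mapping's newborns.
Extinction (`N = 0`) is absorbing and ends the run.

Reproducibility: a run is a pure function of (initial state, parameters,
seed). `sweep_beta()` derives one seed per (beta, replicate) pair from its
base seed by fixed affine mixing, keeps every derived seed below $2^{31}$,
and logs it in the output table, so any single replicate can be re-run in
isolation.

## Closed forms

Three quantities have closed forms used both as fast paths and as
cross-checks on the recursion. The per-mapping death probability
$p = \delta e^{-ys}$ makes the number of mappings survived geometric with
mean $(1-p)/p$ (`expected_lifetime()`; 99 at $y=0$, about 738 at $y=10$).
A cohort with no inflow decays as $n_0(1-p)^t$, and
`expected_elimination_time()` returns the first integer $t$ where that
falls below the threshold. A single-class metapopulation balances deaths
against births at $N^* = N_{max}(1 - \delta e^{-ys} / (\beta e^{-zs}))$
(`equilibrium_size()`), when that is positive; otherwise only decay is
possible. At $\beta = 0.08$ the recursion's terminal value after $10^4$
mappings sits within a fraction of a percent of $N^* \approx 764$ — the
value sometimes quoted as "approximately 800" for this regime is the same
equilibrium read off a trajectory plot, and the analytic number is the one
this package treats as exact.

## The Price decomposition

For class proportions $q_i$ and mean fitness $\bar w$, the one-mapping
change in mean connectivity decomposes exactly as

$$\Delta\bar z = \underbrace{\frac{1}{\bar w}\sum_i q_i (w^m_i - \bar w) z_i}_{\text{selection}}
 + \underbrace{\frac{1}{\bar w}\sum_i q_i w^p_i \left(z_i + E(\Delta z_i)\right)}_{\text{transmission}}$$

The selection sum is never positive in the absence of mutation: $w^m$ falls
with $z$, so colonization opportunity is selection for simplicity. The
transmission sum ratchets upward because $E(\Delta z) > 0$. Which force
wins — and hence whether the gene drifts sessile or itinerant — is exactly
the trade-off the simulations explore. `price_decomposition()` evaluates
both terms with $\beta_N$ at the current `N` (density dependence is part of
fitness at the evaluated state).

The indispensability analog is built from the same ancestor–descendant
bookkeeping with one change: multiplication offspring carry $y = 0$, so the
selection sum loses its $w^m z_i$ part and collapses to $-\bar y$. This
analog is an extension constructed in this package, not a restatement of
the connectivity equation.

Because fitness and transmission in the decomposition are expectations, the
identity is exact for the expected mapping. The test suite verifies it two
independent ways: against a brute-force bookkeeping oracle that never forms
$q_i$ or $\bar w$ (agreement to $10^{-10}$ on hundreds of random states),
and against the mean change actually realized by the lattice engine
`step_expected()` — the lattice redistribution and the mean-shift
bookkeeping have identical means, including at the $x = 0$ boundary, which
is asserted rather than assumed.

## What the simulations emulate, and what they do not

The canned recipes (`recipe("fig1")`, `"fig2"`, `"fig3"`) encode the
model's reference scenarios literally: `fig1`/`fig2` start from 1000
populations at `(10, 10)` (deterministic without mutation, stochastic with
mutation, respectively), `fig3` sweeps `beta` with replicate stochastic
runs from $10^4$ populations at `(10, 10)` — note that the sweep starts *at*
carrying capacity, so colonization is initially shut off and only resumes
as deaths free up hosts. Per-beta summaries average terminal mean characters
over non-extinct replicates only, since an empty metapopulation has no mean
character state; extinct replicates still contribute their zero count to
the mean terminal `N`.

These are simulations of the model, not of nature. The synthetic setting
assumes a single shared environment (one `delta`, one `beta` for all
populations), no spatial structure, no variation in transfer mechanism, and
character changes of at most one unit per coordinate per mapping. Passing
tests therefore demonstrate that the implementation realizes this model
faithfully and reproducibly — that the sessile/itinerant transition sits
where the model puts it — not that real transferable genes behave this way.
The model's authors are explicit that rates like $P(\pm 1)$ have no
empirical estimates yet.

## Numerical choices and scales

Degenerate inputs are handled as signals, not errors, where the model gives
them meaning: `delta = 0` yields an infinite lifetime (`Inf`, not an
exception), an empty metapopulation propagates as `N = 0` with undefined
(NA) means, and the Price decomposition refuses an empty state. Class
aggregation after each step merges duplicate `(y, z)` classes exactly;
every operation is invariant to splitting or merging classes with equal
character state, which the suite asserts.

Test and verification scales were chosen to keep the full suite under a
minute apart from the one replicate sweep: the Price identity runs 500
random states; stochastic/deterministic agreement uses 200 replicates of a
200-population, 50-mapping system compared within three standard errors at
every mapping; single-step moment checks use $10^4$ replicate draws within
four standard errors; and the sessile-plateau check uses 5 replicates per
beta of the full $10^4$-population, $10^4$-mapping system. Statistical
assertions run under fixed seeds, so they are reproducible rather than
flaky.

## Limitations

* Expected-mode mutation expands each class over up to nine descendants per
  mapping; long mutation-enabled deterministic runs therefore grow the
  class lattice and are slower than mutation-free ones. The stochastic
  engine does not share this growth (classes only exist where populations
  are).
* The deterministic extinction time depends on the threshold convention
  (expected `N < 1`); other conventions shift it by a few mappings.
* Single stochastic realizations vary widely near the regime boundary
  (`beta` between 0.06 and 0.08); conclusions there should always come from
  replicate sweeps, which is why `fig3` is the canonical stochastic recipe.
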