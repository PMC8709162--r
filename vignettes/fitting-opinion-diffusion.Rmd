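---
title: "Fitting DeGroot opinion diffusion to ordinal panels on sampled networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting DeGroot opinion diffusion to ordinal panels on sampled networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degrootfit)
```

## The model

Opinions of `N` agents are latent continuous values $x_i(t) \in [0, 1]$
that evolve by linear pooling:

$$X(t+1) = W\,X(t),$$

with $W$ row-stochastic ($0 \le w_{ij} \le 1$, $\sum_j w_{ij} = 1$) so
that $w_{ij}$ is the share of total influence on agent $i$ exerted by
agent $j$, and $w_{ii}$ is self-weight (stubbornness). A symmetric
binary adjacency matrix $A$ with unit diagonal constrains $w_{ij} \le
a_{ij}$: where no link exists, influence is structurally impossible.
Self-links are included deliberately so agents weight their own current
opinion.

Two extensions cover plausible departures from linear pooling, used
here only to *generate* data for robustness assessment (the fitter
always estimates a plain DeGroot model):

* **Bounded confidence.** At each step, pairs with
  $|x_i(t) - x_j(t)| > \Delta$ (strictly) have their mutual weights
  zeroed, and each affected row is rescaled by $1/(1 - \sum
  \text{removed})$ so it sums to one again. Self-weights are never
  removed. $\Delta = 1$ is plain DeGroot.
* **Decay.** $X(t+1) = \big((1-\lambda_t) I + \lambda_t W\big) X(t)$
  with $\lambda_t = \lambda^t$: receptivity to others decays
  geometrically. $\lambda = 1$ is plain DeGroot.

Three choices here were genuinely open and are this package's:

* **Composition order.** When both extensions are active, the
  bounded-confidence mask is applied to $W$ first, defining $W(t)$, and
  the decay convex combination with $I$ is applied second. The decay
  update is written as an adjustment of a given weight matrix, and the
  mask is what defines that matrix at time $t$; applying them in the
  opposite order would let decayed self-weight leak through removed
  links.
* **Decay clock.** $\lambda_t = \lambda^t$ with $t$ the index of the
  *current* state, so $\lambda_0 = 1$ and the first update is always a
  full-weight step.
* **Degenerate rows.** If masking removes a row's entire mass (possible
  only when $w_{ii} = 0$), the row becomes the unit self-weight vector:
  an agent cut off from everyone keeps its opinion. No division by zero
  can occur.

## Ordinal measurement

Scores on an `n`-point scale are assumed to possess interval properties.
`forward_transform()` maps level $x$ to the midpoint $(x - 0.5)/n$ of
the $x$-th of $n$ equal-width bins; `back_transform()` maps a continuous
opinion to its bin index $\lceil y\,n \rceil$, with $y = 0$ mapping to
bin 1. Composite scales on shifted ranges (8–32, 3–15) are first moved
to `1..n` with `rescale_ordinal()`.

Numerical boundary rule: before the ceiling, $y\,n$ is snapped to the
nearest integer when within $10^{-12}$ of it. Midpoints never sit on bin
boundaries, but simulated trajectories can land there exactly, and
without the snap a boundary value computed with a one-ulp excess would
silently move up a bin.

## The objective and the genetic algorithm

Given observed ordinal scores at time steps $t \in \{0\} \cup S$, the
modeled trajectory starts from the mid-bin transforms of the $t = 0$
scores and iterates plain DeGroot steps through every integer step up to
$\max S$ — including unobserved ones, so influence travels through gaps
(two survey waves three months apart are coded $t = 0$ and $t = 3$).
The fit minimises

$$f(\hat X, X) = \sum_i \sum_{t \in S} B\big(\hat x_i(t), x_i(t)\big)\,
\big|\hat x_i(t) - x_i(t)\big|,$$

where $B$ is the bin deviation: continuous error counts only when the
modeled opinion is in the wrong bin, and more when it is further off.
$f = 0$ iff every modeled opinion is ordinally correct. The initial
step is excluded ($\hat x_i(0) = x_i(0)$ by construction, so its term
would be identically zero). Panels with missing scores at observed
steps are rejected — imputation is the caller's responsibility and out
of scope here.

The feasible set (row-stochastic with structural zeros) and the
non-smooth objective motivate a genetic algorithm. A chromosome is a
weight matrix; a gene is a row. The operator suite and hyperparameter
defaults are this package's own design:

| parameter | default | role |
|---|---|---|
| population_size | 100 | chromosomes per generation |
| n_generations | 3000 | search budget (cap) |
| tournament_size | 2 | selection pressure |
| crossover_rate | 0.4 | child swaps whole rows with parent 2 (each row with prob. 1/2) |
| blend_rate | 0.4 | per-row convex combination with parent 2, fresh U(0,1) coefficient |
| mutation_rate | 0.2 | per-row: add N(0, mutation_sd) to permitted entries, clip at 0, renormalise |
| mutation_sd | 0.1 | mutation step size, on the weight scale |
| elite_count | 1 | best chromosome survives unchanged |
| tolerance | 0 | early stop on a perfect ordinal fit |

Every operator is closed over the feasible set: convex combinations and
row swaps of feasible rows are feasible, and mutation renormalises after
clipping (a row whose permitted mass is entirely clipped away is redrawn
uniformly). Elitism makes the best-so-far objective non-increasing. The
generation loop is compiled (Rcpp) but consumes R's RNG stream, so
`set.seed()` reproduces a fit exactly. Since even a perfect ordinal fit
need not pin down $W$ (coarse scales and few steps leave the objective
flat near zero), `degroot_fit(runs = k)` performs independent restarts
and also reports the entrywise mean matrix, which stays row-stochastic.

## What the synthetic generator emulates

`generate_ground_truth()` reproduces the data-generating conditions of
the package's simulation study:

* Erdős–Rényi networks with link probability $d/(N-1)$ — "target
  degree" read as expected degree — rejected until connected (which
  implies minimum degree 1); sizes 10–50, degrees 5 and 9.
* Self-weights drawn from a Beta distribution with mean 0.5 and
  concentration $\alpha + \beta = 4$ (Beta(2, 2) at defaults); the
  remaining mass is split across true neighbours, equally by default
  (a symmetric-Dirichlet split is available — the equal split is the
  simpler convention and the results are insensitive to it at these
  degrees).
* Initial opinions i.i.d. Uniform(0, 1); 20 simulated updates
  (`t0..t20`); all opinions back-transformed to the `n`-point scale
  before the fitter sees them.
* Two-wave snowball sampling: the seed is the maximum-degree agent
  (ties broken uniformly at random — degree centrality alone does not
  order ties, and seeded randomness keeps replicates exchangeable);
  every contacted agent faces exactly one Bernoulli($p$) recruitment
  trial, first decline is final; recruiters are processed in sampling
  order, contacts in ascending index, fixing the random stream's
  meaning. Samples with fewer than four agents signal a rejection and
  the whole truth is regenerated (capped at 1000 tries so failure is an
  explicit error, recorded as an `NA` row by the study harness rather
  than aborting it).
* Adjacency varieties: `correct` is the true adjacency reduced to the
  sampled agents; `build` drops same-wave links and keeps, per wave-2
  agent, one uniformly chosen link to a sampled wave-1 true neighbour
  (its recruiter is always a candidate, so the recruitment chain
  survives); `remove` links all wave-1/wave-2 pairs and leaves the
  seed's row at its true links (the seed names all its contacts, so its
  absent links are known absent); `complete` is all ones. The varieties
  nest: build ≤ correct ≤ remove ≤ complete.

What it does **not** emulate: clustering or degree heterogeneity of
real contact networks (the ER graphs stand in for the small, dense
clusters the recruitment targets), reporting or measurement error
beyond ordinal discretisation, item-level missingness (panels must be
complete), eligibility screening, and any opinion noise — latent
opinions are shared exactly. Passing tests therefore demonstrate
correctness of the machinery and robustness to sampling, coarsening,
and misspecification *as modeled*, not performance on real survey data.

## Performance metrics

With the first `T` of 21 steps given to the fitter:

* **Recovery RMSE** — over the entries not fixed at zero by the
  evaluation adjacency ($P$ of them, diagonal included):
  $\sqrt{\sum_p (w_p - \hat w_p)^2 / P}$. The evaluation adjacency is
  the variety given to the fitter, *except* for build runs, which are
  evaluated against the correct matrix so that build's wrongly imposed
  structural zeros are penalised. The true matrix is reduced to sampled
  agents without renormalising; rows may sum below one because weight
  on missing agents is unobservable.
* **Modeling RMSE** — latent vs modeled continuous opinions on steps
  $1..T-1$, denominator $M(T-1)$.
* **Prediction RMSE** — the same on held-out steps $T..20$, denominator
  $M(21-T)$.
* **Ordinal-fit RMSE** — $\sqrt{\sum B^2 / (M(T-1)n^2)}$ on the fitted
  steps: the only diagnostic available outside a simulation, scaled by
  $n$ for comparability across scales.

The sums for modeling and ordinal fit run over $t = 1..T-1$: the $t=0$
term is identically zero by construction and the $(T-1)$ denominator
matches that range.

## Reproducibility and problem sizes

Every stochastic component draws from R's RNG. The study harness
derives one seed per (cell, replicate) by hashing the master seed with
the cell's field values (`cell_seed()`), so results are independent of
execution order. The packaged test suite and `scripts/acceptance.R`
exercise the full pipeline on the smallest study network (N = 10,
d = 5, p = 0.5, T = 6) with 30 replicates per condition — enough to
separate the variety, scale, and dynamics contrasts cleanly while
keeping a full run in the minutes range; the complete factorial grid
(`full_grid()`, 11,520 cells before replication) is exposed for larger
studies.

## Known limitations

* The GA estimates weights only; $\Delta$ and $\lambda$ are not fitted.
  The harness quantifies the cost of that misspecification instead.
* No uncertainty quantification: restart-to-restart spread is visible
  via `summary()` on a multi-run fit, but no standard errors are
  produced.
* Recovery is fundamentally limited by identifiability: coarse scales
  and short panels admit many perfectly fitting weight matrices, so a
  perfect ordinal fit should not be read as parameter recovery.
* Directed influence (asymmetric adjacency) and continuous-time
  dynamics are out of scope.
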