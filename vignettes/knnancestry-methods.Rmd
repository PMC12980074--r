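---
title: "Methods: nearest-neighbor ancestry regression on genetic components"
author: "knnancestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nearest-neighbor ancestry regression on genetic components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knnancestry)
```

## The problem

An individual's genetic ancestry profile is a vector of proportions over
$S$ predefined source populations — a point on the probability simplex
describing which fraction of the genome is attributed to each population.
Haplotype-based tools estimate such profiles accurately but are too slow
for biobank-scale cohorts. This package estimates profiles from nothing
but each sample's scores on principal components (PCs) of genetic
structure — or any analogous decomposition, such as haplotype components —
by k-nearest-neighbor regression against a reference panel whose profiles
are already known. Crucially, the reference profiles may be *continuous*
(admixed reference individuals are used as-is), with the conventional
one-hot assignment as a special case.

## The estimator

Let $x_{i,m}$ be the score of sample $i$ on component $m$, and
$\lambda_m \ge 0$ the component's eigenvalue. Working with the top $M$
components, the distance between query $i$ and reference $j$ is

$$d(i,j) = \sqrt{\sum_{m=1}^{M} \hat\lambda_m\, (x_{i,m} - x_{j,m})^2},
\qquad \hat\lambda_m = \frac{\lambda_m}{\sum_{m'=1}^{M} \lambda_{m'}},$$

a Euclidean distance whose axes are stretched by the (normalized) share of
variance each component explains. Let $J^{(k)}_i$ index the $k$ nearest
references of query $i$. With inverse-distance weighting exponent
$p \ge 0$ and the floored distance $d'(i,j) = \max\{d(i,j), \varepsilon\}$,

$$q_{i,s} \;=\; \begin{cases}
  \dfrac{1}{k} \sum_{j \in J^{(k)}_i} r_{j,s}, & p = 0,\\[1.2em]
  \dfrac{\sum_{j \in J^{(k)}_i} d'(i,j)^{-p}\, r_{j,s}}
        {\sum_{j \in J^{(k)}_i} d'(i,j)^{-p}}, & p > 0,
\end{cases}$$

where $r_{j,s}$ is reference $j$'s known proportion for population $s$.
Every estimate is a convex combination of simplex points, so it is itself
a valid profile — the method cannot produce negative proportions or rows
that fail to sum to one. Computing the distance matrix costs
$O(n_Q n_R M)$ and the neighbor search $O(n_Q n_R \log n_R)$.

Key modelling assumptions, stated plainly:

* **Local homogeneity in component space.** Samples close together in the
  eigenvalue-weighted component space have similar ancestry profiles. This
  is the entire inductive bias; nothing about haplotypes or allele
  frequencies enters the estimator.
* **The decomposition carries the structure.** Accuracy depends on the
  upstream PCA/HCA actually separating the source populations. Garbage
  components give garbage profiles; the component sweep (below) is the
  diagnostic.
* **Admixture is approximately linear in component space.** An individual
  with profile $\pi$ sits near the $\pi$-weighted average of the source
  population centroids. This first-order behaviour of admixed genotypes in
  PC space is what makes averaging neighbor profiles meaningful, and it is
  exactly the generative model of the synthetic simulator.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $k$ | neighbors averaged | 25 | optimal for large ($n_R > 10^4$) continuous reference panels; small panels ($n_R < 1500$) prefer $k$ near $n_R$ |
| $p$ | inverse-distance exponent | 3 | robust near-optimum across scenarios; $p=0$ disables weighting |
| $\varepsilon$ | distance floor (distance units of the normalized-eigenvalue metric) | 0.1 | caps the weight of near-coincident references at $\varepsilon^{-p}$ |
| $M$ | top components used | 10 | accuracy typically saturates around 8 components |

$k$ and $p$ interact: when $k$ is small the weighting barely matters, and
when $k$ approaches $n_R$ with $p = 0$ every query receives the same
global mean profile — the degenerate worst case. Distance weighting is
what rescues large-$k$ settings. `estimateProfiles()` accepts any real
$p \ge 0$, although grid searches conventionally use integers 0–10.
If `nComponents` exceeds what the input carries, the estimator uses all
available components and warns, rather than erroring: the default $M=10$
must remain usable on inputs decomposed into fewer components.

Self-exclusion is keyed on sample ID: when a query ID also appears in the
reference panel, that row is barred from its own neighbor set (default
on). This gives leave-one-out semantics when a panel is evaluated against
itself; cross-validation additionally enforces it structurally through
disjoint folds.

## Standardization and eigenvalue conventions

Two conventions are configurable upstream of the paper's formulas and are
fixed package-wide:

* **Population SD.** `standardizeComponents()` divides by the
  population standard deviation ($n$ in the denominator), so that a
  self-standardized column has unit variance as a property of the stored
  values. The statistics source is selectable: `"self"`, or an external
  `ComponentMatrix` (the reference panel) when queries are projected into
  an existing space after its statistics were fixed.
* **Normalization after truncation.** Eigenvalues are normalized to sum
  to one *after* subsetting to the $M$ components in use, making results
  independent of how many extra components a file happens to carry, and
  making distances invariant to the overall scale of the spectrum
  (multiplying all raw eigenvalues by any $c > 0$ changes nothing).

Users comparing against other implementations of the same estimator
should check both conventions.

## Evaluation: total variation distance

Agreement between two profiles is measured by
$\mathrm{TVD}(q^{(1)}, q^{(2)}) = \tfrac12 \sum_s |q^{(1)}_s - q^{(2)}_s|$
— the fraction of ancestry mass placed differently, 0 for identical
profiles, 1 for disjoint support. For simplex vectors it equals
$1 - \sum_s \min(q^{(1)}_s, q^{(2)}_s)$, which the tests use as an
independent closed form. `evaluateProfiles()` reports the per-sample TVD,
its mean with a 95% confidence interval, and per-population Pearson
correlations across samples. The CI is the normal approximation
$\bar t \pm 1.96\,\mathrm{sd}(t)/\sqrt{n}$, labelled as such in the CLI
output; no bootstrap is attempted. Populations with zero variance on
either side have undefined correlation and are excluded from the mean
correlation with a warning rather than imputed as 0, which would distort
the metric's meaning.

## Parameter selection

`gridSearch()` evaluates a $(k, p)$ grid under one of three reference
scenarios:

* **DISCRETE** — references carry one-hot profiles; queries are a
  disjoint set. This is the mode comparable to tools that require
  single-population reference assignments.
* **CONTINUOUS** — same split, continuous reference profiles.
* **CONTINUOUSALL** — every available sample is a reference;
  `crossValidate()` assigns samples to 10 folds (sizes differing by at
  most one, seeded and reproducible), estimates each fold from the
  remaining ones, and scores the concatenated out-of-fold estimates.

The selected cell minimizes mean TVD; ties break toward smaller $k$, then
smaller $p$, for determinism. Cells whose $k$ exceeds the feasible
reference count are recorded as skipped with a reason instead of aborting
the search, since conventional $k$ grids deliberately include $n_R$.
`componentSweep()` repeats the search over a range of $M$ to expose where
accuracy saturates.

## The mix-up diagnostic

TVD says how much mass two methods place differently, not where. For each
target population, `mixupAnalysis()` takes the samples whose signed
marginal difference (estimated − reference, computed by
`marginalDifferences()`) reaches a threshold (default 0.05) in magnitude,
splits them by sign, and averages the differences in every *other*
population within each group. Because simplex differences sum to zero,
mass overestimated in the target must be drawn from populations whose
mean difference runs the opposite way; the absolute values of those
opposite-direction means, normalized to sum to one, attribute the
disagreement to specific population pairs. Same-sign populations are
reported with attribution 0. With $S = 2$ the attribution is trivially 1
on the other population. Zero differences belong to neither group, so the
sign-matching rule makes the "threshold on the signed value" and
"threshold on the magnitude" readings coincide. A nonempty group in which
*every* other population moves with the target (possible for $S \ge 3$)
has no opposite-direction mass to normalize; it is reported with an empty
attribution and a warning.

## The synthetic simulator

`simulateAdmixture()` generates component-space data with known ground
truth: $S$ centroids drawn from scaled Gaussian directions and rescaled so
their minimum pairwise distance equals `centroidSeparation`; per-sample
profiles from a symmetric Dirichlet (concentration 0.5 by default —
sparse, realistic admixture — with an optional round-robin one-hot
fraction for the reference panel); coordinates as the profile-weighted
centroid average plus isotropic Gaussian noise; and a geometric
eigenvalue decay (0.7 per component) imitating the spectral shape of
genotype PCA. Reported eigenvalues are the *theoretical* per-component
variances (computable from the Dirichlet moments and centroid geometry),
not empirical ones, so every run is exactly reproducible from its
configuration. All randomness derives from one seed through per-stage
substreams: adding draws to one stage cannot shift another.

Defaults — $S = 4$, $M = 6$, 800 reference and 200 query samples,
separation $8\times$ the noise SD — describe clearly clustered
populations with substantial admixture. `structureDims` confines centroid
differences to the leading components (pure noise beyond), which is how
the component-sweep saturation behaviour is exercised.

What the simulator does *not* emulate: linkage disequilibrium, allele
frequencies, PC projection shrinkage of held-out samples, unequal
population sizes, or non-linear PC geometry of strong bottlenecks. Tests
passing on this generator show the estimator implements its formulas and
behaves correctly *given* the linear-mixture geometry; they do not certify
accuracy on any real cohort.

## Numerical choices

* Distances are computed from explicit coordinate differences, not the
  $|a|^2 + |b|^2 - 2ab$ expansion; the expansion loses about eight digits
  to cancellation near coincident samples, and a query identical to a
  reference must be at distance exactly 0.
* Neighbor ties at the $k$-th position break by ascending reference row
  index — a total order, so selection equals a full stable sort truncated
  at $k$ and is testable under permutation.
* $\varepsilon$ is a *floor* substituted for small distances before
  exponentiation, not an additive offset; $p = 0$ bypasses weighting
  entirely, avoiding $0^0$.
* Non-finite weights (overflow of $d^{-p}$) and all-zero weight sets
  (underflow) are hard errors with advice, never silent NaN propagation.
* Profile rows read from disk may be off simplex by rounding; deviations
  up to $10^{-3}$ renormalize with a warning, larger ones error.
* Grid-cell and fold RNG is isolated: `makeFolds()` restores the caller's
  RNG state.

One property worth stating precisely: increasing $p$ concentrates weight
on the nearest reference — its weight share $w_1/\sum_j w_j$ is
nondecreasing in $p$, and the estimate converges to the nearest profile —
but the *path* is not monotone in TVD. At small $p$, mid-distance
neighbors first gain weight relative to far ones, and the estimate can
transiently move away from the nearest neighbor's profile before
converging to it. The tests assert the true monotone statement and the
endpoints, not the false pathwise claim.

## Problem sizes used by the test-suite

The property suites run on 1000+ randomized small instances
($n_R \le 200$, $M \le 10$) against brute-force loop oracles; trend
properties (continuous vs discretized references, weighting at
$k = n_R$, noise monotonicity) use 10 seeded replicates of 200–300
reference samples; parameter recovery runs the simulator defaults (800
reference, 200 query). These sizes were chosen so the full suite
exercises every code path in about a minute while keeping the majority
properties statistically stable.

## Worked example

```{r example}
sim <- simulateAdmixture(simConfig(seed = 1))
est <- estimateProfiles(sim$query, sim$reference, sim$referenceProfiles,
                        knnParams(k = 25, p = 3, nComponents = 6))
ev <- evaluateProfiles(est, sim$queryProfiles)
ev
```

## Known limitations

* Exact neighbor search only; at $n_R$ in the tens of thousands this is
  the intended regime, but no approximate index is provided for panels
  orders of magnitude larger.
* No uncertainty quantification on estimated profiles.
* The estimator consumes whatever components it is given; it cannot
  detect an upstream PCA that failed to separate the source populations,
  beyond the component sweep showing no TVD improvement.
* Projected samples (queries mapped into a reference PC space) are known
  to shrink toward the origin; the estimator does not correct for this.
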