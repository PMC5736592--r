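---
title: "Quantifying persistent social isolation from grooming networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying persistent social isolation from grooming networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isonet)
```

## The scientific problem

In gregarious primates, some individuals are consistently on the
periphery of their social world while others are tightly integrated.
Whether social isolation behaves like a trait — stable within
individuals across years — and how much of it is explained by the
early environment (who your mother was, the group you were born into)
versus current attributes (age, sex, dominance rank, kin present,
familiarity with groupmates) is a variance-decomposition question.
`isonet` implements that decomposition end to end for focal-sampling
grooming data from stable social groups of rhesus macaques and similar
species: observations of who grooms whom and for how long, collected
over one or more years per group, with demography, pedigree,
membership and agonistic (win--loss) records alongside.

## From observations to networks and metrics

For each group and year, the adults analysed are animals aged six
years or more that were members of the group for the whole year;
animals that entered or left part way through a year are excluded, as
are juveniles.  The directed tie from animal $i$ to animal $j$ is a
grooming rate in seconds per hour,

$$w_{ij} = \frac{s_{ij}}{h_i + h_j},$$

where $s_{ij}$ is the total seconds $i$ spent grooming $j$ and $h_i$,
$h_j$ are the animals' observation hours.  The denominator is the
dyad's combined observation time; the convention is a genuine choice
(per-individual hours would be equally defensible) and is fixed and
documented here so results are comparable across runs.

Five per-individual metrics quantify isolation on each group-year
network:

* **instrength** (column sum of $W$): rate of grooming received;
* **outstrength** (row sum): rate of grooming given;
* **betweenness**: number of shortest paths between other pairs
  passing through the individual.  Tie weights are rates, so path
  length uses the inverse transform $1/w$; shortest paths are found by
  Dijkstra's algorithm with Brandes' dependency accumulation, which
  counts equal-length ties fractionally.  Absent ties are
  non-traversable and disconnected pairs contribute nothing;
* **clustering coefficient**: the fraction of an individual's partner
  pairs (partner = any grooming in either direction) that are
  themselves connected.  Undefined — stored as missing, never zero —
  for animals with fewer than two partners;
* **eigenvector centrality**: the principal eigenvector of the
  symmetrised matrix $W + W^\top$.  Eigenvector centrality on a
  directed graph is ill-defined off strongly connected components,
  and the concept being measured (being connected to well-connected
  partners) is direction-free, so symmetrisation is deliberate.

Raw metric scales differ wildly between a 27-adult group and a
104-adult group, so every metric is z-scored *within its group-year*
(sample SD, $n-1$): isolation is always relative to an animal's
current social environment.  Missing clustering values stay missing
and are excluded from the moments; a group-year with fewer than two
non-missing values or zero spread is z-scored to 0 (with a warning)
rather than dropped, which keeps those animals in the panel.

Before modelling, pairwise $r^2$ between the z-scored metrics is
screened (pooled individual-years, pairwise-complete); a metric is
dropped when $r^2 > 0.7$ with an already-retained metric.  Metrics
measure different facets of isolation and normally all survive.

## Covariates

* **Dominance rank** is computed separately per group, year and sex
  from the win--loss records, ordering individuals by David's score
  (win proportions corrected by opponents' scores; dyads that never
  interacted contribute nothing).  The method is a package choice —
  field studies rarely state how ordinal ranks were derived — and is
  validated by simulation: with no upsets the latent order is
  recovered exactly.  Ranks are expressed as the percentage of
  same-sex groupmates outranked, $100(n - \text{rank})/(n-1)$, and
  classed *high* above 80 (else *low*).  A sole same-sex adult has no
  defined rank and is dropped from rank-using models.
* **Close adult female kin** for each female: the number of other
  females with pedigree relatedness exactly 0.5 (mother, daughters,
  full sisters), aged 6+, resident in the same group that year.
  Relatedness is $2\times$ the kinship coefficient from the standard
  recursion on the pedigree (founders unrelated and non-inbred).
* **Tenure** for each male: consecutive years of membership in his
  current group before the focal year; 0 in the entry year, reset by
  any gap.  The membership table may include pre-study years so that
  tenure at the first observed year is not artificially zero.

## The variance-components model

Each z-scored metric is analysed with Gaussian mixed models
$$y = X\beta + \textstyle\sum_k Z_k u_k + e, \qquad
  u_k \sim \mathcal N(0, \sigma^2_k I), \quad
  e \sim \mathcal N(0, \sigma^2_e I),$$
fitted by a conjugate Gibbs sampler: Normal full-conditional updates
for $\beta$ and each random-intercept vector, inverse-gamma updates
for every variance.  Three model families mirror the study design:

1. **all animals** — fixed age, sex, rank class; random individual,
   mother, current group, year;
2. **females only** — fixed age, rank class, number of close adult
   female kin; same random terms;
3. **males only** — fixed age, rank class, tenure; random terms plus
   natal group (natal group is only separable from current group in
   the dispersing sex).

Variance components are reported as proportions of the total,
computed draw by draw: $\rho_k = \sigma^2_k / (\sum_k \sigma^2_k +
\sigma^2_e)$.  The individual-identity proportion is the
*repeatability* — the upper bound on heritability.  Fixed effects get
posterior means, equal-tailed 95% credible intervals and an MCMC
p-value, $p = \max\{2\min(\Pr(\beta > 0), \Pr(\beta < 0)),\,
1/n_{\text{draws}}\}$.  A component whose posterior-mean proportion
exceeds 0.10 while its lower credible bound falls below 0.01 is
flagged *non-robust*: large on average but not distinguishable from
negligible.  Pairwise fixed-effect interactions can be screened
(added one at a time, retained at $p < 0.05$); this is off by default
because it multiplies run time.

Priors and chain defaults, all configurable via `mcmc_config()`:
inverse-gamma(0.001, 0.001) on every variance (weak, in the style of
the era's MCMC mixed-model software), Normal(0, $10^8$) on fixed
effects, 13,000 iterations, 3,000 burn-in, thinning 10 (1,000
retained draws).  Equal-tailed quantile intervals are used throughout.
Running `gibbs_fit(..., chains = 2)` attaches a Gelman--Rubin
$\widehat R$ per parameter; test fits require $\widehat R < 1.1$.
Categorical covariates are coded sex F = 0 / M = 1 and rank low = 0 /
high = 1.  Rows with missing responses (null clustering) or missing
covariates are dropped per model, never imputed, and the drop counts
are logged.

**Cross-metric association models** regress each z-scored metric on
each other metric (both scaled to unit pooled variance, so
coefficients are standardised), with age, sex and rank as fixed
effects and random intercepts for year and for animal-year
combinations.  The phrase "animal identity nested within year" admits
several readings; with one row per animal-year the animal-year
intercept acts as a second residual, which leaves the standardised
coefficients and their p-values valid — the structure is documented
here as this package's choice, not asserted as the only one.

## The synthetic-data generator

`simulate_dataset()` produces a complete study — demography,
pedigree, membership, effort, grooming, agonistic records — from a
generative model whose ground truth is known, so every pipeline stage
can be tested without field data.  Defaults reproduce the target
study design: six groups, one followed for six consecutive years
(sizes 85, 100, 82, 94, 104, 96) and five observed in a single year
(43, 52, 85, 27, 68), giving exactly 836 individual-years and roughly
430 adults of whom ~150 have two or more years; a 0.646 proportion of
females; female philopatry and male dispersal with an 0.8 per-year
continuation probability and occasional male transfer between study
groups; observation effort per monkey Normal(5.70, 1.98) hours
truncated above 1 h.

Latent grooming-giving and -receiving propensities per
individual-year follow exactly the structure the models assume:
$$\eta = \beta x + a_{\text{animal}} + m_{\text{mother}} +
  g_{\text{group}} + y_{\text{year}} + e,$$
with component SDs $\sqrt{\text{fraction}} \times$ total SD and
default fractions 0.25 / 0.10 / 0.05 / 0.05 / 0.55 (animal, maternal,
group, year, residual) on a total latent SD of 0.6 (log scale —
roughly a 1.8-fold rate difference per total SD, a realistic spread
for grooming rates).  Default true fixed effects are modest: age
slope −0.02 per year, male offset −0.2, high-rank offset +0.4, +0.1
per close kin (females), +0.05 per tenure year (males); kin dyads
(relatedness 0.5) get a +0.8 log-scale lift on their expected rate.
Observed grooming seconds for a directed dyad are negative-binomial
(size 0.2) around $\text{baseline} \times e^{\eta_{g,i} +
\eta_{r,j} + \text{dyad terms}} \times (h_i + h_j)$ with baseline 1
s/h; the overdispersion reflects grooming arriving in bouts.
Agonistic bouts (3 per same-sex dyad-year by default) are won by the
higher-ranked animal with probability 0.95.

**What the generator does and does not emulate.**  It reproduces the
variance structure, study design, sampling effort, rank, kin and
tenure structure of real focal data, and its observation noise
attenuates metric repeatability below the latent fraction just as
finite sampling does in the field.  It does **not** reproduce the
sparsity of real grooming networks: real animals concentrate grooming
on a few preferred partners (so some animals have one or no partners
and undefined clustering), whereas a product-form rate model spreads
expected rate over all dyads.  Persistent dyadic preferences,
seasonality, demography (births/deaths) and spatial structure are
likewise out of scope.  Passing recovery tests on these data
therefore validates the estimation machinery, not the behavioural
realism of any particular field system.

## Numerical choices and degenerate inputs

* Betweenness treats path lengths equal within $10^{-12}$ as tied;
  the power iteration for eigenvector centrality runs to relative
  tolerance $10^{-10}$ on a diagonally shifted matrix (the shift
  leaves eigenvectors unchanged but prevents oscillation on
  bipartite-like graphs); an edgeless network yields all-zero
  centralities with a warning.
* David's-score ties break by total wins, then id order, making ranks
  deterministic.
* Relatedness is compared to 0.5 within $10^{-9}$ (pedigree kinship
  is exact binary arithmetic, so this is a formality).
* Every stage consumes an explicit seed; the same configuration and
  seed reproduce every report file byte for byte.
* Degenerate group-years (fewer than two eligible adults) abort that
  group-year with a logged reason; a grouping factor with a single
  level is dropped from its model with a warning.

## Known limitations

* Variance components with very few levels (calendar year has six in
  the default design) are estimable only up to substantial posterior
  uncertainty, and their posterior *means* under the weak
  inverse-gamma prior sit noticeably above small true values (the
  mean of an inverse-gamma with shape $\approx q/2$ exceeds its
  scale's implied point estimate by a factor $\approx
  (q/2)/(q/2-1)$).  In the study design this matters little — the
  within group-year z-scoring removes group and year means, so those
  components are expected near zero — but simulation studies should
  not expect posterior-mean recovery of a 5%-of-total component from
  six levels to better than a few percentage points.
* Repeatability of observed metrics is attenuated relative to the
  latent fraction by sampling noise; comparisons against latent truth
  must account for this.
* The pipeline models each metric independently; a multivariate
  model (correlated random effects across metrics) is out of scope.

## Problem sizes used in the test-suite and acceptance runs

Unit tests use toy fixtures (3--10 nodes) and small simulated studies
(one group over three years, sizes 10--25).  The sampler's oracle
checks use a balanced 50 × 6 one-way design; parameter recovery uses
balanced panels of 300 individuals × 6 years in 10 groups, five
seeds.  The acceptance script analyses the full default design (836
individual-years) with the standard chain lengths.  These sizes were
chosen to exercise every code path at full statistical scale while
keeping a complete run comfortably within a coffee break.

## A worked example

```{r example, eval = FALSE}
library(isonet)

## simulate a small two-group study with known ground truth
cfg <- sim_config(schedule = rbind(
  data.frame(group = "F", year = 2010:2012, size = 20),
  data.frame(group = "V", year = 2011, size = 12)), seed = 1)
res <- run_pipeline(analysis_config(input = cfg, out_dir = "report",
                                    seed = 1))

## repeatability of grooming given, all-animal model
res$fits$model1_outstrength
```
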