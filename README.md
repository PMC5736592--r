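# isonet

Social isolation as a quantitative trait: networks, metrics, and
Bayesian variance decomposition for focal-sampling grooming data.

`isonet` is for behavioural ecologists who observe stable social
groups (the design it targets is a multi-year rhesus macaque study,
but nothing is species-specific): per-dyad grooming durations with
observation effort, demography, pedigree, group membership and
agonistic win–loss records.  From these it answers, with one
reproducible pipeline:

* how socially isolated is each adult, relative to its current group
  and year, on five network metrics — instrength, outstrength,
  weighted betweenness, clustering coefficient, eigenvector
  centrality;
* how much of the variance in each metric is *repeatable* within
  individuals across years, and how much belongs to maternal
  identity, natal group, current group, or year;
* how isolation relates to age, sex, dominance rank, the number of
  close adult female kin, and male group tenure.

## The model

Directed grooming rates `w_ij = s_ij / (h_i + h_j)` (seconds groomed
per combined observation hour) define one weighted network per
group-year over its full-year adults (age ≥ 6).  Metrics are z-scored
within group-year, then each metric `y` is decomposed with a Gaussian
mixed model fitted by a conjugate Gibbs sampler:

    y = Xb + Z_animal u_a + Z_mother u_m + Z_group u_g + Z_year u_y + e,
    u_k ~ N(0, s2_k I),  e ~ N(0, s2_e I)

Variance proportions are computed draw-wise, `rho_k = s2_k / (sum_k
s2_k + s2_e)`; the animal-identity proportion is the repeatability
`R`.  Fixed effects are reported with 95% credible intervals and MCMC
p-values.  Dominance ranks come from David's score on the win–loss
matrix, kin counts from pedigree relatedness (r = 0.5, adult,
co-resident), tenure from consecutive years of membership.  A
synthetic focal-sampling generator (`simulate_dataset()`) emulates
the whole study design — 6 groups, one followed 6 years, 836
individual-years, effort ~ N(5.70, 1.98) h — with known variance
fractions, so every stage is testable against ground truth.

## Worked example

```r
library(isonet)

## a small two-group study with known ground truth
cfg <- sim_config(schedule = rbind(
  data.frame(group = "F", year = 2010:2012, size = 20),
  data.frame(group = "V", year = 2011, size = 12)), seed = 1)
res <- run_pipeline(analysis_config(input = cfg, seed = 1,
                                    cross_metrics = FALSE))
res$fits$model1_outstrength
```

```
model_spec: z_outstrength ~ 1 + age + sex + rank_class +
  (1 | id) + (1 | mother_id) + (1 | group) + (1 | year) [ all ]
n = 72 rows ( 0 dropped ), 1000 retained draws

Fixed effects:
        term     mean   lower  upper pMCMC
 (Intercept)  0.11620 -0.8630 1.0682 0.788
         age -0.00549 -0.0549 0.0401 0.824
         sex -0.23276 -0.7495 0.2796 0.382
  rank_class  0.14593 -0.4088 0.7386 0.628

Variance components (proportions of total):
 component var_mean var_lower var_upper prop_mean prop_lower prop_upper
        id   0.0292  0.000575     0.173    0.0233   0.000471      0.136
 ...
Repeatability (individual identity): 0.023
```

Reading it: 72 individual-years; each fixed-effect row gives the
posterior mean shift in within-group SD units (e.g. males sit 0.23 SD
below females here, but `pMCMC = 0.38` — no evidence at this tiny
scale), and `prop_mean` for `id` is the repeatability of grooming
given.  With only 20 animals over three years the repeatability
posterior is dominated by its prior-to-data uncertainty; at the full
default design (836 individual-years, `sim_config()` defaults) the
same model recovers the generator's variance structure — the
acceptance run below reports outstrength repeatability around 20%.

A thin CLI wraps the same stages:

```sh
Rscript inst/cli/isonet.R simulate --config cfg.yaml --seed 1 --out data/
Rscript inst/cli/isonet.R all --config cfg.yaml --seed 1 --out report/
```

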