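test_that("population generation is reproducible and philopatric", {
  cfg <- tiny_sim_config(seed = 3)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1, p2)
  # females keep their natal group in every membership year
  fem <- p1$individuals$id[p1$individuals$sex == "F"]
  fmem <- p1$membership[p1$membership$id %in% fem, ]
  natal <- p1$individuals$natal_group[match(fmem$id, p1$individuals$id)]
  expect_true(all(fmem$group == natal))
  # pedigree covers every individual and passes validation
  expect_true(all(p1$individuals$id %in% p1$pedigree$id))
})

test_that("a full synthetic dataset is bit-identical under a fixed seed", {
  cfg <- tiny_sim_config(seed = 12)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  s3 <- simulate_dataset(tiny_sim_config(seed = 13))
  expect_false(identical(s1$tables$grooming, s3$tables$grooming))
})

test_that("the default study design matches the target scale", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  expect_equal(nrow(tr), sum(cfg$schedule$size)) # 836 individual-years
  expect_equal(nrow(tr), 836)
  expect_gt(length(unique(tr$id)), 380) # ~429 adults
  expect_lt(length(unique(tr$id)), 480)
  expect_gt(sum(table(tr$id) >= 2), 110) # ~143 repeated individuals
  expect_true(all(tr$age >= 6))
  expect_equal(mean(sim$tables$effort$hours_observed), 5.70,
               tolerance = 0.05)
  expect_gt(sd(sim$tables$effort$hours_observed), 1.7)
  expect_true(all(sim$tables$effort$hours_observed > 1))
})

test_that("without turnover male tenure advances one year per year", {
  cfg <- panel_config(n_ids = 40, n_years = 4, n_groups = 2, seed = 6)
  pop <- simulate_population(cfg)
  tr <- simulate_latents(pop, cfg)
  males <- unique(tr$id[tr$sex == "M"])
  for (m in males) {
    tn <- tr$tenure_years[tr$id == m][order(tr$year[tr$id == m])]
    expect_equal(diff(tn), rep(1, length(tn) - 1))
  }
})

test_that("latent variance limits behave as configured", {
  # residual fraction 1: no within-individual consistency across years
  cfg <- panel_config(n_ids = 150, n_years = 4, n_groups = 5, seed = 21,
                      variance_fractions = c(animal = 0, maternal = 0,
                                             group = 0, year = 0,
                                             residual = 1),
                      total_latent_sd = 1)
  tr <- simulate_latents(simulate_population(cfg), cfg)
  r0 <- anova_repeatability(tr$eta_give, tr$id)
  expect_lt(abs(r0), 0.08)
  # animal fraction 1: latents constant within individual
  cfg1 <- panel_config(n_ids = 60, n_years = 3, n_groups = 3, seed = 22,
                       variance_fractions = c(animal = 1, maternal = 0,
                                              group = 0, year = 0,
                                              residual = 0))
  tr1 <- simulate_latents(simulate_population(cfg1), cfg1)
  spread <- tapply(tr1$eta_give, tr1$id, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
})

test_that("latent repeatability matches the configured animal fraction", {
  # with only animal + year + residual variance the one-way ANOVA
  # intraclass correlation estimates the animal fraction directly
  # (maternal and group effects are constant within individuals here,
  # so they would load onto the between-individual mean square)
  cfg <- panel_config(n_ids = 300, n_years = 6, seed = 31,
                      total_latent_sd = 1,
                      variance_fractions = c(animal = 0.25, maternal = 0,
                                             group = 0, year = 0.05,
                                             residual = 0.70))
  tr <- simulate_latents(simulate_population(cfg), cfg)
  expect_lt(abs(anova_repeatability(tr$eta_give, tr$id) - 0.25), 0.05)
  # full default fractions: check the realised component shares instead
  cfg2 <- panel_config(n_ids = 300, n_years = 6, seed = 32,
                       total_latent_sd = 1)
  tr2 <- simulate_latents(simulate_population(cfg2), cfg2)
  comp <- attr(tr2, "components")
  expect_lt(abs(stats::var(comp$give$a[tr2$id]) /
                  stats::var(tr2$eta_give) - 0.25), 0.05)
  expect_lt(abs(stats::var(comp$give$m[tr2$mother_id]) /
                  stats::var(tr2$eta_give) - 0.10), 0.04)
})

test_that("grooming seconds have the configured Poisson mean", {
  cfg <- sim_config(schedule = data.frame(group = "G", year = 2010L,
                                          size = 2),
                    sex_ratio = 1, focal_hours_sd = 0,
                    fixed_effects_true = c(age = 0, sex = 0, rank = 0,
                                           kin = 0, tenure = 0),
                    dyad_modifiers = c(kin = 0, rank = 0),
                    bouts_dispersion = Inf,
                    partial_year_prob = 0, juvenile_prob = 0, seed = 40)
  pop <- simulate_population(cfg)
  tr <- simulate_latents(pop, cfg)
  h <- cfg$focal_hours_mean
  expected <- cfg$baseline_rate *
    exp(tr$eta_give[1] + tr$eta_recv[2]) * (h + h)
  tot <- 0
  nrep <- 4000
  for (s in seq_len(nrep)) {
    g <- simulate_grooming(tr, pop, cfg, seed = 1000 + s)$grooming
    sec <- g$seconds[g$actor == tr$id[1] & g$recipient == tr$id[2]]
    tot <- tot + sum(sec)
  }
  expect_equal(tot / nrep, expected, tolerance = 0.03)
})

test_that("kin dyads groom at elevated rates when the kin lift is positive", {
  cfg <- tiny_sim_config(seed = 50, bouts_dispersion = Inf)
  sim <- simulate_dataset(cfg)
  A <- attr(sim$truth, "A")
  grm <- sim$tables$grooming
  r <- A[cbind(grm$actor, grm$recipient)]
  kin_mean <- mean(grm$seconds[abs(r - 0.5) < 1e-9])
  nonkin_mean <- mean(grm$seconds[abs(r - 0.5) >= 1e-9])
  expect_gt(kin_mean, nonkin_mean)
})

test_that("agonistic bouts respect the latent hierarchy", {
  # zero upsets: the win-loss matrix is perfectly transitive
  cfg0 <- tiny_sim_config(seed = 61, upset_probability = 0)
  pop0 <- simulate_population(cfg0)
  ago0 <- simulate_agonistic(pop0, cfg0)
  dom <- pop0$dominance
  expect_true(all(dom[ago0$winner] > dom[ago0$loser]))
  # with upsets, the loser occasionally wins at roughly the upset rate
  cfg5 <- tiny_sim_config(seed = 61, upset_probability = 0.5,
                          bouts_per_dyad = 20L)
  pop5 <- simulate_population(cfg5)
  ago5 <- simulate_agonistic(pop5, cfg5)
  upset <- sum(ago5$count[dom[ago5$winner] < dom[ago5$loser]])
  expect_equal(upset / sum(ago5$count), 0.5, tolerance = 0.05)
})

test_that("hierarchy inference recovers the latent order from simulated bouts", {
  cfg <- tiny_sim_config(seed = 70, upset_probability = 0.05,
                         bouts_per_dyad = 30L)
  pop <- simulate_population(cfg)
  ago <- simulate_agonistic(pop, cfg)
  lr <- pop$latent_ranks
  ids <- lr$id[lr$group == "F" & lr$year == 2011 & lr$sex == "F"]
  latent <- ids[order(-pop$dominance[ids])]
  h <- infer_hierarchy(ago, "F", 2011, "F", ids)
  # fraction of dyads ordered consistently with the latent hierarchy
  rk <- stats::setNames(h$ordinal_rank, h$id)
  pairs <- utils::combn(seq_along(latent), 2)
  agree <- mean(rk[latent[pairs[1, ]]] < rk[latent[pairs[2, ]]])
  expect_gte(agree, 0.95)
})
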