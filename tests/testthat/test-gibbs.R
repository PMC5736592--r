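test_that("pMCMC follows the two-sided tail rule with its floor", {
  expect_equal(pmcmc(c(-1, 1, 2, 3)), 0.5)
  expect_equal(pmcmc(rep(1, 1000)), 0.001)
  set.seed(4)
  expect_gt(pmcmc(stats::rnorm(4000)), 0.9) # symmetric about zero
})

test_that("variance proportions are draw-wise arithmetic with robustness flags", {
  s2 <- matrix(rep(c(2, 1, 1, 0), each = 600), 600, 4,
               dimnames = list(NULL, c("id", "mother_id", "group",
                                       "residual")))
  s2[, "residual"] <- 1e-12 # strictly positive draws
  vp <- variance_proportions(s2)
  expect_equal(vp$prop_mean[1:3], c(0.5, 0.25, 0.25), tolerance = 1e-9)
  # all-zero animal variance -> repeatability 0
  s2z <- s2
  s2z[, "id"] <- 1e-15
  expect_equal(variance_proportions(s2z)$prop_mean[1], 0, tolerance = 1e-6)
  # mean above 0.10 with lower CI near zero -> flagged non-robust
  s2f <- cbind(id = c(rep(0.0002, 500), rep(0.48, 500)),
               residual = rep(1, 1000))
  vpf <- variance_proportions(s2f)
  expect_gt(vpf$prop_mean[1], 0.10)
  expect_lt(vpf$prop_lower[1], 0.01)
  expect_true(vpf$non_robust[1])
  expect_false(vpf$non_robust[2]) # residual never flagged
  # proportions sum to 1 in every draw
  tot <- rowSums(sweep(s2, 1, rowSums(s2), "/"))
  expect_equal(tot, rep(1, nrow(s2)))
})

test_that("intercept-only posterior mean matches the sample mean", {
  set.seed(10)
  d <- data.frame(y = stats::rnorm(120, 3, 1))
  fit <- gibbs_fit(d, model_spec("y"), short_mcmc())
  expect_equal(fit$fixed$mean, mean(d$y), tolerance = 0.05)
})

test_that("identical seed and config give identical draws", {
  set.seed(2)
  d <- data.frame(y = stats::rnorm(60), g = rep(letters[1:10], 6))
  f1 <- gibbs_fit(d, model_spec("y", random = "g"), short_mcmc(seed = 7))
  f2 <- gibbs_fit(d, model_spec("y", random = "g"), short_mcmc(seed = 7))
  expect_identical(f1$draws, f2$draws)
  f3 <- gibbs_fit(d, model_spec("y", random = "g"), short_mcmc(seed = 8))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("balanced one-way repeatability matches the ANOVA estimator", {
  set.seed(42)
  id <- rep(sprintf("I%02d", 1:50), each = 6)
  y <- rep(stats::rnorm(50, 0, sqrt(0.4)), each = 6) +
    stats::rnorm(300, 0, sqrt(0.6))
  d <- data.frame(id = id, y = y, stringsAsFactors = FALSE)
  fit <- gibbs_fit(d, model_spec("y", random = "id"), mcmc_config(seed = 3))
  expect_lt(abs(fit$repeatability - anova_repeatability(y, id)), 0.05)
})

test_that("without random effects the posterior means match least squares", {
  set.seed(6)
  d <- data.frame(y = stats::rnorm(200), x1 = stats::rnorm(200),
                  sex = sample(c("F", "M"), 200, TRUE))
  d$y <- d$y + 0.5 * d$x1 - 0.3 * (d$sex == "M")
  fit <- gibbs_fit(d, model_spec("y", fixed = c("x1", "sex")),
                   mcmc_config(seed = 2))
  ols <- stats::coef(stats::lm(y ~ x1 + I(sex == "M"), d))
  expect_equal(unname(fit$fixed$mean), unname(ols), tolerance = 0.03)
})

test_that("variance components agree with lme4 REML on a crossed design", {
  set.seed(14)
  n_id <- 80
  id <- rep(sprintf("I%02d", 1:n_id), each = 5)
  grp <- sample(paste0("g", 1:8), length(id), TRUE)
  y <- rep(stats::rnorm(n_id, 0, sqrt(0.5)), each = 5) +
    stats::rnorm(8, 0, sqrt(0.3))[as.integer(factor(grp))] +
    stats::rnorm(length(id), 0, 1)
  d <- data.frame(y = y, id = id, grp = grp, stringsAsFactors = FALSE)
  fit <- gibbs_fit(d, model_spec("y", random = c("id", "grp")),
                   mcmc_config(seed = 5))
  lf <- lme4::lmer(y ~ 1 + (1 | id) + (1 | grp), d)
  vc <- as.data.frame(lme4::VarCorr(lf))
  v_lmer <- stats::setNames(vc$vcov, vc$grp)
  p_lmer <- v_lmer / sum(v_lmer)
  p_gibbs <- stats::setNames(fit$components$prop_mean,
                             fit$components$component)
  expect_lt(abs(p_gibbs[["id"]] - p_lmer[["id"]]), 0.06)
  expect_lt(abs(p_gibbs[["residual"]] - p_lmer[["Residual"]]), 0.06)
})

test_that("degenerate inputs are handled as specified", {
  d <- data.frame(y = c(1.5, 2.5, 2, 3), g = "same",
                  stringsAsFactors = FALSE)
  expect_warning(fit <- gibbs_fit(d, model_spec("y", random = "g"),
                                  short_mcmc()),
                 "single level")
  expect_false("g" %in% fit$components$component)
  d$y[2] <- Inf
  expect_error(gibbs_fit(d, model_spec("y"), short_mcmc()),
               class = "isonet_schema_error")
  # missing responses are dropped, not imputed
  d2 <- data.frame(y = c(stats::rnorm(30), NA, NA),
                   g = rep(letters[1:4], 8))
  expect_message(fit2 <- gibbs_fit(d2, model_spec("y", random = "g"),
                                   short_mcmc()),
                 "dropping 2")
  expect_equal(fit2$n_used, 30)
})

test_that("two chains mix with Gelman-Rubin diagnostics below 1.1", {
  set.seed(9)
  d <- data.frame(y = stats::rnorm(150) + rep(stats::rnorm(30, 0, 0.8),
                                              each = 5),
                  id = rep(sprintf("I%02d", 1:30), each = 5),
                  stringsAsFactors = FALSE)
  fit <- gibbs_fit(d, model_spec("y", random = "id"),
                   mcmc_config(n_iter = 6000, burn_in = 1000, thin = 5,
                               seed = 4), chains = 2)
  expect_true(all(fit$rhat < 1.1))
  expect_equal(nrow(fit$draws$beta), 2000) # draws pooled across chains
})

test_that("interaction screen keeps real interactions and drops null ones", {
  set.seed(30)
  n <- 400
  d <- data.frame(age = stats::rnorm(n), sex = sample(c("F", "M"), n, TRUE))
  # no interaction in truth
  d$y <- 0.3 * d$age - 0.2 * (d$sex == "M") + stats::rnorm(n)
  spec <- model_spec("y", fixed = c("age", "sex"))
  s0 <- interaction_screen(d, spec, short_mcmc(seed = 1))
  expect_equal(s0$fixed, c("age", "sex"))
  # strong age x sex interaction is retained
  d$y <- d$y + 0.5 * d$age * (d$sex == "M")
  s1 <- interaction_screen(d, spec, short_mcmc(seed = 1))
  expect_true("age:sex" %in% s1$fixed)
  # nothing to screen without at least two fixed effects
  expect_equal(interaction_screen(d, model_spec("y"), short_mcmc())$fixed,
               character(0))
})
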