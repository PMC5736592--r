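# Conjugate Gibbs sampler for Gaussian mixed models with multiple
# random intercepts, and posterior summaries (variance proportions,
# repeatability, MCMC p-values).

#' Specify a variance-components mixed model
#'
#' @param response Name of the response column (one of the z-scored
#'   metrics in the individual-year table, for the study models).
#' @param fixed Character vector of fixed-effect terms: column names
#'   (`"age"`, `"sex"`, `"rank_class"`, `"n_kin"`, `"tenure_years"`, ...)
#'   or pairwise interactions written `"a:b"`.  An intercept is always
#'   included.
#' @param random Character vector of grouping-factor columns
#'   (`"id"`, `"mother_id"`, `"group"`, `"year"`, `"natal_group"`, ...).
#' @param subset One of `"all"`, `"females_only"`, `"males_only"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, fixed = character(),
                       random = character(),
                       subset = c("all", "females_only", "males_only")) {
  subset <- match.arg(subset)
  structure(list(response = response, fixed = fixed, random = random,
                 subset = subset), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$response, "~",
      paste(c("1", x$fixed), collapse = " + "),
      if (length(x$random)) paste("+ (1 |",
                                  paste(x$random, collapse = ") + (1 | "),
                                  ")") else "",
      "[", x$subset, "]\n")
  invisible(x)
}

#' MCMC sampler settings
#'
#' Defaults follow common practice for variance-component models of
#' behavioural data: weak inverse-gamma(0.001, 0.001) priors on every
#' variance, a diffuse Normal(0, 1e8) prior on fixed effects, 13,000
#' iterations with 3,000 burn-in thinned by 10 (1,000 retained draws).
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Discarded initial iterations (< `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer RNG seed; same seed and config give identical
#'   draws.
#' @param variance_prior Length-2 vector `(shape, rate)` of the
#'   inverse-gamma prior shared by all variance components.
#' @param fixed_prior_variance Prior variance of each fixed effect.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 13000L, burn_in = 3000L, thin = 10L,
                        seed = 1L,
                        variance_prior = c(shape = 0.001, rate = 0.001),
                        fixed_prior_variance = 1e8) {
  stopifnot(burn_in < n_iter, thin >= 1)
  n_keep <- floor((n_iter - burn_in) / thin)
  if (n_keep < 500)
    warning("fewer than 500 retained draws; posterior summaries will be noisy")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 variance_prior = variance_prior,
                 fixed_prior_variance = fixed_prior_variance),
            class = "mcmc_config")
}

# Numeric coding of one covariate column (sex F=0/M=1, rank low=0/high=1).
.code_covariate <- function(data, name) {
  if (!name %in% names(data))
    .abort(paste("covariate column not found:", name), "isonet_schema_error")
  x <- data[[name]]
  if (is.numeric(x)) return(as.numeric(x))
  if (name == "sex") return(as.numeric(x == "M"))
  if (name == "rank_class") return(as.numeric(x == "high"))
  if (is.logical(x)) return(as.numeric(x))
  .abort(paste("cannot code non-numeric covariate:", name),
         "isonet_schema_error")
}

# Design matrix for intercept + terms (terms may be "a:b" interactions).
.build_design <- function(data, fixed) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (term in fixed) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    col <- Reduce(`*`, lapply(parts, .code_covariate, data = data))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- term
  }
  X
}

# One Gibbs chain.  y response; X design; zidx list of integer level
# indices per random factor; nlev levels per factor.
.gibbs_chain <- function(y, X, zidx, nlev, cfg, seed) {
  set.seed(seed)
  n <- length(y)
  p <- ncol(X)
  K <- length(zidx)
  a <- cfg$variance_prior[["shape"]]
  b <- cfg$variance_prior[["rate"]]
  V0 <- cfg$fixed_prior_variance
  XtX <- crossprod(X)
  beta <- rep(0, p)
  u <- lapply(nlev, numeric)
  s2u <- rep(max(stats::var(y), 1e-6), K)
  s2e <- max(stats::var(y), 1e-6)
  fitted_u <- numeric(n)
  n_keep <- floor((cfg$n_iter - cfg$burn_in) / cfg$thin)
  beta_draws <- matrix(NA_real_, n_keep, p,
                       dimnames = list(NULL, colnames(X)))
  s2_draws <- matrix(NA_real_, n_keep, K + 1,
                     dimnames = list(NULL, c(names(zidx), "residual")))
  keep <- 0L
  for (iter in seq_len(cfg$n_iter)) {
    # beta | rest
    r <- y - fitted_u
    prec <- XtX / s2e
    diag(prec) <- diag(prec) + 1 / V0
    ch <- chol(prec)
    mu <- backsolve(ch, forwardsolve(t(ch), crossprod(X, r) / s2e))
    beta <- as.vector(mu + backsolve(ch, stats::rnorm(p)))
    xb <- as.vector(X %*% beta)
    # each u_k | rest, then its variance
    for (k in seq_len(K)) {
      rk <- y - xb - fitted_u + u[[k]][zidx[[k]]]
      s <- as.vector(rowsum(rk, zidx[[k]]))
      nl <- tabulate(zidx[[k]], nlev[k])
      prec_k <- nl / s2e + 1 / s2u[k]
      u_new <- s / s2e / prec_k + stats::rnorm(nlev[k]) / sqrt(prec_k)
      fitted_u <- fitted_u + (u_new - u[[k]])[zidx[[k]]]
      u[[k]] <- u_new
      s2u[k] <- 1 / stats::rgamma(1, a + nlev[k] / 2,
                                  rate = b + sum(u_new^2) / 2)
    }
    e <- y - xb - fitted_u
    s2e <- 1 / stats::rgamma(1, a + n / 2, rate = b + sum(e^2) / 2)
    if (iter > cfg$burn_in && (iter - cfg$burn_in) %% cfg$thin == 0) {
      keep <- keep + 1L
      beta_draws[keep, ] <- beta
      s2_draws[keep, ] <- c(s2u, s2e)
    }
  }
  list(beta = beta_draws, sigma2 = s2_draws)
}

#' Fit a variance-components mixed model by Gibbs sampling
#'
#' Samples the Gaussian mixed model y = X b + sum_k Z_k u_k + e, with
#' u_k ~ N(0, s2_k I) and e ~ N(0, s2_e I), by full-conditional updates:
#' Normal draws for the fixed effects and each random-intercept vector,
#' inverse-gamma draws for every variance.  Rows with a missing response
#' or missing covariates are dropped (reported); grouping factors with a
#' single level are dropped with a warning.  Draws are deterministic
#' given the seed.
#'
#' @param data Individual-year data frame (see [covariate_table()]).
#' @param spec A [model_spec()].
#' @param config An [mcmc_config()].
#' @param chains Number of independent chains (seeds `seed`,
#'   `seed + 1`, ...).  Draws are pooled for summaries; with 2 or more
#'   chains a Gelman-Rubin diagnostic is attached.
#' @return An object of class `vc_fit`: pooled `draws` (`beta`,
#'   `sigma2` matrices), `fixed` summary table (posterior mean, 95%
#'   equal-tailed credible interval, pMCMC), `components` table from
#'   [variance_proportions()], `repeatability` (the `id` component's
#'   proportion, if present), `rhat`, the spec and config echoed, and
#'   drop counts.
#' @export
gibbs_fit <- function(data, spec, config = mcmc_config(), chains = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  if (spec$subset == "females_only") data <- data[data$sex == "F", , drop = FALSE]
  if (spec$subset == "males_only")   data <- data[data$sex == "M", , drop = FALSE]
  y_raw <- data[[spec$response]]
  if (is.null(y_raw))
    .abort(paste("response column not found:", spec$response),
           "isonet_schema_error")
  if (any(!is.finite(y_raw) & !is.na(y_raw)))
    .abort("non-finite response values", "isonet_schema_error")
  used_cols <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  keep <- !is.na(y_raw)
  for (cc in c(used_cols, spec$random)) {
    if (!cc %in% names(data))
      .abort(paste("model column not found:", cc), "isonet_schema_error")
    keep <- keep & !is.na(data[[cc]])
  }
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(sprintf("gibbs_fit: dropping %d row(s) with missing response/covariates",
                    n_dropped))
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 2)
    .abort("fewer than 2 usable rows", "isonet_schema_error")
  y <- data[[spec$response]]
  X <- .build_design(data, spec$fixed)

  random <- spec$random
  zidx <- list()
  nlev <- integer()
  for (g in random) {
    f <- factor(data[[g]])
    if (nlevels(f) < 2) {
      warning(sprintf("grouping factor '%s' has a single level; dropped", g))
      next
    }
    zidx[[g]] <- as.integer(f)
    nlev[g] <- nlevels(f)
  }

  chain_res <- lapply(seq_len(chains), function(ch)
    .gibbs_chain(y, X, zidx, nlev, config, config$seed + ch - 1L))
  beta <- do.call(rbind, lapply(chain_res, `[[`, "beta"))
  sigma2 <- do.call(rbind, lapply(chain_res, `[[`, "sigma2"))

  rhat <- if (chains >= 2L) {
    pars <- cbind(do.call(rbind, lapply(chain_res, `[[`, "beta")),
                  log(do.call(rbind, lapply(chain_res, `[[`, "sigma2"))))
    per_chain <- lapply(chain_res, function(cr) cbind(cr$beta, log(cr$sigma2)))
    .rhat(per_chain)
  } else NULL

  q <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  fixed_tab <- data.frame(
    term = colnames(beta),
    mean = colMeans(beta),
    lower = apply(beta, 2, function(v) q(v)[1]),
    upper = apply(beta, 2, function(v) q(v)[2]),
    pMCMC = apply(beta, 2, pmcmc),
    row.names = NULL, stringsAsFactors = FALSE)
  comp <- variance_proportions(sigma2)
  structure(list(draws = list(beta = beta, sigma2 = sigma2),
                 fixed = fixed_tab, components = comp,
                 repeatability = if ("id" %in% comp$component)
                   comp$prop_mean[comp$component == "id"] else NA_real_,
                 rhat = rhat, spec = spec, config = config,
                 n_used = nrow(data), n_dropped = n_dropped),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, digits = 3, ...) {
  print(x$spec)
  cat("n =", x$n_used, "rows (", x$n_dropped, "dropped ),",
      nrow(x$draws$beta), "retained draws\n\nFixed effects:\n")
  print(format(x$fixed, digits = digits), row.names = FALSE)
  cat("\nVariance components (proportions of total):\n")
  print(format(x$components, digits = digits), row.names = FALSE)
  if (!is.na(x$repeatability))
    cat(sprintf("\nRepeatability (individual identity): %.3f\n",
                x$repeatability))
  invisible(x)
}

# Gelman-Rubin potential scale reduction over a list of chain matrices.
.rhat <- function(chain_mats) {
  m <- length(chain_mats)
  n <- nrow(chain_mats[[1]])
  sapply(colnames(chain_mats[[1]]), function(j) {
    means <- vapply(chain_mats, function(cm) mean(cm[, j]), numeric(1))
    vars <- vapply(chain_mats, function(cm) stats::var(cm[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' Posterior variance proportions and robustness flags
#'
#' Converts variance-component draws to proportions of the total
#' phenotypic variance, draw by draw: rho_k = s2_k / (sum_k s2_k +
#' s2_e).  The `id` component's proportion is the repeatability.  A
#' component is flagged non-robust when its posterior-mean proportion
#' exceeds `robust_mean` but the lower credible bound falls below
#' `robust_lower` (too close to zero to rule out a negligible
#' contribution).
#'
#' @param sigma2 Matrix of variance draws, one column per component
#'   (including `residual`), as in a `vc_fit`'s `draws$sigma2`.
#' @param robust_mean,robust_lower Flag thresholds (defaults 0.10,
#'   0.01).
#' @return Data frame: `component`, posterior mean and 95% CI of the
#'   variance and of its proportion, and `non_robust`.
#' @export
variance_proportions <- function(sigma2, robust_mean = 0.10,
                                 robust_lower = 0.01) {
  if (nrow(sigma2) < 500)
    warning("fewer than 500 draws; proportion summaries will be noisy")
  tot <- rowSums(sigma2)
  prop <- sweep(sigma2, 1, tot, "/")
  q <- function(m) t(apply(m, 2, stats::quantile, c(0.025, 0.975),
                           names = FALSE))
  vq <- q(sigma2)
  pq <- q(prop)
  out <- data.frame(component = colnames(sigma2),
                    var_mean = colMeans(sigma2),
                    var_lower = vq[, 1], var_upper = vq[, 2],
                    prop_mean = colMeans(prop),
                    prop_lower = pq[, 1], prop_upper = pq[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$non_robust <- out$prop_mean > robust_mean &
    out$prop_lower < robust_lower & out$component != "residual"
  out
}

#' MCMC p-value of a fixed effect
#'
#' Two-sided posterior tail probability that the effect crosses zero:
#' twice the smaller of the fractions of draws above and below zero,
#' floored at 1 / (number of draws).
#'
#' @param draws Numeric vector of posterior draws.
#' @return Numeric in (0, 1].
#' @export
pmcmc <- function(draws) {
  n <- length(draws)
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  max(p, 1 / n)
}

#' Forward screen of pairwise fixed-effect interactions
#'
#' Adds each pairwise interaction between the spec's fixed effects to
#' the model one at a time and retains it only when its MCMC p-value is
#' below `alpha`, returning the enriched spec.
#'
#' @inheritParams gibbs_fit
#' @param alpha Retention threshold on pMCMC (default 0.05).
#' @return A [model_spec()] with any retained `"a:b"` terms appended.
#' @export
interaction_screen <- function(data, spec, config = mcmc_config(),
                               alpha = 0.05) {
  fx <- spec$fixed
  if (length(fx) < 2) return(spec)
  retained <- character()
  pairs <- utils::combn(fx, 2, simplify = FALSE)
  for (i in seq_along(pairs)) {
    term <- paste(pairs[[i]], collapse = ":")
    cfg_i <- config
    cfg_i$seed <- config$seed + i # distinct, reproducible chains
    trial <- spec
    trial$fixed <- c(fx, term)
    fit <- gibbs_fit(data, trial, cfg_i)
    if (fit$fixed$pMCMC[fit$fixed$term == term] < alpha)
      retained <- c(retained, term)
  }
  spec$fixed <- c(fx, retained)
  spec
}
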