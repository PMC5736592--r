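# Full-analysis orchestration: metrics, covariates, collinearity screen,
# the three model families, cross-metric association models, reports.

#' Configuration of a full pipeline run
#'
#' @param input Either a [sim_config()] (data are simulated) or a named
#'   list/vector of CSV paths for [load_tables()].
#' @param metrics Metrics to analyse (default all five).
#' @param models Which model families to fit: 1 = all animals (fixed
#'   age, sex, rank; random animal, mother, group, year), 2 = females
#'   only (age, rank, kin count), 3 = males only (age, rank, tenure;
#'   natal group as an extra random effect).
#' @param mcmc An [mcmc_config()] for the variance-component fits.
#' @param collinearity_threshold Pairwise r^2 above which a metric is
#'   dropped (default 0.7).
#' @param screen_interactions Run [interaction_screen()] on each model
#'   before the final fit (off by default; it multiplies run time).
#' @param cross_metrics Fit the cross-metric association models.
#' @param out_dir Output directory for reports, or `NULL` to skip
#'   writing.
#' @param seed Master seed: simulation uses it directly, fit `k` uses
#'   `seed + k`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(input = sim_config(),
                            metrics = .isonet_metrics,
                            models = 1:3,
                            mcmc = mcmc_config(),
                            collinearity_threshold = 0.7,
                            screen_interactions = FALSE,
                            cross_metrics = TRUE,
                            out_dir = NULL,
                            seed = 1L) {
  stopifnot(collinearity_threshold > 0, collinearity_threshold <= 1)
  structure(list(input = input, metrics = metrics, models = models,
                 mcmc = mcmc,
                 collinearity_threshold = collinearity_threshold,
                 screen_interactions = screen_interactions,
                 cross_metrics = cross_metrics, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Individual-year covariate table
#'
#' Derives, for every eligible adult in every observed group-year (a
#' group-year is observed when it has effort records): age, sex,
#' dominance rank (David's score within group-year-sex, percentage
#' outranked, high/low class), number of close adult female kin
#' (females), group tenure (males), mother id, natal group and the
#' animal-year identifier used by the cross-metric models.  Animals
#' whose rank cannot be assigned (no agonistic data, or a single
#' same-sex adult) get `NA` rank and are logged.
#'
#' @param tables A [demography_tables()] object.
#' @param min_age Adult age threshold (default 6).
#' @return Data frame with one row per individual-year; attribute
#'   `log` holds the drop/flag messages.
#' @export
covariate_table <- function(tables, min_age = 6) {
  ind <- tables$individuals
  gys <- unique(tables$effort[, c("group", "year")])
  gys <- gys[order(gys$group, gys$year), , drop = FALSE]
  A <- if (!is.null(tables$pedigree)) relatedness_matrix(tables$pedigree)
  log_lines <- character()
  rows <- list()
  for (r in seq_len(nrow(gys))) {
    g <- gys$group[r]; y <- gys$year[r]
    elig <- filter_eligible(tables, y, min_age)[[as.character(g)]]
    if (length(elig) < 2) {
      log_lines <- c(log_lines, sprintf(
        "group %s year %s: %d eligible adults, skipped", g, y, length(elig)))
      next
    }
    df <- data.frame(id = elig, group = g, year = y, stringsAsFactors = FALSE)
    m <- match(df$id, ind$id)
    df$sex <- ind$sex[m]
    df$age <- y - ind$birth_year[m]
    df$mother_id <- ind$mother_id[m]
    df$natal_group <- ind$natal_group[m]
    df$percent_outranked <- NA_real_
    df$rank_class <- NA_character_
    for (sx in c("F", "M")) {
      ids <- df$id[df$sex == sx]
      if (length(ids) < 2) {
        if (length(ids))
          log_lines <- c(log_lines, sprintf(
            "group %s year %s: single %s adult, rank undefined for %s",
            g, y, sx, ids))
        next
      }
      hier <- tryCatch(
        percent_outranked(infer_hierarchy(tables$agonistic, g, y, sx, ids)),
        isonet_no_rank_error = function(e) {
          log_lines <<- c(log_lines, sprintf(
            "group %s year %s sex %s: %s", g, y, sx, conditionMessage(e)))
          NULL
        })
      if (is.null(hier)) next
      k <- match(hier$id, df$id)
      df$percent_outranked[k] <- hier$percent_outranked
      df$rank_class[k] <- hier$rank_class
    }
    df$n_kin <- NA_integer_
    if (!is.null(A))
      for (k in which(df$sex == "F"))
        df$n_kin[k] <- count_close_adult_female_kin(tables, df$id[k], g, y,
                                                    min_age, A = A)
    df$tenure_years <- NA_integer_
    for (k in which(df$sex == "M"))
      df$tenure_years[k] <- tenure(tables$membership, df$id[k], g, y)
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  out$animal_year <- paste(out$id, out$year, sep = "_")
  rownames(out) <- NULL
  attr(out, "log") <- log_lines
  out
}

#' Pairwise collinearity screen over the z-scored metrics
#'
#' Pearson r^2 between every pair of z-scored metrics over the pooled
#' individual-years (pairwise-complete observations).  Metrics are
#' scanned in order and dropped when their r^2 with an already-retained
#' metric exceeds the threshold.
#'
#' @param metric_tab A [metric_table()] result (or the merged analysis
#'   table).
#' @param threshold r^2 cut-off (default 0.7).
#' @param metrics Metric names to consider.
#' @return List with `r2` (symmetric matrix, unit diagonal), `retained`
#'   and `dropped` metric names.
#' @export
collinearity_screen <- function(metric_tab, threshold = 0.7,
                                metrics = .isonet_metrics) {
  zcols <- paste0("z_", metrics)
  Z <- as.matrix(metric_tab[, zcols, drop = FALSE])
  colnames(Z) <- metrics
  r2 <- stats::cor(Z, use = "pairwise.complete.obs")^2
  retained <- character()
  for (m in metrics) {
    if (length(retained) && any(r2[m, retained] > threshold)) next
    retained <- c(retained, m)
  }
  list(r2 = r2, retained = retained, dropped = setdiff(metrics, retained))
}

# The three model families of the study.
.study_spec <- function(model, metric) {
  resp <- paste0("z_", metric)
  switch(as.character(model),
         "1" = model_spec(resp, fixed = c("age", "sex", "rank_class"),
                          random = c("id", "mother_id", "group", "year"),
                          subset = "all"),
         "2" = model_spec(resp, fixed = c("age", "rank_class", "n_kin"),
                          random = c("id", "mother_id", "group", "year"),
                          subset = "females_only"),
         "3" = model_spec(resp, fixed = c("age", "rank_class",
                                          "tenure_years"),
                          random = c("id", "mother_id", "group", "year",
                                     "natal_group"),
                          subset = "males_only"),
         .abort(paste("unknown model family:", model),
                "isonet_schema_error"))
}

#' Cross-metric association models
#'
#' For every ordered pair of metrics, regresses one z-scored metric on
#' another (both scaled to unit pooled variance, so coefficients are
#' standardised), with age, sex and rank as fixed effects and random
#' intercepts for year and for animal-year combinations.
#'
#' @param analysis_tab Merged metric + covariate table (see
#'   [run_pipeline()]).
#' @param metrics Metrics to cross (default all five retained).
#' @param mcmc An [mcmc_config()].
#' @param seed Base seed; pair `k` uses `seed + k`.
#' @return Data frame: `response`, `predictor`, standardised
#'   `coefficient`, `lower`, `upper`, `pMCMC`.
#' @export
cross_metric_models <- function(analysis_tab, metrics = .isonet_metrics,
                                mcmc = mcmc_config(), seed = mcmc$seed) {
  out <- list()
  k <- 0L
  for (resp in metrics) for (pred in metrics) {
    if (resp == pred) next
    k <- k + 1L
    d <- analysis_tab
    ry <- d[[paste0("z_", resp)]]
    px <- d[[paste0("z_", pred)]]
    if (is.null(ry) || is.null(px)) next
    sy <- stats::sd(ry, na.rm = TRUE)
    sx <- stats::sd(px, na.rm = TRUE)
    if (!isTRUE(sy > 0) || !isTRUE(sx > 0)) {
      warning(sprintf("degenerate variance for pair %s ~ %s; skipped",
                      resp, pred))
      next
    }
    d$.response <- ry / sy
    d$predictor <- px / sx
    cfg_k <- mcmc
    cfg_k$seed <- as.integer(seed + k)
    spec <- model_spec(".response",
                       fixed = c("age", "sex", "rank_class", "predictor"),
                       random = c("year", "animal_year"))
    fit <- suppressMessages(gibbs_fit(d, spec, cfg_k))
    row <- fit$fixed[fit$fixed$term == "predictor", ]
    out[[k]] <- data.frame(response = resp, predictor = pred,
                           coefficient = row$mean, lower = row$lower,
                           upper = row$upper, pMCMC = row$pMCMC,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the complete analysis pipeline
#'
#' Stages: load or simulate the tables; assemble each observed
#' group-year and build its grooming-rate network; compute the metric
#' table with within group-year z-scores; derive the covariates;
#' screen metric collinearity; fit the requested model families for
#' every retained metric (optionally after an interaction screen); fit
#' the cross-metric association models; write tidy CSV/JSON reports.
#' Re-running with the same configuration (and seed) reproduces every
#' output byte for byte.
#'
#' @param cfg An [analysis_config()].
#' @return Invisibly, a list: `tables`, `networks`, `metric_tab`,
#'   `analysis_tab`, `collinearity`, `fits` (named
#'   `model<k>_<metric>`), `cross_metric`, `log`, and `truth` when the
#'   input was simulated.
#' @export
run_pipeline <- function(cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"))
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  truth <- NULL
  if (inherits(cfg$input, "sim_config")) {
    sim <- simulate_dataset(cfg$input)
    tables <- sim$tables
    truth <- sim$truth
    note("input: simulated dataset, seed %d", cfg$input$seed)
  } else {
    tables <- load_tables(cfg$input)
    note("input: tables loaded from disk")
  }

  gys <- unique(tables$effort[, c("group", "year")])
  gys <- gys[order(gys$group, gys$year), , drop = FALSE]
  nets <- list()
  for (r in seq_len(nrow(gys))) {
    g <- gys$group[r]; y <- gys$year[r]
    ds <- tryCatch(assemble_group_year(tables, g, y),
                   isonet_degenerate_group_error = function(e) {
                     note("skipped group %s year %s: %s", g, y,
                          conditionMessage(e))
                     NULL
                   })
    if (is.null(ds)) next
    nets[[paste(g, y, sep = "_")]] <- build_rate_matrix(ds)
    note("network %s %s: %d adults, %d ties", g, y, length(ds$ids),
         sum(nets[[length(nets)]]$W > 0))
  }
  if (!length(nets))
    .abort("pipeline: no analysable group-years", "isonet_schema_error")

  metric_tab <- suppressWarnings(metric_table(nets))
  covs <- covariate_table(tables)
  log_lines <- c(log_lines, attr(covs, "log"))
  analysis_tab <- merge(metric_tab, covs, by = c("id", "group", "year"),
                        all.x = TRUE)
  analysis_tab <- analysis_tab[order(analysis_tab$group, analysis_tab$year,
                                     analysis_tab$id), , drop = FALSE]
  rownames(analysis_tab) <- NULL
  note("metric table: %d individual-years, %d individuals",
       nrow(analysis_tab), length(unique(analysis_tab$id)))
  note("null clustering coefficients: %d",
       sum(is.na(analysis_tab$clustering)))

  coll <- collinearity_screen(metric_tab, cfg$collinearity_threshold,
                              cfg$metrics)
  if (length(coll$dropped))
    note("collinearity screen dropped: %s",
         paste(coll$dropped, collapse = ", "))
  else note("collinearity screen: all metrics retained (max off-diagonal r2 = %.3f)",
            max(coll$r2[upper.tri(coll$r2)]))

  fits <- list()
  k <- 0L
  for (model in cfg$models) for (metric in coll$retained) {
    k <- k + 1L
    spec <- .study_spec(model, metric)
    mc <- cfg$mcmc
    mc$seed <- as.integer(cfg$seed + k)
    if (cfg$screen_interactions)
      spec <- interaction_screen(analysis_tab, spec, mc)
    fit <- suppressMessages(gibbs_fit(analysis_tab, spec, mc))
    nm <- sprintf("model%s_%s", model, metric)
    fits[[nm]] <- fit
    note("fit %s: n = %d (dropped %d), repeatability = %.3f", nm,
         fit$n_used, fit$n_dropped, fit$repeatability)
  }

  cross <- NULL
  if (cfg$cross_metrics) {
    cross <- cross_metric_models(analysis_tab, coll$retained, cfg$mcmc,
                                 seed = cfg$seed + 1000L)
    note("cross-metric models: %d pairs fitted", nrow(cross))
  }

  result <- list(tables = tables, networks = nets, metric_tab = metric_tab,
                 analysis_tab = analysis_tab, collinearity = coll,
                 fits = fits, cross_metric = cross, truth = truth,
                 log = log_lines)
  if (!is.null(cfg$out_dir)) write_report(result, cfg$out_dir)
  invisible(result)
}

#' Write the pipeline report bundle
#'
#' Emits `metrics.csv` (metric table), `analysis_table.csv`,
#' `collinearity.csv` (r^2 matrix), `variance_proportions.csv` and
#' `fixed_effects.csv` (tidy, one row per model x metric x term),
#' `fits/<model>_<metric>.json` (spec echo and full summaries),
#' `cross_metric.csv` and `run.log`.
#'
#' @param result A [run_pipeline()] result list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE, quote = FALSE, na = "")
  wcsv(result$metric_tab, "metrics.csv")
  wcsv(result$analysis_tab, "analysis_table.csv")
  r2 <- as.data.frame(result$collinearity$r2)
  r2 <- cbind(metric = rownames(r2), r2)
  wcsv(r2, "collinearity.csv")
  vp <- list()
  fx <- list()
  fit_dir <- file.path(dir, "fits")
  dir.create(fit_dir, showWarnings = FALSE)
  for (nm in names(result$fits)) {
    fit <- result$fits[[nm]]
    vp[[nm]] <- cbind(fit_id = nm, fit$components)
    fx[[nm]] <- cbind(fit_id = nm, fit$fixed)
    jsonlite::write_json(
      list(fit_id = nm,
           spec = unclass(fit$spec),
           n_used = fit$n_used, n_dropped = fit$n_dropped,
           fixed = fit$fixed, components = fit$components,
           repeatability = fit$repeatability),
      file.path(fit_dir, paste0(nm, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (length(vp)) wcsv(do.call(rbind, vp), "variance_proportions.csv")
  if (length(fx)) wcsv(do.call(rbind, fx), "fixed_effects.csv")
  if (!is.null(result$cross_metric)) wcsv(result$cross_metric,
                                          "cross_metric.csv")
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}
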