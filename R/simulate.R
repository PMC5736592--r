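# Synthetic focal-sampling data generator with known ground truth.
#
# The generative model mirrors the structure the variance-component
# models assume: every individual-year carries a latent grooming-giving
# and grooming-receiving propensity on the log scale,
#   eta = beta * x + a_individual + m_mother + g_group + y_year + e,
# and observed grooming seconds for a directed dyad are Poisson counts
# with mean rate baseline * exp(eta_give_i + eta_recv_j + dyad terms)
# scaled by the dyad's combined observation hours.

#' Configuration of the synthetic study
#'
#' Defaults emulate the study design the package targets: six social
#' groups of rhesus macaques, one followed for six consecutive years
#' (2010-2015) and five observed in a single year, roughly 430 adults
#' and 836 individual-years, female philopatry with male dispersal,
#' observation effort of mean 5.70 h (SD 1.98) per monkey, and latent
#' variance fractions of 0.25 individual, 0.10 maternal, 0.05 group,
#' 0.05 year, 0.55 residual.
#'
#' @param schedule Data frame `group`, `year`, `size`: the adults
#'   analysed per group-year.  Groups listed for several years are
#'   followed longitudinally.
#' @param sex_ratio Proportion of females among adults.
#' @param stay_prob Probability a group member is still present the
#'   next observed year of its group.
#' @param male_transfer_prob Probability an emigrated male joins a
#'   study group observed later (creating males sampled in two groups).
#' @param variance_fractions Named fractions (`animal`, `maternal`,
#'   `group`, `year`, `residual`) of the latent variance; must sum to 1.
#' @param total_latent_sd Total SD of the latent propensities (log
#'   scale).
#' @param fixed_effects_true Named true effects on the latent scale:
#'   `age` (per year, age centred at 12), `sex` (male offset), `rank`
#'   (high-rank offset), `kin` (per close adult female kin, females),
#'   `tenure` (per year of tenure, males).
#' @param dyad_modifiers Named log-scale lifts applied to a directed
#'   dyad's expected rate: `kin` when the pair has relatedness 0.5,
#'   `rank` when the recipient is high ranking.
#' @param baseline_rate Expected seconds per hour for an average
#'   directed dyad.
#' @param focal_hours_mean,focal_hours_sd Per-monkey observation hours,
#'   Normal truncated above 1 h.
#' @param bouts_dispersion Negative-binomial size for overdispersed
#'   grooming counts (grooming accumulates in bouts, so dyad-year
#'   totals are burstier than Poisson; default 0.2).  `Inf` gives pure
#'   Poisson seconds.
#' @param bouts_per_dyad Decided agonistic bouts per same-sex dyad-year.
#' @param upset_probability Probability the lower-ranking animal wins a
#'   bout.
#' @param partial_year_prob,juvenile_prob Rates at which extra
#'   partial-year residents and juveniles are added to group rosters
#'   (they exercise the eligibility filters and are excluded from
#'   analysis).
#' @param seed Integer master seed; stages use `seed`, `seed + 1`, ...
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(schedule = NULL,
                       sex_ratio = 277 / 429,
                       stay_prob = 0.8,
                       male_transfer_prob = 0.5,
                       variance_fractions = c(animal = 0.25, maternal = 0.10,
                                              group = 0.05, year = 0.05,
                                              residual = 0.55),
                       total_latent_sd = 0.6,
                       fixed_effects_true = c(age = -0.02, sex = -0.2,
                                              rank = 0.4, kin = 0.1,
                                              tenure = 0.05),
                       dyad_modifiers = c(kin = 0.8, rank = 0),
                       baseline_rate = 1.0,
                       focal_hours_mean = 5.70,
                       focal_hours_sd = 1.98,
                       bouts_dispersion = 0.2,
                       bouts_per_dyad = 3L,
                       upset_probability = 0.05,
                       partial_year_prob = 0.03,
                       juvenile_prob = 0.05,
                       seed = 1L) {
  if (is.null(schedule))
    schedule <- rbind(
      data.frame(group = "F", year = 2010:2015,
                 size = c(85, 100, 82, 94, 104, 96)),
      data.frame(group = c("HH", "KK", "R", "S", "V"),
                 year = c(2010, 2011, 2013, 2014, 2015),
                 size = c(43, 52, 85, 27, 68)))
  if (abs(sum(variance_fractions) - 1) > 1e-9)
    .abort("variance_fractions must sum to 1", "isonet_schema_error")
  if (any(schedule$size < 2))
    .abort("every scheduled group-year needs size >= 2",
           "isonet_schema_error")
  structure(list(schedule = schedule, sex_ratio = sex_ratio,
                 stay_prob = stay_prob,
                 male_transfer_prob = male_transfer_prob,
                 variance_fractions = variance_fractions,
                 total_latent_sd = total_latent_sd,
                 fixed_effects_true = fixed_effects_true,
                 dyad_modifiers = dyad_modifiers,
                 baseline_rate = baseline_rate,
                 focal_hours_mean = focal_hours_mean,
                 focal_hours_sd = focal_hours_sd,
                 bouts_dispersion = bouts_dispersion,
                 bouts_per_dyad = as.integer(bouts_per_dyad),
                 upset_probability = upset_probability,
                 partial_year_prob = partial_year_prob,
                 juvenile_prob = juvenile_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' A balanced-panel configuration for variance-recovery studies
#'
#' Convenience wrapper around [sim_config()]: `n_groups` groups of
#' equal size all observed for `n_years` consecutive years with no
#' turnover and no true fixed effects, giving a balanced panel of
#' `n_ids` individuals whose latent propensities carry exactly the
#' configured variance fractions.
#'
#' @param n_ids Total individuals (split equally over groups).
#' @param n_years,n_groups Panel dimensions.
#' @param ... Passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
panel_config <- function(n_ids = 300L, n_years = 6L, n_groups = 10L, ...) {
  size <- n_ids / n_groups
  if (size != round(size) || size < 2)
    .abort("n_ids must split into groups of >= 2", "isonet_schema_error")
  sched <- expand.grid(group = paste0("G", seq_len(n_groups)),
                       year = 2010L + seq_len(n_years) - 1L,
                       stringsAsFactors = FALSE)
  sched$size <- size
  sim_config(schedule = sched, stay_prob = 1, male_transfer_prob = 0,
             fixed_effects_true = c(age = 0, sex = 0, rank = 0, kin = 0,
                                    tenure = 0),
             partial_year_prob = 0, juvenile_prob = 0, ...)
}

.init_age <- function(n) sample(6:28, n, replace = TRUE,
                                prob = exp(-0.12 * (0:22)))

#' Simulate the population: demography, membership, pedigree
#'
#' Females are philopatric (natal group equals current group); adult
#' males are immigrants from one of eight natal groups who accrue
#' tenure while they stay and may later move to another study group.
#' Mothers are drawn from older females of the natal group (co-resident
#' subject females where possible, founder females otherwise); fathers
#' come from a smaller founder pool, so some full sibships arise.
#' A latent dominance propensity per individual fixes the rank order
#' within every group-year and sex.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_population`: `individuals`,
#'   `membership`, `pedigree`, `latent_ranks` (id, group, year, sex,
#'   latent_rank, rank_class) and the `dominance` propensity vector.
#' @export
simulate_population <- function(cfg) {
  set.seed(cfg$seed)
  sched <- cfg$schedule
  groups <- unique(sched$group)
  natal_pool <- c(groups, paste0("X", seq_len(max(0, 8 - length(groups)))))

  counter <- 0L
  inds <- list()
  mem <- list()
  new_ind <- function(sex, birth_year, natal_group) {
    counter <<- counter + 1L
    id <- sprintf("A%04d", counter)
    inds[[counter]] <<- data.frame(id = id, sex = sex,
                                   birth_year = as.integer(birth_year),
                                   mother_id = NA_character_,
                                   natal_group = natal_group,
                                   stringsAsFactors = FALSE)
    id
  }
  add_mem <- function(id, group, year, full_year = TRUE) {
    mem[[length(mem) + 1L]] <<- data.frame(id = id, group = group,
                                           year = as.integer(year),
                                           full_year = full_year,
                                           stringsAsFactors = FALSE)
  }
  make_male <- function(group, year, with_history) {
    age <- if (with_history) .init_age(1) else sample(7:15, 1)
    id <- new_ind("M", year - age, sample(setdiff(natal_pool, group), 1))
    if (with_history) {
      tn <- min(stats::rgeom(1, 0.35), 15L, age - 7L)
      if (tn > 0) for (py in (year - tn):(year - 1)) add_mem(id, group, py)
    }
    id
  }

  transfer_pool <- data.frame(id = character(), exit_year = integer(),
                              from = character(), stringsAsFactors = FALSE)
  roster_sex <- character() # named by id, filled as individuals are made

  for (g in groups) {
    yrs <- sort(sched$year[sched$group == g])
    roster <- character()
    for (y in yrs) {
      target <- sched$size[sched$group == g & sched$year == y]
      if (length(roster)) {
        stay <- stats::runif(length(roster)) < cfg$stay_prob
        gone <- roster[!stay]
        roster <- roster[stay]
        if (length(gone)) {
          gm <- gone[roster_sex[gone] == "M"]
          if (length(gm))
            transfer_pool <- rbind(transfer_pool,
                                   data.frame(id = gm, exit_year = y,
                                              from = g,
                                              stringsAsFactors = FALSE))
        }
      }
      need <- target - length(roster)
      if (need < 0) { # trim surplus
        drop <- sample(roster, -need)
        roster <- setdiff(roster, drop)
        need <- 0L
      }
      if (need > 0) {
        first_year <- !length(roster)
        # returning/transferring males first
        avail <- transfer_pool[transfer_pool$exit_year <= y &
                                 transfer_pool$from != g, , drop = FALSE]
        take <- avail$id[stats::runif(nrow(avail)) < cfg$male_transfer_prob]
        take <- utils::head(take, need)
        if (length(take)) {
          transfer_pool <- transfer_pool[!transfer_pool$id %in% take, ,
                                         drop = FALSE]
          roster <- c(roster, take)
          need <- need - length(take)
        }
        if (need > 0) {
          female <- stats::runif(need) < cfg$sex_ratio
          for (k in seq_len(need)) {
            id <- if (female[k]) {
              age <- if (first_year) .init_age(1) else 6L
              new_ind("F", y - age, g)
            } else make_male(g, y, with_history = first_year)
            roster_sex[id] <- if (female[k]) "F" else "M"
            roster <- c(roster, id)
          }
        }
      }
      for (id in roster) add_mem(id, g, y)
      # extra rows that exercise the eligibility filters
      n_part <- stats::rbinom(1, target, cfg$partial_year_prob)
      for (k in seq_len(n_part)) {
        sx <- if (stats::runif(1) < cfg$sex_ratio) "F" else "M"
        id <- new_ind(sx, y - .init_age(1), if (sx == "F") g else
          sample(setdiff(natal_pool, g), 1))
        add_mem(id, g, y, full_year = FALSE)
      }
      n_juv <- stats::rbinom(1, target, cfg$juvenile_prob)
      for (k in seq_len(n_juv)) {
        sx <- if (stats::runif(1) < 0.5) "F" else "M"
        id <- new_ind(sx, y - sample(3:5, 1), g)
        add_mem(id, g, y)
      }
    }
  }

  individuals <- do.call(rbind, inds)
  membership <- do.call(rbind, mem)
  roster_sex <- stats::setNames(individuals$sex, individuals$id)

  # --- pedigree -------------------------------------------------------
  founders <- list()
  founder_pool <- function(prefix, natal, n) {
    ids <- sprintf("%s_%s_%02d", prefix, natal, seq_len(n))
    for (fid in ids)
      founders[[fid]] <<- data.frame(id = fid, mother_id = NA_character_,
                                     father_id = NA_character_,
                                     stringsAsFactors = FALSE)
    ids
  }
  mother_of <- stats::setNames(rep(NA_character_, nrow(individuals)),
                               individuals$id)
  father_of <- mother_of
  for (ng in unique(individuals$natal_group)) {
    here <- individuals[individuals$natal_group == ng, , drop = FALSE]
    moms <- founder_pool("FM", ng, max(3L, round(nrow(here) / 2.5)))
    dads <- founder_pool("FF", ng, max(2L, round(nrow(here) / 6)))
    here <- here[order(here$birth_year), , drop = FALSE]
    for (r in seq_len(nrow(here))) {
      id <- here$id[r]
      subj_moms <- here$id[here$sex == "F" &
                             here$birth_year <= here$birth_year[r] - 6]
      if (here$sex[r] == "F" && length(subj_moms) &&
          stats::runif(1) < 0.5) {
        mother_of[id] <- if (length(subj_moms) == 1) subj_moms else
          sample(subj_moms, 1)
      } else {
        mother_of[id] <- if (length(moms) == 1) moms else sample(moms, 1)
      }
      father_of[id] <- if (length(dads) == 1) dads else sample(dads, 1)
    }
  }
  individuals$mother_id <- unname(mother_of[individuals$id])
  pedigree <- rbind(do.call(rbind, founders),
                    data.frame(id = individuals$id,
                               mother_id = individuals$mother_id,
                               father_id = unname(father_of[individuals$id]),
                               stringsAsFactors = FALSE))
  rownames(pedigree) <- NULL

  # --- latent dominance order ----------------------------------------
  dominance <- stats::setNames(stats::rnorm(nrow(individuals)),
                               individuals$id)
  lr <- list()
  for (r in seq_len(nrow(sched))) {
    g <- sched$group[r]; y <- sched$year[r]
    here <- membership[membership$group == g & membership$year == y &
                         membership$full_year, , drop = FALSE]
    age <- y - individuals$birth_year[match(here$id, individuals$id)]
    here <- here[age >= 6, , drop = FALSE]
    for (sx in c("F", "M")) {
      ids <- here$id[roster_sex[here$id] == sx]
      if (!length(ids)) next
      ord <- ids[order(-dominance[ids])]
      n <- length(ord)
      pct <- if (n > 1) 100 * (n - seq_len(n)) / (n - 1) else NA_real_
      lr[[length(lr) + 1L]] <- data.frame(
        id = ord, group = g, year = y, sex = sx,
        latent_rank = seq_len(n),
        rank_class = ifelse(is.na(pct), NA_character_,
                            ifelse(pct > 80, "high", "low")),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(individuals = individuals, membership = membership,
                 pedigree = pedigree, latent_ranks = do.call(rbind, lr),
                 dominance = dominance),
            class = "sim_population")
}

#' Simulate latent grooming propensities with known variance components
#'
#' For giving and receiving separately, draws the latent propensity of
#' every eligible adult individual-year as the sum of a true
#' fixed-effect part and Normal components for individual, mother,
#' current group, calendar year and residual, each with SD
#' `sqrt(fraction) * total_latent_sd`.
#'
#' @param pop A [simulate_population()] result.
#' @param cfg The [sim_config()] used to build `pop`.
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return Object of class `truth_record`: data frame of individual-years
#'   with true covariates (`age`, `sex`, `rank_class`, `n_kin`,
#'   `tenure_years`, `mother_id`, `natal_group`) and `eta_give`,
#'   `eta_recv`; the component draws are kept in
#'   `attr(, "components")` and the relatedness matrix in `attr(, "A")`.
#' @export
simulate_latents <- function(pop, cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  sched <- cfg$schedule
  ind <- pop$individuals
  mem <- pop$membership
  keep <- logical(nrow(mem))
  for (r in seq_len(nrow(sched)))
    keep <- keep | (mem$group == sched$group[r] & mem$year == sched$year[r])
  mem <- mem[keep & mem$full_year, , drop = FALSE]
  age <- mem$year - ind$birth_year[match(mem$id, ind$id)]
  mem <- mem[age >= 6, , drop = FALSE]

  tr <- data.frame(id = mem$id, group = mem$group, year = mem$year,
                   stringsAsFactors = FALSE)
  m <- match(tr$id, ind$id)
  tr$sex <- ind$sex[m]
  tr$age <- tr$year - ind$birth_year[m]
  tr$mother_id <- ind$mother_id[m]
  tr$natal_group <- ind$natal_group[m]
  lr <- pop$latent_ranks
  tr$rank_class <- lr$rank_class[match(paste(tr$id, tr$group, tr$year),
                                       paste(lr$id, lr$group, lr$year))]
  A <- relatedness_matrix(pop$pedigree)
  tables_min <- list(individuals = ind, membership = pop$membership,
                     pedigree = pop$pedigree)
  tr$n_kin <- NA_integer_
  fem <- which(tr$sex == "F")
  for (r in fem)
    tr$n_kin[r] <- count_close_adult_female_kin(tables_min, tr$id[r],
                                                tr$group[r], tr$year[r],
                                                A = A)
  tr$tenure_years <- NA_integer_
  mal <- which(tr$sex == "M")
  for (r in mal)
    tr$tenure_years[r] <- tenure(pop$membership, tr$id[r], tr$group[r],
                                 tr$year[r])

  fe <- cfg$fixed_effects_true
  fixed_part <- fe[["age"]] * (tr$age - 12) +
    fe[["sex"]] * (tr$sex == "M") +
    fe[["rank"]] * (!is.na(tr$rank_class) & tr$rank_class == "high") +
    fe[["kin"]] * ifelse(tr$sex == "F", tr$n_kin, 0) +
    fe[["tenure"]] * ifelse(tr$sex == "M", tr$tenure_years, 0)

  sds <- sqrt(cfg$variance_fractions) * cfg$total_latent_sd
  comp <- list()
  draw_channel <- function() {
    ids <- unique(tr$id)
    mothers <- unique(tr$mother_id)
    grps <- unique(tr$group)
    yrs <- unique(tr$year)
    a <- stats::setNames(stats::rnorm(length(ids), 0, sds[["animal"]]), ids)
    mo <- stats::setNames(stats::rnorm(length(mothers), 0, sds[["maternal"]]),
                          mothers)
    g <- stats::setNames(stats::rnorm(length(grps), 0, sds[["group"]]), grps)
    y <- stats::setNames(stats::rnorm(length(yrs), 0, sds[["year"]]),
                         as.character(yrs))
    e <- stats::rnorm(nrow(tr), 0, sds[["residual"]])
    list(a = a, m = mo, g = g, y = y, e = e,
         eta = unname(a[tr$id] + mo[tr$mother_id] + g[tr$group] +
                        y[as.character(tr$year)] + e))
  }
  comp$give <- draw_channel()
  comp$recv <- draw_channel()
  tr$eta_give <- fixed_part + comp$give$eta
  tr$eta_recv <- fixed_part + comp$recv$eta
  rownames(tr) <- NULL
  structure(tr, components = comp, A = A, class = c("truth_record",
                                                    "data.frame"))
}

.rtrunc_hours <- function(n, mean, sd, lower = 1) {
  h <- stats::rnorm(n, mean, sd)
  while (any(bad <- h <= lower))
    h[bad] <- stats::rnorm(sum(bad), mean, sd)
  h
}

#' Simulate focal-sampling grooming observations
#'
#' Observation hours per monkey are Normal(`focal_hours_mean`,
#' `focal_hours_sd`) truncated above 1 h.  For every ordered dyad in a
#' group-year the expected rate is
#' `baseline_rate * exp(eta_give_i + eta_recv_j + dyad modifiers)`
#' (kin lift for relatedness-0.5 pairs, optional lift toward
#' high-ranking recipients), and observed grooming seconds are Poisson
#' with mean `rate * (hours_i + hours_j)` (negative binomial when
#' `bouts_dispersion` is finite).
#'
#' @param truth A [simulate_latents()] result.
#' @param pop The matching [simulate_population()].
#' @param cfg The [sim_config()].
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @return List with `grooming` and `effort` data frames in the
#'   [demography_tables()] schemas.
#' @export
simulate_grooming <- function(truth, pop, cfg, seed = cfg$seed + 2L) {
  set.seed(seed)
  A <- attr(truth, "A")
  if (is.null(A)) A <- relatedness_matrix(pop$pedigree)
  grooming <- list()
  effort <- list()
  gys <- unique(truth[, c("group", "year")])
  for (r in seq_len(nrow(gys))) {
    g <- gys$group[r]; y <- gys$year[r]
    here <- truth[truth$group == g & truth$year == y, , drop = FALSE]
    n <- nrow(here)
    h <- .rtrunc_hours(n, cfg$focal_hours_mean, cfg$focal_hours_sd)
    effort[[length(effort) + 1L]] <-
      data.frame(id = here$id, group = g, year = y, hours_observed = h,
                 stringsAsFactors = FALSE)
    if (n < 2) next
    kin <- (abs(A[here$id, here$id] - 0.5) < 1e-9) * cfg$dyad_modifiers[["kin"]]
    # lift[i, j] applies when recipient j is high ranking
    high <- (!is.na(here$rank_class) & here$rank_class == "high") *
      cfg$dyad_modifiers[["rank"]]
    rank_lift <- matrix(high, n, n, byrow = TRUE)
    log_mu <- outer(here$eta_give, here$eta_recv, "+") + kin + rank_lift
    lambda <- cfg$baseline_rate * exp(log_mu) * outer(h, h, "+")
    diag(lambda) <- 0
    sec <- if (is.finite(cfg$bouts_dispersion))
      stats::rnbinom(n * n, size = cfg$bouts_dispersion,
                     mu = as.vector(lambda))
    else stats::rpois(n * n, as.vector(lambda))
    sec <- matrix(sec, n, n)
    diag(sec) <- 0
    nz <- which(sec > 0, arr.ind = TRUE)
    if (nrow(nz))
      grooming[[length(grooming) + 1L]] <-
        data.frame(actor = here$id[nz[, 1]], recipient = here$id[nz[, 2]],
                   group = g, year = y, seconds = sec[nz],
                   stringsAsFactors = FALSE)
  }
  empty_g <- data.frame(actor = character(), recipient = character(),
                        group = character(), year = integer(),
                        seconds = numeric(), stringsAsFactors = FALSE)
  list(grooming = if (length(grooming)) do.call(rbind, grooming) else empty_g,
       effort = do.call(rbind, effort))
}

#' Simulate agonistic win-loss records
#'
#' Every same-sex dyad of eligible adults in a scheduled group-year has
#' `bouts_per_dyad` decided bouts; the animal with the higher latent
#' dominance propensity wins each independently with probability
#' `1 - upset_probability`.
#'
#' @inheritParams simulate_grooming
#' @param seed RNG seed (default `cfg$seed + 3`).
#' @return Agonistic data frame (`winner`, `loser`, `group`, `year`,
#'   `count`).
#' @export
simulate_agonistic <- function(pop, cfg, seed = cfg$seed + 3L) {
  set.seed(seed)
  lr <- pop$latent_ranks
  out <- list()
  gys <- unique(lr[, c("group", "year")])
  for (r in seq_len(nrow(gys))) {
    g <- gys$group[r]; y <- gys$year[r]
    for (sx in c("F", "M")) {
      ids <- lr$id[lr$group == g & lr$year == y & lr$sex == sx]
      ids <- ids[order(-pop$dominance[ids])] # high to low
      n <- length(ids)
      if (n < 2) next
      pr <- t(utils::combn(n, 2)) # row: (higher, lower) indices
      hi_wins <- stats::rbinom(nrow(pr), cfg$bouts_per_dyad,
                               1 - cfg$upset_probability)
      lo_wins <- cfg$bouts_per_dyad - hi_wins
      res <- rbind(
        data.frame(winner = ids[pr[, 1]], loser = ids[pr[, 2]],
                   count = hi_wins, stringsAsFactors = FALSE),
        data.frame(winner = ids[pr[, 2]], loser = ids[pr[, 1]],
                   count = lo_wins, stringsAsFactors = FALSE))
      res <- res[res$count > 0, , drop = FALSE]
      if (nrow(res)) {
        res$group <- g
        res$year <- y
        out[[length(out) + 1L]] <- res[, c("winner", "loser", "group",
                                           "year", "count")]
      }
    }
  }
  if (!length(out))
    return(data.frame(winner = character(), loser = character(),
                      group = character(), year = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Runs [simulate_population()], [simulate_latents()],
#' [simulate_grooming()] and [simulate_agonistic()] and bundles the
#' result as validated [demography_tables()] plus the truth record.
#' Bit-identical for a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_dataset`: `tables`
#'   ([demography_tables()]), `truth` ([simulate_latents()] result),
#'   `population` and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  pop <- simulate_population(cfg)
  truth <- simulate_latents(pop, cfg)
  obs <- simulate_grooming(truth, pop, cfg)
  ago <- simulate_agonistic(pop, cfg)
  tables <- demography_tables(pop$individuals, pop$membership,
                              obs$grooming, obs$effort, ago, pop$pedigree)
  structure(list(tables = tables, truth = truth, population = pop,
                 config = cfg), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$truth), "eligible individual-years,",
      length(unique(x$truth$id)), "adults,",
      nrow(x$config$schedule), "group-years (seed",
      x$config$seed, ")\n")
  invisible(x)
}

#' Write a synthetic dataset (and its truth) to CSV files
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written (tables plus `truth.csv`).
#' @export
write_sim_dataset <- function(sim, dir) {
  paths <- write_tables(sim$tables, dir)
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(as.data.frame(sim$truth), tp, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(c(paths, truth = tp))
}
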