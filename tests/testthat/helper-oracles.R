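# Fixtures built in code and independent brute-force oracles.

# Wrap a weight matrix as a group-year network (unit-test shortcut).
make_net <- function(W, ids = NULL, group = "G", year = 2010L) {
  n <- nrow(W)
  if (is.null(ids)) ids <- paste0("a", seq_len(n))
  dimnames(W) <- list(ids, ids)
  structure(list(ids = ids, W = W, effort = stats::setNames(rep(1, n), ids),
                 group = group, year = year),
            class = "group_year_network")
}

# Random directed weighted graph on n nodes with m directed ties.
rand_W <- function(n, m = NULL) {
  W <- matrix(0, n, n)
  off <- setdiff(seq_len(n * n), seq(1, n * n, n + 1))
  if (is.null(m)) m <- sample(seq_len(length(off)), 1)
  W[sample(off, m)] <- stats::runif(m, 0.5, 2)
  W
}

# Exhaustive-path betweenness oracle: enumerate every simple path per
# ordered pair, keep the shortest (length = sum of 1/weight), count the
# fraction passing through each interior node.
brute_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- Inf
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- list()
    rec <- function(path, len) {
      u <- path[length(path)]
      if (u == t) {
        paths[[length(paths) + 1L]] <<- list(path = path, len = len)
        return()
      }
      for (v in which(is.finite(L[u, ])))
        if (!(v %in% path)) rec(c(path, v), len + L[u, v])
    }
    rec(s, 0)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    short <- paths[lens <= min(lens) + tol]
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(short, function(p) v %in% p$path, logical(1)))
      bc[v] <- bc[v] + through / length(short)
    }
  }
  bc
}

# Clustering oracle: count connected partner pairs directly.
brute_clustering <- function(W, i) {
  A <- (W > 0) | (t(W) > 0)
  partners <- setdiff(which(A[i, ]), i)
  k <- length(partners)
  if (k < 2) return(NA_real_)
  pairs <- utils::combn(partners, 2)
  sum(apply(pairs, 2, function(p) A[p[1], p[2]])) / choose(k, 2)
}

# Closed-form one-way ANOVA repeatability for a balanced design.
anova_repeatability <- function(y, id) {
  k <- unique(table(id))
  stopifnot(length(k) == 1)
  av <- stats::anova(stats::lm(y ~ factor(id)))
  msa <- av[1, "Mean Sq"]
  mse <- av[2, "Mean Sq"]
  va <- (msa - mse) / k
  va / (va + mse)
}

# Three-adult toy study: A grooms B, B grooms A and C, plus a juvenile.
tiny_tables <- function() {
  demography_tables(
    individuals = data.frame(
      id = c("A", "B", "C", "J"), sex = c("F", "F", "M", "F"),
      birth_year = c(2000L, 2002L, 1995L, 2007L),
      mother_id = c(NA, "A", NA, "B"),
      natal_group = c("G1", "G1", "G2", "G1"),
      stringsAsFactors = FALSE),
    membership = data.frame(
      id = c("A", "B", "C", "J"), group = "G1", year = 2012L,
      full_year = TRUE, stringsAsFactors = FALSE),
    grooming = data.frame(
      actor = c("A", "B", "B", "J"), recipient = c("B", "A", "C", "A"),
      group = "G1", year = 2012L, seconds = c(120, 60, 30, 300),
      stringsAsFactors = FALSE),
    effort = data.frame(
      id = c("A", "B", "C", "J"), group = "G1", year = 2012L,
      hours_observed = c(4, 6, 5, 5), stringsAsFactors = FALSE),
    agonistic = data.frame(
      winner = c("A", "A", "B"), loser = c("B", "B", "A"), group = "G1",
      year = 2012L, count = c(3L, 2L, 1L), stringsAsFactors = FALSE),
    pedigree = data.frame(
      id = c("A", "B", "C", "J"), mother_id = c(NA, "A", NA, "B"),
      father_id = NA_character_, stringsAsFactors = FALSE))
}

# Small simulated study used by several pipeline tests: one group
# followed three years plus one single-year group.
tiny_sim_config <- function(seed = 5L, ...) {
  sim_config(schedule = rbind(
    data.frame(group = "F", year = 2010:2012, size = 14),
    data.frame(group = "V", year = 2011, size = 10)),
    seed = seed, ...)
}

short_mcmc <- function(seed = 1L) mcmc_config(n_iter = 2600L,
                                              burn_in = 600L, thin = 4L,
                                              seed = seed)
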