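# Directed weighted grooming-rate networks and the five isolation metrics.

#' Build the directed grooming-rate matrix for a group-year
#'
#' The tie from animal i to animal j is the rate at which i grooms j, in
#' seconds per hour: total seconds of i-grooms-j bouts divided by the
#' dyad's combined observation time (hours of i plus hours of j).
#' Unobserved dyads get rate 0; direction is preserved.
#'
#' @param dataset A `group_year_dataset` from [assemble_group_year()].
#' @return An object of class `group_year_network`: list with `ids`,
#'   `W` (n x n rate matrix, zero diagonal), `effort`, `group`, `year`.
#' @export
build_rate_matrix <- function(dataset) {
  ids <- dataset$ids
  n <- length(ids)
  hours <- dataset$effort[ids]
  if (anyNA(hours) || any(hours <= 0))
    .abort(paste("missing or non-positive observation effort for:",
                 paste(ids[is.na(hours) | hours <= 0], collapse = ", ")),
           "isonet_schema_error")
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  grm <- dataset$grooming
  if (nrow(grm)) {
    sec <- tapply(grm$seconds, list(factor(grm$actor, ids),
                                    factor(grm$recipient, ids)), sum)
    sec[is.na(sec)] <- 0
    W <- sec / outer(unname(hours), unname(hours), "+")
    dimnames(W) <- list(ids, ids)
  }
  diag(W) <- 0
  structure(list(ids = ids, W = W, effort = hours,
                 group = dataset$group, year = dataset$year),
            class = "group_year_network")
}

#' @export
print.group_year_network <- function(x, ...) {
  cat("group_year_network: group", x$group, "year", x$year, "-",
      length(x$ids), "nodes,", sum(x$W > 0), "directed ties\n")
  invisible(x)
}

.net_index <- function(net, id) {
  i <- match(id, net$ids)
  if (is.na(i)) .abort(paste("unknown id:", id), "isonet_schema_error")
  i
}

#' Strength metrics: grooming received and given
#'
#' Instrength is the total rate at which an individual is groomed by
#' others (column sum of the rate matrix); outstrength the total rate at
#' which it grooms others (row sum).
#'
#' @param net A `group_year_network`.
#' @param id Optional single id; when omitted, named vector for all.
#' @return Named numeric vector (or scalar when `id` given).
#' @export
instrength <- function(net, id = NULL) {
  v <- colSums(net$W)
  if (is.null(id)) v else unname(v[.net_index(net, id)])
}

#' @rdname instrength
#' @export
outstrength <- function(net, id = NULL) {
  v <- rowSums(net$W)
  if (is.null(id)) v else unname(v[.net_index(net, id)])
}

#' Weighted directed betweenness centrality
#'
#' Number of shortest paths between other pairs of animals that pass
#' through each individual.  Tie weights (rates) are converted to path
#' lengths as 1/weight; absent ties are non-traversable.  Shortest paths
#' are found by Dijkstra's algorithm and equal-length ties are counted
#' fractionally using Brandes' dependency accumulation.  Endpoints are
#' excluded; disconnected pairs contribute nothing.
#'
#' @param net A `group_year_network`.
#' @param tol Absolute tolerance for treating two path lengths as equal.
#' @return Named numeric vector of betweenness scores.
#' @export
betweenness <- function(net, tol = 1e-12) {
  W <- net$W
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- Inf
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    sigma <- numeric(n)
    sigma[s] <- 1
    preds <- vector("list", n)
    visited <- logical(n)
    order_settled <- integer(0)
    repeat {
      d <- dist
      d[visited] <- Inf
      u <- which.min(d)
      if (!is.finite(d[u])) break
      visited[u] <- TRUE
      order_settled <- c(order_settled, u)
      for (v in which(is.finite(L[u, ]))) {
        if (visited[v]) next
        alt <- dist[u] + L[u, v]
        if (alt < dist[v] - tol) {
          dist[v] <- alt
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        } else if (abs(alt - dist[v]) <= tol) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_settled)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc, net$ids)
}

#' Clustering coefficient
#'
#' Proportion of an individual's grooming partners (in either direction)
#' that are themselves partners with each other.  Undefined (`NA`) for
#' animals with fewer than two distinct partners.
#'
#' @param net A `group_year_network`.
#' @param id Optional single id; when omitted, named vector for all.
#' @return Numeric in \[0, 1\] or `NA`.
#' @export
clustering_coefficient <- function(net, id = NULL) {
  A <- (net$W > 0) | (t(net$W) > 0) # partner = any grooming either way
  one <- function(i) {
    partners <- which(A[i, ])
    k <- length(partners)
    if (k < 2) return(NA_real_)
    sub <- A[partners, partners, drop = FALSE]
    sum(sub[upper.tri(sub)]) / choose(k, 2)
  }
  if (!is.null(id)) return(one(.net_index(net, id)))
  stats::setNames(vapply(seq_along(net$ids), one, numeric(1)), net$ids)
}

#' Eigenvector centrality on the symmetrised network
#'
#' Principal eigenvector of S = W + t(W), computed by power iteration,
#' entries non-negative and scaled to unit Euclidean norm.  Direction is
#' deliberately ignored: the metric captures being connected to
#' well-connected partners, regardless of who grooms whom.
#'
#' @param net A `group_year_network`.
#' @param tol Relative convergence tolerance of the power iteration.
#' @param max_iter Iteration cap.
#' @return Named numeric vector; all zeros (with a warning) for an
#'   edgeless network.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 100000L) {
  S <- net$W + t(net$W)
  n <- nrow(S)
  if (all(S == 0)) {
    warning("network has no grooming ties; eigenvector centrality all zero")
    return(stats::setNames(numeric(n), net$ids))
  }
  # diagonal shift keeps the eigenvectors but makes the principal
  # eigenvalue strictly dominant (power iteration would oscillate on
  # bipartite-like graphs where the most negative eigenvalue matches it)
  shift <- max(rowSums(S))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    v_new <- as.vector(S %*% v) + shift * v
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) { # start vector orthogonal to range; perturb
      v <- abs(v) + stats::runif(n, 0, 1e-6)
      v <- v / sqrt(sum(v^2))
      next
    }
    v_new <- v_new / nrm
    if (sqrt(sum((v_new - v)^2)) < tol * sqrt(sum(v_new^2))) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v <- abs(v) # principal eigenvector of a non-negative matrix
  stats::setNames(v / sqrt(sum(v^2)), net$ids)
}

#' Z-scores within a single group-year
#'
#' Standardises one metric over the adults of one group-year: subtract
#' the mean and divide by the sample standard deviation (n - 1) of the
#' non-missing entries.  Missing values (null clustering coefficients)
#' stay missing.  With fewer than two non-missing values or zero spread,
#' all z-scores are set to 0 with a warning so the animals stay in the
#' panel.
#'
#' @param values Numeric vector (possibly with `NA`s) of one metric for
#'   one group-year.
#' @return Numeric vector of z-scores, same names and `NA` pattern.
#' @export
zscore_within <- function(values) {
  ok <- !is.na(values)
  out <- values
  if (sum(ok) < 2 || stats::sd(values[ok]) == 0) {
    warning("degenerate metric spread in group-year; z-scores set to 0")
    out[ok] <- 0
    return(out)
  }
  out[ok] <- (values[ok] - mean(values[ok])) / stats::sd(values[ok])
  out
}

#' All five isolation metrics for one network
#'
#' @param net A `group_year_network`.
#' @return Data frame with one row per individual: `id`, `group`,
#'   `year`, `instrength`, `outstrength`, `betweenness`, `clustering`,
#'   `eigenvector`.
#' @export
network_metrics <- function(net) {
  data.frame(id = net$ids, group = net$group, year = net$year,
             instrength = unname(instrength(net)),
             outstrength = unname(outstrength(net)),
             betweenness = unname(betweenness(net)),
             clustering = unname(clustering_coefficient(net)),
             eigenvector = unname(eigenvector_centrality(net)),
             stringsAsFactors = FALSE)
}

.isonet_metrics <- c("instrength", "outstrength", "betweenness",
                     "clustering", "eigenvector")

#' Metric table with within group-year z-scores
#'
#' Computes the five metrics for every network and standardises each
#' metric within its group-year ([zscore_within()]), yielding the tidy
#' individual-year table used by all downstream models.
#'
#' @param nets List of `group_year_network` objects (one per group-year).
#' @return Data frame, one row per individual-year: raw metrics plus
#'   `z_instrength` ... `z_eigenvector`.
#' @export
metric_table <- function(nets) {
  raw <- do.call(rbind, lapply(nets, network_metrics))
  gy <- interaction(raw$group, raw$year, drop = TRUE)
  for (m in .isonet_metrics) {
    z <- stats::ave(raw[[m]], gy, FUN = function(v)
      suppressWarnings(zscore_within(v)))
    raw[[paste0("z_", m)]] <- z
  }
  rownames(raw) <- NULL
  raw
}

#' Export a network as an edge list
#'
#' @param net A `group_year_network`.
#' @return Data frame `actor`, `recipient`, `rate` for the non-zero
#'   directed ties.
#' @export
network_edgelist <- function(net) {
  idx <- which(net$W > 0, arr.ind = TRUE)
  data.frame(actor = net$ids[idx[, 1]], recipient = net$ids[idx[, 2]],
             rate = net$W[idx], stringsAsFactors = FALSE)
}
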