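test_that("grooming rates divide seconds by the dyad's combined hours", {
  tabs <- tiny_tables()
  net <- build_rate_matrix(assemble_group_year(tabs, "G1", 2012))
  expect_equal(net$W["A", "B"], 120 / (4 + 6)) # 12 s/h
  expect_equal(net$W["B", "A"], 60 / (4 + 6))
  expect_equal(net$W["B", "C"], 30 / (6 + 5))
  expect_equal(net$W["C", "B"], 0) # direction preserved
  expect_true(all(diag(net$W) == 0))
  # missing effort is an error
  ds <- assemble_group_year(tabs, "G1", 2012)
  ds$effort <- ds$effort[c("A", "B")]
  expect_error(build_rate_matrix(ds), class = "isonet_schema_error")
})

test_that("strengths are row/column sums and conserve total weight", {
  W <- matrix(c(0, 2, 0,
                1, 0, 3,
                0, 0, 0), 3, 3, byrow = TRUE)
  net <- make_net(W, c("A", "B", "C"))
  expect_equal(outstrength(net, "B"), 4)
  expect_equal(instrength(net, "B"), 2)
  expect_error(instrength(net, "Z"), class = "isonet_schema_error")
  set.seed(81)
  for (k in 1:25) {
    net <- make_net(rand_W(sample(3:8, 1)))
    expect_equal(sum(instrength(net)), sum(net$W))
    expect_equal(sum(outstrength(net)), sum(net$W))
  }
})

test_that("betweenness matches hand-worked cases", {
  chain <- make_net(matrix(c(0, 1, 0,
                             0, 0, 1,
                             0, 0, 0), 3, 3, byrow = TRUE), c("A", "B", "C"))
  expect_equal(unname(betweenness(chain)), c(0, 1, 0))
  tri <- make_net(matrix(1, 3, 3) - diag(3))
  expect_equal(unname(betweenness(tri)), c(0, 0, 0))
})

test_that("betweenness and clustering match brute-force enumeration", {
  set.seed(20)
  for (k in 1:60) {
    W <- rand_W(sample(3:6, 1))
    net <- make_net(W)
    expect_equal(unname(betweenness(net)), brute_betweenness(W),
                 tolerance = 1e-12)
    cc <- unname(clustering_coefficient(net))
    oracle <- vapply(seq_len(nrow(W)), function(i) brute_clustering(W, i),
                     numeric(1))
    expect_equal(cc, oracle)
  }
})

test_that("betweenness agrees with igraph on weighted digraphs", {
  set.seed(21)
  for (k in 1:40) {
    W <- rand_W(sample(4:9, 1))
    g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                             weighted = TRUE)
    expect_equal(unname(betweenness(make_net(W))),
                 unname(igraph::betweenness(g, directed = TRUE,
                                            weights = 1 / igraph::E(g)$weight)),
                 tolerance = 1e-9)
  }
})

test_that("clustering handles the defined edge cases", {
  # three mutually connected partners -> 1
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- 1
  W[2, 3] <- W[3, 4] <- W[4, 2] <- 1
  expect_equal(unname(clustering_coefficient(make_net(W), "a1")), 1)
  # star centre with unconnected leaves -> 0, leaves have 1 partner -> NA
  S <- matrix(0, 4, 4)
  S[1, 2:4] <- 1
  cc <- clustering_coefficient(make_net(S))
  expect_equal(unname(cc), c(0, NA, NA, NA))
})

test_that("eigenvector centrality satisfies its defining equation", {
  # complete equal-weight graph: all entries equal
  net <- make_net(matrix(1, 5, 5) - diag(5))
  v <- eigenvector_centrality(net)
  expect_equal(unname(v), rep(1 / sqrt(5), 5))
  set.seed(33)
  for (k in 1:30) {
    W <- rand_W(sample(3:9, 1))
    net <- make_net(W)
    v <- unname(eigenvector_centrality(net))
    S <- W + t(W)
    lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    expect_lt(max(abs(S %*% v - lam * v)), 1e-8)
    expect_equal(sum(v^2), 1)
    expect_true(all(v >= 0))
    # scale invariance
    net2 <- make_net(2 * W)
    expect_equal(unname(eigenvector_centrality(net2)), v, tolerance = 1e-7)
  }
  expect_warning(eigenvector_centrality(make_net(matrix(0, 3, 3))),
                 "no grooming ties")
})

test_that("all metrics are invariant to permutation of id order", {
  set.seed(47)
  for (k in 1:10) {
    n <- sample(4:7, 1)
    W <- rand_W(n)
    ids <- paste0("a", 1:n)
    net <- make_net(W, ids)
    p <- sample(n)
    netp <- make_net(W[p, p], ids[p])
    for (f in list(instrength, outstrength, betweenness,
                   clustering_coefficient, eigenvector_centrality))
      expect_equal(f(net)[ids], f(netp)[ids], tolerance = 1e-8)
  }
})

test_that("z-scores follow the sample-SD definition and degenerate rules", {
  expect_equal(zscore_within(c(1, 3)),
               c(-1, 1) / sqrt(2), tolerance = 1e-6)
  expect_warning(z <- zscore_within(c(2, 2, 2)), "degenerate")
  expect_equal(z, c(0, 0, 0))
  z <- zscore_within(c(0, 0, 0, 8))
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_equal(max(z), 1.5)
  expect_equal(min(z), -0.5)
  # missing entries stay missing and are excluded from the moments
  z <- zscore_within(c(1, NA, 3))
  expect_true(is.na(z[2]))
  expect_equal(z[c(1, 3)], c(-1, 1) / sqrt(2), tolerance = 1e-6)
})

test_that("metric table z-columns have mean 0 and sample SD 1 per group-year", {
  sim <- simulate_dataset(tiny_sim_config(seed = 9))
  gys <- unique(sim$tables$effort[, c("group", "year")])
  nets <- lapply(seq_len(nrow(gys)), function(r)
    build_rate_matrix(assemble_group_year(sim$tables, gys$group[r],
                                          gys$year[r])))
  mt <- metric_table(nets)
  gy <- interaction(mt$group, mt$year, drop = TRUE)
  for (z in paste0("z_", c("instrength", "outstrength", "betweenness",
                           "clustering", "eigenvector"))) {
    for (lev in levels(gy)) {
      v <- mt[[z]][gy == lev]
      v <- v[!is.na(v)]
      if (length(v) < 2 || stats::sd(v) == 0) next
      expect_equal(mean(v), 0, tolerance = 1e-10)
      expect_equal(stats::sd(v), 1, tolerance = 1e-10)
    }
  }
  expect_true(all(mt$clustering >= 0 & mt$clustering <= 1, na.rm = TRUE))
})

test_that("edge-list export lists exactly the non-zero directed ties", {
  tabs <- tiny_tables()
  net <- build_rate_matrix(assemble_group_year(tabs, "G1", 2012))
  el <- network_edgelist(net)
  expect_equal(nrow(el), 3)
  expect_equal(el$rate[el$actor == "A" & el$recipient == "B"], 12)
})
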