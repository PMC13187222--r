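# Item network, walktrap communities, centralities, multi-strategy selection.

test_that("build_network applies a strict threshold and tracks isolated items", {
  expect_equal(nrow(build_network(diag(5))$edges), 0)
  expect_length(build_network(diag(5))$isolated_items, 5)

  corr <- matrix(0.8, 3, 3); diag(corr) <- 1
  net <- build_network(corr, 0.7)
  expect_equal(nrow(net$edges), 3)
  expect_equal(unname(centralities(net)$degree), c(2, 2, 2))

  corr[1, 2] <- corr[2, 1] <- 0.7   # exactly at the threshold: excluded
  expect_equal(nrow(build_network(corr, 0.7)$edges), 2)

  asym <- matrix(c(1, 0.8, 0.2, 1), 2)
  expect_error(build_network(asym), "symmetric")
  bad_diag <- matrix(c(2, 0.1, 0.1, 1), 2)
  expect_error(build_network(bad_diag), "unit diagonal")
})

test_that("near-unity threshold empties the edge set when all |r| < 1", {
  set.seed(9)
  x <- matrix(rnorm(100 * 6), 100)
  corr <- stats::cor(x)
  net <- build_network(corr, threshold = 1 - 1e-9)
  expect_equal(nrow(net$edges), 0)
})

test_that("walktrap recovers planted structure and beats the singleton partition", {
  adj <- matrix(0, 6, 6)
  tri <- function(i) adj[i, i] <<- 0.8 * (1 - diag(3))
  tri(1:3); tri(4:6)
  net <- net_from_adjacency(adj)
  part <- walktrap_communities(net)
  expect_equal(part$n_communities, 2)
  expect_equal(sort(unname(part$sizes)), c(3, 3))

  adj[3, 4] <- adj[4, 3] <- 0.75   # barbell
  net2 <- net_from_adjacency(adj)
  part2 <- walktrap_communities(net2)
  expect_equal(part2$n_communities, 2)
  a2 <- as.matrix(igraph::as_adjacency_matrix(net2$graph, attr = "weight",
                                              sparse = FALSE))
  memb <- part2$assignment[rownames(a2)]
  expect_equal(modularity_oracle(a2, memb), max_modularity_exhaustive(a2),
               tolerance = 1e-10)
  expect_gte(part2$modularity, modularity_oracle(a2, seq_len(6)))
  expect_error(walktrap_communities(net2, steps = 0), "steps")
})

test_that("walktrap modularity is within 0.05 of the exhaustive maximum on small graphs", {
  set.seed(10)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    adj <- random_weighted_graph(n)
    net <- net_from_adjacency(adj)
    part <- walktrap_communities(net)
    a <- as.matrix(igraph::as_adjacency_matrix(net$graph, attr = "weight",
                                               sparse = FALSE))
    memb <- part$assignment[rownames(a)]
    q <- modularity_oracle(a, memb)
    q_best <- max_modularity_exhaustive(a)
    expect_gte(q, q_best - 0.05)
    expect_gte(q, modularity_oracle(a, seq_len(nrow(a))))  # >= singletons
  }
})

test_that("centralities match star/cycle closed forms and an eigen oracle", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.8
  cs <- centralities(net_from_adjacency(star))
  expect_equal(unname(cs$degree[c("IP1", "IP2")]), c(4L, 1L))
  expect_equal(unname(cs$eigenvector["IP1"]), 1)

  cyc <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; cyc[i, j] <- cyc[j, i] <- 0.8 }
  ec <- centralities(net_from_adjacency(cyc))$eigenvector
  expect_equal(unname(ec), rep(1, 5), tolerance = 1e-10)

  set.seed(11)
  adj <- random_weighted_graph(7, p_edge = 0.6)
  net <- net_from_adjacency(adj)
  ec2 <- centralities(net)$eigenvector
  a <- as.matrix(igraph::as_adjacency_matrix(net$graph, attr = "weight",
                                             sparse = FALSE))
  comp <- igraph::components(net$graph)$membership
  for (cc in unique(comp)) {
    idx <- names(comp)[comp == cc]
    if (length(idx) < 2) next
    # power-iteration oracle
    v <- rep(1, length(idx))
    for (it in 1:500) v <- as.numeric(a[idx, idx] %*% v / sqrt(sum((a[idx, idx] %*% v)^2)))
    v <- abs(v) / max(abs(v))
    expect_lt(max(abs(ec2[idx] - v)), 1e-8)
  }
})

test_that("selection is the deduplicated union with provenance and covers communities", {
  # single dominant item picked by all four strategies
  corr <- matrix(0.85, 2, 2); diag(corr) <- 1
  dimnames(corr) <- list(c("IP1", "IP2"), c("IP1", "IP2"))
  net <- build_network(corr)
  part <- walktrap_communities(net)
  cent <- centralities(net)
  sel <- select_items(c(IP1 = 2, IP2 = 0.1), net, part, cent,
                      min_community_size = 2, k_isolated = 1, k_hubs = 1,
                      k_top = 1)
  expect_equal(sel$selected[1], "IP1")
  expect_setequal(sel$provenance$IP1,
                  c("community_representative", "central_hub",
                    "top_discriminator"))

  # planted 12-item fixture with hand-enumerable outcome
  ids <- paste0("IP", 1:12)
  corr <- diag(12)
  dimnames(corr) <- list(ids, ids)
  block <- function(i) corr[i, i] <<- pmax(corr[i, i], 0.8)
  block(1:4)          # community A
  block(5:8)          # community B
  corr[9, 10] <- corr[10, 9] <- 0.75   # community C (pair)
  diag(corr) <- 1
  # IP11, IP12 isolated
  d <- c(IP1 = 1.0, IP2 = 1.2, IP3 = 0.9, IP4 = 1.1,
         IP5 = 1.6, IP6 = 1.4, IP7 = 1.3, IP8 = 1.2,
         IP9 = 0.8, IP10 = 0.7, IP11 = 2.2, IP12 = 1.9)
  net <- build_network(corr)
  part <- walktrap_communities(net)
  cent <- centralities(net)
  sel <- select_items(d, net, part, cent, min_community_size = 2,
                      k_isolated = 2, k_hubs = 2, k_top = 1)
  # hand enumeration: representatives IP2, IP5, IP9; isolated IP11, IP12;
  # top overall IP11; hubs are two networked items (whatever centrality
  # ranks first, they are already a subset of the network nodes)
  expect_true(all(c("IP2", "IP5", "IP9", "IP11", "IP12") %in% sel$selected))
  expect_equal(sel$communities_covered, 3)
  expect_true(all(lengths(sel$provenance) >= 1))
  expect_setequal(sel$selected, unique(unlist(sel$strategies)))

  # invariance to item order permutation
  set.seed(12)
  perm <- sample(ids)
  corr_p <- corr[perm, perm]
  net_p <- build_network(corr_p)
  sel_p <- select_items(d, net_p, walktrap_communities(net_p),
                        centralities(net_p), min_community_size = 2,
                        k_isolated = 2, k_hubs = 2, k_top = 1)
  expect_setequal(sel_p$selected, sel$selected)
})

test_that("network export writes edge lists and GraphML", {
  corr <- matrix(0.8, 3, 3); diag(corr) <- 1
  net <- build_network(corr)
  csv <- tempfile(fileext = ".csv")
  write_network(net, csv)
  edges <- read.csv(csv)
  expect_equal(nrow(edges), 3)
  expect_named(edges, c("item_a", "item_b", "weight"))
  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
})
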