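test_that("perfect correlation yields a category-8 positive edge", {
  set.seed(1)
  x <- stats::rnorm(20)
  X <- cbind(a = x, b = x, c = stats::rnorm(20))
  rownames(X) <- paste0("s", 1:20)
  net <- build_cooccurrence(X, alpha = 0.05)
  e <- net$edges[net$edges$from == "a" & net$edges$to == "b", ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$r, 1, tolerance = 1e-12)
  expect_equal(e$sign, "positive")
  expect_equal(e$category, 8L)
})

test_that("edge categories follow the p-value decade bins", {
  expect_equal(edge_category(c(0.03, 0.01, 0.0005, 1e-8, 1e-9)),
               c(1L, 2L, 3L, 8L, 8L))
  expect_equal(edge_category(10^-(2:8) * 0.99), 2:8)
})

test_that("edge sets shrink with alpha and ignore sample/species order", {
  set.seed(2)
  X <- matrix(stats::rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("s", 1:30), paste0("f", 1:8)))
  X[, 2] <- X[, 1] * 0.8 + stats::rnorm(30, sd = 0.5)
  net05 <- build_cooccurrence(X, alpha = 0.05)
  net01 <- build_cooccurrence(X, alpha = 0.01)
  key <- function(net) paste(net$edges$from, net$edges$to)
  expect_true(all(key(net01) %in% key(net05)))
  # permuted rows and columns: identical edges up to ordering
  net_p <- build_cooccurrence(X[sample(30), sample(8)], alpha = 0.05)
  expect_equal(sort(key(net_p)), sort(key(net05)))
  m <- match(key(net05), key(net_p))
  expect_equal(net_p$edges$r[m], net05$edges$r, tolerance = 1e-12)
})

test_that("the null edge rate tracks alpha", {
  edges <- 0; pairs <- 0
  for (seed in 1:50) {
    set.seed(seed)
    X <- matrix(stats::rnorm(30 * 10), 30, 10,
                dimnames = list(paste0("s", 1:30), paste0("f", 1:10)))
    edges <- edges + nrow(build_cooccurrence(X, alpha = 0.05)$edges)
    pairs <- pairs + choose(10, 2)
  }
  expect_gt(edges / pairs, 0.03)
  expect_lt(edges / pairs, 0.07)
})

test_that("Louvain separates disconnected cliques and pools a complete graph", {
  a <- clique_edges(paste0("a", 1:4)); b <- clique_edges(paste0("b", 1:4))
  net <- manual_network(c(paste0("a", 1:4), paste0("b", 1:4)),
                        c(a$from, b$from), c(a$to, b$to))
  cm <- louvain_communities(net, seed = 1)
  expect_equal(cm$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(cm$partition)), 2L)
  expect_equal(length(unique(cm$partition[paste0("a", 1:4)])), 1L)
  full <- clique_edges(paste0("n", 1:6))
  net2 <- manual_network(paste0("n", 1:6), full$from, full$to)
  cm2 <- louvain_communities(net2, seed = 1)
  expect_equal(length(unique(cm2$partition)), 1L)
  expect_equal(cm2$modularity, 0, tolerance = 1e-12)
  # edgeless network: singletons, Q = 0
  net3 <- manual_network(c("x", "y"), character(), character())
  cm3 <- louvain_communities(net3, seed = 1)
  expect_equal(unname(cm3$partition), c(1L, 2L))
  expect_equal(cm3$modularity, 0)
})

test_that("reported modularity always equals a from-scratch recomputation", {
  set.seed(3)
  X <- matrix(stats::rnorm(40 * 12), 40, 12,
              dimnames = list(paste0("s", 1:40), paste0("f", 1:12)))
  X[, 2] <- X[, 1] + stats::rnorm(40, sd = 0.4)
  X[, 4] <- X[, 3] + stats::rnorm(40, sd = 0.4)
  net <- build_cooccurrence(X, alpha = 0.10)
  cm <- louvain_communities(net, seed = 5)
  expect_equal(cm$modularity,
               modularity_from_partition(net, cm$partition),
               tolerance = 1e-9)
  g <- as_igraph(net)
  expect_equal(cm$modularity,
               igraph::modularity(g, cm$partition[net$nodes$species],
                                  weights = igraph::E(g)$weight),
               tolerance = 1e-9)
})

test_that("centralities match closed forms and brute-force path counting", {
  star <- manual_network(c("hub", paste0("l", 1:4)),
                         rep("hub", 4), paste0("l", 1:4))
  star <- network_centralities(star)
  expect_equal(star$nodes$betweenness[star$nodes$species == "hub"], 6)  # (n-1)(n-2)/2
  expect_equal(star$nodes$degree[star$nodes$species == "hub"], 4L)
  expect_true(all(star$nodes$betweenness[star$nodes$species != "hub"] == 0))
  path <- manual_network(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  path <- network_centralities(path)
  expect_equal(path$nodes$betweenness[path$nodes$species == "B"], 1)
  for (seed in 1:10) {
    set.seed(seed)
    n <- 10
    adj <- matrix(0, n, n)
    pick <- which(upper.tri(adj))[sample(45, 16)]
    adj[pick] <- 1
    adj <- adj + t(adj)
    sp <- paste0("v", 1:n)
    idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    net <- manual_network(sp, sp[idx[, 1]], sp[idx[, 2]])
    net <- network_centralities(net)
    expect_equal(net$nodes$betweenness, bf_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("keystone ranking prefers betweenness and flags degenerate networks", {
  star <- manual_network(c("hub", paste0("l", 1:4)),
                         rep("hub", 4), paste0("l", 1:4))
  ks <- keystone_species(network_centralities(star), top_k = 1)
  expect_equal(ks$species, "hub")
  iso <- manual_network(c("x", "y", "z"), character(), character())
  ks0 <- keystone_species(network_centralities(iso))
  expect_equal(nrow(ks0), 0L)
  expect_true(attr(ks0, "degenerate"))
  # a hub bridging two cliques is always ranked first, whatever the labels
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    ids <- sample(sprintf("n%02d", 1:13))
    hub <- ids[13]
    c1 <- clique_edges(ids[1:6]); c2 <- clique_edges(ids[7:12])
    net <- manual_network(ids,
                          c(c1$from, c2$from, rep(hub, 6)),
                          c(c1$to, c2$to, ids[c(1:3, 7:9)]))
    ks <- keystone_species(network_centralities(net), top_k = 1)
    hits <- hits + (ks$species == hub)
  }
  expect_gte(hits / 50, 0.9)
})

test_that("community co-membership test agrees with the exact null", {
  a <- clique_edges(paste0("a", 1:10)); b <- clique_edges(paste0("b", 1:10))
  net <- manual_network(c(paste0("a", 1:10), paste0("b", 1:10)),
                        c(a$from, b$from), c(a$to, b$to))
  cm <- louvain_communities(net, seed = 1)
  net <- set_communities(net, cm)
  for (k in 4:5) {
    res <- community_separation_test(net, paste0("a", 1:k),
                                     n_perm = 9999, seed = 2)
    expect_equal(res$statistic, k)
    exact <- exact_comembership_p(c(10, 10), k, k)
    expect_lt(abs(res$p_value - exact), 0.01)
  }
  # a five-strong set concentrated in one of two balanced communities is
  # detectably non-random
  res5 <- community_separation_test(net, paste0("a", 1:5),
                                    n_perm = 9999, seed = 2)
  expect_lte(res5$p_value, 0.05)
  single <- community_separation_test(net, "a1", n_perm = 99, seed = 1)
  expect_equal(single$p_value, 1)
  expect_error(community_separation_test(net, "zz", n_perm = 9), "zz")
})

test_that("planted copula blocks are recovered as communities", {
  blocks <- list(list(species = 1:6, rho = 0.8),
                 list(species = 7:12, rho = 0.8),
                 list(species = 13:18, rho = 0.8))
  truth <- rep(1:3, each = 6)
  ok <- 0
  for (seed in 1:10) {
    co <- generate_cohort(synth_config(
      n_samples_per_group = 50, n_species = 60,
      habitat_profile = "polymicrobial", dropout = 0.1,
      power_exponent = 0, blocks = blocks, seed = seed))
    norm <- rank_normalize_standardize(
      prevalence_filter(to_relative(co$abundance), 0.2))
    net <- build_cooccurrence(norm, alpha = 0.01)
    cm <- louvain_communities(net, seed = seed)
    memb <- cm$partition[sprintf("sp%03d", 1:18)]
    ok <- ok + (mclust::adjustedRandIndex(memb, truth) >= 0.9)
  }
  expect_gte(ok / 10, 0.9)
})
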