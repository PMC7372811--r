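empty_edge_frame <- function() {
  data.frame(from = character(), to = character(), r = numeric(),
             p = numeric(), sign = character(), category = integer(),
             weight = numeric(), stringsAsFactors = FALSE)
}

#' Edge significance categories
#'
#' Maps edge p-values to the eight thickness categories by p-value
#' decade: (1e-2, 5e-2\] is category 1, (1e-3, 1e-2\] category 2, and so
#' on down to category 8 for p <= 1e-8 (most significant = thickest).
#'
#' @param p numeric vector of p-values (<= 0.05 for real edges).
#' @param cuts the seven internal cut points (default `10^-(2:8)`).
#' @return Integer categories 1-8.
#' @export
edge_category <- function(p, cuts = 10^-(2:8)) {
  1L + as.integer(rowSums(outer(p, cuts, "<=")))
}

#' Build a Pearson co-occurrence network
#'
#' Nodes are species; an edge joins two species whose pairwise Pearson
#' correlation (on the supplied normalized matrix, which the pipeline
#' prevalence-filters and rank-normalizes beforehand) is significant at
#' `alpha` under the two-sided t test with n - 2 degrees of freedom.
#' Edges carry the correlation `r`, its p-value, a sign
#' (positive/negative), a thickness category 1-8 from p-value decade
#' bins (8 = most significant, p <= 1e-8), and weight `|r|`.
#'
#' @param norm a `norm_table` or numeric samples x species matrix with at
#'   least 3 samples and 2 variable species; zero-variance species are
#'   dropped with a warning.
#' @param alpha edge significance threshold (default 0.05, inclusive).
#' @param node_stats optional data frame with columns `species`,
#'   `prevalence`, `mean_norm_abundance` supplying node annotations.
#' @return An object of class `cooc_network`: list with `nodes` (species,
#'   prevalence, mean_norm_abundance, community, degree, betweenness)
#'   and `edges` data frames.  Degree and betweenness are filled by
#'   [network_centralities()], communities by [set_communities()].
#' @export
build_cooccurrence <- function(norm, alpha = 0.05, node_stats = NULL) {
  X <- norm_values(norm)
  if (nrow(X) < 3L) abort("need at least 3 samples")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warn("dropping %d zero-variance species", sum(sds == 0))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2L) abort("need at least 2 variable species")
  n <- nrow(X)
  R <- stats::cor(X)
  lp <- lower_pairs(ncol(X))
  r <- R[cbind(lp$i, lp$j)]
  r <- pmin(1, pmax(-1, r))
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-tstat, df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  sig <- which(p <= alpha)
  sp <- colnames(X)
  edges <- if (length(sig)) {
    data.frame(from = sp[pmin(lp$i, lp$j)][sig],
               to = sp[pmax(lp$i, lp$j)][sig],
               r = r[sig], p = p[sig],
               sign = ifelse(r[sig] > 0, "positive", "negative"),
               category = edge_category(p[sig]),
               weight = abs(r[sig]),
               stringsAsFactors = FALSE)
  } else empty_edge_frame()
  nodes <- data.frame(species = sp,
                      prevalence = NA_real_,
                      mean_norm_abundance = NA_real_,
                      community = NA_integer_,
                      degree = NA_integer_,
                      betweenness = NA_real_,
                      stringsAsFactors = FALSE)
  if (!is.null(node_stats)) {
    m <- match(nodes$species, node_stats$species)
    if ("prevalence" %in% names(node_stats))
      nodes$prevalence <- node_stats$prevalence[m]
    if ("mean_norm_abundance" %in% names(node_stats))
      nodes$mean_norm_abundance <- node_stats$mean_norm_abundance[m]
  }
  net <- structure(list(nodes = nodes, edges = edges, alpha = alpha),
                   class = "cooc_network")
  network_centralities(net)
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %d nodes, %d edges (alpha = %g)%s\n",
              nrow(x$nodes), nrow(x$edges), x$alpha,
              if (all(is.na(x$nodes$community))) ""
              else sprintf(", %d communities",
                           length(unique(x$nodes$community)))))
  invisible(x)
}

#' Convert a co-occurrence network to igraph
#'
#' @param net a `cooc_network`.
#' @return An undirected `igraph` graph including isolated nodes; edge
#'   attribute `weight` is `|r|`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes["species"])
}

#' Degree and betweenness centralities
#'
#' Degree counts incident edges (the network is undirected); betweenness
#' is the Brandes accumulation over unweighted shortest paths,
#' unnormalized, so the centre of an n-star scores (n-1)(n-2)/2.
#'
#' @param net a `cooc_network`.
#' @return The network with `degree` and `betweenness` node columns
#'   filled; deterministic.
#' @export
network_centralities <- function(net) {
  g <- as_igraph(net)
  net$nodes$degree <- as.integer(igraph::degree(g))
  net$nodes$betweenness <- as.numeric(
    igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE))
  net
}

#' Weighted modularity of a partition, recomputed from scratch
#'
#' `Q = sum_c [ w_c / m - gamma * (K_c / 2m)^2 ]` over communities, with
#' `m` the total edge weight, `w_c` the weight inside community `c` and
#' `K_c` its total node strength.  Used to verify the value reported by
#' the community search.
#'
#' @param net a `cooc_network`.
#' @param membership named (by species) or node-ordered community vector.
#' @param resolution resolution parameter gamma (default 1).
#' @return Numeric modularity in \[-0.5, 1\].
#' @export
modularity_from_partition <- function(net, membership, resolution = 1) {
  sp <- net$nodes$species
  memb <- if (!is.null(names(membership))) membership[sp] else membership
  e <- net$edges
  if (!nrow(e)) return(0)
  m <- sum(e$weight)
  strength <- stats::setNames(numeric(length(sp)), sp)
  for (k in seq_len(nrow(e))) {
    strength[e$from[k]] <- strength[e$from[k]] + e$weight[k]
    strength[e$to[k]] <- strength[e$to[k]] + e$weight[k]
  }
  names(memb) <- sp
  w_in <- tapply(e$weight * (memb[e$from] == memb[e$to]),
                 memb[e$from], sum)
  q <- 0
  for (c in unique(memb)) {
    wc <- if (as.character(c) %in% names(w_in)) w_in[[as.character(c)]] else 0
    if (is.na(wc)) wc <- 0
    Kc <- sum(strength[memb == c])
    q <- q + wc / m - resolution * (Kc / (2 * m))^2
  }
  unname(q)
}

#' Louvain community detection with randomized restarts
#'
#' Runs the Blondel-Louvain algorithm on edge weights `|r|` (signs are
#' kept as edge attributes but dropped for community search, which
#' requires non-negative weights).  Each restart permutes the node order
#' before clustering; the partition with the highest modularity at the
#' requested resolution wins, and the reported modularity is recomputed
#' from the returned partition from scratch.
#'
#' @param net a `cooc_network` with at least one edge (a network with no
#'   edges yields singleton communities and Q = 0).
#' @param resolution resolution gamma (default 1).
#' @param n_restarts randomized restarts (default 10).
#' @param seed optional RNG seed.
#' @return An object of class `community_result`: list with `partition`
#'   (named integer vector), `modularity`, `n_restarts`, `best_restart`.
#' @export
louvain_communities <- function(net, resolution = 1, n_restarts = 10,
                                seed = NULL) {
  sp <- net$nodes$species
  n <- length(sp)
  if (!nrow(net$edges)) {
    return(structure(list(partition = stats::setNames(seq_len(n), sp),
                          modularity = 0, n_restarts = 0L,
                          best_restart = NA_integer_),
                     class = "community_result"))
  }
  g <- as_igraph(net)
  best <- NULL; best_q <- -Inf; best_k <- NA_integer_
  run_seeded(seed, {
    for (k in seq_len(n_restarts)) {
      perm <- sample(n)
      g2 <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(g2, weights = igraph::E(g2)$weight,
                                    resolution = resolution)
      memb <- igraph::membership(cl)[perm]  # map back to original order
      q <- modularity_from_partition(net, stats::setNames(as.integer(memb), sp),
                                     resolution = resolution)
      if (q > best_q + 1e-12) {
        best_q <- q
        best <- as.integer(memb)
        best_k <- k
      }
    }
  })
  structure(list(partition = stats::setNames(best, sp),
                 modularity = best_q,
                 n_restarts = as.integer(n_restarts),
                 best_restart = best_k),
            class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("<community_result> %d communities, modularity = %.4f (%d restarts)\n",
              length(unique(x$partition)), x$modularity, x$n_restarts))
  invisible(x)
}

#' Attach a community partition to a network
#'
#' @param net a `cooc_network`.
#' @param communities a [louvain_communities()] result.
#' @return The network with the `community` node column filled.
#' @export
set_communities <- function(net, communities) {
  net$nodes$community <-
    as.integer(communities$partition[net$nodes$species])
  net
}

#' Keystone species ranking
#'
#' Nodes ranked by betweenness centrality (descending), ties broken by
#' degree then species ID - the "topological biomarker" view of
#' keystoneness.  If every node has zero betweenness there is no
#' meaningful ranking and an empty, flagged data frame is returned.
#'
#' @param net a `cooc_network` with centralities computed.
#' @param top_k how many species to return (default 3).
#' @return Data frame `species`, `betweenness`, `degree`; attribute
#'   `"degenerate"` is `TRUE` when all betweenness values are zero.
#' @export
keystone_species <- function(net, top_k = 3) {
  nodes <- net$nodes
  if (any(is.na(nodes$betweenness))) net <- network_centralities(net)
  nodes <- net$nodes
  if (all(nodes$betweenness == 0)) {
    out <- nodes[integer(), c("species", "betweenness", "degree")]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  o <- order(-nodes$betweenness, -nodes$degree, nodes$species)
  out <- nodes[utils::head(o, top_k), c("species", "betweenness", "degree")]
  rownames(out) <- NULL
  attr(out, "degenerate") <- FALSE
  out
}

#' Permutation test of community co-membership for a species set
#'
#' A defined stand-in for asking whether a set of species of interest is
#' topologically concentrated: the statistic is the largest number of set
#' members sharing a single community, compared with the same statistic
#' for `n_perm` random equal-size node subsets;
#' `p = (b + 1) / (n_perm + 1)`.
#'
#' @param net a `cooc_network` with communities assigned.
#' @param species_set character vector of node species IDs.
#' @param n_perm permutations (default 9999).
#' @param seed optional RNG seed.
#' @return An [test_result()]; statistic is the observed maximum
#'   co-membership count.
#' @export
community_separation_test <- function(net, species_set, n_perm = 9999,
                                      seed = NULL) {
  nodes <- net$nodes
  if (all(is.na(nodes$community)))
    abort("communities not assigned; run louvain_communities + set_communities")
  missing <- setdiff(species_set, nodes$species)
  if (length(missing))
    abort("species not in network: %s", paste(missing, collapse = ", "))
  k <- length(species_set)
  if (k > nrow(nodes)) abort("species set larger than the network")
  comm <- stats::setNames(nodes$community, nodes$species)
  stat <- function(set) max(table(comm[set]))
  obs <- stat(species_set)
  if (k == 1L)
    return(test_result(obs, 1, n_perm, "community co-membership permutation test"))
  perm <- run_seeded(seed, vapply(seq_len(n_perm), function(b)
    stat(sample(nodes$species, k)), 0))
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  test_result(obs, p, n_perm, "community co-membership permutation test")
}
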