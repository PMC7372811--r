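# Independent oracles and small fixture builders used across the suite.
# Every oracle here deliberately takes a different code path from the
# implementation it checks.

# random counts table
random_counts <- function(seed, n = 10, s = 6, lambda = 20) {
  set.seed(seed)
  v <- matrix(stats::rpois(n * s, lambda), n, s,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("sp", seq_len(s))))
  v[1, 1] <- v[1, 1] + 1  # guard against an all-zero table
  abundance_table(v, "counts")
}

random_relative <- function(seed, n = 10, s = 6) {
  set.seed(seed)
  v <- matrix(stats::rexp(n * s), n, s,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("sp", seq_len(s))))
  abundance_table(v / rowSums(v), "relative")
}

# build a cooc_network by hand from an edge list (unit weights)
manual_network <- function(species, edges_from, edges_to,
                           r = rep(1, length(edges_from))) {
  structure(list(
    nodes = data.frame(species = species,
                       prevalence = NA_real_,
                       mean_norm_abundance = NA_real_,
                       community = NA_integer_,
                       degree = NA_integer_,
                       betweenness = NA_real_,
                       stringsAsFactors = FALSE),
    edges = if (length(edges_from)) {
      data.frame(from = edges_from, to = edges_to, r = r,
                 p = rep(1e-9, length(edges_from)),
                 sign = ifelse(r > 0, "positive", "negative"),
                 category = 8L, weight = abs(r),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(), to = character(), r = numeric(),
                 p = numeric(), sign = character(), category = integer(),
                 weight = numeric(), stringsAsFactors = FALSE)
    },
    alpha = 0.05), class = "cooc_network")
}

clique_edges <- function(members) {
  e <- t(utils::combn(members, 2))
  list(from = e[, 1], to = e[, 2])
}

# brute-force Freeman-Halton p-value: enumerate 2-3 free cells of the
# first row(s) with expand.grid (only for small r x c), completely
# independent of the recursive generator in the package
bf_freeman_halton <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  rm <- rowSums(tab); cm <- colSums(tab); N <- sum(tab)
  lp <- function(m) sum(lgamma(rm + 1)) + sum(lgamma(cm + 1)) -
    lgamma(N + 1) - sum(lgamma(m + 1))
  r <- nrow(tab); cc <- ncol(tab)
  free <- expand.grid(rep(list(0:max(rm)), (r - 1) * (cc - 1)))
  probs <- apply(free, 1, function(cells) {
    m <- matrix(0, r, cc)
    m[seq_len(r - 1), seq_len(cc - 1)] <- matrix(cells, r - 1, cc - 1)
    m[seq_len(r - 1), cc] <- rm[seq_len(r - 1)] - rowSums(m[seq_len(r - 1), seq_len(cc - 1), drop = FALSE])
    m[r, ] <- cm - colSums(m[seq_len(r - 1), , drop = FALSE])
    if (any(m < 0)) return(NA_real_)
    exp(lp(m))
  })
  probs <- probs[!is.na(probs)]
  p_obs <- exp(lp(tab))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# literal transcription of the two-stage step-up definition
bf_two_stage <- function(p, q = 0.10) {
  m <- length(p)
  stepup <- function(level) {
    ps <- sort(p)
    k <- 0
    for (i in seq_len(m)) if (ps[i] <= level * i / m) k <- i
    if (k == 0) rep(FALSE, m) else p <= ps[k]
  }
  r1 <- sum(stepup(q / (1 + q)))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  stepup(q * m / m0)
}

# brute-force betweenness by explicit shortest-path enumeration
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  paths_between <- function(s, t, dist_s) {
    # enumerate all shortest s->t paths by walking dist levels backwards
    res <- list()
    walk <- function(v, acc) {
      if (v == s) {
        res[[length(res) + 1]] <<- rev(acc)
        return(invisible())
      }
      for (u in which(adj[, v] > 0))
        if (dist_s[u] == dist_s[v] - 1) walk(u, c(acc, u))
    }
    walk(t, t)
    res
  }
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (u in which(adj[v, ] > 0))
        if (is.infinite(d[u])) { d[u] <- d[v] + 1; nxt <- c(nxt, u) }
      frontier <- unique(nxt)
    }
    d
  }
  for (s in seq_len(n - 1)) {
    ds <- bfs_dist(s)
    for (t in (s + 1):n) {
      if (is.infinite(ds[t])) next
      paths <- paths_between(s, t, ds)
      if (!length(paths)) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(paths)
      }
    }
  }
  btw
}

# exact null for the community co-membership statistic of a random
# k-subset of nodes with community sizes `sizes`: P(max count >= x)
exact_comembership_p <- function(sizes, k, x_obs) {
  # enumerate all compositions of k over the communities
  combos <- expand.grid(rep(list(0:k), length(sizes)))
  combos <- combos[rowSums(combos) == k, , drop = FALSE]
  total <- choose(sum(sizes), k)
  pr <- apply(combos, 1, function(cnt) {
    if (any(cnt > sizes)) return(0)
    prod(choose(sizes, cnt)) / total
  })
  sum(pr[apply(combos, 1, max) >= x_obs])
}
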