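#' Uniform test-result container
#'
#' Every significance procedure in the package returns this structure so
#' reports can be assembled uniformly.
#'
#' @param statistic test statistic.
#' @param p_value p-value in (0, 1\].
#' @param n_permutations number of label permutations, or `NA` for
#'   exact/asymptotic tests.
#' @param method human-readable method name.
#' @param notes optional character notes (ties, approximations, seeds).
#' @return List of class `mn_test`.
#' @export
test_result <- function(statistic, p_value, n_permutations = NA_integer_,
                        method = "", notes = character()) {
  structure(list(statistic = unname(statistic),
                 p_value = unname(p_value),
                 n_permutations = n_permutations,
                 method = method,
                 notes = notes),
            class = "mn_test")
}

#' @export
print.mn_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g%s\n", x$method, x$statistic,
              x$p_value,
              if (!is.na(x$n_permutations))
                sprintf(" (%d permutations)", x$n_permutations) else ""))
  if (length(x$notes)) cat("  ", paste(x$notes, collapse = "; "), "\n", sep = "")
  invisible(x)
}

check_groups <- function(labels, n, min_size = 2L) {
  labels <- as.character(labels)
  if (length(labels) != n)
    abort("labels (%d) do not cover the %d samples", length(labels), n)
  tab <- table(labels)
  if (length(tab) < 2L) abort("need at least 2 groups")
  if (any(tab < min_size))
    abort("group(s) with fewer than %d members: %s", min_size,
          paste(names(tab)[tab < min_size], collapse = ", "))
  labels
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a dissimilarity
#' matrix.  All n(n-1)/2 distances are ranked (ties averaged) and
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)`
#' with `M = n(n-1)/2`; R lies in \[-1, 1\] and is 0 on average under the
#' null.  The p-value is `(b + 1) / (n_perm + 1)` where `b` counts label
#' permutations whose R is at least the observed one.
#'
#' @param d `dist` or symmetric distance matrix.
#' @param labels group labels, one per sample (each group >= 2).
#' @param n_perm number of permutations (default 999).
#' @param seed optional RNG seed for the permutations.
#' @return An [test_result()] with the observed R.
#' @export
anosim_test <- function(d, labels, n_perm = 999, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  labels <- check_groups(labels, n)
  lp <- lower_pairs(n)
  r <- rank(D[lower.tri(D)])
  M <- length(r)
  stat <- function(lab) {
    same <- lab[lp$i] == lab[lp$j]
    (mean(r[!same]) - mean(r[same])) / (M / 2)
  }
  obs <- stat(labels)
  perm <- run_seeded(seed, vapply(seq_len(n_perm),
                                  function(b) stat(sample(labels)), 0))
  p <- (sum(perm >= obs - 1e-12) + 1) / (n_perm + 1)
  out <- test_result(obs, p, n_perm, "ANOSIM",
                     notes = sprintf("groups: %s",
                                     paste(names(table(labels)), collapse = " vs ")))
  out$perm_stats <- perm
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way pseudo-F computed directly from squared dissimilarities:
#' `SS_total = sum(d_ij^2) / n` over all pairs, `SS_within` summed over
#' within-group pairs divided by group sizes, and
#' `F = (SS_between / (a - 1)) / (SS_within / (n - a))`.  On univariate
#' Euclidean data this reproduces the classical one-way ANOVA F exactly.
#' Permutation p-value as in [anosim_test()].
#'
#' @inheritParams anosim_test
#' @return An [test_result()] with the observed pseudo-F.
#' @export
permanova_test <- function(d, labels, n_perm = 999, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  labels <- check_groups(labels, n)
  lp <- lower_pairs(n)
  d2 <- D[lower.tri(D)]^2
  a <- length(unique(labels))
  ss_total <- sum(d2) / n
  stat <- function(lab) {
    ss_within <- 0
    for (g in unique(lab)) {
      ing <- lab[lp$i] == g & lab[lp$j] == g
      ss_within <- ss_within + sum(d2[ing]) / sum(lab == g)
    }
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  obs <- stat(labels)
  perm <- run_seeded(seed, vapply(seq_len(n_perm),
                                  function(b) stat(sample(labels)), 0))
  p <- (sum(perm >= obs - 1e-12) + 1) / (n_perm + 1)
  out <- test_result(obs, p, n_perm, "PERMANOVA")
  out$perm_stats <- perm
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test.  For small samples (n1 + n2 <= 12) the exact
#' conditional p-value is computed by enumerating every assignment of the
#' pooled mid-ranks to the first group, which handles ties and returns
#' exactly 1 for identical multisets.  Larger samples use the normal
#' approximation with tie and continuity corrections (the same path as
#' \code{stats::wilcox.test}).
#'
#' @param x,y numeric vectors, each non-empty.
#' @return An [test_result()] with the U statistic of `x`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) abort("both groups must be non-empty")
  n <- n1 + n2
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- any(duplicated(c(x, y)))
  if (n <= 12L) {
    combos <- utils::combn(n, n1)
    base <- n1 * (n1 + 1) / 2
    Uall <- colSums(matrix(rk[combos], nrow = n1)) - base
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    notes <- c("exact enumeration", if (ties) "ties: mid-rank enumeration")
  } else {
    tie_tab <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- U - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    notes <- c("normal approximation with continuity correction",
               if (ties) "tie-corrected variance")
  }
  test_result(U, p, NA_integer_, "Mann-Whitney U", notes = notes)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with chi-squared reference distribution
#' (`a - 1` degrees of freedom), via \code{stats::kruskal.test}.  When
#' every value is identical H is 0 and p is 1.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, n >= 3).
#' @return An [test_result()].
#' @export
kruskal_wallis_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (length(values) < 3L) abort("need at least 3 observations")
  if (max(values) - min(values) == 0)
    return(test_result(0, 1, NA_integer_, "Kruskal-Wallis",
                       notes = "all values identical"))
  kt <- stats::kruskal.test(values, groups)
  test_result(unname(kt$statistic), unname(kt$p.value), NA_integer_,
              "Kruskal-Wallis")
}

log_table_prob <- function(tab, lp_const) {
  lp_const - sum(lgamma(tab + 1))
}

# enumerate all r x c tables with the given margins, calling fn(table)
enumerate_tables <- function(row_m, col_m, fn) {
  r <- length(row_m)
  tab <- matrix(0L, r, length(col_m))
  rec_row <- function(i, col_left) {
    if (i == r) {
      tab[r, ] <<- col_left
      fn(tab)
      return(invisible())
    }
    rec_cell <- function(j, row_left, col_left) {
      if (j == length(col_m)) {
        if (row_left <= col_left[j]) {
          tab[i, j] <<- row_left
          col_left[j] <- col_left[j] - row_left
          rec_row(i + 1L, col_left)
        }
        return(invisible())
      }
      for (v in 0:min(row_left, col_left[j])) {
        tab[i, j] <<- v
        cl <- col_left
        cl[j] <- cl[j] - v
        rec_cell(j + 1L, row_left - v, cl)
      }
    }
    rec_cell(1L, row_m[i], col_left)
  }
  rec_row(1L, col_m)
  invisible()
}

#' Fisher-Freeman-Halton exact test for r x c tables
#'
#' Exact conditional test of independence in an r x c contingency table:
#' the p-value is the total hypergeometric probability of every table
#' with the observed margins whose probability does not exceed that of
#' the observed table (within a relative guard of 1e-7 against float
#' ties).  Tables are generated by recursive margin-constrained
#' enumeration; all-zero rows and columns are dropped first, and a table
#' reduced below 2 x 2 is degenerate with p = 1.
#'
#' @param table non-negative integer matrix, r, c >= 2.
#' @param max_n,max_cells enumeration budget (defaults: total N <= 200
#'   and r * c <= 12); larger problems are refused with advice to use a
#'   Monte-Carlo fallback (`monte_carlo = TRUE` is reserved and not yet
#'   implemented).
#' @param monte_carlo reserved flag; must be `FALSE`.
#' @return An [test_result()]; the statistic is the log-probability of
#'   the observed table and a `total_prob` note records the enumerated
#'   probability mass (1 up to float error).
#' @export
freeman_halton <- function(table, max_n = 200, max_cells = 12,
                           monte_carlo = FALSE) {
  tab <- as.matrix(table)
  if (any(tab < 0) || max(abs(tab - round(tab))) > 0)
    abort("table must hold non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) abort("need an r x c table with r, c >= 2")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(test_result(0, 1, NA_integer_, "Fisher-Freeman-Halton",
                       notes = "degenerate after dropping empty margins"))
  if (monte_carlo) abort("Monte-Carlo fallback is not implemented")
  N <- sum(tab)
  if (N > max_n || length(tab) > max_cells)
    abort(paste0("table too large for exact enumeration (N = %d, cells = %d); ",
                 "a Monte-Carlo fallback flag is reserved for such tables"),
          N, length(tab))
  row_m <- rowSums(tab); col_m <- colSums(tab)
  lp_const <- sum(lgamma(row_m + 1)) + sum(lgamma(col_m + 1)) - lgamma(N + 1)
  lp_obs <- log_table_prob(tab, lp_const)
  cutoff <- lp_obs + log1p(1e-7)
  p_sum <- 0; total <- 0
  enumerate_tables(row_m, col_m, function(t2) {
    lp <- log_table_prob(t2, lp_const)
    pr <- exp(lp)
    total <<- total + pr
    if (lp <= cutoff) p_sum <<- p_sum + pr
  })
  test_result(lp_obs, min(1, p_sum), NA_integer_, "Fisher-Freeman-Halton",
              notes = sprintf("total_prob=%.12f", total))
}

bh_stepup <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= level * seq_len(m) / m)
  k <- if (length(ok)) max(ok) else 0L
  rej <- logical(m)
  if (k > 0L) rej[o[seq_len(k)]] <- TRUE
  rej
}

#' Two-stage Benjamini-Hochberg FDR control
#'
#' Adaptive linear step-up: stage 1 runs BH at `q / (1 + q)` giving `r1`
#' rejections; the null count is estimated as `m0 = m - r1` and stage 2
#' runs BH at `q * m / m0` (plain BH at `q` when `r1 = 0`).  The adjusted
#' values satisfy `rejected == (adjusted <= q)` and the rejection set is
#' monotone in p.  The procedure always rejects at least as much as
#' one-stage BH at the same `q`.
#'
#' @param p_values p-values in (0, 1\].
#' @param q target false discovery rate (default 0.10).
#' @return List with `rejected` (logical, input order), `adjusted`
#'   (adaptive q-values), `r1` and `m0`.
#' @export
bh_two_stage <- function(p_values, q = 0.10) {
  p <- as.numeric(p_values)
  if (!length(p)) abort("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    abort("p-values must lie in (0, 1]")
  m <- length(p)
  r1 <- sum(bh_stepup(p, q / (1 + q)))
  m0 <- m - r1
  if (m0 == 0L) {
    return(list(rejected = rep(TRUE, m), adjusted = rep(0, m),
                r1 = r1, m0 = m0))
  }
  rejected <- bh_stepup(p, q * m / m0)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m0 / seq_len(m))))
  adjusted <- numeric(m)
  adjusted[o] <- pmin(1, adj_sorted)
  list(rejected = rejected, adjusted = adjusted, r1 = r1, m0 = m0)
}

#' Minimum-data-points gate
#'
#' Retains species observed (value > 0) in at least `k` samples, the
#' "at least five data points" constraint applied before effect-size
#' scoring.
#'
#' @param table an `abund_table`.
#' @param k minimum number of non-zero observations (default 5).
#' @return Filtered `abund_table`.
#' @export
min_datapoints_gate <- function(table, k = 5) {
  v <- abund_values(table)
  keep <- colSums(v > 0) >= k
  abundance_table(v[, keep, drop = FALSE], abund_kind(table))
}
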