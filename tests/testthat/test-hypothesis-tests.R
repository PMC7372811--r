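sep_dist <- function(gap = 10) {
  # two groups of 4 points on a line, far apart: maximal separation
  pts <- c(1, 2, 3, 4, 1 + gap, 2 + gap, 3 + gap, 4 + gap)
  D <- as.matrix(stats::dist(pts))
  rownames(D) <- colnames(D) <- paste0("s", 1:8)
  D
}

test_that("ANOSIM reaches R = 1 at full separation and matches vegan", {
  D <- sep_dist()
  lab <- rep(c("a", "b"), each = 4)
  res <- anosim_test(D, lab, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  set.seed(5)
  pts <- matrix(stats::rnorm(24), 12, 2)
  D2 <- as.matrix(stats::dist(pts))
  rownames(D2) <- colnames(D2) <- paste0("s", 1:12)
  lab2 <- rep(c("a", "b"), each = 6)
  mine <- anosim_test(D2, lab2, n_perm = 9, seed = 1)
  ref <- vegan::anosim(stats::as.dist(D2), lab2, permutations = 9)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
})

test_that("sampled ANOSIM p agrees with exhaustive enumeration at n = 4 + 4", {
  set.seed(11)
  pts <- c(stats::rnorm(4), stats::rnorm(4, mean = 1.2))
  D <- as.matrix(stats::dist(pts))
  rownames(D) <- colnames(D) <- paste0("s", 1:8)
  lab <- rep(c("a", "b"), each = 4)
  # exact p over all 70 labelings, computed from first principles
  r <- rank(D[lower.tri(D)])
  M <- length(r)
  pairs <- which(lower.tri(D), arr.ind = TRUE)
  r_stat <- function(l) {
    same <- l[pairs[, 1]] == l[pairs[, 2]]
    (mean(r[!same]) - mean(r[same])) / (M / 2)
  }
  obs <- r_stat(lab)
  combos <- utils::combn(8, 4)
  all_r <- apply(combos, 2, function(ix) {
    l <- rep("b", 8); l[ix] <- "a"; r_stat(l)
  })
  exact_p <- mean(all_r >= obs - 1e-12)
  sampled <- anosim_test(D, lab, n_perm = 4999, seed = 3)
  expect_lt(abs(sampled$p_value - exact_p), 0.02)
})

test_that("permutation machinery is order-invariant and null-centered", {
  set.seed(2)
  pts <- matrix(stats::rnorm(20), 10, 2)
  D <- as.matrix(stats::dist(pts))
  rownames(D) <- colnames(D) <- paste0("s", 1:10)
  lab <- rep(c("a", "b"), each = 5)
  res <- anosim_test(D, lab, n_perm = 999, seed = 7)
  # reorder samples together with their labels: the statistic is exactly
  # invariant; the sampled p only up to Monte-Carlo noise
  o <- c(3, 1, 9, 7, 5, 2, 10, 8, 6, 4)
  res2 <- anosim_test(D[o, o], lab[o], n_perm = 999, seed = 7)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  expect_lt(abs(res2$p_value - res$p_value), 0.05)
  # permuted-label R distribution is centred on zero
  expect_lt(abs(mean(res$perm_stats)), 0.02)
})

test_that("PERMANOVA equals one-way ANOVA on univariate Euclidean data", {
  set.seed(4)
  y <- stats::rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  D <- as.matrix(stats::dist(y))
  rownames(D) <- colnames(D) <- paste0("s", 1:18)
  f_anova <- summary(stats::aov(y ~ g))[[1]][["F value"]][1]
  res <- permanova_test(D, g, n_perm = 9, seed = 1)
  expect_equal(res$statistic, f_anova, tolerance = 1e-10)
  ref <- vegan::adonis2(stats::as.dist(D) ~ g,
                        data = data.frame(g = g), permutations = 9)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA vanishes on duplicated groups and grows with separation", {
  set.seed(6)
  base <- matrix(stats::rnorm(10), 5, 2)
  dup <- rbind(base, base)
  D <- as.matrix(stats::dist(dup))
  rownames(D) <- colnames(D) <- paste0("s", 1:10)
  lab <- rep(c("a", "b"), each = 5)
  res <- permanova_test(D, lab, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_gt(res$p_value, 0.9)
  fs <- vapply(c(0, 1, 2, 4), function(shift) {
    x <- rbind(base, sweep(base, 2, c(shift, 0), `+`))
    D <- as.matrix(stats::dist(x))
    rownames(D) <- colnames(D) <- paste0("s", 1:10)
    permanova_test(D, lab, n_perm = 9, seed = 1)$statistic
  }, 0)
  expect_true(all(diff(fs) > 0))
})

test_that("Mann-Whitney exact and approximate paths behave as specified", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # approximation error across every 5|5 partition of 10 distinct values
  vals <- c(1.3, 2.1, 3.7, 4.2, 5.9, 6.4, 7.7, 8.1, 9.6, 10.2)
  combos <- utils::combn(10, 5)
  max_gap <- 0
  for (k in seq_len(ncol(combos))) {
    x <- vals[combos[, k]]; y <- vals[-combos[, k]]
    exact <- mann_whitney_u(x, y)$p_value
    # independent normal approximation with continuity correction
    U <- sum(rank(c(x, y))[1:5]) - 15
    z <- (U - 12.5)
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(5 * 5 * 11 / 12)
    approx <- min(1, 2 * stats::pnorm(-abs(z)))
    max_gap <- max(max_gap, abs(exact - approx))
  }
  expect_lt(max_gap, 0.03)
  # the large-sample path coincides with wilcox.test's corrected normal p
  set.seed(9)
  x <- stats::rnorm(20); y <- stats::rnorm(25, 0.4)
  mine <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Kruskal-Wallis handles two-group, degenerate and ordered cases", {
  set.seed(10)
  x <- stats::rnorm(15); y <- stats::rnorm(15, 0.5)
  kw <- kruskal_wallis_test(c(x, y), rep(c("a", "b"), each = 15))
  mw <- mann_whitney_u(x, y)
  expect_lt(abs(kw$p_value - mw$p_value), 0.02)
  expect_equal(kruskal_wallis_test(rep(2, 6), rep(c("a", "b"), 3))$statistic, 0)
  # three fully ordered groups of 5: H = 12/(N(N+1)) * sum n R^2 - 3(N+1)
  ordered <- kruskal_wallis_test(1:15, rep(c("a", "b", "c"), each = 5))
  expect_equal(ordered$statistic, 12.5, tolerance = 1e-12)
})

test_that("Freeman-Halton enumeration matches independent oracles", {
  t22 <- matrix(c(3, 0, 0, 3), 2, 2)
  expect_equal(freeman_halton(t22)$p_value, 0.1, tolerance = 1e-12)
  # the cause-of-infertility 4 x 2 contingency table
  t42 <- matrix(c(2, 0, 1, 1, 11, 3, 6, 8), 4, 2)
  res <- freeman_halton(t42)
  expect_equal(res$p_value, bf_freeman_halton(t42), tolerance = 1e-12)
  expect_equal(res$p_value, stats::fisher.test(t42)$p.value, tolerance = 1e-6)
  # partition-function check: enumerated table probabilities sum to one
  total <- as.numeric(sub("total_prob=", "", res$notes[1]))
  expect_equal(total, 1, tolerance = 1e-9)
  # zero-margin row: degenerate after reduction
  expect_equal(freeman_halton(matrix(c(3, 0, 2, 0), 2, 2))$p_value, 1)
  # random 2 x 3 tables against fisher.test
  for (seed in 1:20) {
    set.seed(seed)
    tab <- matrix(stats::rpois(6, 3), 2, 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(freeman_halton(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-6)
  }
  big <- matrix(300, 2, 2)
  expect_error(freeman_halton(big), "Monte-Carlo")
})

test_that("two-stage BH matches its definition and dominates one-stage BH", {
  expect_true(all(bh_two_stage(rep(0.001, 10), 0.10)$rejected))
  expect_false(any(bh_two_stage(rep(0.9, 10), 0.10)$rejected))
  p_fixed <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074,
               0.205, 0.212, 0.216)
  res <- bh_two_stage(p_fixed, 0.10)
  expect_equal(res$rejected, bf_two_stage(p_fixed, 0.10))
  # rejected set is monotone in p and equals {adjusted <= q}
  expect_true(all(p_fixed[res$rejected] <= min(p_fixed[!res$rejected])))
  expect_equal(res$rejected, res$adjusted <= 0.10)
  for (seed in 1:50) {
    set.seed(seed)
    p <- stats::runif(20)^stats::rexp(1)
    ts <- bh_two_stage(p, 0.10)$rejected
    bh <- stats::p.adjust(p, "BH") <= 0.10
    expect_true(all(bh <= ts))  # one-stage rejections are a subset
    expect_equal(ts, bf_two_stage(p, 0.10))
  }
  expect_error(bh_two_stage(numeric(0)), "empty")
  expect_error(bh_two_stage(c(0.5, 0)), "0, 1")
})

test_that("the minimum-data-points gate keeps the boundary inclusive", {
  v <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
  v[1:5, 1] <- 1  # 5 data points -> kept at k = 5
  v[1:4, 2] <- 1  # 4 -> dropped
  v[, 3] <- 1
  tab <- abundance_table(v, "counts")
  expect_equal(species_ids(min_datapoints_gate(tab, 5)), c("a", "c"))
  expect_equal(species_ids(min_datapoints_gate(tab, 0)), c("a", "b", "c"))
})
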