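gauss_xy <- function(seed, n = 20, p = 8, shift = 0, shifted_col = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", shifted_col] <- X[y == "b", shifted_col] + shift
  list(X = X, y = y)
}

test_that("PLS-DA concentrates on a perfect predictor and keeps scores orthogonal", {
  set.seed(1)
  n <- 400
  X <- matrix(stats::rnorm(n * 8, sd = 0.2), n, 8,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:8)))
  y <- rep(c("a", "b"), each = n / 2)
  X[, 3] <- ifelse(y == "b", 1, 0)  # column equal to the class indicator
  fit <- plsda_fit(X, y, n_components = 2)
  expect_gt(abs(fit$W[3, 1]), 0.99)
  d <- gauss_xy(1)
  fit <- plsda_fit(d$X, d$y, n_components = 2)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_error(plsda_fit(d$X, rep("a", 20)), "2 classes")
})

test_that("VIP scores satisfy the sum identity and match mixOmics", {
  for (seed in 1:5) {
    d <- gauss_xy(seed, shift = 1.5)
    fit <- plsda_fit(d$X, d$y, n_components = 2)
    vip <- vip_scores(fit)
    expect_equal(sum(vip^2), ncol(d$X), tolerance = 1e-8)
  }
  d <- gauss_xy(3, shift = 1.5)
  fit <- plsda_fit(d$X, d$y, n_components = 2)
  ref <- mixOmics::vip(mixOmics::plsda(d$X, factor(d$y), ncomp = 2,
                                       scale = FALSE))[, 2]
  expect_equal(unname(vip_scores(fit)), unname(ref), tolerance = 1e-8)
})

test_that("under exchangeable noise VIP scores cluster near one", {
  meds <- vapply(1:50, function(seed) {
    d <- gauss_xy(seed, n = 20, p = 20)
    stats::median(vip_scores(plsda_fit(d$X, d$y, n_components = 2)))
  }, 0)
  expect_gte(stats::median(meds), 0.8)
  expect_lte(stats::median(meds), 1.2)
})

test_that("leave-one-out VIP averaging is symmetric and equivariant", {
  d <- gauss_xy(2, shift = 2)
  X <- d$X
  X[, 5] <- X[, 4]  # duplicated column
  loo <- loo_mean_vip(X, d$y)
  expect_equal(loo$mean_vip[4], loo$mean_vip[5], tolerance = 1e-8)
  # permuting feature columns permutes the report identically
  perm <- c(3, 1, 4, 2, 8, 7, 5, 6)
  loo_p <- loo_mean_vip(d$X[, perm], d$y)
  loo_o <- loo_mean_vip(d$X, d$y)
  expect_equal(loo_p$mean_vip, loo_o$mean_vip[perm], tolerance = 1e-12)
  expect_equal(loo_p$species, loo_o$species[perm])
  # identical samples within each class: every fold refits the same model
  Xc <- rbind(matrix(rep(c(1, 5, 2, 0, 3, 1, 4, 2), 4), 4, 8, byrow = TRUE),
              matrix(rep(c(2, 1, 5, 3, 0, 2, 1, 4), 4), 4, 8, byrow = TRUE))
  dimnames(Xc) <- list(paste0("s", 1:8), paste0("f", 1:8))
  yc <- rep(c("a", "b"), each = 4)
  loo_c <- loo_mean_vip(Xc, yc, n_components = 1)
  single <- vip_scores(plsda_fit(Xc, yc, n_components = 1))
  expect_equal(loo_c$mean_vip, unname(single), tolerance = 1e-6)
  expect_error(loo_mean_vip(d$X[1:3, ], c("a", "a", "b")), "at least")
})

test_that("a planted biomarker wins the mean-VIP ranking", {
  hits <- vapply(1:30, function(seed) {
    set.seed(seed)
    X <- matrix(stats::rnorm(30 * 50), 30, 50,
                dimnames = list(paste0("s", 1:30), paste0("f", 1:50)))
    y <- rep(c("a", "b"), each = 15)
    X[y == "b", 1] <- X[y == "b", 1] + 2
    loo <- loo_mean_vip(X, y)
    loo$species[which.max(loo$mean_vip)] == "f1"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("fold ratios follow the high/low convention", {
  v <- matrix(c(0.04, 0.04, 0.01, 0.01,
                0.2, 0.2, 0.2, 0.2,
                0.76, 0.76, 0.79, 0.79), 4, 3,
              dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  tab <- abundance_table(v, "relative")
  g <- c("g1", "g1", "g2", "g2")
  fr <- fold_ratio(tab, g)
  expect_equal(fr$fold_ratio[fr$species == "a"], 4)
  expect_equal(fr$high_cohort[fr$species == "a"], "g1")
  expect_equal(fr$fold_ratio[fr$species == "b"], 1)
  # group label order is irrelevant: factors with reversed level order
  fr2 <- fold_ratio(tab, factor(g, levels = c("g2", "g1")))
  expect_equal(fr2, fr)
  # zero mean in one group: pseudocount floor, flagged
  vz <- v; vz[3:4, 1] <- 0
  frz <- fold_ratio(abundance_table(vz, "relative"), g)
  expect_true(frz$pseudocount[frz$species == "a"])
  expect_gt(frz$fold_ratio[frz$species == "a"], 1)
})

test_that("lefse gates are nested and identical groups yield an empty report", {
  rel <- random_relative(8, n = 12, s = 6)
  g <- rep(c("g1", "g2"), 6)
  lf <- lefse_like(rel, g)
  v <- abund_values(rel)
  mwu <- apply(v, 2, function(col)
    mann_whitney_u(col[g == "g1"], col[g == "g2"])$p_value)
  sig <- names(mwu)[mwu <= 0.05]
  expect_true(all(lf$species %in% sig))
  # duplicated cohorts: no species can differ
  vdup <- rbind(v, v)
  rownames(vdup) <- paste0("s", 1:24)
  lfd <- lefse_like(abundance_table(vdup, "relative"),
                    rep(c("g1", "g2"), each = 12))
  expect_equal(nrow(lfd), 0L)
})

test_that("a strongly shifted species is recovered by lefse with few intruders", {
  drop <- rep(0.35, 40); drop[30] <- 0
  sole <- 0; found <- 0
  for (seed in 1:100) {
    co <- generate_cohort(synth_config(
      n_samples_per_group = 15, n_species = 40,
      habitat_profile = "polymicrobial", dropout = drop,
      biomarkers = list(list(species = 30, log2_effect = 4,
                             group = "non_pregnant")),
      seed = seed))
    lf <- lefse_like(to_relative(co$abundance), co$metadata$outcome)
    found <- found + ("sp030" %in% lf$species)
    sole <- sole + (nrow(lf) == 1 && lf$species[1] == "sp030")
  }
  expect_gte(found / 100, 0.95)
  # an FDR-calibrated gate at q = 0.10 admits one extra rejection with
  # probability close to q, so "sole survivor" saturates near 0.9
  expect_gte(sole / 100, 0.80)
})

test_that("lefse effect sizes increase with the planted effect", {
  drop <- rep(0.35, 40); drop[30] <- 0
  med <- vapply(c(1, 2, 3), function(ef) {
    es <- vapply(1:30, function(seed) {
      co <- generate_cohort(synth_config(
        n_samples_per_group = 15, n_species = 40,
        habitat_profile = "polymicrobial", dropout = drop,
        biomarkers = list(list(species = 30, log2_effect = ef,
                               group = "non_pregnant")),
        seed = seed))
      lf <- lefse_like(to_relative(co$abundance), co$metadata$outcome)
      if ("sp030" %in% lf$species) lf$effect_size[lf$species == "sp030"]
      else NA_real_
    }, 0)
    stats::median(es, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(med) > 0))
})
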