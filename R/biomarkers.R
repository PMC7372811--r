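encode_binary <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) != 2L)
    abort("labels must have exactly 2 classes (found %d)", nlevels(y))
  if (any(table(y) < 2L))
    abort("each class needs at least 2 samples")
  y
}

#' Fit a two-class PLS-DA model (NIPALS)
#'
#' Partial least squares regression of a centered 0/1 class indicator on
#' the feature matrix, by the NIPALS algorithm with successive deflation.
#' With a single response column the NIPALS inner loop converges in one
#' pass per component, but the iteration is run to tolerance regardless.
#' Component scores are mutually orthogonal.
#'
#' @param X numeric matrix (samples x features) or `norm_table`; columns
#'   are centered internally.
#' @param y two-class labels, each class with >= 2 samples.
#' @param n_components number of latent components (default 2); must not
#'   exceed the rank of the centered `X`.
#' @param max_iter,tol NIPALS iteration controls.
#' @return An object of class `plsda_model` with weights `W`, loadings
#'   `P`, scores `T`, y-loadings `q`, per-component explained y-variance
#'   `ssy`, and the class encoding.
#' @export
plsda_fit <- function(X, y, n_components = 2, max_iter = 500, tol = 1e-10) {
  X <- norm_values(X)
  y <- encode_binary(y)
  if (nrow(X) != length(y)) abort("X rows and labels disagree")
  yc <- as.numeric(y) - 1
  yc <- yc - mean(yc)
  x_means <- colMeans(X)
  Xa <- sweep(X, 2L, x_means)
  n <- nrow(Xa); p <- ncol(Xa)
  A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A); ssy <- numeric(A)
  ya <- yc
  for (a in seq_len(A)) {
    # NIPALS with a single response column: the score-side vector u is
    # proportional to the (deflated) response at every pass, so the weight
    # direction is fixed after one update; iterate only to guard against a
    # pathological non-convergent sign flip from numerical noise.
    u <- ya
    w <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w_new <- crossprod(Xa, u)[, 1L]
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-12)
        abort("component %d unavailable: n_components exceeds the rank of X", a)
      w_new <- w_new / nw
      done <- min(sqrt(sum((w_new - w)^2)), sqrt(sum((w_new + w)^2))) < tol
      w <- w_new
      if (done) break
      if (it == max_iter)
        abort("NIPALS failed to converge after %d iterations", max_iter)
    }
    tt <- as.numeric(Xa %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-24)
      abort("component %d unavailable: n_components exceeds the rank of X", a)
    pa <- crossprod(Xa, tt)[, 1L] / t2
    qa <- sum(ya * tt) / t2
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tt; q[a] <- qa
    ssy[a] <- qa^2 * t2
    Xa <- Xa - tcrossprod(tt, pa)
    ya <- ya - qa * tt
  }
  rownames(W) <- rownames(P) <- colnames(X)
  structure(list(W = W, P = P, T = Tm, q = q, ssy = ssy,
                 x_means = x_means, levels = levels(y),
                 n_components = A),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d features, %d components (%s vs %s)\n",
              nrow(x$W), x$n_components, x$levels[1L], x$levels[2L]))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)` for unit-norm
#' weight vectors, where `SSY_a` is the response variance captured by
#' component `a`.  By construction `sum_j VIP_j^2 = p`, so VIP scores
#' average around 1 and features above 1 carry more than their share of
#' discrimination.
#'
#' @param model a fitted [plsda_fit()] model.
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "plsda_model")) abort("not a fitted plsda_model")
  p <- nrow(model$W)
  w2 <- model$W^2  # columns already unit-norm
  vip <- sqrt(p * as.numeric(w2 %*% model$ssy) / sum(model$ssy))
  names(vip) <- rownames(model$W)
  vip
}

#' Leave-one-out averaged VIP scores
#'
#' The model is refit n times, once per left-out sample (the full set of
#' leave-one-out folds, whose order is irrelevant to the mean), and the
#' per-feature mean and standard deviation of the n VIP vectors are
#' returned.  A fold whose training set would lose a class entirely is
#' skipped with a warning and the divisor reduced.
#'
#' @inheritParams plsda_fit
#' @return Data frame with `species`, `mean_vip`, `vip_sd`, `n_folds`,
#'   in the input feature order.
#' @export
loo_mean_vip <- function(X, y, n_components = 2) {
  X <- norm_values(X)
  y <- encode_binary(y)
  n <- nrow(X)
  if (n < 4L) abort("need at least 4 samples for leave-one-out")
  vips <- matrix(NA_real_, n, ncol(X))
  used <- logical(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L || any(table(yi) < 2L)) {
      warn("leave-one-out fold %d skipped: a class would drop below 2 samples", i)
      next
    }
    fit <- plsda_fit(X[-i, , drop = FALSE], yi, n_components = n_components)
    vips[i, ] <- vip_scores(fit)
    used[i] <- TRUE
  }
  if (!any(used)) abort("every leave-one-out fold was skipped")
  data.frame(species = colnames(X),
             mean_vip = colMeans(vips[used, , drop = FALSE]),
             vip_sd = apply(vips[used, , drop = FALSE], 2L, stats::sd),
             n_folds = sum(used),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold ratios between two cohorts
#'
#' For each species, the ratio of the higher cohort-mean relative
#' abundance to the lower one (`FR >= 1`).  When the lower mean is zero
#' a pseudocount floor equal to half the smallest non-zero relative
#' abundance in the table is substituted and the species flagged; a
#' species absent from both cohorts is excluded and listed in the
#' `"dropped"` attribute.  Ties in the means give FR = 1 with the
#' lexicographically first label as the high cohort, so the output does
#' not depend on group label order.
#'
#' @param table relative `abund_table`.
#' @param groups two-class labels, one per sample.
#' @return Data frame `species`, `fold_ratio`, `high_cohort`,
#'   `low_cohort`, `pseudocount` (logical).
#' @export
fold_ratio <- function(table, groups) {
  if (abund_kind(table) != "relative") abort("fold_ratio needs relative abundances")
  v <- abund_values(table)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) != 2L) abort("fold_ratio needs exactly 2 groups")
  m1 <- colMeans(v[groups == gl[1L], , drop = FALSE])
  m2 <- colMeans(v[groups == gl[2L], , drop = FALSE])
  nz <- v[v > 0]
  eps <- if (length(nz)) min(nz) / 2 else NA_real_
  hi <- ifelse(m1 >= m2, gl[1L], gl[2L])
  lo <- ifelse(m1 >= m2, gl[2L], gl[1L])
  top <- pmax(m1, m2); bot <- pmin(m1, m2)
  dropped <- colnames(v)[top == 0]
  keep <- top > 0
  pseudo <- keep & bot == 0
  fr <- ifelse(pseudo, top / eps, ifelse(top == bot, 1, top / bot))
  out <- data.frame(species = colnames(v)[keep],
                    fold_ratio = unname(fr[keep]),
                    high_cohort = unname(hi[keep]),
                    low_cohort = unname(lo[keep]),
                    pseudocount = unname(pseudo[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Combined VIP biomarker report
#'
#' Assembles the supervised biomarker table: leave-one-out mean VIP on
#' the normalized matrix, fold ratios and per-species Mann-Whitney tests
#' on relative abundances, with two-stage BH adjustment across species.
#' Sorted by mean VIP, descending.
#'
#' @param rel_table relative `abund_table` (same species set as `norm`).
#' @param norm a `norm_table` (or matrix) for the PLS-DA fit.
#' @param groups two-class labels per sample.
#' @param n_components PLS components (default 2).
#' @param alpha Mann-Whitney significance level (default 0.05).
#' @param q FDR target for the two-stage adjustment (default 0.10).
#' @return Data frame with VIP, FR, MWU p, adjusted p and significance.
#' @export
vip_report <- function(rel_table, norm, groups, n_components = 2,
                       alpha = 0.05, q = 0.10) {
  loo <- loo_mean_vip(norm, groups, n_components = n_components)
  fr <- fold_ratio(rel_table, groups)
  v <- abund_values(rel_table)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  mwu_p <- apply(v, 2L, function(col)
    mann_whitney_u(col[groups == gl[1L]], col[groups == gl[2L]])$p_value)
  adj <- bh_two_stage(mwu_p, q = q)
  out <- merge(loo, fr, by = "species", sort = FALSE)
  out$mwu_p <- mwu_p[out$species]
  out$mwu_p_adjusted <- adj$adjusted[match(out$species, colnames(v))]
  out$significant <- out$mwu_p <= alpha &
    adj$rejected[match(out$species, colnames(v))]
  out[order(-out$mean_vip), ]
}

#' LEfSe-style biomarker discovery
#'
#' Three nested gates followed by a linear-discriminant effect size:
#' species must (1) differ between the cohorts by a two-sided
#' Mann-Whitney test at `alpha`, (2) survive two-stage Benjamini-Hochberg
#' FDR control at `q` applied across all tested species, and (3) carry
#' at least `k` non-zero observations.  Survivors are scaled to 1e6 per
#' sample (counts-per-million convention) and scored as
#' `log10` of the absolute mean of the raw class-mean difference and the
#' feature's first-axis LDA-projected difference, floored at 0.
#'
#' @param table relative `abund_table`.
#' @param groups two-class labels per sample.
#' @param alpha Mann-Whitney gate (default 0.05, inclusive).
#' @param q FDR target (default 0.10).
#' @param k minimum non-zero observations (default 5).
#' @return Data frame `species`, `effect_size`, `enriched_cohort`,
#'   `mwu_p`, `mwu_p_adjusted`, sorted by effect size descending; empty
#'   (zero rows) when no species passes all gates.
#' @export
lefse_like <- function(table, groups, alpha = 0.05, q = 0.10, k = 5) {
  if (abund_kind(table) != "relative") abort("lefse_like needs relative abundances")
  v <- abund_values(table)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) != 2L) abort("lefse_like needs exactly 2 groups")
  empty <- data.frame(species = character(), effect_size = numeric(),
                      enriched_cohort = character(), mwu_p = numeric(),
                      mwu_p_adjusted = numeric(), stringsAsFactors = FALSE)
  mwu_p <- apply(v, 2L, function(col)
    mann_whitney_u(col[groups == gl[1L]], col[groups == gl[2L]])$p_value)
  adj <- bh_two_stage(mwu_p, q = q)
  gate2 <- which(mwu_p <= alpha & adj$rejected)
  if (!length(gate2)) return(empty)
  datapoints <- colSums(v > 0)
  surv <- gate2[datapoints[gate2] >= k]
  if (!length(surv)) return(empty)
  X <- v[, surv, drop = FALSE] * 1e6
  in1 <- groups == gl[1L]
  raw_diff <- colMeans(X[in1, , drop = FALSE]) -
    colMeans(X[!in1, , drop = FALSE])
  lda_diff <- raw_diff
  if (length(surv) >= 2L) {
    w <- tryCatch({
      fit <- MASS::lda(X, grouping = factor(groups))
      sc <- fit$scaling[, 1L]
      sc / sqrt(sum(sc^2))
    }, error = function(e) NULL)
    if (!is.null(w)) {
      proj_diff <- sum(w * raw_diff)  # class-mean difference on the LDA axis
      lda_diff <- w * proj_diff
    }
  }
  eff <- log10(pmax(abs((raw_diff + lda_diff) / 2), 1))
  out <- data.frame(species = colnames(v)[surv],
                    effect_size = unname(eff),
                    enriched_cohort = ifelse(raw_diff >= 0, gl[1L], gl[2L]),
                    mwu_p = unname(mwu_p[surv]),
                    mwu_p_adjusted = unname(adj$adjusted[surv]),
                    stringsAsFactors = FALSE)
  out[order(-out$effect_size), ]
}
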