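#' Shannon diversity index
#'
#' `H = -sum(p_i log_base p_i)` over the non-zero proportions of each
#' sample.  Base 2 by default, so a community spread uniformly over
#' `2^k` species scores `k` bits.
#'
#' @param table an `abund_table` (counts or relative).
#' @param base logarithm base (default 2).
#' @return Named numeric vector, one value per sample.
#' @export
shannon_index <- function(table, base = 2) {
  v <- abund_values(table)
  rs <- rowSums(v)
  if (any(rs <= 0))
    abort("sample(s) with zero total: %s",
          paste(rownames(v)[rs <= 0], collapse = ", "))
  apply(v / rs, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p, base = base))
  })
}

#' Observed species richness
#'
#' @param table an `abund_table`.
#' @return Named integer vector: number of species with value > 0 per sample.
#' @export
observed_species <- function(table) {
  apply(abund_values(table) > 0, 1L, sum)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`; on relative-abundance
#' rows this equals half the L1 distance.  Computed with
#' \code{vegan::vegdist}.
#'
#' @param table an `abund_table` with at least 2 samples, no all-zero rows.
#' @return A `dist` object labelled with sample IDs, entries in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  v <- abund_values(table)
  if (nrow(v) < 2L) abort("need at least 2 samples")
  if (any(rowSums(v) <= 0))
    abort("all-zero sample row(s): %s",
          paste(rownames(v)[rowSums(v) <= 0], collapse = ", "))
  vegan::vegdist(v, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centered
#' Gower matrix `-1/2 J D^2 J`.  Coordinates are the eigenvectors scaled
#' by the square root of their (positive) eigenvalues; axes with
#' non-positive eigenvalues are reported in the eigenvalue vector but
#' excluded from the coordinates, and `proportion_explained` divides by
#' the sum of positive eigenvalues only.  No Lingoes/Cailliez correction
#' is applied.
#'
#' @param d a `dist` or symmetric distance matrix, n >= 3.
#' @return An object of class `pcoa_ordination`: list with `coordinates`
#'   (n x k), `eigenvalues` (all n, descending) and
#'   `proportion_explained` (length k).
#' @export
pcoa_ordination <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3L) abort("need at least 3 samples for PCoA")
  if (max(abs(D - t(D))) > 1e-8) abort("distance matrix is not symmetric")
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lambda <- e$values
  tol <- max(abs(lambda)) * 1e-9
  pos <- which(lambda > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda[pos]),
                                                   length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = lambda,
                 proportion_explained = lambda[pos] / sum(lambda[pos])),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat(sprintf("<pcoa_ordination> %d samples, %d positive axes; first axes explain %s\n",
              nrow(x$coordinates), k,
              paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained, 3L)),
                    collapse = ", ")))
  invisible(x)
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise member distance, so merge heights are non-decreasing.
#'
#' @param d a `dist` or symmetric distance matrix, n >= 2.
#' @return An object of class `hclust`.
#' @export
hca_complete <- function(d) {
  d <- stats::as.dist(as.matrix(d))
  if (attr(d, "Size") < 2L) abort("need at least 2 samples")
  stats::hclust(d, method = "complete")
}
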