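#' Remove low-populated species
#'
#' Species whose total read count across all samples is at most
#' `min_reads` are eliminated before any downstream analysis, mirroring
#' the usual removal of low-populated OTUs in 16S workflows.
#'
#' @param table counts `abund_table`.
#' @param min_reads total-count threshold; species with total `<= min_reads`
#'   are removed (default 5).
#' @return Filtered `abund_table`, species order preserved.
#' @export
min_count_filter <- function(table, min_reads = 5) {
  if (abund_kind(table) != "counts") abort("min_count_filter needs counts")
  v <- abund_values(table)
  keep <- colSums(v) > min_reads
  if (!any(keep)) abort("min_count_filter removed every species")
  dropped <- colnames(v)[!keep]
  if (length(dropped))
    message(sprintf("min_count_filter: removed %d species (total <= %d): %s",
                    length(dropped), min_reads,
                    paste(utils::head(dropped, 10L), collapse = ", ")))
  abundance_table(v[, keep, drop = FALSE], "counts")
}

#' Convert counts to relative abundances
#'
#' @param table counts `abund_table` with positive row sums.
#' @return `abund_table` of kind `"relative"`; every row sums to 1.
#' @export
to_relative <- function(table) {
  v <- abund_values(table)
  rs <- rowSums(v)
  if (any(rs <= 0))
    abort("sample(s) with zero total reads: %s",
          paste(rownames(v)[rs <= 0], collapse = ", "))
  abundance_table(v / rs, "relative")
}

#' Per-species prevalence
#'
#' Fraction of samples in which each species is present (value > 0),
#' independently of its abundance.
#'
#' @param table an `abund_table`.
#' @return Named numeric vector in \[0, 1\].
#' @export
species_prevalence <- function(table) {
  colMeans(abund_values(table) > 0)
}

#' Prevalence filter
#'
#' Keeps species present in at least `threshold` of the samples; the
#' comparison is inclusive, so a species present in exactly 20% of
#' samples survives the default filter.
#'
#' @param table an `abund_table` (counts or relative).
#' @param threshold proportion in (0, 1\] (default 0.20).
#' @return Filtered `abund_table` (possibly with zero species, warned).
#' @export
prevalence_filter <- function(table, threshold = 0.20) {
  if (threshold <= 0 || threshold > 1) abort("threshold must lie in (0, 1]")
  v <- abund_values(table)
  keep <- colMeans(v > 0) >= threshold - 1e-12
  if (!any(keep))
    warn("prevalence_filter: no species at prevalence >= %g", threshold)
  abundance_table(v[, keep, drop = FALSE], abund_kind(table))
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Species columns are summed within their rank label; per-sample totals
#' are conserved exactly.
#'
#' @param table an `abund_table`.
#' @param taxmap a [taxonomy_map()].
#' @param level one of phylum, class, order, family, genus, species.
#' @return `abund_table` with one column per rank label.
#' @export
aggregate_taxonomy <- function(table, taxmap, level) {
  if (!level %in% TAX_RANKS)
    abort("unknown taxonomic level '%s'; expected one of %s", level,
          paste(TAX_RANKS, collapse = ", "))
  v <- abund_values(table)
  missing <- setdiff(colnames(v), taxmap$species_id)
  if (length(missing))
    abort("species missing from taxonomy: %s", paste(missing, collapse = ", "))
  if (level == "species" &&
      all(taxmap$species[match(colnames(v), taxmap$species_id)] ==
            colnames(v)))
    return(table)
  labels <- taxmap[[level]][match(colnames(v), taxmap$species_id)]
  groups <- split(seq_len(ncol(v)), labels)
  agg <- vapply(groups, function(ix) rowSums(v[, ix, drop = FALSE]),
                numeric(nrow(v)))
  if (!is.matrix(agg)) agg <- matrix(agg, nrow = nrow(v),
                                     dimnames = list(rownames(v), names(groups)))
  abundance_table(agg, abund_kind(table))
}

#' Collapse rare taxa into an "Other" category
#'
#' At the requested rank, taxa whose cohort-mean relative abundance falls
#' below `cutoff` are pooled into a single `"Other"` share, the usual
#' convention for composition pie charts.  Shares are conserved.
#'
#' @param table relative `abund_table`.
#' @param taxmap a [taxonomy_map()].
#' @param level taxonomic rank.
#' @param cutoff mean-share threshold (default 0.005, i.e. 0.5%).
#' @return Data frame with columns `taxon` and `share`, `"Other"` last.
#' @export
collapse_other <- function(table, taxmap, level, cutoff = 0.005) {
  if (abund_kind(table) != "relative") abort("collapse_other needs relative abundances")
  agg <- aggregate_taxonomy(table, taxmap, level)
  means <- colMeans(abund_values(agg))
  big <- means >= cutoff
  out <- data.frame(taxon = names(means)[big],
                    share = unname(means[big]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share), ]
  if (any(!big))
    out <- rbind(out, data.frame(taxon = "Other", share = sum(means[!big])))
  rownames(out) <- NULL
  out
}

#' Good's coverage
#'
#' Estimated sampling completeness per sample:
#' `1 - singletons / total reads`, where a singleton is a species observed
#' exactly once in that sample.
#'
#' @param table counts `abund_table` with positive row sums.
#' @return Named numeric vector in \[0, 1\].
#' @export
goods_coverage <- function(table) {
  if (abund_kind(table) != "counts") abort("goods_coverage needs counts")
  v <- abund_values(table)
  rs <- rowSums(v)
  if (any(rs <= 0))
    abort("sample(s) with zero total reads: %s",
          paste(rownames(v)[rs <= 0], collapse = ", "))
  1 - rowSums(v == 1) / rs
}

#' Normal-score normalization followed by standardization
#'
#' Implements the two-step conditioning used before every multivariate
#' stage: each species column is first mapped to a Gaussian shape through
#' van der Waerden scores (mid-ranks r mapped to qnorm(r / (n + 1)), so
#' the transform is monotone and tie-safe, with zeros participating in
#' the ranking), then centered and scaled to mean 0, variance 1.
#'
#' Columns that are constant before the transform carry no information
#' and are excluded with a warning; their IDs are recorded in the result.
#'
#' @param table an `abund_table` with at least 3 samples.
#' @return A `norm_table`: list with `values` (samples x species matrix),
#'   `dropped` (constant species IDs) and `method`.
#' @export
rank_normalize_standardize <- function(table) {
  v <- abund_values(table)
  n <- nrow(v)
  if (n < 3L) abort("need at least 3 samples to normalize")
  const <- apply(v, 2L, function(x) max(x) - min(x) == 0)
  if (all(const)) abort("all species columns are constant")
  if (any(const))
    warn("excluding %d constant species column(s): %s", sum(const),
         paste(colnames(v)[const], collapse = ", "))
  x <- v[, !const, drop = FALSE]
  z <- apply(x, 2L, function(col) stats::qnorm(rank(col) / (n + 1)))
  z <- scale(z)
  out <- matrix(as.numeric(z), n, ncol(x),
                dimnames = list(rownames(v), colnames(x)))
  structure(list(values = out,
                 dropped = colnames(v)[const],
                 method = "van der Waerden + z-score"),
            class = "norm_table")
}

#' @export
print.norm_table <- function(x, ...) {
  cat(sprintf("<norm_table> %d samples x %d species (%s; %d constant column(s) dropped)\n",
              nrow(x$values), ncol(x$values), x$method, length(x$dropped)))
  invisible(x)
}

norm_values <- function(x) {
  if (inherits(x, "norm_table")) x$values
  else if (inherits(x, "abund_table")) abund_values(x)
  else as.matrix(x)
}
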