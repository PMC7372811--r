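#' Cohort-mean composition summary with an "Other" category
#'
#' Mean relative abundance per taxon at the requested rank, computed per
#' cohort when `groups` is given, with rare taxa pooled as in
#' [collapse_other()].  Shares are conserved within each cohort.
#'
#' @param table relative `abund_table`.
#' @param taxmap a [taxonomy_map()].
#' @param level taxonomic rank.
#' @param groups optional cohort labels, one per sample.
#' @param cutoff "Other" pooling cutoff (default 0.005).
#' @return Data frame `cohort`, `taxon`, `share`.
#' @export
summarize_composition <- function(table, taxmap, level, groups = NULL,
                                  cutoff = 0.005) {
  if (is.null(groups)) groups <- rep("all", nrow(abund_values(table)))
  groups <- as.character(groups)
  out <- lapply(sort(unique(groups)), function(g) {
    sub <- abundance_table(
      abund_values(table)[groups == g, , drop = FALSE], "relative")
    cbind(cohort = g, collapse_other(sub, taxmap, level, cutoff = cutoff))
  })
  do.call(rbind, out)
}

comparison_labels <- function(meta, comparison, habitat = NULL) {
  if (comparison == "habitat") {
    stats::setNames(meta$habitat, meta$sample_id)
  } else {
    sub <- meta[meta$habitat == habitat, ]
    stats::setNames(sub$outcome, sub$sample_id)
  }
}

analyse_comparison <- function(rel, labels, params, seed_offset) {
  samples <- names(labels)
  rel_c <- subset_table(rel, samples = samples)
  lab <- unname(labels)
  sizes <- table(lab)
  res <- list(group_sizes = as.list(sizes))
  if (min(sizes) < 3L) {
    warn("comparison skipped: group(s) with fewer than 3 samples (%s)",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
    res$skipped <- TRUE
    return(res)
  }
  res$skipped <- FALSE
  res$low_power <- min(sizes) < 5L

  d <- bray_curtis(rel_c)
  res$pcoa <- pcoa_ordination(d)
  res$hca <- hca_complete(d)
  res$anosim <- anosim_test(d, lab, n_perm = params$n_perm,
                            seed = params$seed + seed_offset)
  res$permanova <- permanova_test(d, lab, n_perm = params$n_perm,
                                  seed = params$seed + seed_offset + 1L)

  # prevalence filter on raw relative values of this cohort, then the
  # normal-score transform restricted to the surviving species
  filt <- prevalence_filter(rel_c, params$prevalence_threshold)
  res$n_prevalent_species <- length(species_ids(filt))
  if (res$n_prevalent_species >= 2L) {
    norm <- rank_normalize_standardize(filt)
    res$vip <- vip_report(filt, norm, lab,
                          n_components = params$n_components,
                          alpha = params$alpha, q = params$fdr_q)
    res$lefse <- lefse_like(filt, lab, alpha = params$alpha,
                            q = params$fdr_q, k = params$min_datapoints)
  }

  # one co-occurrence network per cohort, on that cohort's own
  # prevalence-filtered, normalized data
  res$networks <- list()
  for (g in names(sizes)) {
    gs <- samples[lab == g]
    if (length(gs) < 3L) next
    rel_g <- subset_table(rel, samples = gs)
    filt_g <- prevalence_filter(rel_g, params$prevalence_threshold)
    if (length(species_ids(filt_g)) < 2L) next
    norm_g <- rank_normalize_standardize(filt_g)
    stats_g <- data.frame(species = species_ids(filt_g),
                          prevalence = unname(species_prevalence(filt_g)),
                          mean_norm_abundance =
                            unname(colMeans(abund_values(filt_g))))
    net <- build_cooccurrence(norm_g, alpha = params$edge_alpha,
                              node_stats = stats_g)
    comm <- louvain_communities(net, resolution = params$resolution,
                                n_restarts = params$n_restarts,
                                seed = params$seed + seed_offset + 2L)
    net <- set_communities(net, comm)
    res$networks[[g]] <- list(network = net, communities = comm,
                              keystones = keystone_species(net, params$top_k))
  }
  res
}

default_params <- function() {
  list(min_reads = 5, prevalence_threshold = 0.20, other_cutoff = 0.005,
       alpha = 0.05, fdr_q = 0.10, min_datapoints = 5, n_components = 2,
       n_perm = 999, edge_alpha = 0.05, resolution = 1, n_restarts = 10,
       top_k = 3, seed = 1L)
}

#' Run the full paired-habitat analysis pipeline
#'
#' Orchestrates the study-shaped analysis on an abundance table plus
#' metadata (or a `synthetic_cohort`): low-count filter, relative
#' abundances, alpha diversity on counts, Bray-Curtis, PCoA and
#' complete-linkage clustering, ANOSIM and PERMANOVA, normal-score
#' normalization, prevalence filter, leave-one-out PLS-DA VIP and fold
#' ratios, LEfSe-style effect sizes, and per-cohort co-occurrence
#' networks with Louvain communities and keystone ranking.  The habitat
#' comparison pools both outcome groups; the outcome comparison runs
#' within each habitat.  A comparison group with fewer than 3 samples
#' skips the affected stages with a warning rather than failing.
#'
#' @param x a `synthetic_cohort`, or an `abund_table` of counts.
#' @param metadata a [sample_metadata()] covering the samples (taken from
#'   the cohort when `x` is one).
#' @param taxonomy optional [taxonomy_map()] (for composition summaries).
#' @param comparison `"habitat"`, `"outcome_within_habitat"` or `"both"`.
#' @param out_dir optional directory; when given, all tables, networks
#'   (GEXF) and the manifest are written there.
#' @param ... parameter overrides: `min_reads`, `prevalence_threshold`,
#'   `other_cutoff`, `alpha`, `fdr_q`, `min_datapoints`, `n_components`,
#'   `n_perm`, `edge_alpha`, `resolution`, `n_restarts`, `top_k`, `seed`.
#' @return A `pipeline_report`: list with `alpha_diversity`,
#'   `goods_coverage`, `comparisons`, `composition` (when taxonomy is
#'   available) and `manifest`.  Reruns with an identical manifest are
#'   bit-identical.
#' @export
run_pipeline <- function(x, metadata = NULL, taxonomy = NULL,
                         comparison = c("both", "habitat",
                                        "outcome_within_habitat"),
                         out_dir = NULL, ...) {
  comparison <- match.arg(comparison)
  if (inherits(x, "synthetic_cohort")) {
    metadata <- x$metadata
    taxonomy <- taxonomy %||% x$taxonomy
    x <- x$abundance
  }
  stopifnot(inherits(x, "abund_table"))
  if (is.null(metadata)) abort("metadata is required")
  metadata <- sample_metadata(metadata)
  missing <- setdiff(sample_ids(x), metadata$sample_id)
  if (length(missing))
    abort("metadata does not cover sample(s): %s",
          paste(missing, collapse = ", "))
  metadata <- metadata[match(sample_ids(x), metadata$sample_id), ]

  params <- default_params()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown))
    abort("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  params[names(dots)] <- dots
  params$seed <- as.integer(params$seed)

  counts <- min_count_filter(x, params$min_reads)
  rel <- to_relative(counts)
  alpha_div <- data.frame(sample_id = sample_ids(counts),
                          habitat = metadata$habitat,
                          outcome = metadata$outcome,
                          observed = unname(observed_species(counts)),
                          shannon = unname(shannon_index(counts)),
                          stringsAsFactors = FALSE)
  coverage <- goods_coverage(counts)

  comparisons <- list()
  if (comparison %in% c("both", "habitat")) {
    comparisons$habitat <- analyse_comparison(
      rel, comparison_labels(metadata, "habitat"), params, 0L)
  }
  if (comparison %in% c("both", "outcome_within_habitat")) {
    for (h in intersect(HABITATS, unique(metadata$habitat))) {
      labs <- comparison_labels(metadata, "outcome", habitat = h)
      if (length(unique(unname(labs))) < 2L) next
      comparisons[[paste0("outcome_", h)]] <-
        analyse_comparison(rel, labs, params, 100L)
    }
  }

  composition <- NULL
  if (!is.null(taxonomy)) {
    composition <- lapply(
      stats::setNames(c("phylum", "family", "species"),
                      c("phylum", "family", "species")),
      function(lv) summarize_composition(rel, taxonomy, lv,
                                         groups = metadata$habitat,
                                         cutoff = params$other_cutoff))
  }

  manifest <- list(package = "mucosanet",
                   version = as.character(utils::packageVersion("mucosanet")),
                   comparison = comparison,
                   n_samples = nrow(abund_values(x)),
                   n_species_input = ncol(abund_values(x)),
                   parameters = params)
  report <- structure(list(alpha_diversity = alpha_div,
                           goods_coverage = coverage,
                           comparisons = comparisons,
                           composition = composition,
                           manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d samples, %d comparisons\n",
              nrow(x$alpha_diversity), length(x$comparisons)))
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    if (isTRUE(cmp$skipped)) {
      cat(sprintf("  %s: skipped (group too small)\n", nm))
    } else {
      cat(sprintf("  %s: ANOSIM R = %.3f (p = %.3g), PERMANOVA F = %.2f (p = %.3g), %d prevalent species\n",
                  nm, cmp$anosim$statistic, cmp$anosim$p_value,
                  cmp$permanova$statistic, cmp$permanova$p_value,
                  cmp$n_prevalent_species))
    }
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a pipeline report to a directory
#'
#' Emits per-stage TSV tables, GEXF networks and `manifest.json` plus a
#' `summary.json` of headline numbers.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$alpha_diversity, file.path(out_dir, "alpha_diversity.tsv"))
  write_tsv(data.frame(sample_id = names(report$goods_coverage),
                       coverage = unname(report$goods_coverage)),
            file.path(out_dir, "goods_coverage.tsv"))
  summary <- list()
  for (nm in names(report$comparisons)) {
    cmp <- report$comparisons[[nm]]
    if (isTRUE(cmp$skipped)) next
    pre <- file.path(out_dir, nm)
    co <- cmp$pcoa$coordinates
    write_tsv(cbind(data.frame(sample_id = rownames(co)), as.data.frame(co)),
              file.path(paste0(pre, "_pcoa.tsv")))
    hm <- cmp$hca
    write_tsv(data.frame(merge_left = hm$merge[, 1L],
                         merge_right = hm$merge[, 2L],
                         height = hm$height),
              file.path(paste0(pre, "_linkage.tsv")))
    if (!is.null(cmp$vip)) write_tsv(cmp$vip, paste0(pre, "_vip.tsv"))
    if (!is.null(cmp$lefse)) write_tsv(cmp$lefse, paste0(pre, "_lefse.tsv"))
    for (g in names(cmp$networks)) {
      nw <- cmp$networks[[g]]
      write_network_gexf(nw$network, paste0(pre, "_", g, "_network.gexf"))
      write_tsv(nw$network$nodes, paste0(pre, "_", g, "_nodes.tsv"))
      write_tsv(nw$network$edges, paste0(pre, "_", g, "_edges.tsv"))
    }
    summary[[nm]] <- list(
      anosim_r = cmp$anosim$statistic, anosim_p = cmp$anosim$p_value,
      permanova_f = cmp$permanova$statistic,
      permanova_p = cmp$permanova$p_value,
      n_prevalent_species = cmp$n_prevalent_species,
      modularity = lapply(cmp$networks, function(nw) nw$communities$modularity),
      low_power = cmp$low_power)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
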