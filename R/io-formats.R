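#' Construct an abundance table
#'
#' The central container of the pipeline: a samples x species matrix of
#' either integer read counts (`kind = "counts"`) or relative abundances
#' (`kind = "relative"`).  Row names are sample identifiers, column names
#' species identifiers; both must be unique and non-empty.
#'
#' Relative tables must have rows summing to at most 1 (within 1e-9); a
#' freshly closed table sums to exactly 1, while tables that have passed a
#' species filter may sum to less.  All-zero rows are forbidden for
#' relative tables.
#'
#' @param values numeric matrix, samples in rows, species in columns, with
#'   dimnames set.
#' @param kind `"counts"` (non-negative integers) or `"relative"`.
#' @return An object of class `abund_table`.
#' @export
abundance_table <- function(values, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix")
  sn <- rownames(values)
  sp <- colnames(values)
  if (is.null(sn) || is.null(sp))
    abort("`values` must carry sample (row) and species (column) names")
  if (anyDuplicated(sn))
    abort("duplicate sample ID(s): %s",
          paste(unique(sn[duplicated(sn)]), collapse = ", "))
  if (anyDuplicated(sp))
    abort("duplicate species ID(s): %s",
          paste(unique(sp[duplicated(sp)]), collapse = ", "))
  if (anyNA(values)) abort("abundance values must not contain NA")
  if (any(values < 0)) abort("abundance values must be non-negative")
  if (kind == "counts") {
    if (max(abs(values - round(values))) > 1e-9)
      abort("kind = \"counts\" requires integral values")
    values <- round(values)
  } else if (ncol(values) > 0L) {
    # a freshly closed table has rows summing to exactly 1; tables that
    # passed a species filter may sum to less, but never more
    rs <- rowSums(values)
    if (any(rs > 1 + 1e-9))
      abort("relative abundances of sample(s) %s sum to more than 1",
            paste(sn[rs > 1 + 1e-9], collapse = ", "))
  }
  structure(list(values = values, kind = kind), class = "abund_table")
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("<abund_table> %d samples x %d species, kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' Accessors for abundance tables
#'
#' @param x an `abund_table`.
#' @return `abund_values()` the numeric matrix; `abund_kind()` the kind
#'   string; `sample_ids()`/`species_ids()` character vectors.
#' @export
abund_values <- function(x) x$values

#' @rdname abund_values
#' @export
abund_kind <- function(x) x$kind

#' @rdname abund_values
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname abund_values
#' @export
species_ids <- function(x) colnames(x$values)

#' Subset an abundance table by sample and/or species IDs
#'
#' @param x an `abund_table`.
#' @param samples,species character vectors of IDs to keep (default: all).
#' @return An `abund_table` restricted to the requested rows/columns.
#' @export
subset_table <- function(x, samples = NULL, species = NULL) {
  v <- x$values
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(v))
    if (length(missing))
      abort("unknown sample ID(s): %s", paste(missing, collapse = ", "))
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(species)) {
    missing <- setdiff(species, colnames(v))
    if (length(missing))
      abort("unknown species ID(s): %s", paste(missing, collapse = ", "))
    v <- v[, species, drop = FALSE]
  }
  abundance_table(v, x$kind)
}

split_tsv_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(fields = strsplit(raw[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' Read an abundance table
#'
#' Two dialects are supported.  `"tsv"` is the canonical format: a '#'-
#' commentable UTF-8 file whose header row holds `sample_id` followed by
#' species IDs, one sample per subsequent row.  `"mothur_shared"` is the
#' mothur `.shared` dialect (`label Group numOtus OTU...` header); the
#' `label` column is ignored with a warning, counts only.
#'
#' Tables whose values are all integral are typed `kind = "counts"`,
#' otherwise `kind = "relative"`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mothur_shared"`.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, format = c("tsv", "mothur_shared")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("file not found: %s", path)
  parsed <- split_tsv_lines(path)
  fields <- parsed$fields
  if (length(fields) < 2L) abort("%s: need a header and at least one sample row", path)
  header <- fields[[1L]]
  rows <- fields[-1L]
  lineno <- parsed$lineno[-1L]

  if (format == "mothur_shared") {
    if (length(header) < 4L || !identical(tolower(header[1:3]),
                                          c("label", "group", "numotus")))
      abort("%s: not a mothur shared file (expected 'label Group numOtus ...' header)",
            path)
    species <- header[-(1:3)]
    warn("mothur shared: ignoring 'label' column (%s)",
         paste(unique(vapply(rows, `[`, "", 1L)), collapse = ", "))
    n_otus <- length(species)
    vals <- matrix(NA_real_, length(rows), n_otus)
    samples <- character(length(rows))
    for (k in seq_along(rows)) {
      f <- rows[[k]]
      if (length(f) != length(header))
        abort("%s line %d: expected %d fields, found %d", path,
              lineno[k], length(header), length(f))
      samples[k] <- f[2L]
      if (as.integer(f[3L]) != n_otus)
        abort("%s line %d: numOtus (%s) disagrees with header (%d)",
              path, lineno[k], f[3L], n_otus)
      vals[k, ] <- as.numeric(f[-(1:3)])
    }
  } else {
    if (tolower(header[1L]) != "sample_id")
      abort("%s: first header field must be 'sample_id'", path)
    species <- header[-1L]
    vals <- matrix(NA_real_, length(rows), length(species))
    samples <- character(length(rows))
    for (k in seq_along(rows)) {
      f <- rows[[k]]
      if (length(f) != length(header))
        abort("%s line %d: expected %d fields, found %d", path,
              lineno[k], length(header), length(f))
      samples[k] <- f[1L]
      vals[k, ] <- as.numeric(f[-1L])
    }
  }
  if (anyNA(vals)) abort("%s: non-numeric abundance value", path)
  dimnames(vals) <- list(samples, species)
  kind <- if (max(abs(vals - round(vals))) <= 1e-9) "counts" else "relative"
  abundance_table(vals, kind)
}

#' Write an abundance table as TSV
#'
#' Inverse of [read_abundance()] for the `"tsv"` dialect; numeric values
#' are written at 12 significant digits.
#'
#' @param table an `abund_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path) {
  v <- abund_values(table)
  body <- if (abund_kind(table) == "counts") {
    apply(v, 1L, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                   collapse = "\t"))
  } else {
    apply(v, 1L, function(r) paste(num_chr(r), collapse = "\t"))
  }
  lines <- c(paste(c("sample_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a counts table in the mothur `.shared` dialect
#'
#' @param table an `abund_table` of kind `"counts"`.
#' @param path output file path.
#' @param label OTU-clustering label column value (default `"0.03"`).
#' @return `path`, invisibly.
#' @export
write_mothur_shared <- function(table, path, label = "0.03") {
  if (abund_kind(table) != "counts")
    abort("mothur shared files hold counts")
  v <- abund_values(table)
  lines <- c(paste(c("label", "Group", "numOtus", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(label, rownames(v)[i], ncol(v),
                       format(v[i, ], scientific = FALSE, trim = TRUE)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

HABITATS <- c("endometrium", "vagina")
OUTCOMES <- c("pregnant", "non_pregnant")
TAX_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Construct / validate sample metadata
#'
#' @param df data frame with columns `sample_id`, `habitat`
#'   (endometrium/vagina) and `outcome` (pregnant/non_pregnant).
#' @return The validated data frame, classed `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "habitat", "outcome")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort("metadata is missing column(s): %s", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[need]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$sample_id))
    abort("duplicate sample ID(s) in metadata: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$habitat), HABITATS)
  if (length(bad))
    abort("unknown habitat label(s) %s; allowed: %s",
          paste(bad, collapse = ", "), paste(HABITATS, collapse = ", "))
  bad <- setdiff(unique(df$outcome), OUTCOMES)
  if (length(bad))
    abort("unknown outcome label(s) %s; allowed: %s",
          paste(bad, collapse = ", "), paste(OUTCOMES, collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' @param path TSV with header `sample_id`, `habitat`, `outcome`.
#' @return A [sample_metadata()] data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  sample_metadata(df)
}

#' @rdname read_metadata
#' @param meta a `sample_metadata` data frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / validate a taxonomy map
#'
#' One row per species; required column `species_id`, plus the six ranks
#' phylum..species.  Missing rank columns or empty/NA cells are filled
#' with `"unclassified"`.
#'
#' @param df data frame.
#' @return Data frame classed `taxonomy_map` with all seven columns.
#' @export
taxonomy_map <- function(df) {
  if (!"species_id" %in% names(df))
    abort("taxonomy is missing the species_id column")
  df <- as.data.frame(df)
  df[] <- lapply(df, as.character)
  for (r in TAX_RANKS) {
    if (!r %in% names(df)) df[[r]] <- "unclassified"
    blank <- is.na(df[[r]]) | df[[r]] == ""
    df[[r]][blank] <- "unclassified"
  }
  if (anyDuplicated(df$species_id))
    abort("duplicate species ID(s) in taxonomy: %s",
          paste(unique(df$species_id[duplicated(df$species_id)]), collapse = ", "))
  df <- df[c("species_id", TAX_RANKS)]
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Read a taxonomy map from TSV
#'
#' @param path TSV with header `species_id` plus rank columns.
#' @return A [taxonomy_map()] data frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  taxonomy_map(df)
}

#' @rdname read_taxonomy
#' @param tax a `taxonomy_map` data frame.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

GEXF_NODE_ATTRS <- c(community = "integer", degree = "integer",
                     betweenness = "double", mean_norm_abundance = "double",
                     prevalence = "double")
GEXF_EDGE_ATTRS <- c(r = "double", p = "double", sign = "string",
                     category = "integer")

#' Write a co-occurrence network as GEXF 1.2
#'
#' Gephi's exchange format.  Node attributes: community, degree,
#' betweenness, mean_norm_abundance, prevalence.  Edge attributes: r, p,
#' sign, category; the GEXF edge weight is |r|.
#'
#' @param net a `cooc_network` (see [build_cooccurrence()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_gexf <- function(net, path) {
  stopifnot(inherits(net, "cooc_network"))
  if (nrow(net$nodes) < 1L) abort("network has no nodes")
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  natt <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (k in seq_along(GEXF_NODE_ATTRS))
    xml2::xml_add_child(natt, "attribute", id = as.character(k - 1L),
                        title = names(GEXF_NODE_ATTRS)[k],
                        type = GEXF_NODE_ATTRS[[k]])
  eatt <- xml2::xml_add_child(graph, "attributes", class = "edge")
  for (k in seq_along(GEXF_EDGE_ATTRS))
    xml2::xml_add_child(eatt, "attribute", id = as.character(k - 1L),
                        title = names(GEXF_EDGE_ATTRS)[k],
                        type = GEXF_EDGE_ATTRS[[k]])
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) num_chr(x) else as.character(x)
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = net$nodes$species[i],
                              label = net$nodes$species[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    for (k in seq_along(GEXF_NODE_ATTRS)) {
      val <- net$nodes[[names(GEXF_NODE_ATTRS)[k]]][i]
      if (!is.na(val))
        xml2::xml_add_child(av, "attvalue", `for` = as.character(k - 1L),
                            value = fmt(val))
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  if (nrow(net$edges)) {
    for (i in seq_len(nrow(net$edges))) {
      ed <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                                source = net$edges$from[i],
                                target = net$edges$to[i],
                                weight = num_chr(net$edges$weight[i]))
      av <- xml2::xml_add_child(ed, "attvalues")
      for (k in seq_along(GEXF_EDGE_ATTRS))
        xml2::xml_add_child(av, "attvalue", `for` = as.character(k - 1L),
                            value = fmt(net$edges[[names(GEXF_EDGE_ATTRS)[k]]][i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GEXF 1.2 network written by [write_network_gexf()]
#'
#' @param path GEXF file path.
#' @return A `cooc_network` with the stored node and edge attributes.
#' @export
read_network_gexf <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  get_attvals <- function(node) {
    avs <- xml2::xml_find_all(node, "./attvalues/attvalue")
    stats::setNames(xml2::xml_attr(avs, "value"), xml2::xml_attr(avs, "for"))
  }
  nnodes <- xml2::xml_find_all(doc, ".//nodes/node")
  nodes <- data.frame(species = xml2::xml_attr(nnodes, "id"),
                      stringsAsFactors = FALSE)
  for (k in seq_along(GEXF_NODE_ATTRS)) {
    nm <- names(GEXF_NODE_ATTRS)[k]
    raw <- vapply(nnodes, function(nd) {
      av <- get_attvals(nd)
      if (as.character(k - 1L) %in% names(av)) av[[as.character(k - 1L)]]
      else NA_character_
    }, "")
    nodes[[nm]] <- switch(GEXF_NODE_ATTRS[[k]],
                          integer = as.integer(raw),
                          double = as.numeric(raw),
                          raw)
  }
  nedges <- xml2::xml_find_all(doc, ".//edges/edge")
  if (length(nedges)) {
    edges <- data.frame(from = xml2::xml_attr(nedges, "source"),
                        to = xml2::xml_attr(nedges, "target"),
                        weight = as.numeric(xml2::xml_attr(nedges, "weight")),
                        stringsAsFactors = FALSE)
    for (k in seq_along(GEXF_EDGE_ATTRS)) {
      nm <- names(GEXF_EDGE_ATTRS)[k]
      raw <- vapply(nedges, function(ed) {
        av <- get_attvals(ed)
        if (as.character(k - 1L) %in% names(av)) av[[as.character(k - 1L)]]
        else NA_character_
      }, "")
      edges[[nm]] <- switch(GEXF_EDGE_ATTRS[[k]],
                            integer = as.integer(raw),
                            double = as.numeric(raw),
                            raw)
    }
  } else {
    edges <- empty_edge_frame()
  }
  structure(list(nodes = nodes,
                 edges = edges[c("from", "to", "r", "p", "sign",
                                 "category", "weight")],
                 alpha = NA_real_),
            class = "cooc_network")
}
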