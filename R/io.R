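# Readers/writers for the tabular, tree and network artifacts the pipeline
# touches. All tables are plain TSV with a header row; trees are Newick;
# networks export as Cytoscape-style edge-list TSV (+ node table) or GraphML.

#' Read an ASV count table from TSV
#'
#' The file must be tab-separated with a header row; the first column holds
#' identifiers. Orientation (samples-as-rows vs taxa-as-rows) is resolved by
#' `orientation`, or by matching identifiers against `metadata$sample_id` when
#' `orientation = "auto"` and metadata is supplied. Internally tables are
#' always samples-as-rows.
#'
#' @param path Path to a TSV file.
#' @param orientation One of `"auto"`, `"samples"` (rows are samples) or
#'   `"taxa"` (rows are ASVs; the table is transposed on read).
#' @param metadata Optional sample metadata tibble (columns `sample_id`,
#'   `group`) used to resolve `"auto"` orientation.
#' @return A count tibble (first column `sample_id`, one column per ASV).
#' @export
read_count_table <- function(path, orientation = c("auto", "samples", "taxa"),
                             metadata = NULL) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  if (ncol(raw) < 2) abort("Count table needs an id column plus at least one value column.")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated id(s) in first column of ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (orientation == "auto") {
    if (!is.null(metadata)) {
      row_hits <- mean(ids %in% metadata$sample_id)
      col_hits <- mean(names(raw)[-1] %in% metadata$sample_id)
      orientation <- if (col_hits > row_hits) "taxa" else "samples"
    } else {
      orientation <- "samples"
    }
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(as.data.frame(raw[, -1, drop = FALSE]), is.numeric, logical(1)))[1]
    abort(sprintf("Non-numeric cells in column '%s' of %s.", names(raw)[-1][bad], path))
  }
  rownames(m) <- ids
  if (orientation == "taxa") m <- t(m)
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-integer count at row '%s', column '%s' of %s.",
                  rownames(m)[bad[1]], colnames(m)[bad[2]], path))
  }
  out <- as_count_tibble(m)
  validate_count_table(out, integer_only = TRUE)
  out
}

#' Write a count table to TSV (samples as rows)
#'
#' @param counts Count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read / write two-column sample metadata (sample_id, group)
#'
#' @param path TSV path.
#' @return Tibble with columns `sample_id`, `group`.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  if (!all(c("sample_id", "group") %in% names(md))) {
    abort("Metadata file must have columns `sample_id` and `group`.")
  }
  if (anyDuplicated(md$sample_id)) abort("Duplicated sample ids in metadata.")
  md[, c("sample_id", "group")]
}

#' @rdname read_sample_metadata
#' @param metadata Tibble with columns `sample_id`, `group`.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(metadata[, c("sample_id", "group")], path)
  invisible(path)
}

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read / write a taxonomy table (ASV id + six ranks)
#'
#' Missing or empty rank strings are replaced with `"unclassified"`.
#'
#' @param path TSV path with columns `asv_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`.
#' @return Taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  need <- c("asv_id", TAX_RANKS)
  if (!all(need %in% names(tax))) {
    abort(paste0("Taxonomy file must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tax$asv_id)) abort("Duplicated ASV ids in taxonomy.")
  tax <- tax[, need]
  tax <- mutate(tax, across(all_of(TAX_RANKS),
                            ~ ifelse(is.na(.x) | .x == "", "unclassified", .x)))
  tax
}

#' @rdname read_taxonomy
#' @param taxonomy Taxonomy tibble.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy[, c("asv_id", TAX_RANKS)], path)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Branch lengths are required by downstream Faith PD; any missing lengths are
#' set to 0 with a warning. Duplicate tip labels are an error.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] tree.
#' @export
read_phylo_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort(paste0("Newick parse error in ", path, ": ",
                                                  conditionMessage(e))))
  if (is.null(tr)) abort(paste0("Newick parse error in ", path, ": no tree found."))
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0("Duplicate tip label(s): ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", ")))
  }
  if (is.null(tr$edge.length)) {
    warn("Tree has no branch lengths; setting all to 0.")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warn("Tree has missing branch lengths; setting them to 0.")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) abort("Tree has negative branch lengths.")
  tr
}

#' @rdname read_phylo_tree
#' @param tree An [ape::phylo] tree.
#' @export
write_phylo_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a co-occurrence network for graph viewers
#'
#' Writes either a Cytoscape-compatible edge-list TSV (plus a companion
#' `<path>.nodes.tsv` node-attribute table) or a GraphML file. Node attributes:
#' phylum, mean clr abundance, cluster id, eigenvector centrality; edge
#' attributes: Pearson r, sign, signed weight w = (1 + r) / 2.
#'
#' @param net A `micronet_network` (see [build_network()]).
#' @param path Output path.
#' @param dialect `"edgelist"` or `"graphml"`.
#' @param partition Optional `micronet_partition` supplying cluster ids.
#' @param centrality Optional tibble (`asv_id`, `centrality`), e.g. from
#'   [eigenvector_centrality()].
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("edgelist", "graphml"),
                          partition = NULL, centrality = NULL) {
  if (!inherits(net, "micronet_network")) abort("`net` must be a micronet_network.")
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) abort(
                        "Unknown dialect; supported dialects: edgelist, graphml."))
  nodes <- net$nodes
  if (!is.null(partition)) {
    nodes <- left_join(nodes, partition$membership, by = "asv_id")
  }
  if (!is.null(centrality)) {
    nodes <- left_join(nodes, centrality[, c("asv_id", "centrality")], by = "asv_id")
  }
  if (dialect == "edgelist") {
    readr::write_tsv(net$edges, path)
    readr::write_tsv(nodes, paste0(path, ".nodes.tsv"))
  } else {
    g <- as_igraph(net)
    for (col in setdiff(names(nodes), "asv_id")) {
      val <- nodes[[col]][match(igraph::V(g)$name, nodes$asv_id)]
      g <- igraph::set_vertex_attr(g, col, value = val)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
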