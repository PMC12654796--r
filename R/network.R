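# Compositional co-occurrence networks: prevalence filter, clr transform,
# Pearson correlation, signed-weight thresholded graph, fast-greedy modularity
# clusters, edge-sign architecture, ratio shifts and keystone taxa.

# wide tibble (id column + numeric columns) -> plain matrix, no sign checks
wide_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x[[1]]
  m
}

#' Keep ASVs present in a minimum number of samples
#'
#' @param counts Count tibble (typically one condition's samples only).
#' @param min_samples Minimum number of samples with a nonzero count
#'   (inclusive; default 5).
#' @return Filtered count tibble.
#' @export
prevalence_filter <- function(counts, min_samples = 5) {
  if (min_samples < 1) abort("`min_samples` must be >= 1.")
  m <- as_count_matrix(counts)
  keep <- colSums(m > 0) >= min_samples
  counts[, c(TRUE, keep), drop = FALSE]
}

# core clr math on a samples x taxa matrix
clr_matrix <- function(m, pseudocount = 1) {
  lm_ <- log(m + pseudocount)
  lm_ - rowMeans(lm_)
}

#' Centered log-ratio transform
#'
#' \eqn{x_{ij} = \ln(c_{ij} + pc) - \overline{\ln(c_{i\cdot} + pc)}} per
#' sample; each transformed row sums to zero. The pseudocount (default 1)
#' handles zero counts.
#'
#' @param counts Count tibble.
#' @param pseudocount Positive pseudocount.
#' @return Tibble of clr values (same shape as `counts`), attribute
#'   `pseudocount`.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  m <- as_count_matrix(counts)
  out <- as_count_tibble(clr_matrix(m, pseudocount))
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Signed edge weight from a Pearson correlation
#'
#' The affine map \eqn{w = (1 + r) / 2}: a correlation of 1 maps to weight 1,
#' 0 to 1/2, and -1 to 0, giving non-negative weights for modularity and
#' centrality computations.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Weight(s) in `[0, 1]`.
#' @export
signed_weight <- function(r) (1 + r) / 2

#' Construct a co-occurrence network object
#'
#' Low-level constructor used by [build_network()] and for assembling test
#' networks directly from an edge table.
#'
#' @param edges Tibble with columns `from`, `to` and `r` (Pearson
#'   correlation); `sign` and `weight` are derived.
#' @param nodes Optional tibble with `asv_id` plus attribute columns; default
#'   is derived from the edge endpoints.
#' @param threshold Correlation threshold the edges were selected at.
#' @return A `micronet_network`: list with `nodes`, `edges`, `threshold`.
#' @export
cooccurrence_network <- function(edges, nodes = NULL, threshold = NA_real_) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to", "r") %in% names(edges))) {
    abort("`edges` needs columns from, to, r.")
  }
  if (any(edges$from == edges$to)) abort("Self-edges are not allowed.")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) abort("Each unordered node pair may appear at most once.")
  edges$sign <- ifelse(edges$r >= 0, 1L, -1L)
  edges$weight <- signed_weight(edges$r)
  if (is.null(nodes)) {
    nodes <- tibble(asv_id = sort(unique(c(edges$from, edges$to))),
                    phylum = NA_character_, clr_mean = NA_real_)
  }
  if (!all(c(edges$from, edges$to) %in% nodes$asv_id)) {
    abort("Edge endpoint(s) missing from the node table.")
  }
  deg <- table(c(edges$from, edges$to))
  nodes$degree <- as.integer(deg[nodes$asv_id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "micronet_network")
}

#' Build a signed co-occurrence network from clr abundances
#'
#' Pearson correlations are computed across samples for every ASV pair; pairs
#' with `|r| >= threshold` become edges with sign `sign(r)` and weight
#' `(1 + r) / 2`. Zero-variance ASVs are excluded with a warning (their
#' correlation is undefined), and ASVs left without any edge are dropped from
#' the network but recorded in the `isolated` field.
#'
#' @param clr Clr tibble from [clr_transform()].
#' @param threshold Correlation threshold in `(0, 1)`, e.g. from
#'   [rmt_threshold()].
#' @param taxonomy Optional taxonomy tibble supplying the `phylum` node
#'   attribute.
#' @return A `micronet_network` (nodes carry `phylum`, mean clr abundance and
#'   degree; `isolated` lists dropped ASVs).
#' @export
build_network <- function(clr, threshold, taxonomy = NULL) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  m <- wide_matrix(clr)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("Excluding zero-variance ASV(s): ",
                paste(colnames(m)[sds == 0], collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
  }
  r <- cor(m)
  ut <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  edges <- tibble(from = colnames(r)[ut[, 1]], to = colnames(r)[ut[, 2]],
                  r = r[ut])
  connected <- sort(unique(c(edges$from, edges$to)))
  isolated <- setdiff(colnames(m), connected)
  if (length(isolated) > 0) {
    inform(sprintf("%d ASV(s) have no edge at |r| >= %.3g and were dropped from the network.",
                   length(isolated), threshold))
  }
  nodes <- tibble(asv_id = connected)
  nodes$phylum <- if (!is.null(taxonomy)) {
    taxonomy$phylum[match(nodes$asv_id, taxonomy$asv_id)]
  } else NA_character_
  nodes$clr_mean <- colMeans(m)[nodes$asv_id]
  net <- cooccurrence_network(edges, nodes, threshold = threshold)
  net$isolated <- isolated
  net
}

#' @export
print.micronet_network <- function(x, ...) {
  s <- edge_sign_summary(x)
  cat(sprintf("Co-occurrence network: %d nodes, %d edges (%d positive, %d negative, +/- ratio %.2f), |r| >= %.3g\n",
              s$n_nodes, s$n_edges, s$n_positive, s$n_negative, s$ratio,
              x$threshold))
  invisible(x)
}

#' Convert a network to an igraph graph
#'
#' Vertices are ordered by ASV id so the conversion is invariant to node
#' input order; edge attribute `weight` holds the signed weight.
#'
#' @param net A `micronet_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  nodes <- arrange(net$nodes, .data$asv_id)
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = nodes["asv_id"])
}

#' Fast-greedy modularity clustering
#'
#' Greedy agglomerative modularity maximization (Clauset-Newman-Moore) on the
#' non-negative signed weights `w = (1 + r) / 2`. Cluster ids are
#' canonicalized (decreasing size, ties by smallest member id) so the
#' partition is invariant to node input order. An edgeless network returns
#' every node in its own cluster with Q = 0.
#'
#' @param net A `micronet_network`.
#' @return A `micronet_partition`: `membership` tibble (`asv_id`, `cluster`)
#'   and `modularity`.
#' @export
fast_greedy_clusters <- function(net) {
  if (nrow(net$edges) == 0) {
    memb <- tibble(asv_id = net$nodes$asv_id,
                   cluster = seq_len(nrow(net$nodes)))
    return(structure(list(membership = memb, modularity = 0),
                     class = "micronet_partition"))
  }
  g <- as_igraph(net)
  w <- igraph::E(g)$weight
  cfg <- igraph::cluster_fast_greedy(g, weights = w)
  memb <- igraph::membership(cfg)
  q <- igraph::modularity(g, memb, weights = w)
  tb <- tibble(asv_id = names(memb), cluster = as.integer(memb))
  ## canonical ids: by decreasing size, ties by smallest member asv_id
  info <- summarise(group_by(tb, .data$cluster),
                    size = n(), first_id = min(.data$asv_id), .groups = "drop")
  info <- arrange(info, desc(.data$size), .data$first_id)
  relabel <- setNames(seq_len(nrow(info)), info$cluster)
  tb$cluster <- as.integer(relabel[as.character(tb$cluster)])
  structure(list(membership = arrange(tb, .data$cluster, .data$asv_id),
                 modularity = q),
            class = "micronet_partition")
}

#' @export
print.micronet_partition <- function(x, ...) {
  cat(sprintf("Partition: %d clusters, modularity Q = %.4f\n",
              length(unique(x$membership$cluster)), x$modularity))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.micronet_partition <- function(x, ...) x$membership

#' @exportS3Method generics::glance
glance.micronet_partition <- function(x, ...) {
  tibble(n_clusters = length(unique(x$membership$cluster)),
         modularity = x$modularity)
}

#' Modularity of an arbitrary node partition
#'
#' Weighted Newman modularity of `membership` on the network's signed weights;
#' used e.g. to score alternative partitions against [fast_greedy_clusters()].
#'
#' @param net A `micronet_network`.
#' @param membership Named vector (`asv_id` -> cluster) or a membership
#'   tibble.
#' @return Modularity Q.
#' @export
partition_modularity <- function(net, membership) {
  if (is.data.frame(membership)) {
    membership <- setNames(membership$cluster, membership$asv_id)
  }
  g <- as_igraph(net)
  memb <- membership[igraph::V(g)$name]
  igraph::modularity(g, as.integer(factor(memb)), weights = igraph::E(g)$weight)
}

#' Positive-to-negative edge ratio
#'
#' `n_pos / max(n_neg, 1)`, rounded to two decimals: a network with no
#' negative edges reports `n_pos` itself (so 23 positive / 0 negative gives
#' 23.0, and 2136/417 gives 5.12).
#'
#' @param n_pos,n_neg Edge counts.
#' @return Ratio(s), rounded to 2 decimals.
#' @export
pn_ratio <- function(n_pos, n_neg) round(n_pos / pmax(n_neg, 1), 2)

#' Edge-sign summary, optionally split by cluster
#'
#' Counts positive and negative edges and their ratio; with a partition the
#' counts are additionally split into intra-cluster (both endpoints in the
#' same cluster) and inter-cluster edges.
#'
#' @param net A `micronet_network`.
#' @param partition Optional `micronet_partition`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_positive`, `n_negative`,
#'   `ratio`, and with a partition `intra_positive`, `intra_negative`,
#'   `inter_positive`, `inter_negative`.
#' @export
edge_sign_summary <- function(net, partition = NULL) {
  e <- net$edges
  out <- tibble(n_nodes = nrow(net$nodes), n_edges = nrow(e),
                n_positive = sum(e$sign > 0), n_negative = sum(e$sign < 0),
                ratio = pn_ratio(sum(e$sign > 0), sum(e$sign < 0)))
  if (!is.null(partition)) {
    cl <- setNames(partition$membership$cluster, partition$membership$asv_id)
    intra <- cl[e$from] == cl[e$to]
    out$intra_positive <- sum(intra & e$sign > 0)
    out$intra_negative <- sum(intra & e$sign < 0)
    out$inter_positive <- sum(!intra & e$sign > 0)
    out$inter_negative <- sum(!intra & e$sign < 0)
  }
  out
}

#' @exportS3Method generics::tidy
tidy.micronet_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.micronet_network <- function(x, ...) edge_sign_summary(x)

# per-node incident positive/negative edge counts
node_sign_counts <- function(net) {
  e <- net$edges
  long <- bind_rows(tibble(asv_id = e$from, sign = e$sign),
                    tibble(asv_id = e$to, sign = e$sign))
  out <- summarise(group_by(long, .data$asv_id),
                   pos = sum(.data$sign > 0), neg = sum(.data$sign < 0),
                   .groups = "drop")
  out$ratio <- out$pos / pmax(out$neg, 1)
  out
}

#' Per-ASV positive/negative ratio shifts between two networks
#'
#' For every ASV present in both networks, reports its incident positive and
#' negative edge counts and their ratio (`pos / max(neg, 1)`) in each network
#' and the ratio fold-change `network B / network A`, sorted by decreasing
#' fold-change.
#'
#' @param net_a,net_b Two `micronet_network` objects over comparable ASV id
#'   spaces (e.g. the two conditions).
#' @return Tibble: `asv_id`, `pos_a`, `neg_a`, `ratio_a`, `pos_b`, `neg_b`,
#'   `ratio_b`, `fold_change`. Empty (with a warning) when no ASV is shared.
#' @export
ratio_shift <- function(net_a, net_b) {
  a <- node_sign_counts(net_a)
  b <- node_sign_counts(net_b)
  shared <- inner_join(a, b, by = "asv_id", suffix = c("_a", "_b"))
  if (nrow(shared) == 0) {
    warn("No ASVs shared between the two networks.")
    return(tibble(asv_id = character(), pos_a = integer(), neg_a = integer(),
                  ratio_a = double(), pos_b = integer(), neg_b = integer(),
                  ratio_b = double(), fold_change = double()))
  }
  shared$fold_change <- shared$ratio_b / shared$ratio_a
  arrange(shared, desc(.data$fold_change))
}

#' Eigenvector centrality on signed weights (power iteration)
#'
#' Computed per connected component on the non-negative weight matrix
#' `w = (1 + r) / 2` via shifted power iteration (the shift `W + I` leaves the
#' eigenvector unchanged and prevents oscillation on bipartite components),
#' tolerance 1e-10, at most 10,000 iterations; each component's vector is
#' scaled to max 1 and nodes are ranked across the whole network.
#'
#' @param net A `micronet_network`.
#' @param tol Convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Tibble: `asv_id`, `centrality`, `component`.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  cent <- setNames(rep(0, length(ids)), ids)
  for (ci in seq_len(comp$no)) {
    members <- ids[comp$membership == ci]
    if (length(members) == 1) { cent[members] <- 0; next }
    sub <- igraph::induced_subgraph(g, members)
    w <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    w <- w[members, members, drop = FALSE] + diag(length(members))
    v <- rep(1 / sqrt(length(members)), length(members))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      v2 <- as.vector(w %*% v)
      nv <- sqrt(sum(v2^2))
      if (nv == 0) { v <- v2; converged <- TRUE; break }
      v2 <- v2 / nv
      if (max(abs(v2 - v)) < tol) { v <- v2; converged <- TRUE; break }
      v <- v2
    }
    if (!converged) {
      abort(sprintf("Eigenvector centrality did not converge in %d iterations (component %d).",
                    max_iter, ci))
    }
    if (max(v) > 0) v <- v / max(v)
    cent[members] <- v
  }
  tibble(asv_id = ids, centrality = unname(cent),
         component = as.integer(comp$membership))
}

#' Keystone taxa: high-centrality, low-abundance nodes
#'
#' A node is flagged keystone when its eigenvector centrality is strictly
#' above the 90th percentile of network centralities (top decile, strict) and
#' its mean relative abundance is strictly below the median across network
#' nodes (ties at either boundary are excluded).
#'
#' @param net A `micronet_network`.
#' @param counts Count tibble for the same condition (used for relative
#'   abundances).
#' @param partition Optional `micronet_partition` to attach cluster ids.
#' @return Tibble: `asv_id`, `centrality`, `rel_abundance`, `cluster`,
#'   `keystone` (logical).
#' @export
keystone_taxa <- function(net, counts, partition = NULL) {
  cent <- eigenvector_centrality(net)
  rel <- as_count_matrix(counts)
  rel <- rel / rowSums(rel)
  missing <- setdiff(cent$asv_id, colnames(rel))
  if (length(missing) > 0) {
    abort(paste0("Network ASV(s) missing from `counts`: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  cent$rel_abundance <- colMeans(rel[, cent$asv_id, drop = FALSE])
  thr_c <- quantile(cent$centrality, 0.9, names = FALSE)
  thr_a <- median(cent$rel_abundance)
  cent$cluster <- if (!is.null(partition)) {
    partition$membership$cluster[match(cent$asv_id, partition$membership$asv_id)]
  } else NA_integer_
  cent$keystone <- cent$centrality > thr_c & cent$rel_abundance < thr_a
  arrange(select(cent, "asv_id", "centrality", "rel_abundance", "cluster",
                 "keystone"),
          desc(.data$centrality))
}
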