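# Shared fixtures and small oracles, all built in code.

# 4-sample, 4-ASV toy table with two groups
tiny_counts <- function() {
  tibble::tibble(
    sample_id = c("H1", "H2", "N1", "N2"),
    a = c(5L, 3L, 0L, 0L),
    b = c(2L, 1L, 4L, 6L),
    c = c(0L, 0L, 0L, 0L),
    d = c(1L, 2L, 3L, 0L)
  )
}

tiny_metadata <- function() {
  tibble::tibble(sample_id = c("H1", "H2", "N1", "N2"),
                 group = c("H", "H", "NI", "NI"))
}

tiny_taxonomy <- function(asvs = c("a", "b", "c", "d"),
                          phyla = c("P1", "P1", "P2", "P3")) {
  tibble::tibble(asv_id = asvs, domain = "Bacteria", phylum = phyla,
                 class = paste0(phyla, "_c"), order = paste0(phyla, "_o"),
                 family = paste0(phyla, "_f"), genus = paste0(phyla, "_g"))
}

# network from an edge data frame (from, to, r)
toy_network <- function(...) {
  cooccurrence_network(tibble::tibble(...), threshold = 0.5)
}

# ANOSIM R by the definitional rank formula (independent of vegan)
anosim_r_bruteforce <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  dv <- dm[pairs]
  rk <- rank(dv)
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  m <- length(dv)
  (mean(rk[!within]) - mean(rk[within])) / (m / 2)
}

# all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# eigenvector centrality oracle: dense eigen-decomposition of the weight
# matrix, per component, max-normalized (matches the package convention)
centrality_eigen_oracle <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  cent <- stats::setNames(rep(0, length(ids)), ids)
  for (ci in seq_len(comp$no)) {
    members <- ids[comp$membership == ci]
    if (length(members) == 1) next
    sub <- igraph::induced_subgraph(g, members)
    w <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    w <- w[members, members, drop = FALSE]
    es <- eigen(w, symmetric = TRUE)
    v <- es$vectors[, which.max(es$values)]
    v <- abs(v)
    if (max(v) > 0) v <- v / max(v)
    cent[members] <- v
  }
  cent
}

# random signed network on n nodes (for invariant sweeps)
random_network <- function(n, p_edge = 0.3, seed = 1) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p_edge
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0) pairs <- t(utils::combn(n, 2))[1, , drop = FALSE]
    r <- stats::runif(nrow(pairs), -1, 1)
    nodes <- tibble::tibble(asv_id = paste0("n", seq_len(n)),
                            phylum = NA_character_, clr_mean = NA_real_)
    cooccurrence_network(
      tibble::tibble(from = paste0("n", pairs[, 1]),
                     to = paste0("n", pairs[, 2]), r = r),
      nodes = nodes, threshold = 0)
  })
}

# graph with a low-abundance hub attached to well-connected nodes, plus
# background community structure; returns network + the hub id
planted_hub_network <- function(seed) {
  withr::with_seed(seed, {
    n_core <- 12
    core <- paste0("c", seq_len(n_core))
    # dense positively-weighted core
    pairs <- t(utils::combn(n_core, 2))
    keep <- stats::runif(nrow(pairs)) < 0.6
    e <- tibble::tibble(from = core[pairs[keep, 1]], to = core[pairs[keep, 2]],
                        r = stats::runif(sum(keep), 0.5, 0.9))
    # peripheral nodes, one edge each into the core
    periph <- paste0("p", 1:10)
    e <- dplyr::bind_rows(e, tibble::tibble(
      from = periph, to = sample(core, 10, replace = TRUE),
      r = stats::runif(10, 0.4, 0.7)))
    # hub: strongly connected to the whole core
    e <- dplyr::bind_rows(e, tibble::tibble(
      from = "hub", to = core, r = stats::runif(n_core, 0.8, 0.95)))
    e <- dplyr::distinct(e, pmin(from, to), pmax(from, to), .keep_all = TRUE)[, 1:3]
    net <- cooccurrence_network(e, threshold = 0.3)
    # abundances: hub rare, core abundant, periphery middling
    ids <- net$nodes$asv_id
    ab <- stats::setNames(stats::runif(length(ids), 50, 200), ids)
    ab[grepl("^c", ids)] <- stats::runif(sum(grepl("^c", ids)), 500, 1000)
    ab["hub"] <- 5
    counts <- tibble::tibble(sample_id = "s1", !!!as.list(round(ab)))
    list(net = net, hub = "hub", counts = counts)
  })
}
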