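# Beta diversity: Bray-Curtis distances, ANOSIM, NMDS, PCoA, UPGMA.

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}; entries lie in
#' `[0, 1]`, the matrix is symmetric with zero diagonal (Bray-Curtis is a
#' semi-metric: the triangle inequality is not guaranteed).
#'
#' @param x Count tibble or abundance-profile tibble (non-negative rows, at
#'   least one positive entry per sample).
#' @return A [stats::dist] object labelled by sample id.
#' @export
bray_curtis <- function(x) {
  m <- as_count_matrix(x)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(paste0("All-zero sample(s): ", paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  vegan::vegdist(m, method = "bray")
}

#' ANOSIM: analysis of similarities
#'
#' Rank-based permutation test of between- versus within-group
#' dissimilarities. `R = (mean between-group rank - mean within-group rank) /
#' (M / 2)` with `M = n(n-1)/2` pairs and mid-ranks for ties; the permutation
#' p-value uses the +1 correction: `p = (1 + #\{R* >= R\}) / (1 + n_perm)`.
#'
#' @param d A distance object or symmetric matrix.
#' @param metadata Sample metadata (`sample_id`, `group`); two or more groups,
#'   each with at least 2 samples.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `micronet_anosim` object (fields `statistic`, `p`, `n_perm`,
#'   `seed`, `perm` = permuted statistics); see [tidy()].
#' @export
anosim_test <- function(d, metadata, n_perm = 999, seed = 1) {
  d <- as.dist(d)
  ids <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  g <- group_labels(tibble(sample_id = ids), metadata, require_two = FALSE)
  if (length(unique(g)) < 2) abort("ANOSIM needs at least two groups.")
  if (any(table(g) < 2)) abort("Every group needs at least 2 samples.")
  if (n_perm < 99) warn("Fewer than 99 permutations gives a coarse p-value.")
  res <- withr::with_seed(seed, vegan::anosim(d, factor(g), permutations = n_perm))
  structure(list(statistic = unname(res$statistic), p = unname(res$signif),
                 n_perm = n_perm, seed = seed, perm = res$perm),
            class = "micronet_anosim")
}

#' @export
print.micronet_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.micronet_anosim <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p, n_perm = x$n_perm)
}

#' @exportS3Method generics::glance
glance.micronet_anosim <- function(x, ...) tidy(x)

#' Nonmetric multidimensional scaling (NMDS)
#'
#' Minimizes Kruskal stress-1 against a monotone (isotonic, primary
#' tie-treatment) regression of configuration distances on the input
#' dissimilarities, keeping the best of `n_restarts` runs (vegan's
#' `metaMDS`/`monoMDS` engine). Non-convergence is flagged, not an error.
#'
#' @param d Distance object or symmetric matrix.
#' @param k Target dimensionality (default 2).
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Iterations per run.
#' @param tol Stress convergence floor passed to the optimizer.
#' @param seed Integer seed.
#' @return A `micronet_ordination` with `coordinates` (tibble: `sample_id`,
#'   `axis1`, ...), `stress` (Kruskal stress-1), `converged`, `n_restarts`.
#' @export
nmds_ordination <- function(d, k = 2, n_restarts = 20, max_iter = 500,
                            tol = 1e-7, seed = 1) {
  d <- as.dist(d)
  fit <- withr::with_seed(seed, suppressMessages(suppressWarnings(
    vegan::metaMDS(d, k = k, trymax = n_restarts, trace = 0,
                   autotransform = FALSE, wascores = FALSE,
                   maxit = max_iter, smin = tol, sfgrmin = 1e-8)
  )))
  ids <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  coords <- as_tibble(fit$points, .name_repair = ~ paste0("axis", seq_along(.x)))
  coords <- bind_cols(tibble(sample_id = ids), coords)
  if (!isTRUE(fit$converged > 0 || isTRUE(fit$converged))) {
    inform("NMDS did not formally converge in any restart; best solution returned.")
  }
  structure(list(method = "NMDS", coordinates = coords,
                 stress = fit$stress,
                 converged = isTRUE(fit$converged > 0 || isTRUE(fit$converged)),
                 n_restarts = n_restarts, seed = seed),
            class = "micronet_ordination")
}

#' Principal coordinates analysis (PCoA)
#'
#' Eigen-decomposition of the double-centered \eqn{-d^2/2} matrix; coordinates
#' come from the positive eigenvalues, and negative eigenvalues (possible for
#' semi-metric input) are reported.
#'
#' @inheritParams nmds_ordination
#' @param k Number of axes to return (default: all positive eigenvalues).
#' @return A `micronet_ordination` with `eigenvalues` sorted descending.
#' @export
pcoa_ordination <- function(d, k = NULL) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  ## cmdscale warns whenever some of the n-1 requested axes have non-positive
  ## eigenvalues; that is the expected situation for semi-metric input and the
  ## eigenvalues are reported, so the warning is noise here
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k <- min(k %||% n_pos, n_pos)
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  coords <- as_tibble(pts, .name_repair = ~ paste0("axis", seq_along(.x)))
  coords <- bind_cols(tibble(sample_id = ids), coords)
  structure(list(method = "PCoA", coordinates = coords,
                 eigenvalues = sort(eig, decreasing = TRUE)),
            class = "micronet_ordination")
}

#' @export
print.micronet_ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes",
              x$method, nrow(x$coordinates), ncol(x$coordinates) - 1))
  if (!is.null(x$stress)) cat(sprintf(", stress = %.4g", x$stress))
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.micronet_ordination <- function(x, ...) x$coordinates

#' @exportS3Method generics::glance
glance.micronet_ordination <- function(x, ...) {
  tibble(method = x$method,
         n_axes = ncol(x$coordinates) - 1,
         stress = x$stress %||% NA_real_,
         converged = x$converged %||% NA)
}

#' UPGMA (average-linkage) clustering tree
#'
#' Agglomerative average-linkage merge tree; the result is ultrametric (all
#' root-to-tip distances equal), with tips at height 0 and merges at half the
#' average between-cluster distance.
#'
#' @param d Distance object or symmetric matrix.
#' @return An [ape::phylo] tree.
#' @export
upgma_tree <- function(d) {
  ape::as.phylo(hclust(as.dist(d), method = "average"))
}
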