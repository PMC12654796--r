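# End-to-end orchestration: simulate/load -> filter -> alpha (rarefied) ->
# beta -> differential -> per-condition networks -> summary bundle.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full two-group analysis pipeline
#'
#' Stages: low-abundance ASV filter; rarefaction to a standard depth and
#' per-sample alpha diversity with group tests; phylum profile and core/shared
#' sets; Bray-Curtis beta diversity with NMDS, PCoA, UPGMA and ANOSIM;
#' moderated t differential abundance; and per-condition co-occurrence
#' networks (prevalence filter, clr, RMT threshold, signed network,
#' fast-greedy clusters, edge-sign architecture, keystone taxa) plus
#' cross-network ratio shifts. The run is deterministic given `seed`.
#'
#' @param data List with `counts`, `metadata`, and optionally `taxonomy` and
#'   `tree` — e.g. the output of [simulate_community()]. Alternatively supply
#'   `spec` to simulate first.
#' @param spec Optional [synthetic_spec()] used when `data` is `NULL`.
#' @param out_dir Optional directory; when given, tables, networks and a
#'   machine-readable `summary.json` are written there.
#' @param seed Integer seed for every stochastic stage.
#' @param abundance_threshold Overall relative-abundance ASV filter
#'   (default 1e-4, i.e. 0.01%).
#' @param rarefy_depth Standardized depth for alpha diversity (default
#'   33,000); samples below it are dropped with a warning.
#' @param prevalence_min Per-condition prevalence filter for networks
#'   (default 5 samples).
#' @param pseudocount Clr pseudocount (default 1).
#' @param others_cutoff "Others" bucket cutoff for the phylum profile.
#' @param n_perm ANOSIM permutations (default 999).
#' @param rmt_grid Candidate-threshold grid for [rmt_threshold()].
#' @return A `micronet_run` list with every stage's result and a `summary`
#'   list mirroring `summary.json`.
#' @export
run_pipeline <- function(data = NULL, spec = NULL, out_dir = NULL, seed = 1,
                         abundance_threshold = 1e-4, rarefy_depth = 33000,
                         prevalence_min = 5, pseudocount = 1,
                         others_cutoff = 0.01, n_perm = 999,
                         rmt_grid = seq(0.10, 0.98, by = 0.01)) {
  if (is.null(data)) {
    if (is.null(spec)) abort("Supply `data` or `spec`.")
    data <- run_stage("simulate", simulate_community(spec))
  }
  counts <- data$counts; metadata <- data$metadata
  taxonomy <- data$taxonomy; tree <- data$tree
  g <- group_labels(counts, metadata)
  gl <- unique(g)

  filtered <- run_stage("abundance_filter",
                        filter_min_abundance(counts, abundance_threshold))

  rarefied <- run_stage("rarefaction",
                        rarefy_counts(filtered, rarefy_depth, seed = seed))
  alpha <- run_stage("alpha_diversity", alpha_diversity(rarefied, tree))
  alpha_tests <- run_stage("alpha_tests", compare_alpha(alpha, metadata))

  profile <- if (!is.null(taxonomy)) {
    run_stage("phylum_profile",
              aggregate_rank(filtered, taxonomy, "phylum", others_cutoff))
  }
  core_shared <- run_stage("core_shared",
                           core_and_shared(filtered, metadata,
                                           taxonomy = taxonomy,
                                           rank = if (!is.null(taxonomy)) "genus"))

  bray <- run_stage("bray_curtis", bray_curtis(filtered))
  anosim <- run_stage("anosim", anosim_test(bray, metadata, n_perm = n_perm,
                                            seed = seed))
  nmds <- run_stage("nmds", nmds_ordination(bray, seed = seed))
  pcoa <- run_stage("pcoa", pcoa_ordination(bray))
  upgma <- run_stage("upgma", upgma_tree(bray))

  diff <- run_stage("differential", moderated_t_test(filtered, metadata))

  networks <- list()
  for (lab in gl) {
    networks[[lab]] <- run_stage(paste0("network_", lab), {
      sub <- filtered[g == lab, , drop = FALSE]
      sub <- prevalence_filter(sub, prevalence_min)
      clr <- clr_transform(sub, pseudocount)
      rmt <- suppressWarnings(rmt_threshold(clr, grid = rmt_grid))
      net <- build_network(clr, rmt$threshold, taxonomy = taxonomy)
      part <- fast_greedy_clusters(net)
      list(counts = sub, rmt = rmt, network = net, partition = part,
           summary = edge_sign_summary(net, part),
           keystone = keystone_taxa(net, sub, part))
    })
  }
  shifts <- run_stage("ratio_shift",
                      suppressWarnings(ratio_shift(networks[[gl[2]]]$network,
                                                   networks[[gl[1]]]$network)))

  summary <- list(
    seed = seed,
    params = list(abundance_threshold = abundance_threshold,
                  rarefy_depth = rarefy_depth, prevalence_min = prevalence_min,
                  pseudocount = pseudocount, n_perm = n_perm),
    n_samples = as.list(table(g)),
    n_asvs_filtered = ncol(filtered) - 1,
    alpha_means = lapply(setNames(gl, gl), function(lab) {
      idx <- intersect(c("richness", "chao1", "shannon", "faith_pd",
                         "goods_coverage"), names(alpha))
      ids <- names(g)[g == lab]
      as.list(colMeans(alpha[alpha$sample_id %in% ids, idx, drop = FALSE],
                       na.rm = TRUE))
    }),
    alpha_p = setNames(as.list(alpha_tests$p), alpha_tests$index),
    anosim = list(R = anosim$statistic, p = anosim$p),
    nmds_stress = nmds$stress,
    n_significant_q05 = sum(diff$q < 0.05),
    networks = lapply(networks, function(nw) {
      c(as.list(nw$summary),
        list(threshold = nw$rmt$threshold,
             modularity = nw$partition$modularity,
             n_clusters = length(unique(nw$partition$membership$cluster)),
             n_keystone = sum(nw$keystone$keystone)))
    })
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(filtered, file.path(out_dir, "counts_filtered.tsv"))
    readr::write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))
    readr::write_tsv(alpha_tests, file.path(out_dir, "alpha_tests.tsv"))
    readr::write_tsv(diff, file.path(out_dir, "differential_abundance.tsv"))
    if (!is.null(profile)) readr::write_tsv(profile, file.path(out_dir, "phylum_profile.tsv"))
    readr::write_tsv(core_shared, file.path(out_dir, "core_shared.tsv"))
    if (nrow(shifts) > 0) readr::write_tsv(shifts, file.path(out_dir, "ratio_shifts.tsv"))
    for (lab in gl) {
      nw <- networks[[lab]]
      write_network(nw$network, file.path(out_dir, paste0("network_", lab, ".tsv")),
                    dialect = "edgelist", partition = nw$partition,
                    centrality = nw$keystone)
      readr::write_tsv(nw$keystone, file.path(out_dir, paste0("keystone_", lab, ".tsv")))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(counts_filtered = filtered, metadata = metadata,
                 alpha = alpha, alpha_tests = alpha_tests,
                 profile_phylum = profile, core_shared = core_shared,
                 bray_curtis = bray, anosim = anosim, nmds = nmds,
                 pcoa = pcoa, upgma = upgma, differential = diff,
                 networks = networks, ratio_shifts = shifts,
                 summary = summary),
            class = "micronet_run")
}

#' @export
print.micronet_run <- function(x, ...) {
  s <- x$summary
  cat("micronet pipeline run\n")
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s = %d", names(s$n_samples), unlist(s$n_samples)),
                    collapse = ", ")))
  cat(sprintf("  ASVs after filter: %d\n", s$n_asvs_filtered))
  cat(sprintf("  ANOSIM R = %.3f (p = %.3g)\n", s$anosim$R, s$anosim$p))
  for (lab in names(s$networks)) {
    nw <- s$networks[[lab]]
    cat(sprintf("  network %s: tau = %.2f, %d nodes, %d edges (+/- ratio %.2f), Q = %.3f\n",
                lab, nw$threshold, nw$n_nodes, nw$n_edges, nw$ratio, nw$modularity))
  }
  invisible(x)
}
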