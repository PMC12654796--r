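# Relative-abundance computation, the dataset-wide 0.01% ASV filter, rank
# aggregation with an "Others" bucket, prevalence, and core/shared taxon sets.

#' Per-sample relative abundances
#'
#' @param counts Count tibble.
#' @return Tibble of the same shape with each row summing to 1.
#' @export
relative_abundance <- function(counts) {
  m <- as_count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(paste0("All-zero sample(s): ",
                 paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  as_count_tibble(m / tot)
}

#' Drop ASVs below an overall relative-abundance threshold
#'
#' An ASV is retained when its total count across all samples, divided by the
#' grand total, is at least `threshold` (inclusive boundary). The default
#' 1e-4 is the conventional 0.01% cut against uninformative low-representation
#' ASVs. Column order is preserved.
#'
#' @param counts Count tibble.
#' @param threshold Fraction in `[0, 1)`.
#' @return Filtered count tibble.
#' @export
filter_min_abundance <- function(counts, threshold = 1e-4) {
  if (threshold < 0 || threshold >= 1) abort("`threshold` must be in [0, 1).")
  m <- as_count_matrix(counts)
  rel <- colSums(m) / sum(m)
  keep <- rel >= threshold
  if (!any(keep)) {
    abort("No ASVs pass the abundance filter; reduce `threshold`.")
  }
  counts[, c(TRUE, keep), drop = FALSE]
}

#' Aggregate to a taxonomic rank with an "Others" bucket
#'
#' Counts are summed per taxon at `rank` and converted to per-sample relative
#' abundances. Taxa whose overall relative abundance (across all samples)
#' falls below `others_cutoff`, and taxa unclassified at that rank, are merged
#' into `"Others"`. Rows sum to 1.
#'
#' @param counts Count tibble.
#' @param taxonomy Taxonomy tibble ([read_taxonomy()] layout).
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param others_cutoff Fraction in `[0, 1)`; default 0.01 (the 1% rule used
#'   for stacked profiles).
#' @return An abundance-profile tibble (first column `sample_id`; columns are
#'   taxa, "Others" last when present) with attribute `rank`.
#' @export
aggregate_rank <- function(counts, taxonomy, rank = "phylum", others_cutoff = 0.01) {
  if (!rank %in% TAX_RANKS) {
    abort(paste0("Unknown rank '", rank, "'; valid ranks: ",
                 paste(TAX_RANKS, collapse = ", ")))
  }
  if (others_cutoff < 0 || others_cutoff >= 1) abort("`others_cutoff` must be in [0, 1).")
  m <- as_count_matrix(counts)
  lab <- taxonomy[[rank]][match(colnames(m), taxonomy$asv_id)]
  if (anyNA(lab)) {
    abort(paste0("ASV(s) missing from taxonomy: ",
                 paste(colnames(m)[is.na(lab)], collapse = ", ")))
  }
  agg <- t(rowsum(t(m), group = lab))  # samples x taxa
  rel_overall <- colSums(agg) / sum(agg)
  to_others <- rel_overall < others_cutoff | colnames(agg) == "unclassified"
  if (any(to_others)) {
    others <- rowSums(agg[, to_others, drop = FALSE])
    agg <- agg[, !to_others, drop = FALSE]
    agg <- cbind(agg, Others = others)
  }
  prof <- agg / rowSums(agg)
  out <- as_count_tibble(prof)
  attr(out, "rank") <- rank
  attr(out, "others_cutoff") <- others_cutoff
  out
}

#' Core, present and shared taxa per group, with prevalence
#'
#' A taxon is *core* for a group when it has a nonzero count in every sample
#' of that group, *present* when nonzero in at least one sample, and *shared*
#' when present in both groups. Prevalence is the fraction of all samples with
#' a nonzero count. With `taxonomy` and `rank`, counts are first aggregated to
#' that rank (e.g. shared genera).
#'
#' @param counts Count tibble.
#' @param metadata Sample metadata (`sample_id`, `group`); exactly two groups.
#' @param taxonomy,rank Optional aggregation before set computation.
#' @return Tibble with one row per taxon: `taxon`, `prevalence`, and logical
#'   columns `present_<group>`, `core_<group>`, `shared`.
#' @export
core_and_shared <- function(counts, metadata, taxonomy = NULL, rank = NULL) {
  m <- as_count_matrix(counts)
  if (!is.null(rank)) {
    if (is.null(taxonomy)) abort("`taxonomy` is required when `rank` is given.")
    lab <- taxonomy[[rank]][match(colnames(m), taxonomy$asv_id)]
    m <- t(rowsum(t(m), group = lab))
  }
  g <- group_labels(counts, metadata)
  gl <- unique(g)
  pres <- m > 0
  out <- tibble(taxon = colnames(m), prevalence = unname(colMeans(pres)))
  for (lab in gl) {
    sub <- pres[g == lab, , drop = FALSE]
    out[[paste0("present_", lab)]] <- colSums(sub) > 0
    out[[paste0("core_", lab)]] <- colSums(sub) == nrow(sub)
  }
  out$shared <- out[[paste0("present_", gl[1])]] & out[[paste0("present_", gl[2])]]
  out
}
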