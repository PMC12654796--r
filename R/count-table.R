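# Count tables travel as wide tibbles: first column `sample_id`, remaining
# columns one ASV each, cells non-negative integer counts. Helpers below
# convert to/from the numeric matrix form the math runs on.

#' Convert a count tibble to a numeric matrix
#'
#' @param counts Count tibble: first column `sample_id`, remaining columns one
#'   ASV each with non-negative integer counts.
#' @return Numeric matrix with samples as rows (rownames = sample ids) and
#'   ASVs as columns.
#' @export
#' @examples
#' ct <- tibble::tibble(sample_id = c("s1", "s2"), a = c(3L, 1L), b = c(0L, 2L))
#' as_count_matrix(ct)
as_count_matrix <- function(counts) {
  validate_count_table(counts)
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts[[1]]
  m
}

# matrix -> wide tibble (inverse of as_count_matrix)
as_count_tibble <- function(m, id_col = "sample_id") {
  stopifnot(!is.null(rownames(m)))
  out <- as_tibble(m)
  out <- bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

validate_count_table <- function(counts, integer_only = FALSE) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort("`counts` must be a data frame with a sample-id column plus at least one ASV column.")
  }
  ids <- counts[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated sample id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(names(counts))) {
    abort(paste0("Duplicated ASV id(s): ",
                 paste(unique(names(counts)[duplicated(names(counts))]), collapse = ", ")))
  }
  vals <- counts[, -1, drop = FALSE]
  ok_num <- vapply(vals, is.numeric, logical(1))
  if (!all(ok_num)) {
    abort(paste0("Non-numeric count column(s): ",
                 paste(names(vals)[!ok_num], collapse = ", ")))
  }
  mm <- as.matrix(vals)
  if (anyNA(mm)) abort("Count table contains missing values.")
  if (any(mm < 0)) abort("Count table contains negative entries.")
  if (integer_only && any(mm != round(mm))) {
    bad <- which(mm != round(mm), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-integer count at sample '%s', ASV '%s'.",
                  counts[[1]][bad[1]], colnames(mm)[bad[2]]))
  }
  invisible(counts)
}

# Resolve the per-sample group labels for the samples in `counts`, in order.
# `metadata` is a tibble with columns sample_id, group.
group_labels <- function(counts, metadata, require_two = TRUE) {
  if (!is.data.frame(metadata) || !all(c("sample_id", "group") %in% names(metadata))) {
    abort("`metadata` must have columns `sample_id` and `group`.")
  }
  ids <- counts[[1]]
  idx <- match(ids, metadata$sample_id)
  if (anyNA(idx)) {
    abort(paste0("Sample(s) missing from metadata: ",
                 paste(ids[is.na(idx)], collapse = ", ")))
  }
  g <- as.character(metadata$group[idx])
  if (require_two && length(unique(g)) != 2) {
    abort(sprintf("Exactly two group labels required; found: %s",
                  paste(unique(g), collapse = ", ")))
  }
  setNames(g, ids)
}
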