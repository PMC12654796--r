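# Per-sample alpha diversity (richness, bias-corrected Chao1, Shannon in log
# base 2, Faith PD, Good's coverage), rarefaction, and nonparametric group
# comparisons with exact small-sample enumeration.

#' Per-sample alpha diversity indices
#'
#' Computes observed richness, bias-corrected Chao1
#' \eqn{S + F_1(F_1-1) / (2(F_2+1))} (with \eqn{F_1, F_2} the singleton and
#' doubleton counts), Shannon diversity \eqn{-\sum p_i \log_2 p_i} (log base
#' 2), Good's coverage \eqn{100\,(1 - F_1/N)} (a percentage), and — when a
#' tree is supplied — Faith phylogenetic diversity (total branch length of
#' the rooted subtree spanning the observed tips).
#'
#' Empty samples (zero reads) get richness 0 and `NA` for the remaining
#' indices, with a warning.
#'
#' @param counts Count tibble.
#' @param tree Optional rooted [ape::phylo] whose tips cover all ASV columns.
#' @return Tibble with one row per sample: `sample_id`, `richness`, `chao1`,
#'   `shannon`, `goods_coverage`, and `faith_pd` when `tree` is given.
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  m <- as_count_matrix(counts)
  n_tot <- rowSums(m)
  s <- rowSums(m > 0)
  f1 <- rowSums(m == 1)
  f2 <- rowSums(m == 2)
  chao1 <- s + f1 * (f1 - 1) / (2 * (f2 + 1))
  shannon <- apply(m, 1, function(x) {
    p <- x[x > 0] / sum(x)
    if (length(p) == 0) return(NA_real_)
    -sum(p * log2(p))
  })
  goods <- 100 * (1 - f1 / n_tot)
  empty <- n_tot == 0
  if (any(empty)) {
    warn(paste0("Empty sample(s) with undefined indices: ",
                paste(rownames(m)[empty], collapse = ", ")))
    chao1[empty] <- NA_real_; shannon[empty] <- NA_real_; goods[empty] <- NA_real_
  }
  out <- tibble(sample_id = rownames(m), richness = unname(s),
                chao1 = unname(chao1), shannon = unname(shannon),
                goods_coverage = unname(goods))
  if (!is.null(tree)) {
    missing_tips <- setdiff(colnames(m), tree$tip.label)
    if (length(missing_tips) > 0) {
      abort(paste0("ASV(s) absent from tree: ",
                   paste(head(missing_tips, 5), collapse = ", "),
                   if (length(missing_tips) > 5) ", ..."))
    }
    pd <- picante::pd(m, tree, include.root = TRUE)
    out$faith_pd <- pd$PD[match(out$sample_id, rownames(pd))]
    out$faith_pd[empty] <- NA_real_
  }
  out
}

#' Rarefy samples to a fixed depth (subsampling without replacement)
#'
#' Samples whose read total is below `depth` are dropped with a warning (they
#' cannot be standardized to that depth). Each retained sample is subsampled
#' without replacement to exactly `depth` reads.
#'
#' @param counts Count tibble.
#' @param depth Target reads per sample (default 33,000, the standardization
#'   depth used for soil surveys of this design).
#' @param seed Optional integer seed.
#' @return Rarefied count tibble (row sums all equal `depth`).
#' @export
rarefy_counts <- function(counts, depth = 33000, seed = NULL) {
  if (depth <= 0) abort("`depth` must be positive.")
  m <- as_count_matrix(counts)
  tot <- rowSums(m)
  drop <- tot < depth
  if (all(drop)) abort("No sample reaches the rarefaction depth.")
  if (any(drop)) {
    warn(paste0("Dropping sample(s) below rarefaction depth ", depth, ": ",
                paste(rownames(m)[drop], collapse = ", ")))
    m <- m[!drop, , drop = FALSE]
  }
  do_r <- function() vegan::rrarefy(m, depth)
  r <- if (is.null(seed)) do_r() else withr::with_seed(seed, do_r())
  as_count_tibble(r)
}

#' Rarefaction curves of alpha indices
#'
#' For each depth in `depths`, samples at or above that depth are repeatedly
#' rarefied (`n_iter` independent subsamples) and each alpha index recomputed;
#' the curve reports the mean and standard deviation across iterations.
#'
#' @inheritParams alpha_diversity
#' @param depths Increasing vector of subsampling depths.
#' @param n_iter Rarefaction iterations per depth (default 10).
#' @param seed Integer seed.
#' @return Long tibble: `depth`, `sample_id`, `index`, `mean`, `sd`.
#' @export
rarefaction_curves <- function(counts, depths, n_iter = 10, seed = 1, tree = NULL) {
  if (any(depths <= 0)) abort("`depths` must be positive.")
  withr::with_seed(seed, {
    res <- purrr::map_dfr(sort(depths), function(d) {
      m <- as_count_matrix(counts)
      keep <- rowSums(m) >= d
      if (!any(keep)) return(NULL)
      sub <- counts[keep, , drop = FALSE]
      iters <- purrr::map_dfr(seq_len(n_iter), function(i) {
        r <- suppressWarnings(rarefy_counts(sub, d))
        mutate(alpha_diversity(r, tree), .iter = i)
      })
      long <- tidyr::pivot_longer(iters, -c("sample_id", ".iter"),
                                  names_to = "index", values_to = "value")
      long <- summarise(group_by(long, .data$sample_id, .data$index),
                        mean = mean(.data$value), sd = sd(.data$value),
                        .groups = "drop")
      mutate(long, depth = d, .before = 1)
    })
    res
  })
}

#' Exact / approximate Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Reports the U statistic for the first sample. For combined n of at most 10
#' (the default switch) the p-value is computed by exhaustive enumeration of
#' all label assignments (mid-ranks for ties); otherwise a normal
#' approximation with tie correction is used (no continuity correction, so the
#' squared z equals the Kruskal-Wallis statistic for two groups).
#'
#' @param x,y Numeric observations for the two groups (each of length >= 2).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x` relative
#'   to `y`).
#' @param exact Force exact enumeration (`TRUE`/`FALSE`); default `NULL`
#'   switches on combined n <= 10.
#' @return Tibble: `statistic` (U), `p`, `method`.
#' @export
mann_whitney_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                              exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) abort("Each group needs at least 2 observations.")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  v <- c(x, y)
  rk <- rank(v)
  u_of <- function(idx1) sum(rk[idx1]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- n <= 10
  if (exact) {
    combos <- combn(n, n1)
    u_all <- apply(combos, 2, u_of)
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12),
      less      = mean(u_all <= u_obs + 1e-12),
      greater   = mean(u_all >= u_obs - 1e-12))
    method <- "Mann-Whitney (exact enumeration)"
  } else {
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      less      = stats::pnorm(z),
      greater   = stats::pnorm(z, lower.tail = FALSE))
    p <- min(p, 1)
    method <- "Mann-Whitney (normal approximation, tie-corrected)"
  }
  tibble(statistic = u_obs, p = p, method = method)
}

#' Exact / approximate Kruskal-Wallis test
#'
#' Tie-corrected H statistic; exact permutation p by exhaustive enumeration of
#' label assignments for combined n <= 10, chi-squared approximation
#' otherwise.
#'
#' @param values Numeric vector.
#' @param groups Group labels (each group with >= 2 observations).
#' @param exact See [mann_whitney_test()].
#' @return Tibble: `statistic` (H), `p`, `method`.
#' @export
kruskal_wallis_test <- function(values, groups, exact = NULL) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) abort("Each group needs at least 2 observations.")
  n <- length(values)
  k <- length(sizes)
  rk <- rank(values)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h_of <- function(lab) {
    rs <- tapply(rk, lab, sum)
    ns <- tapply(rk, lab, length)
    h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
    h / tie_corr
  }
  h_obs <- h_of(groups)
  if (is.null(exact)) exact <- n <= 10
  if (exact) {
    perms <- label_assignments(sizes)
    h_all <- apply(perms, 1, h_of)
    p <- mean(h_all >= h_obs - 1e-12)
    method <- "Kruskal-Wallis (exact enumeration)"
  } else {
    p <- stats::pchisq(h_obs, df = k - 1, lower.tail = FALSE)
    method <- "Kruskal-Wallis (chi-squared approximation)"
  }
  tibble(statistic = h_obs, p = p, method = method)
}

# All distinct assignments of a label multiset to n positions; rows are
# assignments, values are label names. Sizes come from table(groups).
label_assignments <- function(sizes) {
  labs <- names(sizes)
  recurse <- function(positions, remaining) {
    if (length(remaining) == 1) {
      m <- matrix(labs[length(labs)], 1, length(positions))
      colnames(m) <- positions
      return(m)
    }
    lab_i <- labs[length(labs) - length(remaining) + 1]
    take <- combn(length(positions), remaining[1])
    out <- lapply(seq_len(ncol(take)), function(j) {
      idx <- take[, j]
      rest <- recurse(positions[-idx], remaining[-1])
      full <- matrix(NA_character_, nrow(rest), length(positions))
      colnames(full) <- positions
      full[, positions[idx]] <- lab_i
      full[, positions[-idx]] <- rest[, positions[-idx], drop = FALSE]
      full
    })
    do.call(rbind, out)
  }
  m <- recurse(as.character(seq_len(sum(sizes))), as.integer(sizes))
  m[, as.character(seq_len(sum(sizes))), drop = FALSE]
}

#' Compare alpha indices between groups
#'
#' Runs a nonparametric test per index; exact enumeration is used
#' automatically for combined n of at most 10 (see [mann_whitney_test()]).
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @param indices Index columns to test (default: all present).
#' @param test `"mann-whitney"` (two groups) or `"kruskal-wallis"`.
#' @return Tibble: `index`, `statistic`, `p`, `method`.
#' @export
compare_alpha <- function(alpha, metadata,
                          indices = intersect(c("richness", "chao1", "shannon",
                                                "goods_coverage", "faith_pd"),
                                              names(alpha)),
                          test = c("mann-whitney", "kruskal-wallis")) {
  test <- match.arg(test)
  g <- group_labels(alpha, metadata, require_two = (test == "mann-whitney"))
  purrr::map_dfr(indices, function(idx) {
    v <- alpha[[idx]]
    ok <- !is.na(v)
    res <- if (test == "mann-whitney") {
      gl <- unique(g)
      mann_whitney_test(v[ok & g == gl[1]], v[ok & g == gl[2]])
    } else {
      kruskal_wallis_test(v[ok], g[ok])
    }
    mutate(res, index = idx, .before = 1)
  })
}
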