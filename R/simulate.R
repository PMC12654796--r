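# Seeded logistic-normal-multinomial community simulator. The default spec
# emulates a two-condition soil survey: 9 "H" vs 8 "NI" samples, per-sample
# depths of 33,000-69,000 reads, thousands of ASVs, a planted evenness gap
# between groups (per-group concentration), sparse per-ASV group effects in
# log space, and planted positively correlated ASV modules.
#
# RNG stream order (single seed governs everything, in this order):
#   1. baseline log-weights; 2. group-effect ASV choice + effect sizes;
#   3. per-sample depths; 4. module factor scores; 5. per-sample gamma draws,
#   module idiosyncratic noise and multinomial counts (sample by sample);
#   6. taxonomy assignment; 7. random bifurcating tree.

#' Specify a synthetic two-group community design
#'
#' The sampling model is logistic-normal-multinomial: per-sample latent
#' log-abundances are baseline + group effect + module-structured Gaussian
#' noise + independent log-gamma noise, mapped through a softmax and sampled
#' multinomially at a depth drawn from `depth_range`. The per-group
#' `concentration` plays the role of a Dirichlet concentration (with no
#' modules and no group effect the model reduces exactly to a
#' Dirichlet-multinomial): a smaller value yields sparser, less even samples,
#' hence lower alpha diversity.
#'
#' @param n_samples Named integer pair: samples per group (names become group
#'   labels).
#' @param n_asvs Number of ASVs.
#' @param depth_range Integer `(min, max)` reads per sample.
#' @param concentration Named per-group Dirichlet-like concentration; smaller
#'   means lower evenness/diversity for that group.
#' @param group_effect Optional numeric vector (length `n_asvs`) of log-fold
#'   differences between the groups (applied as -effect/2 to the first group
#'   and +effect/2 to the second, keeping the two baselines equally skewed).
#'   `NULL` draws effects at simulation time: `prop_affected` of ASVs get
#'   N(0, `effect_sd`) effects.
#' @param prop_affected,effect_sd Parameters of the drawn group effect.
#' @param modules List of planted correlation modules, each
#'   `list(members = <ASV indices>, strength = <|correlation| in (0,1)>,
#'   sign = +1/-1)`. Memberships must be disjoint.
#' @param module_sd Standard deviation of the module-structured log-noise.
#' @param baseline_sd Standard deviation of baseline log-weights.
#' @param baseline_boost Log-scale abundance boost for module members (keeps
#'   network-forming taxa above detection/prevalence filters).
#' @param seed Integer seed governing all randomness.
#' @return A `micronet_spec` list.
#' @export
synthetic_spec <- function(n_samples = c(H = 9, NI = 8),
                           n_asvs = 3000,
                           depth_range = c(33000, 69000),
                           concentration = c(H = 0.2, NI = 2),
                           group_effect = NULL,
                           prop_affected = 0.45,
                           effect_sd = 2,
                           modules = default_modules(n_asvs),
                           module_sd = 1,
                           baseline_sd = 1,
                           baseline_boost = 1.5,
                           seed = 1) {
  if (length(n_samples) != 2 || is.null(names(n_samples))) {
    abort("`n_samples` must be a named pair, e.g. c(H = 9, NI = 8).")
  }
  if (any(n_samples < 1)) abort("Each group needs at least one sample.")
  if (length(depth_range) != 2 || depth_range[1] < 1 || depth_range[2] < depth_range[1]) {
    abort("`depth_range` must be (min, max) with min >= 1.")
  }
  if (!all(names(n_samples) %in% names(concentration))) {
    abort("`concentration` must be named with the group labels.")
  }
  if (any(concentration <= 0)) abort("Concentrations must be > 0.")
  if (!is.null(group_effect) && length(group_effect) != n_asvs) {
    abort("`group_effect` must have length `n_asvs`.")
  }
  all_members <- integer(0)
  for (m in modules) {
    if (!all(c("members", "strength") %in% names(m))) {
      abort("Each module needs `members` and `strength`.")
    }
    if (any(m$members < 1) || any(m$members > n_asvs)) {
      abort("Module member index out of range.")
    }
    if (m$strength <= 0 || m$strength >= 1) abort("Module strength must be in (0, 1).")
    all_members <- c(all_members, m$members)
  }
  if (anyDuplicated(all_members)) abort("Module memberships must be disjoint.")
  structure(list(
    n_samples = n_samples, n_asvs = n_asvs, depth_range = depth_range,
    concentration = concentration, group_effect = group_effect,
    prop_affected = prop_affected, effect_sd = effect_sd,
    modules = modules, module_sd = module_sd, baseline_sd = baseline_sd,
    baseline_boost = baseline_boost, seed = seed
  ), class = "micronet_spec")
}

#' @rdname synthetic_spec
#' @export
default_modules <- function(n_asvs, n_modules = 3, module_size = 25,
                            strength = 0.85) {
  if (n_asvs < n_modules * module_size) return(list())
  lapply(seq_len(n_modules), function(i) {
    list(members = ((i - 1) * module_size + 1):(i * module_size),
         strength = strength, sign = 1L)
  })
}

#' Simulate a two-group community: counts, taxonomy, tree and ground truth
#'
#' @param spec A `micronet_spec` from [synthetic_spec()].
#' @return A list with elements `counts` (count tibble), `metadata`
#'   (`sample_id`, `group`), `taxonomy`, `tree` ([ape::phylo]) and `truth`
#'   (baseline, realized group effects, module memberships, depths).
#' @export
simulate_community <- function(spec) {
  if (!inherits(spec, "micronet_spec")) abort("`spec` must come from synthetic_spec().")
  k <- spec$n_asvs
  groups_lab <- names(spec$n_samples)
  group_of <- rep(groups_lab, times = spec$n_samples)
  n <- length(group_of)
  sample_ids <- unlist(lapply(groups_lab, function(g) {
    paste0(g, seq_len(spec$n_samples[[g]]))
  }))
  asv_ids <- sprintf("ASV%05d", seq_len(k))

  withr::with_seed(spec$seed, {
    ## 1. baseline log-weights (module members boosted above detection limits)
    baseline <- rnorm(k, 0, spec$baseline_sd)
    for (m in spec$modules) baseline[m$members] <- baseline[m$members] + spec$baseline_boost

    ## 2. group effect on the second group's log-abundance
    if (is.null(spec$group_effect)) {
      n_aff <- round(spec$prop_affected * k)
      affected <- sort(sample.int(k, n_aff))
      effect <- numeric(k)
      effect[affected] <- rnorm(n_aff, 0, spec$effect_sd)
    } else {
      effect <- spec$group_effect
      affected <- which(effect != 0)
    }

    ## 3. depths
    depths <- sample(spec$depth_range[1]:spec$depth_range[2], n, replace = TRUE)

    ## 4. module factor scores (one latent factor per module per sample)
    n_mod <- length(spec$modules)
    fscores <- if (n_mod > 0) matrix(rnorm(n * n_mod), n, n_mod) else NULL

    ## module loadings: sign = -1 flips half the members so within-module
    ## correlations are negative between the two halves
    loadings <- lapply(spec$modules, function(m) {
      l <- rep(1, length(m$members))
      if (!is.null(m$sign) && m$sign < 0) l[seq_along(l) %% 2 == 0] <- -1
      l
    })

    ## 5. per-sample composition and counts
    counts <- matrix(0L, n, k, dimnames = list(sample_ids, asv_ids))
    for (i in seq_len(n)) {
      g <- group_of[i]
      ## symmetric split keeps the two baselines equally skewed, so the
      ## planted evenness gap stays governed by `concentration` alone
      mu <- baseline + if (g == groups_lab[2]) effect / 2 else -effect / 2
      w <- exp(mu - max(mu)); w <- w / sum(w)
      shape <- spec$concentration[[g]] * k * w
      gam <- rgamma(k, shape = shape, rate = 1)
      noise <- numeric(k)
      for (mi in seq_along(spec$modules)) {
        m <- spec$modules[[mi]]
        rho <- m$strength
        eps <- rnorm(length(m$members))
        noise[m$members] <- spec$module_sd *
          (sqrt(rho) * loadings[[mi]] * fscores[i, mi] + sqrt(1 - rho) * eps)
      }
      u <- gam * exp(noise)
      if (all(u == 0)) abort("Degenerate sample: all latent weights are zero.")
      p <- u / sum(u)
      counts[i, ] <- as.integer(rmultinom(1, depths[i], p))
    }

    ## 6. taxonomy from a fixed synthetic rank hierarchy
    taxonomy <- simulate_taxonomy(asv_ids)

    ## 7. random bifurcating tree with exponential branch lengths
    tree <- ape::rtree(k, br = rexp)
    tree$tip.label <- sample(asv_ids)
  })

  list(
    counts = as_count_tibble(counts),
    metadata = tibble(sample_id = sample_ids, group = group_of),
    taxonomy = taxonomy,
    tree = tree,
    truth = list(
      baseline = setNames(baseline, asv_ids),
      group_effect = setNames(effect, asv_ids),
      affected = asv_ids[affected],
      modules = lapply(spec$modules, function(m)
        list(members = asv_ids[m$members], strength = m$strength,
             sign = m$sign %||% 1L)),
      concentration = spec$concentration,
      depths = setNames(depths, sample_ids),
      seed = spec$seed
    )
  )
}

# Fixed synthetic hierarchy: phyla drawn with soil-survey-like weights, lower
# ranks nested labels; ~15% of genera left "unclassified".
simulate_taxonomy <- function(asv_ids) {
  phyla <- c("Proteobacteria", "Acidobacteriota", "Actinobacteriota",
             "Chloroflexi", "Bacteroidota", "Gemmatimonadota",
             "Verrucomicrobiota", "Planctomycetota", "Patescibacteria", "WPS-2")
  wts <- c(0.30, 0.16, 0.15, 0.10, 0.07, 0.05, 0.05, 0.04, 0.04, 0.04)
  k <- length(asv_ids)
  ph <- sample(phyla, k, replace = TRUE, prob = wts)
  cl <- paste0(ph, "_c", sample.int(3, k, replace = TRUE))
  or <- paste0(cl, "_o", sample.int(3, k, replace = TRUE))
  fa <- paste0(or, "_f", sample.int(4, k, replace = TRUE))
  ge <- ifelse(runif(k) < 0.15, "unclassified",
               paste0(fa, "_g", sample.int(5, k, replace = TRUE)))
  tibble(asv_id = asv_ids, domain = "Bacteria", phylum = ph, class = cl,
         order = or, family = fa, genus = ge)
}
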