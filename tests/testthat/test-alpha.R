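test_that("alpha indices match hand-computed values", {
  ct <- tibble::tibble(sample_id = c("even", "skew"),
                       a = c(5L, 2L), b = c(5L, 1L), c = c(5L, 1L), d = c(5L, 0L))
  a <- alpha_diversity(ct)
  even <- a[a$sample_id == "even", ]
  expect_equal(even$richness, 4)
  expect_equal(even$shannon, 2)            # uniform 4 taxa, log2
  expect_equal(even$chao1, 4)              # no singletons
  expect_equal(even$goods_coverage, 100)

  skew <- a[a$sample_id == "skew", ]       # counts (2,1,1): F1 = 2, F2 = 1
  expect_equal(skew$shannon, 1.5)
  expect_equal(skew$chao1, 3 + 2 * 1 / (2 * (1 + 1)))  # = 3.5
  expect_equal(skew$goods_coverage, 100 * (1 - 2 / 4)) # = 50
})

test_that("shannon of a uniform S-taxon sample is log2(S); chao1 bounds hold", {
  for (S in c(2, 8, 33)) {
    ct <- tibble::tibble(sample_id = "s",
                         !!!stats::setNames(as.list(rep(7L, S)), paste0("t", 1:S)))
    a <- alpha_diversity(ct)
    expect_equal(a$shannon, log2(S))
    expect_equal(a$chao1, S)  # F1 = 0 -> chao1 = richness
  }
  # chao1 monotone non-decreasing in F1 at fixed F2
  chao <- function(counts) {
    ct <- tibble::tibble(sample_id = "s",
                         !!!stats::setNames(as.list(as.integer(counts)),
                                            paste0("t", seq_along(counts))))
    alpha_diversity(ct)$chao1
  }
  vals <- sapply(0:4, function(f1) chao(c(rep(1L, f1), rep(2L, 2), rep(5L, 3))))
  expect_true(all(diff(vals) >= 0))
})

test_that("faith PD follows the rooted-subtree convention", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  total <- sum(tr$edge.length)
  all_tips <- tibble::tibble(sample_id = c("all", "oneA", "ab"),
                             A = c(1L, 4L, 1L), B = c(1L, 0L, 1L),
                             C = c(1L, 0L, 0L), D = c(1L, 0L, 0L))
  a <- alpha_diversity(all_tips, tr)
  expect_equal(a$faith_pd[a$sample_id == "all"], total)
  # single tip: root-to-tip path (A: 1 + 1 = 2)
  expect_equal(a$faith_pd[a$sample_id == "oneA"], 2)
  # monotone under adding observed tips
  expect_true(a$faith_pd[a$sample_id == "ab"] >= a$faith_pd[a$sample_id == "oneA"])
  expect_true(a$faith_pd[a$sample_id == "ab"] <= total)
})

test_that("empty samples are flagged, not silently zeroed", {
  ct <- tibble::tibble(sample_id = c("ok", "empty"), a = c(3L, 0L), b = c(1L, 0L))
  expect_warning(a <- alpha_diversity(ct), "empty")
  e <- a[a$sample_id == "empty", ]
  expect_equal(e$richness, 0)
  expect_true(is.na(e$shannon) && is.na(e$chao1) && is.na(e$goods_coverage))
})

test_that("rarefaction subsamples without replacement to exact depth", {
  sim <- simulate_community(synthetic_spec(
    n_asvs = 150, depth_range = c(800, 1500), seed = 3))
  ct <- sim$counts
  r <- rarefy_counts(ct, 800, seed = 1)
  expect_true(all(rowSums(as_count_matrix(r)) == 800))
  # rarefied counts never exceed the originals (without replacement)
  expect_true(all(as_count_matrix(r) <= as_count_matrix(ct)))
  # depth equal to a sample's total leaves that sample unchanged
  tot1 <- sum(as_count_matrix(ct)[1, ])
  expect_warning(r1 <- rarefy_counts(ct, tot1, seed = 1), "Dropping")
  if (ct$sample_id[1] %in% r1$sample_id) {
    expect_equal(as_count_matrix(r1)[ct$sample_id[1], ],
                 as_count_matrix(ct)[ct$sample_id[1], ])
  }
  expect_error(rarefy_counts(ct, 0), "positive")
  expect_error(rarefy_counts(ct, 1e7), "No sample")
})

test_that("mean rarefied richness is non-decreasing in depth", {
  sim <- simulate_community(synthetic_spec(
    n_asvs = 200, depth_range = c(2000, 2500), seed = 9))
  depths <- seq(100, 1900, length.out = 10)
  curves <- rarefaction_curves(sim$counts, depths, n_iter = 8, seed = 2)
  rich <- curves[curves$index == "richness", ]
  by_depth <- tapply(rich$mean, rich$depth, mean)
  expect_true(all(diff(by_depth[order(as.numeric(names(by_depth)))]) >= 0))
})

test_that("exact Mann-Whitney enumeration matches brute force and wilcox.test", {
  # canonical worked example: complete separation of 3 vs 3
  res <- mann_whitney_test(c(1, 2, 3), c(10, 11, 12), alternative = "less")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1 / choose(6, 3))  # = 0.05

  # identical groups: exact two-sided p = 1
  res2 <- mann_whitney_test(c(4, 4, 4), c(4, 4, 4))
  expect_equal(res2$p, 1)

  # oracle: wilcox.test exact p on tie-free draws (odd vs even values)
  withr::with_seed(42, {
    for (i in 1:20) {
      x <- sample(seq(1, 199, 2), 4); y <- sample(seq(2, 200, 2), 5)
      mine <- mann_whitney_test(x, y)
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
      expect_equal(mine$statistic, unname(ref$statistic))
    }
  })
})

test_that("kruskal-wallis agrees with stats::kruskal.test and the MW decision", {
  withr::with_seed(7, {
    # exact enumeration beats stats only in convention; check approx identity
    for (i in 1:10) {
      v <- rnorm(14); g <- rep(c("a", "b"), each = 7)
      mine <- kruskal_wallis_test(v, g, exact = FALSE)
      ref <- stats::kruskal.test(v, factor(g))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
      # for two groups the KW decision matches the MW (no continuity corr.)
      mw <- mann_whitney_test(v[g == "a"], v[g == "b"], exact = FALSE)
      expect_equal(mw$p, mine$p, tolerance = 1e-10)
    }
    # exact path: small groups, p from full enumeration is a valid p in (0,1]
    v <- c(1, 5, 3, 8, 9, 12, 2)
    g <- c("a", "a", "b", "b", "c", "c", "c")
    ex <- kruskal_wallis_test(v, g)
    expect_true(ex$p > 0 && ex$p <= 1)
    expect_match(ex$method, "exact")
  })
  expect_error(kruskal_wallis_test(1:5, c("a", "a", "b", "b", "b")[c(1, 1, 2, 2, 2)]), NA)
  expect_error(mann_whitney_test(1, c(2, 3)), "at least 2")
})

test_that("compare_alpha runs the chosen test per index", {
  a <- tibble::tibble(sample_id = paste0("s", 1:8),
                      richness = c(10, 12, 11, 13, 30, 31, 29, 32),
                      shannon = c(1, 1.2, 1.1, 1.3, 3, 3.1, 2.9, 3.2))
  md <- tibble::tibble(sample_id = paste0("s", 1:8),
                       group = rep(c("lo", "hi"), each = 4))
  res <- compare_alpha(a, md, indices = c("richness", "shannon"))
  expect_equal(nrow(res), 2)
  expect_true(all(res$p < 0.05))
})
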