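test_that("prevalence filter keeps ASVs at the inclusive boundary", {
  m <- matrix(0L, 9, 3, dimnames = list(paste0("s", 1:9), c("in5", "in4", "in9")))
  m[1:5, "in5"] <- 1L; m[1:4, "in4"] <- 1L; m[, "in9"] <- 2L
  ct <- tibble::tibble(sample_id = rownames(m), !!!as.data.frame(m))
  kept <- prevalence_filter(ct, 5)
  expect_setequal(names(kept)[-1], c("in5", "in9"))
  # hand-enumerated retained set on a random fixture
  withr::with_seed(1, {
    mm <- matrix(rbinom(9 * 20, 1, 0.5) * rpois(180, 4), 9, 20,
                 dimnames = list(paste0("s", 1:9), paste0("a", 1:20)))
    ctt <- tibble::tibble(sample_id = rownames(mm), !!!as.data.frame(mm))
    expect_setequal(names(prevalence_filter(ctt, 5))[-1],
                    colnames(mm)[colSums(mm > 0) >= 5])
  })
})

test_that("clr transform matches the formula and rows sum to zero", {
  ct <- tibble::tibble(sample_id = c("e", "s"), a = c(4L, 10L), b = c(4L, 1L))
  clr <- clr_transform(ct, pseudocount = 1)
  x <- as.matrix(clr[, -1])
  expect_equal(unname(x[1, ]), c(0, 0))  # equal counts row
  expect_equal(unname(x[2, 1]), 0.5 * log(11 / 2), tolerance = 1e-12)
  expect_equal(unname(x[2, 2]), -0.5 * log(11 / 2), tolerance = 1e-12)
  expect_equal(unname(rowSums(x)), c(0, 0), tolerance = 1e-12)
  expect_error(clr_transform(ct, pseudocount = 0), "pseudocount")
})

test_that("the signed weight map has the prescribed endpoints and midpoint", {
  expect_equal(signed_weight(-1), 0)
  expect_equal(signed_weight(0), 0.5)
  expect_equal(signed_weight(1), 1)
  r <- seq(-1, 1, 0.05)
  expect_true(all(diff(signed_weight(r)) > 0))  # strictly increasing
})

test_that("perfect correlations give the boundary edge weights", {
  base <- c(1, 3, 5, 9, 12, 15)
  ct <- tibble::tibble(sample_id = paste0("s", 1:6),
                       up = as.integer(base * 10),
                       up2 = as.integer(base * 20),
                       down = as.integer(rev(base) * 10),
                       flat = rep(7L, 6))
  clr <- tibble::tibble(sample_id = ct$sample_id,
                        up = base, up2 = 2 * base, down = -base,
                        flat = rep(0, 6))
  expect_warning(net <- build_network(clr, 0.9), "zero-variance")
  e <- net$edges
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  pos <- e[key == "up up2", ]
  expect_equal(pos$r, 1, tolerance = 1e-12)
  expect_equal(pos$sign, 1L)
  expect_equal(pos$weight, 1)
  neg <- e[key == "down up", ]
  expect_equal(neg$r, -1, tolerance = 1e-12)
  expect_equal(neg$sign, -1L)
  expect_equal(neg$weight, 0)
  expect_false("flat" %in% c(e$from, e$to))
})

test_that("uncorrelated pairs never form edges at positive thresholds", {
  withr::with_seed(6, {
    clr <- tibble::tibble(sample_id = paste0("s", 1:100),
                          a = rnorm(100), b = rnorm(100))
    net <- suppressMessages(build_network(clr, 0.5))
    expect_equal(nrow(net$edges), 0)
  })
})

test_that("the network constructor enforces its invariants", {
  expect_error(toy_network(from = "a", to = "a", r = 0.5), "Self-edges")
  expect_error(toy_network(from = c("a", "b"), to = c("b", "a"), r = c(0.5, 0.7)),
               "at most once")
  expect_error(cooccurrence_network(
    tibble::tibble(from = "a", to = "b", r = 0.5),
    nodes = tibble::tibble(asv_id = "a")), "missing")
})

test_that("fast-greedy clustering splits the canonical two-clique graph", {
  cl1 <- t(utils::combn(paste0("x", 1:4), 2))
  cl2 <- t(utils::combn(paste0("y", 1:4), 2))
  e <- tibble::tibble(from = c(cl1[, 1], cl2[, 1], "x1"),
                      to = c(cl1[, 2], cl2[, 2], "y1"),
                      r = 0.9)
  net <- cooccurrence_network(e, threshold = 0.5)
  part <- fast_greedy_clusters(net)
  memb <- stats::setNames(part$membership$cluster, part$membership$asv_id)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[paste0("x", 1:4)])), 1)
  expect_equal(length(unique(memb[paste0("y", 1:4)])), 1)
  expect_gt(part$modularity, 0.3)
})

test_that("cluster partitions are invariant to node input order", {
  net <- random_network(12, 0.35, seed = 21)
  p1 <- fast_greedy_clusters(net)
  net_shuffled <- net
  withr::with_seed(3, {
    ord <- sample(nrow(net$nodes))
    net_shuffled$nodes <- net$nodes[ord, ]
    eord <- sample(nrow(net$edges))
    net_shuffled$edges <- net$edges[eord, ]
  })
  p2 <- fast_greedy_clusters(net_shuffled)
  expect_equal(dplyr::arrange(p1$membership, asv_id),
               dplyr::arrange(p2$membership, asv_id))
  expect_equal(p1$modularity, p2$modularity)
})

test_that("an edgeless network yields singleton clusters with Q = 0", {
  net <- toy_network(from = "a", to = "b", r = 0.9)
  net$edges <- net$edges[0, ]
  part <- fast_greedy_clusters(net)
  expect_equal(nrow(part$membership), 2)
  expect_equal(length(unique(part$membership$cluster)), 2)
  expect_equal(part$modularity, 0)
})

test_that("greedy modularity never exceeds the exhaustive-partition optimum", {
  n_match <- 0; n_graphs <- 8
  for (s in seq_len(n_graphs)) {
    net <- random_network(7, 0.3, seed = 100 + s)
    part <- fast_greedy_clusters(net)
    ids <- sort(net$nodes$asv_id)
    best <- -Inf
    for (pp in all_partitions(length(ids))) {
      q <- partition_modularity(net, stats::setNames(pp, ids))
      if (q > best) best <- q
    }
    expect_lte(part$modularity, best + 1e-12)
    if (abs(part$modularity - best) < 1e-12) n_match <- n_match + 1
  }
  # greedy merging reaches the optimum on most of these small graphs
  expect_gte(n_match, ceiling(0.6 * n_graphs))
})

test_that("edge sign summaries count, split and ratio correctly", {
  expect_equal(pn_ratio(2136, 417), 5.12)
  expect_equal(pn_ratio(2902, 922), 3.15)
  expect_equal(pn_ratio(19, 19), 1.0)
  expect_equal(pn_ratio(23, 0), 23.0)

  net <- random_network(15, 0.4, seed = 33)
  part <- fast_greedy_clusters(net)
  s <- edge_sign_summary(net, part)
  expect_equal(s$n_positive + s$n_negative, s$n_edges)
  expect_equal(s$intra_positive + s$inter_positive, s$n_positive)
  expect_equal(s$intra_negative + s$inter_negative, s$n_negative)
  expect_equal(s$ratio, pn_ratio(s$n_positive, s$n_negative))
})

test_that("ratio shifts reproduce the balanced-to-positive archetype", {
  # focal ASV: 19 positive + 19 negative in A, 23 positive + 0 negative in B
  mk_star <- function(pos, neg, prefix) {
    tibble::tibble(
      from = "focal",
      to = paste0(prefix, seq_len(pos + neg)),
      r = c(rep(0.8, pos), rep(-0.8, neg)))
  }
  net_a <- cooccurrence_network(mk_star(19, 19, "a"), threshold = 0.5)
  net_b <- cooccurrence_network(mk_star(23, 0, "b"), threshold = 0.5)
  shift <- suppressWarnings(ratio_shift(net_a, net_b))
  focal <- shift[shift$asv_id == "focal", ]
  expect_equal(focal$ratio_a, 1.0)
  expect_equal(focal$ratio_b, 23.0)
  expect_equal(focal$fold_change, 23.0)
  # ASVs absent from either network are excluded
  expect_false(any(grepl("^a", shift$asv_id) & grepl("^b", shift$asv_id)))

  # hand-checked 3-ASV fixture ordering
  ea <- tibble::tibble(from = c("x", "x", "y", "z"), to = c("y", "z", "z", "w"),
                       r = c(0.9, -0.9, 0.9, -0.9))
  eb <- tibble::tibble(from = c("x", "x", "y"), to = c("y", "z", "z"),
                       r = c(0.9, 0.9, -0.9))
  sh <- ratio_shift(cooccurrence_network(ea, threshold = 0.5),
                    cooccurrence_network(eb, threshold = 0.5))
  # x: A (1 pos, 1 neg) ratio 1 -> B (2 pos, 0 neg) ratio 2: fold 2 (largest)
  expect_equal(sh$asv_id[1], "x")
  expect_equal(sh$fold_change[1], 2)

  expect_warning(
    empty <- ratio_shift(
      cooccurrence_network(tibble::tibble(from = "a", to = "b", r = 0.5),
                           threshold = 0.2),
      cooccurrence_network(tibble::tibble(from = "c", to = "d", r = 0.5),
                           threshold = 0.2)),
    "shared")
  expect_equal(nrow(empty), 0)
})

test_that("eigenvector centrality: star center is maximal, cycles are flat", {
  star <- cooccurrence_network(
    tibble::tibble(from = "hub", to = paste0("leaf", 1:6), r = 0.9),
    threshold = 0.5)
  cent <- eigenvector_centrality(star)
  expect_equal(cent$asv_id[which.max(cent$centrality)], "hub")
  expect_equal(max(cent$centrality), 1)

  cyc <- cooccurrence_network(
    tibble::tibble(from = paste0("n", 1:6),
                   to = paste0("n", c(2:6, 1)), r = 0.8),
    threshold = 0.5)
  cc <- eigenvector_centrality(cyc)
  expect_equal(diff(range(cc$centrality)), 0, tolerance = 1e-8)
  # strict top-decile rule leaves the keystone set empty under full ties
  counts <- tibble::tibble(sample_id = "s1",
                           !!!as.list(stats::setNames(rep(10L, 6), paste0("n", 1:6))))
  ks <- keystone_taxa(cyc, counts)
  expect_equal(sum(ks$keystone), 0)
})

test_that("power iteration agrees with a dense eigen-decomposition oracle", {
  for (s in 1:6) {
    net <- random_network(sample(10:50, 1), 0.15, seed = 200 + s)
    cent <- eigenvector_centrality(net)
    oracle <- centrality_eigen_oracle(net)
    expect_equal(stats::setNames(cent$centrality, cent$asv_id)[names(oracle)],
                 oracle, tolerance = 1e-8)
  }
})

test_that("a planted low-abundance hub is detected as keystone", {
  hits <- 0
  for (s in 1:20) {
    ph <- planted_hub_network(300 + s)
    ks <- keystone_taxa(ph$net, ph$counts)
    if (isTRUE(ks$keystone[ks$asv_id == ph$hub])) hits <- hits + 1
  }
  expect_gte(hits, 19)  # >= 95% of 20 replicates
})
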