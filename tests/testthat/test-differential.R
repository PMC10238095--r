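test_that("exact rank-sum p-values match full permutation enumeration", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p, 1 / 3, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    n_a <- sample(2:5, 1); n_b <- sample(2:5, 1)
    a <- sample(1:8, n_a, replace = TRUE)   # replace -> ties exercised
    b <- sample(1:8, n_b, replace = TRUE)
    if (length(unique(c(a, b))) == 1L) next
    expect_equal(rank_sum_test(a, b, mode = "exact")$p, oracle_rank_sum_p(a, b),
                 tolerance = 1e-12)
  }
  # tie-free case agrees with the reference exact implementation
  a <- c(1.2, 3.4, 2.2); b <- c(5.1, 0.3, 4.4, 6.2)
  expect_equal(rank_sum_test(a, b, mode = "exact")$p,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("rank-sum symmetry and degenerate-input conventions hold", {
  a <- c(1, 5, 3); b <- c(2, 8, 9, 4)
  ra <- rank_sum_test(a, b); rb <- rank_sum_test(b, a)
  expect_equal(ra$p, rb$p)
  expect_equal(ra$statistic, -rb$statistic)
  expect_equal(rank_sum_test(c(2, 2), c(2, 2))$p, 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("BH adjustment follows the step-up rule and dominates p", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  expect_equal(q, p.adjust(p, "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("one-vs-rest detects a planted shift and returns one table per class", {
  set.seed(6)
  mat <- matrix(rnorm(50 * 160), 50, 160,
                dimnames = list(paste0("f", 1:50), paste0("s", 1:160)))
  labs <- rep(paste0("C", 1:4), each = 40)
  mat["f1", labs == "C1"] <- mat["f1", labs == "C1"] + 2
  ovr <- one_vs_rest_differential(mat, labs)
  expect_equal(length(unique(ovr$comparison)), 4)
  hit <- ovr[ovr$feature == "f1" & ovr$comparison == "C1-vs-rest", ]
  expect_lt(hit$p, 1e-3)
  expect_equal(unname(hit$direction), "up")
  expect_true(all(ovr$fdr >= ovr$p - 1e-15))
  expect_error(one_vs_rest_differential(mat, c("A", rep("B", 159))), "size < 2")
})

test_that("null features stay non-significant in most replicates", {
  nonsig <- 0
  for (s in 1:20) {
    set.seed(s + 100)
    mat <- matrix(rnorm(1 * 120), 1, 120,
                  dimnames = list("f1", paste0("s", 1:120)))
    labs <- rep(paste0("C", 1:4), each = 30)
    ovr <- one_vs_rest_differential(mat, labs)
    if (all(ovr$p > 0.05)) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 0.95 * 20 - 3)   # binomial slack on 20 replicates
})

test_that("subtype-specific selection applies the exclusion rule and stays disjoint", {
  ovr <- tibble::tibble(
    feature = c("f1", "f2", "f3", "f1", "f2", "f3", "f1", "f2", "f3"),
    comparison = rep(c("C1-vs-rest", "C2-vs-rest", "C3-vs-rest"), each = 3),
    effect = c(2, 1.5, 0.1, -0.2, 1.8, 0.1, 0.3, 0.2, 0.1),
    statistic = 0, p = c(1e-5, 1e-4, 0.9, 0.8, 1e-6, 0.9, 0.7, 0.6, 0.9))
  ovr$fdr <- ovr$p
  ovr$direction <- ifelse(ovr$effect >= 0, "up", "down")
  out <- subtype_specific_features(ovr, fdr_cut = 0.05)
  expect_equal(out$C1, "f1")          # significant only in C1
  expect_false("f2" %in% out$C1)      # f2 significant in C1 and C2 -> excluded
  expect_false("f2" %in% out$C2)
  # disjointness on random inputs
  set.seed(12)
  mat <- matrix(rnorm(200 * 60), 200, 60,
                dimnames = list(sprintf("f%03d", 1:200), paste0("s", 1:60)))
  labs <- rep(paste0("C", 1:4), each = 15)
  mat[1:10, labs == "C1"] <- mat[1:10, labs == "C1"] + 3
  mat[11:20, labs == "C2"] <- mat[11:20, labs == "C2"] + 3
  # a strict cut keeps the exclusion rule from firing on the weak
  # "shadow" significance a C1 marker leaves in other classes' rest groups
  lists <- subtype_specific_features(one_vs_rest_differential(mat, labs),
                                     fdr_cut = 1e-3)
  for (i in seq_along(lists)) for (j in seq_along(lists)) {
    if (i < j) expect_length(intersect(lists[[i]], lists[[j]]), 0)
  }
  expect_setequal(lists$C1, sprintf("f%03d", 1:10))
  expect_setequal(lists$C2, sprintf("f%03d", 11:20))
})

test_that("DMG filtering uses strict thresholds and recovers planted genes", {
  expect_equal(dmg_filter(c(g1 = 0.1), c(g1 = 0.6), c(g1 = 0.01)), "g1")
  expect_length(dmg_filter(c(g1 = 0.2), c(g1 = 0.6), c(g1 = 0.01)), 0)
  expect_length(dmg_filter(c(g1 = 0.1), c(g1 = 0.5), c(g1 = 0.01)), 0)
  expect_length(dmg_filter(c(g1 = 0.1), c(g1 = 0.6), c(g1 = 0.05)), 0)
  expect_error(dmg_filter(c(g1 = -0.1), c(g1 = 0.6), c(g1 = 0.01)), "\\[0, 1\\]")
  set.seed(21)
  genes <- sprintf("g%03d", 1:200)
  normal <- runif(200, 0.3, 0.9); tumor <- runif(200, 0, 0.45)
  fdr <- runif(200, 0.05, 1)
  planted <- sample(genes, 30)
  normal[genes %in% planted] <- runif(30, 0, 0.19)
  tumor[genes %in% planted] <- runif(30, 0.51, 1)
  fdr[genes %in% planted] <- runif(30, 0, 0.049)
  names(normal) <- names(tumor) <- names(fdr) <- genes
  expect_setequal(dmg_filter(normal, tumor, fdr), planted)
})

test_that("promoter probes aggregate to per-gene medians with NA probes dropped", {
  betas <- matrix(c(0.1, 0.2, 0.9,
                    0.4, NA, 0.6,
                    0.5, 0.5, 0.5), 3, 3, byrow = FALSE,
                  dimnames = list(c("p1", "p2", "p3"), c("s1", "s2", "s3")))
  map <- c(p1 = "GENE1", p2 = "GENE1", p3 = "GENE1")
  agg <- aggregate_promoter_probes(betas, map)
  expect_equal(agg["GENE1", "s1"], median(c(0.1, 0.2, 0.9)))
  expect_equal(agg["GENE1", "s2"], median(c(0.4, 0.6)))   # NA probe dropped
  single <- aggregate_promoter_probes(betas, c(p2 = "GENE2"))
  expect_equal(unname(single["GENE2", ]), unname(betas["p2", ]))
  expect_false("GENE3" %in% rownames(aggregate_promoter_probes(betas, map)))
})
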