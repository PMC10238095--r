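canonical_pairs <- function() {
  pairs <- combn(paste0("C", 1:4), 2)
  paste0(pairs[1, ], "-vs-", pairs[2, ])
}

# Signs implied by values increasing along an ordering.
signs_for_ordering <- function(ordering) {
  pos <- setNames(seq_along(ordering), ordering)
  pairs <- combn(sort(ordering), 2)
  setNames(ifelse(pos[pairs[2, ]] > pos[pairs[1, ]], 1, -1),
           paste0(pairs[1, ], "-vs-", pairs[2, ]))
}

test_that("common feature set is the three-layer set-algebra intersection", {
  mk <- function(features, ps, col = "fdr") {
    tab <- tibble::tibble(feature = features, comparison = "C1-vs-C2",
                          effect = 1, statistic = 0, p = ps, fdr = ps,
                          direction = "up")
    tab
  }
  dmg <- mk(c("a", "b", "c"), c(0.01, 0.01, 0.5))
  deg <- mk(c("a", "b", "d"), c(0.01, 0.2, 0.01))
  dep <- mk(c("a", "b", "e"), c(0.1, 0.1, 0.1))
  out <- common_feature_set(dmg, deg, dep)
  # oracle by direct set algebra
  oracle <- intersect(intersect(c("a", "b"), c("a", "d")), c("a", "b", "e"))
  expect_setequal(out, oracle)
  # feature passing two layers only is excluded
  expect_false("b" %in% out)
  expect_message(common_feature_set(mk("x", 0.9), deg, dep), "empty")
})

test_that("ordering consistency recognises monotone patterns and rejects conflicts", {
  ord <- c("C1", "C4", "C2", "C3")
  s <- signs_for_ordering(ord)
  expect_equal(ordering_consistency(s, ord), "monotone_increasing")
  expect_equal(ordering_consistency(-s, ord), "monotone_decreasing")
  s2 <- s; s2[1] <- -s2[1]
  expect_equal(ordering_consistency(s2, ord), "inconsistent")
  expect_error(ordering_consistency(s[-1], ord), "missing")
})

test_that("fraction of sign tournaments consistent with some ordering matches enumeration", {
  pn <- canonical_pairs()
  consistent_pkg <- 0
  consistent_oracle <- 0
  for (bits in 0:63) {
    s <- ifelse(bitwAnd(bits, 2^(0:5)) > 0, 1, -1)
    names(s) <- pn
    mo <- match_orderings(matrix(s, 1, dimnames = list("f", pn)))
    if (mo$matched_ordering != "inconsistent") consistent_pkg <- consistent_pkg + 1
    # oracle: check all 24 permutations directly from pair positions
    perms <- list()
    for (p1 in paste0("C", 1:4)) for (p2 in setdiff(paste0("C", 1:4), p1))
      for (p3 in setdiff(paste0("C", 1:4), c(p1, p2))) {
        perms[[length(perms) + 1]] <- c(p1, p2, p3, setdiff(paste0("C", 1:4), c(p1, p2, p3)))
      }
    hit <- any(vapply(perms, function(o) all(s == signs_for_ordering(o)), logical(1)))
    if (hit) consistent_oracle <- consistent_oracle + 1
  }
  expect_equal(consistent_pkg, consistent_oracle)
  expect_equal(consistent_pkg, 24)   # transitive tournaments on 4 items
})

test_that("UpSet counts equal brute-force membership tabulation and partition the union", {
  sets <- list(A = c("x", "y", "z"), B = c("y", "w"), C = c("q"))
  out <- upset_counts(sets)
  expect_equal(sum(out$count), length(unique(unlist(sets))))
  expect_equal(out$count[out$combination == "A & B"], 1L)   # y
  expect_equal(out$count[out$combination == "A"], 2L)       # x, z
  # disjoint sets: no multi-set combination present
  dis <- upset_counts(list(A = c("a", "b"), B = c("c")))
  expect_false(any(grepl("&", dis$combination)))
  # random sets vs direct tabulation
  set.seed(14)
  rs <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(rs) <- paste0("S", 1:4)
  rout <- upset_counts(rs)
  expect_equal(sum(rout$count), length(unique(unlist(rs))))
  for (el in unique(unlist(rs))) {
    combo <- paste(names(rs)[vapply(rs, function(s) el %in% s, logical(1))],
                   collapse = " & ")
    expect_true(combo %in% rout$combination)
  }
})

test_that("reversal symmetry: flipping the data flips increasing to decreasing", {
  sim <- gen_multiomics_evolution(n_features = 120, n_monotone = 15,
                                  n_per_subtype = 25, seed = 17)
  ord <- sim$truth$ordering
  up <- monotone_features(sim$expression, sim$truth$labels, ord)
  down <- monotone_features(-sim$expression, sim$truth$labels, ord)
  expect_setequal(up$increasing, down$decreasing)
  expect_setequal(up$decreasing, down$increasing)
})

test_that("cross-cohort gene derivation is the sorted intersection", {
  expect_equal(derive_cccrc_genes(c("b", "a", "c"), c("c", "d", "a")), c("a", "c"))
  expect_length(derive_cccrc_genes(c("a"), c("b")), 0)
})

test_that("evolution score equals a single-set GSVA call and tracks planted rank structure", {
  expr <- toy_expr(20, 5, 23)
  genes <- paste0("g", c(1, 5, 9, 13))
  sc <- cccrc_score(expr, genes)
  direct <- gsva_scores(expr, signature_panel(list(cccrc = genes)))
  expect_equal(unname(sc), unname(direct["cccrc", ]))
  expect_error(cccrc_score(expr, "g1"), "fewer than 2")
  # samples with the set at the top ranks outscore samples with it at the bottom
  e <- matrix(rnorm(20 * 4, sd = 0.1), 20, 4,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  e[genes, 1:2] <- e[genes, 1:2] + 5     # set occupies top ranks in s1, s2
  e[genes, 3:4] <- e[genes, 3:4] - 5     # and bottom ranks in s3, s4
  s2 <- cccrc_score(e, genes)
  expect_true(min(s2[1:2]) > max(s2[3:4]))
})

test_that("under the null no ordering dominates the tournament counts", {
  ok <- 0
  for (s in 1:10) {
    sim <- gen_multiomics_evolution(n_features = 300, n_monotone = 0,
                                    n_per_subtype = 15, step_effect = 0, seed = s)
    pw <- pairwise_differential(sim$expression, sim$truth$labels)
    signs <- pairwise_signs(pw)         # sign-only mode: every feature matches
    mo <- match_orderings(signs)
    counts <- table(mo$matched_ordering[mo$matched_ordering != "inconsistent"])
    if (length(counts) == 0 || max(counts) <= 3 * median(as.numeric(counts))) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
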