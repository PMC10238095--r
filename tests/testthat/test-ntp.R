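make_line_panel <- function(effect = 2, n_lines = 60, seed = 2) {
  set.seed(seed)
  genes <- sprintf("g%04d", 1:500)
  markers <- split(genes[1:80], rep(paste0("C", 1:4), each = 20))
  expr <- matrix(rnorm(500 * n_lines), 500, n_lines,
                 dimnames = list(genes, sprintf("L%02d", 1:n_lines)))
  labs <- sample(paste0("C", 1:4), n_lines, replace = TRUE)
  for (k in paste0("C", 1:4)) {
    expr[markers[[k]], labs == k] <- expr[markers[[k]], labs == k] + effect
  }
  list(expr = expr, labels = labs, markers = markers)
}

test_that("intrinsic filter applies the PDX and cell-line gates as pure filters", {
  genes <- sprintf("g%02d", 1:40)
  markers <- list(C1 = genes[1:10], C2 = genes[11:20])
  pdx <- tibble::tibble(feature = genes,
                        effect = rep(0.2, 40), fdr = rep(0.9, 40))
  # gene g01 is stroma-driven: strong PDX depletion signal
  pdx$fdr[1] <- 0.01; pdx$effect[1] <- 2.5
  set.seed(31)
  lines <- matrix(rnorm(40 * 20, mean = 5), 40, 20,
                  dimnames = list(genes, sprintf("L%02d", 1:20)))
  out <- intrinsic_gene_filter(markers, pdx, lines,
                               range_quantiles = c(0, 1), top_fraction = 1,
                               min_high_lines = 0)
  expect_false("g01" %in% out$C1)              # PDX-significant gene removed
  expect_setequal(out$C1, genes[2:10])         # everything else retained
  # pure filter: output is a subset of the input lists
  expect_true(all(unlist(out) %in% unlist(markers)))
  # gene with high |log2FC| removed even at high FDR
  pdx2 <- pdx; pdx2$effect[2] <- 1.5
  out2 <- intrinsic_gene_filter(markers, pdx2, lines,
                                range_quantiles = c(0, 1), top_fraction = 1,
                                min_high_lines = 0)
  expect_false("g02" %in% out2$C1)
})

test_that("cell-line expression gates remove extreme, low-rank and narrow genes", {
  genes <- sprintf("g%02d", 1:50)
  set.seed(32)
  lines <- matrix(rnorm(50 * 30, mean = 3), 50, 30,
                  dimnames = list(genes, sprintf("L%02d", 1:30)))
  lines["g01", ] <- 50          # max above the 90th percentile of maxima
  lines["g02", ] <- -50         # max below the 10th percentile
  pdx <- tibble::tibble(feature = genes, effect = 0, fdr = 1)
  out <- intrinsic_gene_filter(list(A = genes), pdx, lines)
  expect_false("g01" %in% out$A)
  expect_false("g02" %in% out$A)
  # survivors sit in the top 25% by gene maximum
  gene_max <- apply(lines, 1, max)
  expect_true(all(gene_max[out$A] >= quantile(gene_max, 0.75)))
  # a broadly expressed gene whose maximum sits in the upper mid-range passes
  lines2 <- lines
  lines2["g03", ] <- quantile(gene_max, 0.8)  # high in every line, max in range
  out2 <- intrinsic_gene_filter(list(A = genes), pdx, lines2)
  expect_true("g03" %in% out2$A)
  # empty class dropped with a warning
  expect_warning(
    res <- intrinsic_gene_filter(list(A = "g01", B = out$A), pdx, lines),
    "dropped")
  expect_named(res, "B")
})

test_that("nearest-template calls recover planted archetypes and ignore extra genes", {
  sim <- make_line_panel(effect = 2)
  ts <- template_set(sim$markers)
  calls <- ntp_classify(sim$expr, ts, n_perm = 200, seed = 4)
  expect_gte(mean(calls$label == sim$labels), 0.9)
  expect_true(all(calls$fdr[order(calls$p)] == cummax(calls$fdr[order(calls$p)])))
  # adding non-marker genes leaves labels unchanged
  set.seed(5)
  extra <- matrix(rnorm(100 * ncol(sim$expr)), 100, ncol(sim$expr),
                  dimnames = list(sprintf("x%03d", 1:100), colnames(sim$expr)))
  calls2 <- suppressWarnings(ntp_classify(rbind(sim$expr, extra), ts,
                                          n_perm = 100, seed = 4))
  expect_equal(calls2$label, calls$label)
  # at zero effect accuracy collapses to chance levels
  sim0 <- make_line_panel(effect = 0, seed = 6)
  calls0 <- ntp_classify(sim0$expr, template_set(sim0$markers),
                         n_perm = 100, seed = 7)
  expect_lt(mean(calls0$label == sim0$labels), 0.6)
})

test_that("template and marker contracts are enforced", {
  expect_error(template_set(list(A = c("g1", "g2"), B = c("g2", "g3"))), "disjoint")
  expect_error(template_set(list(A = character(0), B = "g1")), ">= 1 marker")
  sim <- make_line_panel()
  ts <- template_set(list(A = sim$markers$C1, B = c("absent1", "absent2",
                                                    "absent3", "absent4", "absent5")))
  expect_error(suppressWarnings(ntp_classify(sim$expr, ts, n_perm = 100, seed = 1)),
               "min_markers")
  # a sample built exactly on class-k markers lands on class k
  genes <- rownames(sim$expr)
  e <- matrix(0, length(genes), 2, dimnames = list(genes, c("a", "b")))
  e[sim$markers$C2, 1] <- 3
  e[, 2] <- rnorm(length(genes))
  calls <- suppressWarnings(ntp_classify(e, template_set(sim$markers),
                                         n_perm = 100, seed = 2))
  expect_equal(calls$label[1], "C2")
})
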