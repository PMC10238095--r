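#' Common feature set across omics layers
#'
#' Features passing the per-layer significance cut in at least one pairwise
#' subtype comparison, intersected across the methylation, expression and
#' protein layers. The conventional cuts are FDR < 0.05 for methylation and
#' expression and a plain p-value cut for the protein layer.
#'
#' @param dmg,deg,dep Tibbles from [pairwise_differential()] for the
#'   methylation, expression and protein layers (shared gene-symbol
#'   namespace).
#' @param dmg_cut,deg_cut FDR cuts (default 0.05).
#' @param dep_cut P-value cut for proteins (default 0.5; set 0.05 for the
#'   stricter reading).
#' @return Character vector (possibly empty; an empty intersection is
#'   reported with a message, not an error).
#' @export
common_feature_set <- function(dmg, deg, dep, dmg_cut = 0.05, deg_cut = 0.05,
                               dep_cut = 0.5) {
  pass <- function(tab, col, cut) unique(tab$feature[tab[[col]] < cut])
  out <- Reduce(intersect, list(pass(dmg, "fdr", dmg_cut),
                                pass(deg, "fdr", deg_cut),
                                pass(dep, "p", dep_cut)))
  if (length(out) == 0L) message("common feature set across layers is empty")
  sort(out)
}

# All 6 unordered pairs of 4 subtypes in canonical label order.
subtype_pairs <- function(classes) {
  pairs <- combn(sort(classes), 2)
  paste0(pairs[1, ], "-vs-", pairs[2, ])
}

#' Pairwise sign matrix from a pairwise differential table
#'
#' @param pw Tibble from [pairwise_differential()].
#' @param features Features to keep (default all).
#' @param cut Optional significance cut; when given, a feature keeps `NA`
#'   signs for non-significant pairs.
#' @param cut_col Column the cut applies to (`"fdr"` or `"p"`).
#' @return Features x pairs matrix of signs (+1 / -1, 0 for zero effect,
#'   NA when below the cut).
#' @export
pairwise_signs <- function(pw, features = NULL, cut = NULL, cut_col = "fdr") {
  wide <- tidyr::pivot_wider(pw[, c("feature", "comparison", "effect", cut_col)],
                             names_from = "comparison",
                             values_from = dplyr::all_of(c("effect", cut_col)))
  if (!is.null(features)) wide <- wide[match(features, wide$feature), ]
  comparisons <- unique(pw$comparison)
  signs <- sapply(comparisons, function(cp) {
    e <- sign(wide[[paste0("effect_", cp)]])
    if (!is.null(cut)) e[wide[[paste0(cut_col, "_", cp)]] >= cut] <- NA
    e
  })
  signs <- matrix(signs, ncol = length(comparisons),
                  dimnames = list(wide$feature, comparisons))
  signs
}

#' Consistency of pairwise signs with a subtype ordering
#'
#' Given the 6 pairwise signs of a feature (sign of `mean(b) - mean(a)` for
#' the canonical pair `a-vs-b`), decides whether the feature increases
#' monotonically along `ordering`, decreases monotonically (the full
#' reversal), or is inconsistent. All 6 signs must be present and nonzero.
#'
#' @param signs Named numeric vector of +1/-1 over the 6 canonical pairs
#'   (`"Ca-vs-Cb"`, a < b lexicographically).
#' @param ordering Character permutation of the subtype labels.
#' @return `"monotone_increasing"`, `"monotone_decreasing"` or
#'   `"inconsistent"`.
#' @export
ordering_consistency <- function(signs, ordering) {
  expected <- expected_pair_signs(ordering)
  if (!all(names(expected) %in% names(signs))) {
    stop("missing pairwise sign(s): ",
         paste(setdiff(names(expected), names(signs)), collapse = ", "),
         call. = FALSE)
  }
  s <- signs[names(expected)]
  if (anyNA(s) || any(s == 0)) return("inconsistent")
  if (all(s == expected)) return("monotone_increasing")
  if (all(s == -expected)) return("monotone_decreasing")
  "inconsistent"
}

# Expected sign of mean(b) - mean(a) for each canonical pair when values
# increase along `ordering`.
expected_pair_signs <- function(ordering) {
  pairs <- combn(sort(ordering), 2)
  pos <- setNames(seq_along(ordering), ordering)
  sgn <- ifelse(pos[pairs[2, ]] > pos[pairs[1, ]], 1, -1)
  setNames(sgn, paste0(pairs[1, ], "-vs-", pairs[2, ]))
}

#' Match each feature's sign pattern to a subtype ordering
#'
#' Scans all orderings of the subtype labels and reports, per feature, the
#' canonical (increasing-direction) ordering its 6 pairwise signs are
#' monotone for, or `"inconsistent"`. A fully signed feature matches at
#' most one increasing ordering (an acyclic sign tournament has a unique
#' topological order).
#'
#' @param signs Features x pairs sign matrix from [pairwise_signs()].
#' @param classes Subtype labels (default derived from the pair names).
#' @return Tibble with `feature`, `matched_ordering` (comma-separated
#'   labels or `"inconsistent"`) and `direction`.
#' @export
match_orderings <- function(signs, classes = NULL) {
  if (is.null(classes)) {
    classes <- sort(unique(unlist(strsplit(colnames(signs), "-vs-", fixed = TRUE))))
  }
  perms <- permutations_of(classes)
  # keep one representative per {ordering, reversal} pair; report increasing
  expected <- lapply(perms, expected_pair_signs)
  res <- apply(signs, 1, function(s) {
    if (anyNA(s) || any(s == 0)) return(c("inconsistent", "none"))
    for (i in seq_along(perms)) {
      e <- expected[[i]][colnames(signs)]
      if (all(s == e)) {
        return(c(paste(perms[[i]], collapse = ","), "increasing"))
      }
    }
    c("inconsistent", "none")
  })
  tibble::tibble(feature = rownames(signs), matched_ordering = res[1, ],
                 direction = res[2, ])
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Exclusive intersection counts (UpSet-style)
#'
#' Tabulates every exclusive membership combination of the input sets; the
#' exclusive counts partition the union.
#'
#' @param sets Named list of character vectors.
#' @return Tibble with one indicator column per set, `combination`
#'   (ampersand-joined member names) and `count`, sorted by decreasing
#'   count.
#' @export
upset_counts <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- unique(unlist(sets))
  if (length(universe) == 0L) {
    return(tibble::tibble(combination = character(), count = integer()))
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = length(sets), dimnames = list(universe, names(sets)))
  key <- apply(member, 1, function(m) paste(names(sets)[m], collapse = " & "))
  tab <- table(key)
  out <- tibble::as_tibble(member) |>
    dplyr::mutate(combination = key) |>
    dplyr::distinct(dplyr::across(dplyr::everything())) |>
    dplyr::mutate(count = as.integer(tab[.data$combination])) |>
    dplyr::arrange(dplyr::desc(.data$count))
  out
}

#' Derive the cross-cohort monotone gene list
#'
#' Intersection of the genes called monotone increasing along the subtype
#' ordering in two cohorts, sorted lexicographically. With the ordering
#' C1, C4, C2, C3 this is the derivation of the 20-gene evolution list.
#'
#' @param monotone_up_cohort_a,monotone_up_cohort_b Character vectors of
#'   monotone-increasing genes per cohort.
#' @return Sorted character vector.
#' @export
derive_cccrc_genes <- function(monotone_up_cohort_a, monotone_up_cohort_b) {
  sort(intersect(monotone_up_cohort_a, monotone_up_cohort_b))
}

#' Per-sample evolution (CCCRC) score
#'
#' GSVA score of the derived monotone gene list, quantifying each sample's
#' position along the nongenetic evolution axis.
#'
#' @param expr Genes x samples expression matrix.
#' @param cccrc_genes Gene set (>= 2 genes must be present in the matrix).
#' @param ... Passed to [gsva_scores()].
#' @return Named numeric vector, one score per sample.
#' @export
cccrc_score <- function(expr, cccrc_genes, ...) {
  present <- intersect(cccrc_genes, rownames(expr))
  if (length(present) < 2L) {
    stop("fewer than 2 evolution genes present in the expression matrix", call. = FALSE)
  }
  s <- gsva_scores(expr, signature_panel(list(cccrc = present)), ...)
  setNames(s["cccrc", ], colnames(s))
}

#' Monotone features along a subtype ordering in one layer
#'
#' Runs all pairwise comparisons, applies the layer's significance cut to
#' every pair (strict mode) or no cut (sign-only mode), and returns the
#' features whose 6 signs are monotone increasing (and separately
#' decreasing) along `ordering`.
#'
#' @param mat Features x samples matrix for one layer.
#' @param labels Subtype label per sample.
#' @param ordering Subtype ordering to test (e.g. `c("C1","C4","C2","C3")`).
#' @param cut Significance cut applied to each pair (default 0.05); `NULL`
#'   for sign-only mode.
#' @param cut_col `"fdr"` or `"p"`.
#' @param test Passed to [pairwise_differential()].
#' @return List with `increasing`, `decreasing` (character vectors) and
#'   the `pairwise` tibble.
#' @export
monotone_features <- function(mat, labels, ordering, cut = 0.05,
                              cut_col = "fdr", test = "rank_sum") {
  pw <- pairwise_differential(mat, labels, test = test)
  signs <- pairwise_signs(pw, cut = cut, cut_col = cut_col)
  expected <- expected_pair_signs(ordering)[colnames(signs)]
  complete <- !apply(signs, 1, function(s) anyNA(s) || any(s == 0))
  inc <- complete & apply(signs, 1, function(s) all(s == expected))
  dec <- complete & apply(signs, 1, function(s) all(s == -expected))
  list(increasing = rownames(signs)[inc], decreasing = rownames(signs)[dec],
       pairwise = pw)
}
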