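#' Construct a signature panel
#'
#' A signature panel is a named collection of gene sets, each tagged with a
#' coarse biological category. The tumor-microenvironment panel used for
#' subtyping (tumor, immune, stroma and metabolic reprogramming signatures)
#' is one instance; any GMT file yields another.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param categories Character vector (recycled if length 1) of category
#'   labels, one per set; one of `"tumor"`, `"immune"`, `"stroma"`,
#'   `"metabolism"`, `"other"`.
#' @return A `signature_panel` object.
#' @examples
#' panel <- signature_panel(list(ifn = c("STAT1", "IRF1"), emt = c("VIM", "FN1")),
#'                          categories = c("immune", "stroma"))
#' panel
#' @export
signature_panel <- function(sets, categories = "other") {
  if (!is.list(sets) || length(sets) == 0L || is.null(names(sets)) ||
      any(names(sets) == "")) {
    stop("`sets` must be a non-empty named list of gene id vectors", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("signature names must be unique", call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    bad <- names(sets)[lengths(sets) == 0L][1]
    stop(sprintf("gene set '%s' is empty", bad), call. = FALSE)
  }
  categories <- rep_len(as.character(categories), length(sets))
  allowed <- c("tumor", "immune", "stroma", "metabolism", "other")
  if (!all(categories %in% allowed)) {
    stop("categories must be one of: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets, categories = setNames(categories, names(sets))),
            class = "signature_panel")
}

#' @export
print.signature_panel <- function(x, ...) {
  cat(sprintf("<signature_panel> %d signatures, %d unique genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  tab <- table(x$categories)
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.signature_panel <- function(x) length(x$sets)

#' Restrict a panel to the gene universe of an expression matrix
#'
#' Intersects every gene set with the matrix's gene ids and drops (or errors
#' on) sets falling below `min_size`.
#'
#' @param panel A [signature_panel()].
#' @param universe Character vector of gene ids (e.g. `rownames(expr)`).
#' @param min_size Minimum retained set size (default 2).
#' @param on_small `"error"` (default) or `"drop"` for sets below `min_size`.
#' @return A `signature_panel` restricted to `universe`.
#' @export
restrict_panel <- function(panel, universe, min_size = 2L, on_small = c("error", "drop")) {
  check_panel(panel)
  on_small <- match.arg(on_small)
  sets <- lapply(panel$sets, intersect, y = universe)
  small <- lengths(sets) < min_size
  if (any(small)) {
    if (on_small == "error") {
      stop(sprintf("gene set(s) below min_size %d after intersection with the gene universe: %s",
                   min_size, paste(names(sets)[small], collapse = ", ")), call. = FALSE)
    }
    sets <- sets[!small]
    if (length(sets) == 0L) stop("no gene set survives the universe intersection", call. = FALSE)
  }
  signature_panel(sets, panel$categories[names(sets)])
}

#' Collapse duplicated gene ids by their median profile
#'
#' When a gene symbol maps to multiple probes or rows, the median value per
#' sample is used as its relative expression profile.
#'
#' @param values Numeric matrix, rows = (possibly duplicated) gene ids.
#' @return Matrix with unique rownames.
#' @export
collapse_duplicate_genes <- function(values) {
  if (is.null(rownames(values))) stop("`values` must have gene rownames", call. = FALSE)
  if (!anyDuplicated(rownames(values))) return(values)
  ids <- rownames(values)
  out <- t(vapply(split(seq_along(ids), ids), function(idx) {
    if (length(idx) == 1L) values[idx, ] else matrixStats::colMedians(values[idx, , drop = FALSE])
  }, numeric(ncol(values))))
  colnames(out) <- colnames(values)
  out[unique(ids), , drop = FALSE]
}
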