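#' Read a gene-set panel from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. The description field carries the category tag when it is
#' one of the recognised categories; otherwise the set is tagged `"other"`.
#'
#' @param path Path to a GMT file.
#' @return A [signature_panel()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1]), call. = FALSE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- nm
  allowed <- c("tumor", "immune", "stroma", "metabolism", "other")
  categories <- ifelse(tolower(desc) %in% allowed, tolower(desc), "other")
  signature_panel(sets, categories)
}

#' Write a signature panel to GMT
#'
#' @param panel A [signature_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(panel, path) {
  check_panel(panel)
  lines <- vapply(names(panel$sets), function(nm) {
    paste(c(nm, panel$categories[[nm]], panel$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression (or score) matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene (or
#' signature) ids. Values are log-scale intensities or log2(TPM+1).
#' Duplicated gene ids are collapsed to their per-sample median.
#'
#' @param path Path to a TSV file. Lines starting with `#` are skipped.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE, name_repair = "minimal")
  if (ncol(df) < 2L) stop("expression TSV needs an id column plus >= 1 sample column", call. = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (anyNA(mat)) stop("expression TSV contains missing values", call. = FALSE)
  collapse_duplicate_genes(mat)
}

#' Write a matrix to TSV with an optional method comment header
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param method Optional method tag written as a `# method=` comment line.
#' @param id_col Name of the first (id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, method = NULL, id_col = "id") {
  df <- tibble::as_tibble(mat, rownames = id_col)
  if (!is.null(method)) {
    writeLines(paste0("# method=", method), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a patch-label table from CSV
#'
#' Columns: `x`, `y` (grid coordinates), `label` (eight-class tissue
#' vocabulary), `region` (`CT`, `IM` or `outside`), optional
#' `p_non_muscle`.
#'
#' @param path CSV path.
#' @return A `patch_grid` tibble (see [patch_grid()]).
#' @export
read_patch_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  patch_grid(df)
}

#' Read region polygons from GeoJSON
#'
#' Accepts a FeatureCollection of (multi)polygons in pixel coordinates;
#' each feature's `properties$region` names the region (e.g. `"CT"`).
#' Only the exterior ring of the first polygon per feature is used.
#'
#' @param path GeoJSON path.
#' @return Named list of two-column matrices (x, y vertex coordinates).
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    nm <- if (!is.null(f$properties$region)) f$properties$region else paste0("region", length(out) + 1)
    coords <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = geom$coordinates[[1]][[1]],
      stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE))
    ring <- do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    colnames(ring) <- c("x", "y")
    out[[nm]] <- ring
  }
  out
}
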