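TISSUE_LABELS <- c("ADI", "DEB", "LYM", "MUC", "MUS", "NORM", "STR", "TUM")
REGION_LABELS <- c("CT", "IM", "outside")

#' Patch-label grid constructor
#'
#' Validates a per-patch tissue-label table: unique `(x, y)` grid
#' coordinates, the eight-class tissue vocabulary (ADI, DEB, LYM, MUC, MUS,
#' NORM, STR, TUM), a region for every patch (`CT`, `IM`, `outside`) and an
#' optional non-muscle probability.
#'
#' @param df Data frame with columns `x`, `y`, `label`, `region` and
#'   optionally `p_non_muscle`.
#' @param patch_size_px Patch edge in pixels (default 224).
#' @param microns_per_pixel Physical scale (default 0.5).
#' @return A `patch_grid` tibble with the scale parameters as attributes.
#' @export
patch_grid <- function(df, patch_size_px = 224, microns_per_pixel = 0.5) {
  need <- c("x", "y", "label", "region")
  if (!all(need %in% names(df))) {
    stop("patch table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[, c("x", "y")])) stop("patch coordinates must be unique", call. = FALSE)
  if (!all(df$label %in% TISSUE_LABELS)) {
    stop("labels outside the 8-class vocabulary: ",
         paste(setdiff(unique(df$label), TISSUE_LABELS), collapse = ", "), call. = FALSE)
  }
  if (!all(df$region %in% REGION_LABELS)) {
    stop("regions must be one of: ", paste(REGION_LABELS, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "patch_size_px") <- patch_size_px
  attr(out, "microns_per_pixel") <- microns_per_pixel
  class(out) <- c("patch_grid", class(out))
  out
}

#' Valid patch extraction over a region polygon
#'
#' Tiles the polygon's bounding box with a non-overlapping grid of
#' `patch_size_px` squares anchored at the origin and emits a patch when
#' the polygon covers at least `min_coverage` of its area. Coverage is
#' exact polygon clipping (Sutherland-Hodgman against the patch square,
#' shoelace area).
#'
#' @param region_polygon Two-column matrix of vertex coordinates (pixels),
#'   a simple polygon.
#' @param patch_size_px Patch edge (default 224).
#' @param min_coverage Minimum covered area fraction (default 0.75).
#' @return Tibble of grid coordinates `x`, `y` (patch indices, origin 0)
#'   and `coverage`.
#' @export
extract_valid_patches <- function(region_polygon, patch_size_px = 224,
                                  min_coverage = 0.75) {
  poly <- as.matrix(region_polygon)
  if (nrow(poly) < 3L || abs(shoelace_area(poly)) <= 0) {
    stop("degenerate region polygon (zero area)", call. = FALSE)
  }
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  ix <- seq(floor(xr[1] / patch_size_px), ceiling(xr[2] / patch_size_px) - 1)
  iy <- seq(floor(yr[1] / patch_size_px), ceiling(yr[2] / patch_size_px) - 1)
  grid <- expand.grid(x = ix, y = iy)
  cov <- vapply(seq_len(nrow(grid)), function(i) {
    x0 <- grid$x[i] * patch_size_px; y0 <- grid$y[i] * patch_size_px
    clipped <- clip_polygon_rect(poly, x0, y0, x0 + patch_size_px, y0 + patch_size_px)
    if (is.null(clipped)) 0 else abs(shoelace_area(clipped)) / patch_size_px^2
  }, numeric(1))
  keep <- cov >= min_coverage
  tibble::tibble(x = grid$x[keep], y = grid$y[keep], coverage = cov[keep])
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Sutherland-Hodgman clip of a simple polygon against an axis-aligned
# rectangle; returns NULL when the intersection is empty.
clip_polygon_rect <- function(poly, xmin, ymin, xmax, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    if (is.null(pts) || nrow(pts) == 0L) return(NULL)
    n <- nrow(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    if (nrow(out) == 0L) NULL else out
  }
  lerp <- function(a, b, t) a + t * (b - a)
  pts <- poly
  pts <- clip_edge(pts, function(p) p[1] >= xmin,
                   function(p, q) lerp(p, q, (xmin - p[1]) / (q[1] - p[1])))
  pts <- clip_edge(pts, function(p) p[1] <= xmax,
                   function(p, q) lerp(p, q, (xmax - p[1]) / (q[1] - p[1])))
  pts <- clip_edge(pts, function(p) p[2] >= ymin,
                   function(p, q) lerp(p, q, (ymin - p[2]) / (q[2] - p[2])))
  pts <- clip_edge(pts, function(p) p[2] <= ymax,
                   function(p, q) lerp(p, q, (ymax - p[2]) / (q[2] - p[2])))
  pts
}

#' Muscle gate on the non-muscle probability
#'
#' A patch is non-muscle when its non-muscle probability strictly exceeds
#' 0.99; muscle patches are excluded from seven-class composition.
#'
#' @param non_muscle_probability Numeric vector in `[0, 1]`.
#' @param threshold Gate (default 0.99, strict).
#' @return Character vector of `"non_muscle"` / `"muscle"`.
#' @export
muscle_gate <- function(non_muscle_probability, threshold = 0.99) {
  if (any(non_muscle_probability < 0 | non_muscle_probability > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  ifelse(non_muscle_probability > threshold, "non_muscle", "muscle")
}

#' Tissue composition of one region
#'
#' Patch-count area fractions per tissue label within a region (all
#' patches have equal area, so count ratios equal area ratios). All 8
#' labels are reported, zeros included; fractions sum to 1.
#'
#' @param grid A [patch_grid()].
#' @param region `"CT"` or `"IM"`.
#' @param exclude_muscle If `TRUE`, MUS patches are removed from the
#'   denominator (default `FALSE`: all region patches count).
#' @return Tibble with `region`, `label`, `count`, `fraction`.
#' @export
region_abundances <- function(grid, region, exclude_muscle = FALSE) {
  sub <- grid[grid$region == region, ]
  if (exclude_muscle) sub <- sub[sub$label != "MUS", ]
  if (nrow(sub) == 0L) stop("region '", region, "' has no patches", call. = FALSE)
  counts <- table(factor(sub$label, levels = TISSUE_LABELS))
  tibble::tibble(region = region, label = TISSUE_LABELS,
                 count = as.integer(counts),
                 fraction = as.numeric(counts) / nrow(sub))
}

#' Spatial lymphocyte/tumor/stroma ratios from region compositions
#'
#' Computes the lymphocyte-to-tumor and lymphocyte-to-stroma area-fraction
#' ratios within the core tumor region and the invasive-margin to core
#' lymphocyte ratio. Zero denominators yield `NA` with an `undefined`
#' marker rather than infinity.
#'
#' @param ct,im Tibbles from [region_abundances()] for the CT and IM
#'   regions of the same slide.
#' @return Tibble with `ratio`, `value`, `undefined`.
#' @export
spatial_ratios <- function(ct, im) {
  f <- function(comp, lab) comp$fraction[comp$label == lab]
  safe_div <- function(num, den) {
    if (den == 0) list(value = NA_real_, undefined = TRUE)
    else list(value = num / den, undefined = FALSE)
  }
  r1 <- safe_div(f(ct, "LYM"), f(ct, "TUM"))
  r2 <- safe_div(f(ct, "LYM"), f(ct, "STR"))
  r3 <- safe_div(f(im, "LYM"), f(ct, "LYM"))
  tibble::tibble(ratio = c("ct_lym_tum", "ct_lym_str", "im_ct_lym"),
                 value = c(r1$value, r2$value, r3$value),
                 undefined = c(r1$undefined, r2$undefined, r3$undefined))
}
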