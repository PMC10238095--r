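#' Generate a synthetic signature panel
#'
#' Gene sets drawn without replacement from a synthetic gene universe,
#' except for a controlled overlap fraction: each set after the first
#' re-uses `round(overlap_fraction * genes_per_signature)` genes already
#' placed in earlier sets. Categories are assigned round-robin over tumor,
#' immune, stroma and metabolism.
#'
#' @param n_signatures,genes_per_signature,n_genes Panel dimensions.
#' @param overlap_fraction Fraction of each set shared with earlier sets
#'   (default 0).
#' @param seed Seed.
#' @return A [signature_panel()] with the full gene universe stored in
#'   `attr(, "universe")`.
#' @export
gen_panel <- function(n_signatures, genes_per_signature, n_genes,
                      overlap_fraction = 0, seed = 1L) {
  n_shared <- round(overlap_fraction * genes_per_signature)
  n_fresh <- genes_per_signature - n_shared
  needed <- genes_per_signature + (n_signatures - 1) * n_fresh
  if (needed > n_genes) {
    stop(sprintf("infeasible: %d signatures of %d genes at overlap %.2f need %d genes, universe has %d",
                 n_signatures, genes_per_signature, overlap_fraction, needed, n_genes),
         call. = FALSE)
  }
  universe <- sprintf("g%05d", seq_len(n_genes))
  sets <- with_seed(seed, {
    unused <- universe
    used <- character(0)
    out <- list()
    for (s in seq_len(n_signatures)) {
      take_shared <- if (s == 1) character(0) else sample(used, n_shared)
      take_fresh <- sample(unused, if (s == 1) genes_per_signature else n_fresh)
      unused <- setdiff(unused, take_fresh)
      used <- union(used, take_fresh)
      out[[sprintf("sig%02d", s)]] <- c(take_shared, take_fresh)
    }
    out
  })
  categories <- rep_len(c("tumor", "immune", "stroma", "metabolism"), n_signatures)
  panel <- signature_panel(sets, categories)
  attr(panel, "universe") <- universe
  panel
}

#' Default archetype matrix: each subtype elevates one signature category
#'
#' C1 elevates tumor signatures, C2 metabolism, C3 stroma, C4 immune -
#' mirroring the proliferative / metabolically reprogrammed /
#' stroma-rich immune-excluded / immunomodulatory subtype phenotypes.
#'
#' @param panel A [signature_panel()].
#' @param subtypes Subtype labels (default `C1..C4`).
#' @return Signatures x subtypes 0/1 matrix.
#' @export
default_archetypes <- function(panel, subtypes = c("C1", "C2", "C3", "C4")) {
  map <- c(C1 = "tumor", C2 = "metabolism", C3 = "stroma", C4 = "immune")
  A <- vapply(subtypes, function(k) {
    as.numeric(panel$categories == map[[k]])
  }, numeric(length(panel$sets)))
  rownames(A) <- names(panel$sets)
  A
}

#' Generate a synthetic cohort with planted TME archetypes
#'
#' Background expression is Gaussian noise on the log scale; a sample of
#' subtype `k` receives an additive shift `effect * A[s, k]` on every gene
#' of signature `s`. An optional batch shift (scalar, or one offset per
#' gene) emulates a cohort-level technical effect. The defaults encode the
#' reference study conditions: 200 samples at subtype prevalences
#' 35/21/24/20%, effect 2.5, unit noise.
#'
#' @param n_samples Cohort size (default 200).
#' @param subtype_proportions Named proportions summing to 1.
#' @param panel A [signature_panel()] (ideally from [gen_panel()], which
#'   carries the full gene universe).
#' @param archetype Signatures x subtypes shift matrix (default
#'   [default_archetypes()]).
#' @param effect Additive shift size (default 2.5).
#' @param noise_sd Gaussian noise sd (default 1).
#' @param batch_shift Scalar or per-gene vector added to every sample
#'   (default 0).
#' @param seed Seed.
#' @return List with `expr` (genes x samples) and `truth` (labels,
#'   archetype, effect, noise_sd, batch_shift, seed).
#' @export
gen_cohort <- function(n_samples = 200L,
                       subtype_proportions = c(C1 = 0.35, C2 = 0.21, C3 = 0.24, C4 = 0.20),
                       panel, archetype = NULL, effect = 2.5, noise_sd = 1,
                       batch_shift = 0, seed = 1L) {
  check_panel(panel)
  if (abs(sum(subtype_proportions) - 1) > 1e-8) {
    stop("subtype proportions must sum to 1", call. = FALSE)
  }
  subtypes <- names(subtype_proportions)
  if (is.null(archetype)) archetype <- default_archetypes(panel, subtypes)
  universe <- attr(panel, "universe")
  if (is.null(universe)) universe <- sort(unique(unlist(panel$sets)))
  n_genes <- length(universe)

  counts <- diff(c(0, round(cumsum(subtype_proportions) * n_samples)))
  drawn <- with_seed(seed, {
    list(labels = sample(rep(subtypes, counts)),
         mat = matrix(rnorm(n_genes * n_samples, sd = noise_sd),
                      n_genes, n_samples))
  })
  labels <- drawn$labels
  expr <- drawn$mat
  rownames(expr) <- universe
  colnames(expr) <- sprintf("s%04d", seq_len(n_samples))
  for (s in names(panel$sets)) {
    idx <- match(panel$sets[[s]], universe)
    for (k in subtypes) {
      if (archetype[s, k] != 0) {
        cols <- labels == k
        expr[idx, cols] <- expr[idx, cols] + effect * archetype[s, k]
      }
    }
  }
  expr <- expr + batch_shift      # scalar or per-gene vector (recycled by row)
  list(expr = expr,
       truth = list(labels = setNames(labels, colnames(expr)),
                    archetype = archetype, effect = effect,
                    noise_sd = noise_sd, batch_shift = batch_shift,
                    seed = seed))
}

#' Generate three omics layers with a planted monotone subtype ordering
#'
#' `n_monotone` features increase by `step_effect` per position along
#' `ordering` in all three layers (expression, methylation, protein);
#' methylation values are squashed into `[0, 1]` by the logistic function.
#' The remaining features are exchangeable across subtypes.
#'
#' @param n_features Total features per layer (default 2000).
#' @param n_monotone Planted monotone features (default 50).
#' @param ordering Subtype ordering (default `C1, C4, C2, C3`).
#' @param step_effect Mean increment per ordering step (default 1.5).
#' @param n_per_subtype Samples per subtype (default 50).
#' @param seed Seed.
#' @return List with `expression`, `methylation`, `protein` (features x
#'   samples) and `truth` (labels, monotone feature ids, ordering, seed).
#' @export
gen_multiomics_evolution <- function(n_features = 2000L, n_monotone = 50L,
                                     ordering = c("C1", "C4", "C2", "C3"),
                                     step_effect = 1.5, n_per_subtype = 50L,
                                     seed = 1L) {
  if (n_monotone > n_features) stop("n_monotone must not exceed n_features", call. = FALSE)
  features <- sprintf("f%05d", seq_len(n_features))
  n <- n_per_subtype * length(ordering)
  labels <- rep(ordering, each = n_per_subtype)
  samples <- sprintf("s%04d", seq_len(n))
  pos <- setNames(seq_along(ordering), ordering)   # position along the ordering
  centered <- (pos[labels] - mean(pos)) * step_effect

  with_seed(seed, {
    monotone <- sort(sample(features, n_monotone))
    base_mean <- matrix(0, n_features, n, dimnames = list(features, samples))
    base_mean[monotone, ] <- matrix(rep(centered, each = n_monotone),
                                    n_monotone, n)
    expression <- base_mean + matrix(rnorm(n_features * n), n_features, n)
    protein <- base_mean + matrix(rnorm(n_features * n), n_features, n)
    methylation <- stats::plogis(base_mean + matrix(rnorm(n_features * n), n_features, n))
    dimnames(expression) <- dimnames(protein) <- dimnames(methylation) <-
      list(features, samples)
    list(expression = expression, methylation = methylation, protein = protein,
         truth = list(labels = setNames(labels, samples),
                      monotone_features = monotone, ordering = ordering,
                      step_effect = step_effect, seed = seed))
  })
}

#' Generate a synthetic patch-label grid with CT core and IM band
#'
#' Places a rectangular core-tumor (CT) region, an invasive-margin (IM)
#' band of patches whose centers lie within `im_band_um` microns outside
#' the CT rectangle, and labels every patch by a region-specific
#' categorical draw. By construction every IM patch center respects the
#' stated band offset at the declared physical scale.
#'
#' @param width,height Grid size in patches.
#' @param ct_bounds CT rectangle in patch indices `c(x0, x1, y0, y1)`
#'   (inclusive); default a centered block of roughly half each dimension.
#' @param class_proportions Named list with elements `CT`, `IM`,
#'   `outside`: named label-proportion vectors each summing to 1.
#' @param seed Seed.
#' @param patch_size_px,microns_per_pixel Physical scale (224 px, 0.5
#'   micron/px).
#' @param im_band_um IM band width in microns (default 500).
#' @return A [patch_grid()] tibble including `p_non_muscle` (high for
#'   non-MUS labels, low for MUS).
#' @export
gen_patch_grid <- function(width = 30L, height = 30L, ct_bounds = NULL,
                           class_proportions = default_region_proportions(),
                           seed = 1L, patch_size_px = 224,
                           microns_per_pixel = 0.5, im_band_um = 500) {
  for (rg in names(class_proportions)) {
    if (abs(sum(class_proportions[[rg]]) - 1) > 1e-8) {
      stop("class proportions for region '", rg, "' must sum to 1", call. = FALSE)
    }
  }
  if (is.null(ct_bounds)) {
    ct_bounds <- c(floor(width / 4), ceiling(3 * width / 4) - 1,
                   floor(height / 4), ceiling(3 * height / 4) - 1)
  }
  grid <- expand.grid(x = seq_len(width) - 1L, y = seq_len(height) - 1L)
  cx <- (grid$x + 0.5) * patch_size_px
  cy <- (grid$y + 0.5) * patch_size_px
  rect <- ct_bounds * patch_size_px + c(0, patch_size_px, 0, patch_size_px)
  inside <- grid$x >= ct_bounds[1] & grid$x <= ct_bounds[2] &
    grid$y >= ct_bounds[3] & grid$y <= ct_bounds[4]
  dx <- pmax(rect[1] - cx, cx - rect[2], 0)
  dy <- pmax(rect[3] - cy, cy - rect[4], 0)
  dist_um <- sqrt(dx^2 + dy^2) * microns_per_pixel
  region <- ifelse(inside, "CT", ifelse(dist_um <= im_band_um, "IM", "outside"))

  labels <- character(nrow(grid))
  p_non_muscle <- numeric(nrow(grid))
  with_seed(seed, {
    for (rg in unique(region)) {
      idx <- region == rg
      props <- class_proportions[[rg]]
      if (is.null(props)) stop("no class proportions for region '", rg, "'", call. = FALSE)
      labels[idx] <- sample(names(props), sum(idx), replace = TRUE, prob = props)
    }
    mus <- labels == "MUS"
    p_non_muscle[mus] <- runif(sum(mus), 0, 0.99)
    p_non_muscle[!mus] <- runif(sum(!mus), 0.9905, 1)
  })
  patch_grid(tibble::tibble(x = grid$x, y = grid$y, label = labels,
                            region = region, p_non_muscle = p_non_muscle),
             patch_size_px = patch_size_px,
             microns_per_pixel = microns_per_pixel)
}

#' @rdname gen_patch_grid
#' @export
default_region_proportions <- function() {
  list(CT = c(TUM = 0.55, STR = 0.25, LYM = 0.12, DEB = 0.05, MUC = 0.03),
       IM = c(STR = 0.40, LYM = 0.25, TUM = 0.15, NORM = 0.10, MUS = 0.10),
       outside = c(NORM = 0.5, ADI = 0.3, MUS = 0.2))
}
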