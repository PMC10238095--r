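#' Fit a nearest-shrunken-centroid (PAMR-style) subtype classifier
#'
#' Standardised class-centroid differences
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` are soft-thresholded at a
#' shrinkage threshold chosen by stratified cross-validation:
#' `d'_ik = sign(d_ik) (|d_ik| - delta)_+`, with `s_i` the pooled
#' within-class standard deviation, `s0 = median(s_i)` and
#' `m_k = sqrt(1/n_k - 1/n)`. The threshold grid spans
#' `[0, max |d_ik|]` uniformly; the selected threshold is the smallest one
#' achieving the minimum cross-validation error (favouring more surviving
#' features).
#'
#' @param scores Features x samples matrix, typically row z-scored.
#' @param labels Class label per sample (length `ncol(scores)`).
#' @param n_thresholds Grid size (default 30).
#' @param n_folds Cross-validation folds (default 10); reduced with a
#'   warning when the smallest class has fewer members.
#' @param seed Seed for the stratified fold assignment (default 11).
#' @param priors `"empirical"` class proportions (default) or `"uniform"`.
#' @return An `nsc_model` object.
#' @export
fit_nsc <- function(scores, labels, n_thresholds = 30L, n_folds = 10L,
                    seed = 11L, priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  if (!is.matrix(scores)) stop("`scores` must be a features x samples matrix", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != ncol(scores)) stop("`labels` must match the number of samples", call. = FALSE)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("class(es) with < 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  stats <- nsc_statistics(scores, labels, priors)
  grid <- seq(0, max(abs(stats$d)), length.out = n_thresholds)

  min_class <- min(sizes)
  if (min_class < n_folds) {
    warning(sprintf("smallest class has %d members; folds reduced from %d to %d",
                    min_class, n_folds, min_class), call. = FALSE)
    n_folds <- min_class
  }
  folds <- stratified_folds(labels, n_folds, seed)
  errors <- numeric(length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit_f <- nsc_statistics(scores[, tr, drop = FALSE], labels[tr], priors)
    for (g in seq_along(grid)) {
      pred <- nsc_discriminant(fit_f, scores[, !tr, drop = FALSE], grid[g])$label
      errors[g] <- errors[g] + sum(pred != labels[!tr])
    }
  }
  errors <- errors / length(labels)
  delta <- grid[which.min(errors)]   # smallest threshold at the minimum

  structure(c(stats,
              list(grid = grid, cv_error = errors, delta = delta,
                   n_folds = n_folds, seed = seed, prior_mode = priors)),
            class = "nsc_model")
}

# Centroids, pooled dispersions and standardised differences.
nsc_statistics <- function(scores, labels, priors = "empirical") {
  classes <- sort(unique(labels))
  n <- length(labels)
  n_k <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  centroid <- vapply(classes, function(cl) {
    rowMeans(scores[, labels == cl, drop = FALSE])
  }, numeric(nrow(scores)))
  centroid <- matrix(centroid, nrow = nrow(scores),
                     dimnames = list(rownames(scores), classes))
  overall <- rowMeans(scores)
  ss <- rowSums(vapply(classes, function(cl) {
    rowSums((scores[, labels == cl, drop = FALSE] - centroid[, cl])^2)
  }, numeric(nrow(scores))))
  s_i <- sqrt(ss / (n - length(classes)))
  s0 <- median(s_i)
  m_k <- sqrt(1 / n_k - 1 / n)
  d <- sweep(centroid - overall, 1, s_i + s0, "/")
  d <- sweep(d, 2, m_k, "/")
  pi_k <- if (identical(priors, "uniform")) {
    rep(1 / length(classes), length(classes))
  } else n_k / n
  names(pi_k) <- classes
  list(feature_names = rownames(scores), classes = classes, n = n, n_k = n_k,
       centroid = centroid, overall = overall, s_i = s_i, s0 = s0,
       m_k = m_k, d = d, priors = pi_k)
}

# Soft-threshold, shrunken centroids and discriminant scores for new data.
nsc_discriminant <- function(model, scores, delta) {
  d_shr <- sign(model$d) * pmax(abs(model$d) - delta, 0)
  surviving <- matrixStats::rowMaxs(abs(d_shr)) > 0
  shrunk <- model$overall +
    sweep(sweep(d_shr, 1, model$s_i + model$s0, "*"), 2, model$m_k, "*")
  n_cls <- length(model$classes)
  delta_scores <- matrix(0, ncol(scores), n_cls,
                         dimnames = list(colnames(scores), model$classes))
  if (any(surviving)) {
    x <- scores[model$feature_names[surviving], , drop = FALSE]
    denom <- (model$s_i + model$s0)[surviving]
    for (k in seq_len(n_cls)) {
      delta_scores[, k] <- colSums(((x - shrunk[surviving, k]) / denom)^2)
    }
  }
  delta_scores <- sweep(delta_scores, 2, 2 * log(model$priors), "-")
  lab <- model$classes[apply(delta_scores, 1, which.min)]
  post <- exp(-(delta_scores - matrixStats::rowMins(delta_scores)) / 2)
  post <- post / rowSums(post)
  list(label = lab, delta_scores = delta_scores, posterior = post,
       surviving = model$feature_names[surviving], shrunken_centroids = shrunk)
}

#' Predict subtypes with a fitted nearest-shrunken-centroid model
#'
#' Discriminant
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k` over
#' surviving features; the label is the arg-min class and posteriors are
#' proportional to `exp(-delta_k / 2)`.
#'
#' @param model An `nsc_model` from [fit_nsc()].
#' @param scores Features x samples matrix covering the model's features
#'   (standardised the same way as the training scores).
#' @param delta Shrinkage threshold (default: the model's CV-selected one).
#' @return Tibble with `sample_id`, `label`, one `delta_<class>`
#'   discriminant column and one `post_<class>` posterior column per class.
#' @export
nsc_predict <- function(model, scores, delta = model$delta) {
  stopifnot(inherits(model, "nsc_model"))
  missing <- setdiff(model$feature_names, rownames(scores))
  if (length(missing) > 0) {
    stop("prediction scores are missing model feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scores <- scores[model$feature_names, , drop = FALSE]
  disc <- nsc_discriminant(model, scores, delta)
  out <- tibble::tibble(sample_id = colnames(scores), label = disc$label)
  for (k in seq_along(model$classes)) {
    out[[paste0("delta_", model$classes[k])]] <- disc$delta_scores[, k]
    out[[paste0("post_", model$classes[k])]] <- disc$posterior[, k]
  }
  out
}

#' Features surviving shrinkage at a threshold
#'
#' The features that exhibit at least one non-zero shrunken difference
#' between a subtype and the overall centroid at the given threshold. The
#' count is nonincreasing in `delta`.
#'
#' @param model An `nsc_model`.
#' @param delta Shrinkage threshold (default: the model's selected one).
#' @return Character vector of feature names.
#' @export
nsc_surviving_features <- function(model, delta = model$delta) {
  stopifnot(inherits(model, "nsc_model"), delta >= 0)
  d_shr <- sign(model$d) * pmax(abs(model$d) - delta, 0)
  model$feature_names[matrixStats::rowMaxs(abs(d_shr)) > 0]
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("<nsc_model> %d features, %d classes (%s), n = %d\n",
              length(x$feature_names), length(x$classes),
              paste(x$classes, collapse = ", "), x$n))
  cat(sprintf("  selected threshold %.4f (CV error %.3f, %d-fold, seed %d); %d surviving features\n",
              x$delta, min(x$cv_error), x$n_folds, x$seed,
              length(nsc_surviving_features(x))))
  invisible(x)
}

#' Tidiers for fitted cccrc objects
#'
#' `tidy()` returns per-element tables (assignments, standardised
#' differences, CV curves); `glance()` one-row (or one-row-per-k) model
#' summaries.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidy-cccrc
NULL

#' @rdname tidy-cccrc
#' @export
tidy.nsc_model <- function(x, ...) {
  tibble::as_tibble(x$d, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "class", values_to = "d") |>
    dplyr::mutate(d_shrunken = sign(.data$d) * pmax(abs(.data$d) - x$delta, 0))
}

#' @rdname tidy-cccrc
#' @export
glance.nsc_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$feature_names),
                 n_classes = length(x$classes), delta = x$delta,
                 cv_error = min(x$cv_error),
                 n_surviving = length(nsc_surviving_features(x)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
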