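# Recursive feature elimination: importance-ranked nested subsets
# evaluated by cross-validated accuracy.

#' Importance ranking of all features
#'
#' Fits the base model on each training fold, averages the per-fold
#' importance scores, and returns the features in descending importance.
#' Ties break deterministically by canonical column order.
#'
#' @inheritParams cross_validate
#' @return Character vector of feature names, most important first, with
#'   attribute `importance` (the averaged scores in ranked order).
#' @export
importance_ranking <- function(table, model = "xgboost", n_folds = 10,
                               seed = 1, unit = c("window", "subject"),
                               folds = NULL, params = list()) {
  unit <- match.arg(unit)
  ad <- get_learner(model)
  if (is.null(ad$importance))
    stop("model '", model, "' provides no importance scores")
  fc <- feature_cols(table)
  if (is.null(folds)) folds <- make_folds(table, n_folds, seed, unit)
  x <- as.matrix(table[, fc, drop = FALSE])
  y <- factor(table$group, levels = c("HC", "SCZ"))
  acc <- structure(numeric(length(fc)), names = fc)
  ids <- sort(unique(folds))
  for (i in seq_along(ids)) {
    tr <- folds != ids[i]
    fit <- ad$fit(x[tr, , drop = FALSE], y[tr], params, seed + i)
    acc <- acc + ad$importance(fit, fc)
  }
  acc <- acc / length(ids)
  ord <- order(-acc, seq_along(acc))
  structure(fc[ord], importance = unname(acc[ord]))
}

# strict elimination reading: refit on the whole table after removing the
# least important feature, one per step; ranking = reverse elimination order
rescoring_ranking <- function(table, model = "xgboost", seed = 1,
                              params = list()) {
  ad <- get_learner(model)
  if (is.null(ad$importance))
    stop("model '", model, "' provides no importance scores")
  remaining <- feature_cols(table)
  y <- factor(table$group, levels = c("HC", "SCZ"))
  eliminated <- character(0)
  step <- 0L
  while (length(remaining) > 1L) {
    step <- step + 1L
    x <- as.matrix(table[, remaining, drop = FALSE])
    fit <- ad$fit(x, y, params, seed + step)
    imp <- ad$importance(fit, remaining)
    worst <- remaining[order(imp, -seq_along(remaining))][1L]
    eliminated <- c(eliminated, worst)
    remaining <- setdiff(remaining, worst)
  }
  rev(c(eliminated, remaining))
}

#' Accuracy-versus-subset-size curve over nested feature prefixes
#'
#' For each subset size `k`, cross-validates the model on the top-`k`
#' ranked features (always a prefix of the ranking, so subsets are
#' nested) under identical folds and seeds, and locates the optimal size
#' at the accuracy argmax, ties broken toward the smaller subset.
#'
#' @param table an `eeg_features` table.
#' @param ranking feature names in descending importance, covering all
#'   feature columns (see [importance_ranking()]).
#' @param stride evaluate every `stride`-th subset size (the full size is
#'   always included); default 1.
#' @inheritParams cross_validate
#' @return Object of class `eeg_rfe`: list with `curve` (data.frame:
#'   size, accuracy, accuracy_sd), `ranking`, `optimal_size`,
#'   `optimal_subset`, `model`, `seed`, `stride`.
#' @export
rfe_curve <- function(table, ranking, model = "xgboost", n_folds = 10,
                      seed = 1, unit = c("window", "subject"),
                      folds = NULL, params = list(), stride = 1) {
  unit <- match.arg(unit)
  fc <- feature_cols(table)
  if (!setequal(ranking, fc))
    stop("ranking must cover exactly the feature columns of the table")
  K <- length(ranking)
  if (is.null(folds)) folds <- make_folds(table, n_folds, seed, unit)
  sizes <- unique(c(seq(1L, K, by = stride), K))
  acc <- acc_sd <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    cv <- cross_validate(table, model = model, seed = seed, folds = folds,
                         params = params,
                         features = ranking[seq_len(sizes[i])])
    acc[i] <- cv$mean[["accuracy"]]
    acc_sd[i] <- cv$sd[["accuracy"]]
  }
  best <- sizes[which.max(acc)]  # which.max takes the first (smallest) tie
  structure(list(
    curve = data.frame(size = sizes, accuracy = acc, accuracy_sd = acc_sd),
    ranking = ranking,
    optimal_size = best,
    optimal_subset = ranking[seq_len(best)],
    model = model, seed = seed, stride = stride,
    folds = folds
  ), class = "eeg_rfe")
}

#' Recursive feature elimination
#'
#' Convenience wrapper: ranks features by model importance, then
#' evaluates nested prefixes with [rfe_curve()]. The default ranks once
#' from the cross-validated full model; `rescoring = TRUE` instead
#' re-fits and re-ranks after each single-feature elimination (much
#' slower, classical RFE).
#'
#' @inheritParams rfe_curve
#' @param rescoring use iterative re-scored elimination for the ranking.
#' @return An `eeg_rfe` object.
#' @export
rfe <- function(table, model = "xgboost", n_folds = 10, seed = 1,
                unit = c("window", "subject"), params = list(),
                stride = 1, rescoring = FALSE) {
  unit <- match.arg(unit)
  folds <- make_folds(table, n_folds, seed, unit)
  ranking <- if (rescoring)
    rescoring_ranking(table, model, seed, params)
  else
    importance_ranking(table, model, seed = seed, folds = folds,
                       params = params)
  rfe_curve(table, ranking, model = model, seed = seed, folds = folds,
            params = params, stride = stride)
}

#' @export
print.eeg_rfe <- function(x, ...) {
  cat(sprintf("<eeg_rfe> %s base, %d features ranked, stride %d\n",
              x$model, length(x$ranking), x$stride))
  cat(sprintf("  optimal subset: %d features, accuracy %.2f %%\n",
              x$optimal_size, max(x$curve$accuracy)))
  invisible(x)
}

#' @export
plot.eeg_rfe <- function(x, ...) {
  plot(x$curve$size, x$curve$accuracy, type = "l",
       xlab = "number of features", ylab = "CV accuracy (%)",
       main = "Accuracy vs feature-subset size", ...)
  abline(v = x$optimal_size, lty = 2, col = "grey40")
  points(x$optimal_size, max(x$curve$accuracy), pch = 19, col = "red3")
  invisible(x)
}

#' Family-by-band distribution of a feature subset
#'
#' Cross-tabulates a feature subset (by default the optimal RFE subset)
#' over feature family (RP, FuzEn, PLI) and frequency band, with row and
#' column totals.
#'
#' @param x an `eeg_rfe` object or a character vector of feature names.
#' @param channels,bands configuration used to parse the names.
#' @return Integer matrix, rows RP/FuzEn/PLI/Total, columns Delta through
#'   Gamma plus Total.
#' @export
subset_distribution <- function(x, channels = default_channels(),
                                bands = eeg_bands()) {
  nms <- if (inherits(x, "eeg_rfe")) x$optimal_subset else as.character(x)
  keys <- feature_keys(channels, bands)
  miss <- setdiff(nms, keys$name)
  if (length(miss))
    stop("unknown feature name(s): ", paste(head(miss, 5), collapse = ", "))
  fams <- c("RP", "FuzEn", "PLI")
  bn <- bands$band
  tab <- matrix(0L, nrow = length(fams) + 1L, ncol = length(bn) + 1L,
                dimnames = list(c(fams, "Total"), c(bn, "Total")))
  sub <- keys[keys$name %in% nms, ]
  for (f in fams)
    for (b in bn)
      tab[f, b] <- sum(sub$family == f & sub$band == b)
  tab[, "Total"] <- rowSums(tab[, bn, drop = FALSE])
  tab["Total", ] <- colSums(tab[fams, , drop = FALSE])
  tab
}
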