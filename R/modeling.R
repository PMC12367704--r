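# Ensemble classification under stratified k-fold cross-validation.
#
# Learners sit behind a small adapter interface (fit / predict /
# importance) so fold handling and metric code never depend on the
# library in use. Adapters for random forest (ranger) and gradient
# boosting (xgboost) ship with the package; register_learner() adds
# others without touching pipeline code.

.learners <- new.env(parent = emptyenv())

#' Register a learner adapter
#'
#' @param name model name used in `model =` arguments.
#' @param fit function(x, y, params, seed) -> fitted model; `x` numeric
#'   matrix, `y` factor with levels `c("HC", "SCZ")`.
#' @param predict function(fit, x) -> factor of predicted labels.
#' @param importance function(fit, feature_names) -> named non-negative
#'   numeric over all features, or `NULL` if the model has none.
#' @return `name`, invisibly.
#' @export
register_learner <- function(name, fit, predict, importance = NULL) {
  assign(tolower(name),
         list(fit = fit, predict = predict, importance = importance),
         envir = .learners)
  invisible(name)
}

get_learner <- function(name) {
  key <- tolower(name)
  if (!exists(key, envir = .learners)) {
    known <- paste(sort(ls(.learners)), collapse = ", ")
    stop(sprintf(
      "unknown model '%s' (registered: %s); use register_learner() to add one",
      name, known))
  }
  get(key, envir = .learners)
}

# ---- built-in adapters -------------------------------------------------

fit_rf <- function(x, y, params, seed) {
  # matrix input keeps feature names (incl. "-" in pair names) unmangled
  ranger::ranger(
    x = x, y = y,
    num.trees = params$num.trees %||% 500,
    importance = "impurity",
    seed = seed, num.threads = 1
  )
}

predict_rf <- function(fit, x) {
  stats::predict(fit, data = x, num.threads = 1)$predictions
}

importance_rf <- function(fit, feature_names) {
  imp <- ranger::importance(fit)
  out <- structure(numeric(length(feature_names)), names = feature_names)
  out[names(imp)] <- pmax(imp, 0)
  out
}

fit_xgb <- function(x, y, params, seed) {
  set.seed(seed)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth %||% 6,
                  eta = params$eta %||% 0.3,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = as.integer(y == "SCZ")),
    nrounds = params$nrounds %||% 80,
    verbose = 0
  )
}

predict_xgb <- function(fit, x) {
  p <- stats::predict(fit, xgboost::xgb.DMatrix(x))
  factor(ifelse(p > 0.5, "SCZ", "HC"), levels = c("HC", "SCZ"))
}

importance_xgb <- function(fit, feature_names) {
  imp <- xgboost::xgb.importance(model = fit)
  out <- structure(numeric(length(feature_names)), names = feature_names)
  out[imp$Feature] <- imp$Gain
  out
}

# data.frame feature names survive as-is in a matrix; xgboost accepts them
local({
  register_learner("rf", fit_rf, predict_rf, importance_rf)
  register_learner("ranger", fit_rf, predict_rf, importance_rf)
  register_learner("xgboost", fit_xgb, predict_xgb, importance_xgb)
  register_learner("xgb", fit_xgb, predict_xgb, importance_xgb)
})

# ---- folds -------------------------------------------------------------

#' Cross-validation fold assignment
#'
#' Stratified-by-class partition of the feature table rows. With
#' `unit = "window"` rows are split independently; with
#' `unit = "subject"` all windows of a subject stay in one fold (the
#' leakage-safe alternative; see the vignette).
#'
#' @param table an `eeg_features` table (needs `group`, `subject_id`).
#' @param n_folds number of folds (default 10).
#' @param seed seed for the fold shuffle.
#' @param unit `"window"` or `"subject"`.
#' @return Integer vector of fold ids (1..n_folds), one per row, with
#'   attributes `unit` and `seed`.
#' @export
make_folds <- function(table, n_folds = 10, seed = 1,
                       unit = c("window", "subject")) {
  unit <- match.arg(unit)
  stopifnot(n_folds >= 2)
  set.seed(seed)
  fold <- integer(nrow(table))
  if (unit == "window") {
    if (n_folds > nrow(table)) stop("more folds than rows")
    for (g in unique(table$group)) {
      idx <- which(table$group == g)
      fold[idx] <- (sample(seq_along(idx)) %% n_folds) + 1L
    }
  } else {
    subj <- unique(table$subject_id)
    if (n_folds > length(subj)) stop("more folds than subjects")
    sf <- integer(length(subj))
    sg <- table$group[match(subj, table$subject_id)]
    for (g in unique(sg)) {
      idx <- which(sg == g)
      sf[idx] <- (sample(seq_along(idx)) %% n_folds) + 1L
    }
    fold <- sf[match(table$subject_id, subj)]
  }
  structure(fold, unit = unit, seed = seed)
}

# ---- metrics -----------------------------------------------------------

# SCZ is the positive class; percent scale
confusion_metrics <- function(truth, pred) {
  tp <- sum(truth == "SCZ" & pred == "SCZ")
  tn <- sum(truth == "HC" & pred == "HC")
  fp <- sum(truth == "HC" & pred == "SCZ")
  fn <- sum(truth == "SCZ" & pred == "HC")
  acc <- 100 * (tp + tn) / (tp + tn + fp + fn)
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(tp = tp, tn = tn, fp = fp, fn = fn, accuracy = acc,
    precision = prec, recall = rec, f1 = f1)
}

#' Cross-validated classification of a feature table
#'
#' Fits the chosen learner on 9/10 of the data and evaluates on the
#' held-out tenth, over every fold; reports accuracy, precision, recall
#' and F1 (percent, SCZ as the positive class) per fold and as mean and
#' standard deviation over folds.
#'
#' @param table an `eeg_features` table.
#' @param model learner name (`"rf"`, `"xgboost"`, or any registered
#'   adapter).
#' @param n_folds number of folds when `folds` is not supplied.
#' @param seed seed for fold shuffling and the learner.
#' @param unit fold unit, see [make_folds()].
#' @param folds optional precomputed fold assignment.
#' @param params named list of learner hyperparameters (library defaults
#'   otherwise).
#' @param features optional character vector restricting the feature
#'   columns used.
#' @return Object of class `eeg_cv`: list with `per_fold` (data.frame),
#'   `mean`, `sd` (named, percent), `folds`, `model`, `seed`.
#' @export
cross_validate <- function(table, model = "xgboost", n_folds = 10, seed = 1,
                           unit = c("window", "subject"), folds = NULL,
                           params = list(), features = NULL) {
  unit <- match.arg(unit)
  if (length(unique(table$group)) < 2)
    stop("feature table must contain both groups")
  ad <- get_learner(model)
  fc <- feature_cols(table)
  if (!is.null(features)) {
    miss <- setdiff(features, fc)
    if (length(miss))
      stop("unknown feature column(s): ", paste(head(miss, 5), collapse = ", "))
    # keep canonical column order so results do not depend on the order in
    # which a subset was supplied (e.g. by an importance ranking)
    fc <- fc[fc %in% features]
  }
  if (is.null(folds)) folds <- make_folds(table, n_folds, seed, unit)
  x <- as.matrix(table[, fc, drop = FALSE])
  y <- factor(table$group, levels = c("HC", "SCZ"))
  ids <- sort(unique(folds))
  per <- matrix(NA_real_, nrow = length(ids), ncol = 8,
                dimnames = list(NULL, c("tp", "tn", "fp", "fn", "accuracy",
                                        "precision", "recall", "f1")))
  for (i in seq_along(ids)) {
    te <- folds == ids[i]
    if (length(unique(y[!te])) < 2)
      stop("training fold ", ids[i], " contains a single class")
    fit <- ad$fit(x[!te, , drop = FALSE], y[!te], params, seed + i)
    pred <- ad$predict(fit, x[te, , drop = FALSE])
    per[i, ] <- confusion_metrics(y[te], pred)
  }
  per <- data.frame(fold = ids, per, check.names = FALSE)
  mt <- c("accuracy", "precision", "recall", "f1")
  structure(list(
    per_fold = per,
    mean = vapply(per[mt], mean, numeric(1), na.rm = TRUE),
    sd = vapply(per[mt], sd, numeric(1), na.rm = TRUE),
    folds = folds, model = model, params = params, seed = seed,
    n_features = length(fc)
  ), class = "eeg_cv")
}

#' @export
print.eeg_cv <- function(x, ...) {
  cat(sprintf("<eeg_cv> %s, %d folds (%s unit), %d features\n",
              x$model, nrow(x$per_fold), attr(x$folds, "unit") %||% "window",
              x$n_features))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %6.2f +/- %.2f %%\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' @export
summary.eeg_cv <- function(object, ...) {
  data.frame(metric = names(object$mean),
             mean = unname(object$mean),
             sd = unname(object$sd))
}
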