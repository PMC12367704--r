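# Result surfaces: window-length sweep, spatio-spectral group-difference
# summaries, PLI edge directions and region proportions, CSV reports.

#' Window-length sweep
#'
#' Runs the full pipeline (feature extraction then cross-validated
#' classification) once per requested window length and tabulates the
#' accuracy.
#'
#' @param cohort an `eeg_cohort`.
#' @param window_lengths window lengths in seconds (default 1:6).
#' @inheritParams cross_validate
#' @inheritParams extract_features
#' @return data.frame of class `eeg_sweep`: window_length_s, accuracy,
#'   accuracy_sd, n_rows, n_features.
#' @export
window_sweep <- function(cohort, window_lengths = 1:6, model = "xgboost",
                         n_folds = 10, seed = 1,
                         unit = c("window", "subject"), params = list(),
                         families = c("RP", "FuzEn", "PLI")) {
  unit <- match.arg(unit)
  dur <- cohort$config$duration_s %||%
    (ncol(cohort$recordings[[1]]$data) / cohort$recordings[[1]]$fs)
  if (any(window_lengths > dur))
    stop("window length exceeds the recording duration of ", dur, " s")
  out <- data.frame(window_length_s = window_lengths, accuracy = NA_real_,
                    accuracy_sd = NA_real_, n_rows = NA_integer_,
                    n_features = NA_integer_)
  for (i in seq_along(window_lengths)) {
    tab <- extract_features(cohort, window_lengths[i], families = families)
    cv <- cross_validate(tab, model = model, n_folds = n_folds,
                         seed = seed, unit = unit, params = params)
    out$accuracy[i] <- cv$mean[["accuracy"]]
    out$accuracy_sd[i] <- cv$sd[["accuracy"]]
    out$n_rows[i] <- nrow(tab)
    out$n_features[i] <- cv$n_features
  }
  class(out) <- c("eeg_sweep", "data.frame")
  out
}

#' @export
plot.eeg_sweep <- function(x, ...) {
  plot(x$window_length_s, x$accuracy, type = "b", pch = 19,
       xlab = "window length (s)", ylab = "CV accuracy (%)",
       main = "Accuracy vs window length", ...)
  invisible(x)
}

#' Spatio-spectral group-difference summary
#'
#' Per-feature group means (window-level, plus a subject-level
#' mean-of-means variant), difference direction, standardized effect
#' size, and the aggregations used for result tables: family-by-band
#' counts, the PLI edge list with direction and region endpoints, and
#' per-band region proportions of PLI edge endpoints.
#'
#' @param table an `eeg_features` table containing both groups.
#' @param subset optional character vector of feature names restricting
#'   the summary (e.g. an RFE optimal subset).
#' @param regions channel-to-region map, see [channel_regions()].
#' @return Object of class `eeg_groupdiff`: list with `features`
#'   (per-feature data.frame), `band_family` (count matrix), `edges`
#'   (PLI edge data.frame), `region_props` (per band x region).
#' @export
summarize_groups <- function(table, subset = NULL,
                             regions = channel_regions()) {
  if (length(unique(table$group)) < 2)
    stop("feature table must contain both groups")
  fc <- feature_cols(table)
  if (!is.null(subset)) {
    miss <- setdiff(subset, fc)
    if (length(miss))
      stop("subset references unknown feature(s): ",
           paste(head(miss, 5), collapse = ", "))
    fc <- fc[fc %in% subset]   # keep canonical order
  }
  keys <- attr(table, "feature_keys")
  keys <- keys[match(fc, keys$name), ]
  hc <- table$group == "HC"
  x <- as.matrix(table[, fc, drop = FALSE])

  mean_hc <- colMeans(x[hc, , drop = FALSE])
  mean_scz <- colMeans(x[!hc, , drop = FALSE])
  # pooled window-level sd for the standardized effect size
  v_hc <- apply(x[hc, , drop = FALSE], 2, var)
  v_scz <- apply(x[!hc, , drop = FALSE], 2, var)
  n1 <- sum(hc); n2 <- sum(!hc)
  pooled <- sqrt(((n1 - 1) * v_hc + (n2 - 1) * v_scz) / (n1 + n2 - 2))
  d <- (mean_scz - mean_hc) / pooled

  # subject-level: each subject contributes one mean per feature
  subj_means <- rowsum(x, table$subject_id)
  cnt <- table(table$subject_id)
  subj_means <- subj_means / as.vector(cnt[rownames(subj_means)])
  sg <- table$group[match(rownames(subj_means), table$subject_id)]
  mean_hc_subj <- colMeans(subj_means[sg == "HC", , drop = FALSE])
  mean_scz_subj <- colMeans(subj_means[sg == "SCZ", , drop = FALSE])

  feats <- data.frame(
    name = fc, family = keys$family, band = keys$band, site = keys$site,
    mean_hc = unname(mean_hc), mean_scz = unname(mean_scz),
    mean_hc_subject = unname(mean_hc_subj),
    mean_scz_subject = unname(mean_scz_subj),
    direction = ifelse(mean_scz > mean_hc, "SCZ>HC", "SCZ<HC"),
    effect_size = unname(d),
    stringsAsFactors = FALSE
  )

  band_family <- subset_distribution(fc)

  pli <- feats[feats$family == "PLI", , drop = FALSE]
  if (nrow(pli)) {
    ends <- do.call(rbind, strsplit(pli$site, "-", fixed = TRUE))
    edges <- data.frame(
      chan_i = ends[, 1], chan_j = ends[, 2], band = pli$band,
      direction = pli$direction, effect_size = pli$effect_size,
      region_i = unname(regions[ends[, 1]]),
      region_j = unname(regions[ends[, 2]]),
      stringsAsFactors = FALSE
    )
    # region proportions: each edge contributes both endpoints
    rp <- expand.grid(band = unique(edges$band),
                      region = sort(unique(unname(regions))),
                      stringsAsFactors = FALSE)
    rp$count <- mapply(function(b, r)
      sum((edges$band == b) * ((edges$region_i == r) + (edges$region_j == r))),
      rp$band, rp$region)
    tot <- stats::ave(rp$count, rp$band, FUN = sum)
    rp$proportion <- ifelse(tot > 0, rp$count / tot, 0)
  } else {
    edges <- data.frame(chan_i = character(0), chan_j = character(0),
                        band = character(0), direction = character(0),
                        effect_size = numeric(0), region_i = character(0),
                        region_j = character(0), stringsAsFactors = FALSE)
    rp <- data.frame(band = character(0), region = character(0),
                     count = integer(0), proportion = numeric(0),
                     stringsAsFactors = FALSE)
  }
  structure(list(features = feats, band_family = band_family,
                 edges = edges, region_props = rp),
            class = "eeg_groupdiff")
}

#' @export
print.eeg_groupdiff <- function(x, ...) {
  cat(sprintf("<eeg_groupdiff> %d features summarized\n", nrow(x$features)))
  print(x$band_family)
  if (nrow(x$edges)) {
    up <- sum(x$edges$direction == "SCZ>HC")
    cat(sprintf("PLI edges: %d (SCZ>HC: %d, SCZ<HC: %d)\n",
                nrow(x$edges), up, nrow(x$edges) - up))
  }
  invisible(x)
}

#' Write analysis reports as CSV files
#'
#' Writes the group-difference tables and, when given, the RFE curve,
#' cross-validation metrics and window sweep, plus a plain-text run log.
#' Outputs are deterministic: re-running with identical inputs produces
#' byte-identical files.
#'
#' @param summary an `eeg_groupdiff`.
#' @param trace optional `eeg_rfe`.
#' @param cv optional `eeg_cv`.
#' @param sweep optional `eeg_sweep`.
#' @param out_dir output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
render_reports <- function(summary, trace = NULL, cv = NULL, sweep = NULL,
                           out_dir = ".") {
  stopifnot(inherits(summary, "eeg_groupdiff"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0)
    stop("cannot write to directory: ", out_dir)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(summary$features, "group_differences.csv")
  bf <- as.data.frame(summary$band_family)
  bf <- cbind(family = rownames(summary$band_family), bf)
  wr(bf, "band_family_counts.csv")
  wr(summary$edges, "pli_edges.csv")
  wr(summary$region_props, "region_proportions.csv")
  if (!is.null(trace)) wr(trace$curve, "rfe_curve.csv")
  if (!is.null(cv)) wr(cv$per_fold, "cv_metrics.csv")
  if (!is.null(sweep)) wr(as.data.frame(sweep), "window_sweep.csv")
  log <- c("eegmarkers report",
           sprintf("features summarized: %d", nrow(summary$features)),
           sprintf("PLI edges: %d", nrow(summary$edges)),
           if (!is.null(trace))
             sprintf("RFE: optimal %d of %d features (seed %d)",
                     trace$optimal_size, length(trace$ranking), trace$seed),
           if (!is.null(cv))
             sprintf("CV: %s, accuracy %.2f +/- %.2f %% (seed %d)",
                     cv$model, cv$mean[["accuracy"]], cv$sd[["accuracy"]],
                     cv$seed),
           sprintf("files: %s", paste(basename(files), collapse = ", ")))
  lp <- file.path(out_dir, "run_log.txt")
  writeLines(log, lp)
  invisible(c(files, lp))
}
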