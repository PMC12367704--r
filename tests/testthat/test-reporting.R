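test_that("group summaries label directions anti-symmetrically and partition counts", {
  tab <- noise_table(n_rows = 60, n_feat = 0, seed = 1)
  # graft canonical EEG feature names onto a synthetic table
  keys <- feature_keys()
  set.seed(2)
  x <- matrix(rnorm(60 * 760), 60, dimnames = list(NULL, keys$name))
  x[tab$group == "SCZ", "RP_Alpha_O1"] <- x[tab$group == "SCZ", "RP_Alpha_O1"] - 3
  x[tab$group == "SCZ", "PLI_Beta_F3-C3"] <- x[tab$group == "SCZ", "PLI_Beta_F3-C3"] + 3
  tab <- cbind(tab, as.data.frame(x, check.names = FALSE))
  attr(tab, "feature_keys") <- keys
  class(tab) <- c("eeg_features", "data.frame")

  s <- summarize_groups(tab)
  expect_equal(nrow(s$features), 760L)
  f <- s$features
  expect_identical(f$direction[f$name == "RP_Alpha_O1"], "SCZ<HC")
  expect_identical(f$direction[f$name == "PLI_Beta_F3-C3"], "SCZ>HC")
  expect_lt(f$effect_size[f$name == "RP_Alpha_O1"], -1)
  # direction is consistent with the sign of the mean difference everywhere
  expect_identical(f$direction, ifelse(f$mean_scz > f$mean_hc, "SCZ>HC", "SCZ<HC"))

  # anti-symmetry under group-label swap
  tab2 <- tab
  tab2$group <- ifelse(tab$group == "HC", "SCZ", "HC")
  f2 <- summarize_groups(tab2)$features
  expect_identical(f2$direction,
                   ifelse(f$direction == "SCZ>HC", "SCZ<HC", "SCZ>HC"))
  expect_equal(f2$effect_size, -f$effect_size)

  # aggregation bookkeeping
  expect_equal(unname(s$band_family["Total", "Total"]), 760L)
  expect_equal(nrow(s$edges), 600L)
  pr <- tapply(s$region_props$proportion, s$region_props$band, sum)
  expect_true(all(abs(pr - 1) < 1e-12))

  # subset restriction and error paths
  s2 <- summarize_groups(tab, subset = c("RP_Alpha_O1", "FuzEn_Theta_Cz"))
  expect_equal(nrow(s2$features), 2L)
  expect_equal(nrow(s2$edges), 0L)
  expect_error(summarize_groups(tab, subset = "bogus"), "unknown feature")
  one <- tab[tab$group == "HC", ]
  expect_error(summarize_groups(one), "both groups")
})

test_that("subject-level means weight each subject once", {
  tab <- noise_table(n_rows = 40, n_feat = 1, seed = 3,
                     windows_per_subject = 10)
  names(tab)[4] <- "RP_Delta_F3"
  attr(tab, "feature_keys") <- feature_keys()[1, ]
  # make one subject an extreme outlier in half its windows
  tab$RP_Delta_F3[tab$subject_id == "x001" & tab$window_index <= 5] <- 100
  s <- summarize_groups(tab)
  by_subj <- tapply(tab$RP_Delta_F3, tab$subject_id, mean)
  grp <- tapply(tab$group, tab$subject_id, unique)
  expect_equal(s$features$mean_hc_subject, mean(by_subj[grp == "HC"]))
  expect_equal(s$features$mean_hc, mean(tab$RP_Delta_F3[tab$group == "HC"]))
})

test_that("the window sweep runs the pipeline once per length", {
  coh <- tiny_cohort(n_per_group = 3, duration_s = 8, seed = 4)
  sw <- window_sweep(coh, window_lengths = c(2, 4), model = "xgboost",
                     n_folds = 3, seed = 5, families = "RP",
                     params = list(nrounds = 30))
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$n_rows, c(6 * 4, 6 * 2))
  expect_true(all(is.finite(sw$accuracy)))
  expect_error(window_sweep(coh, window_lengths = 9), "exceeds")
})

test_that("reports are written completely and byte-identically on re-run", {
  tab <- noise_table(n_rows = 40, n_feat = 0, seed = 6)
  keys <- feature_keys()
  set.seed(7)
  x <- matrix(rnorm(40 * 760), 40, dimnames = list(NULL, keys$name))
  tab <- cbind(tab, as.data.frame(x, check.names = FALSE))
  attr(tab, "feature_keys") <- keys
  class(tab) <- c("eeg_features", "data.frame")
  s <- summarize_groups(tab)
  cv <- cross_validate(tab, model = "xgboost", n_folds = 4, seed = 8,
                       params = list(nrounds = 10))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- render_reports(s, cv = cv, out_dir = d1)
  f2 <- render_reports(s, cv = cv, out_dir = d2)
  need <- c("group_differences.csv", "band_family_counts.csv",
            "pli_edges.csv", "region_proportions.csv", "cv_metrics.csv",
            "run_log.txt")
  expect_true(all(need %in% basename(f1)))
  expect_equal(nrow(utils::read.csv(file.path(d1, "group_differences.csv"))),
               760L)
  for (nm in need)
    expect_identical(readLines(file.path(d1, nm)),
                     readLines(file.path(d2, nm)))

  # an RP-only summary has no PLI edges but still writes valid tables
  s0 <- summarize_groups(tab, subset = keys$name[keys$family == "RP"])
  f3 <- render_reports(s0, out_dir = withr::local_tempdir())
  edges <- utils::read.csv(f3[grep("pli_edges", f3)])
  expect_equal(nrow(edges), 0L)
  expect_true(all(c("chan_i", "chan_j", "band") %in% names(edges)))
})
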