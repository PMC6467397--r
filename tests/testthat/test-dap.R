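make_toy_table <- function(n_per_class = rep(30, 3), p = 20, n_inf = 3,
                           sep = 3, seed = 7) {
  make_feature_table(feature_table_spec(
    n_samples_per_class = n_per_class, n_features = p, n_informative = n_inf,
    class_separation = sep, seed = seed))
}

test_that("the external split is stratified, disjoint, exhaustive and seeded", {
  ft <- make_toy_table(rep(20, 5), p = 4)
  sp <- stratified_external_split(ft, 0.2, seed = 3)
  expect_equal(nrow(sp$external$x), 20)
  expect_equal(unname(c(base::table(sp$external$label))), rep(4L, 5))
  expect_length(intersect(sp$train_idx, sp$external_idx), 0)
  expect_setequal(c(sp$train_idx, sp$external_idx), 1:100)
  sp2 <- stratified_external_split(ft, 0.2, seed = 3)
  expect_identical(sp$external_idx, sp2$external_idx)
  # unbalanced rounding rule: (60, 40) at 0.2 -> (12, 8)
  ft2 <- make_toy_table(c(60, 40), p = 3)
  sp3 <- stratified_external_split(ft2, 0.2, seed = 1)
  expect_equal(unname(c(base::table(sp3$external$label))), c(12L, 8L))
  # tiny class is named in the error
  ft3 <- make_toy_table(c(30, 3), p = 3)
  expect_error(stratified_external_split(ft3, 0.2), "C2")
})

test_that("10 x 5 internal CV yields 50 stratified partitions of the training set", {
  lab <- factor(rep(c("a", "b", "c"), times = c(30, 24, 18)))
  folds <- internal_cv_folds(lab, 10, 5, seed = 2)
  expect_length(folds, 50)
  for (r in 1:10) {
    these <- Filter(function(f) f$repeat_id == r, folds)
    vals <- lapply(these, `[[`, "val_idx")
    expect_setequal(unlist(vals), seq_along(lab))      # partition
    expect_equal(sum(lengths(vals)), length(lab))      # pairwise disjoint
    for (f in these) {
      cnt <- base::table(lab[f$val_idx])
      expect_true(all(abs(cnt - c(base::table(lab)) / 5) <= 1))
    }
  }
  expect_error(internal_cv_folds(factor(rep(c("a", "b"), c(30, 4))), 10, 5),
               "smaller than n_folds")
})

test_that("slide-grouped splitting never lets a slide straddle a boundary", {
  ft <- make_feature_table(feature_table_spec(
    n_samples_per_class = rep(40, 3), n_features = 10, n_informative = 2,
    class_separation = 2, n_tiles_per_slide = 4, seed = 6))
  sp <- stratified_external_split(ft, 0.2, seed = 2, group_by_slide = TRUE)
  expect_length(intersect(sp$train$slide_id, sp$external$slide_id), 0)
  folds <- internal_cv_folds(sp$train$label, 2, 5, seed = 3,
                             slide_id = sp$train$slide_id)
  for (f in folds)
    expect_length(intersect(sp$train$slide_id[f$train_idx],
                            sp$train$slide_id[f$val_idx]), 0)
  out <- run_dap(ft, dap_config(n_repeats = 2, n_boot = 100, seed = 2,
                                group_by_slide = TRUE))
  expect_equal(nrow(out$per_split), 2 * 5 * 4)
  rl <- run_dap(ft, dap_config(n_repeats = 2, n_boot = 100, seed = 2,
                               group_by_slide = TRUE, mode = "random_labels"))
  expect_lt(mean(rl$per_split$mcc), 0.3)
})

test_that("the DAP report has full cardinality, a clean audit and is reproducible", {
  ft <- make_toy_table()
  cfg <- dap_config(n_repeats = 2, n_boot = 200, seed = 5)
  rep1 <- run_dap(ft, cfg)
  expect_equal(nrow(rep1$per_split), 2 * 5 * 4)
  expect_equal(sort(unique(rep1$per_split$fraction)), c(0.1, 0.25, 0.5, 1))
  expect_equal(rep1$audit$external_accesses, 1L)
  expect_equal(rep1$audit$external_n + rep1$audit$train_n, nrow(ft$x))
  expect_true(all(rep1$summary$mcc_lower <= rep1$summary$mcc_mean + 1e-12))
  rep2 <- run_dap(ft, cfg)
  keep <- setdiff(names(rep1), "elapsed")
  expect_identical(rep1[keep], rep2[keep])
  # serialization round trip
  js <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_dap_report(rep1, js, per_split_csv = csv)
  expect_equal(jsonlite::fromJSON(js)$external$mcc, rep1$external$mcc)
  expect_equal(nrow(read.csv(csv)), nrow(rep1$per_split))
})

test_that("feature ranking never sees validation or external rows", {
  # plant the signal only in rows that the first split holds out: if ranking
  # was computed on the full table these features would lead; computed on
  # the split's training part only, they must not systematically lead
  ft <- make_toy_table(rep(30, 3), p = 40, n_inf = 0, sep = 0, seed = 10)
  # reproduce the split run_dap(seed = 1) will draw internally
  sp <- stratified_external_split(ft, 0.2, seed = child_seed(1, 1))
  # inject a huge class signal into the *external* rows only
  ft2 <- ft
  ext_rows <- sp$external_idx
  ft2$x[ext_rows, 1] <- ft2$x[ext_rows, 1] +
    10 * as.integer(ft2$label[ext_rows])
  cfg <- dap_config(n_repeats = 2, n_boot = 100, seed = 1)
  out <- run_dap(ft2, cfg)
  # feature 1 is pure noise inside the training part, so it should not rank
  # top in the Borda consensus
  expect_false(out$borda$ranking[1] == 1)
  expect_equal(out$audit$external_accesses, 1L)
  expect_setequal(out$audit$external_idx, ext_rows)
})

test_that("separable toy data is classified perfectly by every head", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  y <- factor(c("a", "a", "b", "b"))
  svm_head <- fit_head(classifier_spec("linear_max_margin"), x, y, seed = 1)
  expect_equal(as.character(predict(svm_head, x)), as.character(y))
  rf_head <- fit_head(classifier_spec("randomized_tree_ensemble", n_trees = 50),
                      x, y, seed = 1)
  expect_equal(as.character(predict(rf_head, x)), as.character(y))
  set.seed(30)
  x2 <- rbind(matrix(rnorm(40), 20) - 4, matrix(rnorm(40), 20) + 4)
  y2 <- factor(rep(c("a", "b"), each = 20))
  ffh <- fit_head(classifier_spec("feed_forward_head", hidden = c(8),
                                  learning_rate = 0.01, epochs = 60,
                                  batch_size = 8), x2, y2, seed = 2)
  expect_equal(as.character(predict(ffh, x2)), as.character(y2))
  expect_error(fit_head(classifier_spec(), x, factor(rep("a", 4))),
               "2 classes")
})

test_that("randomized heads are deterministic under a fixed seed", {
  ft <- make_toy_table(rep(20, 2), p = 10)
  for (kind in c("randomized_tree_ensemble", "feed_forward_head")) {
    spec <- if (kind == "feed_forward_head")
      classifier_spec(kind, hidden = c(6), epochs = 5, learning_rate = 1e-3)
    else classifier_spec(kind, n_trees = 50)
    h1 <- fit_head(spec, ft$x, ft$label, seed = 11)
    h2 <- fit_head(spec, ft$x, ft$label, seed = 11)
    expect_identical(predict(h1, ft$x), predict(h2, ft$x))
  }
})

test_that("class weighting raises minority recall on imbalanced data", {
  recall_gain <- vapply(1:20, function(s) {
    tbl <- withr::with_seed(s, {
      n1 <- 90; n2 <- 10
      x <- rbind(matrix(rnorm(n1 * 2), n1), matrix(rnorm(n2 * 2) + 1.5, n2))
      list(x = x, y = factor(rep(c("maj", "min"), c(n1, n2))))
    })
    spec <- classifier_spec("linear_max_margin")
    w_eq <- c(maj = 1, min = 1)
    h_un <- fit_head(spec, tbl$x, tbl$y, weights = w_eq, seed = s)
    h_w <- fit_head(spec, tbl$x, tbl$y, seed = s)   # n_max/n_i weights
    rec <- function(h) mean(predict(h, tbl$x[tbl$y == "min", ]) == "min")
    rec(h_w) - rec(h_un)
  }, numeric(1))
  expect_gt(mean(recall_gain), 0)
})

test_that("random-ranking mode needs all features while standard mode does not", {
  ft <- make_toy_table(rep(30, 3), p = 60, n_inf = 5, sep = 4, seed = 21)
  cfg_rr <- dap_config(n_repeats = 2, n_boot = 100, seed = 21,
                       mode = "random_ranking")
  rep_rr <- run_dap(ft, cfg_rr)
  s <- rep_rr$summary
  expect_lt(s$mcc_mean[s$fraction == 0.1], s$mcc_mean[s$fraction == 1])
  cfg_std <- dap_config(n_repeats = 2, n_boot = 100, seed = 21)
  rep_std <- run_dap(ft, cfg_std)
  s2 <- rep_std$summary
  expect_gt(s2$mcc_mean[s2$fraction == 0.1], 0.9)
})

test_that("mean internal MCC degrades as the number of classes grows", {
  mean_mcc <- function(k, seed) {
    ft <- make_feature_table(feature_table_spec(
      n_samples_per_class = rep(25, k), n_features = 40, n_informative = 10,
      class_separation = 1, seed = seed))
    cfg <- dap_config(n_repeats = 2, feature_fractions = 1,
                      n_boot = 50, seed = seed)
    mean(run_dap(ft, cfg)$per_split$mcc)
  }
  ks <- c(5, 10, 20)
  avg <- vapply(ks, function(k)
    mean(vapply(1:3, function(s) mean_mcc(k, 100 + s), numeric(1))),
    numeric(1))
  expect_true(all(diff(avg) <= 0))
})
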