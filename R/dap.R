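#' Data Analysis Plan configuration
#'
#' The prespecified validation protocol: an external stratified split
#' (default 80/20), an internal 10 x 5-fold stratified cross-validation on
#' the training part (50 internal validation sets), per-split univariate
#' feature ranking, model fits on increasing feature fractions, studentized
#' bootstrap confidence intervals over the per-split metrics, Borda
#' aggregation of the 50 ranked lists with a Canberra stability score, and
#' a single final evaluation on the external set.  Two diagnostic modes
#' probe for selection bias: \code{random_labels} scrambles the training
#' labels once before the CV (an unbiased pipeline must score near
#' MCC 0), and \code{random_ranking} replaces the data-driven feature
#' ranking with a fresh random permutation per split (top performance
#' should then require all features).
#'
#' @param external_fraction held-out external fraction (default 0.2).
#' @param n_repeats CV repeats (default 10).
#' @param n_folds folds per repeat (default 5).
#' @param feature_fractions fractions of top-ranked features to fit
#'   (default \code{c(0.10, 0.25, 0.50, 1.00)}), each in (0, 1].
#' @param classifier a [classifier_spec()] (default linear max-margin).
#' @param mode \code{"standard"}, \code{"random_labels"} or
#'   \code{"random_ranking"}.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it via [child_seed()].
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @param group_by_slide if TRUE, the external split and the CV folds
#'   assign whole slides, never individual tiles, to one side (default
#'   FALSE: plain per-sample class stratification).
#' @return an object of class \code{dap_config}.
#' @export
dap_config <- function(external_fraction = 0.2, n_repeats = 10, n_folds = 5,
                       feature_fractions = c(0.10, 0.25, 0.50, 1.00),
                       classifier = classifier_spec("linear_max_margin"),
                       mode = c("standard", "random_labels", "random_ranking"),
                       seed = 1L, n_boot = 1000, group_by_slide = FALSE) {
  stopifnot(external_fraction > 0, external_fraction < 1,
            n_repeats >= 1, n_folds >= 2,
            all(feature_fractions > 0), all(feature_fractions <= 1),
            inherits(classifier, "classifier_spec"), n_boot >= 2)
  structure(list(external_fraction = external_fraction,
                 n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 feature_fractions = sort(unique(feature_fractions)),
                 classifier = classifier, mode = match.arg(mode),
                 seed = as.integer(seed), n_boot = as.integer(n_boot),
                 group_by_slide = isTRUE(group_by_slide)),
            class = "dap_config")
}

# one class per slide, or error; returns named vector slide -> class
.slide_classes <- function(slide_id, label) {
  sc <- tapply(as.character(label), as.character(slide_id), function(v) {
    u <- unique(v)
    if (length(u) > 1)
      stop("slide-grouped splitting needs one class per slide")
    u
  })
  sc[sort(names(sc))]
}

#' Stratified external split
#'
#' Splits a feature table into a training part and a held-out external
#' validation part, preserving per-class proportions to within rounding:
#' each class contributes \code{round(fraction * n_class)} samples (at
#' least 1) to the external set.  The external part must never be touched
#' again until the single final evaluation.
#'
#' @param table a [feature_table()].
#' @param fraction external fraction in (0, 1).
#' @param seed integer seed.
#' @param group_by_slide if TRUE, whole slides (all tiles of a slide) are
#'   assigned to one side of the split, stratified by the slides' class;
#'   prevents tiles of one slide straddling the split when tiles within a
#'   slide are correlated.  Requires one class per slide.
#' @return a list with elements \code{train} and \code{external}
#'   ([feature_table()]s) and the index vectors \code{train_idx},
#'   \code{external_idx} into the input rows.
#' @export
stratified_external_split <- function(table, fraction = 0.2, seed = 1L,
                                      group_by_slide = FALSE) {
  stopifnot(inherits(table, "feature_table"), fraction > 0, fraction < 1)
  y <- droplevels(table$label)
  if (group_by_slide) {
    slide_class <- .slide_classes(table$slide_id, y)
    s_cnt <- base::table(slide_class)
    small <- s_cnt < ceiling(1 / fraction)
    if (any(small))
      stop("class with too few slides for the external split: ",
           paste(names(s_cnt)[small], collapse = ", "))
    ext <- with_seed(seed, {
      unlist(lapply(levels(y), function(cl) {
        sl <- names(slide_class)[slide_class == cl]
        sel <- sample(sl, max(1L, round(fraction * length(sl))))
        which(table$slide_id %in% sel)
      }))
    })
    ext <- sort(ext)
    trn <- setdiff(seq_len(nrow(table$x)), ext)
    return(list(train = table[trn], external = table[ext],
                train_idx = trn, external_idx = ext))
  }
  cnt <- base::table(y)
  small <- cnt < ceiling(1 / fraction)
  if (any(small))
    stop("class too small for the external split: ",
         paste(names(cnt)[small], collapse = ", "))
  ext <- with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      n_ext <- max(1L, round(fraction * length(idx)))
      sample(idx, n_ext)
    }))
  })
  ext <- sort(ext)
  trn <- setdiff(seq_len(nrow(table$x)), ext)
  list(train = table[trn], external = table[ext],
       train_idx = trn, external_idx = ext)
}

#' Repeated stratified cross-validation folds
#'
#' Generates \code{n_repeats x n_folds} (train, validation) index pairs on
#' the training set.  Within each repeat the folds partition the samples,
#' stratified by class (per-fold class counts within one sample of
#' proportionality); repeats differ by reshuffling.
#'
#' @param label class labels of the training samples.
#' @param n_repeats,n_folds the CV schema (default 10 x 5 gives 50
#'   internal validation sets).
#' @param seed integer seed; repeat \code{r} shuffles under
#'   \code{child_seed(seed, r)}.
#' @param slide_id optional slide of origin per sample; when given, whole
#'   slides are dealt to folds (stratified by the slides' class) so tiles
#'   of one slide never span a fold boundary.
#' @return a list of \code{n_repeats * n_folds} elements, each a list with
#'   \code{train_idx}, \code{val_idx}, \code{repeat_id}, \code{fold_id}.
#' @export
internal_cv_folds <- function(label, n_repeats = 10, n_folds = 5, seed = 1L,
                              slide_id = NULL) {
  y <- droplevels(factor(label))
  if (is.null(slide_id)) {
    cnt <- table(y)
    if (any(cnt < n_folds))
      stop("class smaller than n_folds: ",
           paste(names(cnt)[cnt < n_folds], collapse = ", "))
  } else {
    slide_class <- .slide_classes(slide_id, y)
    s_cnt <- base::table(slide_class)
    if (any(s_cnt < n_folds))
      stop("class with fewer slides than n_folds: ",
           paste(names(s_cnt)[s_cnt < n_folds], collapse = ", "))
  }
  n <- length(y)
  out <- vector("list", n_repeats * n_folds)
  k <- 0L
  for (r in seq_len(n_repeats)) {
    fold_of <- integer(n)
    with_seed(child_seed(seed, r), {
      if (is.null(slide_id)) {
        for (cl in levels(y)) {
          idx <- sample(which(y == cl))
          fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
        }
      } else {
        for (cl in levels(y)) {
          sl <- sample(names(slide_class)[slide_class == cl])
          sf <- rep_len(seq_len(n_folds), length(sl))
          fold_of[slide_id %in% sl] <- sf[match(slide_id[slide_id %in% sl], sl)]
        }
      }
    })
    for (f in seq_len(n_folds)) {
      k <- k + 1L
      out[[k]] <- list(train_idx = which(fold_of != f),
                       val_idx = which(fold_of == f),
                       repeat_id = r, fold_id = f)
    }
  }
  out
}

#' Run the full Data Analysis Plan
#'
#' Executes the protocol described in [dap_config()] on a feature table:
#' \enumerate{
#'   \item stratified external split (external rows locked away);
#'   \item in \code{random_labels} mode, the training labels are scrambled
#'     once, before the CV;
#'   \item for each of the \code{n_repeats x n_folds} internal splits:
#'     features are ranked on the split's training part only
#'     ([anova_f_rank()]; a fresh seeded random permutation in
#'     \code{random_ranking} mode), then one model per feature fraction is
#'     fitted on the top-ranked features and scored (MCC, ACC) on the
#'     internal validation part;
#'   \item per-split metrics are averaged per fraction with
#'     [studentized_bootstrap_ci()]; the per-split ranked lists are fused
#'     by [borda_aggregate()] and their disagreement scored by
#'     [canberra_stability()];
#'   \item the feature fraction with the best mean internal MCC is selected
#'     (ties to the smaller fraction), the head is refitted on the whole
#'     training part using the top Borda features at that fraction, and the
#'     external set is scored exactly once.
#' }
#' Class weights \eqn{w_i = n_{max}/n_i} from the training counts are
#' applied to every fit.  An audit record proves the external rows were
#' accessed only once, at the final evaluation.
#'
#' @param table a [feature_table()].
#' @param config a [dap_config()].
#' @param verbose print progress.
#' @return an object of class \code{dap_report}; see
#'   [print.dap_report()], [summary.dap_report()], [plot.dap_report()].
#' @examples
#' \donttest{
#' ft <- make_feature_table(feature_table_spec(
#'   n_samples_per_class = rep(30, 3), n_features = 20, n_informative = 3,
#'   class_separation = 3, seed = 7))
#' rep <- run_dap(ft, dap_config(n_repeats = 2, n_boot = 200, seed = 7))
#' rep
#' }
#' @export
run_dap <- function(table, config = dap_config(), verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "dap_config"))
  t0 <- Sys.time()
  p <- ncol(table$x)
  sp <- stratified_external_split(table, config$external_fraction,
                                  seed = child_seed(config$seed, 1),
                                  group_by_slide = config$group_by_slide)
  train <- sp$train
  external_access <- 0L

  if (config$mode == "random_labels") {
    train$label <- with_seed(child_seed(config$seed, 2), {
      if (config$group_by_slide) {
        # permute the slide -> label assignment, keeping slides intact
        sc <- .slide_classes(train$slide_id, train$label)
        sc[] <- sample(sc)
        factor(unname(sc[train$slide_id]), levels = levels(train$label))
      } else sample(train$label)
    })
  }

  folds <- internal_cv_folds(train$label, config$n_repeats, config$n_folds,
                             seed = child_seed(config$seed, 3),
                             slide_id = if (config$group_by_slide)
                               train$slide_id else NULL)
  fracs <- config$feature_fractions
  n_feat <- vapply(fracs, function(fr) max(1L, as.integer(ceiling(fr * p))),
                   integer(1))

  records <- vector("list", length(folds) * length(fracs))
  lists <- vector("list", length(folds))
  rec <- 0L
  for (s in seq_along(folds)) {
    fo <- folds[[s]]
    xtr <- train$x[fo$train_idx, , drop = FALSE]
    ytr <- train$label[fo$train_idx]
    xva <- train$x[fo$val_idx, , drop = FALSE]
    yva <- train$label[fo$val_idx]
    ranking <- if (config$mode == "random_ranking")
      with_seed(child_seed(config$seed, 1000 + s), sample.int(p))
    else anova_f_rank(xtr, ytr)$ranking
    lists[[s]] <- ranking
    w <- class_weights(base::table(ytr))
    for (j in seq_along(fracs)) {
      top <- ranking[seq_len(n_feat[j])]
      head_fit <- fit_head(config$classifier, xtr[, top, drop = FALSE], ytr,
                           weights = w,
                           seed = child_seed(config$seed, 2000 + s))
      cm <- confusion_matrix(yva, predict(head_fit, xva[, top, drop = FALSE]))
      rec <- rec + 1L
      records[[rec]] <- data.frame(
        repeat_id = fo$repeat_id, fold_id = fo$fold_id, fraction = fracs[j],
        n_features = n_feat[j], mcc = multiclass_mcc(cm), acc = accuracy(cm))
    }
    if (verbose && s %% 10 == 0)
      message(sprintf("  split %d/%d done", s, length(folds)))
  }
  per_split <- do.call(rbind, records)

  summ <- do.call(rbind, lapply(seq_along(fracs), function(j) {
    sub <- per_split[per_split$fraction == fracs[j], ]
    ci_m <- studentized_bootstrap_ci(sub$mcc, n_boot = config$n_boot,
                                     seed = child_seed(config$seed, 3000 + j))
    ci_a <- studentized_bootstrap_ci(sub$acc, n_boot = config$n_boot,
                                     seed = child_seed(config$seed, 4000 + j))
    data.frame(fraction = fracs[j], n_features = n_feat[j],
               mcc_mean = ci_m$estimate, mcc_lower = ci_m$lower,
               mcc_upper = ci_m$upper, acc_mean = ci_a$estimate,
               acc_lower = ci_a$lower, acc_upper = ci_a$upper)
  }))

  borda <- borda_aggregate(lists, feature_names = colnames(table$x))
  stability <- canberra_stability(lists)

  # fraction selection: best mean internal MCC, ties to the smaller fraction
  sel <- which(summ$mcc_mean >= max(summ$mcc_mean) - 1e-12)[1]
  sel_frac <- summ$fraction[sel]
  sel_feat <- borda$ranking[seq_len(summ$n_features[sel])]

  w_full <- class_weights(base::table(train$label))
  final_fit <- fit_head(config$classifier,
                        train$x[, sel_feat, drop = FALSE], train$label,
                        weights = w_full,
                        seed = child_seed(config$seed, 5000))
  external_access <- external_access + 1L
  if (external_access != 1L)
    stop("internal error: external set accessed more than once")
  ext <- sp$external
  cm_ext <- confusion_matrix(
    ext$label, predict(final_fit, ext$x[, sel_feat, drop = FALSE]))

  structure(list(
    config = config,
    per_split = per_split,
    summary = summ,
    borda = borda,
    stability = stability,
    selected_fraction = sel_frac,
    selected_features = sel_feat,
    external = list(mcc = multiclass_mcc(cm_ext), acc = accuracy(cm_ext),
                    confusion = cm_ext, n = sum(cm_ext)),
    class_weights = w_full,
    n_samples = nrow(table$x), n_features = p,
    audit = list(external_n = length(sp$external_idx),
                 external_accesses = external_access,
                 external_idx = sp$external_idx,
                 train_n = nrow(train$x)),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "dap_report")
}

#' @export
print.dap_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Data Analysis Plan report (%s mode)\n%d samples x %d features; %dx%d-fold CV; head: %s\n\n",
    cfg$mode, x$n_samples, x$n_features, cfg$n_repeats, cfg$n_folds,
    cfg$classifier$kind))
  s <- x$summary
  cat("Internal cross-validation (mean with 95% studentized bootstrap CI):\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %4.0f%% features (%d): MCC %.3f [%.3f, %.3f]  ACC %.3f\n",
                100 * s$fraction[i], s$n_features[i], s$mcc_mean[i],
                s$mcc_lower[i], s$mcc_upper[i], s$acc_mean[i]))
  cat(sprintf("\nSelected fraction: %.0f%%; Canberra stability %.3f\n",
              100 * x$selected_fraction, x$stability$stability))
  cat(sprintf("External validation (n = %d): MCC %.3f, ACC %.3f\n",
              x$external$n, x$external$mcc, x$external$acc))
  invisible(x)
}

#' Summarize a Data Analysis Plan report
#'
#' @param object a \code{dap_report}.
#' @param ... ignored.
#' @return a list with the per-fraction summary table, the selected
#'   fraction, stability, top Borda features and the external metrics.
#' @export
summary.dap_report <- function(object, ...) {
  out <- list(mode = object$config$mode,
              internal = object$summary,
              selected_fraction = object$selected_fraction,
              stability = object$stability$stability,
              top_features = head(
                object$borda$feature_names[object$borda$ranking], 10),
              external_mcc = object$external$mcc,
              external_acc = object$external$acc)
  class(out) <- "summary.dap_report"
  out
}

#' @export
print.summary.dap_report <- function(x, ...) {
  cat(sprintf("DAP summary (%s mode)\n", x$mode))
  print(x$internal, row.names = FALSE)
  cat(sprintf(
    "selected fraction %.0f%%; stability %.3f; external MCC %.3f, ACC %.3f\n",
    100 * x$selected_fraction, x$stability, x$external_mcc, x$external_acc))
  cat("top features:", paste(x$top_features, collapse = ", "), "\n")
  invisible(x)
}

#' Plot internal-vs-external performance of a DAP run
#'
#' Mean internal MCC per feature fraction with its 95\% CI, and the
#' external MCC at the selected fraction.
#'
#' @param x a \code{dap_report}.
#' @param ... passed to \code{plot}.
#' @export
plot.dap_report <- function(x, ...) {
  s <- x$summary
  ylim <- range(c(s$mcc_lower, s$mcc_upper, x$external$mcc, 0), na.rm = TRUE)
  plot(100 * s$fraction, s$mcc_mean, type = "b", pch = 19,
       xlab = "% of ranked features", ylab = "MCC", ylim = ylim, ...)
  suppressWarnings(arrows(100 * s$fraction, s$mcc_lower,
                          100 * s$fraction, s$mcc_upper,
                          angle = 90, code = 3, length = 0.04))
  points(100 * x$selected_fraction, x$external$mcc, pch = 17, col = 2)
  legend("bottomright", pch = c(19, 17), col = c(1, 2), bty = "n",
         legend = c("internal CV mean (95% CI)", "external validation"))
  invisible(x)
}

#' Serialize a DAP report to JSON (plus per-split CSV)
#'
#' @param report a \code{dap_report}.
#' @param path output JSON path.
#' @param per_split_csv optional CSV path for the per-split metric records.
#' @param borda_csv optional CSV path for the Borda consensus
#'   (`rank,feature_name,mean_position`).
#' @return \code{path}, invisibly.
#' @export
write_dap_report <- function(report, path, per_split_csv = NULL,
                             borda_csv = NULL) {
  stopifnot(inherits(report, "dap_report"))
  cfg <- report$config
  obj <- list(
    config = list(mode = cfg$mode, n_repeats = cfg$n_repeats,
                  n_folds = cfg$n_folds,
                  feature_fractions = cfg$feature_fractions,
                  external_fraction = cfg$external_fraction,
                  classifier = cfg$classifier$kind, seed = cfg$seed,
                  n_boot = cfg$n_boot),
    internal = report$summary,
    selected_fraction = report$selected_fraction,
    stability = report$stability[c("stability", "mean_distance",
                                   "expected_random")],
    external = list(mcc = report$external$mcc, acc = report$external$acc,
                    n = report$external$n),
    audit = report$audit[c("external_n", "external_accesses", "train_n")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(per_split_csv))
    write.csv(report$per_split, per_split_csv, row.names = FALSE)
  if (!is.null(borda_csv)) {
    b <- report$borda
    write.csv(data.frame(rank = seq_along(b$ranking),
                         feature_name = b$feature_names[b$ranking],
                         mean_position = b$mean_position[b$ranking]),
              borda_csv, row.names = FALSE)
  }
  invisible(path)
}
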