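#' Confusion matrix from true and predicted labels
#'
#' Builds the N x N count matrix with \code{C[s, t]} = number of samples of
#' true class \code{s} predicted as class \code{t}, over the union of the
#' factor levels of both inputs.
#'
#' @param truth,predicted vectors of class labels (coerced to factors on a
#'   common level set).
#' @return an integer matrix with classes as dimnames.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  lev <- union(levels(factor(truth)), levels(factor(predicted)))
  table(factor(truth, levels = lev), factor(predicted, levels = lev),
        dnn = NULL)
}

.check_cm <- function(cm) {
  cm <- as.matrix(unclass(cm))
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix counts must be non-negative")
  if (sum(cm) == 0) stop("confusion matrix is empty")
  cm
}

#' Multiclass accuracy from a confusion matrix
#'
#' The fraction of correctly classified samples: the trace of the
#' confusion matrix divided by the total count.
#'
#' @param cm square count matrix (\code{C[s, t]} = true class s predicted
#'   as t).
#' @return a number in \code{[0, 1]}.
#' @export
accuracy <- function(cm) {
  cm <- .check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Multiclass Matthews correlation coefficient
#'
#' The multiclass generalization of the MCC computed directly from the
#' confusion matrix:
#' \deqn{MCC = \frac{c\,s - \sum_k p_k t_k}
#'   {\sqrt{s^2 - \sum_k p_k^2}\,\sqrt{s^2 - \sum_k t_k^2}}}
#' where \eqn{c} is the trace (correct predictions), \eqn{s} the total
#' count, \eqn{t_k} the number of samples of true class \eqn{k} and
#' \eqn{p_k} the number of predictions of class \eqn{k}.  This equals the
#' Pearson correlation between the vectorized one-of-N indicator encodings
#' of truth and prediction.  MCC = 1 is perfect classification, MCC = -1
#' extreme (binary) misclassification, and MCC = 0 is chance-level.  When a
#' marginal is degenerate (one of the square-root factors is 0) the MCC is
#' defined as 0: such a classifier is no better than random.
#'
#' @inheritParams accuracy
#' @return a number in \code{[-1, 1]}.
#' @export
multiclass_mcc <- function(cm) {
  cm <- .check_cm(cm)
  s <- sum(cm)
  c0 <- sum(diag(cm))
  tk <- rowSums(cm)   # true-class marginals
  pk <- colSums(cm)   # predicted-class marginals
  num <- c0 * s - sum(pk * tk)
  d1 <- s^2 - sum(pk^2)
  d2 <- s^2 - sum(tk^2)
  if (d1 <= 0 || d2 <= 0) return(0)
  num / sqrt(d1 * d2)
}

#' ANOVA F statistics and feature ranking
#'
#' Scores every feature with the one-way ANOVA F statistic over the class
#' labels (between-group mean square over within-group mean square) and
#' ranks features by decreasing F.  Tie-break is always ascending feature
#' index.  A feature with zero within-class variance but distinct class
#' means gets \code{F = +Inf} and ranks first; a feature constant across
#' all samples (0/0) ranks last.
#'
#' @param x numeric matrix, samples x features, or a [feature_table()].
#' @param label class labels (ignored when \code{x} is a feature table).
#' @return an object of class \code{ranked_list}: a list with
#'   \code{ranking} (feature indices, best first), \code{scores} (F per
#'   feature, in feature order) and \code{feature_names}.
#' @export
anova_f_rank <- function(x, label = NULL) {
  if (inherits(x, "feature_table")) { label <- x$label; x <- x$x }
  label <- droplevels(factor(label))
  k <- nlevels(label); n <- nrow(x)
  if (k < 2) stop("need at least 2 classes")
  nc <- tabulate(label, k)
  if (any(nc < 1)) stop("every class needs at least one sample")
  if (n - k < 1) stop("need more samples than classes")
  ind <- matrix(0, n, k); ind[cbind(seq_len(n), as.integer(label))] <- 1
  gm <- crossprod(ind, x) / nc            # class means, k x p
  grand <- colMeans(x)
  ssb <- colSums(nc * (gm - rep(grand, each = k))^2)
  sst <- colSums(x^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  zw <- ssw <= 1e-12 * (abs(sst) + 1)     # zero within-class variance
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[zw & ssb > 1e-12 * (abs(sst) + 1)] <- Inf
  f[zw & ssb <= 1e-12 * (abs(sst) + 1)] <- NaN  # constant feature: no signal
  ord <- order(-ifelse(is.nan(f), -Inf, f), seq_along(f))
  structure(list(ranking = ord, scores = f,
                 feature_names = colnames(x) %||%
                   sprintf("f%04d", seq_len(ncol(x)) - 1L)),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, n = 10, ...) {
  cat(sprintf("ranked_list of %d features; top %d:\n",
              length(x$ranking), min(n, length(x$ranking))))
  top <- head(x$ranking, n)
  print(data.frame(rank = seq_along(top), feature = x$feature_names[top],
                   score = x$scores[top]), row.names = FALSE)
  invisible(x)
}

# accept ranked_list objects or plain index vectors; return matrix of
# rank positions (n_features x n_lists): row i = position of feature i
.rank_positions <- function(lists) {
  perms <- lapply(lists, function(l) if (inherits(l, "ranked_list")) l$ranking else as.integer(l))
  n <- length(perms[[1]])
  for (p in perms)
    if (length(p) != n || !setequal(p, seq_len(n)))
      stop("all lists must be permutations of the same feature set")
  vapply(perms, function(p) { r <- integer(n); r[p] <- seq_len(n); r },
         integer(n))
}

#' Borda aggregation of ranked feature lists
#'
#' Fuses a collection of ranked lists into one consensus list by sorting
#' features on their mean rank position across lists (lower is better);
#' ties are broken by ascending feature index.
#'
#' @param lists a list of \code{ranked_list} objects or permutation
#'   vectors over the same feature set.
#' @param feature_names optional names for the report.
#' @return an object of class \code{borda_list}: list with \code{ranking},
#'   \code{mean_position} (per feature, in feature order) and
#'   \code{feature_names}.
#' @export
borda_aggregate <- function(lists, feature_names = NULL) {
  stopifnot(length(lists) >= 1)
  pos <- .rank_positions(lists)
  mp <- rowMeans(pos)
  ord <- order(mp, seq_along(mp))
  structure(list(ranking = ord, mean_position = mp,
                 feature_names = feature_names %||%
                   (if (inherits(lists[[1]], "ranked_list"))
                      lists[[1]]$feature_names
                    else sprintf("f%04d", seq_along(mp) - 1L))),
            class = c("borda_list"))
}

#' @export
print.borda_list <- function(x, n = 10, ...) {
  cat(sprintf("Borda consensus of %d features; top %d:\n",
              length(x$ranking), min(n, length(x$ranking))))
  top <- head(x$ranking, n)
  print(data.frame(rank = seq_along(top), feature = x$feature_names[top],
                   mean_position = x$mean_position[top]), row.names = FALSE)
  invisible(x)
}

# exact expected Canberra distance between two independent uniform random
# permutations of 1..n (ranks capped at k+1 for the top-k variant):
# E = (1/n) * sum_{s,t} |s'-t'| / (s'+t')
.expected_random_canberra <- function(n, top_k = NULL) {
  v <- seq_len(n)
  if (!is.null(top_k)) v <- pmin(v, top_k + 1L)
  tot <- 0
  for (s in v) tot <- tot + sum(abs(s - v) / (s + v))
  tot / n
}

#' Canberra stability of a collection of ranked lists
#'
#' Measures how much a set of ranked feature lists (e.g. the 50 per-split
#' rankings of a repeated cross-validation) disagree: the mean pairwise
#' Canberra distance between their rank-position vectors,
#' \eqn{d(a, b) = \sum_i |a_i - b_i| / (a_i + b_i)}, normalized by the
#' exact expected distance between two independent uniform random
#' permutations.  0 means the lists are identical; values near 1 mean the
#' rankings are as unstable as random.  Lower is better.  The optional
#' top-\code{k} variant caps all rank positions at \code{k + 1} so only
#' disagreement within the head of the lists counts.
#'
#' @param lists a list (length >= 2) of \code{ranked_list} objects or
#'   permutation vectors over the same feature set.
#' @param top_k optional head size for the truncated variant.
#' @return a list of class \code{canberra_stability} with
#'   \code{stability} (the normalized statistic), \code{mean_distance}
#'   (raw mean pairwise distance), \code{expected_random},
#'   \code{n_features} and \code{n_lists}.
#' @export
canberra_stability <- function(lists, top_k = NULL) {
  if (length(lists) < 2) stop("need at least 2 ranked lists")
  pos <- .rank_positions(lists)
  if (!is.null(top_k)) {
    stopifnot(top_k >= 1, top_k <= nrow(pos))
    pos <- pmin(pos, as.integer(top_k) + 1L)
  }
  m <- ncol(pos)
  tot <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    tot <- tot + sum(abs(pos[, i] - pos[, j]) / (pos[, i] + pos[, j]))
  mean_d <- tot / (m * (m - 1) / 2)
  e0 <- .expected_random_canberra(nrow(pos), top_k)
  structure(list(stability = mean_d / e0, mean_distance = mean_d,
                 expected_random = e0, n_features = nrow(pos),
                 n_lists = m),
            class = "canberra_stability")
}

#' @export
print.canberra_stability <- function(x, ...) {
  cat(sprintf(
    "Canberra stability: %.4f (raw mean distance %.2f, random expectation %.2f)\n%d lists x %d features; 0 = identical lists, ~1 = random\n",
    x$stability, x$mean_distance, x$expected_random, x$n_lists, x$n_features))
  invisible(x)
}

#' Studentized bootstrap confidence interval for a mean
#'
#' Bootstrap-t interval for the mean of a sample of performance values:
#' resample with replacement, form the studentized pivot
#' \eqn{(\bar{x}^*_b - \bar{x}) / \widehat{se}^*_b} with the analytic
#' standard error of the mean inside each resample, and invert the pivot
#' quantiles.  For a constant input the interval degenerates to
#' \code{[v, v]} with a warning (the pivot is undefined).  The interval is
#' widened to contain the point estimate in the (rare, finite-resample)
#' case where the pivot quantiles do not straddle zero.
#'
#' @param values numeric vector (e.g. 50 per-split MCC values).
#' @param level confidence level (default 0.95).
#' @param n_boot number of bootstrap resamples (default 1,000).
#' @param seed seed for the resampling.
#' @return a list of class \code{boot_ci}: \code{estimate}, \code{lower},
#'   \code{upper}, \code{level}, \code{n_boot}.
#' @export
studentized_bootstrap_ci <- function(values, level = 0.95, n_boot = 1000,
                                     seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  stopifnot(n >= 2, level > 0, level < 1, n_boot >= 2)
  est <- mean(values)
  if (var(values) == 0) {
    warning("constant input: studentization undefined, degenerate interval")
    return(structure(list(estimate = est, lower = est, upper = est,
                          level = level, n_boot = 0L), class = "boot_ci"))
  }
  se <- sd(values) / sqrt(n)
  piv <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    bx <- matrix(values[idx], n, n_boot)
    bm <- colMeans(bx)
    bse <- sqrt(pmax(colMeans(bx^2) - bm^2, 0) * n / (n - 1)) / sqrt(n)
    ifelse(bse > 0, (bm - est) / bse, 0)
  })
  a <- (1 - level) / 2
  q <- quantile(piv, c(1 - a, a), names = FALSE, type = 7)
  structure(list(estimate = est,
                 lower = min(est - q[1] * se, est),
                 upper = max(est - q[2] * se, est),
                 level = level, n_boot = as.integer(n_boot)),
            class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("%.4f  [%0.4f, %.4f]  (%.0f%% studentized bootstrap, B = %d)\n",
              x$estimate, x$lower, x$upper, 100 * x$level, x$n_boot))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' The weight of class \eqn{i} is \eqn{w_i = n_{max} / n_i}, where
#' \eqn{n_{max}} is the size of the largest class; the largest class always
#' has weight exactly 1.  Used to weight the classification loss under
#' class imbalance.
#'
#' @param class_counts named (or unnamed) vector of per-class counts, all
#'   >= 1.
#' @return a numeric vector of weights, same names and order as the input.
#' @examples
#' class_weights(c(C1 = 1009, C2 = 2424))
#' @export
class_weights <- function(class_counts) {
  counts <- as.numeric(class_counts)
  if (length(counts) == 0 || any(counts < 1))
    stop("all class counts must be >= 1")
  w <- max(counts) / counts
  names(w) <- names(class_counts)
  w
}
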