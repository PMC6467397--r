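# Independent oracles used across the test files.  These deliberately use
# naive loops / from-scratch formulas, never the package's own code paths.

# exhaustive Otsu: scan every threshold t in 0..254, maximize the
# between-class variance of the two groups {<= t}, {> t}
brute_force_otsu <- function(gray) {
  lv <- as.integer(pmin(pmax(round(gray), 0), 255))
  best_t <- -1L; best_v <- -Inf
  n <- length(lv)
  for (t in 0:254) {
    lo <- lv[lv <= t]; hi <- lv[lv > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / n; w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# pixels of a rasterized disk of radius r centered on a grid
disk_pixel_count <- function(r) {
  cnt <- 0L
  for (dy in -ceiling(r):ceiling(r))
    for (dx in -ceiling(r):ceiling(r))
      if (dy * dy + dx * dx <= r * r) cnt <- cnt + 1L
  cnt
}

# expand a confusion matrix into aligned truth/prediction label vectors
expand_cm <- function(cm) {
  truth <- character(0); pred <- character(0)
  cls <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  for (s in seq_len(nrow(cm))) for (t in seq_len(ncol(cm))) {
    k <- cm[s, t]
    if (k > 0) {
      truth <- c(truth, rep(cls[s], k))
      pred <- c(pred, rep(cls[t], k))
    }
  }
  list(truth = truth, pred = pred)
}

# multiclass MCC via per-class indicator covariances (sample expansion)
mcc_expansion_oracle <- function(cm) {
  e <- expand_cm(cm)
  cls <- sort(unique(c(e$truth, e$pred)))
  Ti <- sapply(cls, function(c) as.numeric(e$truth == c))
  Pi <- sapply(cls, function(c) as.numeric(e$pred == c))
  cxy <- sum(sapply(seq_along(cls), function(k) cov(Ti[, k], Pi[, k])))
  cxx <- sum(sapply(seq_along(cls), function(k) var(Ti[, k])))
  cyy <- sum(sapply(seq_along(cls), function(k) var(Pi[, k])))
  if (cxx == 0 || cyy == 0) return(0)
  cxy / sqrt(cxx * cyy)
}

# one-way ANOVA F by textbook sums of squares, one feature at a time
anova_f_oracle <- function(x, label) {
  label <- factor(label)
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    gm <- mean(v)
    ssb <- 0; ssw <- 0
    for (cl in levels(label)) {
      vi <- v[label == cl]
      ssb <- ssb + length(vi) * (mean(vi) - gm)^2
      ssw <- ssw + sum((vi - mean(vi))^2)
    }
    (ssb / (nlevels(label) - 1)) / (ssw / (length(v) - nlevels(label)))
  }, numeric(1))
}

# Borda by brute-force mean position
borda_oracle <- function(perms) {
  n <- length(perms[[1]])
  pos <- sapply(perms, function(p) match(seq_len(n), p))
  mp <- rowMeans(pos)
  order(mp, seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
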