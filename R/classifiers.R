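#' Classifier head specification
#'
#' The downstream predictor consuming the (adapted) feature vectors.  Three
#' kinds are supported, matching common practice for deep-feature
#' classification:
#' \describe{
#'   \item{\code{linear_max_margin}}{linear-kernel support vector machine,
#'     regularization constant \code{C} (default 1), class weights applied.}
#'   \item{\code{randomized_tree_ensemble}}{random forest with
#'     \code{n_trees} (default 500) trees, seeded, class weights applied.}
#'   \item{\code{feed_forward_head}}{fully connected network with hidden
#'     layers \code{hidden} (default \code{c(1000, 1000, 256)}) plus a
#'     softmax output over the classes, trained by Adam (fixed learning
#'     rate \code{1e-5}) on the class-weighted cross-entropy for
#'     \code{epochs} (default 50) epochs with mini-batches of
#'     \code{batch_size} (default 32).}
#' }
#'
#' @param kind one of \code{"linear_max_margin"},
#'   \code{"randomized_tree_ensemble"}, \code{"feed_forward_head"}.
#' @param ... kind-specific hyperparameters overriding the defaults above
#'   (\code{C}; \code{n_trees}; \code{hidden}, \code{learning_rate},
#'   \code{epochs}, \code{batch_size}).
#' @return an object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(kind = c("linear_max_margin",
                                     "randomized_tree_ensemble",
                                     "feed_forward_head"), ...) {
  kind <- match.arg(kind)
  hp <- switch(kind,
    linear_max_margin = list(C = 1),
    randomized_tree_ensemble = list(n_trees = 500),
    feed_forward_head = list(hidden = c(1000, 1000, 256),
                             learning_rate = 1e-5, epochs = 50,
                             batch_size = 32))
  dots <- list(...)
  bad <- setdiff(names(dots), names(hp))
  if (length(bad)) stop("unknown hyperparameter(s): ", paste(bad, collapse = ", "))
  hp[names(dots)] <- dots
  structure(c(list(kind = kind), hp), class = "classifier_spec")
}

#' Fit a classifier head
#'
#' Fits the head described by a [classifier_spec()] on a feature matrix.
#' Class weights (see [class_weights()]) enter the SVM and forest fits
#' through their native class-weighting and the feed-forward head through
#' the weighted cross-entropy loss.  Randomized heads are fully determined
#' by \code{seed}.
#'
#' @param spec a [classifier_spec()].
#' @param x numeric matrix, samples x features.
#' @param y class labels (factor).
#' @param weights optional named per-class weights; default
#'   \code{class_weights()} of the training counts.
#' @param seed integer seed.
#' @return an object of class \code{histodap_head} with a
#'   [predict.histodap_head()] method returning class labels.
#' @export
fit_head <- function(spec, x, y, weights = NULL, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes to fit a head")
  if (nrow(x) != length(y)) stop("features and labels must align")
  cnt <- table(y)
  weights <- weights %||% class_weights(cnt)
  if (is.null(names(weights))) names(weights) <- names(cnt)
  weights <- weights[levels(y)]
  fit <- switch(spec$kind,
    linear_max_margin = with_seed(seed,
      e1071::svm(x, y, kernel = "linear", cost = spec$C, scale = FALSE,
                 class.weights = weights)),
    randomized_tree_ensemble =
      ranger::ranger(x = x, y = y, num.trees = spec$n_trees,
                     seed = as.integer(seed), num.threads = 1,
                     class.weights = as.numeric(weights)),
    feed_forward_head = .fit_ffh(x, y, weights, spec, seed))
  structure(list(kind = spec$kind, fit = fit, levels = levels(y),
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "histodap_head")
}

#' Predict class labels from a fitted head
#'
#' @param object a fitted [fit_head()] object.
#' @param newdata numeric matrix with the same feature width as training.
#' @param ... ignored.
#' @return a factor of predicted class labels.
#' @export
predict.histodap_head <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("expected %d features, got %d", object$n_features,
                 ncol(newdata)))
  colnames(newdata) <- object$feature_names
  switch(object$kind,
    linear_max_margin = predict(object$fit, newdata),
    randomized_tree_ensemble =
      predict(object$fit, data = newdata, num.threads = 1)$predictions,
    feed_forward_head = .predict_ffh(object$fit, newdata))
}

#' @export
print.histodap_head <- function(x, ...) {
  cat(sprintf("histodap_head: %s over %d classes, %d features\n",
              x$kind, length(x$levels), x$n_features))
  invisible(x)
}

# ---- feed-forward head: dense ReLU layers + softmax, class-weighted
# cross-entropy, Adam at a fixed learning rate ----

.fit_ffh <- function(x, y, weights, spec, seed) {
  k <- nlevels(y)
  sizes <- c(ncol(x), spec$hidden, k)
  nl <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(nl), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(nl), function(l) rep(0, sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    lr <- spec$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    n <- nrow(x)
    yid <- as.integer(y)
    wsamp <- as.numeric(weights)[yid]
    step <- 0L
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        # forward
        acts <- vector("list", nl + 1); acts[[1]] <- xb
        for (l in seq_len(nl)) {
          z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
          acts[[l + 1]] <- if (l < nl) pmax(z, 0) else z
        }
        z <- acts[[nl + 1]]
        z <- z - apply(z, 1, max)
        p <- exp(z); p <- p / rowSums(p)
        # weighted cross-entropy gradient at the softmax input
        tgt <- matrix(0, length(idx), k)
        tgt[cbind(seq_along(idx), yid[idx])] <- 1
        wb <- wsamp[idx] / sum(wsamp[idx])
        delta <- (p - tgt) * wb
        step <- step + 1L
        for (l in nl:1) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
          }
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
          mhW <- mW[[l]] / (1 - b1^step); vhW <- vW[[l]] / (1 - b2^step)
          mhb <- mb[[l]] / (1 - b1^step); vhb <- vb[[l]] / (1 - b2^step)
          W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
    }
    list(W = W, b = b, levels = levels(y))
  })
}

.predict_ffh <- function(fit, x) {
  a <- as.matrix(x)
  nl <- length(fit$W)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+")
    a <- if (l < nl) pmax(z, 0) else z
  }
  factor(fit$levels[max.col(a, ties.method = "first")], levels = fit$levels)
}
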