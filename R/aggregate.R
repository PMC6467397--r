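#' Aggregate tile-level predictions to slide-level calls
#'
#' Each slide is called as the plurality (most common) class among the
#' predictions of its tiles.  Ties are broken deterministically toward the
#' lexicographically smallest class label and flagged.  The result is
#' invariant to the order of the input rows.
#'
#' @param predictions data frame with columns \code{slide_id},
#'   \code{predicted}, and optionally \code{tile_id} and \code{true}.
#' @return a data frame with one row per slide: \code{slide_id},
#'   \code{called}, \code{n_tiles}, \code{top_votes}, \code{tie}
#'   (logical), and \code{true} when available; attribute \code{votes}
#'   holds the full slide x class vote-count table.
#' @examples
#' aggregate_by_slide(data.frame(
#'   slide_id = c("s1", "s1", "s1", "s2", "s2"),
#'   predicted = c("A", "A", "B", "B", "B")))
#' @export
aggregate_by_slide <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("slide_id", "predicted") %in% names(predictions)))
  if (nrow(predictions) == 0) stop("no predictions to aggregate")
  if (any(!nzchar(as.character(predictions$slide_id))))
    stop("slide_id must be non-empty")
  votes <- base::table(slide_id = as.character(predictions$slide_id),
                       class = as.character(predictions$predicted))
  cls <- sort(colnames(votes))
  votes <- votes[, cls, drop = FALSE]
  top <- apply(votes, 1, max)
  # plurality; ties -> lexicographically smallest label (columns sorted)
  called <- cls[apply(votes, 1, which.max)]
  tie <- apply(votes, 1, function(v) sum(v == max(v)) > 1)
  out <- data.frame(slide_id = rownames(votes), called = called,
                    n_tiles = as.integer(rowSums(votes)),
                    top_votes = as.integer(top), tie = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  if ("true" %in% names(predictions)) {
    tr <- tapply(as.character(predictions$true),
                 as.character(predictions$slide_id),
                 function(v) {
                   u <- unique(v)
                   if (length(u) > 1) stop("inconsistent true class within a slide")
                   u
                 })
    out$true <- as.character(tr[out$slide_id])
  }
  attr(out, "votes") <- votes
  out
}

#' Slide-level performance as a function of tiles per slide
#'
#' For each requested number of tiles \code{n}, subsamples \code{n} tile
#' predictions per slide at random (seeded), aggregates them by plurality
#' vote, and scores the slide-level calls against the slide truth with
#' multiclass MCC and accuracy.  Slides with fewer than
#' \code{max(n_tiles_list)} predictions are excluded (with a warning and a
#' reported count) so every point of the curve uses the same slides.
#'
#' @param predictions data frame with \code{slide_id}, \code{predicted}
#'   and \code{true} columns.
#' @param n_tiles_list numbers of tiles per slide to evaluate
#'   (default \code{c(3, 5, 7, 10)}).
#' @param seed integer seed for the per-slide subsampling.
#' @return a data frame with one row per \code{n}: \code{n_tiles},
#'   \code{n_slides}, \code{mcc}, \code{acc}; attribute
#'   \code{n_excluded} gives the number of dropped slides.
#' @export
tiles_per_wsi_curve <- function(predictions, n_tiles_list = c(3, 5, 7, 10),
                                seed = 1L) {
  stopifnot(all(c("slide_id", "predicted", "true") %in% names(predictions)),
            all(n_tiles_list >= 1))
  sid <- as.character(predictions$slide_id)
  avail <- base::table(sid)
  need <- max(n_tiles_list)
  keep_slides <- names(avail)[avail >= need]
  n_excl <- sum(avail < need)
  if (n_excl > 0)
    warning(sprintf("excluded %d slide(s) with fewer than %d tiles",
                    n_excl, need))
  if (length(keep_slides) == 0) stop("no slide has enough tiles")
  keep <- sid %in% keep_slides
  preds <- predictions[keep, , drop = FALSE]
  sid <- sid[keep]
  by_slide <- split(seq_len(nrow(preds)), sid)
  out <- do.call(rbind, lapply(seq_along(n_tiles_list), function(k) {
    n <- n_tiles_list[k]
    idx <- with_seed(child_seed(seed, k), {
      unlist(lapply(by_slide, function(ii) ii[sample.int(length(ii), n)]))
    })
    calls <- aggregate_by_slide(preds[idx, , drop = FALSE])
    cm <- confusion_matrix(calls$true, calls$called)
    data.frame(n_tiles = n, n_slides = nrow(calls),
               mcc = multiclass_mcc(cm), acc = accuracy(cm))
  }))
  attr(out, "n_excluded") <- n_excl
  out
}

#' Simulate tile-level predictions with a known per-tile accuracy
#'
#' A vote simulator for studying plurality aggregation: every slide gets
#' one true class, and each of its tiles is predicted correctly with
#' probability \code{tile_accuracy}, errors being uniform over the other
#' classes.
#'
#' @param n_slides_per_class slides per class.
#' @param n_classes number of classes.
#' @param n_tiles tiles per slide.
#' @param tile_accuracy per-tile probability of a correct prediction.
#' @param seed integer seed.
#' @return a data frame with \code{slide_id}, \code{tile_id},
#'   \code{predicted}, \code{true}.
#' @export
simulate_tile_predictions <- function(n_slides_per_class = 15, n_classes = 20,
                                      n_tiles = 10, tile_accuracy = 0.8,
                                      seed = 1L) {
  stopifnot(n_slides_per_class >= 1, n_classes >= 2, n_tiles >= 1,
            tile_accuracy >= 0, tile_accuracy <= 1)
  cls <- sprintf("C%02d", seq_len(n_classes))
  slides <- data.frame(
    slide_id = sprintf("s%s_%03d", rep(cls, each = n_slides_per_class),
                       rep(seq_len(n_slides_per_class), n_classes)),
    true = rep(cls, each = n_slides_per_class), stringsAsFactors = FALSE)
  n_total <- nrow(slides) * n_tiles
  with_seed(seed, {
    true_tile <- rep(slides$true, each = n_tiles)
    correct <- runif(n_total) < tile_accuracy
    wrong <- vapply(true_tile, function(tc)
      sample(setdiff(cls, tc), 1), character(1))
    data.frame(slide_id = rep(slides$slide_id, each = n_tiles),
               tile_id = sprintf("t%05d", seq_len(n_total)),
               predicted = ifelse(correct, true_tile, wrong),
               true = true_tile, stringsAsFactors = FALSE)
  })
}
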