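#' Slide image container
#'
#' A thin container for a raster image (grayscale matrix or RGB array with
#' values in 0--255) plus slide-level metadata: the slide identifier and,
#' when known, the pixel size in microns per pixel.
#'
#' @param pixels numeric matrix (grayscale) or \code{nr x nc x 3} array (RGB).
#' @param mpp microns per pixel at this resolution, or \code{NULL}.
#' @param slide_id slide identifier string.
#' @return an object of class \code{slide_image}.
#' @export
slide_image <- function(pixels, mpp = NULL, slide_id = "slide") {
  if (is.null(dim(pixels)) || length(pixels) == 0)
    stop("pixels must be a non-empty matrix or array")
  nd <- length(dim(pixels))
  if (!(nd == 2 || (nd == 3 && dim(pixels)[3] == 3)))
    stop("pixels must be a grayscale matrix or an RGB array with 3 channels")
  structure(list(pixels = pixels, mpp = mpp, slide_id = as.character(slide_id)),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("slide_image '%s': %d x %d %s%s\n", x$slide_id, d[1], d[2],
              if (length(d) == 3) "RGB" else "grayscale",
              if (is.null(x$mpp)) "" else sprintf(", %.3f um/px", x$mpp)))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)

#' Read a PNG image into a slide_image
#'
#' @param path path to a PNG file.
#' @param mpp,slide_id metadata; \code{slide_id} defaults to the file stem.
#' @return a [slide_image()] with pixel values on the 0--255 scale.
#' @export
read_slide_image <- function(path, mpp = NULL, slide_id = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]   # drop alpha
    if (dim(px)[3] == 1) px <- px[, , 1]
  }
  slide_image(px * 255, mpp = mpp,
              slide_id = slide_id %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Write a slide_image (or plain matrix) as PNG
#'
#' @param image a [slide_image()], matrix or RGB array on the 0--255 scale.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_slide_image <- function(image, path) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  png::writePNG(pmin(pmax(px / 255, 0), 1), path)
  invisible(path)
}

#' Feature table: samples x features with labels and slide provenance
#'
#' The tabular container consumed by the Data Analysis Plan: a numeric
#' matrix of one row per sample (tile), a class label and a slide of origin
#' per row, and feature names.  No missing values are allowed.
#'
#' @param x numeric matrix, samples in rows.
#' @param label class label per row (coerced to factor).
#' @param slide_id slide of origin per row.
#' @param sample_id optional unique sample identifiers.
#' @param feature_names optional feature names (default \code{f0000...}).
#' @return an object of class \code{feature_table}.
#' @export
feature_table <- function(x, label, slide_id = NULL, sample_id = NULL,
                          feature_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (n == 0 || p == 0) stop("feature table must be non-empty")
  if (anyNA(x)) stop("feature table must not contain missing values")
  label <- factor(label)
  if (length(label) != n) stop("label length must match number of rows")
  slide_id <- as.character(slide_id %||% sprintf("s%05d", seq_len(n)))
  if (length(slide_id) != n) stop("slide_id length must match number of rows")
  sample_id <- as.character(sample_id %||% sprintf("t%05d", seq_len(n)))
  feature_names <- feature_names %||% sprintf("f%04d", seq_len(p) - 1L)
  stopifnot(length(sample_id) == n, length(feature_names) == p,
            !anyDuplicated(sample_id))
  colnames(x) <- feature_names
  structure(list(x = x, label = label, slide_id = slide_id,
                 sample_id = sample_id),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features, %d classes, %d slides\n",
              nrow(x$x), ncol(x$x), nlevels(x$label),
              length(unique(x$slide_id))))
  print(table(class = x$label))
  invisible(x)
}

#' Subset the rows of a feature table
#'
#' @param x a [feature_table()].
#' @param i row index vector.
#' @param ... ignored.
#' @return a [feature_table()] with the selected rows; factor levels are kept.
#' @export
`[.feature_table` <- function(x, i, ...) {
  ft <- feature_table(x$x[i, , drop = FALSE], x$label[i],
                      slide_id = x$slide_id[i], sample_id = x$sample_id[i],
                      feature_names = colnames(x$x))
  ft$label <- factor(ft$label, levels = levels(x$label))
  ft
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(sample_id = x$sample_id, slide_id = x$slide_id,
             label = as.character(x$label), x$x,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read a feature table as CSV
#'
#' The on-disk layout is `sample_id,slide_id,label,f0000..fNNNN` with one
#' header row.  Feature values are serialized at 9 significant digits
#' (single-precision fidelity); reading back a written table reproduces the
#' values at that precision.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return \code{path} (writer) or a [feature_table()] (reader).
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 9, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("sample_id", "slide_id", "label")
  if (!all(meta %in% names(df)))
    stop("feature table CSV must have sample_id, slide_id, label columns")
  feat <- setdiff(names(df), meta)
  feature_table(as.matrix(df[feat]), df$label, slide_id = df$slide_id,
                sample_id = df$sample_id, feature_names = feat)
}

#' Specification of a synthetic multiclass feature table
#'
#' Describes a planted-signal feature table emulating deep-feature matrices
#' extracted from tiles: each class has its own mean pattern on a small set
#' of informative features, all other features are pure unit-variance noise,
#' and consecutive tiles are grouped into slides that share one class label
#' (one tissue per slide).
#'
#' @param n_samples_per_class integer vector of per-class sample counts.
#' @param n_features total number of features.
#' @param n_informative number of informative features (<= n_features).
#' @param class_separation effect size: the s.d. of class means on
#'   informative features, in units of the noise s.d.  0 plants no signal.
#' @param n_tiles_per_slide consecutive tiles grouped per slide.
#' @param seed integer seed.
#' @return an object of class \code{feature_table_spec}.
#' @export
feature_table_spec <- function(n_samples_per_class = c(100, 100, 100, 100, 100),
                               n_features = 100, n_informative = 5,
                               class_separation = 5, n_tiles_per_slide = 10,
                               seed = 1L) {
  stopifnot(all(n_samples_per_class >= 1), n_features >= 1,
            n_informative >= 0, class_separation >= 0, n_tiles_per_slide >= 1)
  if (n_informative > n_features)
    stop("n_informative must not exceed n_features")
  structure(list(n_samples_per_class = as.integer(n_samples_per_class),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 class_separation = class_separation,
                 n_tiles_per_slide = as.integer(n_tiles_per_slide),
                 seed = as.integer(seed)),
            class = "feature_table_spec")
}

#' Generate a synthetic feature table with planted informative features
#'
#' Samples are standard normal noise on every feature; on the
#' \code{n_informative} planted features each class additionally receives its
#' own mean offset, drawn once per seed as
#' \code{class_separation * N(0, 1)}, so that \code{class_separation} is the
#' typical between-class mean difference in noise-s.d. units and scaling it
#' up never weakens the planted signal for a fixed seed.  The indices of the
#' planted features are returned as ground truth.
#'
#' @param spec a [feature_table_spec()].
#' @return a [feature_table()] with attributes \code{informative} (1-based
#'   planted feature indices) and \code{class_means} (the planted mean
#'   matrix, classes x informative features).
#' @examples
#' ft <- make_feature_table(feature_table_spec(
#'   n_samples_per_class = c(10, 10), n_features = 4, seed = 7))
#' dim(ft)
#' @export
make_feature_table <- function(spec) {
  if (!inherits(spec, "feature_table_spec"))
    stop("spec must be a feature_table_spec")
  k <- length(spec$n_samples_per_class)
  n <- sum(spec$n_samples_per_class)
  p <- spec$n_features
  inf_idx <- seq_len(spec$n_informative)
  with_seed(spec$seed, {
    mu <- matrix(rnorm(k * spec$n_informative) * spec$class_separation,
                 k, spec$n_informative)
    x <- matrix(rnorm(n * p), n, p)
  })
  label <- factor(rep(sprintf("C%d", seq_len(k)), spec$n_samples_per_class))
  if (spec$n_informative > 0) {
    cls <- as.integer(label)
    x[, inf_idx] <- x[, inf_idx, drop = FALSE] + mu[cls, , drop = FALSE]
  }
  # consecutive tiles of one class share a slide (one tissue per slide)
  slide_id <- unlist(lapply(seq_len(k), function(c) {
    nc <- spec$n_samples_per_class[c]
    sprintf("slide_C%d_%03d", c, (seq_len(nc) - 1L) %/% spec$n_tiles_per_slide + 1L)
  }))
  ft <- feature_table(x, label, slide_id = slide_id)
  attr(ft, "informative") <- if (spec$n_informative > 0) inf_idx else integer(0)
  attr(ft, "class_means") <- mu
  ft
}
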