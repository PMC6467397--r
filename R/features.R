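#' Data augmentation policy for tiles
#'
#' Augmentation at training time mirrors common practice for histology
#' tiles, where orientation carries no information: independent horizontal
#' and vertical flips, a uniform multiplicative rescale, and a crop to a
#' fixed size.
#'
#' @param p_hflip,p_vflip flip probabilities in \code{[0, 1]}.
#' @param scale_range \code{c(min, max)} multiplicative scale factors (> 0).
#' @param crop_size crop side in pixels, or \code{NULL} for no crop.
#' @param crop \code{"center"} or \code{"random"} crop placement.
#' @return an object of class \code{augmentation_policy}.
#' @export
augmentation_policy <- function(p_hflip = 0.5, p_vflip = 0.5,
                                scale_range = c(1, 1), crop_size = NULL,
                                crop = c("center", "random")) {
  stopifnot(p_hflip >= 0, p_hflip <= 1, p_vflip >= 0, p_vflip <= 1,
            length(scale_range) == 2, all(scale_range > 0),
            scale_range[1] <= scale_range[2])
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 scale_range = scale_range, crop_size = crop_size,
                 crop = match.arg(crop)),
            class = "augmentation_policy")
}

#' Apply a random augmentation to a tile
#'
#' Draws an independent horizontal flip, vertical flip and uniform scale,
#' then crops to the policy's crop size.  With flip probabilities 0, unit
#' scale range and no crop the transform is the identity.
#'
#' @param tile grayscale matrix (0--255).
#' @param policy an [augmentation_policy()].
#' @param seed optional seed; with a fixed seed the output is reproducible.
#' @return the augmented tile matrix.
#' @export
augment <- function(tile, policy, seed = NULL) {
  stopifnot(is.matrix(tile), inherits(policy, "augmentation_policy"))
  run <- function() {
    out <- tile
    if (runif(1) < policy$p_hflip) out <- out[, ncol(out):1, drop = FALSE]
    if (runif(1) < policy$p_vflip) out <- out[nrow(out):1, , drop = FALSE]
    s <- runif(1, policy$scale_range[1], policy$scale_range[2])
    if (s != 1) {
      out <- EBImage::resize(out, w = max(1, round(nrow(out) * s)),
                             h = max(1, round(ncol(out) * s)))
      out <- matrix(out, nrow = dim(out)[1])
    }
    if (!is.null(policy$crop_size)) {
      cs <- policy$crop_size
      if (cs > nrow(out) || cs > ncol(out))
        stop("crop size exceeds the scaled tile")
      if (policy$crop == "center") {
        r0 <- (nrow(out) - cs) %/% 2 + 1
        c0 <- (ncol(out) - cs) %/% 2 + 1
      } else {
        r0 <- sample.int(nrow(out) - cs + 1, 1)
        c0 <- sample.int(ncol(out) - cs + 1, 1)
      }
      out <- out[r0:(r0 + cs - 1), c0:(c0 + cs - 1), drop = FALSE]
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Feature extractor interface
#'
#' An extractor maps a tile image to a fixed-width real vector.  Deep
#' convolutional backbones plug in through this interface; the package
#' ships [reference_extractor()], a deterministic hand-computable
#' descriptor, so the whole pipeline is testable without pretrained
#' weights.
#'
#' @param name extractor name.
#' @param output_width the constant output width.
#' @param extract function(tile) returning a numeric vector of
#'   \code{output_width} reals.
#' @return an object of class \code{feature_extractor}.
#' @export
feature_extractor <- function(name, output_width, extract) {
  stopifnot(is.character(name), output_width >= 1, is.function(extract))
  structure(list(name = name, output_width = as.integer(output_width),
                 extract = extract),
            class = "feature_extractor")
}

#' Reference tile descriptor
#'
#' A deterministic, documented descriptor of width 38 computed on the
#' grayscale tile:
#' \itemize{
#'   \item 16 intensity-histogram proportions over equal bins of
#'     \code{[0, 256)} (positions 1--16);
#'   \item 6 gradient-magnitude statistics — mean, s.d., quartiles
#'     (25/50/75\%) and maximum of
#'     \eqn{\sqrt{g_x^2 + g_y^2}} from forward differences (positions
#'     17--22);
#'   \item 16 block means over a 4 x 4 grid of equal-as-possible blocks, in
#'     row-major block order (positions 23--38).
#' }
#' Histogram components are invariant to flips; a constant tile has all its
#' histogram mass in one bin and zero gradient statistics.
#'
#' @param tile grayscale matrix or RGB array (0--255); RGB is converted to
#'   luminance first so the width is constant.
#' @return a named numeric vector of length 38.
#' @seealso [make_reference_extractor()]
#' @export
reference_extractor <- function(tile) {
  g <- to_grayscale(tile)
  h <- tabulate(pmin(floor(pmin(pmax(g, 0), 255) / 16), 15) + 1L,
                nbins = 16L) / length(g)
  gx <- g[, -1, drop = FALSE] - g[, -ncol(g), drop = FALSE]
  gy <- g[-1, , drop = FALSE] - g[-nrow(g), , drop = FALSE]
  mag <- sqrt(gx[-nrow(gx), , drop = FALSE]^2 + gy[, -ncol(gy), drop = FALSE]^2)
  gs <- if (length(mag) == 0) rep(0, 6) else
    c(mean(mag), if (length(mag) > 1) sd(mag) else 0,
      quantile(mag, c(.25, .5, .75), names = FALSE), max(mag))
  rb <- cut(seq_len(nrow(g)), 4, labels = FALSE)
  cb <- cut(seq_len(ncol(g)), 4, labels = FALSE)
  bm <- as.vector(t(tapply(g, list(rb[row(g)], cb[col(g)]), mean)))
  out <- c(h, gs, bm)
  names(out) <- c(sprintf("hist%02d", 1:16),
                  c("grad_mean", "grad_sd", "grad_q25", "grad_q50",
                    "grad_q75", "grad_max"),
                  sprintf("block%02d", 1:16))
  out
}

#' @rdname reference_extractor
#' @return \code{make_reference_extractor()}: a [feature_extractor()]
#'   wrapping the descriptor.
#' @export
make_reference_extractor <- function() {
  feature_extractor("reference", 38L, reference_extractor)
}

#' Width-normalizing affine adapter
#'
#' Different extractors emit different widths; the adapter is an affine map
#' to a fixed width (1,000 by default) so every downstream head sees the
#' same input size.  For non-neural heads the adapter is a fixed seeded
#' random projection (entries \eqn{N(0, 1/\sqrt{d_{in}})}); the
#' \code{"identity"} method zero-pads or truncates instead, which is the
#' exact identity when the widths already agree.  For the neural head the
#' adapter can be trained jointly with the head (see [fit_head()]).
#'
#' @param input_width extractor output width.
#' @param output_width adapter output width (default 1,000).
#' @param method \code{"random_projection"} or \code{"identity"}.
#' @param seed seed for the random projection.
#' @return an object of class \code{adapter} with fields \code{weights}
#'   (\code{output_width x input_width}) and \code{bias}.
#' @export
make_adapter <- function(input_width, output_width = 1000,
                         method = c("random_projection", "identity"),
                         seed = 1L) {
  method <- match.arg(method)
  stopifnot(input_width >= 1, output_width >= 1)
  w <- if (method == "identity") {
    m <- matrix(0, output_width, input_width)
    d <- min(input_width, output_width)
    m[cbind(1:d, 1:d)] <- 1
    m
  } else {
    with_seed(seed,
      matrix(rnorm(output_width * input_width, sd = 1 / sqrt(input_width)),
             output_width, input_width))
  }
  structure(list(weights = w, bias = rep(0, output_width), method = method,
                 input_width = as.integer(input_width),
                 output_width = as.integer(output_width)),
            class = "adapter")
}

#' Apply an adapter to a feature vector
#'
#' @param v numeric vector of length \code{adapter$input_width}.
#' @param adapter an [make_adapter()] object.
#' @return a numeric vector of length \code{adapter$output_width}.
#' @export
adapt <- function(v, adapter) {
  stopifnot(inherits(adapter, "adapter"))
  if (length(v) != adapter$input_width)
    stop(sprintf("adapter expects width %d, got %d",
                 adapter$input_width, length(v)))
  drop(adapter$weights %*% as.numeric(v)) + adapter$bias
}

#' Build a feature table from a tile manifest
#'
#' Reads every tile listed in a manifest, applies the extractor and the
#' adapter, and assembles the [feature_table()] the Data Analysis Plan
#' consumes.  Inference is augmentation-free by default; pass a policy to
#' augment each tile once before extraction (training-style loading).
#' Unreadable tiles are skipped with a warning and recorded in the
#' \code{skipped} attribute, never silently dropped.
#'
#' @param manifest a data frame (or CSV path) with columns
#'   \code{slide_id}, \code{tile_path} and \code{label}.
#' @param extractor a [feature_extractor()]
#'   (default [make_reference_extractor()]).
#' @param adapter an [make_adapter()] object, or \code{NULL} to build a
#'   seeded random projection from the extractor width to
#'   \code{adapter_width}.
#' @param adapter_width used when \code{adapter} is NULL (default 1,000).
#' @param augment_policy optional [augmentation_policy()] applied per tile.
#' @param seed seed for adapter construction and augmentation draws.
#' @return a [feature_table()]; attribute \code{skipped} lists unreadable
#'   tile paths.
#' @export
build_feature_table <- function(manifest,
                                extractor = make_reference_extractor(),
                                adapter = NULL, adapter_width = 1000,
                                augment_policy = NULL, seed = 1L) {
  if (is.character(manifest)) manifest <- read.csv(manifest,
                                                   stringsAsFactors = FALSE)
  stopifnot(all(c("slide_id", "tile_path", "label") %in% names(manifest)))
  adapter <- adapter %||% make_adapter(extractor$output_width, adapter_width,
                                       seed = child_seed(seed, 1))
  n <- nrow(manifest)
  rows <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    tile <- tryCatch(to_grayscale(read_slide_image(manifest$tile_path[i])),
                     error = function(e) NULL)
    if (is.null(tile)) next
    if (!is.null(augment_policy))
      tile <- augment(tile, augment_policy, seed = child_seed(seed, 100 + i))
    rows[[i]] <- adapt(extractor$extract(tile), adapter)
    keep[i] <- TRUE
  }
  if (!all(keep)) {
    skipped <- manifest$tile_path[!keep]
    warning(sprintf("skipped %d unreadable tile(s): %s", length(skipped),
                    paste(head(skipped, 3), collapse = ", ")))
  } else skipped <- character(0)
  if (!any(keep)) stop("no readable tiles in manifest")
  ft <- feature_table(do.call(rbind, rows[keep]),
                      manifest$label[keep],
                      slide_id = manifest$slide_id[keep],
                      sample_id = make.unique(
                        sub("\\.[^.]+$", "", basename(manifest$tile_path[keep]))))
  attr(ft, "skipped") <- skipped
  attr(ft, "extractor") <- extractor$name
  ft
}
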