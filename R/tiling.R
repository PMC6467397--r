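#' Convert an image to grayscale
#'
#' RGB input is collapsed with the Rec. 601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale input is returned unchanged,
#' so the operation is idempotent.
#'
#' @param image a [slide_image()], grayscale matrix or RGB array (0--255).
#' @return a numeric matrix on the 0--255 scale.
#' @export
to_grayscale <- function(image) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  if (is.null(dim(px)) || length(px) == 0) stop("empty image")
  if (length(dim(px)) == 2) return(px)
  if (dim(px)[3] != 3) stop("RGB image must have exactly 3 channels")
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Otsu threshold of a grayscale image
#'
#' Finds the integer threshold \code{t} in 0--254 maximizing the
#' between-class variance of the gray-level histogram (pixels are binned to
#' integer levels 0--255).  Ties are broken toward the lowest threshold.
#' In H&E histology the tissue is dark on a light background, so the
#' foreground (tissue) side of the threshold is \code{gray <= t}.
#'
#' @param gray numeric matrix on the 0--255 scale.
#' @return the threshold, a number in \code{[0, 254]}, with attribute
#'   \code{separability}: the fraction of total gray-level variance explained
#'   by the two classes (Otsu's effectiveness metric, in \code{[0, 1]}).
#' @export
otsu_threshold <- function(gray) {
  lv <- as.integer(pmin(pmax(round(gray), 0), 255))
  if (length(unique(lv)) < 2)
    stop("no threshold exists: image has a single gray level")
  h <- as.double(tabulate(lv + 1L, nbins = 256L))
  w <- cumsum(h)                    # pixels at level <= t
  m <- cumsum(h * (0:255))          # intensity mass at level <= t
  n <- w[256]; mt <- m[256]
  w0 <- w[1:255]; m0 <- m[1:255]
  valid <- w0 > 0 & w0 < n
  # between-class variance sigma_B^2(t) = w0 w1 (mu0 - mu1)^2 / n^2
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mt * w0[valid] - n * m0[valid])^2 /
    (as.double(w0[valid]) * (n - w0[valid]))
  t_best <- which.max(bcv) - 1L
  tot_var <- sum(h * ((0:255) - mt / n)^2)
  structure(t_best,
            separability = (bcv[t_best + 1L] / n^2) / (tot_var / n))
}

#' Binarize a grayscale image by Otsu's method
#'
#' @inheritParams otsu_threshold
#' @return a list with \code{mask} (logical matrix, TRUE = foreground =
#'   dark/tissue side), \code{threshold} and \code{separability}.
#' @export
otsu_binarize <- function(gray) {
  t <- otsu_threshold(gray)
  list(mask = round(gray) <= as.numeric(t), threshold = as.numeric(t),
       separability = attr(t, "separability"))
}

# disk structuring element: pixels at Euclidean distance <= r from center
.disk_kernel <- function(radius) {
  r <- as.integer(radius)
  n <- 2L * r + 1L
  d2 <- outer((-r:r)^2, (-r:r)^2, "+")
  matrix(as.numeric(d2 <= radius^2), n, n)
}

#' Morphological refinement of a tissue mask
#'
#' Dilates the binary mask with a disk structuring element (pixels within
#' Euclidean distance \code{dilation_radius} of the center), then fills all
#' enclosed holes.  The output always contains the input, and re-applying
#' the hole fill is a no-op.
#'
#' @param mask logical matrix.
#' @param dilation_radius disk radius in pixels; 0 skips the dilation.
#' @return a logical matrix of the same size.
#' @export
refine_mask <- function(mask, dilation_radius = 5) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  if (!any(m)) return(m)
  out <- if (dilation_radius > 0)
    EBImage::dilate(m * 1, .disk_kernel(dilation_radius)) > 0 else m
  EBImage::fillHull(out * 1) > 0
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default) neighbour connectivity.
#' @return an integer matrix; 0 = background, components numbered 1..k in
#'   raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- mask != 0
  idx <- which(m)
  lab <- matrix(0L, nrow(m), ncol(m))
  if (length(idx) == 0) return(lab)
  nr <- nrow(m)
  pos <- matrix(NA_integer_, nrow(m), ncol(m))
  pos[idx] <- seq_along(idx)
  offs <- if (connectivity == 4) list(c(1, 0), c(0, 1)) else
    list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))
  edges <- integer(0)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 <= ncol(m)
    if (!any(ok)) next
    nb <- pos[cbind(r2[ok], c2[ok])]
    hit <- !is.na(nb)
    if (any(hit))
      edges <- c(edges, rbind(pos[idx[ok]][hit], nb[hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by raster order (row-major) of their first pixel
  raster <- order(r, cc)
  first_seen <- comp[raster][!duplicated(comp[raster])]
  relabel <- integer(max(comp)); relabel[first_seen] <- seq_along(first_seen)
  lab[idx] <- relabel[comp]
  lab
}

#' Select the largest connected tissue region and its bounding box
#'
#' Among the connected components of a refined mask, keeps the one with the
#' most pixels (ties broken by the component whose first pixel comes first
#' in raster order, which is also the component numbering order) and
#' computes its tight axis-aligned bounding box.
#'
#' @param mask logical matrix (typically the output of [refine_mask()]).
#' @param connectivity 4 or 8 (default).
#' @param scale thumbnail-to-full-resolution scale factor carried as
#'   metadata.
#' @return an object of class \code{tissue_mask}: a list with \code{mask}
#'   (logical matrix of the selected region only), \code{bbox}
#'   (\code{c(row_min, col_min, row_max, col_max)}, 1-based inclusive, in
#'   thumbnail pixels), \code{scale}, \code{n_regions} and \code{area}.
#' @export
largest_region_bbox <- function(mask, connectivity = 8, scale = 1) {
  if (!any(mask != 0)) stop("no tissue detected: mask is empty")
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))[1]   # ties: lowest label = raster order
  sel <- lab == best
  rows <- which(rowSums(sel) > 0); cols <- which(colSums(sel) > 0)
  structure(list(mask = sel,
                 bbox = c(row_min = min(rows), col_min = min(cols),
                          row_max = max(rows), col_max = max(cols)),
                 scale = scale, n_regions = length(sizes),
                 area = sizes[best]),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf(
    "tissue_mask: %d px region (of %d regions), bbox [%d,%d]-[%d,%d], scale %gx\n",
    x$area, x$n_regions, x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4], x$scale))
  invisible(x)
}

# nearest-neighbour downsample of a grayscale matrix by integer-ish factor
.downsample <- function(gray, factor) {
  if (factor <= 1) return(gray)
  ri <- round(seq(1, nrow(gray), by = factor))
  ci <- round(seq(1, ncol(gray), by = factor))
  gray[ri, ci, drop = FALSE]
}

#' Detect the tissue region of a slide
#'
#' The full detection pipeline applied to a slide thumbnail: grayscale
#' conversion, Otsu binarization (tissue = dark side), disk dilation plus
#' hole filling, and selection of the largest connected region with its
#' bounding box.
#'
#' @param slide a [slide_image()] (or matrix/array).
#' @param downsample thumbnail downsample factor relative to the slide as
#'   given (1 = run detection at native resolution).
#' @param dilation_radius disk radius in thumbnail pixels.
#' @param connectivity 4 or 8.
#' @return a \code{tissue_mask} (see [largest_region_bbox()]) with the
#'   slide-level Otsu threshold attached as attribute \code{threshold}.
#' @export
detect_tissue <- function(slide, downsample = 32, dilation_radius = 5,
                          connectivity = 8) {
  gray <- .downsample(to_grayscale(slide), downsample)
  ob <- otsu_binarize(gray)
  tm <- largest_region_bbox(refine_mask(ob$mask, dilation_radius),
                            connectivity, scale = downsample)
  attr(tm, "threshold") <- ob$threshold
  tm
}

# tissue fraction of one tile: tile-local Otsu when the tile histogram is
# convincingly bimodal, otherwise classify with the slide-level threshold
.tile_tissue_fraction <- function(tile_gray, slide_threshold,
                                  min_separability = 0.8) {
  f_slide <- mean(round(tile_gray) <= slide_threshold)
  ob <- tryCatch(otsu_binarize(tile_gray), error = function(e) NULL)
  if (is.null(ob) || ob$separability < min_separability) return(f_slide)
  mean(ob$mask)
}

#' Randomly sample mostly-tissue tiles from a slide
#'
#' Draws candidate tile origins uniformly at random inside the tissue
#' bounding box (mapped to full resolution), evaluates the tissue fraction
#' of each candidate by re-applying the detection criterion to the tile
#' itself, and keeps the tile iff its tissue fraction reaches
#' \code{min_tissue_fraction}.  Sampling stops when \code{max_tiles} tiles
#' are accepted or the attempt budget (\code{attempt_factor * max_tiles}
#' draws) is exhausted.  On a tile whose gray-level histogram is not
#' convincingly bimodal (e.g. all tissue or all background) the slide-level
#' Otsu threshold classifies the pixels instead of a tile-local one.
#'
#' @param slide a [slide_image()].
#' @param tissue_mask a \code{tissue_mask} from [detect_tissue()].
#' @param max_tiles maximum number of tiles to accept.
#' @param tile_size tile side in full-resolution pixels.
#' @param min_tissue_fraction acceptance threshold in \code{[0, 1]}.
#' @param seed integer seed for the origin draws.
#' @param attempt_factor attempt budget multiplier.
#' @param min_separability bimodality cutoff for using a tile-local
#'   threshold (Otsu effectiveness metric).
#' @return an object of class \code{tile_set}: list with \code{tiles}
#'   (list of grayscale matrices), \code{origins} (n x 2 matrix of 1-based
#'   top-left row/col at full resolution), \code{tissue_fraction},
#'   \code{slide_id}, and \code{warning} (NULL, or a message when the box
#'   is smaller than a tile, in which case the set is empty).
#' @export
sample_tiles <- function(slide, tissue_mask, max_tiles = 100, tile_size = 512,
                         min_tissue_fraction = 0.85, seed = 1L,
                         attempt_factor = 50, min_separability = 0.8) {
  if (tile_size <= 0) stop("tile_size must be positive")
  if (min_tissue_fraction < 0 || min_tissue_fraction > 1)
    stop("min_tissue_fraction must be in [0, 1]")
  stopifnot(inherits(tissue_mask, "tissue_mask"))
  gray <- to_grayscale(slide)
  sc <- tissue_mask$scale
  bb <- tissue_mask$bbox
  # bbox mapped to full resolution (1-based inclusive)
  r0 <- (bb[1] - 1) * sc + 1; r1 <- min(bb[3] * sc, nrow(gray))
  c0 <- (bb[2] - 1) * sc + 1; c1 <- min(bb[4] * sc, ncol(gray))
  empty <- function(msg) structure(
    list(tiles = list(), origins = matrix(numeric(0), 0, 2,
                                          dimnames = list(NULL, c("row", "col"))),
         tissue_fraction = numeric(0), slide_id = slide$slide_id,
         warning = msg),
    class = "tile_set")
  if (r1 - r0 + 1 < tile_size || c1 - c0 + 1 < tile_size)
    return(empty("tissue bounding box smaller than tile size"))
  thr <- attr(tissue_mask, "threshold") %||% otsu_binarize(gray)$threshold
  budget <- ceiling(attempt_factor * max_tiles)
  tiles <- vector("list", max_tiles)
  origins <- matrix(NA_real_, max_tiles, 2,
                    dimnames = list(NULL, c("row", "col")))
  fracs <- numeric(max_tiles)
  n_acc <- 0L
  with_seed(seed, {
    for (a in seq_len(budget)) {
      orow <- floor(runif(1, r0, r1 - tile_size + 2))
      ocol <- floor(runif(1, c0, c1 - tile_size + 2))
      tile <- gray[orow:(orow + tile_size - 1), ocol:(ocol + tile_size - 1)]
      f <- .tile_tissue_fraction(tile, thr, min_separability)
      if (f >= min_tissue_fraction) {
        n_acc <- n_acc + 1L
        tiles[[n_acc]] <- tile
        origins[n_acc, ] <- c(orow, ocol)
        fracs[n_acc] <- f
        if (n_acc >= max_tiles) break
      }
    }
  })
  structure(list(tiles = tiles[seq_len(n_acc)],
                 origins = origins[seq_len(n_acc), , drop = FALSE],
                 tissue_fraction = fracs[seq_len(n_acc)],
                 slide_id = slide$slide_id, warning = NULL),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("tile_set from '%s': %d tiles", x$slide_id, length(x$tiles)))
  if (length(x$tiles))
    cat(sprintf(", tissue fraction %.2f-%.2f",
                min(x$tissue_fraction), max(x$tissue_fraction)))
  if (!is.null(x$warning)) cat(" [", x$warning, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.tile_set <- function(x) length(x$tiles)

#' Write a tile set to PNG files with a CSV manifest
#'
#' Tiles are written as `{slide_id}_{index}_{row}_{col}.png` and listed in a
#' manifest CSV (`slide_id,tile_path,row,col,tissue_fraction`) that the
#' feature stage consumes.
#'
#' @param tile_set a \code{tile_set} from [sample_tiles()].
#' @param dir output directory (created if needed).
#' @param manifest manifest CSV path (default `manifest.csv` inside `dir`);
#'   appended to if it already exists.
#' @return the manifest path, invisibly.
#' @export
write_tiles <- function(tile_set, dir, manifest = file.path(dir, "manifest.csv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(tile_set$tiles)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d_%d_%d.png", tile_set$slide_id,
                                       i, tile_set$origins[i, 1],
                                       tile_set$origins[i, 2]))
    write_slide_image(tile_set$tiles[[i]], paths[i])
  }
  df <- data.frame(slide_id = rep(tile_set$slide_id, n), tile_path = paths,
                   row = tile_set$origins[, 1], col = tile_set$origins[, 2],
                   tissue_fraction = tile_set$tissue_fraction)
  write.table(df, manifest, sep = ",", row.names = FALSE,
              col.names = !file.exists(manifest), append = file.exists(manifest),
              quote = FALSE)
  invisible(manifest)
}
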