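#' Specification of a synthetic slide phantom
#'
#' A phantom emulates the thumbnail of an H&E-stained whole-slide image:
#' dark tissue blobs on a light background, with optional holes (tears,
#' fat vacuoles) carved out of the blobs.  Blobs carry band-limited texture
#' so that thresholding sees a realistic, not degenerate, gray-level
#' histogram.
#'
#' @param width,height image size in pixels.
#' @param background_level background gray value in \code{[0, 255]}; must be
#'   strictly lighter than every blob mean.
#' @param blobs list of blobs, each a list with elements \code{center}
#'   (\code{c(row, col)}), \code{radius} (pixels, > 0), \code{mean}
#'   (gray value) and \code{texture} (additive texture amplitude, gray
#'   levels; 0 for a flat blob).
#' @param holes list of holes, each a list with \code{center} and
#'   \code{radius}; hole pixels revert to the background level and are not
#'   tissue in the ground truth.
#' @param texture_grain spatial scale (pixels) of the band-limited texture.
#' @param seed integer seed for the texture noise.
#' @return an object of class \code{slide_phantom_spec}.
#' @seealso [make_slide_phantom()]
#' @export
slide_phantom_spec <- function(width = 512, height = 512,
                               background_level = 235,
                               blobs = list(list(center = c(height / 2, width / 2),
                                                 radius = min(width, height) / 4,
                                                 mean = 110, texture = 15)),
                               holes = list(),
                               texture_grain = 8,
                               seed = 1L) {
  stopifnot(width >= 1, height >= 1,
            background_level >= 0, background_level <= 255,
            length(blobs) >= 1, texture_grain >= 1)
  for (b in blobs) {
    stopifnot(length(b$center) == 2, b$radius > 0,
              b$mean >= 0, b$mean <= 255, b$texture >= 0)
    if (b$mean >= background_level)
      stop("every blob mean must be strictly darker than background_level")
  }
  for (h in holes) stopifnot(length(h$center) == 2, h$radius > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_level = background_level, blobs = blobs,
                 holes = holes, texture_grain = texture_grain,
                 seed = as.integer(seed)),
            class = "slide_phantom_spec")
}

# band-limited noise: white noise on a coarse grid, bilinearly upsampled
.texture_field <- function(nr, nc, grain) {
  gr <- max(2L, ceiling(nr / grain) + 1L)
  gc <- max(2L, ceiling(nc / grain) + 1L)
  coarse <- matrix(rnorm(gr * gc), gr, gc)
  ry <- seq(1, gr, length.out = nr)
  rx <- seq(1, gc, length.out = nc)
  y0 <- pmin(floor(ry), gr - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), gc - 1L); fx <- rx - x0
  a <- coarse[cbind(rep(y0, nc), rep(x0, each = nr))]
  b <- coarse[cbind(rep(y0 + 1, nc), rep(x0, each = nr))]
  cc <- coarse[cbind(rep(y0, nc), rep(x0 + 1, each = nr))]
  d <- coarse[cbind(rep(y0 + 1, nc), rep(x0 + 1, each = nr))]
  wfy <- rep(fy, nc); wfx <- rep(fx, each = nr)
  matrix(a * (1 - wfy) * (1 - wfx) + b * wfy * (1 - wfx) +
           cc * (1 - wfy) * wfx + d * wfy * wfx, nr, nc)
}

.disk_mask <- function(nr, nc, center, radius) {
  dy <- (seq_len(nr) - center[1])^2
  dx <- (seq_len(nc) - center[2])^2
  outer(dy, dx, "+") <= radius^2
}

#' Generate a synthetic slide phantom with exact ground truth
#'
#' Renders the phantom described by a [slide_phantom_spec()] and returns,
#' alongside the image, the exact tissue mask (blob pixels with holes carved
#' out), the hole-filled mask, and the identity and bounding box of the
#' largest tissue region.  Overlapping blobs are merged into one region;
#' regions are compared by hole-filled pixel count (ties broken by the first
#' pixel in raster order).  Identical spec and seed give bit-identical
#' output.
#'
#' @param spec a [slide_phantom_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{image}{a [slide_image()] (grayscale matrix, values 0--255)}
#'     \item{mask}{logical matrix; tissue truth, holes carved out}
#'     \item{mask_filled}{logical matrix; tissue truth with holes filled}
#'     \item{largest_mask}{logical matrix for the largest region (filled)}
#'     \item{largest_bbox}{\code{c(row_min, col_min, row_max, col_max)},
#'       1-based inclusive}
#'   }
#' @examples
#' ph <- make_slide_phantom(slide_phantom_spec(width = 128, height = 128,
#'   blobs = list(list(center = c(64, 64), radius = 40, mean = 100, texture = 10))))
#' sum(ph$mask)
#' @export
make_slide_phantom <- function(spec) {
  if (!inherits(spec, "slide_phantom_spec"))
    stop("spec must be a slide_phantom_spec")
  nr <- spec$height; nc <- spec$width
  img <- matrix(spec$background_level, nr, nc)
  blob_masks <- lapply(spec$blobs, function(b)
    .disk_mask(nr, nc, b$center, b$radius))
  filled <- Reduce(`|`, blob_masks)
  with_seed(spec$seed, {
    for (i in seq_along(spec$blobs)) {
      b <- spec$blobs[[i]]
      m <- blob_masks[[i]]
      img[m] <- b$mean
      if (b$texture > 0) {
        tex <- .texture_field(nr, nc, spec$texture_grain) * b$texture
        img[m] <- img[m] + tex[m]
      }
    }
  })
  mask <- filled
  for (h in spec$holes) {
    hm <- .disk_mask(nr, nc, h$center, h$radius) & filled
    img[hm] <- spec$background_level
    mask <- mask & !hm
  }
  img <- pmin(pmax(img, 0), 255)

  # merge blobs whose disks intersect into regions (analytic union-find)
  k <- length(spec$blobs)
  grp <- seq_len(k)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      bi <- spec$blobs[[i]]; bj <- spec$blobs[[j]]
      if (sqrt(sum((bi$center - bj$center)^2)) <= bi$radius + bj$radius)
        grp[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  region_masks <- lapply(unique(roots), function(r)
    Reduce(`|`, blob_masks[roots == r]))
  areas <- vapply(region_masks, sum, numeric(1))
  first_px <- vapply(region_masks, function(m) which(t(m))[1], numeric(1))
  best <- order(-areas, first_px)[1]
  lm <- region_masks[[best]]
  rows <- which(rowSums(lm) > 0); cols <- which(colSums(lm) > 0)
  list(image = slide_image(img, slide_id = "phantom"),
       mask = mask, mask_filled = filled, largest_mask = lm,
       largest_bbox = c(row_min = min(rows), col_min = min(cols),
                        row_max = max(rows), col_max = max(cols)))
}
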