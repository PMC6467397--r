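test_that("grayscale conversion is luminance-weighted and idempotent", {
  white <- array(255, c(4, 4, 3))
  expect_true(all(to_grayscale(white) == 255))
  g <- matrix(runif(16, 0, 255), 4)
  expect_identical(to_grayscale(g), g)
  rgb <- array(c(rep(100, 16), rep(200, 16), rep(50, 16)), c(4, 4, 3))
  expect_equal(to_grayscale(rgb)[1, 1], 0.299 * 100 + 0.587 * 200 + 0.114 * 50)
  expect_error(to_grayscale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("a two-blob phantom has two gray-level modes where planted", {
  ph <- make_slide_phantom(slide_phantom_spec(width = 200, height = 200,
    background_level = 240,
    blobs = list(list(center = c(100, 100), radius = 70, mean = 80,
                      texture = 8)), seed = 5))
  g <- to_grayscale(ph$image)
  h <- tabulate(floor(g / 16) + 1, nbins = 16)
  # mass concentrated around gray 80 (bin 6) and 240 (bin 16)
  expect_gt(sum(h[5:7]) / length(g), 0.2)
  expect_gt(h[16] / length(g), 0.3)
})

test_that("Otsu separates a two-level image and marks the dark side as tissue", {
  img <- matrix(c(rep(50, 40), rep(200, 60)), 10)
  ob <- otsu_binarize(img)
  expect_gte(ob$threshold, 50)
  expect_lt(ob$threshold, 200)
  expect_identical(ob$mask, img == 50)
  expect_error(otsu_threshold(matrix(7, 3, 3)), "no threshold")
})

test_that("Otsu equals the exhaustive between-class-variance scan", {
  set.seed(42)
  for (i in 1:30) {
    img <- matrix(sample(0:255, 400, replace = TRUE,
                         prob = runif(256)^2), 20)
    if (length(unique(c(img))) < 2) next
    expect_equal(as.numeric(otsu_threshold(img)), brute_force_otsu(img))
  }
})

test_that("inverting the image swaps Otsu foreground and background", {
  set.seed(7)
  img <- matrix(c(rnorm(150, 70, 12), rnorm(250, 210, 15)), 20)
  img <- pmin(pmax(round(img), 0), 255)
  m1 <- otsu_binarize(img)$mask
  m2 <- otsu_binarize(255 - img)$mask
  expect_identical(m2, !m1)
})

test_that("mask refinement fills holes, is extensive, and fill is idempotent", {
  ann <- matrix(FALSE, 41, 41)
  d <- sqrt(outer((1:41 - 21)^2, (1:41 - 21)^2, "+"))
  ann[d <= 15 & d >= 8] <- TRUE
  filled <- refine_mask(ann, dilation_radius = 0)
  expect_identical(filled, d <= 15)
  expect_identical(refine_mask(filled, 0), filled)      # fill o fill = fill
  set.seed(1)
  m <- matrix(runif(400) < 0.3, 20)
  out <- refine_mask(m, 2)
  expect_true(all(out[m]))                              # extensive
  expect_identical(refine_mask(matrix(FALSE, 5, 5), 3), matrix(FALSE, 5, 5))
})

test_that("dilating a single pixel yields the rasterized disk", {
  for (r in c(1, 3, 5)) {
    m <- matrix(FALSE, 21, 21); m[11, 11] <- TRUE
    out <- refine_mask(m, r)
    expect_equal(sum(out), disk_pixel_count(r))
    d <- sqrt(outer((1:21 - 11)^2, (1:21 - 11)^2, "+"))
    expect_identical(out, d <= r)
  }
})

test_that("largest-region selection and bounding box behave on components and ties", {
  m <- matrix(FALSE, 30, 30)
  m[5:10, 5:10] <- TRUE          # 36 px
  m[20:28, 20:28] <- TRUE        # 81 px
  tm <- largest_region_bbox(m)
  expect_equal(unname(tm$bbox), c(20, 20, 28, 28))
  expect_equal(tm$n_regions, 2)
  full <- largest_region_bbox(matrix(TRUE, 8, 12))
  expect_equal(unname(full$bbox), c(1, 1, 8, 12))
  # equal areas: tie broken by the component first in raster order
  t2 <- matrix(FALSE, 10, 10); t2[2:3, 8:9] <- TRUE; t2[6:7, 1:2] <- TRUE
  tie <- largest_region_bbox(t2)
  expect_equal(unname(tie$bbox), c(2, 8, 3, 9))
  expect_error(largest_region_bbox(matrix(FALSE, 4, 4)), "no tissue")
})

test_that("8-connectivity joins diagonal pixels, 4-connectivity does not", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
})

test_that("detection recovers the planted blob bounding box within the dilation radius", {
  ph <- make_slide_phantom(slide_phantom_spec(width = 400, height = 400,
    blobs = list(list(center = c(200, 200), radius = 120, mean = 110, texture = 12),
                 list(center = c(60, 340), radius = 30, mean = 90, texture = 8)),
    holes = list(list(center = c(200, 200), radius = 25)), seed = 3))
  down <- 2; dil <- 3
  tm <- detect_tissue(ph$image, downsample = down, dilation_radius = dil)
  got <- c((tm$bbox[1] - 1) * down + 1, (tm$bbox[2] - 1) * down + 1,
           tm$bbox[3] * down, tm$bbox[4] * down)
  tol <- dil * down + down   # dilation plus downsample rounding
  expect_true(all(abs(got - unname(ph$largest_bbox)) <= tol))
})

test_that("an all-tissue field saturates tile acceptance at fraction 1", {
  set.seed(10)
  img <- slide_image(pmin(pmax(110 + matrix(rnorm(200 * 200, 0, 8), 200), 0), 255),
                     slide_id = "full")
  tm <- structure(list(mask = matrix(TRUE, 200, 200),
                       bbox = c(row_min = 1, col_min = 1,
                                row_max = 200, col_max = 200),
                       scale = 1, n_regions = 1, area = 200 * 200),
                  class = "tissue_mask")
  attr(tm, "threshold") <- 180
  ts <- sample_tiles(img, tm, max_tiles = 12, tile_size = 32, seed = 2)
  expect_equal(length(ts), 12L)
  expect_true(all(ts$tissue_fraction == 1))
})

test_that("an all-background field yields an empty tile set", {
  img <- slide_image(matrix(240, 150, 150), slide_id = "bg")
  tm <- structure(list(mask = matrix(TRUE, 150, 150),
                       bbox = c(row_min = 1, col_min = 1,
                                row_max = 150, col_max = 150),
                       scale = 1, n_regions = 1, area = 150 * 150),
                  class = "tissue_mask")
  attr(tm, "threshold") <- 120
  ts <- sample_tiles(img, tm, max_tiles = 5, tile_size = 32, seed = 2,
                     attempt_factor = 10)
  expect_equal(length(ts), 0L)
  # bounding box smaller than a tile: empty set with a warning record
  ts2 <- sample_tiles(img, tm, max_tiles = 5, tile_size = 512, seed = 2)
  expect_equal(length(ts2), 0L)
  expect_match(ts2$warning, "smaller than tile")
})

test_that("accepted tiles pass the 85% filter under an independent truth recount", {
  ph <- make_slide_phantom(slide_phantom_spec(width = 300, height = 300,
    background_level = 240,
    blobs = list(list(center = c(150, 80), radius = 130, mean = 110,
                      texture = 10)), seed = 6))
  tm <- detect_tissue(ph$image, downsample = 1, dilation_radius = 2)
  ts <- sample_tiles(ph$image, tm, max_tiles = 25, tile_size = 48,
                     min_tissue_fraction = 0.85, seed = 4)
  expect_gt(length(ts), 0)
  for (i in seq_len(length(ts))) {
    o <- ts$origins[i, ]
    truth_frac <- mean(ph$mask[o[1]:(o[1] + 47), o[2]:(o[2] + 47)])
    expect_gte(truth_frac, 0.85)
  }
  # reproducible under the seed
  ts2 <- sample_tiles(ph$image, tm, max_tiles = 25, tile_size = 48,
                      min_tissue_fraction = 0.85, seed = 4)
  expect_identical(ts$origins, ts2$origins)
  expect_error(sample_tiles(ph$image, tm, tile_size = 0), "tile_size")
  expect_error(sample_tiles(ph$image, tm, min_tissue_fraction = 1.2),
               "min_tissue_fraction")
})

test_that("tiles round-trip through PNG files and the manifest", {
  ph <- make_slide_phantom(slide_phantom_spec(width = 150, height = 150,
    blobs = list(list(center = c(75, 75), radius = 60, mean = 100,
                      texture = 6)), seed = 8))
  tm <- detect_tissue(ph$image, downsample = 1, dilation_radius = 2)
  ts <- sample_tiles(ph$image, tm, max_tiles = 3, tile_size = 32, seed = 1)
  dir <- withr::local_tempdir()
  man <- write_tiles(ts, dir)
  df <- read.csv(man)
  expect_equal(nrow(df), length(ts))
  back <- to_grayscale(read_slide_image(df$tile_path[1]))
  expect_equal(back, ts$tiles[[1]], tolerance = 1 / 255)
})
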