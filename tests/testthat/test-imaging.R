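test_that("grayscale conversion uses the fixed luma weights", {
  rgb <- array(0, c(2, 2, 3))
  rgb[, , 1] <- 255
  g <- to_grayscale(rgb)
  expect_equal(round(g[1, 1]), 76)  # 0.299 * 255
  white <- array(255, c(2, 2, 3))
  expect_true(all(to_grayscale(white) == 255))
  # idempotent on grayscale input
  expect_identical(to_grayscale(g), g)
  expect_error(to_grayscale(numeric(0)), "empty")
})

test_that("thresholding separates a two-level image exactly", {
  img <- matrix(10, 20, 20)
  img[5:15, 5:15] <- 200
  mask <- binarize(img)  # Otsu
  expect_identical(mask, img == 200)
  # strict '>' boundary convention for a fixed threshold
  img128 <- matrix(c(128, 129), 2, 2)
  m <- binarize(img128, threshold = 128)
  expect_identical(m, img128 > 128)
  expect_false(m[1, 1])
  # inverted polarity
  expect_identical(binarize(img, threshold = 100, invert = TRUE),
                   img < 100)
  # constant image degenerates with a warning
  expect_warning(m0 <- binarize(matrix(5, 4, 4)), "degenerate")
  expect_false(any(m0))
})

test_that("Otsu recovers a noisy disk's area to one percent", {
  size <- 128
  disk <- disk_mask(size, 40)
  img <- matrix(30, size, size)
  img[disk] <- 220
  set.seed(12)
  img <- img + matrix(rnorm(size^2, 0, 10), size, size)
  mask <- binarize(img)
  expect_lt(abs(sum(mask) - sum(disk)) / sum(disk), 0.01)
})

test_that("hole filling closes enclosed background only", {
  size <- 64
  solid <- disk_mask(size, 20)
  expect_identical(fill_holes(solid), solid)
  ring <- solid & !disk_mask(size, 10)
  expect_identical(fill_holes(ring), solid)
  # monotone and idempotent
  set.seed(5)
  noisy <- matrix(runif(400) > 0.6, 20, 20)
  filled <- fill_holes(noisy)
  expect_true(all(filled | !noisy))
  expect_gte(sum(filled), sum(noisy))
  expect_identical(fill_holes(filled), filled)
  # background touching the border stays background
  bay <- matrix(TRUE, 9, 9)
  bay[1:5, 5] <- FALSE  # channel open to the border
  expect_identical(fill_holes(bay), bay)
})

test_that("particle filtering removes specks and keeps the slice", {
  size <- 100
  slice <- disk_mask(size, 30)
  mask <- slice
  specks <- list(c(5, 5), c(90, 8), c(8, 92), c(95, 95))
  for (sp in specks) mask <- mask | disk_mask(size, 2, sp[1], sp[2])
  out <- filter_particles(mask, min_area = 50)
  expect_identical(out, slice)
  # min_area = 0 without keep_largest is the identity
  expect_identical(filter_particles(mask, 0, keep_largest = FALSE), mask)
  # idempotent
  expect_identical(filter_particles(out, min_area = 50), out)
  # empty in, empty out
  empty <- matrix(FALSE, 5, 5)
  expect_identical(filter_particles(empty, 10), empty)
  # diagonal contact joins components (8-connectivity)
  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_identical(filter_particles(diag2, min_area = 2), diag2)
})

test_that("equal-size largest components resolve by column-major position", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 8:9] <- TRUE  # later in column-major order
  m[6:7, 2:3] <- TRUE  # earlier column: wins
  out <- filter_particles(m)
  expect_equal(sum(out), 4)
  expect_true(out[6, 2])
  expect_false(out[2, 8])
})

test_that("shrinkage ratio matches rasterised disk areas", {
  expect_equal(shrinkage(500, 500), 1)
  expect_equal(shrinkage(0, 400), 0)
  a50 <- sum(disk_mask(256, 50))
  a100 <- sum(disk_mask(256, 100))
  expect_lt(abs(shrinkage(a50, a100) - 0.25), 0.005)
  expect_error(shrinkage(10, 0), "positive")
})

test_that("the full pipeline tracks the commanded area schedule", {
  stack <- generate_image_stack(kmax = 6, size = 160, r0 = 60,
                                noise_sd = 0.03, seed = 2)
  res <- process_frames(stack$frames)
  expect_equal(res$shrinkage[1], 1)
  expect_lt(max(abs(res$shrinkage - stack$truth$area_ratio)), 0.02)
  # identical frames give shrinkage exactly 1
  same <- replicate(3, stack$frames[[1]], simplify = FALSE)
  expect_true(all(process_frames(same)$shrinkage == 1))
  # single frame
  one <- process_frames(stack$frames[1])
  expect_equal(nrow(one), 1)
  expect_equal(one$shrinkage, 1)
})

test_that("measured shrinkage is invariant to uniform brightness scaling", {
  stack <- generate_image_stack(kmax = 4, size = 128, r0 = 48, seed = 3)
  res <- process_frames(stack$frames)
  dimmed <- lapply(stack$frames, function(f) f * 0.7)
  res_dim <- process_frames(dimmed)
  expect_equal(res_dim$shrinkage, res$shrinkage)
  # deterministic: same frames, same parameters, same masks
  expect_identical(process_frames(stack$frames), res)
})

test_that("a region-of-interest crop isolates the intended slice", {
  # two disks per frame; the ROI restricts measurement to the left one
  make_frame <- function(r) {
    img <- matrix(0.1, 120, 240)
    img[cbind(disk_mask(120, r), disk_mask(120, 40))] <- 0.9
    img
  }
  frames <- lapply(c(30, 24), make_frame)
  res <- process_frames(frames, roi = c(1, 120, 1, 120), min_area = 0)
  expect_equal(res$shrinkage[2], sum(disk_mask(120, 24)) /
                 sum(disk_mask(120, 30)), tolerance = 1e-12)
  expect_error(process_frames(frames, roi = c(10, 5, 1, 120)), "roi")
})

test_that("an empty frame is recorded as shrinkage zero with a warning", {
  stack <- generate_image_stack(kmax = 3, size = 96, r0 = 36, seed = 4,
                                n_specks = 0, n_holes = 0)
  frames <- stack$frames
  frames[[3]] <- matrix(0.12, 96, 96) + 1e-3 * disk_mask(96, 2)
  expect_warning(res <- process_frames(frames, threshold = 0.5), "empty")
  expect_equal(res$shrinkage[3], 0)
  expect_equal(nrow(res), 3)
})
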