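# Pixel-set geometry: components, contours, chain length, overlap.

test_that("component labelling handles empty, single and multi-blob masks", {
  expect_equal(label_components(matrix(FALSE, 8, 8))$k, 0L)
  expect_equal(label_components(matrix(FALSE, 8, 8))$areas, integer(0))

  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  cs <- label_components(m)
  expect_equal(cs$k, 1L)
  expect_equal(cs$areas, 9L)

  tb <- two_blob_mask()
  cs <- label_components(tb)
  expect_equal(cs$k, 2L)
  expect_equal(cs$areas, c(12L, 7L))  # raster-scan label order
})

test_that("labelling agrees with a brute-force flood-fill oracle", {
  set.seed(401)
  for (i in 1:60) {
    h <- sample(4:28, 1); w <- sample(4:28, 1)
    m <- random_mask(h, w, runif(1, 0.2, 0.6))
    got <- label_components(m)
    want <- oracle_components(m)
    expect_identical(got$k, want$k)
    expect_identical(got$areas, want$areas)
    expect_identical(got$labels, want$labels)  # same raster-scan order
  }
})

test_that("largest_component picks by area with deterministic ties", {
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  lc <- largest_component(label_components(m))
  expect_identical(lc$mask, m)
  expect_false(lc$ambiguous)

  lc <- largest_component(two_blob_mask())
  expect_equal(sum(lc$mask), 12)
  expect_true(lc$ambiguous)

  # equal areas: lowest label (first in raster order) wins
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE; m[8:10, 8:10] <- TRUE
  lc <- largest_component(m)
  expect_true(lc$ambiguous)
  expect_true(lc$mask[2, 2]); expect_false(lc$mask[8, 8])

  # idempotent: reapplying to its own output is unambiguous identity
  lc2 <- largest_component(lc$mask)
  expect_identical(lc2$mask, lc$mask)
  expect_false(lc2$ambiguous)

  # empty input gives an empty mask
  lc <- largest_component(matrix(FALSE, 5, 5))
  expect_equal(sum(lc$mask), 0)
  expect_false(lc$ambiguous)
})

test_that("border following produces closed chains with expected length", {
  # degenerate single pixel
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  ch <- trace_contour(m)
  expect_equal(nrow(ch$points), 1L)
  expect_true(ch$closed)
  expect_equal(chain_length(ch), 0)

  # 3x3 square: the 8 border pixels, 8 unit moves
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  ch <- trace_contour(m)
  expect_equal(nrow(ch$points), 8L)
  expect_equal(chain_length(ch), 8)
  # every border pixel appears exactly once
  expect_equal(anyDuplicated(ch$points), 0L)
  # consecutive points are 8-neighbours and the chain closes
  pts <- rbind(ch$points, ch$points[1, ])
  steps <- abs(diff(pts))
  expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))

  # rasterized disks: perimeter close to 2*pi*r
  for (r in c(20, 30, 50)) {
    ratio <- chain_length(trace_contour(disk_mask(r))) / (2 * pi * r)
    expect_gt(ratio, 0.9)
    expect_lt(ratio, 1.12)
  }

  expect_error(trace_contour(two_blob_mask()), "components")
})

test_that("chain_length sums Euclidean steps with optional closure", {
  expect_equal(chain_length(matrix(c(1, 1), 1, 2)), 0)
  expect_equal(chain_length(matrix(c(0, 1, 0, 1), 2, 2), closed = FALSE),
               sqrt(2))
  # open vs closed 2-point chain
  expect_equal(chain_length(matrix(c(0, 1, 0, 1), 2, 2), closed = TRUE),
               2 * sqrt(2))
})

test_that("mask_overlap counts exact pixel sets and obeys identities", {
  m <- matrix(FALSE, 6, 6); m[2:4, 2:4] <- TRUE
  expect_equal(mask_overlap(m, m),
               c(intersection = 9L, union = 9L))

  a <- matrix(FALSE, 8, 8); a[1:3, 1:3] <- TRUE
  b <- matrix(FALSE, 8, 8); b[6:7, 6:7] <- TRUE
  expect_equal(mask_overlap(a, b),
               c(intersection = 0L, union = 13L))

  shifted <- matrix(FALSE, 6, 6); shifted[2:4, 3:5] <- TRUE
  expect_equal(mask_overlap(m, shifted),
               c(intersection = 6L, union = 12L))

  expect_error(mask_overlap(m, matrix(FALSE, 5, 5)), "shape")

  set.seed(77)
  for (i in 1:50) {
    p <- random_mask(15, 15); t <- random_mask(15, 15)
    ov <- mask_overlap(p, t)
    expect_identical(ov, mask_overlap(t, p))
    expect_lte(ov[["intersection"]], min(sum(p), sum(t)))
    expect_gte(ov[["union"]], max(sum(p), sum(t)))
    expect_equal(ov[["intersection"]] + ov[["union"]], sum(p) + sum(t))
  }
})

test_that("masks and contours round-trip through PNG/JSON/CSV", {
  m <- disk_mask(7, 20)
  f <- tempfile(fileext = ".png")
  write_mask_png(m, f)
  expect_identical(read_mask_png(f), m)

  ch <- trace_contour(m)
  fj <- tempfile(fileext = ".json")
  write_contour(ch, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back, unname(ch$points - 1L))  # exported 0-based

  fc <- tempfile(fileext = ".csv")
  write_contour(ch, fc)
  backc <- read.csv(fc)
  expect_equal(as.matrix(backc), ch$points - 1L,
               ignore_attr = TRUE)
})
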