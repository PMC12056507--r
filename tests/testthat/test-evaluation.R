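# Accuracy metrics: JCD, RDD/RCD, radial error, per-image case flags
# and dataset summaries.

test_that("jcd matches the set-arithmetic definition", {
  t <- disk_mask(6, 20)
  expect_equal(jcd(t, t), 0)

  p <- matrix(FALSE, 20, 20); p[1:2, 1:2] <- TRUE
  t2 <- matrix(FALSE, 20, 20); t2[10:12, 10:12] <- TRUE
  expect_equal(jcd(p, t2), 1)

  m <- matrix(FALSE, 6, 6); m[2:4, 2:4] <- TRUE
  shifted <- matrix(FALSE, 6, 6); shifted[2:4, 3:5] <- TRUE
  expect_equal(jcd(shifted, m), 0.5)

  expect_equal(jcd(matrix(FALSE, 6, 6), m), 1)  # empty prediction
  expect_error(jcd(m, matrix(FALSE, 6, 6)), "non-empty")

  set.seed(101)
  for (i in 1:50) {
    p <- random_mask(16, 16); t <- random_mask(16, 16)
    t[8, 8] <- TRUE
    expect_identical(jcd(p, t), oracle_jcd(p, t))
    if (any(p)) expect_identical(jcd(p, t), jcd(t, p))
  }
})

test_that("relative deviation is |cP - cT| / cT", {
  expect_equal(relative_deviation(3.3, 3.3), 0)
  expect_equal(relative_deviation(4, 2), 1)
  expect_error(relative_deviation(1, 0), "positive")

  rdd <- relative_deviation(mean_diameter(disk_mask(10)),
                            mean_diameter(disk_mask(20)))
  expect_equal(rdd, 0.5, tolerance = 0.02)
})

test_that("delta_r matches its closed forms and pixel counting", {
  t <- disk_mask(20, 61)
  expect_equal(delta_r(t, t), 0)

  # empty prediction: mismatch = |T|, so delta_r = d_T (1/sqrt(2) - 1/2)
  dt <- mean_diameter(t)
  expect_equal(delta_r(matrix(FALSE, 61, 61), t),
               dt * (1 / sqrt(2) - 1 / 2), tolerance = 1e-9)

  # concentric disks r_T = 20, r_P = 25: the error is the ring width
  p <- disk_mask(25, 61)
  expect_equal(delta_r(p, t), 5, tolerance = 0.02 * 5)

  # micrometre conversion is linear in pixel_size
  expect_equal(delta_r(p, t, pixel_size = 2.04),
               2.04 * delta_r(p, t))

  set.seed(103)
  for (i in 1:30) {
    pp <- random_mask(16, 16); tt <- random_mask(16, 16)
    tt[8, 8] <- TRUE
    expect_equal(delta_r(pp, tt), oracle_delta_r(pp, tt),
                 tolerance = 1e-9)
  }
})

test_that("per-image evaluation assigns the documented case flags", {
  t <- disk_mask(10, 40)

  # correct single spheroid: no ISF/ASF contribution
  rec <- evaluate_image(extract_spheroid(ifelse(t, 0.9, 0.1)), t)
  expect_false(rec$invalid); expect_false(rec$ambiguous)
  expect_equal(rec$jcd, 0)
  expect_equal(rec$rdd, 0); expect_equal(rec$rcd, 0)

  # extra blob beyond a valid largest spheroid: ambiguous only
  p <- ifelse(t, 0.9, 0.1); p[2:4, 2:4] <- 0.9
  rec <- evaluate_image(extract_spheroid(p), t)
  expect_false(rec$invalid); expect_true(rec$ambiguous)
  expect_lt(rec$jcd, 1); expect_gt(rec$iou, 0)

  # no overlap at all: invalid, metrics forced to 1
  p2 <- matrix(0.1, 40, 40); p2[30:34, 30:34] <- 0.9
  rec <- evaluate_image(extract_spheroid(p2), t)
  expect_true(rec$invalid); expect_false(rec$ambiguous)
  expect_equal(rec$jcd, 1)
  expect_equal(rec$rdd, 1); expect_equal(rec$rcd, 1)
  # radial error against the empty prediction
  expect_equal(rec$delta_r_px,
               mean_diameter(t) * (1 / sqrt(2) - 1 / 2),
               tolerance = 1e-9)

  expect_error(evaluate_image(extract_spheroid(p2),
                              matrix(FALSE, 40, 40)), "non-empty")
})

test_that("nested shrinking predictions degrade every metric monotonically", {
  t <- disk_mask(25, 61)
  radii <- c(24, 20, 15, 10, 5)
  recs <- do.call(rbind, lapply(radii, function(r)
    evaluate_image(disk_mask(r, 61), t)))
  expect_true(all(diff(recs$jcd) > 0))
  expect_true(all(diff(recs$rdd) > 0))
  expect_true(all(diff(recs$delta_r_px) > 0))
})

test_that("excess and missing areas do not compensate in delta_r", {
  # a shifted disk of the same size has RDD ~ 0 (no implied radial
  # error) yet a large delta_r, because both P\T and T\P count
  t <- disk_mask(20, 81)
  p <- disk_mask(20, 81, center = c(41 + 10, 41))
  rec <- evaluate_image(p, t)
  expect_lt(rec$rdd, 0.02)
  implied <- abs(rec$d_pred_px - rec$d_target_px) / 2
  expect_gt(rec$delta_r_px, 10 * max(implied, 0.1))
})

test_that("summaries aggregate records with binomial SEs", {
  t <- disk_mask(8, 30)
  perfect <- evaluate_image(extract_spheroid(ifelse(t, 1, 0)), t)
  recs <- do.call(rbind, replicate(5, perfect, simplify = FALSE))
  s <- summarize_evaluation(recs)
  expect_equal(s$jcd[["mean"]], 0)
  expect_equal(s$isf[["fraction"]], 0)
  expect_equal(s$asf[["fraction"]], 0)
  expect_equal(s$isf[["se"]], 0)

  # one invalid among 100
  bad <- evaluate_image(matrix(FALSE, 30, 30), t)
  recs100 <- do.call(rbind, c(replicate(99, perfect, simplify = FALSE),
                              list(bad)))
  s <- summarize_evaluation(recs100)
  expect_equal(s$isf[["fraction"]], 0.01)
  expect_equal(s$isf[["se"]], sqrt(0.01 * 0.99 / 100))

  # medians agree with a sort-based oracle
  set.seed(107)
  jvals <- runif(31)
  recs <- recs100[seq_along(jvals), ]
  recs$jcd <- jvals
  s <- summarize_evaluation(recs)
  srt <- sort(jvals)
  expect_equal(s$jcd[["median"]], srt[(length(srt) + 1) / 2])

  one <- summarize_evaluation(perfect)
  expect_equal(one$n, 1)
  expect_equal(one$jcd[["sd"]], 0)
  expect_equal(one$jcd[["mean"]], perfect$jcd)
})

test_that("interobserver tables enumerate lexicographic rater pairs", {
  set.seed(109)
  imgs <- lapply(1:4, function(i) {
    m <- disk_mask(8, 30)
    m
  })
  raters <- list(
    H2 = lapply(imgs, function(m) perturb_as_rater(m, 2, seed = 1)),
    H3 = lapply(imgs, function(m) perturb_as_rater(m, 2, seed = 2)),
    H4 = lapply(imgs, function(m) perturb_as_rater(m, 3, seed = 3)),
    H5 = lapply(imgs, function(m) perturb_as_rater(m, 1, seed = 4)),
    UNet = imgs)
  tab <- interobserver_matrix(raters)
  expect_equal(dim(tab), c(4, 10))  # 5 raters -> 10 unordered pairs
  expect_identical(colnames(tab), sort(colnames(tab)))

  # duplicated rater: its pair column is all zeros
  dup <- list(A = imgs, B = imgs)
  expect_true(all(interobserver_matrix(dup)[["A~B"]] == 0))

  # symmetry of the underlying metric
  expect_identical(jcd(raters$H2[[1]], raters$H3[[1]]),
                   jcd(raters$H3[[1]], raters$H2[[1]]))

  bad <- raters; bad$H2 <- bad$H2[1:3]
  expect_error(interobserver_matrix(bad), "same number")
})
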