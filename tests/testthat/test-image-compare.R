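test_that("edge mask recovers the synthetic foreground", {
  pair <- make_image_pair(256, 192)
  mask <- edge_mask(pair$reference)
  iou <- sum(mask & pair$true_mask) / sum(mask | pair$true_mask)
  expect_gte(iou, 0.95)
})

test_that("edge mask is stable under monotone brightness maps", {
  pair <- make_image_pair(256, 192, "gamma", gamma = 0.5)
  m_ref <- edge_mask(pair$reference)
  m_gam <- edge_mask(pair$distorted)
  iou <- sum(m_ref & m_gam) / sum(m_ref | m_gam)
  expect_gte(iou, 0.9)
})

test_that("constant images yield a no-edges error", {
  flat <- gray_image(matrix(37, 32, 32))
  expect_error(edge_mask(flat), "no edges")
})

test_that("histogram matching maps source quantiles onto the reference", {
  pair <- make_image_pair(128, 96, "gamma", gamma = 0.5)
  mask <- pair$true_mask
  matched <- histogram_match(pair$distorted, pair$reference, mask)
  # monotone distortion inverted within one gray level
  expect_lte(max(abs(matched$pixels[mask] - pair$reference$pixels[mask])), 1)
  # out-of-mask pixels untouched
  expect_identical(matched$pixels[!mask], pair$distorted$pixels[!mask])
  # source == reference is a fixed point
  same <- histogram_match(pair$reference, pair$reference, mask)
  expect_identical(same$pixels, pair$reference$pixels)
})

test_that("histogram matching is idempotent", {
  pair <- make_image_pair(128, 96, "gamma", gamma = 0.7, noise_sd = 4,
                          seed = 11)
  mask <- pair$true_mask
  once <- histogram_match(pair$distorted, pair$reference, mask)
  twice <- histogram_match(once, pair$reference, mask)
  expect_identical(once$pixels, twice$pixels)
})

test_that("a constant source maps to the reference median", {
  const <- gray_image(matrix(42, 10, 10))
  ref <- gray_image(matrix(1:100, 10, 10))
  out <- histogram_match(const, ref, matrix(TRUE, 10, 10))
  expect_equal(unique(as.vector(out$pixels)), stats::median(1:100))
  expect_error(histogram_match(const, ref, matrix(FALSE, 10, 10)), "empty")
})

test_that("relative difference follows |M - S| / S with zero-denominator exclusion", {
  full <- matrix(TRUE, 1, 2)
  m <- gray_image(matrix(c(50, 0), 1, 2))
  s <- gray_image(matrix(c(100, 0), 1, 2))
  res <- relative_difference(m, s, full)
  expect_equal(res$reldiff[1, 1], 0.5)
  expect_true(is.na(res$reldiff[1, 2]))
  expect_identical(res$n_defined, 1L)
  expect_identical(res$excluded_zero_pixels, 1L)
  # uniform 10% offset
  m2 <- gray_image(matrix(110, 4, 4))
  s2 <- gray_image(matrix(100, 4, 4))
  res2 <- relative_difference(m2, s2, matrix(TRUE, 4, 4))
  expect_equal(res2$mean_reldiff, 0.1)
  expect_equal(res2$median_reldiff, 0.1)
  # all-zero denominators
  z <- gray_image(matrix(0, 2, 2))
  m3 <- gray_image(matrix(5, 2, 2))
  expect_error(relative_difference(m3, z, matrix(TRUE, 2, 2)), "zero")
})

test_that("relative difference is asymmetric in its arguments by design", {
  m <- gray_image(matrix(110, 4, 4))
  s <- gray_image(matrix(100, 4, 4))
  mask <- matrix(TRUE, 4, 4)
  expect_equal(relative_difference(m, s, mask)$mean_reldiff, 0.1)
  expect_equal(relative_difference(s, m, mask)$mean_reldiff, 10 / 110)
})

test_that("the full pipeline inverts a noiseless gamma distortion", {
  pair <- make_image_pair(256, 192, "gamma", gamma = 0.5)
  res <- compare_pair(pair$distorted, pair$reference)
  expect_lte(res$mean_reldiff, 0.01)
  # identical inputs give exactly zero and bit-identical reruns
  res0a <- compare_pair(pair$reference, pair$reference)
  res0b <- compare_pair(pair$reference, pair$reference)
  expect_equal(res0a$mean_reldiff, 0)
  expect_identical(res0a$reldiff, res0b$reldiff)
})

test_that("pipeline error grows with noise and vanishes as noise does", {
  means <- vapply(c(0, 2, 8), function(sd) {
    pair <- make_image_pair(192, 144, "gamma", gamma = 0.5,
                            noise_sd = sd, seed = 3)
    compare_pair(pair$distorted, pair$reference)$mean_reldiff
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lte(means[1], 0.01)
})

test_that("gray image IO round-trips through TIFF and PNG", {
  pair <- make_image_pair(64, 48)
  for (ext in c(".tif", ".png")) {
    path <- withr::local_tempfile(fileext = ext)
    write_gray(pair$reference, path)
    back <- read_gray(path)
    expect_equal(back$pixels, pair$reference$pixels)
  }
  # float TIFF reldiff map
  res <- compare_pair(pair$distorted, pair$reference)
  fpath <- withr::local_tempfile(fileext = ".tif")
  write_gray(res$reldiff, fpath, float = TRUE)
  expect_true(file.size(fpath) > 0)
})

test_that("comparison results tidy and glance coherently", {
  pair <- make_image_pair(96, 72, "gamma", gamma = 0.5)
  res <- compare_pair(pair$distorted, pair$reference)
  td <- tidy(res)
  expect_identical(nrow(td), res$n_defined)
  gl <- glance(res)
  expect_equal(gl$mean_reldiff, mean(td$reldiff))
  expect_s3_class(autoplot(res), "ggplot")
})
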