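test_that("contrast stretch handles degenerate and two-level images", {
  const <- field_image(array(100, c(8, 8, 3)), 1, "HE")
  expect_warning(g <- preprocess_he(const), "constant")
  expect_true(all(g == 100))

  two <- array(0, c(10, 10, 3))
  two[, , 1] <- two[, , 2] <- two[, , 3] <- matrix(c(50, 200), 10, 10)
  f <- field_image(two, 1, "HE")
  g2 <- preprocess_he(f, p_low = 0, p_high = 1)
  expect_setequal(unique(as.vector(g2)), c(0, 255))
})

test_that("contrast stretch is monotone and spans the full range", {
  mz <- make_adipocyte_mosaic(n_cells = 60, mean_area_um2 = 1500, seed = 21)
  px <- mz$field$pixels
  raw <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
  g <- preprocess_he(mz$field)
  expect_equal(range(g), c(0, 255))
  # ordering of distinct intensities is preserved (ties allowed at clips)
  o <- order(raw)
  expect_true(all(diff(g[o]) >= 0))
})

test_that("adipocyte segmentation handles trivial fields", {
  dark <- matrix(0, 32, 32)
  expect_warning(
    expect_warning(seg <- segment_adipocytes(dark, 1, white_threshold = 128),
                   "no adipocytes"),
    "intensity range")
  expect_equal(nrow(seg$cells), 0L)

  sq <- matrix(0, 100, 100)
  sq[26:75, 26:75] <- 255
  seg2 <- segment_adipocytes(sq, 1, white_threshold = 128)
  expect_equal(nrow(seg2$cells), 1L)
  expect_equal(seg2$cells$area_um2, 2500)
})

test_that("mosaic recovery: counts exact, per-cell areas near truth", {
  mz <- make_adipocyte_mosaic(n_cells = 120, mean_area_um2 = 2000, seed = 4)
  seg <- segment_adipocytes(preprocess_he(mz$field), mz$field$pixel_size_um,
                            min_area_um2 = 100)
  expect_equal(nrow(seg$cells), 120L)
  # recovered areas match truth up to a membrane-width perimeter band
  got <- sort(seg$cells$area_um2)
  tru <- sort(mz$truth$area_um2)
  band <- 2 * 4 * sqrt(tru)   # ~ perimeter * 2 px in um^2
  expect_true(all(abs(got - tru) <= band))
  expect_lt(abs(mean(got) - mean(tru)) / mean(tru), 0.02)
})

test_that("segmentation is invariant under 90-degree rotation", {
  mz <- make_adipocyte_mosaic(n_cells = 50, mean_area_um2 = 1200, seed = 13)
  g <- preprocess_he(mz$field)
  a <- segment_adipocytes(g, 1, white_threshold = 140)
  b <- segment_adipocytes(t(g)[ncol(g):1, ], 1, white_threshold = 140)
  expect_equal(sort(a$cells$area_um2), sort(b$cells$area_um2))
})

test_that("size distribution bins, overflow and moments", {
  d <- size_distribution(c(100, 100, 300), bin_edges = c(0, 200, 400))
  expect_equal(d$bins$count, c(2L, 1L))
  expect_equal(d$mean_area_um2, mean(c(100, 100, 300)))
  expect_equal(sum(d$bins$proportion), 1)

  # half-open convention: values on an inner edge land in the upper bin
  d2 <- size_distribution(rep(200, 5), bin_edges = c(0, 200, 400))
  expect_equal(d2$bins$count, c(0L, 5L))
  # final bin is closed at the top edge
  d3 <- size_distribution(400, bin_edges = c(0, 200, 400))
  expect_equal(d3$bins$count, c(0L, 1L))
  # out-of-range values go to the overflow bin and stay in the proportions
  expect_warning(d4 <- size_distribution(c(100, 900), bin_edges = c(0, 200, 400)),
                 "overflow")
  expect_equal(d4$overflow, 1L)
  expect_equal(sum(d4$bins$proportion) + d4$overflow / d4$n_cells, 1)

  # lognormal sample mean within 3 SE of the analytic lognormal mean
  set.seed(99)
  x <- rlnorm(10000, meanlog = 7, sdlog = 0.5)
  dd <- suppressWarnings(size_distribution(x, seq(0, 10000, 500)))
  mu <- exp(7 + 0.5^2 / 2)
  se <- sqrt((exp(0.5^2) - 1) * exp(2 * 7 + 0.5^2)) / sqrt(10000)
  expect_lt(abs(dd$mean_area_um2 - mu), 3 * se)
  expect_equal(dd$mean_area_um2, sum(x) / length(x))
})

test_that("stain quantification: reference colors, bounds and errors", {
  # field fully painted in the PSR reference red
  px <- array(0, c(20, 20, 3))
  px[, , 1] <- 190; px[, , 2] <- 35; px[, , 3] <- 45
  f <- field_image(px, 1, "PSR")
  expect_equal(quantify_stain_area(f)$percent_stained, 100)
  # yellow background only
  px0 <- array(0, c(20, 20, 3))
  px0[, , 1] <- 235; px0[, , 2] <- 205; px0[, , 3] <- 90
  expect_equal(quantify_stain_area(field_image(px0, 1, "PSR"))$percent_stained, 0)
  expect_error(quantify_stain_area(f, roi = matrix(FALSE, 20, 20)),
               class = "empty_roi")
  expect_error(quantify_stain_area(field_image(px, 1, "HE")), "PSR or DAB")
})

test_that("generated stain fields are recovered within half a point", {
  for (kind in c("psr", "dab")) {
    sf <- make_stain_field(kind, 0.175, dims = c(200, 200), seed = 8)
    r <- quantify_stain_area(sf$field, sf$roi)
    expect_lt(abs(r$percent_stained - sf$true_percent), 0.5)
  }
})

test_that("stain percentage is monotone in added stained pixels", {
  sf <- make_stain_field("psr", 0.10, dims = c(150, 150), seed = 3)
  base <- quantify_stain_area(sf$field, sf$roi)$percent_stained
  px <- sf$field$pixels
  # paint an extra patch in reference red
  px[1:20, 1:20, 1] <- 190; px[1:20, 1:20, 2] <- 35; px[1:20, 1:20, 3] <- 45
  more <- quantify_stain_area(field_image(px, sf$field$pixel_size_um, "PSR"),
                              sf$roi)$percent_stained
  expect_gte(more, base)
})

test_that("polygon ROIs restrict the stained-area denominator", {
  sf <- make_stain_field("psr", 1, dims = c(60, 60), seed = 1)
  roi <- polygon_roi(cbind(c(10, 50, 50, 10), c(10, 10, 50, 50)), c(60, 60))
  r <- quantify_stain_area(sf$field, roi)
  expect_equal(r$roi_area_px, sum(roi))
  expect_equal(r$percent_stained, 100)
})
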