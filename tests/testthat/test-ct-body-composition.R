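test_that("segment_body errors on all-air input and recovers an ellipsoid", {
  air <- voxel_volume(array(-1000, c(16, 16, 16)), c(0.2, 0.2, 0.2), "CT_HU")
  expect_error(segment_body(air), class = "no_body_found")

  tc <- tiny_ct()
  body <- segment_body(tc$volume)
  # agreement within a one-voxel boundary band of the analytic ellipsoid
  mism <- xor(body$data, tc$body)
  band <- dilate_mask(tc$body, 1L) & !erode_mask(tc$body, 1L)
  expect_true(all(mism <= band))
})

test_that("segment_body keeps only the largest connected object", {
  tc <- tiny_ct()
  vals <- tc$volume$data
  vals[2:4, 2:4, 2:4] <- 0  # separate small cube
  v <- voxel_volume(vals, tc$volume$spacing, "CT_HU")
  body <- segment_body(v)
  expect_false(any(body$data[2:4, 2:4, 2:4]))
  ref <- oracle_label(vals >= -700, 26L)
  sizes <- tabulate(ref$labels[ref$labels > 0])
  expect_equal(sum(body$data) <= sum(vals >= -700), TRUE)
  expect_equal(length(sizes) >= 2, TRUE)
})

test_that("fat thresholds behave on uniform bodies", {
  # whole grid is soft tissue at 0 HU: everything is fat, no air anywhere
  v <- voxel_volume(array(0, c(16, 16, 16)), c(0.2, 0.2, 0.2), "CT_HU")
  body <- segment_body(v)
  seg <- suppressWarnings(segment_fat(v, body))
  expect_identical(seg$fat$data, body$data)
  expect_equal(sum(seg$air$data), 0L)
  res <- compute_fat_fraction(seg$fat, body, seg$air, v$spacing)
  expect_equal(res$percent_fat, 100)

  # +200 HU body: nothing in the fat window
  v2 <- voxel_volume(array(200, c(16, 16, 16)), c(0.2, 0.2, 0.2), "CT_HU")
  seg2 <- suppressWarnings(segment_fat(v2, segment_body(v2)))
  expect_equal(sum(seg2$fat$data), 0L)
})

test_that("fat segmentation recovers a phantom shell with Jaccard >= 0.95", {
  ph <- make_ct_phantom(dims = c(64, 64, 80), fat_fraction = 0.25,
                        noise_sd_hu = 0, seed = 3)
  r <- suppressWarnings(ct_fat_pipeline(ph$volume))
  jac <- sum(r$fat$data & ph$fat$data) / sum(r$fat$data | ph$fat$data)
  expect_gte(jac, 0.95)
  expect_true(any(r$lung$data))
  expect_true(all(r$lung$data <= r$air$data))
})

test_that("mask containment invariants hold on noisy phantoms", {
  ph <- make_ct_phantom(dims = c(64, 64, 80), fat_fraction = 0.3,
                        noise_sd_hu = 25, seed = 9)
  r <- suppressWarnings(ct_fat_pipeline(ph$volume))
  expect_true(all(r$fat$data <= r$candidate$data))
  expect_true(all(r$candidate$data <= r$body$data))
  expect_true(all(r$lung$data <= r$air$data))
  expect_false(any(r$fat$data & r$excluded))
})

test_that("percent fat is invariant under 90-degree rotations and flips", {
  ph <- make_ct_phantom(dims = c(48, 48, 48), fat_fraction = 0.15,
                        noise_sd_hu = 15, lungs = FALSE, seed = 5)
  base <- suppressWarnings(ct_fat_pipeline(ph$volume))$result$percent_fat
  rot <- aperm(ph$volume$data, c(2, 1, 3))[, rev(seq_len(48)), ]
  v_rot <- voxel_volume(rot, ph$volume$spacing, "CT_HU")
  expect_equal(suppressWarnings(ct_fat_pipeline(v_rot))$result$percent_fat,
               base)
  flip <- ph$volume$data[rev(seq_len(48)), , ]
  v_flip <- voxel_volume(flip, ph$volume$spacing, "CT_HU")
  expect_equal(suppressWarnings(ct_fat_pipeline(v_flip))$result$percent_fat,
               base)
})

test_that("widening the fat window never decreases percent fat", {
  ph <- make_ct_phantom(dims = c(64, 64, 80), fat_fraction = 0.25,
                        noise_sd_hu = 20, seed = 7)
  pf <- vapply(list(c(-200, 20), c(-250, 50), c(-300, 80)), function(w) {
    suppressWarnings(
      ct_fat_pipeline(ph$volume, fat_range_hu = w))$result$percent_fat
  }, numeric(1))
  expect_true(all(diff(pf) >= 0))
})

test_that("fat fraction arithmetic and degenerate input", {
  d <- c(4, 4, 4)
  body <- binary_mask(array(TRUE, d), "BODY")
  air <- binary_mask(array(FALSE, d), "AIR")
  fat_all <- binary_mask(array(TRUE, d), "FAT_FINAL")
  fat_none <- binary_mask(array(FALSE, d), "FAT_FINAL")
  expect_equal(compute_fat_fraction(fat_all, body, air)$percent_fat, 100)
  expect_equal(compute_fat_fraction(fat_none, body, air)$percent_fat, 0)
  r <- compute_fat_fraction(fat_all, body, air, c(0.2, 0.2, 0.2))
  expect_equal(r$voxel_volume_mm3, 0.008)
  expect_equal(r$percent_fat, 100 * r$fat_voxels / r$body_voxels_excl_air)
  expect_error(compute_fat_fraction(fat_none, binary_mask(array(FALSE, d), "BODY"), air),
               class = "undefined_fraction")
})

test_that("partial-volume correction reduces error under blurred interfaces", {
  ph <- make_ct_phantom(dims = c(64, 64, 80), fat_fraction = 0.25,
                        noise_sd_hu = 20, blurred_interfaces = TRUE, seed = 2)
  rc <- suppressWarnings(ct_fat_pipeline(ph$volume))
  ru <- suppressWarnings(ct_fat_pipeline(ph$volume, pv_correction = FALSE))
  expect_lt(abs(rc$result$percent_fat - ph$true_percent_fat),
            abs(ru$result$percent_fat - ph$true_percent_fat))
})
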