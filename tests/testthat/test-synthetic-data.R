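test_that("generators are pure functions of (parameters, seed)", {
  a <- make_ct_phantom(dims = c(32, 32, 40), fat_fraction = 0.1,
                       lungs = FALSE, seed = 5)
  b <- make_ct_phantom(dims = c(32, 32, 40), fat_fraction = 0.1,
                       lungs = FALSE, seed = 5)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$fat$data, b$fat$data)
  # different seed: different noise, identical geometry and truth
  c2 <- make_ct_phantom(dims = c(32, 32, 40), fat_fraction = 0.1,
                        lungs = FALSE, seed = 6)
  expect_false(identical(a$volume$data, c2$volume$data))
  expect_identical(a$body$data, c2$body$data)
  expect_equal(a$true_percent_fat, c2$true_percent_fat)

  m1 <- make_adipocyte_mosaic(n_cells = 40, mean_area_um2 = 1000, seed = 3)
  m2 <- make_adipocyte_mosaic(n_cells = 40, mean_area_um2 = 1000, seed = 3)
  expect_identical(m1$field$pixels, m2$field$pixels)
  expect_identical(m1$truth, m2$truth)

  p1 <- make_pet_phantom(seed = 4); p2 <- make_pet_phantom(seed = 4)
  expect_identical(p1$volume$data, p2$volume$data)

  # generators restore the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(make_ct_phantom(dims = c(24, 24, 24), fat_fraction = 0,
                                           lungs = FALSE, seed = 1))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("CT phantom truth is exact and honors edge cases", {
  ph <- make_ct_phantom(dims = c(64, 64, 80), fat_fraction = 0.3,
                        noise_sd_hu = 10, seed = 2)
  denom <- sum(ph$body$data) - sum(ph$lung$data)
  expect_equal(ph$true_percent_fat, 100 * sum(ph$fat$data) / denom)
  expect_equal(round(denom * 0.3), sum(ph$fat$data))
  expect_true(all(ph$fat$data <= ph$body$data))
  expect_false(any(ph$fat$data & ph$lung$data))

  ph0 <- make_ct_phantom(dims = c(32, 32, 40), fat_fraction = 0, seed = 1)
  expect_equal(ph0$true_percent_fat, 0)
  expect_equal(sum(ph0$fat$data), 0L)
  expect_error(make_ct_phantom(fat_fraction = 0.7), "0, 0.6")
})

test_that("noiseless CT phantom is recovered within a boundary-voxel bound", {
  ph <- make_ct_phantom(dims = c(64, 64, 80), fat_fraction = 0.25,
                        noise_sd_hu = 0, seed = 8)
  r <- suppressWarnings(ct_fat_pipeline(ph$volume))
  surf <- sum(ph$fat$data & !erode_mask(ph$fat$data, 1L))
  denom <- sum(ph$body$data) - sum(ph$lung$data)
  expect_lt(abs(r$result$percent_fat - ph$true_percent_fat),
            100 * surf / denom)
})

test_that("mosaic truth partitions the field and matches the request", {
  mz <- make_adipocyte_mosaic(n_cells = 500, mean_area_um2 = 2500,
                              sdlog = 0.35, seed = 17)
  n_px <- prod(dim(mz$labels))
  expect_equal(sum(mz$truth$area_px) + sum(mz$labels == 0L), n_px)
  # empirical mean within 3 SE of the requested lognormal mean
  se <- sd(mz$truth$area_um2) / sqrt(nrow(mz$truth))
  expect_lt(abs(mean(mz$truth$area_um2) - 2500), 3 * se)
  # single cell: lumen covers the field minus the membrane frame
  m1 <- make_adipocyte_mosaic(n_cells = 1, mean_area_um2 = 4000, seed = 1)
  side <- nrow(m1$labels)
  expect_equal(m1$truth$area_px, (side - 2L)^2)
})

test_that("PET phantom: noiseless pipeline equals the closed form", {
  ph <- make_pet_phantom(c_bg = 0, noise_sd = 0, seed = 3)
  up <- compute_pet_uptake(ph$volume, ph$true_mask, ph$injected_dose)
  expect_equal(up$percent_id_per_g, 100 * ph$params$c_hot / ph$injected_dose,
               tolerance = 1e-12)
  expect_equal(ph$true_percent_id_per_g, 20)
  # doubling the hot concentration doubles recovered uptake
  ph2 <- make_pet_phantom(c_hot = 4, c_bg = 0, noise_sd = 0, seed = 3)
  up2 <- compute_pet_uptake(ph2$volume, ph2$true_mask, ph2$injected_dose)
  expect_equal(up2$percent_id_per_g, 2 * up$percent_id_per_g)
})

test_that("noisy PET phantoms recover truth without bias", {
  ests <- vapply(1:12, function(s) {
    ph <- make_pet_phantom(dims = c(40, 40, 40), radii_vox = c(8, 7, 9),
                           noise_sd = 0.05, seed = s)
    compute_pet_uptake(ph$volume, ph$true_mask,
                       ph$injected_dose)$percent_id_per_g
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 20), 2 * se + 1e-3)
})

test_that("table generators hit their specified effects exactly at zero noise", {
  q <- make_qpcr_table(c(ucp1 = 1, lpl = 1), seed = 5)
  for (g in c("ucp1", "lpl"))
    expect_true(all(fold_change(q$table, g)$fold == 1))
  q10 <- make_qpcr_table(c(ucp1 = 10), seed = 5)
  fc <- fold_change(q10$table, "ucp1")
  expect_equal(attr(fc, "group_means")$mean_fold, c(1, 10))
  d <- make_densitometry_table(c(ucp1 = 3), cv = 0, seed = 5)
  nd <- normalize_densitometry(d$table, "ucp1")
  expect_equal(attr(nd, "group_means")$mean_idv, c(1, 3))
})
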