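test_that("contour validation rejects degenerate inputs", {
  sq <- circle_contour(16, 16, 6, 3)
  expect_error(contour_set(list(sq), c(1, 1, 1)), class = "single_contour")
  bow <- list(slice = 1L,
              vertices = cbind(c(0, 10, 10, 0), c(0, 10, 0, 10)))
  expect_error(contour_set(list(bow, sq), c(1, 1, 1)),
               class = "invalid_contour")
})

test_that("interpolation between identical contours reproduces the shape", {
  sq <- function(z) list(slice = z,
                         vertices = cbind(c(10, 30, 30, 10) - 0.5,
                                          c(10, 10, 30, 30) - 0.5))
  roi <- interpolate_roi(contour_set(list(sq(1L), sq(5L)), c(1, 1, 1)),
                         c(40, 40, 5))
  for (z in 2:4) expect_identical(roi$data[, , z], roi$data[, , 1])
  expect_equal(sum(roi$data[, , 1]), 20 * 20)
  # contour slices are rasterization-exact
  expect_identical(roi$data[, , 1],
                   adipophen:::rasterize_contour(sq(1L)$vertices, 40, 40,
                                                 c(1, 1, 1)))
  # slices outside the contoured range stay empty
  roi2 <- interpolate_roi(contour_set(list(sq(2L), sq(4L)), c(1, 1, 1)),
                          c(40, 40, 6))
  expect_equal(sum(roi2$data[, , 1]) + sum(roi2$data[, , 5:6]), 0)
})

test_that("cone interpolation gives the analytic mid-slice radius", {
  cs <- contour_set(list(circle_contour(32, 32, 10, 1L),
                         circle_contour(32, 32, 20, 11L)), c(1, 1, 1))
  roi <- interpolate_roi(cs, c(64, 64, 11))
  r_mid <- sqrt(sum(roi$data[, , 6]) / pi)
  expect_lt(abs(r_mid - 15), 1)
})

test_that("traced ellipsoid is reconstructed with Jaccard >= 0.95", {
  ph <- make_pet_phantom(seed = 12)
  roi <- interpolate_roi(ph$contours, dim(ph$volume$data))
  jac <- sum(roi$data & ph$true_mask$data) / sum(roi$data | ph$true_mask$data)
  expect_gte(jac, 0.95)
})

test_that("%ID/g closed forms, scaling laws and mask-sum oracle", {
  v <- voxel_volume(array(2.5, c(10, 10, 10)), c(0.4, 0.4, 0.4),
                    "PET_ACTIVITY")
  roi <- binary_mask(array(TRUE, c(10, 10, 10)), "ROI")
  up <- compute_pet_uptake(v, roi, injected_dose = 10)
  expect_equal(up$percent_id_per_g, 100 * 2.5 / 10, tolerance = 1e-12)
  up2 <- compute_pet_uptake(v, roi, injected_dose = 20)
  expect_equal(up2$percent_id_per_g, up$percent_id_per_g / 2,
               tolerance = 1e-12)
  # density rescales the denominator
  up3 <- compute_pet_uptake(v, roi, 10, tissue_density_g_per_ml = 1.05)
  expect_equal(up3$percent_id_per_g, up$percent_id_per_g / 1.05)

  # hot sphere with partial ROI overlap vs brute-force voxel sum
  ph <- make_pet_phantom(dims = c(32, 32, 32), radii_vox = c(7, 6, 8),
                         noise_sd = 0.1, seed = 33)
  roi2 <- ph$true_mask$data
  roi2[, , 1:14] <- FALSE
  got <- compute_pet_uptake(ph$volume, binary_mask(roi2, "ROI"),
                            ph$injected_dose)$percent_id_per_g
  ref <- 100 * (sum(ph$volume$data[roi2]) / sum(roi2)) / ph$injected_dose
  expect_equal(got, ref, tolerance = 1e-9)
  expect_error(compute_pet_uptake(v, binary_mask(array(FALSE, c(10, 10, 10)),
                                                 "ROI"), 10),
               class = "empty_roi")
})

test_that("gamma-count uptake matches the hand formula", {
  expect_equal(gamma_uptake(1000, 1000, 1), 100)
  expect_equal(gamma_uptake(0, 1000, 0.5), 0)
  set.seed(5)
  counts <- runif(20, 10, 1e5)
  inj <- runif(20, 1e5, 1e6)
  w <- runif(20, 0.05, 0.3)
  expect_equal(gamma_uptake(counts, inj, w),
               vapply(1:20, function(i) 100 * counts[i] / (inj[i] * w[i]),
                      numeric(1)))
  expect_error(gamma_uptake(10, 100, 0), "weight")
})

test_that("agreement regression recovers exact linear relations", {
  x <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(correlate_pet_gamma(x, x))  # lm warns on perfect fits
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0); expect_equal(r$r, 1)
  r2 <- suppressWarnings(correlate_pet_gamma(x, 2 * x + 1))
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 1)
  expect_equal(r2$r_squared, 1)
  expect_error(correlate_pet_gamma(rep(1, 5), x),
               class = "degenerate_regression")
})

test_that("slope confidence intervals achieve near-nominal coverage", {
  set.seed(2024)
  n_rep <- 400
  cover <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- runif(9, 2, 25)
    y <- 0.9 * x + rnorm(9, 0, 1)
    fit <- lm(y ~ x)
    ci <- confint(fit)[2, ]
    cover[i] <- ci[1] <= 0.9 && 0.9 <= ci[2]
  }
  expect_gte(mean(cover), 0.93)
})

test_that("ROI growth into cold background never raises mean uptake", {
  ph <- make_pet_phantom(dims = c(40, 40, 40), radii_vox = c(8, 7, 9),
                         noise_sd = 0, seed = 2)
  inner <- ph$true_mask$data
  grown <- dilate_mask(inner, 2L)
  u1 <- compute_pet_uptake(ph$volume, binary_mask(inner, "ROI"), 10)
  u2 <- compute_pet_uptake(ph$volume, binary_mask(grown, "ROI"), 10)
  expect_lte(u2$percent_id_per_g, u1$percent_id_per_g)
})

test_that("packaged example gamma-count table quantifies as expected", {
  f <- system.file("extdata", "example_gamma_counts.csv",
                   package = "adipophen")
  tab <- gamma_uptake_table(read.csv(f, stringsAsFactors = FALSE))
  expect_equal(tab$percent_id_per_g,
               100 * tab$counts / (tab$injected_counts * tab$tissue_weight_g))
  # BAT uptake dominates the peripheral tissues within each animal
  for (s in unique(tab$subject)) {
    d <- tab[tab$subject == s, ]
    expect_true(all(d$percent_id_per_g[d$tissue == "BAT"] >
                      d$percent_id_per_g[d$tissue != "BAT"]))
  }
})
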