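test_that("radial profile of a constant image is constant", {
  img <- matrix(4.2, 50, 50)
  p <- radial_profile(img, c(12.5, 12.5), r_max_um = 5, pixel_size_um = 0.5)
  expect_true(all(abs(p$mean_intensity - 4.2) < 1e-12))
  expect_true(all(diff(p$radii) > 0))
  expect_error(radial_profile(img, c(12.5, 12.5), r_max_um = -1,
                              pixel_size_um = 0.5), "r_max")
})

test_that("profile of a rendered linear-decay plaque matches the closed form", {
  sc <- make_scene(one_plaque_config(seed = 4, core_radius_um = 2,
                                     peak = 100, slope = 5, side_px = 120))
  img <- sc$stack$data[3, , , 1]
  tr <- sc$truth$plaques
  p <- radial_profile(img, c(tr$center_y_um, tr$center_x_um), r_max_um = 20,
                      pixel_size_um = 0.5)
  expected <- ifelse(p$radii <= 2, 100, pmax(0, 100 - 5 * (p$radii - 2)))
  rel <- abs(p$mean_intensity - expected) / 100
  expect_true(all(rel < 0.02))
})

test_that("direction-averaged trace matches the annulus pixel-binning oracle", {
  # radially symmetric image: I = 200 / (1 + r)
  px <- 0.5; n <- 120
  cy <- cx <- n / 2 * px
  yy <- (seq_len(n) - 0.5) * px - cy
  xx <- (seq_len(n) - 0.5) * px - cx
  rr <- sqrt(outer(yy^2, xx^2, `+`))
  img <- 200 / (1 + rr)
  p <- radial_profile(img, c(cy, cx), r_max_um = 20, pixel_size_um = px)
  # oracle: mean over pixels whose radius falls in each bin; innermost bins
  # hold too few pixels for the annulus mean to be comparable
  for (k in seq(10, length(p$radii), by = 5)) {
    sel <- rr >= p$radii[k] - px / 2 & rr < p$radii[k] + px / 2
    expect_lt(abs(p$mean_intensity[k] - mean(img[sel])) / mean(img[sel]), 0.02)
  }
})

test_that("compaction slope is exact on a collinear declining trace", {
  prof <- structure(list(plaque_id = 1, center_um = c(0, 0),
                         radii = seq(0.5, 15, by = 0.5),
                         mean_intensity = pmax(0, 100 - 5 * seq(0.5, 15, by = 0.5)),
                         ray_matrix = NULL, n_rays = 1, bin_width_um = 0.5),
                    class = "radial_profile")
  cs <- compaction_slope(prof, background = 0)
  expect_true(cs$valid)
  expect_equal(cs$slope, -5, tolerance = 1e-9)
  expect_equal(cs$r_squared, 1, tolerance = 1e-9)
})

test_that("flat trace is flagged invalid, not an error", {
  prof <- structure(list(plaque_id = 1, center_um = c(0, 0),
                         radii = seq(0.5, 10, by = 0.5),
                         mean_intensity = rep(7, 20),
                         ray_matrix = NULL, n_rays = 1, bin_width_um = 0.5),
                    class = "radial_profile")
  cs <- compaction_slope(prof, background = 0)
  expect_false(cs$valid)
  expect_true(is.na(cs$slope))
})

test_that("plateau then decline: fit starts at the plateau edge", {
  r <- seq(0.5, 20, by = 0.5)
  I <- ifelse(r < 5, 100, pmax(0, 100 - 10 * (r - 5)))
  prof <- structure(list(plaque_id = 1, center_um = c(0, 0), radii = r,
                         mean_intensity = I, ray_matrix = NULL, n_rays = 1,
                         bin_width_um = 0.5), class = "radial_profile")
  cs <- compaction_slope(prof, background = 0)
  expect_true(cs$valid)
  expect_lt(abs(cs$r_peak - 5), 1)        # plateau edge, not plateau start
  expect_lt(abs(cs$slope + 10) / 10, 0.02)
})

test_that("steeper generated decay gives a more negative recovered slope", {
  slopes <- vapply(c(2, 5, 10), function(s) {
    sc <- make_scene(one_plaque_config(seed = 20 + s, core_radius_um = 3,
                                       peak = 100, slope = s, side_px = 240))
    img <- suppressMessages(project_max(sc$stack, "ThioS", n_slices = 5))
    tr <- sc$truth$plaques
    p <- suppressMessages(radial_profile(
      img, c(tr$center_y_um, tr$center_x_um),
      r_max_um = min(55, tr$extent_um + 4), pixel_size_um = 0.5))
    compaction_slope(p, background = 0)$slope
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
  expect_lt(max(abs(slopes + c(2, 5, 10)) / c(2, 5, 10)), 0.01)
})

test_that("regional burden equals the pixel-counting oracle and conserves totals", {
  set.seed(30)
  plq <- matrix(runif(2500) < 0.2, 50, 50)
  regions <- matrix(0L, 50, 50)
  regions[1:25, ] <- 1L; regions[26:50, 1:25] <- 2L; regions[26:50, 26:50] <- 3L
  b <- plaque_burden(plq, regions, region_names = c("cortex", "hippocampus", "thalamus"),
                     pixel_size_um = 1, min_area_um2 = 0)
  for (k in 1:3)
    expect_equal(b$percent_area[k], 100 * sum(plq & regions == k) / sum(regions == k))
  # partition conservation: region-weighted percents recover the global fraction
  w <- vapply(1:3, function(k) sum(regions == k), numeric(1))
  expect_equal(sum(b$percent_area * w) / sum(w), 100 * sum(plq) / 2500)
  # forced 10% case
  plq2 <- matrix(FALSE, 10, 10); plq2[1, ] <- TRUE
  b2 <- plaque_burden(plq2, matrix(1L, 10, 10), "all", pixel_size_um = 1,
                      min_area_um2 = 0)
  expect_equal(b2$percent_area, 10)
  # empty plaque mask gives 0 everywhere
  b3 <- plaque_burden(matrix(FALSE, 10, 10), matrix(1L, 10, 10), "all",
                      pixel_size_um = 1)
  expect_equal(b3$percent_area, 0)
  expect_error(plaque_burden(plq, matrix(0L, 50, 50), pixel_size_um = 1),
               "region")
})

test_that("intensity-distribution modality: unimodal, bimodal, small-n flag", {
  set.seed(31)
  uni <- intensity_distribution(rnorm(200, 100, 5))
  expect_equal(uni$modality, 1L)
  expect_true(uni$reliable)
  bi <- intensity_distribution(c(rnorm(100, 100, 5), rnorm(100, 130, 5)))
  expect_equal(bi$modality, 2L)
  small <- intensity_distribution(rnorm(5, 100, 5))
  expect_false(small$reliable)
  expect_error(intensity_distribution(numeric()), "particle")
})
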