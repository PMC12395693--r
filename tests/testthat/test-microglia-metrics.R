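disc_mask <- function(n, cy, cx, r, px = 1) {
  yy <- (seq_len(n) - 0.5) * px - cy
  xx <- (seq_len(n) - 0.5) * px - cx
  sqrt(outer(yy^2, xx^2, `+`)) <= r
}

test_that("coverage is 1 for a fully enclosing annulus and 0 for no barrier", {
  plq <- disc_mask(60, 30, 30, 8)
  ring <- disc_mask(60, 30, 30, 12) & !disc_mask(60, 30, 30, 9)
  full <- barrier_coverage(binary_mask(plq, 1), ring, pixel_size_um = 1)
  expect_equal(full$coverage_fraction, 1)
  none <- barrier_coverage(binary_mask(plq, 1), matrix(FALSE, 60, 60),
                           pixel_size_um = 1)
  expect_equal(none$coverage_fraction, 0)
  expect_error(barrier_coverage(binary_mask(matrix(FALSE, 10, 10), 1),
                                matrix(FALSE, 10, 10), pixel_size_um = 1),
               "empty")
})

test_that("generated arcs are recovered across the sweep and monotonically", {
  fr <- vapply(c(0, 90, 180, 270, 360), function(d) {
    sc <- make_scene(one_plaque_config(coverage_deg = d, seed = 100 + d))
    measure_coverages(sc)
  }, numeric(1))
  expect_true(all(abs(fr - c(0, 90, 180, 270, 360) / 360) <= 1 / 360 + 0.02))
  expect_true(all(diff(fr) >= 0))
})

test_that("coverage is exactly invariant under 90-degree scene rotation", {
  sc <- make_scene(one_plaque_config(coverage_deg = 135, seed = 55))
  proj <- suppressMessages(project_max(sc$stack, "ThioS", n_slices = 5))
  iba <- suppressMessages(project_max(sc$stack, "Iba1", n_slices = 5))
  plq <- threshold_mean_sd(proj)
  cut <- soma_cutoff(iba, pixel_size_um = 0.5)
  bar <- iba > cut
  rot90 <- function(m) t(m[nrow(m):1, ])
  c0 <- barrier_coverage(binary_mask(unclass(plq)[, , drop = FALSE], 0.5), bar,
                         pixel_size_um = 0.5)
  c1 <- barrier_coverage(binary_mask(rot90(unclass(plq)), 0.5), rot90(bar),
                         pixel_size_um = 0.5)
  expect_equal(c1$coverage_fraction, c0$coverage_fraction, tolerance = 1e-12)
})

test_that("near-process ratio follows the weighted-mean hand formula", {
  img <- matrix(3, 20, 20)
  expect_equal(near_process_intensity_ratio(img, img > 0, img > 0)$ratio, 1)
  # near region at 2c (30 px), whole cell mixing 2c and c
  img2 <- matrix(5, 20, 20)
  near <- matrix(FALSE, 20, 20); near[1:3, 1:10] <- TRUE
  img2[near] <- 10
  cell <- matrix(TRUE, 20, 20)
  hand <- 10 / ((30 * 10 + 370 * 5) / 400)
  r <- near_process_intensity_ratio(img2, near, cell)
  expect_equal(r$ratio, hand, tolerance = 1e-9)
  inv <- near_process_intensity_ratio(img2, matrix(FALSE, 20, 20), cell)
  expect_false(inv$valid)
})

test_that("microglia counting near plaques matches a brute-force distance oracle", {
  plq <- disc_mask(120, 60, 30, 6)
  somata <- data.frame(centroid_y_um = c(60, 60, 60),
                       centroid_x_um = 30 + 6 + c(5, 20, 60))
  expect_equal(count_microglia_near_plaque(somata, plq, radius_um = 50,
                                           pixel_size_um = 1), 2L)
  expect_equal(count_microglia_near_plaque(somata[0, ], plq,
                                           pixel_size_um = 1), 0L)
  # random placements vs all-pairs oracle
  set.seed(60)
  for (rep in 1:5) {
    m <- matrix(runif(1600) < 0.02, 40, 40)
    if (!any(m)) next
    pts <- data.frame(centroid_y_um = runif(25, 0, 40),
                      centroid_x_um = runif(25, 0, 40))
    idx <- which(m)
    py <- ((idx - 1L) %% 40 + 0.5); px_ <- ((idx - 1L) %/% 40 + 0.5)
    oracle <- sum(vapply(seq_len(25), function(i) {
      ry <- round(pts$centroid_y_um[i] + 0.5); rx <- round(pts$centroid_x_um[i] + 0.5)
      ry <- min(max(ry, 1), 40); rx <- min(max(rx, 1), 40)
      min(sqrt((py - (ry - 0.5))^2 + (px_ - (rx - 0.5))^2)) <= 10
    }, logical(1)))
    expect_equal(count_microglia_near_plaque(pts, m, radius_um = 10,
                                             pixel_size_um = 1), oracle)
  }
})

test_that("AND colocalization equals brute-force conjunction and is bounded", {
  set.seed(61)
  for (rep in 1:10) {
    a <- matrix(runif(400) < 0.4, 20, 20)
    b <- matrix(runif(400) < 0.4, 20, 20)
    r <- coloc_and(list(A = a, B = b), pixel_size_um = 1)
    brute <- sum(a & b)
    expect_equal(r$intersection_area_um2, brute)
    expect_lte(r$intersection_area_um2, min(r$areas_um2))
    # symmetric
    expect_equal(coloc_and(list(B = b, A = a), pixel_size_um = 1)$intersection_area_um2,
                 brute)
  }
  # identical and disjoint masks
  a <- matrix(runif(100) < 0.5, 10, 10)
  expect_equal(coloc_and(list(a, a), pixel_size_um = 1)$intersection_area_um2, sum(a))
  expect_equal(coloc_and(list(a, !a), pixel_size_um = 1)$intersection_area_um2, 0)
  # associative with three masks
  c3 <- matrix(runif(100) < 0.5, 10, 10)
  expect_equal(coloc_and(list(a, !a, c3), pixel_size_um = 1)$intersection_area_um2, 0)
  expect_error(coloc_and(list(a, matrix(TRUE, 5, 5)), pixel_size_um = 1), "shape")
})

test_that("spheroid area: subtraction rule, exact noiseless recovery, monotonicity", {
  plq <- disc_mask(60, 30, 30, 8)
  blank <- matrix(0, 60, 60)
  expect_equal(spheroid_area(blank, plq, background = 10, pixel_size_um = 1)$spheroid_area_um2, 0)
  # signal only inside the plaque vanishes after subtraction
  inside <- matrix(0, 60, 60); inside[plq] <- 100
  expect_equal(spheroid_area(inside, plq, background = 10, pixel_size_um = 1)$spheroid_area_um2, 0)
  # halo at 3x background recovered exactly without noise
  halo <- disc_mask(60, 30, 30, 12) & !disc_mask(60, 30, 30, 10)
  img <- matrix(10, 60, 60); img[halo] <- 30
  s <- spheroid_area(img, plq, background = 10, pixel_size_um = 1)
  expect_equal(s$spheroid_area_um2, sum(halo & !plq))
  # monotone non-increasing in the background estimate
  areas <- vapply(c(5, 10, 15, 19.9),
                  function(b) spheroid_area(img, plq, background = b,
                                            pixel_size_um = 1)$spheroid_area_um2,
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_error(spheroid_area(img, plq, background = 0, pixel_size_um = 1),
               "background")
})

test_that("RNA-scope fraction: trivial cases and generator recovery at 92%", {
  lab <- matrix(0L, 20, 20)
  lab[2:4, 2:4] <- 1L; lab[10:12, 10:12] <- 2L; lab[16:18, 16:18] <- 3L
  ms <- lab > 0                      # every nucleus Ms4a6d+
  ai <- lab > 0
  expect_equal(rnascope_microglia_fraction(lab, ms, ai)$fraction, 1)
  expect_equal(rnascope_microglia_fraction(lab, ms, matrix(FALSE, 20, 20))$fraction, 0)
  none <- rnascope_microglia_fraction(lab, matrix(FALSE, 20, 20), ai)
  expect_false(none$valid)
  # generator assigns Aif1 to 92% of Ms4a6d+ nuclei (n = 200, seeded)
  cfg <- scene_config(image_shape = c(1, 320, 320), pixel_size_um = 0.5,
                      nuclei = list(count = 200, radius_um = 3, intensity = 120,
                                    ms4a6d_positive_frac = 1,
                                    aif1_given_ms4a6d = 0.92,
                                    spots_per_gene = 3, spot_radius_um = 0.5),
                      seed = 92)
  sc <- make_scene(cfg)
  res <- rnascope_microglia_fraction(
    sc$truth$nuclei_labels,
    sc$stack$data[1, , , match("Ms4a6d", sc$stack$channel_names)] > 0,
    sc$stack$data[1, , , match("Aif1", sc$stack$channel_names)] > 0)
  truth_frac <- mean(sc$truth$nuclei$aif1_pos[sc$truth$nuclei$ms4a6d_pos])
  expect_equal(res$fraction, truth_frac, tolerance = 1e-12)
  expect_lt(abs(res$fraction - 0.92), 0.05)
})
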