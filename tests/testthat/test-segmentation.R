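make_stack <- function(arr, names = "c", px = 1) image_stack(arr, names, px)

test_that("project_max takes the per-pixel maximum over the z window", {
  arr <- array(0, c(6, 4, 4, 1))
  arr[3, 2, 2, 1] <- 7
  st <- make_stack(arr)
  expect_equal(project_max(st, "c", z_center = 2, n_slices = 6)[2, 2], 7)
  # constant stack projects to the constant
  stc <- make_stack(array(3.5, c(5, 3, 3, 1)))
  expect_true(all(project_max(stc, "c", z_center = 2, n_slices = 5) == 3.5))
  # random stack equals an explicit per-pixel loop oracle
  set.seed(41)
  arr <- array(runif(5 * 6 * 7), c(5, 6, 7, 1))
  st <- make_stack(arr)
  proj <- project_max(st, "c", z_center = 2, n_slices = 5)
  oracle <- matrix(0, 6, 7)
  for (y in 1:6) for (x in 1:7) oracle[y, x] <- max(arr[1:5, y, x, 1])
  expect_equal(unclass(proj), oracle, ignore_attr = TRUE)
  expect_error(project_max(st, "nope", z_center = 2), "channel")
  expect_message(project_max(st, "c", z_center = 0, n_slices = 5), "clipped")
})

test_that("mean + k SD threshold matches the two-pass oracle and defaults to k = 2", {
  set.seed(42)
  img <- matrix(rexp(400, 1 / 50), 20, 20)
  m <- threshold_mean_sd(img, pixel_size_um = 1)
  mu <- sum(img) / length(img)
  sdv <- sqrt(sum((img - mu)^2) / length(img))   # population SD
  expect_equal(attr(m, "threshold"), mu + 2 * sdv, tolerance = 1e-9)
  expect_identical(unclass(m)[1:400], (img > mu + 2 * sdv)[1:400])
  # constant image: T = c, strict inequality gives an empty mask
  cm <- threshold_mean_sd(matrix(5, 4, 4), pixel_size_um = 1)
  expect_equal(attr(cm, "threshold"), 5)
  expect_false(any(cm))
  expect_error(threshold_mean_sd(img, k = -1), "k")
})

test_that("IsoData reaches the intermeans fixed point (hand case + property)", {
  # two spikes at the histogram extremes: fixed point at the midpoint bin
  img <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  T <- threshold_isodata(img)
  expect_equal(T, 127.5, tolerance = 1.0)   # bin edge at the midpoint, +-1 bin
  expect_error(threshold_isodata(matrix(1, 5, 5)), "constant")
  # fixed-point property on 100 seeded random 8-bit images
  set.seed(7)
  for (i in 1:100) {
    img <- matrix(sample(0:255, 256, TRUE, prob = runif(256)^2), 16, 16)
    if (length(unique(as.vector(img))) < 2) next
    T <- threshold_isodata(img)
    lo <- min(img); w <- (max(img) - lo) / 256
    bin <- pmin(floor((img - lo) / w), 255)
    t_bin <- round((T - lo) / w) - 1
    mu1 <- mean(bin[bin <= t_bin]); mu2 <- mean(bin[bin > t_bin])
    expect_lt(abs(t_bin - (mu1 + mu2) / 2), 1 + 1e-9)
  }
})

test_that("Triangle threshold equals the brute-force distance-maximisation oracle", {
  # spike at 0 with a geometric tail
  set.seed(8)
  img <- matrix(c(rep(0, 300), floor(rexp(100, 1 / 40))), 20, 20)
  expect_equal(threshold_triangle(img), triangle_oracle(img), tolerance = 1e-9)
  # 100 random histograms, every case
  for (i in 1:100) {
    img <- matrix(c(rep(0, sample(50:300, 1)),
                    floor(rexp(sample(50:200, 1), 1 / sample(10:80, 1)))), ncol = 1)
    if (length(unique(as.vector(img))) < 2) next
    expect_equal(threshold_triangle(img), triangle_oracle(img), tolerance = 1e-9)
  }
})

test_that("label_particles applies 8-connectivity and the min-size filter", {
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2:3] <- TRUE        # 4 px
  m[6:8, 6:8] <- TRUE        # 9 px
  m[12:15, 12:15] <- TRUE    # 16 px
  parts <- label_particles(binary_mask(m, 1), min_area_um2 = 5, pixel_size_um = 1)
  expect_equal(sort(parts$area_um2), c(9, 16))
  # empty mask
  expect_equal(nrow(label_particles(binary_mask(matrix(FALSE, 5, 5), 1),
                                    pixel_size_um = 1)), 0L)
  # diagonal touch is one particle
  d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  pd <- label_particles(binary_mask(d, 1), min_area_um2 = 0, pixel_size_um = 1)
  expect_equal(nrow(pd), 1L)
  expect_equal(pd$area_um2, 2)
  expect_error(label_particles(binary_mask(m, 1), matrix(0, 3, 3),
                               pixel_size_um = 1), "shape")
})

test_that("particle areas conserve total foreground area (kept + dropped)", {
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.25, 30, 30)
    all_parts <- label_particles(binary_mask(m, 1), min_area_um2 = 0,
                                 pixel_size_um = 1)
    kept <- label_particles(binary_mask(m, 1), min_area_um2 = 4,
                            pixel_size_um = 1)
    expect_equal(sum(all_parts$area_um2), sum(m))
    dropped <- sum(all_parts$area_um2[all_parts$area_um2 < 4])
    expect_equal(sum(kept$area_um2) + dropped, sum(m))
  }
})

test_that("particle intensity statistics come from the intensity image", {
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE
  inten <- matrix(1, 6, 6); inten[2, 2] <- 9; inten[3, 3] <- 5
  p <- label_particles(binary_mask(m, 1), inten, min_area_um2 = 0,
                       pixel_size_um = 1)
  expect_equal(p$mean_intensity, (9 + 5 + 1 + 1) / 4)
  expect_equal(p$max_intensity, 9)
  expect_equal(p$centroid_y_um, 2)   # pixels at rows 2:3 -> centre 2.5 - 0.5
  expect_equal(p$centroid_x_um, 2)
})

test_that("foreground area is non-increasing in the threshold", {
  set.seed(10)
  img <- matrix(runif(400, 0, 100), 20, 20)
  areas <- vapply(seq(0, 100, by = 5),
                  function(T) sum(apply_threshold(img, T, pixel_size_um = 1)),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("soma cutoff: supplied mask, auto detection, and failure modes", {
  img <- matrix(7, 10, 10)
  soma <- matrix(FALSE, 10, 10); soma[3:5, 3:5] <- TRUE
  expect_equal(soma_cutoff(img, soma), 7)
  # synthetic somata at 200 on background 10: auto recovers the soma mean
  set.seed(13)
  big <- matrix(10, 60, 60)
  big[10:20, 10:20] <- 200; big[35:48, 35:48] <- 200
  big <- big + matrix(rnorm(3600, 0, 2), 60, 60)
  cut <- soma_cutoff(big, pixel_size_um = 1)
  expect_lt(abs(cut - 200), 3)
  expect_error(soma_cutoff(matrix(0, 10, 10), pixel_size_um = 1))
})
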