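# Scene builders shared across test files. All geometry in um; pixel size
# 0.5 um/px unless stated.

# single plaque (sharp linear decay) with an optional barrier arc
one_plaque_config <- function(coverage_deg = 180, seed = 1, sigma = 0,
                              side_px = 200, core_radius_um = 4,
                              peak = 200, slope = 50, start_deg = 15,
                              poisson = FALSE) {
  scene_config(
    image_shape = c(5, side_px, side_px), pixel_size_um = 0.5,
    plaques = list(list(center = c(2, side_px / 2, side_px / 2),
                        core_radius_um = core_radius_um,
                        peak_intensity = peak, decay_slope = slope)),
    microglia = list(coverage_deg = coverage_deg, barrier_start_deg = start_deg),
    noise = list(gaussian_sigma = sigma, poisson = poisson),
    seed = seed)
}

# grid of n plaques with per-plaque barrier arcs; spacing chosen so that
# plaque + barrier + somata of neighbours never interact
plaque_grid_config <- function(coverage_degs, seed, sigma = 0,
                               spacing_um = 50, core_radius_um = 3,
                               peak = 150, slope = 50) {
  n <- length(coverage_degs)
  n_col <- ceiling(sqrt(n))
  n_row <- ceiling(n / n_col)
  px <- 0.5
  side_y <- round(n_row * spacing_um / px)
  side_x <- round(n_col * spacing_um / px)
  centers <- lapply(seq_len(n) - 1L, function(k) {
    i <- k %/% n_col; j <- k %% n_col
    c(1, round((i + 0.5) * spacing_um / px), round((j + 0.5) * spacing_um / px))
  })
  scene_config(
    image_shape = c(3, side_y, side_x), pixel_size_um = px,
    plaques = lapply(centers, function(cen)
      list(center = cen, core_radius_um = core_radius_um,
           peak_intensity = peak, decay_slope = slope)),
    microglia = lapply(coverage_degs, function(d) list(coverage_deg = d)),
    noise = list(gaussian_sigma = sigma, poisson = FALSE),
    seed = seed)
}

# run segmentation + per-plaque coverage on a scene, matching recovered
# plaques to manifest entries by centroid
measure_coverages <- function(scene, annulus_width_um = 5) {
  st <- scene$stack
  proj <- suppressMessages(project_max(st, "ThioS", n_slices = min(10L, dim(st$data)[1])))
  pm <- threshold_mean_sd(proj)
  iba <- suppressMessages(project_max(st, "Iba1", n_slices = min(10L, dim(st$data)[1])))
  cut <- soma_cutoff(iba, pixel_size_um = st$pixel_size_um)
  barrier <- iba > cut
  parts <- label_particles(pm, proj, pixel_size_um = st$pixel_size_um)
  lab <- attr(parts, "label_image")
  tr <- scene$truth$plaques
  vapply(seq_len(nrow(tr)), function(i) {
    d2 <- (parts$centroid_y_um - tr$center_y_um[i])^2 +
      (parts$centroid_x_um - tr$center_x_um[i])^2
    j <- which.min(d2)
    r <- round(parts$centroid_y_um[j] / st$pixel_size_um + 0.5)
    c <- round(parts$centroid_x_um[j] / st$pixel_size_um + 0.5)
    this <- lab == lab[r, c]
    barrier_coverage(binary_mask(this, st$pixel_size_um), barrier,
                     annulus_width_um = annulus_width_um,
                     pixel_size_um = st$pixel_size_um)$coverage_fraction
  }, numeric(1))
}

# angular occupancy of a mask around a centre: the brute-force coverage
# oracle (fraction of sectors holding any mask pixel). Sectors must be at
# least as wide as a pixel's angular footprint at the mask radius, or
# covered sectors can be empty by discretisation.
angular_occupancy <- function(mask, center_um, pixel_size_um, n_sectors = 72) {
  idx <- which(mask)
  if (!length(idx)) return(0)
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  th <- atan2((rows - 0.5) * pixel_size_um - center_um[1],
              (cols - 0.5) * pixel_size_um - center_um[2])
  sec <- floor((th %% (2 * pi)) / (2 * pi) * n_sectors)
  length(unique(sec)) / n_sectors
}
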