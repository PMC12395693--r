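#' Angular coverage of a plaque by the microglial barrier
#'
#' Quantifies how much of the plaque perimeter is enveloped by
#' barrier-grade microglial processes, normalised by 360 degrees. From the
#' plaque centroid, `n_rays` rays are cast at uniform angular spacing; a ray
#' counts as covered when any barrier pixel lies within the annulus
#' \[boundary, boundary + annulus_width_um\] along that ray, where the
#' boundary is the outermost plaque-mask crossing of the ray. The covered
#' angle is 360 times the covered-ray fraction — equivalent, for contiguous
#' arcs, to the angle between the barrier contact points seen from the
#' plaque centre, and well defined also for fragmented barriers.
#'
#' @param plaque_mask logical matrix (non-empty) of the plaque.
#' @param barrier_mask logical matrix of barrier-grade Iba1 signal (the Iba1
#'   projection thresholded at the soma cutoff, see [soma_cutoff()]).
#' @param n_rays number of rays (default 360).
#' @param annulus_width_um barrier search depth beyond the plaque boundary
#'   (default 5).
#' @param pixel_size_um pixel size.
#' @param center_um optional c(y, x) centre in um; default: plaque centroid.
#' @return list of class `coverage_result`: plaque_id, covered_angle_deg,
#'   coverage_fraction, n_rays, annulus_width_um, ray_covered (logical).
#' @export
barrier_coverage <- function(plaque_mask, barrier_mask, n_rays = 360L,
                             annulus_width_um = 5,
                             pixel_size_um = attr(plaque_mask, "pixel_size_um"),
                             center_um = NULL, plaque_id = NA) {
  if (is.null(pixel_size_um) || is.na(pixel_size_um)) stop("pixel_size_um required")
  if (!all(dim(plaque_mask) == dim(barrier_mask))) stop("mask shapes differ")
  if (!any(plaque_mask)) stop("plaque mask is empty")
  ny <- nrow(plaque_mask); nx <- ncol(plaque_mask)
  if (is.null(center_um)) {
    idx <- which(plaque_mask)
    rows <- (idx - 1L) %% ny + 1L; cols <- (idx - 1L) %/% ny + 1L
    center_um <- c((mean(rows) - 0.5) * pixel_size_um,
                   (mean(cols) - 0.5) * pixel_size_um)
  }
  step <- pixel_size_um / 2                 # half-pixel sampling along rays
  r_img <- sqrt((ny * pixel_size_um)^2 + (nx * pixel_size_um)^2)
  radii <- seq(step, r_img, by = step)
  ang <- (seq_len(n_rays) - 1L) * 2 * pi / n_rays
  yy <- outer(sin(ang), radii) + center_um[1]
  xx <- outer(cos(ang), radii) + center_um[2]
  ry <- pmin(pmax(round(yy / pixel_size_um + 0.5), 1L), ny)
  rx <- pmin(pmax(round(xx / pixel_size_um + 0.5), 1L), nx)
  inside <- yy >= 0 & yy <= ny * pixel_size_um & xx >= 0 & xx <= nx * pixel_size_um
  plq <- matrix(plaque_mask[cbind(as.vector(ry), as.vector(rx))], n_rays) & inside
  bar <- matrix(barrier_mask[cbind(as.vector(ry), as.vector(rx))], n_rays) & inside
  rmat <- matrix(radii, n_rays, length(radii), byrow = TRUE)
  covered <- vapply(seq_len(n_rays), function(i) {
    hit <- which(plq[i, ])
    boundary <- if (length(hit)) radii[max(hit)] else 0
    any(bar[i, ] & rmat[i, ] >= boundary &
          rmat[i, ] <= boundary + annulus_width_um)
  }, logical(1))
  structure(list(plaque_id = plaque_id,
                 covered_angle_deg = 360 * mean(covered),
                 coverage_fraction = mean(covered),
                 n_rays = n_rays, annulus_width_um = annulus_width_um,
                 center_um = center_um, ray_covered = covered),
            class = "coverage_result")
}

#' Near-plaque to whole-cell Iba1 intensity ratio
#'
#' Mean Iba1 intensity over the near-plaque process region divided by the
#' mean over the whole-cell mask; barrier-forming microglia concentrate
#' Iba1 in the processes apposed to the plaque, giving ratios above 1.
#'
#' @param iba1_image numeric matrix.
#' @param near_plaque_region logical matrix (conventionally the coverage
#'   annulus intersected with Iba1 foreground).
#' @param whole_cell_mask logical matrix of the full cell(s).
#' @return list: ratio, near_mean, cell_mean, valid (FALSE with an empty
#'   region instead of an error).
#' @export
near_process_intensity_ratio <- function(iba1_image, near_plaque_region,
                                         whole_cell_mask) {
  if (!all(dim(iba1_image) == dim(near_plaque_region)) ||
      !all(dim(iba1_image) == dim(whole_cell_mask)))
    stop("shapes differ")
  if (!any(near_plaque_region) || !any(whole_cell_mask))
    return(list(ratio = NA_real_, near_mean = NA_real_, cell_mean = NA_real_,
                valid = FALSE))
  near <- mean(iba1_image[near_plaque_region])
  cell <- mean(iba1_image[whole_cell_mask])
  list(ratio = near / cell, near_mean = near, cell_mean = cell, valid = TRUE)
}

#' Count microglia with somata near a plaque
#'
#' Counts somata whose centroid lies within `radius_um` of the nearest
#' plaque-mask pixel (Euclidean distance transform).
#'
#' @param soma_records data.frame with centroid_y_um, centroid_x_um (e.g.
#'   [label_particles()] on a soma mask).
#' @param plaque_mask logical matrix.
#' @param radius_um distance cutoff (default 50).
#' @param pixel_size_um pixel size.
#' @return integer count (0 for empty inputs).
#' @export
count_microglia_near_plaque <- function(soma_records, plaque_mask, radius_um = 50,
                                        pixel_size_um = attr(plaque_mask, "pixel_size_um")) {
  if (is.null(soma_records) || nrow(soma_records) == 0L || !any(plaque_mask))
    return(0L)
  if (is.null(pixel_size_um) || is.na(pixel_size_um)) stop("pixel_size_um required")
  # distmap of the complement: for every pixel, distance to nearest plaque px
  d <- EBImage::distmap(matrix(as.numeric(!plaque_mask), nrow(plaque_mask)))
  ry <- pmin(pmax(round(soma_records$centroid_y_um / pixel_size_um + 0.5), 1L),
             nrow(plaque_mask))
  rx <- pmin(pmax(round(soma_records$centroid_x_um / pixel_size_um + 0.5), 1L),
             ncol(plaque_mask))
  sum(d[cbind(ry, rx)] * pixel_size_um <= radius_um)
}

#' AND-colocalization of binary masks
#'
#' Pixel-wise conjunction of two or three thresholded channels (each
#' produced upstream, conventionally with the IsoData preset), reporting
#' input areas, the intersection area, and the intersection as a fraction
#' of each input. The operation is symmetric and associative; the
#' intersection area can never exceed the smallest input.
#'
#' @param masks named list of 2 or 3 logical matrices (equal shapes).
#' @param pixel_size_um pixel size; defaults to the first mask's attribute.
#' @return list of class `coloc_result`: channels, areas_um2 (named),
#'   intersection_area_um2, fraction_of_input (named), mask (the
#'   conjunction).
#' @export
coloc_and <- function(masks, pixel_size_um = attr(masks[[1]], "pixel_size_um")) {
  if (!is.list(masks) || length(masks) < 2L || length(masks) > 3L)
    stop("supply a list of 2 or 3 masks")
  dims <- dim(masks[[1]])
  for (m in masks) if (!all(dim(m) == dims)) stop("mask shapes differ")
  if (is.null(pixel_size_um) || is.na(pixel_size_um)) stop("pixel_size_um required")
  nms <- names(masks) %||% paste0("mask", seq_along(masks))
  px2 <- pixel_size_um^2
  conj <- Reduce(`&`, masks)
  areas <- vapply(masks, sum, numeric(1)) * px2
  inter <- sum(conj) * px2
  structure(list(channels = nms, areas_um2 = stats::setNames(areas, nms),
                 intersection_area_um2 = inter,
                 fraction_of_input = stats::setNames(
                   ifelse(areas > 0, inter / areas, NA_real_), nms),
                 mask = binary_mask(matrix(conj, dims[1], dims[2]), pixel_size_um,
                                    method = "AND")),
            class = "coloc_result")
}

#' Axonal-spheroid area around a plaque
#'
#' Thresholds the Lamp1 projection at 150% of the background intensity and
#' subtracts the plaque area; the remaining foreground area (um^2) scores
#' the halo of dystrophic, Lamp1-positive axonal spheroids surrounding the
#' plaque. Background defaults to the mean Lamp1 intensity outside plaque
#' masks dilated by 5 um ([estimate_background()]).
#'
#' @param lamp1_projection numeric matrix (10-slice max projection through
#'   the plaque core, see [project_max()]).
#' @param plaque_mask logical matrix of the plaque.
#' @param background scalar background level; must be > 0.
#' @param bg_factor threshold multiple of background (default 1.5).
#' @param pixel_size_um pixel size.
#' @return list of class `spheroid_result`: plaque_id, spheroid_area_um2,
#'   background, threshold, mask.
#' @export
spheroid_area <- function(lamp1_projection, plaque_mask, background = NULL,
                          bg_factor = 1.5,
                          pixel_size_um = attr(lamp1_projection, "pixel_size_um"),
                          plaque_id = NA) {
  if (!all(dim(lamp1_projection) == dim(plaque_mask))) stop("shapes differ")
  if (is.null(pixel_size_um) || is.na(pixel_size_um)) stop("pixel_size_um required")
  if (is.null(background))
    background <- estimate_background(lamp1_projection, plaque_mask,
                                      pixel_size_um = pixel_size_um)
  if (background <= 0) stop("background must be > 0")
  thr <- bg_factor * background
  fg <- lamp1_projection > thr & !plaque_mask
  structure(list(plaque_id = plaque_id,
                 spheroid_area_um2 = sum(fg) * pixel_size_um^2,
                 background = background, threshold = thr,
                 mask = binary_mask(matrix(fg, nrow(fg)), pixel_size_um,
                                    method = sprintf("%g x background", bg_factor),
                                    threshold = thr)),
            class = "spheroid_result")
}

#' Fraction of gene-expressing cells that are microglia (RNA in situ)
#'
#' A nucleus is positive for a gene when at least `min_spots` spot pixels of
#' that gene's mask overlap its label region. The reported fraction is the
#' share of Ms4a6d-positive nuclei that are also Aif1-positive (Aif1/Iba1
#' transcripts mark microglia), i.e. the microglial specificity of Ms4a6d
#' expression.
#'
#' @param nuclei_labels integer matrix of nucleus labels (0 = no nucleus).
#' @param ms4a6d_spot_mask,aif1_spot_mask logical matrices of transcript
#'   spots.
#' @param min_spots minimum overlapping spot pixels for positivity
#'   (default 1).
#' @return list: fraction, n_ms4a6d_pos, n_double_pos, per_nucleus
#'   (data.frame), valid (FALSE when no nucleus is Ms4a6d-positive).
#' @export
rnascope_microglia_fraction <- function(nuclei_labels, ms4a6d_spot_mask,
                                        aif1_spot_mask, min_spots = 1L) {
  if (!all(dim(nuclei_labels) == dim(ms4a6d_spot_mask)) ||
      !all(dim(nuclei_labels) == dim(aif1_spot_mask)))
    stop("shapes differ")
  n <- max(nuclei_labels)
  if (n == 0L) return(list(fraction = NA_real_, n_ms4a6d_pos = 0L,
                           n_double_pos = 0L, per_nucleus = NULL, valid = FALSE))
  ms <- tabulate(nuclei_labels[ms4a6d_spot_mask & nuclei_labels > 0L], nbins = n)
  ai <- tabulate(nuclei_labels[aif1_spot_mask & nuclei_labels > 0L], nbins = n)
  pos_ms <- ms >= min_spots; pos_ai <- ai >= min_spots
  per <- data.frame(nucleus = seq_len(n), ms4a6d_spots = ms, aif1_spots = ai,
                    ms4a6d_pos = pos_ms, aif1_pos = pos_ai)
  n_ms <- sum(pos_ms); n_both <- sum(pos_ms & pos_ai)
  if (n_ms == 0L)
    return(list(fraction = NA_real_, n_ms4a6d_pos = 0L, n_double_pos = 0L,
                per_nucleus = per, valid = FALSE))
  list(fraction = n_both / n_ms, n_ms4a6d_pos = n_ms, n_double_pos = n_both,
       per_nucleus = per, valid = TRUE)
}
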