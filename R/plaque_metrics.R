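#' Radial intensity profile of a plaque
#'
#' Casts `n_rays` rays at uniform angular spacing from the plaque centre and
#' samples the image bilinearly at `bin_width_um` steps along each ray. The
#' direction-averaged trace I(r) — the per-bin mean over rays — quantifies
#' how fluorescence decays from the dense core to the periphery: compact
#' plaques show a sharp boundary, diffuse deposits a gradual decline. Rays
#' that would leave the image before `r_max_um` are dropped and the drop is
#' logged.
#'
#' @param image numeric matrix (typically a max projection of the plaque
#'   channel).
#' @param center_um plaque centre, c(y, x) in micrometres (voxel-centre
#'   convention).
#' @param r_max_um maximum radius sampled (> 0).
#' @param n_rays number of rays (default 360, i.e. 1 degree resolution).
#' @param bin_width_um radial step; defaults to one pixel.
#' @param pixel_size_um pixel size; defaults to the image's attribute.
#' @param plaque_id identifier carried into results.
#' @return object of class `radial_profile`: list with `radii` (bin centres,
#'   um), `mean_intensity`, `ray_matrix` (rays x bins), `n_rays`,
#'   `bin_width_um`, `center_um`, `plaque_id`.
#' @export
radial_profile <- function(image, center_um, r_max_um, n_rays = 360L,
                           bin_width_um = NULL,
                           pixel_size_um = attr(image, "pixel_size_um"),
                           plaque_id = NA) {
  if (is.null(pixel_size_um)) stop("pixel_size_um required")
  if (r_max_um <= 0) stop("r_max_um must be > 0")
  if (is.null(bin_width_um)) bin_width_um <- pixel_size_um
  ny <- nrow(image); nx <- ncol(image)
  cy <- center_um[1]; cx <- center_um[2]
  if (cy < 0 || cy > ny * pixel_size_um || cx < 0 || cx > nx * pixel_size_um)
    stop("center outside image")
  radii <- seq(bin_width_um / 2, r_max_um, by = bin_width_um)
  ang <- (seq_len(n_rays) - 1L) * 2 * pi / n_rays
  # sample points for all (ray, bin) at once
  yy <- outer(sin(ang), radii) + cy
  xx <- outer(cos(ang), radii) + cx
  inside <- yy >= pixel_size_um / 2 & yy <= (ny - 0.5) * pixel_size_um &
            xx >= pixel_size_um / 2 & xx <= (nx - 0.5) * pixel_size_um
  keep <- rowSums(!inside) == 0L
  if (!all(keep))
    plq_log("radial_profile: dropped %d/%d border-clipped rays", sum(!keep), n_rays)
  if (!any(keep)) stop("all rays clipped at image border; reduce r_max_um")
  vals <- matrix(bilinear_sample(image, yy[keep, , drop = FALSE],
                                 xx[keep, , drop = FALSE], pixel_size_um),
                 nrow = sum(keep))
  structure(list(plaque_id = plaque_id, center_um = c(cy, cx), radii = radii,
                 mean_intensity = colMeans(vals), ray_matrix = vals,
                 n_rays = sum(keep), bin_width_um = bin_width_um),
            class = "radial_profile")
}

# bilinear interpolation at physical points (y, x) um; pixel centres at
# (i - 0.5) * px for 1-based row/col i
bilinear_sample <- function(image, y_um, x_um, pixel_size_um) {
  fy <- y_um / pixel_size_um + 0.5
  fx <- x_um / pixel_size_um + 0.5
  ny <- nrow(image); nx <- ncol(image)
  y0 <- pmin(pmax(floor(fy), 1), ny - 1); x0 <- pmin(pmax(floor(fx), 1), nx - 1)
  wy <- fy - y0; wx <- fx - x0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  v00 <- image[i00]
  v10 <- image[i00 + rep(c(1L, 0L), each = nrow(i00))]
  v01 <- image[i00 + rep(c(0L, 1L), each = nrow(i00))]
  v11 <- image[i00 + rep(c(1L, 1L), each = nrow(i00))]
  wy <- as.vector(wy); wx <- as.vector(wx)
  v00 * (1 - wy) * (1 - wx) + v10 * wy * (1 - wx) +
    v01 * (1 - wy) * wx + v11 * wy * wx
}

#' Compaction slope from a radial profile
#'
#' Fits the declining segment of the direction-averaged trace by ordinary
#' least squares. The segment starts at `r_peak`, the radius of the maximum
#' of the averaged trace (ties broken toward the last bin attaining the
#' maximum, so core plateaus contribute their edge), and ends at `r_end`,
#' the first radius beyond the peak where the trace falls to within 5% of
#' the background above `B` — i.e. I(r) <= B + 0.05 (I(r_peak) - B) — or the
#' last bin if it never does. Slopes are in intensity units per micrometre;
#' compact plaques give steeply negative slopes, diffuse plaques shallow
#' ones.
#'
#' @param profile a `radial_profile`.
#' @param background background level B (>= 0); see [estimate_background()].
#' @param end_frac declining-segment endpoint fraction above background
#'   (default 0.05).
#' @param peak_tol relative tolerance for the peak: the segment starts at
#'   the last bin with I >= B + (1 - peak_tol)(max(I) - B). Bilinear
#'   sampling blurs the core edge by a fraction of a bin, so demanding the
#'   exact maximum would start the fit one bin into the plateau; default
#'   0.05.
#' @return list of class `compaction_result`: plaque_id, slope, intercept,
#'   r_peak, r_end, r_squared, background, n_bins, valid (FALSE when the
#'   segment holds fewer than 3 bins — e.g. a flat trace — rather than an
#'   error).
#' @export
compaction_slope <- function(profile, background = 0, end_frac = 0.05,
                             peak_tol = 0.05) {
  stopifnot(inherits(profile, "radial_profile"))
  if (background < 0) stop("background must be >= 0")
  r <- profile$radii; I <- profile$mean_intensity
  invalid <- function(reason) structure(
    list(plaque_id = profile$plaque_id, slope = NA_real_, intercept = NA_real_,
         r_peak = NA_real_, r_end = NA_real_, r_squared = NA_real_,
         background = background, n_bins = 0L, valid = FALSE, reason = reason),
    class = "compaction_result")
  # last bin attaining the (tolerance-band) maximum: plateaus contribute
  # their edge, not their first bin
  ipk <- max(which(I >= background + (1 - peak_tol) * (max(I) - background)))
  if (ipk >= length(r)) return(invalid("no declining segment after peak"))
  floor_lvl <- background + end_frac * (I[ipk] - background)
  after <- which(seq_along(I) > ipk & I <= floor_lvl)
  iend <- if (length(after)) min(after) else length(r)
  seg <- ipk:iend
  if (length(seg) < 3L) return(invalid("declining segment has < 3 bins"))
  x <- r[seg]; y <- I[seg]
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    plaque_id = profile$plaque_id,
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    r_peak = r[ipk], r_end = r[iend],
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    background = background, n_bins = length(seg), valid = TRUE,
    reason = NA_character_), class = "compaction_result")
}

#' Background level outside plaques
#'
#' Mean intensity over pixels outside all plaque masks dilated by
#' `dilate_um`, the default background for the compaction-slope endpoint
#' and the spheroid threshold when none is supplied.
#'
#' @param image numeric matrix.
#' @param plaque_mask logical matrix of plaque foreground.
#' @param dilate_um dilation radius in micrometres (default 5).
#' @param pixel_size_um pixel size.
#' @return scalar mean background intensity.
#' @export
estimate_background <- function(image, plaque_mask, dilate_um = 5,
                                pixel_size_um = attr(image, "pixel_size_um")) {
  if (is.null(pixel_size_um)) stop("pixel_size_um required")
  r_px <- max(1L, round(dilate_um / pixel_size_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  dil <- EBImage::dilate(matrix(as.numeric(plaque_mask), nrow(plaque_mask)), brush) > 0
  outside <- !dil
  if (!any(outside)) stop("no pixels outside dilated plaque masks")
  mean(image[outside])
}

#' Plaque burden per anatomical region
#'
#' For each region of a label mask (cortex, hippocampus, thalamus, ...),
#' the percent area covered by the plaque mask, the plaque count (particles
#' assigned by centroid), and the mean plaque size.
#'
#' @param plaque_mask logical matrix of plaque foreground.
#' @param region_label_mask integer matrix of region labels (0 = outside any
#'   region) or a list of named logical masks.
#' @param region_names optional names for integer labels.
#' @param pixel_size_um pixel size.
#' @param min_area_um2 minimum particle size for the count (default 10).
#' @return data.frame: region, percent_area, plaque_count, mean_size_um2.
#' @export
plaque_burden <- function(plaque_mask, region_label_mask, region_names = NULL,
                          pixel_size_um = attr(plaque_mask, "pixel_size_um"),
                          min_area_um2 = 10) {
  if (is.null(pixel_size_um) || is.na(pixel_size_um)) stop("pixel_size_um required")
  if (is.list(region_label_mask)) {
    lab <- matrix(0L, nrow(plaque_mask), ncol(plaque_mask))
    for (i in seq_along(region_label_mask)) lab[region_label_mask[[i]]] <- i
    region_names <- names(region_label_mask)
    region_label_mask <- lab
  }
  if (!all(dim(plaque_mask) == dim(region_label_mask)))
    stop("mask shapes differ")
  ids <- sort(unique(as.vector(region_label_mask)))
  ids <- ids[ids > 0]
  if (!length(ids)) stop("region label mask holds no regions")
  if (is.null(region_names)) region_names <- paste0("region_", ids)
  parts <- label_particles(binary_mask(plaque_mask & TRUE, pixel_size_um),
                           min_area_um2 = min_area_um2,
                           pixel_size_um = pixel_size_um)
  cy <- round(parts$centroid_y_um / pixel_size_um + 0.5)
  cx <- round(parts$centroid_x_um / pixel_size_um + 0.5)
  part_region <- if (nrow(parts)) region_label_mask[cbind(cy, cx)] else integer()
  out <- lapply(seq_along(ids), function(k) {
    id <- ids[k]
    in_region <- region_label_mask == id
    n_region <- sum(in_region)
    if (n_region == 0L) stop(sprintf("region '%s' is empty", region_names[k]))
    n_plq <- sum(plaque_mask & in_region)
    here <- part_region == id
    data.frame(region = region_names[k],
               percent_area = 100 * n_plq / n_region,
               plaque_count = sum(here),
               mean_size_um2 = if (any(here)) mean(parts$area_um2[here]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Distribution summary and modality of per-plaque intensities
#'
#' Returns the raw values, a Gaussian-kernel density (Silverman's
#' rule-of-thumb bandwidth), and a modality count: the number of local
#' density maxima whose prominence is at least 10% of the global density
#' maximum. Unimodal intensity distributions indicate a homogeneous plaque
#' population; extra modes (e.g. a low-intensity shoulder) indicate the
#' emergence of diffuse deposits. With fewer than 20 values the modality
#' count is flagged unreliable.
#'
#' @param values numeric vector of per-plaque mean intensities, or a
#'   data.frame with a `mean_intensity` column (e.g. [label_particles()]
#'   output).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   global density maximum (default 0.1).
#' @return list: values, density (stats::density object), modality,
#'   reliable, n.
#' @export
intensity_distribution <- function(values, prominence_frac = 0.1) {
  if (is.data.frame(values)) values <- values$mean_intensity
  if (!length(values)) stop("no particles supplied")
  n <- length(values)
  if (n == 1L)
    return(list(values = values, density = NULL, modality = 1L,
                reliable = FALSE, n = n))
  d <- stats::density(values, bw = "nrd0")
  modality <- count_modes(d$y, prominence_frac * max(d$y))
  list(values = values, density = d, modality = modality,
       reliable = n >= 20L, n = n)
}

# local maxima with prominence >= min_prom; prominence of a peak is its
# height above the highest of the two minimal saddles separating it from
# higher terrain (boundary treated as height 0)
count_modes <- function(y, min_prom) {
  n <- length(y)
  is_peak <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) is_peak <- c(1L, is_peak)
  if (y[n] > y[n - 1]) is_peak <- c(is_peak, n)
  if (!length(is_peak)) return(0L)
  prom <- vapply(is_peak, function(p) {
    h <- y[p]
    left <- if (p > 1) y[1:(p - 1)] else numeric()
    right <- if (p < n) y[(p + 1):n] else numeric()
    lh <- which(left >= h); rh <- which(right >= h)
    lmin <- if (length(lh)) min(y[(max(lh) ):(p - 1)]) else 0
    rmin <- if (length(rh)) min(y[(p + 1):(p + min(rh))]) else 0
    h - max(lmin, rmin)
  }, numeric(1))
  sum(prom >= min_prom)
}
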