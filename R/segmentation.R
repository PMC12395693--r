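#' Maximum-intensity projection through a z window
#'
#' Projects one channel over an `n_slices`-slice window centred on `z_center`
#' (0-based slice index), the standard preparation for per-plaque analysis:
#' ten optical slices through the plaque core collapse the 3-D stain into a
#' single plane while rejecting out-of-focus planes. Windows that would
#' extend past the stack border are shrunk to fit and the shrink is logged.
#'
#' @param stack an `image_stack`.
#' @param channel channel name.
#' @param z_center 0-based index of the central slice.
#' @param n_slices window depth (default 10).
#' @return numeric matrix (y, x) with attributes `pixel_size_um`, `channel`.
#' @export
project_max <- function(stack, channel, z_center = NULL, n_slices = 10L) {
  arr <- get_channel(stack, channel)   # errors on unknown channel
  nz <- dim(arr)[1]
  if (is.null(z_center)) z_center <- (nz - 1L) %/% 2L
  if (n_slices < 1L || n_slices > nz)
    stop("n_slices must be in [1, stack depth]")
  zc <- as.integer(z_center) + 1L      # to 1-based
  if (zc < 1L || zc > nz) stop("z_center outside stack")
  lo <- max(1L, zc - (n_slices - 1L) %/% 2L)
  hi <- min(nz, zc + n_slices %/% 2L)
  if (hi - lo + 1L < n_slices)
    plq_log("projection window clipped at stack border: %d of %d slices used",
            hi - lo + 1L, n_slices)
  out <- apply(arr[lo:hi, , , drop = FALSE], c(2, 3), max)
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  attr(out, "channel") <- channel
  out
}

#' Construct a binary mask with threshold provenance
#'
#' @param fg logical matrix (foreground TRUE).
#' @param pixel_size_um pixel size in micrometres.
#' @param channel,method,threshold provenance: source channel, threshold
#'   method name, and the threshold value T actually applied.
#' @return logical matrix of class `binary_mask` with provenance attributes.
#' @export
binary_mask <- function(fg, pixel_size_um, channel = NA_character_,
                        method = NA_character_, threshold = NA_real_) {
  stopifnot(is.logical(fg), is.matrix(fg))
  structure(fg, pixel_size_um = pixel_size_um, channel = channel,
            method = method, threshold = threshold,
            class = c("binary_mask", "matrix", "array"))
}

#' Apply a scalar threshold to an image (strict inequality)
#'
#' Foreground is `image > threshold` everywhere in this package; on a
#' constant image any threshold at or above the constant therefore yields an
#' empty mask rather than a full one.
#'
#' @param image numeric matrix.
#' @param threshold scalar T.
#' @param pixel_size_um pixel size (defaults to the image's attribute).
#' @param channel,method provenance strings.
#' @return a `binary_mask`.
#' @export
apply_threshold <- function(image, threshold,
                            pixel_size_um = attr(image, "pixel_size_um"),
                            channel = attr(image, "channel"), method = "manual") {
  if (is.null(pixel_size_um)) pixel_size_um <- NA_real_
  binary_mask(matrix(image > threshold, nrow(image), ncol(image)),
              pixel_size_um, channel %||% NA_character_, method, threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean + k·SD threshold
#'
#' T = mean + k·SD over all pixels (population SD, divide by N, matching
#' common image-software convention); foreground is intensity strictly above
#' T. With the default k = 2 this is the plaque-shape threshold: two
#' standard deviations above the average fluorescence intensity of the
#' image.
#'
#' @param image numeric matrix.
#' @param k number of SDs above the mean (>= 0); default 2.
#' @inheritParams apply_threshold
#' @return a `binary_mask` whose `threshold` attribute records T.
#' @export
threshold_mean_sd <- function(image, k = 2,
                              pixel_size_um = attr(image, "pixel_size_um"),
                              channel = attr(image, "channel")) {
  if (length(image) == 0L) stop("empty image")
  if (k < 0) stop("k must be >= 0")
  m <- mean(image)
  s <- sqrt(mean((image - m)^2))
  T <- m + k * s
  apply_threshold(image, T, pixel_size_um, channel, method = sprintf("mean+%gsd", k))
}

# 256-bin histogram spanning [min, max] of the image; reproduces 8-bit-style
# behaviour of the classic auto-threshold presets on arbitrary dtypes.
image_histogram <- function(image, n_bins = 256L) {
  lo <- min(image); hi <- max(image)
  if (hi <= lo) stop("constant image: histogram is degenerate")
  w <- (hi - lo) / n_bins
  idx <- pmin(floor((image - lo) / w), n_bins - 1L)   # bin indices 0..n-1
  counts <- tabulate(as.integer(idx) + 1L, nbins = n_bins)
  list(counts = counts, lo = lo, width = w, n_bins = n_bins)
}

#' IsoData (iterative intermeans) automatic threshold
#'
#' The classic "Default" auto-threshold: on a 256-bin histogram, iterate
#' T_{i+1} = (mean of bins <= T_i + mean of bins > T_i) / 2 (bin-index
#' arithmetic, floor at each step) to its fixed point. Returns the upper
#' edge of the fixed-point bin in image units, so `image > T` separates the
#' two classes. For a perfectly bimodal histogram with spikes at bins 0 and
#' 255 the floor tie rule lands the fixed point on bin 127, i.e. the
#' midpoint.
#'
#' @param image numeric matrix with at least two distinct values.
#' @return scalar threshold in image units.
#' @export
threshold_isodata <- function(image) {
  h <- image_histogram(image)
  cts <- h$counts
  bins <- seq_len(h$n_bins) - 1L
  t <- h$n_bins %/% 2L
  for (iter in 1:1000) {
    below <- bins <= t
    c1 <- sum(cts[below]); c2 <- sum(cts[!below])
    if (c1 == 0L) { t <- t + 1L; next }
    if (c2 == 0L) { t <- t - 1L; next }
    mu1 <- sum(cts[below] * bins[below]) / c1
    mu2 <- sum(cts[!below] * bins[!below]) / c2
    t_new <- as.integer(floor((mu1 + mu2) / 2))
    if (t_new == t) break
    t <- t_new
  }
  h$lo + (t + 1) * h$width
}

#' Triangle automatic threshold
#'
#' On a 256-bin histogram, draws the line from the histogram peak to the
#' farthest non-empty tail bin (the side with the longer tail) and returns
#' the bin that maximises the perpendicular distance from the histogram to
#' that line. Ties break toward the lower threshold. Returns the upper edge
#' of the selected bin in image units.
#'
#' @param image numeric matrix with at least two distinct values.
#' @return scalar threshold in image units.
#' @export
threshold_triangle <- function(image) {
  h <- image_histogram(image)
  cts <- as.numeric(h$counts)
  nz <- which(cts > 0)
  first <- min(nz) - 1L; last <- max(nz) - 1L     # 0-based
  peak <- which.max(cts) - 1L
  # choose the longer tail; if equal, the right tail (then flip is a no-op
  # for symmetric histograms and the lower-threshold tie rule applies below)
  right <- (last - peak) >= (peak - first)
  if (right) { a <- peak; b <- last } else { a <- peak; b <- first }
  if (a == b) stop("degenerate histogram: peak coincides with tail end")
  xs <- if (right) a:b else b:a
  # perpendicular distance from (x, h[x]) to line (a, h[a]) -- (b, 0)
  x1 <- a; y1 <- cts[a + 1]; x2 <- b; y2 <- 0
  d <- abs((y2 - y1) * xs - (x2 - x1) * cts[xs + 1] + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  best <- xs[d == max(d)]
  t <- min(best)                                   # tie: lower threshold
  h$lo + (t + 1) * h$width
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch only diagonally with a union-find pass over label pairs.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  ny <- nrow(lab); nx <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-ny, -nx]), as.vector(lab[-1, -1])),   # NW-SE
    cbind(as.vector(lab[-ny, -1]), as.vector(lab[-1, -nx])))   # NE-SW
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Particle analysis: label and measure connected components
#'
#' 8-connected components of a binary mask (pixels touching diagonally
#' belong to one particle), with components smaller than `min_area_um2`
#' discarded, and per-particle geometry and intensity recorded — area,
#' centroid (voxel-centre physical coordinates), mean and maximum intensity
#' over the particle's pixels.
#'
#' @param mask a `binary_mask` (or logical matrix with `pixel_size_um`).
#' @param intensity_image numeric matrix, same shape as `mask`.
#' @param min_area_um2 minimum particle area kept (default 10).
#' @param pixel_size_um pixel size; defaults to the mask's attribute.
#' @return data.frame with columns label, area_um2, centroid_y_um,
#'   centroid_x_um, mean_intensity, max_intensity.
#' @export
label_particles <- function(mask, intensity_image = NULL, min_area_um2 = 10,
                            pixel_size_um = attr(mask, "pixel_size_um")) {
  if (is.null(pixel_size_um) || is.na(pixel_size_um))
    stop("pixel_size_um required")
  if (is.null(intensity_image))
    intensity_image <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!all(dim(mask) == dim(intensity_image)))
    stop("mask and intensity image shapes differ")
  lab <- label_components_8(mask)
  n <- max(lab)
  empty <- data.frame(label = integer(), area_um2 = double(),
                      centroid_y_um = double(), centroid_x_um = double(),
                      mean_intensity = double(), max_intensity = double())
  if (n == 0L) return(empty)
  px2 <- pixel_size_um^2
  idx <- which(lab > 0L)
  l <- lab[idx]
  npx <- tabulate(l, nbins = n)
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  inten <- intensity_image[idx]
  sum_y <- tapply(rows, l, sum); sum_x <- tapply(cols, l, sum)
  mean_i <- tapply(inten, l, mean); max_i <- tapply(inten, l, max)
  out <- data.frame(
    label = seq_len(n),
    area_um2 = npx * px2,
    centroid_y_um = (as.numeric(sum_y) / npx - 0.5) * pixel_size_um,
    centroid_x_um = (as.numeric(sum_x) / npx - 0.5) * pixel_size_um,
    mean_intensity = as.numeric(mean_i),
    max_intensity = as.numeric(max_i))
  out <- out[out$area_um2 >= min_area_um2, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "label_image") <- lab
  out
}

#' Microglial soma intensity cutoff
#'
#' The Iba1 intensity of microglial cell bodies defines the cutoff that
#' separates barrier-grade processes (brighter than baseline processes) from
#' baseline arborisation. With a supplied soma mask the cutoff is the mean
#' Iba1 intensity over soma pixels. In `auto` mode somata are found as
#' 8-connected components of the IsoData-thresholded Iba1 image with area at
#' least `soma_min_area_um2`, and the cutoff is the mean over their pixels.
#'
#' @param iba1_image numeric matrix (Iba1 projection).
#' @param soma_mask optional logical matrix marking soma pixels; NULL = auto.
#' @param soma_min_area_um2 minimum soma area in auto mode (default 30).
#' @param pixel_size_um pixel size (required in auto mode).
#' @return scalar cutoff intensity.
#' @export
soma_cutoff <- function(iba1_image, soma_mask = NULL, soma_min_area_um2 = 30,
                        pixel_size_um = attr(iba1_image, "pixel_size_um")) {
  if (length(iba1_image) == 0L) stop("empty image")
  if (!is.null(soma_mask)) {
    if (!any(soma_mask)) stop("supplied soma mask is empty")
    return(mean(iba1_image[soma_mask]))
  }
  T <- tryCatch(threshold_isodata(iba1_image),
                error = function(e) stop("auto soma detection failed: ", conditionMessage(e)))
  fg <- binary_mask(iba1_image > T, pixel_size_um %||% NA_real_)
  parts <- label_particles(fg, iba1_image, min_area_um2 = soma_min_area_um2,
                           pixel_size_um = pixel_size_um)
  if (nrow(parts) == 0L)
    stop("auto soma detection found no soma-sized component; no cutoff definable")
  lab <- attr(parts, "label_image")
  # restrict to pixels of the retained (soma-sized) components
  keep_px <- tabulate(lab[lab > 0L], nbins = max(lab)) * pixel_size_um^2 >= soma_min_area_um2
  mean(iba1_image[lab > 0L & keep_px[pmax(lab, 1L)]])
}
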