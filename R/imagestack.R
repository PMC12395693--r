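#' Multi-channel 3-D image stack
#'
#' Container for a multi-channel confocal stack: a numeric array with
#' dimensions (z, y, x, channel), unique channel names, and the physical
#' voxel spacing. All analysis functions in the package report physical
#' units (micrometres) derived from `pixel_size_um` and `z_step_um`.
#'
#' Coordinate convention: voxel indices are 0-based in the external
#' interfaces (configs, manifests); the physical coordinate of voxel `i`
#' along an axis with spacing `s` is the voxel centre, `(i + 0.5) * s`.
#'
#' @param data numeric array, dim = c(nz, ny, nx, n_channels); non-negative.
#'   A 3-D array is promoted to a single-channel stack.
#' @param channel_names character vector, one unique name per channel.
#' @param pixel_size_um lateral pixel size in micrometres (> 0).
#' @param z_step_um axial step in micrometres (> 0).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, channel_names, pixel_size_um, z_step_um = pixel_size_um) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("`data` must be a (z, y, x, channel) array")
  if (length(channel_names) != dim(data)[4L])
    stop("length(channel_names) must equal the channel-axis extent")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (!is.numeric(z_step_um) || z_step_um <= 0)
    stop("z_step_um must be > 0")
  if (min(data) < 0)
    stop("intensities must be non-negative")
  structure(
    list(data = data, channel_names = as.character(channel_names),
         pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = as.numeric(z_step_um)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d channel(s) [%s], z=%d, %d x %d px, %.4g um/px, z-step %.4g um\n",
              d[4], paste(x$channel_names, collapse = ", "), d[1], d[2], d[3],
              x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Extract one channel of a stack as a (z, y, x) array
#'
#' @param stack an `image_stack`.
#' @param channel channel name.
#' @return 3-D numeric array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(channel, stack$channel_names)
  if (is.na(i))
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(stack$channel_names, collapse = ", ")))
  arr <- stack$data[, , , i, drop = FALSE]
  dim(arr) <- dim(stack$data)[1:3]
  arr
}

#' Write an image stack to multi-page TIFF with a YAML sidecar
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...)
#' and stored as 32-bit float scaled into \[0, 1\]; the scale factor and all
#' metadata (channel names, pixel size, z-step) go to `<path>.yaml` so that
#' [read_stack()] round-trips data and metadata.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (ci in seq_len(d[4])) for (zi in seq_len(d[1])) {
    pages[[k]] <- matrix(stack$data[zi, , , ci] / scale, d[2], d[3])
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channel_names = as.list(stack$channel_names),
               n_z = d[1], n_y = d[2], n_x = d[3],
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               intensity_scale = scale)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Read an image stack from TIFF
#'
#' Metadata are taken from the YAML sidecar written by [write_stack()] when
#' present. Without a sidecar the file is read as a flat page list: supply
#' `channel_map` to name the channels (pages are split channel-major) and
#' `pixel_size_um` / `z_step_um` as fallbacks; using a fallback logs a
#' warning, since silent unit changes corrupt every downstream metric.
#'
#' @param path TIFF path.
#' @param channel_map optional character vector of channel names expected in
#'   the file; every name must be present or an error names the missing one.
#' @param pixel_size_um,z_step_um fallback spacing used (with a warning) when
#'   the file carries no resolution metadata.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, channel_map = NULL, pixel_size_um = NULL, z_step_um = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    nms <- unlist(meta$channel_names)
    nz <- meta$n_z; nc <- length(nms)
    px <- meta$pixel_size_um; zs <- meta$z_step_um
    scale <- meta$intensity_scale
  } else {
    if (is.null(channel_map))
      stop("file has no sidecar metadata; supply channel_map")
    nms <- channel_map
    nc <- length(nms)
    if (length(pages) %% nc != 0L)
      stop(sprintf("%d pages cannot be split into %d channels", length(pages), nc))
    nz <- length(pages) %/% nc
    if (is.null(pixel_size_um))
      stop("file carries no pixel size; supply pixel_size_um")
    plq_log("no resolution tags in %s; falling back to configured pixel_size_um = %g",
            path, pixel_size_um)
    warning(sprintf("pixel size for %s taken from config (%g um/px), not file tags",
                    basename(path), pixel_size_um))
    px <- pixel_size_um
    zs <- if (is.null(z_step_um)) pixel_size_um else z_step_um
    scale <- 1
  }
  if (!is.null(channel_map)) {
    missing <- setdiff(channel_map, nms)
    if (length(missing))
      stop(sprintf("channel(s) not present in %s: %s", basename(path),
                   paste(missing, collapse = ", ")))
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(nz, ny, nx, nc))
  k <- 1L
  for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
    arr[zi, , , ci] <- pages[[k]] * scale
    k <- k + 1L
  }
  image_stack(arr, nms, px, zs)
}
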