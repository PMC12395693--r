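#' Configuration for a synthetic confocal scene
#'
#' Describes a scene the generator can render exactly: amyloid plaques with
#' radially decaying intensity (compact = steep decay, diffuse = shallow),
#' microglial somata and barrier arcs of controlled angular extent around
#' each plaque, punctate channels (phagosomes, engulfed amyloid, spheroid
#' halos), nuclei with transcript spots, and shot/read noise. Every rendered
#' object gets exactly one manifest entry in the returned ground truth, so
#' each analysis metric has an exact recovery target.
#'
#' @param image_shape c(z, y, x) voxel counts.
#' @param pixel_size_um,z_step_um voxel spacing in micrometres.
#' @param plaques list of plaque descriptors:
#'   `center` c(z, y, x) 0-based voxels, `core_radius_um` (> 0),
#'   `peak_intensity` (>= 0), `decay_slope` intensity per um (>= 0),
#'   `decay_kind` "linear" (I = peak - slope (r - core), clipped at 0) or
#'   "exponential" (I = peak exp(-slope (r - core) / peak), same initial
#'   slope).
#' @param microglia one descriptor recycled over plaques, or a list of
#'   per-plaque descriptors: `coverage_deg` in \[0, 360\],
#'   `barrier_annulus_um`, `barrier_intensity`, optional
#'   `barrier_start_deg` (uniform random when absent), `n_somata`,
#'   `soma_radius_um`, `soma_intensity`, `process_baseline_intensity`,
#'   optional `soma_positions` (list of c(y, x) um).
#' @param puncta_channels named list per channel: `count`, `radius_um`,
#'   `intensity`, `placement` one of "inside_microglia", "spheroid_halo",
#'   "nuclei", "random", optional `halo_width_um` (default 10) and
#'   `baseline` (uniform channel background, default 0).
#' @param nuclei NULL or list: `count`, `radius_um`, `intensity`,
#'   `ms4a6d_positive_frac`, `aif1_given_ms4a6d`, `spot_radius_um`,
#'   `spots_per_gene`.
#' @param noise list: `gaussian_sigma` (>= 0), `poisson` (TRUE/FALSE).
#' @param seed integer seed; required, all randomness in the scene derives
#'   from it and a fixed seed makes the rendered stack bit-identical.
#' @return validated list of class `scene_config`.
#' @export
scene_config <- function(image_shape, pixel_size_um, z_step_um = 1,
                         plaques = list(), microglia = NULL,
                         puncta_channels = list(), nuclei = NULL,
                         noise = list(gaussian_sigma = 0, poisson = FALSE),
                         seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (length(image_shape) != 3L || any(image_shape < 1))
    stop("image_shape must be c(z, y, x)")
  if (pixel_size_um <= 0 || z_step_um <= 0) stop("voxel spacing must be > 0")
  plaques <- lapply(plaques, function(p) {
    p$decay_kind <- p$decay_kind %||% "linear"
    p$decay_slope <- p$decay_slope %||% 0
    if (p$core_radius_um <= 0) stop("core_radius_um must be > 0")
    if (p$peak_intensity < 0 || p$decay_slope < 0) stop("intensities/slopes must be >= 0")
    if (!p$decay_kind %in% c("linear", "exponential")) stop("unknown decay_kind")
    p
  })
  if (!is.null(microglia)) {
    if (!is.null(microglia$coverage_deg)) microglia <- rep(list(microglia), length(plaques))
    if (length(microglia) != length(plaques))
      stop("need one microglia descriptor per plaque")
    microglia <- lapply(microglia, function(m) {
      # barrier processes are brighter than somata: the analyzer thresholds
      # Iba1 at the soma-mean cutoff, so the rendered barrier must exceed it
      m$barrier_annulus_um <- m$barrier_annulus_um %||% 3
      m$barrier_intensity <- m$barrier_intensity %||% 200
      m$n_somata <- m$n_somata %||% 2L
      m$soma_radius_um <- m$soma_radius_um %||% 4
      m$soma_intensity <- m$soma_intensity %||% 150
      m$process_baseline_intensity <- m$process_baseline_intensity %||% 10
      if (m$coverage_deg < 0 || m$coverage_deg > 360)
        stop("coverage_deg must be in [0, 360]")
      if (m$barrier_annulus_um <= 0 || m$soma_radius_um <= 0)
        stop("radii must be > 0")
      m
    })
  }
  for (nm in names(puncta_channels)) {
    pc <- puncta_channels[[nm]]
    if (pc$radius_um <= 0) stop("puncta radius must be > 0")
    if (pc$intensity < 0) stop("puncta intensity must be >= 0")
    puncta_channels[[nm]]$placement <- pc$placement %||% "random"
    puncta_channels[[nm]]$halo_width_um <- pc$halo_width_um %||% 10
    puncta_channels[[nm]]$baseline <- pc$baseline %||% 0
    if (puncta_channels[[nm]]$baseline < 0) stop("baseline must be >= 0")
  }
  noise$gaussian_sigma <- noise$gaussian_sigma %||% 0
  noise$poisson <- isTRUE(noise$poisson)
  if (noise$gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 plaques = plaques, microglia = microglia,
                 puncta_channels = puncta_channels, nuclei = nuclei,
                 noise = noise, seed = as.integer(seed)),
            class = "scene_config")
}

# outer radius at which a plaque's rendered intensity reaches (near) zero
plaque_extent_um <- function(p) {
  if (p$decay_kind == "linear") {
    if (p$decay_slope > 0) p$core_radius_um + p$peak_intensity / p$decay_slope
    else p$core_radius_um
  } else {
    # exponential never reaches 0; use the 1%-of-peak radius
    rate <- p$decay_slope / max(p$peak_intensity, 1e-12)
    if (rate > 0) p$core_radius_um + log(100) / rate else p$core_radius_um
  }
}

# radial intensity law at distance r (um) from the centre, before noise
plaque_intensity_at <- function(p, r) {
  inside <- r <= p$core_radius_um
  out <- numeric(length(r))
  out[inside] <- p$peak_intensity
  ro <- r[!inside] - p$core_radius_um
  out[!inside] <- if (p$decay_kind == "linear") {
    pmax(0, p$peak_intensity - p$decay_slope * ro)
  } else {
    p$peak_intensity * exp(-p$decay_slope * ro / max(p$peak_intensity, 1e-12))
  }
  out
}

# paint values into plane by pmax over a bounding box around (cy, cx) um
paint_radial <- function(plane, cy, cx, r_um, px, value_fn) {
  ny <- nrow(plane); nx <- ncol(plane)
  r0 <- max(1L, floor((cy - r_um) / px + 0.5)); r1 <- min(ny, ceiling((cy + r_um) / px + 0.5))
  c0 <- max(1L, floor((cx - r_um) / px + 0.5)); c1 <- min(nx, ceiling((cx + r_um) / px + 0.5))
  if (r0 > r1 || c0 > c1) return(plane)
  yy <- ((r0:r1) - 0.5) * px - cy
  xx <- ((c0:c1) - 0.5) * px - cx
  rr <- sqrt(outer(yy^2, xx^2, `+`))
  th <- atan2(matrix(yy, length(yy), length(xx)),
              matrix(xx, length(yy), length(xx), byrow = TRUE))
  vals <- value_fn(rr, th)
  plane[r0:r1, c0:c1] <- pmax(plane[r0:r1, c0:c1], vals)
  plane
}

#' Render a synthetic scene with its ground-truth manifest
#'
#' Renders every configured object into a noiseless multi-channel stack,
#' records the exact generative parameters and the realised (discretised)
#' object geometry in a manifest, then applies the configured noise
#' (Poisson resampling first, then additive Gaussian — shot noise precedes
#' detector read noise). Plaques whose centres are closer than the sum of
#' their rendered extents raise an error, since overlapping deposits have
#' no unambiguous ground truth.
#'
#' Channels rendered: `ThioS` (plaques), `Iba1` (process baseline + somata +
#' barrier arcs) when microglia are configured, one channel per configured
#' puncta channel, and `DAPI`, `Ms4a6d`, `Aif1` when nuclei are configured.
#'
#' @param config a [scene_config()].
#' @return list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `ground_truth`): `plaques` data.frame (id, centre, core radius,
#'   peak, decay slope/kind, true coverage, barrier geometry, realised mask
#'   area um^2), `puncta` data.frame (channel, n, realised areas inside /
#'   outside the plaque mask), `nuclei` data.frame and `nuclei_labels`
#'   matrix, `noise`, `seed`.
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  nz <- config$image_shape[1]; ny <- config$image_shape[2]; nx <- config$image_shape[3]
  px <- config$pixel_size_um; zs <- config$z_step_um
  np <- length(config$plaques)

  # overlap guard in the lateral plane
  if (np >= 2L) {
    cen <- t(vapply(config$plaques, function(p)
      c((p$center[2] + 0.5) * px, (p$center[3] + 0.5) * px), numeric(2)))
    ext <- vapply(config$plaques, plaque_extent_um, numeric(1))
    for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
      d <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      if (d < ext[i] + ext[j])
        stop(sprintf("plaques %d and %d overlap (distance %.1f um < %.1f um): ambiguous ground truth",
                     i, j, d, ext[i] + ext[j]))
    }
  }

  channels <- character()
  if (np > 0L || TRUE) channels <- "ThioS"
  if (!is.null(config$microglia)) channels <- c(channels, "Iba1")
  channels <- c(channels, names(config$puncta_channels))
  if (!is.null(config$nuclei)) channels <- c(channels, "DAPI", "Ms4a6d", "Aif1")
  arr <- array(0, c(nz, ny, nx, length(channels)))
  chan <- function(nm) match(nm, channels)
  zwin <- function(cz, extent_um) {
    h <- ceiling(extent_um / zs)
    max(1L, cz + 1L - h):min(nz, cz + 1L + h)
  }

  plq_rows <- list()
  plaque_plane <- matrix(0, ny, nx)  # noiseless composite, for realised areas

  for (i in seq_len(np)) {
    p <- config$plaques[[i]]
    cz <- as.integer(p$center[1])
    cy <- (p$center[2] + 0.5) * px; cx <- (p$center[3] + 0.5) * px
    ext <- plaque_extent_um(p)
    plane <- paint_radial(matrix(0, ny, nx), cy, cx, ext + px, px,
                          function(rr, th) plaque_intensity_at(p, rr))
    for (z in zwin(cz, ext)) arr[z, , , chan("ThioS")] <- pmax(arr[z, , , chan("ThioS")], plane)
    plaque_plane <- pmax(plaque_plane, plane)

    cov_deg <- NA_real_; start_deg <- NA_real_; ann <- NA_real_
    if (!is.null(config$microglia)) {
      m <- config$microglia[[i]]
      cov_deg <- m$coverage_deg
      ann <- m$barrier_annulus_um
      start_deg <- m$barrier_start_deg %||% stats::runif(1, 0, 360)
      iba <- matrix(0, ny, nx)
      if (cov_deg > 0) {
        mid <- (start_deg + cov_deg / 2) * pi / 180
        half <- cov_deg / 2 * pi / 180
        iba <- paint_radial(iba, cy, cx, ext + ann + px, px, function(rr, th) {
          dth <- abs(((th - mid + pi) %% (2 * pi)) - pi)
          ifelse(rr >= ext & rr <= ext + ann & dth <= half + 1e-12,
                 m$barrier_intensity, 0)
        })
      }
      somata <- m$soma_positions
      if (is.null(somata)) {
        somata <- lapply(seq_len(m$n_somata), function(k) {
          a <- stats::runif(1, 0, 2 * pi)
          d <- ext + ann + 3 * m$soma_radius_um + stats::runif(1, 0, 5)
          c(cy + d * sin(a), cx + d * cos(a))
        })
      }
      for (s in somata)
        iba <- paint_radial(iba, s[1], s[2], m$soma_radius_um + px, px,
                            function(rr, th) ifelse(rr <= m$soma_radius_um,
                                                    m$soma_intensity, 0))
      for (z in zwin(cz, ext + ann))
        arr[z, , , chan("Iba1")] <- pmax(arr[z, , , chan("Iba1")], iba)
    }

    plq_rows[[i]] <- data.frame(
      plaque_id = i, center_z = cz,
      center_y_um = cy, center_x_um = cx,
      core_radius_um = p$core_radius_um, peak_intensity = p$peak_intensity,
      decay_slope = p$decay_slope, decay_kind = p$decay_kind,
      extent_um = ext,
      coverage_deg = cov_deg, coverage_fraction = cov_deg / 360,
      barrier_start_deg = start_deg, barrier_annulus_um = ann,
      area_um2 = NA_real_)
  }
  truth_plaques <- if (np) do.call(rbind, plq_rows) else
    data.frame(plaque_id = integer(), center_z = integer(), center_y_um = double(),
               center_x_um = double(), core_radius_um = double(),
               peak_intensity = double(), decay_slope = double(),
               decay_kind = character(), extent_um = double(),
               coverage_deg = double(), coverage_fraction = double(),
               barrier_start_deg = double(), barrier_annulus_um = double(),
               area_um2 = double())
  if (np) {
    # realised per-plaque mask area: noiseless pixels > 0 nearest to each centre
    lab_src <- label_components_8(plaque_plane > 0)
    for (i in seq_len(np)) {
      r <- round(truth_plaques$center_y_um[i] / px + 0.5)
      c <- round(truth_plaques$center_x_um[i] / px + 0.5)
      li <- lab_src[r, c]
      truth_plaques$area_um2[i] <- if (li > 0) sum(lab_src == li) * px^2 else 0
    }
  }
  if (!is.null(config$microglia)) {
    base <- vapply(config$microglia, `[[`, numeric(1), "process_baseline_intensity")
    arr[, , , chan("Iba1")] <- arr[, , , chan("Iba1")] + max(base)
  }

  # nuclei grid with jitter (non-overlapping by construction)
  truth_nuclei <- NULL; nuclei_labels <- NULL
  if (!is.null(config$nuclei)) {
    ncfg <- config$nuclei
    n_nuc <- ncfg$count
    r_nuc <- ncfg$radius_um
    n_side <- ceiling(sqrt(n_nuc))
    cell_y <- ny * px / n_side; cell_x <- nx * px / n_side
    jit <- pmax(0, min(cell_y, cell_x) / 2 - r_nuc - px)
    ord <- sample.int(n_side^2, n_nuc)
    dapi <- matrix(0, ny, nx); nuclei_labels <- matrix(0L, ny, nx)
    spots_ms <- matrix(FALSE, ny, nx); spots_ai <- matrix(FALSE, ny, nx)
    is_ms <- stats::runif(n_nuc) < (ncfg$ms4a6d_positive_frac %||% 0.5)
    is_ai <- rep(FALSE, n_nuc)
    is_ai[is_ms] <- stats::runif(sum(is_ms)) < (ncfg$aif1_given_ms4a6d %||% 0.92)
    centres <- matrix(0, n_nuc, 2)
    for (k in seq_len(n_nuc)) {
      gi <- (ord[k] - 1L) %/% n_side; gj <- (ord[k] - 1L) %% n_side
      cyk <- (gi + 0.5) * cell_y + stats::runif(1, -jit, jit)
      cxk <- (gj + 0.5) * cell_x + stats::runif(1, -jit, jit)
      centres[k, ] <- c(cyk, cxk)
      dapi <- paint_radial(dapi, cyk, cxk, r_nuc + px, px,
                           function(rr, th) ifelse(rr <= r_nuc, ncfg$intensity %||% 100, 0))
      # label pixels of this nucleus
      bb <- which(dapi > 0 & nuclei_labels == 0L)
      nuclei_labels[bb] <- k
      nspot <- ncfg$spots_per_gene %||% 3L
      rs <- ncfg$spot_radius_um %||% (px)
      add_spots <- function(mask) {
        for (s in seq_len(nspot)) {
          a <- stats::runif(1, 0, 2 * pi); d <- stats::runif(1, 0, max(r_nuc - rs, 0))
          sy <- cyk + d * sin(a); sx <- cxk + d * cos(a)
          pr <- round(sy / px + 0.5); pc <- round(sx / px + 0.5)
          rr <- max(1L, round(rs / px))
          ys <- max(1L, pr - rr):min(ny, pr + rr)
          xs <- max(1L, pc - rr):min(nx, pc + rr)
          mask[ys, xs] <- TRUE
        }
        mask
      }
      if (is_ms[k]) spots_ms <- add_spots(spots_ms)
      if (is_ai[k]) spots_ai <- add_spots(spots_ai)
    }
    zmid <- (nz + 1L) %/% 2L
    for (z in seq_len(nz)) arr[z, , , chan("DAPI")] <- dapi
    spot_int <- ncfg$intensity %||% 100
    for (z in seq_len(nz)) {
      arr[z, , , chan("Ms4a6d")] <- spots_ms * spot_int
      arr[z, , , chan("Aif1")] <- spots_ai * spot_int
    }
    truth_nuclei <- data.frame(nucleus = seq_len(n_nuc),
                               center_y_um = centres[, 1], center_x_um = centres[, 2],
                               ms4a6d_pos = is_ms, aif1_pos = is_ai)
  }

  # puncta channels
  punc_rows <- list()
  plaque_fg <- plaque_plane > 0
  for (nm in names(config$puncta_channels)) {
    pc <- config$puncta_channels[[nm]]
    plane <- matrix(0, ny, nx)
    for (k in seq_len(pc$count)) {
      pos <- switch(pc$placement,
        inside_microglia = {
          if (is.null(config$microglia) || np == 0L) stop("inside_microglia placement needs microglia")
          i <- sample.int(np, 1L)
          m <- config$microglia[[i]]
          ext <- plaque_extent_um(config$plaques[[i]])
          cy <- truth_plaques$center_y_um[i]; cx <- truth_plaques$center_x_um[i]
          a <- stats::runif(1, 0, 2 * pi)
          d <- stats::runif(1, ext, ext + m$barrier_annulus_um)
          c(cy + d * sin(a), cx + d * cos(a))
        },
        spheroid_halo = {
          if (np == 0L) stop("spheroid_halo placement needs a plaque")
          i <- sample.int(np, 1L)
          ext <- plaque_extent_um(config$plaques[[i]])
          cy <- truth_plaques$center_y_um[i]; cx <- truth_plaques$center_x_um[i]
          a <- stats::runif(1, 0, 2 * pi)
          d <- stats::runif(1, ext + pc$radius_um + px,
                            ext + pc$radius_um + px + pc$halo_width_um)
          c(cy + d * sin(a), cx + d * cos(a))
        },
        nuclei = {
          if (is.null(truth_nuclei)) stop("nuclei placement needs nuclei")
          i <- sample.int(nrow(truth_nuclei), 1L)
          c(truth_nuclei$center_y_um[i], truth_nuclei$center_x_um[i])
        },
        random = c(stats::runif(1, 0, ny * px), stats::runif(1, 0, nx * px)),
        stop(sprintf("unknown placement '%s'", pc$placement)))
      plane <- paint_radial(plane, pos[1], pos[2], pc$radius_um + px, px,
                            function(rr, th) ifelse(rr <= pc$radius_um, pc$intensity, 0))
    }
    zmid <- if (np) as.integer(config$plaques[[1]]$center[1]) else (nz - 1L) %/% 2L
    for (z in zwin(zmid, 5 * zs))
      arr[z, , , chan(nm)] <- pmax(arr[z, , , chan(nm)], plane)
    if (pc$baseline > 0)
      arr[, , , chan(nm)] <- arr[, , , chan(nm)] + pc$baseline
    fg <- plane > 0
    punc_rows[[nm]] <- data.frame(
      channel = nm, n = pc$count, placement = pc$placement,
      area_um2 = sum(fg) * px^2,
      area_inside_plaque_um2 = sum(fg & plaque_fg) * px^2,
      area_outside_plaque_um2 = sum(fg & !plaque_fg) * px^2)
  }
  truth_puncta <- if (length(punc_rows)) do.call(rbind, c(punc_rows, make.row.names = FALSE)) else
    data.frame(channel = character(), n = integer(), placement = character(),
               area_um2 = double(), area_inside_plaque_um2 = double(),
               area_outside_plaque_um2 = double())

  stack <- image_stack(arr, channels, px, zs)
  if (config$noise$gaussian_sigma > 0 || config$noise$poisson)
    stack <- add_noise(stack, config$noise$gaussian_sigma,
                       poisson_flag = config$noise$poisson,
                       seed = config$seed + 1L)
  truth <- structure(list(plaques = truth_plaques, puncta = truth_puncta,
                          nuclei = truth_nuclei, nuclei_labels = nuclei_labels,
                          noise = config$noise, seed = config$seed),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Add shot and read noise to a stack
#'
#' Poisson resampling of each voxel (if enabled) models shot noise and is
#' applied first; additive Gaussian noise of SD `gaussian_sigma` models
#' detector read noise and is applied second; the result is clipped at 0.
#' The input stack is not modified.
#'
#' @param stack an `image_stack`.
#' @param gaussian_sigma read-noise SD (>= 0).
#' @param poisson_flag apply Poisson resampling first (default FALSE).
#' @param seed integer seed; a fixed seed reproduces the noise field
#'   exactly.
#' @return a new `image_stack`.
#' @export
add_noise <- function(stack, gaussian_sigma, poisson_flag = FALSE, seed) {
  stopifnot(inherits(stack, "image_stack"))
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  d <- stack$data
  if (poisson_flag) d[] <- stats::rpois(length(d), lambda = as.vector(d))
  if (gaussian_sigma > 0) d <- d + stats::rnorm(length(d), 0, gaussian_sigma)
  d[d < 0] <- 0
  image_stack(d, stack$channel_names, stack$pixel_size_um, stack$z_step_um)
}

#' Write a scene to disk: TIFF stack, YAML manifest, TSV manifest tables
#'
#' @param scene list(stack, truth) from [make_scene()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(scene$stack, file.path(dir, "scene.tif"))
  tr <- scene$truth
  yaml::write_yaml(list(seed = tr$seed, noise = tr$noise,
                        n_plaques = nrow(tr$plaques),
                        n_nuclei = if (is.null(tr$nuclei)) 0L else nrow(tr$nuclei)),
                   file.path(dir, "manifest.yaml"))
  write_results(tr$plaques, file.path(dir, "manifest_plaques.tsv"))
  write_results(tr$puncta, file.path(dir, "manifest_puncta.tsv"))
  if (!is.null(tr$nuclei))
    write_results(tr$nuclei, file.path(dir, "manifest_nuclei.tsv"))
  invisible(dir)
}
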