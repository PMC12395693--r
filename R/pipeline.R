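#' Run the per-scene analysis pipeline
#'
#' Orchestrates the standard per-scene workflow: obtain the stack (simulate
#' a configured scene or read a TIFF), segment plaques on the plaque
#' channel (max projection, mean + 2 SD threshold, particle analysis), then
#' per plaque — on a crop of radius `r_max + margin` around the centroid —
#' compute the enabled metrics: barrier coverage (Iba1 thresholded at the
#' soma cutoff), compaction slope from the radial profile, AND-
#' colocalization of the configured coloc channels, and spheroid area from
#' the Lamp1 channel. Results come back in long form, one row per (plaque,
#' metric), with every parameter that influenced a number echoed to the log;
#' reruns with the same config are byte-identical.
#'
#' @param config named list (or YAML path): fields `seed`; either `simulate`
#'   (arguments to [scene_config()]) or `input` (list(path, channel_map,
#'   pixel_size_um)); optional `channels` (roles: plaque, microglia,
#'   spheroid, coloc = vector), `params` (min_area_um2, n_rays,
#'   annulus_width_um, r_max_factor, soma_min_area_um2, bg_dilate_um),
#'   `metrics` (subset of coverage, compaction, coloc, spheroid; default all
#'   whose channels are present).
#' @param out_dir optional directory for the results TSV and overlay masks.
#' @param scene_id identifier copied into the results.
#' @return data.frame (scene_id, plaque_id, metric, value, units) with the
#'   scene's ground truth (when simulated) in attribute `truth`.
#' @export
run_scene_analysis <- function(config, out_dir = NULL, scene_id = "scene") {
  if (is.character(config)) config <- load_run_config(config)
  if (is.null(config$seed)) stop("config must carry a seed")
  ch <- config$channels %||% list()
  ch$plaque <- ch$plaque %||% "ThioS"
  ch$microglia <- ch$microglia %||% "Iba1"
  ch$spheroid <- ch$spheroid %||% "Lamp1"
  prm <- config$params %||% list()
  prm$min_area_um2 <- prm$min_area_um2 %||% 10
  prm$n_rays <- prm$n_rays %||% 360L
  prm$annulus_width_um <- prm$annulus_width_um %||% 5
  prm$r_max_factor <- prm$r_max_factor %||% 3
  prm$soma_min_area_um2 <- prm$soma_min_area_um2 %||% 30
  prm$bg_dilate_um <- prm$bg_dilate_um %||% 5
  prm$crop_margin_um <- prm$crop_margin_um %||% 10

  truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    sc$seed <- sc$seed %||% config$seed
    scene <- make_scene(do.call(scene_config, sc))
    stack <- scene$stack; truth <- scene$truth
  } else if (!is.null(config$input)) {
    stack <- read_stack(config$input$path, channel_map = config$input$channel_map,
                        pixel_size_um = config$input$pixel_size_um,
                        z_step_um = config$input$z_step_um)
  } else stop("config needs a `simulate` or `input` block")

  metrics <- config$metrics %||% {
    m <- "compaction"
    if (ch$microglia %in% stack$channel_names) m <- c(m, "coverage")
    if (ch$spheroid %in% stack$channel_names) m <- c(m, "spheroid")
    if (!is.null(ch$coloc)) m <- c(m, "coloc")
    m
  }
  for (m in metrics) {
    need <- switch(m, coverage = ch$microglia, spheroid = ch$spheroid,
                   coloc = ch$coloc, compaction = ch$plaque, character())
    miss <- setdiff(need, stack$channel_names)
    if (length(miss))
      stop(sprintf("metric '%s' needs missing channel(s): %s", m,
                   paste(miss, collapse = ", ")))
  }
  plq_log("run_scene_analysis %s: seed=%d metrics=[%s] min_area=%g n_rays=%d annulus=%g r_max_factor=%g",
          scene_id, config$seed, paste(metrics, collapse = ","), prm$min_area_um2,
          prm$n_rays, prm$annulus_width_um, prm$r_max_factor)

  px <- stack$pixel_size_um
  nz <- dim(stack$data)[1]
  proj_plq <- project_max(stack, ch$plaque, n_slices = min(10L, nz))
  plq_mask <- threshold_mean_sd(proj_plq, k = 2)
  parts <- label_particles(plq_mask, proj_plq, min_area_um2 = prm$min_area_um2,
                           pixel_size_um = px)
  lab_img <- attr(parts, "label_image")
  bg <- if (any(plq_mask)) estimate_background(proj_plq, plq_mask,
                                               dilate_um = prm$bg_dilate_um,
                                               pixel_size_um = px) else 0

  cutoff <- NULL
  if ("coverage" %in% metrics) {
    proj_iba <- project_max(stack, ch$microglia, n_slices = min(10L, nz))
    cutoff <- soma_cutoff(proj_iba, soma_min_area_um2 = prm$soma_min_area_um2,
                          pixel_size_um = px)
    barrier_full <- proj_iba > cutoff
    plq_log("soma cutoff = %.3f on channel %s", cutoff, ch$microglia)
  }
  proj_sph <- bg_sph <- NULL
  if ("spheroid" %in% metrics) {
    proj_sph <- project_max(stack, ch$spheroid, n_slices = min(10L, nz))
    bg_sph <- max(estimate_background(proj_sph, plq_mask,
                                      dilate_um = prm$bg_dilate_um,
                                      pixel_size_um = px), 1e-9)
  }
  coloc_masks <- if ("coloc" %in% metrics) {
    lapply(stats::setNames(ch$coloc, ch$coloc), function(cn) {
      pr <- project_max(stack, cn, n_slices = min(10L, nz))
      T <- threshold_isodata(pr)
      matrix(pr > T, nrow(pr))
    })
  } else NULL

  rows <- list()
  emit <- function(pid, metric, value, units)
    rows[[length(rows) + 1L]] <<- data.frame(
      scene_id = scene_id, plaque_id = pid, metric = metric,
      value = value, units = units)

  ny <- nrow(proj_plq); nx <- ncol(proj_plq)
  for (i in seq_len(nrow(parts))) {
    eq_r <- sqrt(parts$area_um2[i] / pi)
    r_max <- prm$r_max_factor * eq_r
    cy <- parts$centroid_y_um[i]; cx <- parts$centroid_x_um[i]
    # crop bounds (um -> px) with margin for annulus search and profile
    half <- r_max + prm$annulus_width_um + prm$crop_margin_um
    r0 <- max(1L, floor((cy - half) / px)); r1 <- min(ny, ceiling((cy + half) / px))
    c0 <- max(1L, floor((cx - half) / px)); c1 <- min(nx, ceiling((cx + half) / px))
    crop <- function(m) m[r0:r1, c0:c1, drop = FALSE]
    off_y <- (r0 - 1L) * px; off_x <- (c0 - 1L) * px
    this_mask <- crop(lab_img == attr_label(parts, i, lab_img, px))
    emit(i, "area", parts$area_um2[i], "um2")
    emit(i, "mean_intensity", parts$mean_intensity[i], "a.u.")

    if ("coverage" %in% metrics) {
      cov <- barrier_coverage(binary_mask(this_mask, px),
                              crop(barrier_full), n_rays = prm$n_rays,
                              annulus_width_um = prm$annulus_width_um,
                              pixel_size_um = px,
                              center_um = c(cy - off_y, cx - off_x), plaque_id = i)
      emit(i, "coverage_fraction", cov$coverage_fraction, "fraction")
      emit(i, "covered_angle", cov$covered_angle_deg, "deg")
    }
    if ("compaction" %in% metrics) {
      prof <- radial_profile(crop(proj_plq), c(cy - off_y, cx - off_x),
                             r_max_um = min(half - px, r_max + prm$crop_margin_um),
                             n_rays = prm$n_rays, pixel_size_um = px, plaque_id = i)
      cs <- compaction_slope(prof, background = bg)
      emit(i, "compaction_slope", if (cs$valid) cs$slope else NA_real_, "a.u./um")
      emit(i, "compaction_r2", if (cs$valid) cs$r_squared else NA_real_, "")
    }
    if ("spheroid" %in% metrics) {
      sph <- spheroid_area(crop(proj_sph), this_mask, background = bg_sph,
                           pixel_size_um = px, plaque_id = i)
      emit(i, "spheroid_area", sph$spheroid_area_um2, "um2")
    }
  }
  if ("coloc" %in% metrics && length(coloc_masks) >= 2L) {
    cr <- coloc_and(coloc_masks, pixel_size_um = px)
    emit(NA_integer_, "coloc_intersection_area", cr$intersection_area_um2, "um2")
    for (nm in cr$channels)
      emit(NA_integer_, paste0("coloc_fraction_", nm), cr$fraction_of_input[[nm]], "fraction")
  }

  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scene_id = character(), plaque_id = integer(),
               metric = character(), value = double(), units = character())
  attr(res, "truth") <- truth
  attr(res, "params") <- prm
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(res, file.path(out_dir, paste0(scene_id, "_results.tsv")))
    # audit overlays: plaque mask and (if computed) barrier mask
    ov <- list(matrix(as.numeric(plq_mask), ny, nx))
    if (!is.null(cutoff)) ov <- c(ov, list(matrix(as.numeric(barrier_full), ny, nx)))
    tiff::writeTIFF(ov, file.path(out_dir, paste0(scene_id, "_overlays.tif")),
                    bits.per.sample = 8L)
  }
  res
}

# label id of particle i in the full label image (labels were renumbered
# after the size filter, so look it up from the centroid)
attr_label <- function(parts, i, lab_img, px) {
  r <- round(parts$centroid_y_um[i] / px + 0.5)
  c <- round(parts$centroid_x_um[i] / px + 0.5)
  li <- lab_img[r, c]
  if (li == 0L) {
    # centroid may fall outside a concave particle; fall back to the
    # nearest labelled pixel
    idx <- which(lab_img > 0L)
    rows <- (idx - 1L) %% nrow(lab_img) + 1L
    cols <- (idx - 1L) %/% nrow(lab_img) + 1L
    li <- lab_img[idx[which.min((rows - r)^2 + (cols - c)^2)]]
  }
  li
}

#' Group-level summary of per-plaque results
#'
#' Aggregates long-form results tables to per-group mean ± SEM for each
#' metric, optionally normalising to a reference group's mean, and attaches
#' p-values from the standard routines: Welch's t-test for two groups,
#' one-way ANOVA with post hoc Tukey HSD for more. When an `animal` column
#' is present, values are averaged within animal first and the animal means
#' are the inferential unit; per-plaque summaries are reported alongside.
#'
#' @param tables a results data.frame or list of them (rows: metric, value,
#'   plus a grouping column and optionally `animal`).
#' @param group_col grouping column name (default "group").
#' @param normalize_to optional group whose mean is scaled to 1 (applied to
#'   the reported means).
#' @param by_animal average within animal before testing (default TRUE when
#'   an `animal` column exists).
#' @return list: `summary` data.frame (metric, group, n, mean, sem,
#'   mean_normalized), `tests` data.frame (metric, comparison, p_value,
#'   test).
#' @export
group_report <- function(tables, group_col = "group", normalize_to = NULL,
                         by_animal = NULL) {
  df <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  if (!group_col %in% names(df)) stop(sprintf("grouping column '%s' missing", group_col))
  if (!is.null(normalize_to) && !normalize_to %in% df[[group_col]])
    stop(sprintf("unknown grouping value '%s'", normalize_to))
  if (is.null(by_animal)) by_animal <- "animal" %in% names(df)
  df <- df[!is.na(df$value), , drop = FALSE]
  sums <- list(); tsts <- list()
  for (m in unique(df$metric)) {
    sub <- df[df$metric == m, , drop = FALSE]
    unit <- if (by_animal && "animal" %in% names(sub)) {
      agg <- stats::aggregate(sub$value,
                              by = list(group = sub[[group_col]], animal = sub$animal),
                              FUN = mean)
      names(agg)[3] <- "value"; agg
    } else data.frame(group = sub[[group_col]], value = sub$value)
    gmeans <- stats::aggregate(value ~ group, unit, mean)
    gsem <- stats::aggregate(value ~ group, unit,
                             function(v) stats::sd(v) / sqrt(length(v)))
    gn <- stats::aggregate(value ~ group, unit, length)
    s <- data.frame(metric = m, group = gmeans$group, n = gn$value,
                    mean = gmeans$value, sem = gsem$value)
    s$mean_normalized <- if (!is.null(normalize_to))
      s$mean / s$mean[s$group == normalize_to] else s$mean
    sums[[m]] <- s
    gs <- unique(unit$group)
    if (length(gs) == 2L) {
      p <- tryCatch(stats::t.test(value ~ group, data = unit)$p.value,
                    error = function(e) NA_real_)  # zero-variance groups
      tsts[[m]] <- data.frame(metric = m,
                              comparison = paste(sort(gs), collapse = " vs "),
                              p_value = p, test = "Welch t-test")
    } else if (length(gs) > 2L) {
      fit <- stats::aov(value ~ group, data = transform(unit, group = factor(group)))
      tk <- stats::TukeyHSD(fit)$group
      tsts[[m]] <- data.frame(metric = m, comparison = rownames(tk),
                              p_value = tk[, "p adj"], test = "ANOVA + Tukey HSD")
    }
  }
  list(summary = do.call(rbind, c(sums, make.row.names = FALSE)),
       tests = if (length(tsts)) do.call(rbind, c(tsts, make.row.names = FALSE)) else NULL)
}
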