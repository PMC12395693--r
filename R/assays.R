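#' Express a microdialysis series as percent of baseline
#'
#' Baseline is the mean concentration over the observations with hour in
#' \[3, 5\] after probe insertion; every value is then rescaled to
#' 100 * value / baseline. The transform is scale-invariant: multiplying
#' the raw series by any positive constant leaves the %-baseline series
#' unchanged.
#'
#' @param hours numeric, strictly increasing hours since probe insertion.
#' @param concentration numeric, non-negative concentrations (one per hour).
#' @param baseline_window baseline hours, inclusive (default c(3, 5)).
#' @return data.frame: hour, concentration, pct_baseline; attribute
#'   `baseline_mean`.
#' @export
percent_baseline <- function(hours, concentration, baseline_window = c(3, 5)) {
  if (length(hours) != length(concentration)) stop("lengths differ")
  if (is.unsorted(hours, strictly = TRUE)) stop("hours must be strictly increasing")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  in_base <- hours >= baseline_window[1] & hours <= baseline_window[2]
  if (!any(in_base)) stop("no observations in the baseline window")
  b <- mean(concentration[in_base])
  if (b == 0) stop("baseline mean is zero; percent of baseline undefined")
  out <- data.frame(hour = hours, concentration = concentration,
                    pct_baseline = 100 * concentration / b)
  attr(out, "baseline_mean") <- b
  out
}

#' Clearance slope of a %-baseline series
#'
#' Ordinary least-squares slope of percent-baseline on hours, restricted to
#' hour >= `from_hour` (the treatment time, e.g. gamma-secretase inhibitor
#' administration). The linear fit on the percent scale matches the
#' linear-trend convention for interstitial-fluid clearance; a log-linear
#' fit (slope of log %-baseline, for half-life style summaries) is available
#' but not the default.
#'
#' @param series data.frame from [percent_baseline()] (columns hour,
#'   pct_baseline).
#' @param from_hour first hour included in the fit.
#' @param log_linear fit log(pct_baseline) instead (default FALSE).
#' @return list: slope (% per hour), intercept, r_squared, n, from_hour.
#' @export
clearance_slope <- function(series, from_hour, log_linear = FALSE) {
  keep <- series$hour >= from_hour
  x <- series$hour[keep]
  y <- series$pct_baseline[keep]
  if (log_linear) y <- log(y)
  if (length(x) < 3L) stop("need >= 3 post-treatment points")
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = length(x), from_hour = from_hour, log_linear = log_linear)
}

#' qPCR fold changes by the 2^(-ddCt) method
#'
#' Technical replicates are averaged (arithmetic mean of Ct) to one Ct per
#' (sample, gene); dCt = Ct_target - Ct_reference per sample;
#' ddCt = dCt_sample - mean dCt of the control group; fold = 2^(-ddCt).
#' By construction the control group's geometric mean fold is exactly 1.
#'
#' @param records data.frame with columns sample, group, gene, ct (one row
#'   per technical replicate).
#' @param target_gene target gene name.
#' @param reference_gene reference (housekeeping) gene name, e.g. "GAPDH".
#' @param control_group group label used for normalisation.
#' @return data.frame: sample, group, dct, ddct, fold.
#' @export
ddct_fold_change <- function(records, target_gene, reference_gene = "GAPDH",
                             control_group = "control") {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(records)))
    stop("records must have columns sample, group, gene, ct")
  if (any(records$ct <= 0)) stop("Ct values must be > 0")
  mean_ct <- stats::aggregate(ct ~ sample + group + gene, records, mean)
  samples <- unique(mean_ct[, c("sample", "group")])
  get_ct <- function(s, g) {
    v <- mean_ct$ct[mean_ct$sample == s & mean_ct$gene == g]
    if (!length(v)) stop(sprintf("sample '%s' lacks a %s Ct", s, g))
    v
  }
  dct <- vapply(seq_len(nrow(samples)), function(i)
    get_ct(samples$sample[i], target_gene) -
      get_ct(samples$sample[i], reference_gene), numeric(1))
  is_ctrl <- samples$group == control_group
  if (!any(is_ctrl)) stop(sprintf("control group '%s' is empty", control_group))
  ddct <- dct - mean(dct[is_ctrl])
  data.frame(sample = samples$sample, group = samples$group,
             dct = dct, ddct = ddct, fold = 2^(-ddct))
}

#' Novel-object-recognition metrics with exclusion rules
#'
#' Per animal, the investigation ratio novel / (novel + familiar); chance
#' is 0.5. Animals are excluded (flagged, not dropped) when total
#' exploration is below `min_total_s`, when the familiarization-phase left
#' fraction falls outside `side_pref_band` (a one-side preference), or when
#' total exploration is zero.
#'
#' @param trials data.frame with columns animal, novel_s, familiar_s and
#'   optionally fam_left_s, fam_right_s for the side-preference check.
#' @param min_total_s minimum total exploration time (default 20).
#' @param side_pref_band acceptable familiarization left-fraction range
#'   (default c(0.35, 0.65)); the rule is a documented parameter choice, no
#'   numeric cutoff being standard.
#' @return data.frame: animal, ratio, total_s, included, exclusion_reason.
#' @export
nor_metrics <- function(trials, min_total_s = 20, side_pref_band = c(0.35, 0.65)) {
  need <- c("animal", "novel_s", "familiar_s")
  if (!all(need %in% names(trials)))
    stop("trials must have columns animal, novel_s, familiar_s")
  if (any(trials$novel_s < 0 | trials$familiar_s < 0)) stop("times must be >= 0")
  total <- trials$novel_s + trials$familiar_s
  ratio <- ifelse(total > 0, trials$novel_s / total, NA_real_)
  reason <- rep(NA_character_, nrow(trials))
  reason[total == 0] <- "zero exploration"
  reason[is.na(reason) & total < min_total_s] <-
    sprintf("total exploration < %g s", min_total_s)
  if (all(c("fam_left_s", "fam_right_s") %in% names(trials))) {
    fam_tot <- trials$fam_left_s + trials$fam_right_s
    left_frac <- ifelse(fam_tot > 0, trials$fam_left_s / fam_tot, 0.5)
    side <- left_frac < side_pref_band[1] | left_frac > side_pref_band[2]
    reason[is.na(reason) & side] <- "side preference in familiarization"
  }
  data.frame(animal = trials$animal, ratio = ratio, total_s = total,
             included = is.na(reason),
             exclusion_reason = reason)
}

#' Occupancy heatmap of an open-field trajectory
#'
#' 2-D histogram of (x, y) samples over a regular grid spanning the arena;
#' points outside the arena are dropped and counted. Optionally normalised
#' to sum to 1.
#'
#' @param x,y trajectory coordinates.
#' @param arena_bounds list(x = c(min, max), y = c(min, max)).
#' @param n_bins bins per axis (scalar or c(nx, ny); default 32).
#' @param normalize divide by the number of retained samples (default TRUE).
#' @return matrix (ny rows, nx cols) with attribute `n_dropped`.
#' @export
occupancy_heatmap <- function(x, y, arena_bounds, n_bins = 32L, normalize = TRUE) {
  if (!length(x)) stop("empty trajectory")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(n_bins) == 1L) n_bins <- c(n_bins, n_bins)
  xb <- arena_bounds$x; yb <- arena_bounds$y
  inside <- x >= xb[1] & x <= xb[2] & y >= yb[1] & y <= yb[2]
  n_drop <- sum(!inside)
  if (n_drop) plq_log("occupancy_heatmap: dropped %d out-of-arena points", n_drop)
  x <- x[inside]; y <- y[inside]
  if (!length(x)) stop("no trajectory points inside the arena")
  ix <- pmin(1L + floor((x - xb[1]) / (xb[2] - xb[1]) * n_bins[1]), n_bins[1])
  iy <- pmin(1L + floor((y - yb[1]) / (yb[2] - yb[1]) * n_bins[2]), n_bins[2])
  grid <- matrix(tabulate((ix - 1L) * n_bins[2] + iy, nbins = n_bins[1] * n_bins[2]),
                 n_bins[2], n_bins[1])
  if (normalize) grid <- grid / sum(grid)
  attr(grid, "n_dropped") <- n_drop
  grid
}
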