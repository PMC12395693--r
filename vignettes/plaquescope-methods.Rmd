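---
title: "Methods: plaque-microglia morphometry in plaquescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plaque-microglia morphometry in plaquescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

plaquescope quantifies plaque-centric pathology in multi-channel confocal
stacks of amyloid-depositing mouse brain. The biological model behind the
metrics: plaque-associated microglia build a barrier of thickened,
Iba1-bright processes around compact Thioflavin S⁺ deposits; loss of that
barrier (as in microglial risk-gene knockouts) leaves plaques diffuse,
enlarges Lamp1⁺ axonal spheroid halos, and reduces amyloid engulfment into
CD68⁺ phagosomes. Each of these phenotypes maps to one measurable quantity
per plaque, and each quantity is defined operationally below so that two
labs (or one lab and a synthetic benchmark) compute the same number.

All geometry is specified in micrometres and converted through the pixel
size; voxel indices are 0-based in configs and manifests, and the physical
coordinate of voxel *i* at spacing *s* is the voxel centre, (*i* + 0.5)·*s*.
Metrics are computed in floating point regardless of the acquisition dtype.

# Segmentation primitives

**Projection.** Per-plaque analysis operates on a maximum-intensity
projection across a 10-slice z window through the plaque core
(`project_max`). Windows clipped at the stack border shrink and the shrink
is logged.

**Thresholds.** Three auto-thresholds cover every downstream mask:

- `threshold_mean_sd` — T = mean + k·SD with k = 2 by default; this is the
  plaque-shape threshold. The SD is the population SD (divide by N),
  matching common image-software convention.
- `threshold_isodata` — iterative intermeans on a 256-bin histogram
  spanning [min, max] of the image (the classic "Default" preset); the
  fixed point is found in bin-index arithmetic with a floor tie rule, so a
  perfectly bimodal histogram with spikes in the first and last bins
  resolves to the midpoint bin (127). The value returned is the upper edge
  of the fixed-point bin in image units.
- `threshold_triangle` — maximal perpendicular distance from the histogram
  to the peak-to-tail line, scanning toward the longer tail; ties break
  toward the lower threshold.

Foreground is strictly `intensity > T` everywhere: on a constant image any
threshold at the constant yields an *empty* mask, never a full one. The
256-bin choice reproduces 8-bit-preset behaviour on arbitrary dtypes;
constant images raise a degenerate-histogram error rather than returning an
arbitrary cut.

**Particles.** `label_particles` uses 8-connectivity (diagonal neighbours
merge), the convention of the standard particle-analysis tools, and drops
components below `min_area_um2` (default 10 µm² — the plaque-counting
literature states no minimum, so this is a documented package choice, small
enough to keep genuine micro-deposits and large enough to reject
single-pixel noise). Merged plaques are reported as one particle; no
watershed splitting is attempted.

**Soma cutoff.** The barrier definition needs the Iba1 intensity of
microglial cell bodies. With a drawn soma mask the cutoff is the mean
intensity over its pixels; in auto mode somata are IsoData-foreground
components of at least `soma_min_area_um2` (default 30 µm², roughly a 6 µm
diameter cell body) and the cutoff is the mean over their pixels. A blank
image in auto mode is an error — no cutoff is definable.

# Barrier coverage

From the plaque centroid, `n_rays` rays (default 360, i.e. 1° resolution)
are cast; for each ray the plaque boundary radius is the outermost
plaque-mask crossing, and the ray is covered when any barrier-mask pixel
falls within [boundary, boundary + `annulus_width_um`] (default 5 µm) along
it. Coverage is the covered-ray fraction; multiplied by 360 it is the
covered angle. For a contiguous arc this equals the angle between the
barrier contact points seen from the plaque centre; unlike the
contact-point construction it remains well defined for fragmented barriers,
which is why the ray-sector form is used. Coverage is exactly invariant
under scene rotations that are multiples of the ray spacing, and monotone
in the true arc length.

Whether to compute coverage on a single optical plane or a projection is a
genuine choice; plaquescope computes it on the 10-slice projection, the
same plane on which the soma cutoff is estimated.

# Compaction slope

`radial_profile` samples the plaque channel bilinearly along rays at
`bin_width_um` steps (default one pixel) and averages over directions;
border-clipped rays are dropped and logged. `compaction_slope` then fits
I(r) over the declining segment by OLS:

- the segment **starts** at the last bin within `peak_tol` (default 5%) of
  the trace maximum above background. Bilinear sampling blurs the core edge
  by a fraction of a bin, so demanding the exact maximum would start the
  fit inside the core plateau and bias steep slopes shallow; the tolerance
  band restores the plateau-edge start the definition intends. On an
  exactly collinear declining trace the OLS slope is independent of the
  start bin, so this choice cannot move an ideal result.
- the segment **ends** at the first radius where I(r) ≤ B + 5% of
  (I(peak) − B), or the last bin if never reached. The 5% endpoint is
  configurable (`end_frac`) and logged; it makes the endpoint robust to
  noise floors.
- background B defaults to the mean intensity outside all plaque masks
  dilated by 5 µm (`estimate_background`), since the source procedures
  never define the decay endpoint's background level.

Segments of fewer than 3 bins (flat traces, peak at the last bin) return a
result flagged invalid rather than an error, so batch runs keep going.

Resolution limit: a decay spanning fewer than ~6 radial bins (for example
150 intensity units at 50 units/µm with 0.5 µm pixels) is dominated by the
edge blur and recovers biased-shallow slopes. The validation grid
{−2, −5, −10} units/µm sits safely inside the well-resolved regime;
steeper generated decays are used only where the plaque merely needs a
sharp boundary (coverage scenes).

# Colocalization, spheroids, RNA spots

`coloc_and` is the pixel-wise conjunction of 2–3 upstream-thresholded
masks (convention: IsoData), symmetric and associative, with areas in µm².
The engulfment readout is the triple conjunction amyloid ∧ phagosome ∧
microglia (4G8 ∧ CD68 ∧ Iba1); pairwise fractions are also emitted.

`spheroid_area` thresholds the Lamp1 projection at 150% of background and
subtracts plaque pixels; the background defaults to the same 5 µm-dilated
outside-plaque mean. The area is monotone non-increasing in the background
estimate, which the tests assert.

`rnascope_microglia_fraction` declares a nucleus gene-positive when at
least `min_spots` (default 1) spot pixels overlap its label region, and
reports the fraction of Ms4a6d⁺ nuclei that are also Aif1⁺. Zero Ms4a6d⁺
nuclei yields an invalid-flagged result (the fraction is undefined).

# Non-imaging assays

- `percent_baseline`: baseline is the mean concentration over hours 3–5
  after probe insertion, regardless of series length; the transform is
  scale-invariant.
- `clearance_slope`: OLS of %-baseline on hours from the treatment hour,
  on the percent scale (matching linear-trend-line practice); a log-linear
  option exists for half-life-style summaries but is not the default.
- `ddct_fold_change`: technical replicates are averaged by arithmetic mean
  of Ct before ΔCt (standard practice; the source protocol is silent);
  the control group's geometric mean fold is 1 by construction.
- `nor_metrics`: ratio = novel/(novel + familiar); exclusions for total
  exploration < 20 s, zero exploration, and familiarization side
  preference. No numeric side-preference cutoff is standard, so the band
  (0.35, 0.65) on the left-fraction is a documented parameter, flagged in
  the output.

# The synthetic generator and what passing tests mean

`make_scene` renders, noiselessly and exactly: plaques with
I(r) = peak − slope·(r − r_core) (linear, clipped at 0) or an exponential
with matched initial slope; barrier arcs in the annulus
[plaque extent, extent + annulus] at a start angle drawn uniformly unless
pinned; somata as discs; puncta channels with configurable placement
(barrier zone, spheroid halo, nuclei, uniform); nuclei on a jittered grid
(non-overlapping by construction) with per-gene transcript spots. Noise is
applied afterwards — Poisson resampling first (shot noise), then additive
Gaussian (read noise), clipped at zero. Every rendered object has exactly
one manifest entry, including *realised* discretised areas, so recovery is
judged against what was actually drawn, not the idealised formula.

Generator defaults (peak intensities, barrier 200 vs soma 150 on a process
baseline of 10, 0.5 µm pixels, 1 µm z-steps) are stated choices in the
plausible range of 60× confocal acquisitions; the source studies report no
dynamic range or PSF, so none is inferred, and no PSF or 3-D deconvolution
is modelled. Plaques whose lateral extents overlap raise an error because
overlapping deposits have no unambiguous per-plaque truth.

What passing recovery tests show: the analyzers measure what the
definitions say, at the discretisation the pixel grid allows. What they do
not show: robustness to optical blur, depth-dependent attenuation,
autofluorescence structure, or segmentation of genuinely merged plaques —
real-tissue properties the generator deliberately does not emulate.

# Validation problem sizes

The shipped validation suite uses: coverage — 5 scenes × 10 plaques (arcs
0–360°, Gaussian noise at 5% of barrier intensity, 150 × 200 µm scenes at
0.5 µm/px); compaction — single-plaque 120 µm scenes over slopes
{−2, −5, −10} units/µm, noiseless and at 5%-of-peak noise; thresholds —
100 seeded histograms per method against exhaustive oracles; spheroids —
halos of ~20–200 µm² at 3× background; RNA spots — 200 nuclei with 92%
Aif1 assignment; and an end-to-end two-group comparison (5 + 5 animals,
20 plaques each, barrier arcs drawn around 216° vs 108° with SD 30°)
summarised at animal level. These sizes make the whole suite run in well
under a minute per component while keeping every estimate's sampling error
far below the acceptance tolerances.

# Orchestration

`run_scene_analysis` composes the steps in the order the per-plaque
workflow dictates: plaque-channel projection → mean + 2 SD plaque mask →
particle analysis → per-plaque crops of radius r_max + margin (bounding
memory and matching the ≥ 20-plaques-per-mouse acquisition style) →
coverage / compaction / colocalization / spheroid metrics → long-form
results, one row per (plaque, metric), with all parameters echoed to the
log. Runs are deterministic given config + seed, and reruns write
byte-identical tables. `group_report` aggregates by animal first (the
default inferential unit; per-plaque summaries are also available),
normalises to a reference group on request, and delegates testing to
Welch's t-test or one-way ANOVA with Tukey HSD.

# Known limitations

- Merged plaques are one particle; coverage of two fused deposits is
  measured around their joint centroid.
- The coverage annulus is radial: a barrier lying flush against a highly
  non-convex plaque boundary can be missed where the boundary folds.
- Modality counting (`intensity_distribution`) uses kernel-density peak
  prominence, not mixture fitting; it is flagged unreliable below n = 20.
- Steep-decay slopes are resolution-limited as described above.
- TIFF round-trips store float32; values agree to ~1e-7 relative, not
  bit-exactly.
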