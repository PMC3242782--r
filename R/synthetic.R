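#' Parameters for one synthetic Feulgen-stained nucleus
#'
#' The generator emulates the measurement substrate of scanning
#' microspectrophotometry: an elliptical nucleus whose in-mask pixels are
#' partitioned into two chromatin compartments — spatially coherent
#' condensed foci around `od_condensed` and diffuse chromatin around
#' `od_diffuse` — plus Gaussian noise, clipped at OD 0. Foci are obtained
#' by thresholding a Gaussian-smoothed seeded random field at the
#' quantile that realizes the requested area fraction, which gives
#' blob-like condensed regions with exact-by-construction area control.
#'
#' @param nucleus_radius_px semi-major axis of the elliptical mask, px.
#' @param condensed_fraction target fraction of nuclear area occupied by
#'   condensed foci, in `[0, 1]`.
#' @param od_diffuse mean OD of diffuse (non-condensed) chromatin;
#'   default below the 0.100 condensed cutoff.
#' @param od_condensed mean OD of condensed foci; must exceed
#'   `od_diffuse` and defaults above the cutoff.
#' @param od_noise_sd Gaussian OD noise, absorbance units.
#' @param focus_scale_px spatial correlation length (Gaussian sigma) of
#'   the focus field, px.
#' @param target_iod `"unconstrained"`, or a positive number: in-mask
#'   ODs are rescaled so their sum equals this integrated optical
#'   density exactly (ploidy control).
#' @param pixel_pitch_um physical pixel pitch, um (default 0.5).
#' @param axis_ratio minor/major axis ratio of the ellipse, in (0, 1].
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical images.
#' @return An object of class `nucleus_sim_params`.
#' @export
nucleus_sim_params <- function(nucleus_radius_px = 35,
                               condensed_fraction = 0.60,
                               od_diffuse = 0.08,
                               od_condensed = 0.20,
                               od_noise_sd = 0.01,
                               focus_scale_px = 4,
                               target_iod = "unconstrained",
                               pixel_pitch_um = 0.5,
                               axis_ratio = 0.8,
                               seed = 1L) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(nucleus_radius_px) || nucleus_radius_px <= 0)
    stop("`nucleus_radius_px` must be a positive number")
  if (!num1(condensed_fraction) || condensed_fraction < 0 ||
      condensed_fraction > 1)
    stop("`condensed_fraction` must lie in [0, 1]")
  if (!num1(od_diffuse) || od_diffuse < 0)
    stop("`od_diffuse` must be >= 0")
  if (!num1(od_condensed) || od_condensed <= od_diffuse)
    stop("`od_condensed` must exceed `od_diffuse`")
  if (!num1(od_noise_sd) || od_noise_sd < 0)
    stop("`od_noise_sd` must be >= 0")
  if (!num1(focus_scale_px) || focus_scale_px <= 0)
    stop("`focus_scale_px` must be positive")
  if (!identical(target_iod, "unconstrained") &&
      !(num1(target_iod) && target_iod > 0))
    stop("`target_iod` must be \"unconstrained\" or a positive number")
  if (!num1(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("`pixel_pitch_um` must be positive")
  if (!num1(axis_ratio) || axis_ratio <= 0 || axis_ratio > 1)
    stop("`axis_ratio` must lie in (0, 1]")
  structure(
    list(nucleus_radius_px = nucleus_radius_px,
         condensed_fraction = condensed_fraction,
         od_diffuse = od_diffuse, od_condensed = od_condensed,
         od_noise_sd = od_noise_sd, focus_scale_px = focus_scale_px,
         target_iod = target_iod, pixel_pitch_um = pixel_pitch_um,
         axis_ratio = axis_ratio, seed = as.integer(seed)),
    class = "nucleus_sim_params"
  )
}

# Elliptical mask indices on a padded grid; returns list(dim, idx).
ellipse_mask <- function(radius_px, axis_ratio, pad = 4L) {
  a <- radius_px
  b <- radius_px * axis_ratio
  nc <- 2L * ceiling(a) + 2L * pad + 1L
  nr <- 2L * ceiling(b) + 2L * pad + 1L
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- ((col - cx) / a)^2 + ((row - cy) / b)^2 <= 1
  list(dim = c(nr, nc), idx = which(inside))
}

# Smoothed random field over the grid; in-mask values drive focus
# placement. Must be called with the RNG already seeded. The Gaussian
# brush is capped at the image size so small nuclei remain valid.
focus_field <- function(dm, sigma) {
  field <- matrix(rnorm(prod(dm)), dm[1L], dm[2L])
  r <- 2L * ceiling(3 * sigma) + 1L
  mx <- min(dm)
  if (r > mx) r <- mx - (1L - mx %% 2L)  # largest odd radius that fits
  as.matrix(EBImage::gblur(field, sigma = sigma, radius = r))
}

#' Generate one synthetic nucleus with ground truth
#'
#' @param params a [nucleus_sim_params()].
#' @return A list with elements
#'   `image` (an [absorbance_image()], zero outside the nucleus),
#'   `mask` (a [nucleus_mask()]), and
#'   `truth` — a list with `true_condensed_fraction` (the realized, not
#'   requested, fraction), `true_iod`, `true_nuclear_area_um2`, `seed`,
#'   and the `params` used.
#' @examples
#' nuc <- generate_nucleus(nucleus_sim_params(seed = 42))
#' nuc$truth$true_condensed_fraction
#' @export
generate_nucleus <- function(params) {
  stopifnot(inherits(params, "nucleus_sim_params"))
  em <- ellipse_mask(params$nucleus_radius_px, params$axis_ratio)
  n <- length(em$idx)
  k <- round(params$condensed_fraction * n)
  if (n < 16L)
    stop("degenerate geometry: nucleus too small (", n, " px)")
  f <- params$condensed_fraction
  if (f > 0 && f < 1 && (k == 0L || k == n))
    stop("degenerate geometry: radius too small to realize ",
         "condensed_fraction ", f)
  vals <- with_seed(params$seed, {
    fld <- focus_field(em$dim, params$focus_scale_px)[em$idx]
    cond <- logical(n)
    if (k > 0L) cond[order(fld, decreasing = TRUE)[seq_len(k)]] <- TRUE
    mu <- ifelse(cond, params$od_condensed, params$od_diffuse)
    mu + rnorm(n, 0, params$od_noise_sd)
  })
  vals <- pmax(vals, 0)
  if (!identical(params$target_iod, "unconstrained")) {
    s <- sum(vals)
    if (s <= 0) stop("cannot rescale an all-zero nucleus to target_iod")
    vals <- vals * (params$target_iod / s)
  }
  m <- matrix(0, em$dim[1L], em$dim[2L])
  m[em$idx] <- vals
  img <- absorbance_image(m, params$pixel_pitch_um, source = "synthetic")
  list(
    image = img,
    mask = nucleus_mask(em$idx, em$dim),
    truth = list(true_condensed_fraction = k / n,
                 true_iod = sum(vals),
                 true_nuclear_area_um2 = n * params$pixel_pitch_um^2,
                 seed = params$seed,
                 params = params)
  )
}

#' Population presets for the synthetic generator
#'
#' Two presets emulate the decondensation phenomenology of
#' HDAC-inhibitor experiments: `"control"` nuclei carry a mean condensed
#' area fraction of 0.60 and `"decondensed"` nuclei of 0.40, mirroring
#' the direction and rough magnitude of the median Sc% shift observed
#' between untreated and inhibitor-treated cells. Per-nucleus
#' variability is logit-normal on the condensed fraction (sd 0.5 on the
#' log-odds scale) and normal on the radius, truncated at `radius_min`.
#' These are configuration values, not hard-coded truth: every field can
#' be overridden per call.
#'
#' @return Named list of preset parameter lists.
#' @export
population_presets <- function() {
  base <- list(
    condensed_fraction_mean = 0.60, logit_sd = 0.5,
    radius_mean = 35, radius_sd = 3, radius_min = 30,
    od_diffuse = 0.08, od_condensed = 0.20, od_noise_sd = 0.01,
    focus_scale_px = 4, axis_ratio = 0.8, pixel_pitch_um = 0.5,
    target_iod = "unconstrained"
  )
  list(
    control = base,
    decondensed = modifyList(base, list(condensed_fraction_mean = 0.40))
  )
}

#' Generate a seeded population of synthetic nuclei
#'
#' Draws per-nucleus condensed fractions (logit-normal around the preset
#' mean), radii (truncated normal) and child seeds, then renders each
#' nucleus with [generate_nucleus()]. Identical `(preset, overrides, n,
#' seed)` reproduce the population exactly.
#'
#' @param preset `"control"` or `"decondensed"` (see
#'   [population_presets()]).
#' @param n number of nuclei, >= 1.
#' @param seed integer population seed.
#' @param overrides named list overriding preset fields; additionally,
#'   `target_iod` may be a numeric vector of length `n` assigning a
#'   per-nucleus integrated OD (ploidy mixture simulations).
#' @return A list with `nuclei` (list of [generate_nucleus()] results),
#'   `truth` (data.frame: `id`, `seed`, `true_condensed_fraction`,
#'   `true_iod`, `true_nuclear_area_um2`), `preset`, and the merged
#'   parameter list `config`.
#' @examples
#' pop <- generate_population("control", n = 3, seed = 1)
#' pop$truth
#' @export
generate_population <- function(preset, n, seed = 1L, overrides = list()) {
  presets <- population_presets()
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% names(presets))
    stop("unknown preset \"", paste(preset, collapse = ","),
         "\"; available: ", paste(names(presets), collapse = ", "))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be >= 1")
  n <- as.integer(n)
  per_nucleus_iod <- NULL
  if (!is.null(overrides$target_iod) && is.numeric(overrides$target_iod) &&
      length(overrides$target_iod) > 1L) {
    per_nucleus_iod <- rep_len(overrides$target_iod, n)
    overrides$target_iod <- NULL
  }
  cfg <- modifyList(presets[[preset]], overrides)
  draws <- with_seed(seed, {
    list(
      frac = plogis(rnorm(n, qlogis(cfg$condensed_fraction_mean),
                          cfg$logit_sd)),
      radius = pmax(cfg$radius_min,
                    rnorm(n, cfg$radius_mean, cfg$radius_sd)),
      seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  nuclei <- lapply(seq_len(n), function(i) {
    generate_nucleus(nucleus_sim_params(
      nucleus_radius_px = draws$radius[i],
      condensed_fraction = draws$frac[i],
      od_diffuse = cfg$od_diffuse, od_condensed = cfg$od_condensed,
      od_noise_sd = cfg$od_noise_sd, focus_scale_px = cfg$focus_scale_px,
      target_iod = if (is.null(per_nucleus_iod)) cfg$target_iod
                   else per_nucleus_iod[i],
      pixel_pitch_um = cfg$pixel_pitch_um, axis_ratio = cfg$axis_ratio,
      seed = draws$seeds[i]))
  })
  truth <- data.frame(
    id = sprintf("%s_%04d", preset, seq_len(n)),
    seed = draws$seeds,
    true_condensed_fraction =
      vapply(nuclei, function(x) x$truth$true_condensed_fraction, 0),
    true_iod = vapply(nuclei, function(x) x$truth$true_iod, 0),
    true_nuclear_area_um2 =
      vapply(nuclei, function(x) x$truth$true_nuclear_area_um2, 0)
  )
  list(nuclei = nuclei, truth = truth, preset = preset, config = cfg)
}

#' Write a synthetic population to disk
#'
#' Images go to `<dir>/<id>.tif` (32-bit float absorbance TIFF) and the
#' ground-truth table to `<dir>/truth.csv`.
#'
#' @param pop result of [generate_population()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pop$nuclei))
    write_absorbance_tiff(pop$nuclei[[i]]$image,
                          file.path(dir, paste0(pop$truth$id[i], ".tif")))
  write.csv(pop$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Generate a synthetic TUNEL-stained cell image
#'
#' Renders an elliptical nucleus in a methyl-green counterstain tone
#' (8-bit luminance above the detection window) on a near-white
#' background, with dark DAB-brown spots whose luminance falls inside
#' the configured gray window (default 60-100). Spot pixels are the
#' top fraction of a smoothed seeded random field, so the realized
#' coverage equals the request up to one-pixel rounding.
#'
#' @param spot_coverage target fraction of the nuclear area covered by
#'   dark spots, in `[0, 1]`.
#' @param nucleus_radius_px semi-major axis of the nucleus, px.
#' @param seed integer RNG seed.
#' @param axis_ratio ellipse minor/major axis ratio.
#' @param focus_scale_px spatial correlation length of the spot field.
#' @param counterstain_rgb,spot_rgb,background_rgb 8-bit colors; the
#'   defaults give luminances of about 172 (counterstain), 84 (spot,
#'   inside the 60-100 window) and 245 (background).
#' @return A list with `image` (numeric `nrow x ncol x 3` array on the
#'   0-255 scale), `mask` (a [nucleus_mask()]), and `truth` — a list
#'   with `true_relative_area_pct` and `true_rank` (computed with the
#'   same classification rule as [classify_tunel()]).
#' @examples
#' cell <- generate_tunel_cell(0.6, seed = 1)
#' cell$truth$true_rank  # "strong"
#' @export
generate_tunel_cell <- function(spot_coverage, nucleus_radius_px = 30,
                                seed = 1L, axis_ratio = 0.85,
                                focus_scale_px = 3,
                                counterstain_rgb = c(150, 195, 170),
                                spot_rgb = c(120, 75, 40),
                                background_rgb = c(245, 245, 245)) {
  if (!is.numeric(spot_coverage) || length(spot_coverage) != 1L ||
      spot_coverage < 0 || spot_coverage > 1)
    stop("`spot_coverage` must lie in [0, 1]")
  em <- ellipse_mask(nucleus_radius_px, axis_ratio)
  n <- length(em$idx)
  if (n < 16L) stop("degenerate geometry: nucleus too small")
  k <- round(spot_coverage * n)
  spot_local <- if (k > 0L) {
    fld <- with_seed(seed, focus_field(em$dim, focus_scale_px))[em$idx]
    order(fld, decreasing = TRUE)[seq_len(k)]
  } else integer(0)
  npx <- prod(em$dim)
  img <- array(0, c(em$dim, 3L))
  for (ch in 1:3) {
    plane <- rep(background_rgb[ch], npx)
    plane[em$idx] <- counterstain_rgb[ch]
    plane[em$idx[spot_local]] <- spot_rgb[ch]
    img[, , ch] <- plane
  }
  rel_pct <- 100 * k / n
  list(
    image = img,
    mask = nucleus_mask(em$idx, em$dim),
    truth = list(true_relative_area_pct = rel_pct,
                 true_rank = tunel_rank(rel_pct),
                 seed = as.integer(seed))
  )
}
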