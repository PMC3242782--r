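#' Pipeline run configuration
#'
#' One place for every tunable of the orchestrated pipeline, pre-filled
#' with the conventional instrument values: background OD threshold
#' 0.020, condensed-chromatin cutoff 0.100, 0.5 um pixel pitch, 200
#' nuclei per condition for karyometry, 1000 cells per condition for
#' TUNEL, gray window 60-100, rank boundaries 5/50%, alpha 0.05.
#'
#' @param out_dir output directory for tables, plots and the manifest.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param background_threshold OD at or below which pixels are
#'   background.
#' @param condensed_cutoff condensed-chromatin OD cutoff.
#' @param pixel_pitch_um physical pixel pitch, um.
#' @param min_area_px smallest connected component kept as a nucleus.
#' @param nuclei_per_condition simulated nuclei per karyometry preset.
#' @param tunel_cells_per_condition simulated cells per TUNEL condition.
#' @param tunel_gray_window inclusive 8-bit window for dark-spot
#'   detection.
#' @param tunel_area_thresholds weak/moderate and moderate/strong rank
#'   boundaries, percent.
#' @param alpha significance level.
#' @param input_dir optional directory of measured absorbance TIFFs
#'   (one subdirectory per group); when `NULL` the synthetic generator
#'   supplies the data.
#' @param karyometry_presets preset names simulated when no input
#'   directory is given; the first is the reference/control group.
#' @param preset_overrides named list of per-preset override lists
#'   passed to [generate_population()].
#' @param tunel_conditions named list describing the simulated TUNEL
#'   conditions (see [default_tunel_conditions()]).
#' @param make_plots write PNG figures (disable for fast headless runs).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       background_threshold = 0.020,
                       condensed_cutoff = 0.100,
                       pixel_pitch_um = 0.5,
                       min_area_px = 50L,
                       nuclei_per_condition = 200L,
                       tunel_cells_per_condition = 1000L,
                       tunel_gray_window = c(60, 100),
                       tunel_area_thresholds = c(5, 50),
                       alpha = 0.05,
                       input_dir = NULL,
                       karyometry_presets = c("control", "decondensed"),
                       preset_overrides = list(),
                       tunel_conditions = default_tunel_conditions(),
                       make_plots = TRUE) {
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1L)
    stop("`out_dir` is required")
  stopifnot(background_threshold > 0, condensed_cutoff > 0,
            pixel_pitch_um > 0, nuclei_per_condition >= 1,
            tunel_cells_per_condition >= 1,
            length(tunel_gray_window) == 2L,
            length(tunel_area_thresholds) == 2L,
            alpha > 0, alpha < 1)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         background_threshold = background_threshold,
         condensed_cutoff = condensed_cutoff,
         pixel_pitch_um = pixel_pitch_um,
         min_area_px = as.integer(min_area_px),
         nuclei_per_condition = as.integer(nuclei_per_condition),
         tunel_cells_per_condition = as.integer(tunel_cells_per_condition),
         tunel_gray_window = tunel_gray_window,
         tunel_area_thresholds = tunel_area_thresholds,
         alpha = alpha, input_dir = input_dir,
         karyometry_presets = karyometry_presets,
         preset_overrides = preset_overrides,
         tunel_conditions = tunel_conditions,
         make_plots = isTRUE(make_plots)),
    class = "run_config"
  )
}

#' Default simulated TUNEL conditions
#'
#' Each condition draws a per-cell response rank from fixed
#' probabilities and then a spot coverage uniformly inside that rank's
#' band (weak 0.5-4.9%, moderate 5-49%, strong 50-85% of the nuclear
#' area). The defaults sketch an untreated culture (about 6% positive,
#' almost all weak) against an HDAC-inhibitor-treated one (about 36%
#' positive, still dominated by weak responses) — the late-treatment
#' pattern of TUNEL positivity tables.
#'
#' @return Named list of condition parameter lists with fields
#'   `p_negative`, `p_weak`, `p_moderate`, `p_strong`,
#'   `coverage_bands`.
#' @export
default_tunel_conditions <- function() {
  bands <- list(weak = c(0.005, 0.049), moderate = c(0.05, 0.49),
                strong = c(0.50, 0.85))
  list(
    control = list(p_negative = 0.941, p_weak = 0.052,
                   p_moderate = 0.004, p_strong = 0.003,
                   coverage_bands = bands),
    treated = list(p_negative = 0.640, p_weak = 0.317,
                   p_moderate = 0.036, p_strong = 0.007,
                   coverage_bands = bands)
  )
}

# Serializable echo of a run_config for the manifest.
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$tunel_conditions <- lapply(cfg$tunel_conditions, function(cd) {
    cd$coverage_bands <- lapply(cd$coverage_bands, as.numeric)
    cd
  })
  cfg
}

write_manifest <- function(config, stage_counts, path) {
  jsonlite::write_json(
    list(package = "karyodens",
         version = as.character(packageVersion("karyodens")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = config_echo(config),
         stage_counts = stage_counts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

# Measure one simulated nucleus through the real segmentation path:
# background removal + 8-connected labeling, keeping the largest
# component (a single synthetic nucleus yields exactly one).
measure_via_segmentation <- function(nuc, config) {
  masks <- segment_nuclei(nuc$image, config$background_threshold,
                          config$min_area_px)
  if (length(masks) == 0L) return(NULL)
  measure_nucleus(nuc$image, masks[[1L]], config$condensed_cutoff)
}

#' Run the karyometry pipeline
#'
#' Simulates (or ingests) Feulgen absorbance images, segments and
#' measures every nucleus, and writes: `measurements.csv` (per-nucleus
#' karyometry), `summary.csv` (n/X/S/Md per group and variable),
#' `comparisons.csv` (control vs each group: test, statistic, P,
#' significance for Sc%, AAR, A_T and S_T), `c_class.csv` (ploidy-class
#' histograms anchored on the control group), `truth.csv` (simulated
#' runs only), a Sc%-vs-AAR `scatter.png` (optional) and
#' `manifest_karyometry.json`. Outputs are deterministic given the
#' config seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `measurements`, `summaries`,
#'   `comparisons`, `c_class`, and `paths`.
#' @export
run_karyometry <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  # -- stage: acquire -------------------------------------------------
  groups <- list()   # name -> list(images, truth or NULL)
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir))
      stop_stage("acquire", "input directory not found: ",
                 config$input_dir)
    subs <- list.dirs(config$input_dir, recursive = FALSE)
    if (length(subs) == 0L) subs <- config$input_dir
    for (s in subs) {
      tifs <- list.files(s, pattern = "\\.tiff?$", full.names = TRUE)
      if (length(tifs) == 0L) next
      groups[[basename(s)]] <- list(
        images = lapply(tifs, read_absorbance_tiff,
                        pixel_pitch_um = config$pixel_pitch_um),
        ids = tools::file_path_sans_ext(basename(tifs)),
        truth = NULL)
    }
    if (length(groups) == 0L)
      stop_stage("acquire", "no TIFF images under ", config$input_dir)
  } else {
    seeds <- derive_seeds(config$seed,
                          length(config$karyometry_presets))
    for (i in seq_along(config$karyometry_presets)) {
      preset <- config$karyometry_presets[i]
      ov <- config$preset_overrides[[preset]]
      if (is.null(ov)) ov <- list()
      pop <- generate_population(preset, config$nuclei_per_condition,
                                 seed = seeds[i], overrides = ov)
      groups[[preset]] <- list(
        images = lapply(pop$nuclei, `[[`, "image"),
        ids = pop$truth$id, truth = pop$truth)
    }
  }

  # -- stage: measure -------------------------------------------------
  meas <- list()
  for (g in names(groups)) {
    rows <- list()
    for (j in seq_along(groups[[g]]$images)) {
      img <- groups[[g]]$images[[j]]
      masks <- segment_nuclei(img, config$background_threshold,
                              config$min_area_px)
      if (length(masks) == 0L) next
      for (k in seq_along(masks)) {
        m <- measure_nucleus(img, masks[[k]], config$condensed_cutoff)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(group = g, image_id = groups[[g]]$ids[j],
                     nucleus_id = k),
          as.data.frame(m),
          data.frame(background_threshold = config$background_threshold))
      }
    }
    if (length(rows) == 0L)
      stop_stage("measure", "no nuclei survived segmentation in group ",
                 g)
    meas[[g]] <- do.call(rbind, rows)
  }
  measurements <- do.call(rbind, meas)
  rownames(measurements) <- NULL

  # -- stage: stats ---------------------------------------------------
  variables <- c("Sc_pct", "AAR", "A_T", "S_T_um2")
  summaries <- do.call(rbind, lapply(names(meas), function(g) {
    do.call(rbind, lapply(variables, function(v) {
      vals <- meas[[g]][[v]]
      vals <- vals[is.finite(vals)]
      s <- summarize_group(vals)
      data.frame(group = g, variable = v, n = s$n, X = s$X, S = s$S,
                 Md = s$Md)
    }))
  }))
  ref_group <- names(meas)[1L]
  comparisons <- NULL
  if (length(meas) > 1L) {
    comparisons <- do.call(rbind, lapply(names(meas)[-1L], function(g) {
      do.call(rbind, lapply(variables, function(v) {
        va <- meas[[ref_group]][[v]]; va <- va[is.finite(va)]
        vb <- meas[[g]][[v]]; vb <- vb[is.finite(vb)]
        cmp <- compare_groups(va, vb, alpha = config$alpha)
        data.frame(group_a = ref_group, group_b = g, variable = v,
                   test = cmp$test, statistic = cmp$statistic,
                   p = cmp$p_two_sided, significant = cmp$significant)
      }))
    }))
  }
  c_class <- NULL
  if (nrow(meas[[ref_group]]) >= 10L) {
    c_class <- do.call(rbind, lapply(names(meas), function(g) {
      h <- c_class_histogram(meas[[g]]$A_T, meas[[ref_group]]$A_T)
      cbind(data.frame(group = g), as.data.frame(h))
    }))
  } else {
    message("reference group too small for C-class calibration (< 10 ",
            "nuclei); skipping ploidy histogram")
  }

  # -- stage: report --------------------------------------------------
  write.csv(measurements, p("measurements.csv"), row.names = FALSE)
  write.csv(summaries, p("summary.csv"), row.names = FALSE)
  if (!is.null(comparisons))
    write.csv(comparisons, p("comparisons.csv"), row.names = FALSE)
  if (!is.null(c_class))
    write.csv(c_class, p("c_class.csv"), row.names = FALSE)
  truth <- do.call(rbind, lapply(names(groups), function(g) {
    t <- groups[[g]]$truth
    if (is.null(t)) NULL else cbind(data.frame(group = g), t)
  }))
  if (!is.null(truth)) write.csv(truth, p("truth.csv"), row.names = FALSE)
  if (config$make_plots) {
    sc <- scatter_diagram(measurements, measurements$group)
    grDevices::png(p("scatter.png"), width = 900, height = 700, res = 120)
    print(sc$plot)
    grDevices::dev.off()
  }
  write_manifest(config,
                 list(groups = lengths(lapply(groups, `[[`, "images")),
                      nuclei_measured = as.list(table(measurements$group))),
                 p("manifest_karyometry.json"))
  invisible(list(measurements = measurements, summaries = summaries,
                 comparisons = comparisons, c_class = c_class,
                 paths = p(c("measurements.csv", "summary.csv",
                             "comparisons.csv", "c_class.csv"))))
}

#' Run the TUNEL pipeline
#'
#' Simulates TUNEL-stained cells for each configured condition, detects
#' dark spots by the gray-window rule, ranks every cell, and writes
#' `tunel_cells.csv` (per-cell scores), `tunel_table.csv` (per-condition
#' positivity percentages) and `manifest_tunel.json`. Deterministic
#' given the config seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `cells`, `table`, `paths`.
#' @export
run_tunel <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$tunel_conditions) == 0L)
    stop_stage("tunel", "no TUNEL conditions configured")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  n <- config$tunel_cells_per_condition
  seeds <- derive_seeds(config$seed + 1L,
                        length(config$tunel_conditions))
  all_scores <- list()
  for (i in seq_along(config$tunel_conditions)) {
    cname <- names(config$tunel_conditions)[i]
    cd <- config$tunel_conditions[[i]]
    draws <- with_seed(seeds[i], {
      ranks <- sample(c("negative", "weak", "moderate", "strong"), n,
                      replace = TRUE,
                      prob = c(cd$p_negative, cd$p_weak, cd$p_moderate,
                               cd$p_strong))
      cov <- numeric(n)
      for (r in c("weak", "moderate", "strong")) {
        sel <- ranks == r
        band <- cd$coverage_bands[[r]]
        cov[sel] <- runif(sum(sel), band[1L], band[2L])
      }
      list(cov = cov, seeds = sample.int(.Machine$integer.max - 1L, n))
    })
    cells <- lapply(seq_len(n), function(j)
      generate_tunel_cell(draws$cov[j], seed = draws$seeds[j]))
    all_scores[[cname]] <- score_tunel_cells(
      cells, condition = cname,
      low = config$tunel_gray_window[1L],
      high = config$tunel_gray_window[2L],
      thresholds = config$tunel_area_thresholds)
  }
  cells_df <- do.call(rbind, all_scores)
  rownames(cells_df) <- NULL
  tab <- positivity_table(cells_df)
  write.csv(cells_df, p("tunel_cells.csv"), row.names = FALSE)
  write.csv(tab, p("tunel_table.csv"), row.names = FALSE)
  write_manifest(config,
                 list(cells_scored = as.list(table(cells_df$condition))),
                 p("manifest_tunel.json"))
  invisible(list(cells = cells_df, table = tab,
                 paths = p(c("tunel_cells.csv", "tunel_table.csv"))))
}
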