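#' Per-nucleus karyometric measurement
#'
#' Computes the classical Feulgen image-densitometry parameters for one
#' segmented nucleus:
#'
#' * `A_T` — total integrated absorbance over the nuclear mask (the
#'   Feulgen-DNA value / integrated optical density, arbitrary units);
#' * `A_C` — integrated absorbance over the condensed-chromatin pixels,
#'   i.e. those with OD strictly above `cutoff` (default 0.100);
#' * `Ac_pct` — `100 * A_C / A_T`;
#' * `S_T` — nuclear area in um^2 (`|mask| * pitch^2`);
#' * `S_C` — condensed-chromatin area in um^2;
#' * `Sc_pct` — `100 * S_C / S_T`, the relative condensed-chromatin
#'   area;
#' * `AAR` — average absorption ratio `(A_C/S_C) / (A_T/S_T)`: how many
#'   times the mean absorbance of condensed chromatin exceeds that of
#'   the whole nucleus. `AAR >= 1` whenever defined, since the condensed
#'   pixels are exactly the high-OD subset; it is reported as `NA` when
#'   no pixel exceeds the cutoff (`S_C = 0`), and such nuclei are
#'   excluded from group statistics.
#'
#' @param img an [absorbance_image()].
#' @param mask a [nucleus_mask()] into `img`.
#' @param cutoff condensed-chromatin OD cutoff (strictly-above rule).
#' @return An object of class `nucleus_measurement`: a named list with
#'   fields `A_T`, `A_C`, `Ac_pct`, `S_T_um2`, `S_C_um2`, `Sc_pct`,
#'   `AAR`, `cutoff`, `n_px`.
#' @examples
#' img <- absorbance_image(matrix(c(0.30, 0.30, 0.05, 0.05), 2))
#' m <- measure_nucleus(img, nucleus_mask(1:4, c(2, 2)))
#' m$Sc_pct  # 50
#' m$AAR     # (0.6/0.5)/(0.7/1.0) = 1.714...
#' @export
measure_nucleus <- function(img, mask, cutoff = 0.100) {
  stopifnot(inherits(img, "absorbance_image"))
  if (!inherits(mask, "nucleus_mask") || length(mask$idx) == 0L)
    stop("`mask` must be a non-empty nucleus_mask")
  if (!identical(mask$dim, dim(img$values)))
    stop("mask and image dimensions disagree")
  v <- img$values[mask$idx]
  px_area <- img$pixel_pitch_um^2
  A_T <- sum(v)
  S_T <- length(v) * px_area
  cond <- v > cutoff
  A_C <- sum(v[cond])
  S_C <- sum(cond) * px_area
  Sc_pct <- 100 * S_C / S_T
  Ac_pct <- if (A_T > 0) 100 * A_C / A_T else NA_real_
  AAR <- if (S_C > 0) (A_C / S_C) / (A_T / S_T) else NA_real_
  structure(
    list(A_T = A_T, A_C = A_C, Ac_pct = Ac_pct,
         S_T_um2 = S_T, S_C_um2 = S_C, Sc_pct = Sc_pct, AAR = AAR,
         cutoff = cutoff, n_px = length(v)),
    class = "nucleus_measurement"
  )
}

#' @export
print.nucleus_measurement <- function(x, ...) {
  cat(sprintf(
    "nucleus_measurement (%d px): A_T=%.4g S_T=%.4g um2 Sc%%=%.2f AAR=%s\n",
    x$n_px, x$A_T, x$S_T_um2, x$Sc_pct,
    if (is.na(x$AAR)) "NA" else sprintf("%.3f", x$AAR)))
  invisible(x)
}

#' @export
as.data.frame.nucleus_measurement <- function(x, ...) {
  data.frame(A_T = x$A_T, A_C = x$A_C, Ac_pct = x$Ac_pct,
             S_T_um2 = x$S_T_um2, S_C_um2 = x$S_C_um2,
             Sc_pct = x$Sc_pct, AAR = x$AAR,
             cutoff = x$cutoff, n_px = x$n_px)
}

#' Measure every nucleus in an image
#'
#' @param img an [absorbance_image()].
#' @param masks list of [nucleus_mask()] (e.g. from [segment_nuclei()]).
#' @param cutoff condensed-chromatin OD cutoff.
#' @return A data.frame with one row per nucleus (`nucleus_id` plus the
#'   [measure_nucleus()] fields).
#' @export
measure_nuclei <- function(img, masks, cutoff = 0.100) {
  if (length(masks) == 0L)
    return(cbind(data.frame(nucleus_id = integer(0)),
                 as.data.frame(measure_nucleus(
                   absorbance_image(matrix(1)), nucleus_mask(1L, c(1L, 1L)),
                   cutoff))[0, ]))
  rows <- lapply(seq_along(masks), function(i) {
    cbind(data.frame(nucleus_id = i),
          as.data.frame(measure_nucleus(img, masks[[i]], cutoff)))
  })
  do.call(rbind, rows)
}
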