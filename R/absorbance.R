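#' Absorbance image container
#'
#' Wraps a 2D grid of per-pixel optical densities (dimensionless
#' absorbance, >= 0) together with the physical pixel pitch. All
#' densitometric measurements in the package operate on this container;
#' one pixel covers `pixel_pitch_um^2` square micrometres (0.25 um^2 at
#' the default 0.5 um pitch of a scanning microspectrophotometer spot).
#'
#' @param values numeric matrix of optical densities; finite, >= 0.
#' @param pixel_pitch_um physical edge length of one pixel in micrometres.
#' @param source provenance tag: `"measured-absorbance"` for instruments
#'   that report OD directly, `"converted-from-transmittance"` for images
#'   converted with [absorbance_map()], `"synthetic"` for generated data.
#' @return An object of class `absorbance_image`.
#' @seealso [absorbance_map()], [segment_nuclei()], [measure_nucleus()]
#' @export
absorbance_image <- function(values, pixel_pitch_um = 0.5,
                             source = c("measured-absorbance",
                                        "converted-from-transmittance",
                                        "synthetic")) {
  source <- match.arg(source)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix of optical densities")
  if (any(!is.finite(values)))
    stop("absorbance values must all be finite")
  if (any(values < 0))
    stop("absorbance values must be >= 0")
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1L ||
      !is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("`pixel_pitch_um` must be a single positive number")
  structure(
    list(values = values, pixel_pitch_um = as.numeric(pixel_pitch_um),
         source = source),
    class = "absorbance_image"
  )
}

#' @export
print.absorbance_image <- function(x, ...) {
  cat(sprintf("absorbance_image: %d x %d px, pitch %.3g um (%s)\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch_um, x$source))
  cat(sprintf("  OD range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.absorbance_image <- function(x) dim(x$values)

#' Convert a transmittance image to optical density
#'
#' Applies the Beer-Lambert relation `OD = log10(white_reference / I)` to
#' a grayscale intensity image. Intensities at or below `floor` (default
#' one count) are clipped to the floor before conversion so that zero
#' transmission does not produce infinite OD; the number of clipped
#' pixels is recorded in the `"saturated_px"` attribute of the result.
#'
#' @param raw numeric matrix of measured intensities, in
#'   `[0, white_reference]`.
#' @param white_reference intensity of the clear background (100%
#'   transmission); must be positive.
#' @param pixel_pitch_um physical pixel pitch passed through to the
#'   result.
#' @param floor lowest usable intensity count; lower values saturate.
#' @return An [absorbance_image()] with source
#'   `"converted-from-transmittance"` and attribute `saturated_px` (count
#'   of clipped pixels).
#' @examples
#' a <- absorbance_map(matrix(c(255, 25.5), 1), white_reference = 255)
#' a$values  # 0 and 1 OD
#' @export
absorbance_map <- function(raw, white_reference, pixel_pitch_um = 0.5,
                           floor = 1) {
  if (!is.numeric(white_reference) || length(white_reference) != 1L ||
      !is.finite(white_reference) || white_reference <= 0)
    stop("`white_reference` must be a single positive intensity")
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("`raw` must be a numeric intensity matrix")
  if (any(!is.finite(raw)) || any(raw < 0) || any(raw > white_reference))
    stop("intensities must lie in [0, white_reference]")
  saturated <- raw <= floor
  clipped <- pmax(raw, floor)
  od <- log10(white_reference / clipped)
  img <- absorbance_image(od, pixel_pitch_um,
                          source = "converted-from-transmittance")
  attr(img, "saturated_px") <- sum(saturated)
  img
}

#' Read / write absorbance images as 32-bit float TIFF
#'
#' Absorbance grids are stored losslessly as single-channel 32-bit float
#' TIFF. The pixel pitch is not a standard TIFF tag and must be supplied
#' on read (it defaults to the 0.5 um scanning-spot pitch).
#'
#' @param img an [absorbance_image()].
#' @param path file path.
#' @param pixel_pitch_um pixel pitch to attach on read.
#' @return `write_absorbance_tiff()` returns `path` invisibly;
#'   `read_absorbance_tiff()` returns an [absorbance_image()].
#' @export
write_absorbance_tiff <- function(img, path) {
  stopifnot(inherits(img, "absorbance_image"))
  tiff::writeTIFF(img$values, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_absorbance_tiff
#' @export
read_absorbance_tiff <- function(path, pixel_pitch_um = 0.5) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]  # tolerate replicated channels
  absorbance_image(v, pixel_pitch_um, source = "measured-absorbance")
}

#' Read / write 8-bit transmittance PNG with a JSON sidecar
#'
#' An absorbance image can be exchanged as an 8-bit transmittance PNG
#' (`I = white_reference * 10^-OD`). Because 8-bit quantization is lossy
#' and the white reference is not stored in the PNG itself, the white
#' reference and pixel pitch are written to a `<path>.json` sidecar which
#' the reader consults.
#'
#' @inheritParams write_absorbance_tiff
#' @param white_reference white level on the 8-bit scale.
#' @return `write_transmittance_png()` returns `path` invisibly;
#'   `read_transmittance_png()` returns an [absorbance_image()].
#' @export
write_transmittance_png <- function(img, path, white_reference = 255) {
  stopifnot(inherits(img, "absorbance_image"))
  trans <- white_reference * 10^(-img$values)
  png::writePNG(trans / white_reference, path)
  jsonlite::write_json(
    list(white_reference = white_reference,
         pixel_pitch_um = img$pixel_pitch_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transmittance_png
#' @export
read_transmittance_png <- function(path) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar)
          else list(white_reference = 255, pixel_pitch_um = 0.5)
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  raw <- v * meta$white_reference
  absorbance_map(raw, meta$white_reference, meta$pixel_pitch_um)
}
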