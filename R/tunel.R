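#' TUNEL rank from relative dark-spot area
#'
#' Classification rule for TUNEL positivity by nuclear relative spot
#' area: 0% is negative, below 5% weak, 5% up to (but excluding) 50%
#' moderate, and 50% or more strong. Boundaries are closed on the lower
#' side (exactly 5% is moderate, exactly 50% strong).
#'
#' @param relative_area_pct percentage of nuclear area covered by dark
#'   spots, in `[0, 100]`.
#' @param thresholds two ascending percentages: the weak/moderate and
#'   moderate/strong boundaries (default `c(5, 50)`).
#' @return Character vector of ranks in
#'   `{"negative", "weak", "moderate", "strong"}`.
#' @export
tunel_rank <- function(relative_area_pct, thresholds = c(5, 50)) {
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    stop("`thresholds` must be two ascending percentages")
  if (any(relative_area_pct < 0 | relative_area_pct > 100))
    stop("relative areas must lie in [0, 100]")
  ifelse(relative_area_pct == 0, "negative",
  ifelse(relative_area_pct < thresholds[1L], "weak",
  ifelse(relative_area_pct < thresholds[2L], "moderate", "strong")))
}

#' Detect dark DAB spots inside a nucleus by the gray-window rule
#'
#' Spot pixels are the in-nucleus pixels whose 8-bit gray value lies in
#' `[low, high]` inclusive (default 60-100). For color input the gray
#' value is by default the Rec.601 luminance
#' `0.299 R + 0.587 G + 0.114 B`; a single channel can be selected
#' instead, since the instrument convention does not fix the channel.
#'
#' @param img numeric matrix (grayscale) or `nrow x ncol x 3` array
#'   (color); values on the 0-255 scale, or 0-1 (rescaled
#'   automatically).
#' @param nucleus_mask a [nucleus_mask()] delimiting the nucleus.
#' @param low,high inclusive gray window on the 8-bit scale.
#' @param channel `"luminance"` (default) or one of `"red"`, `"green"`,
#'   `"blue"` for color input.
#' @return Integer vector of linear pixel indices of the detected spot
#'   pixels (a subset of `nucleus_mask$idx`).
#' @export
detect_spots <- function(img, nucleus_mask, low = 60, high = 100,
                         channel = c("luminance", "red", "green", "blue")) {
  channel <- match.arg(channel)
  if (!(low >= 0 && low <= high && high <= 255))
    stop("invalid gray window: need 0 <= low <= high <= 255")
  if (!inherits(nucleus_mask, "nucleus_mask"))
    stop("`nucleus_mask` must be a nucleus_mask")
  if (is.matrix(img)) {
    gray <- img
  } else if (is.array(img) && length(dim(img)) == 3L && dim(img)[3L] >= 3L) {
    d <- dim(img)
    chan <- function(k) matrix(img[, , k], d[1L], d[2L])
    gray <- switch(channel,
      luminance = 0.299 * chan(1L) + 0.587 * chan(2L) +
                  0.114 * chan(3L),
      red = chan(1L), green = chan(2L), blue = chan(3L))
  } else stop("`img` must be a grayscale matrix or an RGB array")
  if (!identical(dim(gray)[1:2], as.integer(nucleus_mask$dim)))
    stop("image and mask dimensions disagree")
  if (max(gray) <= 1) gray <- gray * 255
  g <- gray[nucleus_mask$idx]
  nucleus_mask$idx[g >= low & g <= high]
}

#' Score one nucleus from its spot mask
#'
#' @param nucleus_mask a [nucleus_mask()] with at least one pixel.
#' @param spot_idx integer vector of spot pixel indices (subset of the
#'   nucleus, e.g. from [detect_spots()]).
#' @param thresholds rank boundaries passed to [tunel_rank()].
#' @return An object of class `tunel_score`: list with
#'   `nucleus_area_px`, `spot_area_px`, `relative_area_pct`, `rank`.
#' @examples
#' m <- nucleus_mask(1:100, c(10, 10))
#' classify_tunel(m, 1:50)$rank  # "strong"
#' @export
classify_tunel <- function(nucleus_mask, spot_idx, thresholds = c(5, 50)) {
  if (!inherits(nucleus_mask, "nucleus_mask") ||
      length(nucleus_mask$idx) < 1L)
    stop("`nucleus_mask` must be a non-empty nucleus_mask")
  spot_idx <- unique(as.integer(spot_idx))
  if (!all(spot_idx %in% nucleus_mask$idx))
    stop("spot pixels must lie inside the nucleus mask")
  n <- length(nucleus_mask$idx)
  s <- length(spot_idx)
  rel <- 100 * s / n
  structure(
    list(nucleus_area_px = n, spot_area_px = s,
         relative_area_pct = rel,
         rank = tunel_rank(rel, thresholds)),
    class = "tunel_score"
  )
}

#' @export
print.tunel_score <- function(x, ...) {
  cat(sprintf("tunel_score: %d/%d px (%.2f%%) -> %s\n",
              x$spot_area_px, x$nucleus_area_px,
              x$relative_area_pct, x$rank))
  invisible(x)
}

#' Per-condition TUNEL positivity table
#'
#' Aggregates per-cell scores into the conventional positivity layout:
#' per condition, the percentage of cells with weak, moderate and strong
#' responses and their total (a cell is positive when its rank is not
#' `"negative"`).
#'
#' @param scores data.frame with columns `condition` and `rank`
#'   (ranks as produced by [classify_tunel()]).
#' @return data.frame with columns `condition`, `n_cells`,
#'   `pct_total_positive`, `pct_strong`, `pct_moderate`, `pct_weak`.
#' @examples
#' df <- data.frame(condition = "c",
#'                  rank = c(rep("negative", 982), rep("weak", 10),
#'                           rep("moderate", 5), rep("strong", 3)))
#' positivity_table(df)  # total 1.8%
#' @export
positivity_table <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0L ||
      !all(c("condition", "rank") %in% names(scores)))
    stop("`scores` must be a non-empty data.frame with ",
         "`condition` and `rank` columns")
  bad <- setdiff(unique(scores$rank),
                 c("negative", "weak", "moderate", "strong"))
  if (length(bad)) stop("unknown rank(s): ", paste(bad, collapse = ", "))
  out <- lapply(split(scores, scores$condition), function(d) {
    n <- nrow(d)
    pct <- function(r) 100 * sum(d$rank == r) / n
    data.frame(condition = d$condition[1L], n_cells = n,
               pct_total_positive = 100 * sum(d$rank != "negative") / n,
               pct_strong = pct("strong"), pct_moderate = pct("moderate"),
               pct_weak = pct("weak"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score a batch of TUNEL cell images
#'
#' Convenience wrapper running [detect_spots()] and [classify_tunel()]
#' over a list of cells (as produced by [generate_tunel_cell()] or
#' assembled from read images).
#'
#' @param cells list of lists with elements `image` and `mask`.
#' @param condition label(s) recycled over cells.
#' @param low,high gray window (see [detect_spots()]).
#' @param thresholds rank boundaries (see [tunel_rank()]).
#' @param channel gray channel (see [detect_spots()]).
#' @return data.frame: `condition`, `cell_id`, `nucleus_area_px`,
#'   `spot_area_px`, `relative_area_pct`, `rank`.
#' @export
score_tunel_cells <- function(cells, condition = "all", low = 60,
                              high = 100, thresholds = c(5, 50),
                              channel = "luminance") {
  stopifnot(length(cells) >= 1L)
  condition <- rep_len(condition, length(cells))
  rows <- lapply(seq_along(cells), function(i) {
    sc <- classify_tunel(
      cells[[i]]$mask,
      detect_spots(cells[[i]]$image, cells[[i]]$mask, low, high,
                   channel = channel),
      thresholds)
    data.frame(condition = condition[i], cell_id = i,
               nucleus_area_px = sc$nucleus_area_px,
               spot_area_px = sc$spot_area_px,
               relative_area_pct = sc$relative_area_pct,
               rank = sc$rank)
  })
  do.call(rbind, rows)
}
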