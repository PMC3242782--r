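#' Nucleus pixel mask
#'
#' A set of pixel positions (linear, column-major indices into the image
#' grid) belonging to one nucleus, with its bounding box. Produced by
#' [segment_nuclei()] or by the synthetic generator.
#'
#' @param idx integer vector of linear pixel indices (1-based).
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return An object of class `nucleus_mask` with elements `idx`, `dim`,
#'   `bbox` (`rmin, rmax, cmin, cmax`) and `area_px`.
#' @export
nucleus_mask <- function(idx, dim) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) stop("a nucleus mask cannot be empty")
  if (min(idx) < 1L || max(idx) > prod(dim))
    stop("mask indices outside the image grid")
  row <- (idx - 1L) %% dim[1L] + 1L
  col <- (idx - 1L) %/% dim[1L] + 1L
  structure(
    list(idx = idx, dim = as.integer(dim),
         bbox = c(rmin = min(row), rmax = max(row),
                  cmin = min(col), cmax = max(col)),
         area_px = length(idx)),
    class = "nucleus_mask"
  )
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("nucleus_mask: %d px, bbox rows %d-%d cols %d-%d (grid %d x %d)\n",
              x$area_px, x$bbox["rmin"], x$bbox["rmax"],
              x$bbox["cmin"], x$bbox["cmax"], x$dim[1], x$dim[2]))
  invisible(x)
}

# 8-connected component labeling of a set of foreground pixels.
# Builds the pixel adjacency graph (E, S, SE, SW neighbors — the
# symmetric closure covers all eight directions) and labels components
# with igraph. Returns an integer membership vector parallel to `fg`.
label_components8 <- function(dm, fg) {
  nfg <- length(fg)
  if (nfg == 0L) return(integer(0))
  nr <- dm[1L]; nc <- dm[2L]
  pos <- integer(nr * nc)
  pos[fg] <- seq_len(nfg)
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L
  edges <- vector("list", 4L)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (i in seq_along(offs)) {
    r2 <- row + offs[[i]][1L]
    c2 <- col + offs[[i]][2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- pos[(c2[ok] - 1L) * nr + r2[ok]]
    sel <- nb > 0L
    edges[[i]] <- rbind(pos[fg[ok]][sel], nb[sel])
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_graph(as.vector(el), n = nfg, directed = FALSE)
  igraph::components(g)$membership
}

#' Segment nuclei by the background absorbance rule
#'
#' Pixels with optical density no higher than `background_threshold`
#' (default 0.020) are treated as background and removed; the surviving
#' pixels are grouped into 8-connected components, and components smaller
#' than `min_area_px` are discarded as debris. Each retained component
#' becomes one [nucleus_mask()]. Touching nuclei are not split (no
#' watershed); see the package vignette for this limitation.
#'
#' @param img an [absorbance_image()].
#' @param background_threshold OD at or below which a pixel is
#'   background.
#' @param min_area_px smallest component (in pixels) retained as a
#'   nucleus.
#' @return A list of [nucleus_mask()] objects, ordered by decreasing
#'   area (ties broken by first pixel position); empty list when nothing
#'   survives.
#' @examples
#' img <- absorbance_image(matrix(c(0.02, 0.3, 0.3, 0.3), 2))
#' segment_nuclei(img, min_area_px = 1)
#' @export
segment_nuclei <- function(img, background_threshold = 0.020,
                           min_area_px = 50L) {
  stopifnot(inherits(img, "absorbance_image"))
  if (!is.numeric(background_threshold) || background_threshold < 0)
    stop("`background_threshold` must be a non-negative OD")
  fg <- which(img$values > background_threshold)
  if (length(fg) == 0L) return(list())
  memb <- label_components8(dim(img$values), fg)
  comps <- split(fg, memb)
  comps <- comps[lengths(comps) >= min_area_px]
  if (length(comps) == 0L) return(list())
  ord <- order(-lengths(comps), vapply(comps, min, integer(1L)))
  lapply(comps[ord], nucleus_mask, dim = dim(img$values))
}
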