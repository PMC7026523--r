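# Cell segmentation from height maps.

# Otsu threshold computed on a vector of (nonzero) heights
otsu_threshold <- function(v, nbins = 256) {
  if (length(v) < 2 || diff(range(v)) == 0) return(min(v))
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = nbins + 1),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}

#' Segment cells from a height map
#'
#' Threshold (Otsu on the nonzero heights by default), fill holes, split
#' touching cells by distance-transform watershed, and discard components
#' below `min_area` pixels. Deterministic for a fixed input; an all-background
#' map yields an empty labelling, not an error.
#'
#' @param height height map (nm) or a `phase_field` (converted via
#'   [phase_to_height()]).
#' @param min_area minimum component area in pixels.
#' @param threshold `"otsu"` (default) or a numeric height threshold in nm.
#' @param threshold_frac fraction of the Otsu level actually used as the cut;
#'   values below 1 retain the smooth roll-off rim of each cell, which the
#'   Otsu criterion (driven by the plateau heights) would otherwise clip.
#' @param watershed_tolerance minimum object-separation depth (px) passed to
#'   the watershed; larger values merge shallow splits.
#' @return object of class `cell_masks`: list with `labels` (integer matrix,
#'   0 = background) and `info` (data.frame: label, area_px, border flag,
#'   bounding box).
#' @export
segment_cells <- function(height, min_area = 50, threshold = "otsu",
                          threshold_frac = 0.3, watershed_tolerance = 2) {
  if (inherits(height, "phase_field")) height <- phase_to_height(height)
  stopifnot(is.matrix(height))
  stopifnot_finite(height, "height map")
  nz <- height[height > 0]
  empty <- structure(list(labels = matrix(0L, nrow(height), ncol(height)),
                          info = data.frame(label = integer(),
                                            area_px = integer(),
                                            border = logical())),
                     class = "cell_masks")
  if (length(nz) < min_area) return(empty)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(nz) * threshold_frac
    else as.numeric(threshold)
  bw <- height > thr
  bw <- as.matrix(EBImage::fillHull(EBImage::Image(bw * 1)) > 0.5)
  if (!any(bw)) return(empty)
  dm <- EBImage::distmap(EBImage::Image(bw * 1))
  lab <- as.matrix(EBImage::watershed(dm, tolerance = watershed_tolerance,
                                      ext = 1))
  storage.mode(lab) <- "integer"
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= min_area)
  if (!length(keep)) return(empty)
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  info <- do.call(rbind, lapply(seq_along(keep), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    data.frame(label = i, area_px = nrow(idx),
               border = min(idx) == 1L || max(idx[, 1]) == nrow(lab) ||
                 max(idx[, 2]) == ncol(lab))
  }))
  structure(list(labels = lab, info = info), class = "cell_masks")
}

#' @export
print.cell_masks <- function(x, ...) {
  cat(sprintf("<cell_masks> %d cells in a %dx%d field\n",
              nrow(x$info), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}
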