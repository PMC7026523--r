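# Per-cell phase-signature extraction: 6 shape features, 5 height statistics,
# intensity entropy and 4 GLCM (Haralick) texture features.

#' Names of the 17 phase parameters
#' @return character vector of feature column names.
#' @export
em_feature_names <- function() {
  c("area_um2", "perimeter_um", "circularity", "eccentricity", "solidity",
    "aspect_ratio", "mean_height_nm", "max_height_nm", "sd_height_nm",
    "phase_volume_um3", "height_skewness", "height_kurtosis", "entropy_bits",
    "glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity")
}

# grey-level co-occurrence statistics of a patch (NA outside the cell),
# quantized to `levels` over the patch's own range; offsets averaged,
# symmetric, normalized
glcm_stats <- function(patch, levels = 32,
                       offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  v <- patch[!is.na(patch)]
  rg <- range(v)
  q <- if (diff(rg) == 0) {
    matrix(ifelse(is.na(patch), NA_integer_, 1L), nrow(patch))
  } else {
    qi <- pmin(floor((patch - rg[1]) / diff(rg) * levels) + 1L, levels)
    matrix(as.integer(qi), nrow(patch))
  }
  n1 <- nrow(q); n2 <- ncol(q)
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(n1, n1 - dr)
    c1 <- max(1, 1 - dc):min(n2, n2 - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    okp <- !is.na(a) & !is.na(b)
    if (!any(okp)) next
    counts <- counts + matrix(tabulate(a[okp] + levels * (b[okp] - 1L),
                                       nbins = levels * levels), levels)
  }
  counts <- counts + t(counts)  # symmetric
  tot <- sum(counts)
  if (tot == 0) {
    return(c(glcm_contrast = 0, glcm_correlation = 1, glcm_energy = 1,
             glcm_homogeneity = 1))
  }
  p <- counts / tot
  i <- matrix(rep(seq_len(levels), levels), levels)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (s_i > 0 && s_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j) else 1
  c(glcm_contrast = sum(p * (i - j)^2),
    glcm_correlation = corr,
    glcm_energy = sum(p^2),
    glcm_homogeneity = sum(p / (1 + abs(i - j))))
}

# perimeter of a binary mask (matrix) via its oriented 8-connected contour,
# in pixels; Kulpa's 0.948 correction removes the systematic staircase
# overestimate of digitized smooth boundaries
mask_perimeter <- function(bw) {
  oc <- EBImage::ocontour(EBImage::Image(bw * 1))
  if (!length(oc)) return(0)
  per <- vapply(oc, function(ct) {
    d <- diff(rbind(ct, ct[1, , drop = FALSE]))
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
  0.948 * max(per)
}

shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Extract the 17-parameter phase signature of one cell
#'
#' Shape features come from the pixel-coordinate moments and the mask contour;
#' height statistics from the in-mask height values; texture features from the
#' in-mask heights quantized to 32 grey levels with the four standard GLCM
#' offsets averaged. Skewness and kurtosis (excess) are defined as 0 for a
#' constant interior, and GLCM correlation as 1 for a single occupied level.
#' Cells touching the field border are flagged (`border = TRUE`), not dropped.
#'
#' @param height height map of the field (nm).
#' @param labels integer label matrix (e.g. from [segment_cells()] or a
#'   `phase_field`).
#' @param id cell label to extract.
#' @param pixel_pitch lateral pixel pitch in um.
#' @return one-row data.frame: 17 features plus `border`.
#' @export
extract_features <- function(height, labels, id, pixel_pitch = 0.18) {
  idx <- which(labels == id, arr.ind = TRUE)
  if (nrow(idx) == 0) stop(sprintf("empty mask for label %s", id))
  h <- height[idx]
  stopifnot_finite(h, "heights on mask")
  npx <- nrow(idx)
  area <- npx * pixel_pitch^2

  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  border <- rr[1] == 1L || cr[1] == 1L ||
    rr[2] == nrow(labels) || cr[2] == ncol(labels)

  # crop with a 1-px margin for the contour and GLCM
  r0 <- max(rr[1] - 1L, 1L); c0 <- max(cr[1] - 1L, 1L)
  r1 <- min(rr[2] + 1L, nrow(labels)); c1 <- min(cr[2] + 1L, ncol(labels))
  sub <- labels[r0:r1, c0:c1, drop = FALSE] == id
  perim <- mask_perimeter(sub) * pixel_pitch
  circ <- if (perim > 0) min(1, 4 * pi * area / perim^2) else 1

  # second-order moments of the pixel coordinates
  xy <- sweep(idx, 2, colMeans(idx))
  cv <- crossprod(xy) / npx
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-9)
  ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  aspect <- sqrt(ev[1] / ev[2])

  hull <- grDevices::chull(idx)
  hull_area <- shoelace_area(idx[hull, , drop = FALSE])
  solidity <- if (hull_area > 0) min(1, npx / hull_area) else 1

  sdh <- stats::sd(h)
  if (!is.finite(sdh)) sdh <- 0
  skw <- if (sdh > 0) e1071::skewness(h, type = 2) else 0
  krt <- if (sdh > 0) e1071::kurtosis(h, type = 2) else 0

  # entropy of the 32-bin height histogram (bits)
  rgh <- range(h)
  ent <- if (diff(rgh) == 0) 0 else {
    p <- tabulate(pmin(floor((h - rgh[1]) / diff(rgh) * 32) + 1L, 32L), 32L)
    p <- p[p > 0] / length(h)
    -sum(p * log2(p))
  }

  patch <- height[r0:r1, c0:c1, drop = FALSE]
  patch[!sub] <- NA_real_
  g <- glcm_stats(patch)

  out <- data.frame(
    area_um2 = area, perimeter_um = perim, circularity = circ,
    eccentricity = ecc, solidity = solidity, aspect_ratio = aspect,
    mean_height_nm = mean(h), max_height_nm = max(h), sd_height_nm = sdh,
    phase_volume_um3 = sum(h) * 1e-3 * pixel_pitch^2,
    height_skewness = skw, height_kurtosis = krt, entropy_bits = ent,
    glcm_contrast = unname(g["glcm_contrast"]),
    glcm_correlation = unname(g["glcm_correlation"]),
    glcm_energy = unname(g["glcm_energy"]),
    glcm_homogeneity = unname(g["glcm_homogeneity"]),
    border = border)
  stopifnot_finite(as.matrix(out[em_feature_names()]), "feature vector")
  out
}

#' Build the per-cell feature table of one or more fields
#'
#' Each field contributes one row per cell. Fields may be `phase_field`
#' objects (the generator's ground-truth labels are used, and blend/phenotype
#' metadata is attached) or plain lists with elements `height` (nm matrix),
#' `line`, `field_id` and optionally `labels`; fields without labels are
#' segmented with [segment_cells()].
#'
#' @param fields list of fields.
#' @param min_area minimum component area (px) when segmentation is needed.
#' @return data.frame with the 17 feature columns of [em_feature_names()] plus
#'   `cell_id`, `line`, `field_id`, `border`, `blend`, `phenotype`.
#' @export
build_feature_table <- function(fields, min_area = 50) {
  if (!length(fields)) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(em_feature_names())), em_feature_names()))
    out$border <- logical(0)
    out <- cbind(data.frame(cell_id = character(0), line = character(0),
                            field_id = character(0), blend = numeric(0),
                            phenotype = numeric(0)), out)
    return(out)
  }
  ids <- vapply(fields, function(f) f$field_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate field ids")
  rows <- lapply(fields, function(f) {
    if (inherits(f, "phase_field")) {
      height <- phase_to_height(f)
      labels <- f$labels
      pitch <- f$pixel_pitch
      truth <- f$truth
    } else {
      height <- f$height
      labels <- f$labels %||% segment_cells(height, min_area = min_area)$labels
      pitch <- f$pixel_pitch %||% 0.18
      truth <- f$truth %||% NULL
    }
    labs <- sort(unique(labels[labels > 0L]))
    if (!length(labs)) return(NULL)
    feats <- do.call(rbind, lapply(labs, function(id) {
      extract_features(height, labels, id, pitch)
    }))
    meta <- data.frame(
      cell_id = sprintf("%s_c%03d", f$field_id, labs),
      line = f$line, field_id = f$field_id,
      blend = if (!is.null(truth)) truth$blend[match(labs, truth$cell_label)]
        else NA_real_,
      phenotype = if (!is.null(truth))
        truth$phenotype[match(labs, truth$cell_label)] else NA_real_)
    cbind(meta, feats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
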