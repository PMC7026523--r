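# Field-of-view assembly: place phantom cells into phase maps with ground truth.

place_offsets <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  list(rows = idx[, 1], cols = idx[, 2],
       cr = mean(range(idx[, 1])), cc = mean(range(idx[, 2])),
       reff = sqrt(nrow(idx) / pi))
}

#' Generate one synthetic field of view
#'
#' Places all `n_cells` of one line profile into a single phase map of side
#' `config$field_size`. Cells never overlap; with probability
#' `clustering_rate` a cell is placed adjacent (touching allowed) to an
#' already-placed cell, emulating epithelial aggregation. Deterministic for a
#' fixed `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param line name of a line in `config$line_profiles`.
#' @param seed RNG seed for this field; derived from `config$seed` by default.
#' @param field_id identifier stored in the ground truth.
#' @return object of class `phase_field`: list with `phase` (matrix, rad),
#'   `labels` (integer matrix, 0 = background), `truth` (data.frame of per-cell
#'   ground truth), `field_id`, `line`, plus the optical constants, and a
#'   `hologram` slot (NULL until [render_hologram()] is used).
#' @export
generate_field <- function(config, line, seed = NULL, field_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!line %in% names(config$line_profiles)) {
    stop(sprintf("line '%s' not present in config", line))
  }
  profile <- config$line_profiles[[line]]
  li <- match(line, names(config$line_profiles))
  seed <- seed %||% derive_seed(config$seed, li)
  field_id <- field_id %||% sprintf("%s_f01", line)
  n <- config$field_size

  with_seed(seed, {
    phase <- matrix(0, n, n)
    labels <- matrix(0L, n, n)
    truth <- list()
    placed <- list()  # centers and radii of placed cells
    crate <- profile$clustering_rate %||%
      interp_anchors(if (is.null(profile$blend_beta)) profile$blend_m else
        mean(stats::rbeta(200, profile$blend_beta[1], profile$blend_beta[2])))$clustering

    if (profile$n_cells > 0) {
      for (ci in seq_len(profile$n_cells)) {
        cell <- generate_cell_phantom(profile, config)
        po <- place_offsets(cell$mask)
        ok <- FALSE
        for (try in seq_len(400)) {
          cluster <- length(placed) > 0 && stats::runif(1) < crate && try <= 200
          if (cluster) {
            anchor <- placed[[sample.int(length(placed), 1)]]
            ang <- stats::runif(1, 0, 2 * pi)
            d <- (anchor$reff + po$reff) * stats::runif(1, 1.02, 1.15)
            r0 <- round(anchor$r + d * cos(ang) - po$cr)
            col0 <- round(anchor$c + d * sin(ang) - po$cc)
          } else {
            r0 <- sample.int(n - nrow(cell$mask), 1)
            col0 <- sample.int(n - ncol(cell$mask), 1)
          }
          rows <- po$rows + r0; cols <- po$cols + col0
          if (min(rows) < 1 || min(cols) < 1 || max(rows) > n || max(cols) > n) next
          lin <- rows + (cols - 1L) * n
          if (any(labels[lin] != 0L)) next
          phase[lin] <- cell$phase[cell$mask]
          labels[lin] <- ci
          placed[[length(placed) + 1L]] <-
            list(r = r0 + po$cr, c = col0 + po$cc, reff = po$reff)
          truth[[ci]] <- data.frame(
            field_id = field_id, line = line, cell_label = ci,
            blend = cell$params$blend, phenotype = cell$params$phenotype,
            area_um2 = cell$params$area_um2,
            eccentricity = cell$params$eccentricity,
            peak_height_nm = cell$params$peak_height_nm,
            centroid_row = mean(rows), centroid_col = mean(cols),
            area_px = length(rows))
          ok <- TRUE
          break
        }
        if (!ok) {
          stop(sprintf("placement error: could not place cell %d of line %s in a %dpx field",
                       ci, line, n))
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(field_id = character(), line = character(),
                 cell_label = integer(), blend = numeric(),
                 phenotype = numeric(), area_um2 = numeric(),
                 eccentricity = numeric(), peak_height_nm = numeric(),
                 centroid_row = numeric(), centroid_col = numeric(),
                 area_px = integer())
    structure(list(
      field_id = field_id, line = line, phase = phase, labels = labels,
      truth = truth, pixel_pitch = config$pixel_pitch,
      wavelength = config$wavelength, delta_n = config$delta_n,
      hologram = NULL
    ), class = "phase_field")
  })
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("<phase_field> %s (%s): %dx%d px, %d cells\n", x$field_id,
              x$line, nrow(x$phase), ncol(x$phase), nrow(x$truth)))
  invisible(x)
}

#' Simulate the full dataset described by a configuration
#'
#' Splits every line into fields of at most `config$cells_per_field` cells and
#' generates each field with a seed derived from `config$seed`, so the whole
#' dataset is a pure function of the configuration.
#'
#' @param config a [sim_config()].
#' @return list with `fields` (list of `phase_field`) and `truth` (combined
#'   ground-truth data.frame).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fields <- list()
  k <- 0L
  for (li in seq_along(config$line_profiles)) {
    profile <- config$line_profiles[[li]]
    n_left <- profile$n_cells
    fi <- 0L
    while (n_left > 0L || (fi == 0L && profile$n_cells == 0L)) {
      fi <- fi + 1L
      chunk <- min(n_left, config$cells_per_field)
      sub <- profile
      sub$n_cells <- as.integer(chunk)
      subcfg <- config
      subcfg$line_profiles[[li]] <- sub
      k <- k + 1L
      fields[[k]] <- generate_field(
        subcfg, profile$name,
        seed = derive_seed(config$seed, li * 1000L + fi),
        field_id = sprintf("%s_f%02d", profile$name, fi))
      n_left <- n_left - chunk
      if (profile$n_cells == 0L) break
    }
  }
  truth <- do.call(rbind, lapply(fields, `[[`, "truth"))
  list(fields = fields, truth = truth)
}

#' Simulate and featurize the configured dataset in one step
#'
#' Runs [simulate_dataset()], converts each phase map to a height map and
#' extracts the 17-parameter signature of every cell using the generator's own
#' ground-truth labels (placement is guaranteed, so the row count equals the
#' configured cell count).
#'
#' @param config a [sim_config()].
#' @return feature table (data.frame), one row per cell; see
#'   [build_feature_table()].
#' @export
simulate_feature_table <- function(config) {
  sim <- simulate_dataset(config)
  build_feature_table(sim$fields)
}
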