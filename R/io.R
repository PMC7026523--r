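# File interfaces: float32 TIFF phase/height maps, uint16 hologram and label
# TIFFs, JSON sidecars.

#' Write a phase or height map as float32 TIFF
#'
#' TIFF samples are stored normalized to \[0,1\]; the affine transform back to
#' physical units is recorded in a JSON sidecar (`<path>.json`).
#'
#' @param x numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  stopifnot_finite(x, "map")
  lo <- min(x, 0)
  span <- max(max(x) - lo, 1e-12)
  tiff::writeTIFF((x - lo) / span, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = lo, scale = span),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a float32 TIFF written by [write_phase_tiff()]
#' @param path file path (sidecar `<path>.json` must exist).
#' @return numeric matrix in physical units.
#' @export
read_phase_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (is.list(m)) m <- m[[1]]
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  m * side$scale + side$offset
}

# holograms stored as uint16; intensity of the unit-amplitude two-beam model
# lies in [0, 4], so a fixed scale of 4 is used (recorded in the sidecar)
hologram_scale <- 4

#' Write a hologram as uint16 TIFF with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the intensity scale, carrier and the
#' ground-truth aberration coefficients.
#'
#' @param holo a `hologram`.
#' @param path output path of the TIFF.
#' @return `path`, invisibly.
#' @export
write_hologram_tiff <- function(holo, path) {
  stopifnot(inherits(holo, "hologram"))
  m <- clamp(holo$intensity / hologram_scale, 0, 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(list(scale = hologram_scale, carrier = holo$carrier,
                            tilt = holo$tilt, quadratic = holo$quadratic,
                            center = holo$center),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Read a hologram written by [write_hologram_tiff()]
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return a `hologram`.
#' @export
read_hologram_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(list(intensity = m * side$scale, carrier = side$carrier,
                 tilt = side$tilt, quadratic = side$quadratic,
                 center = side$center),
            class = "hologram")
}

#' Write a simulated field to disk
#'
#' Phase as float32 TIFF, labels as uint16 TIFF, ground truth as a JSON
#' sidecar; the hologram (if rendered) as uint16 TIFF.
#'
#' @param field a `phase_field`.
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
write_field <- function(field, dir) {
  stopifnot(inherits(field, "phase_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, field$field_id)
  paths <- c(phase = paste0(base, "_phase.tif"),
             labels = paste0(base, "_labels.tif"),
             truth = paste0(base, "_truth.json"))
  write_phase_tiff(field$phase, paths["phase"])
  tiff::writeTIFF(field$labels / 65535, paths["labels"],
                  bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(list(field_id = field$field_id, line = field$line,
                            pixel_pitch = field$pixel_pitch,
                            wavelength = field$wavelength,
                            delta_n = field$delta_n, truth = field$truth),
                       paths["truth"], digits = NA, dataframe = "columns")
  if (!is.null(field$hologram)) {
    paths <- c(paths, hologram = paste0(base, "_holo.tif"))
    write_hologram_tiff(field$hologram, paths[["hologram"]])
  }
  invisible(paths)
}

#' Write a feature or score table as CSV with a versioned header comment
#' @param table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# emscore table v1; columns=%d", ncol(table)), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
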