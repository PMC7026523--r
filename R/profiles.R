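# Cell-line profiles and simulation configuration for the synthetic generator.

# Archetype anchor parameters. A cell's expected morphology is the interpolation
# of these two anchors at its latent phenotype p in [0,1] (0 = epithelial,
# 1 = mesenchymal). Values are the generator's calibration constants:
#   - epithelial cells: smaller, rounder, taller (peak height ~6 um), smoother
#     texture, strong clustering;
#   - mesenchymal cells: larger, elongated, flatter (~2.5 um), grainier texture,
#     mostly isolated.
# latent_sd is the s.d. of the within-line phenotype scatter around the line's
# blend value; it sets the archetype separability in feature space.
.em_anchors <- list(
  epithelial = list(
    area_meanlog   = log(340),  # um^2
    area_sdlog     = 0.12,
    ecc_mean       = 0.25,
    ecc_prec       = 80,
    height_meanlog = log(6000), # nm, peak height
    height_sdlog   = 0.10,
    texture        = 0.12,      # speckle spatial-frequency parameter (1/px)
    boundary_amp   = 0.04,      # Fourier boundary irregularity amplitude
    clustering     = 0.55
  ),
  mesenchymal = list(
    area_meanlog   = log(520),
    area_sdlog     = 0.13,
    ecc_mean       = 0.75,
    ecc_prec       = 80,
    height_meanlog = log(2500),
    height_sdlog   = 0.10,
    texture        = 0.24,
    boundary_amp   = 0.14,
    clustering     = 0.08
  ),
  latent_sd = 0.14
)

#' Define a synthetic cell-line profile
#'
#' A line profile fixes the number of cells, the mesenchymal blend law and
#' (optionally) overrides of the per-archetype morphology distributions used by
#' [generate_cell_phantom()]. With `blend_m = 0` the line is a pure epithelial
#' archetype; with `blend_m = 1` a pure mesenchymal archetype. Cancer-like
#' lines draw a per-cell blend from a Beta distribution (`blend_beta`).
#'
#' @param name line label.
#' @param n_cells number of cells to generate (>= 0).
#' @param blend_m fixed mesenchymal blend fraction in \[0,1\]; ignored when
#'   `blend_beta` is given.
#' @param blend_beta optional `c(shape1, shape2)` of a Beta distribution from
#'   which each cell draws its own blend.
#' @param area_dist optional `c(meanlog, sdlog)` lognormal override for cell
#'   area (um^2).
#' @param eccentricity_dist optional `c(mean, precision)` Beta override for
#'   eccentricity; `precision = Inf` makes it degenerate at `mean`.
#' @param height_dist optional `c(meanlog, sdlog)` lognormal override for peak
#'   height (nm).
#' @param texture_granularity optional speckle spatial-frequency override
#'   (0 = smooth interior).
#' @param clustering_rate optional probability in \[0,1\] that a cell is placed
#'   adjacent to an already-placed cell.
#' @return an object of class `line_profile`.
#' @export
line_profile <- function(name, n_cells, blend_m = 0, blend_beta = NULL,
                         area_dist = NULL, eccentricity_dist = NULL,
                         height_dist = NULL, texture_granularity = NULL,
                         clustering_rate = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 0 ||
      n_cells != round(n_cells)) {
    stop("n_cells must be a non-negative integer")
  }
  if (!is.null(blend_beta)) {
    if (length(blend_beta) != 2L || any(blend_beta <= 0)) {
      stop("blend_beta must be two strictly positive shape parameters")
    }
  } else if (!is.numeric(blend_m) || blend_m < 0 || blend_m > 1) {
    stop("blend_m must lie in [0, 1]")
  }
  for (d in list(area_dist, height_dist)) {
    if (!is.null(d) && (length(d) != 2L || d[2] <= 0)) {
      stop("distribution overrides must be c(meanlog, sdlog) with sdlog > 0")
    }
  }
  if (!is.null(eccentricity_dist)) {
    if (length(eccentricity_dist) != 2L || eccentricity_dist[1] < 0 ||
        eccentricity_dist[1] >= 1 || eccentricity_dist[2] <= 0) {
      stop("eccentricity_dist must be c(mean in [0,1), precision > 0)")
    }
  }
  if (!is.null(texture_granularity) && texture_granularity < 0) {
    stop("texture_granularity must be >= 0")
  }
  if (!is.null(clustering_rate) &&
      (clustering_rate < 0 || clustering_rate > 1)) {
    stop("clustering_rate must lie in [0, 1]")
  }
  structure(list(
    name = name, n_cells = as.integer(n_cells),
    blend_m = blend_m, blend_beta = blend_beta,
    area_dist = area_dist, eccentricity_dist = eccentricity_dist,
    height_dist = height_dist, texture_granularity = texture_granularity,
    clustering_rate = clustering_rate
  ), class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  bl <- if (is.null(x$blend_beta)) sprintf("blend_m = %.2f", x$blend_m) else
    sprintf("blend ~ Beta(%.2g, %.2g)", x$blend_beta[1], x$blend_beta[2])
  cat(sprintf("<line_profile> %s: %d cells, %s\n", x$name, x$n_cells, bl))
  invisible(x)
}

#' Default synthetic cell populations
#'
#' Four populations totalling 1295 cells: an epithelial archetype line
#' (332 cells, blend 0), a mesenchymal archetype line (309 cells, blend 1) and
#' two cancer-like lines whose per-cell blends are Beta-distributed, skewed
#' epithelial (307 cells) and skewed mesenchymal (347 cells) respectively.
#'
#' @return list of [line_profile()] objects.
#' @export
default_line_profiles <- function() {
  list(
    line_profile("GIE",  332, blend_m = 0),
    line_profile("HGF",  309, blend_m = 1),
    line_profile("MCF7", 307, blend_beta = c(2, 5)),
    line_profile("MDA",  347, blend_beta = c(5, 2))
  )
}

#' Simulation configuration
#'
#' @param line_profiles list of [line_profile()]s; defaults to
#'   [default_line_profiles()].
#' @param field_size field side length in pixels (>= 64).
#' @param pixel_pitch lateral pixel pitch in um.
#' @param wavelength illumination wavelength in nm.
#' @param delta_n assumed cell/medium refractive-index mismatch.
#' @param cells_per_field maximum cells placed in one field of view.
#' @param seed master seed; every generator draw derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(line_profiles = default_line_profiles(),
                       field_size = 1024, pixel_pitch = 0.18,
                       wavelength = 632, delta_n = 0.044,
                       cells_per_field = 12, seed = 1) {
  stopifnot(field_size >= 64, pixel_pitch > 0, wavelength > 0, delta_n > 0,
            cells_per_field >= 1)
  if (!all(vapply(line_profiles, inherits, logical(1), "line_profile"))) {
    stop("line_profiles must be a list of line_profile objects")
  }
  nm <- vapply(line_profiles, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate line names in line_profiles")
  structure(list(
    line_profiles = stats::setNames(line_profiles, nm),
    field_size = as.integer(field_size), pixel_pitch = pixel_pitch,
    wavelength = wavelength, delta_n = delta_n,
    cells_per_field = as.integer(cells_per_field),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d lines, %d cells total, field %dpx @ %.2f um, %g nm, seed %d\n",
              length(x$line_profiles),
              sum(vapply(x$line_profiles, `[[`, integer(1), "n_cells")),
              x$field_size, x$pixel_pitch, x$wavelength, x$seed))
  invisible(x)
}

# interpolate anchor parameters at phenotype p
interp_anchors <- function(p) {
  e <- .em_anchors$epithelial; m <- .em_anchors$mesenchymal
  lapply(stats::setNames(nm = names(e)), function(f) (1 - p) * e[[f]] + p * m[[f]])
}

# draw the per-cell morphology targets for one cell of a profile
draw_cell_params <- function(profile) {
  b <- if (!is.null(profile$blend_beta)) {
    stats::rbeta(1, profile$blend_beta[1], profile$blend_beta[2])
  } else profile$blend_m
  p <- clamp(b + stats::rnorm(1, 0, .em_anchors$latent_sd), 0, 1)
  a <- interp_anchors(p)

  area <- if (!is.null(profile$area_dist)) {
    stats::rlnorm(1, profile$area_dist[1], profile$area_dist[2])
  } else stats::rlnorm(1, a$area_meanlog, a$area_sdlog)

  ecc <- if (!is.null(profile$eccentricity_dist)) {
    em <- profile$eccentricity_dist[1]; ep <- profile$eccentricity_dist[2]
    if (is.infinite(ep)) em else stats::rbeta(1, em * ep, (1 - em) * ep)
  } else {
    em <- clamp(a$ecc_mean, 0.02, 0.97)
    stats::rbeta(1, em * a$ecc_prec, (1 - em) * a$ecc_prec)
  }
  ecc <- clamp(ecc, 0, 0.995)

  height <- if (!is.null(profile$height_dist)) {
    stats::rlnorm(1, profile$height_dist[1], profile$height_dist[2])
  } else stats::rlnorm(1, a$height_meanlog, a$height_sdlog)

  list(blend = b, phenotype = p, area_um2 = area, eccentricity = ecc,
       peak_height_nm = height,
       texture = profile$texture_granularity %||% a$texture,
       boundary_amp = a$boundary_amp)
}
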