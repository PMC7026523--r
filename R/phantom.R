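# Single-cell phase phantoms: superellipse/Fourier-perturbed blobs with a
# plateau height profile and band-limited interior speckle.

#' Generate one synthetic cell phase patch
#'
#' Draws a cell from a line profile and renders its phase map on a minimal
#' patch. The cell outline is an ellipse (area and eccentricity drawn from the
#' profile's distributions, interpolated at the cell's latent phenotype) with a
#' low-order Fourier boundary perturbation; the height profile is a plateau
#' with a smooth edge roll-off, modulated by band-limited speckle whose spatial
#' frequency is set by the profile's texture granularity. Phase is
#' `2 pi * height * delta_n / wavelength`, non-negative inside the mask and 0
#' outside. Draws come from the current RNG stream; seed it (or use
#' [generate_field()]) for reproducibility.
#'
#' @param profile a [line_profile()].
#' @param config a [sim_config()] supplying pixel pitch, wavelength and
#'   delta_n.
#' @param params optional pre-drawn cell parameters (internal use).
#' @return list with `phase` (matrix, rad), `mask` (logical matrix), and
#'   `params` (the drawn ground-truth morphology).
#' @export
generate_cell_phantom <- function(profile, config = sim_config(), params = NULL) {
  stopifnot(inherits(profile, "line_profile"))
  if (is.null(params)) params <- draw_cell_params(profile)

  pitch <- config$pixel_pitch
  area_px <- params$area_um2 / pitch^2
  e <- params$eccentricity
  ax <- sqrt(area_px / (pi * sqrt(1 - e^2)))  # semi-major (px)
  bx <- ax * sqrt(1 - e^2)                    # semi-minor (px)

  # low-order Fourier boundary perturbation, amplitude falling with order
  modes <- 2:5
  cm <- stats::rnorm(length(modes), 0, params$boundary_amp / (modes - 1))
  ph <- stats::runif(length(modes), 0, 2 * pi)
  theta0 <- stats::runif(1, 0, pi)

  radius_fun <- function(theta) {
    t <- theta - theta0
    base <- ax * bx / sqrt((bx * cos(t))^2 + (ax * sin(t))^2)
    f <- 1
    for (i in seq_along(modes)) f <- f + cm[i] * cos(modes[i] * theta + ph[i])
    base * pmax(f, 0.5)
  }

  rmax <- max(radius_fun(seq(0, 2 * pi, length.out = 256)))
  n <- 2L * ceiling(rmax) + 9L
  c0 <- (n + 1) / 2
  dx <- matrix(rep(seq_len(n) - c0, n), n)         # row offsets
  dy <- t(dx)                                      # col offsets
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  R <- matrix(radius_fun(as.vector(th)), n)

  # one area-correction pass so the pixel count matches the drawn area
  scale <- sqrt(area_px / max(sum(r <= R), 1))
  R <- R * scale
  rho <- r / pmax(R, 1e-9)
  mask <- rho <= 1

  # plateau envelope with cosine roll-off over the outer rim; the ~6 px
  # roll-off keeps the phantom band-limited well below the off-axis carrier
  # separation, so demodulation does not clip cell-edge frequencies
  reff <- sqrt(area_px / pi)
  w <- max(6 / reff, 0.1)
  rho0 <- 1 - w
  S <- matrix(0, n, n)
  S[mask] <- ifelse(rho[mask] < rho0, 1,
                    0.5 * (1 + cos(pi * (rho[mask] - rho0) / w)))

  tex <- matrix(0, n, n)
  if (params$texture > 0) {
    z <- matrix(stats::rnorm(n * n), n)
    sigma <- max(1 / params$texture, 0.8)
    z <- as.matrix(EBImage::gblur(EBImage::Image(z), sigma = sigma))
    zs <- stats::sd(z[mask])
    if (is.finite(zs) && zs > 0) tex <- tanh(z / zs) * 0.18
  }

  height <- params$peak_height_nm * S * (1 + tex)
  height[!mask] <- 0
  height <- pmax(height, 0)
  phase <- height * config$delta_n * 2 * pi / config$wavelength
  list(phase = phase, mask = mask, params = params)
}
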