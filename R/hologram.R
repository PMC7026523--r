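# Forward model: off-axis hologram synthesis from a phase map.

#' Render an off-axis hologram from a phase map
#'
#' Two-beam interference forward model: the recorded intensity is
#' `I = |1 + exp(j(phi_obj + phi_ab + 2 pi carrier . r))|^2` plus optional
#' additive Gaussian noise. The aberration surface is
#' `phi_ab = tx*kc + ty*lc + qx*kc^2 + qy*lc^2` over centred pixel coordinates
#' `(kc, lc)`; the applied coefficients are recorded in the returned object so
#' compensation can be validated against ground truth.
#'
#' For clean demodulation the carrier (cycles/pixel) should place the +1 order
#' well away from DC given the object bandwidth; a low carrier triggers a
#' warning. Carriers that are integer multiples of `1/n` land on FFT bins and
#' avoid spectral leakage.
#'
#' @param phase object phase map (matrix, rad) or a `phase_field`.
#' @param carrier `c(fx, fy)` carrier frequency in cycles/pixel.
#' @param tilt `c(tx, ty)` linear aberration coefficients (rad/px).
#' @param quadratic `c(qx, qy)` quadratic aberration coefficients (rad/px^2).
#' @param noise_sd s.d. of additive Gaussian intensity noise (>= 0).
#' @param seed optional seed for the noise draw.
#' @return object of class `hologram`: list with `intensity` (matrix),
#'   `carrier`, `tilt`, `quadratic`, `center` (coordinate origin used for the
#'   aberration polynomial). If `phase` was a `phase_field`, the field is
#'   returned with its `hologram` slot filled instead.
#' @export
render_hologram <- function(phase, carrier = c(0.35, 0.15),
                            tilt = c(0, 0), quadratic = c(0, 0),
                            noise_sd = 0, seed = NULL) {
  if (inherits(phase, "phase_field")) {
    fld <- phase
    holo <- render_hologram(fld$phase, carrier, tilt, quadratic, noise_sd, seed)
    fld$hologram <- holo
    return(fld)
  }
  stopifnot(is.matrix(phase))
  stopifnot_finite(phase, "phase")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n1 <- nrow(phase); n2 <- ncol(phase)
  if (min(abs(carrier)) * max(n1, n2) < 8 && max(abs(carrier)) < 0.05) {
    warning("carrier frequency is low; +1 order may not separate from DC")
  }
  k <- matrix(rep(seq_len(n1), n2), n1)   # row index
  l <- matrix(rep(seq_len(n2), each = n1), n1)
  kc <- k - (n1 + 1) / 2
  lc <- l - (n2 + 1) / 2
  phi_ab <- tilt[1] * kc + tilt[2] * lc +
    quadratic[1] * kc^2 + quadratic[2] * lc^2
  phi <- phase + phi_ab + 2 * pi * (carrier[1] * (k - 1) + carrier[2] * (l - 1))
  I <- Mod(1 + exp(1i * phi))^2
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(n1 * n2, 0, noise_sd) else
      with_seed(seed, stats::rnorm(n1 * n2, 0, noise_sd))
    I <- I + matrix(noise, n1)
  }
  structure(list(intensity = I, carrier = carrier, tilt = tilt,
                 quadratic = quadratic, center = c((n1 + 1) / 2, (n2 + 1) / 2)),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %dx%d px, carrier (%.3f, %.3f) cyc/px\n",
              nrow(x$intensity), ncol(x$intensity), x$carrier[1], x$carrier[2]))
  invisible(x)
}
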