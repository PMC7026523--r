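# Holographic reconstruction: Fresnel propagation, +1-order demodulation,
# SVD/PCA aberration compensation, phase unwrapping, phase-to-height.

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# FFT frequencies in cycles/sample for length n (0, 1/n, ..., -1/n)
fft_freq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

#' Fresnel propagation of a complex field
#'
#' Angular-spectrum / Fresnel transfer-function propagation,
#' `U(z) = IFFT[ FFT(u) * exp(-j pi lambda z (fx^2 + fy^2)) ]`, with the
#' unitary convention (the transfer function is unimodular, so total power is
#' conserved). A positive distance propagates toward the image plane; distance
#' 0 returns the input unchanged.
#'
#' @param field complex (or real) matrix, or a `hologram` (its intensity is
#'   propagated as a real field).
#' @param distance propagation distance in um.
#' @param wavelength wavelength in nm.
#' @param pixel_pitch pixel pitch in um.
#' @return complex matrix of the propagated field.
#' @export
fresnel_reconstruct <- function(field, distance, wavelength = 632,
                                pixel_pitch = 0.18) {
  if (inherits(field, "hologram")) field <- field$intensity
  stopifnot(is.matrix(field))
  if (!all(is.finite(Mod(field)))) stop("non-finite values in field")
  if (distance == 0) return(field + 0i)
  lambda_um <- wavelength * 1e-3
  fx <- fft_freq(nrow(field)) / pixel_pitch
  fy <- fft_freq(ncol(field)) / pixel_pitch
  f2 <- outer(fx^2, fy^2, `+`)
  H <- exp(-1i * pi * lambda_um * distance * f2)
  ifft2(fft2(field) * H)
}

#' Demodulate the +1 diffraction order of an off-axis hologram
#'
#' Locates the strongest spectral peak outside a DC exclusion zone (or uses a
#' supplied carrier estimate), band-passes a circular region of radius half
#' the peak-to-DC distance around it, and recentres the peak to DC. The
#' returned complex field carries the object phase plus any residual
#' aberration surface.
#'
#' @param holo a `hologram` or a real intensity matrix.
#' @param carrier optional `c(fx, fy)` carrier estimate in cycles/pixel;
#'   `NULL` (default) autodetects the strongest non-DC peak.
#' @return complex matrix with attributes `carrier_bin` (0-based FFT bin of
#'   the detected peak) and `carrier` (cycles/pixel).
#' @export
isolate_plus_one_order <- function(holo, carrier = NULL) {
  I <- if (inherits(holo, "hologram")) holo$intensity else holo
  stopifnot(is.matrix(I))
  stopifnot_finite(I, "hologram intensity")
  n1 <- nrow(I); n2 <- ncol(I)
  F <- fft2(I)
  P <- Mod(F)^2
  # torus distance (in bins) of each bin from DC
  d1 <- pmin(seq_len(n1) - 1, n1 - (seq_len(n1) - 1))
  d2 <- pmin(seq_len(n2) - 1, n2 - (seq_len(n2) - 1))
  dist_dc <- sqrt(outer(d1^2, d2^2, `+`))
  rdc <- max(3, round(min(n1, n2) / 24))
  if (is.null(carrier)) {
    cand <- P
    cand[dist_dc <= rdc] <- 0
    # a real-valued hologram has Hermitian spectrum: the +1 and -1 orders tie
    # in magnitude, so restrict to the positive-frequency half-plane
    fr1 <- ifelse(seq_len(n1) - 1 <= n1 / 2, seq_len(n1) - 1, seq_len(n1) - 1 - n1)
    fr2 <- ifelse(seq_len(n2) - 1 <= n2 / 2, seq_len(n2) - 1, seq_len(n2) - 1 - n2)
    neg_half <- outer(fr1, rep(1, n2)) < 0 |
      outer(fr1 == 0, fr2 < 0)
    cand[neg_half] <- 0
    pk <- arrayInd(which.max(cand), dim(cand))
    if (max(cand) < 25 * stats::median(P[dist_dc > rdc])) {
      stop("demodulation error: no off-axis peak above the noise floor")
    }
  } else {
    pk <- cbind(round(carrier[1] * n1) %% n1 + 1, round(carrier[2] * n2) %% n2 + 1)
  }
  pb <- c(pk[1] - 1L, pk[2] - 1L)  # 0-based peak bin
  # band-pass: circular window of radius half the peak-to-DC torus distance
  dpk1 <- pmin(abs(seq_len(n1) - pk[1]), n1 - abs(seq_len(n1) - pk[1]))
  dpk2 <- pmin(abs(seq_len(n2) - pk[2]), n2 - abs(seq_len(n2) - pk[2]))
  dpk <- sqrt(outer(dpk1^2, dpk2^2, `+`))
  rpk <- max(dist_dc[pk[1], pk[2]] * 0.6, 2)
  Fm <- F
  Fm[dpk > rpk] <- 0
  # recentre the peak to DC by circular shift
  sh1 <- (seq_len(n1) + pb[1] - 1L) %% n1 + 1L
  sh2 <- (seq_len(n2) + pb[2] - 1L) %% n2 + 1L
  u <- ifft2(Fm[sh1, sh2])
  attr(u, "carrier_bin") <- pb
  attr(u, "carrier") <- c(pb[1] / n1, pb[2] / n2)
  u
}

#' Unwrap a 2-D wrapped phase map
#'
#' Path-following (Itoh) unwrapping: the central column is unwrapped first,
#' then each row is integrated outward from it. The output is congruent with
#' the input modulo 2 pi at every pixel and spatially continuous wherever the
#' true phase gradient stays below pi per pixel.
#'
#' @param wrapped matrix of phase values (rad).
#' @return unwrapped phase matrix.
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(is.matrix(wrapped))
  stopifnot_finite(wrapped, "wrapped phase")
  n1 <- nrow(wrapped); n2 <- ncol(wrapped)
  c0 <- ceiling(n2 / 2)
  out <- matrix(0, n1, n2)
  ref <- wrapped[, c0]
  out[, c0] <- cumsum(c(ref[1], wrap_phase(diff(ref))))
  if (c0 < n2) {
    dw <- wrap_phase(wrapped[, (c0 + 1):n2, drop = FALSE] -
                       wrapped[, c0:(n2 - 1), drop = FALSE])
    cs <- if (ncol(dw) == 1) dw else t(apply(dw, 1, cumsum))
    out[, (c0 + 1):n2] <- out[, c0] + cs
  }
  if (c0 > 1) {
    dw <- wrap_phase(wrapped[, (c0 - 1):1, drop = FALSE] -
                       wrapped[, c0:2, drop = FALSE])
    cs <- if (ncol(dw) == 1) dw else t(apply(dw, 1, cumsum))
    out[, (c0 - 1):1] <- out[, c0] + cs
  }
  out
}

aberration_basis <- function(n1, n2) {
  kc <- rep(seq_len(n1) - (n1 + 1) / 2, n2)
  lc <- rep(seq_len(n2) - (n2 + 1) / 2, each = n1)
  cbind(const = 1, k = kc, l = lc, k2 = kc^2, l2 = lc^2)
}

#' PCA-based aberration compensation
#'
#' Implements the four-step principal-component compensation of residual tilt
#' and quadratic phase aberrations: (1) SVD of the unwrapped demodulated
#' phase; (2) least-squares fit of linear + quadratic polynomials to the
#' surface spanned by the two dominant singular-vector pairs; (3) evaluation
#' of the aberration surface phi(k,l) over centred pixel coordinates; (4)
#' multiplication of the field by the conjugate exp(-j phi(k,l)), leaving the
#' object phase. A refinement pass re-fits the polynomial on background
#' (non-object) pixels, which makes coefficient recovery exact on noiseless
#' fields, and the background median is subtracted so empty regions sit at
#' phase 0.
#'
#' @param field complex matrix (demodulated +1 order) or an unwrapped phase
#'   matrix.
#' @param refine logical; run the background-masked refinement pass.
#' @return list with `phase` (compensated, unwrapped object phase) and
#'   `model` (class `aberration_model`: `tilt`, `quadratic`, `const`,
#'   `center`, `fit_rms`).
#' @export
pca_aberration_compensate <- function(field, refine = TRUE) {
  phi <- if (is.complex(field)) unwrap_phase(Arg(field)) else field
  stopifnot(is.matrix(phi))
  if (min(dim(phi)) < 8) stop("field too small for aberration compensation")
  n1 <- nrow(phi); n2 <- ncol(phi)
  sv <- tryCatch(svd(phi, nu = 2, nv = 2),
                 error = function(e) stop("SVD failure on degenerate input"))
  rank2 <- sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1]) +
    sv$d[2] * tcrossprod(sv$u[, 2], sv$v[, 2])
  X <- aberration_basis(n1, n2)
  beta <- solve(crossprod(X), crossprod(X, as.vector(rank2)))
  if (refine) {
    resid <- as.vector(phi) - as.vector(X %*% beta)
    md <- stats::median(resid); s <- stats::mad(resid)
    bg <- resid - md < 3 * max(s, 1e-6)  # objects carry positive phase
    if (sum(bg) > 5 * ncol(X)) {
      beta <- solve(crossprod(X[bg, , drop = FALSE]),
                    crossprod(X[bg, , drop = FALSE], as.vector(phi)[bg]))
    }
  }
  surf <- matrix(X %*% beta, n1, n2)
  comp <- phi - surf
  resid2 <- as.vector(comp)
  bg2 <- abs(resid2 - stats::median(resid2)) <
    3 * max(stats::mad(resid2), 1e-6)
  comp <- comp - stats::median(resid2[bg2])
  fit_rms <- sqrt(mean(resid2[bg2]^2))
  if (fit_rms > 0.5) {
    warning(sprintf("aberration fit residual RMS %.2f rad exceeds 0.5 rad", fit_rms))
  }
  model <- structure(list(
    tilt = c(beta[2], beta[3]), quadratic = c(beta[4], beta[5]),
    const = beta[1], center = c((n1 + 1) / 2, (n2 + 1) / 2),
    fit_rms = fit_rms), class = "aberration_model")
  list(phase = comp, model = model)
}

#' Evaluate an aberration model over a pixel grid
#'
#' @param model an `aberration_model`.
#' @param dims `c(nrow, ncol)` of the grid.
#' @return matrix of the polynomial phase surface (rad).
#' @export
aberration_surface <- function(model, dims) {
  X <- aberration_basis(dims[1], dims[2])
  matrix(X %*% c(model$const, model$tilt, model$quadratic), dims[1], dims[2])
}

#' @export
print.aberration_model <- function(x, ...) {
  cat(sprintf("<aberration_model> tilt (%.4g, %.4g) rad/px, quad (%.4g, %.4g) rad/px^2, bg RMS %.3g rad\n",
              x$tilt[1], x$tilt[2], x$quadratic[1], x$quadratic[2], x$fit_rms))
  invisible(x)
}

#' Convert phase to geometric height
#'
#' `height = (phase * wavelength / 2 pi) / delta_n`: the optical pathlength
#' divided by the assumed refractive-index mismatch between cell and medium
#' (default 0.044 = 1.381 - 1.337).
#'
#' @param phase phase matrix (rad) or a `phase_field`.
#' @param wavelength wavelength in nm.
#' @param delta_n refractive-index mismatch (> 0).
#' @return height map in nm (matrix), same shape as the input.
#' @export
phase_to_height <- function(phase, wavelength = 632, delta_n = 0.044) {
  if (delta_n <= 0) stop("delta_n must be > 0")
  if (inherits(phase, "phase_field")) {
    return(phase_to_height(phase$phase, phase$wavelength, phase$delta_n))
  }
  phase * wavelength / (2 * pi) / delta_n
}

#' Reconstruct the object phase of a hologram end to end
#'
#' Convenience wrapper chaining [isolate_plus_one_order()] and
#' [pca_aberration_compensate()].
#'
#' @param holo a `hologram`.
#' @param carrier optional carrier estimate passed to the demodulator.
#' @return list with `phase`, `model`, and the detected `carrier`.
#' @export
reconstruct_phase <- function(holo, carrier = NULL) {
  u <- isolate_plus_one_order(holo, carrier)
  res <- pca_aberration_compensate(u)
  res$carrier <- attr(u, "carrier")
  res
}
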