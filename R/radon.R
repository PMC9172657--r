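# Small bespoke parallel-beam forward model: discrete Radon transform by
# linear splatting of pixel centers onto the detector, and filtered
# back-projection with a Ram-Lak (ramp) filter applied in the frequency
# domain. Exactness is not the goal -- determinism and a physically sensible
# noise mechanism are; structures are assumed to lie inside the inscribed
# circle of the image.

# Pixel/detector geometry: an N x N image lives on [-0.5, 0.5]^2 with pixel
# spacing 1/N; the detector has N bins with the same spacing, centered at 0.
radon_geom <- function(n) {
  cc <- ((seq_len(n)) - (n + 1) / 2) / n
  list(x = rep(cc, each = n), y = rep(cc, times = n), n = n)
}

#' Discrete Radon transform
#'
#' @param img square image matrix.
#' @param n_angles number of projection angles, uniformly spaced over
#'   `[0, pi)`.
#' @return matrix `n x n_angles` of line integrals (detector bins in rows).
#' @export
radon_transform <- function(img, n_angles = 120L) {
  n <- nrow(img)
  stopifnot(ncol(img) == n, n_angles >= 2L)
  g <- radon_geom(n)
  v <- as.numeric(img)   # column-major: g$y runs over rows, g$x over columns
  angles <- (seq_len(n_angles) - 1L) * pi / n_angles
  sino <- matrix(0, n, n_angles)
  for (a in seq_len(n_angles)) {
    t_ <- g$x * cos(angles[a]) + g$y * sin(angles[a])
    u <- t_ * n + (n + 1) / 2
    k0 <- floor(u)
    fr <- u - k0
    bins <- c(k0, k0 + 1)
    wts <- c(v * (1 - fr), v * fr)
    keep <- bins >= 1 & bins <= n
    acc <- rowsum(wts[keep], bins[keep])
    sino[as.integer(rownames(acc)), a] <- acc
  }
  sino / n
}

#' Filtered back-projection
#'
#' Ram-Lak-filtered back-projection matching the geometry of
#' [radon_transform()].
#'
#' @param sino sinogram (`n x n_angles`).
#' @return reconstructed `n x n` image (not clipped).
#' @export
fbp_reconstruct <- function(sino) {
  n <- nrow(sino)
  n_angles <- ncol(sino)
  g <- radon_geom(n)
  m <- 2L^ceiling(log2(2L * n))
  # frequencies in cycles per unit t (detector spacing 1/n)
  fk <- c(0:(m %/% 2L), (m %/% 2L - 1L):1L) / m * n
  angles <- (seq_len(n_angles) - 1L) * pi / n_angles
  recon <- numeric(n * n)
  for (a in seq_len(n_angles)) {
    p <- c(sino[, a], numeric(m - n))
    q <- Re(fft(fft(p) * fk, inverse = TRUE)) / m
    t_ <- g$x * cos(angles[a]) + g$y * sin(angles[a])
    u <- t_ * n + (n + 1) / 2
    k0 <- floor(u)
    fr <- u - k0
    q0 <- ifelse(k0 >= 1 & k0 <= n, q[pmin(pmax(k0, 1L), n)], 0)
    q1 <- ifelse(k0 + 1 >= 1 & k0 + 1 <= n, q[pmin(pmax(k0 + 1L, 1L), n)], 0)
    recon <- recon + q0 * (1 - fr) + q1 * fr
  }
  matrix(recon, n, n) * pi / n_angles
}
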