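# Quantitative image-quality evaluation: RMSE, PSNR and SSIM on the
# normalized [0, 1] intensity scale, plus CT display windowing for figure
# rendering. Windowing is display-only and is never used inside metrics or
# losses.

#' Root mean square error
#'
#' @param I,K images of identical shape.
#' @return `sqrt(mean((I - K)^2))`.
#' @export
rmse <- function(I, K) {
  if (!identical(dim(I), dim(K)))
    stop("rmse: images have different shapes", call. = FALSE)
  sqrt(mean((I - K)^2))
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(max_i^2 / MSE)`. Identical images yield `Inf` with a warning.
#'
#' @param I,K images of identical shape.
#' @param max_i maximum intensity of the scale (1 for normalized images).
#' @return PSNR in dB.
#' @export
psnr <- function(I, K, max_i = 1) {
  if (max_i <= 0) stop("max_i must be > 0", call. = FALSE)
  mse <- mean((I - K)^2)
  if (mse == 0) {
    warning("identical images: PSNR is infinite")
    return(Inf)
  }
  10 * log10(max_i^2 / mse)
}

gaussian_kernel1d <- function(size = 11L, sigma = 1.5) {
  r <- (seq_len(size) - (size + 1) / 2)
  g <- exp(-r^2 / (2 * sigma^2))
  g / sum(g)
}

# "valid" separable 2-D filtering via banded matrices
filter2_valid <- function(img, g) {
  n <- length(g)
  H <- nrow(img); W <- ncol(img)
  Rm <- matrix(0, H - n + 1L, H)
  for (i in seq_len(H - n + 1L)) Rm[i, i:(i + n - 1L)] <- g
  Cm <- matrix(0, W - n + 1L, W)
  for (j in seq_len(W - n + 1L)) Cm[j, j:(j + n - 1L)] <- g
  Rm %*% img %*% t(Cm)
}

#' Structural similarity index
#'
#' Two-factor SSIM with `c1 = (k1 L)^2`, `c2 = (k2 L)^2` and the constants
#' `k1 = 0.01`, `k2 = 0.02`. By default statistics are computed in 11x11
#' Gaussian-weighted sliding windows (sigma 1.5, valid region) and averaged;
#' `method = "global"` evaluates the plain formula once on whole-image
#' statistics (population variance/covariance).
#'
#' @param x,y images of identical shape.
#' @param k1,k2 stabilization constants.
#' @param L intensity range of the data.
#' @param method `"window"` (default) or `"global"`.
#' @param window_size,sigma Gaussian window parameters.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, k1 = 0.01, k2 = 0.02, L = 1,
                 method = c("window", "global"),
                 window_size = 11L, sigma = 1.5) {
  method <- match.arg(method)
  if (!identical(dim(x), dim(y)))
    stop("ssim: images have different shapes", call. = FALSE)
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  if (method == "window" &&
      (nrow(x) < window_size || ncol(x) < window_size)) {
    warning("image smaller than the SSIM window: falling back to global statistics")
    method <- "global"
  }
  if (method == "global") {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  g <- gaussian_kernel1d(window_size, sigma)
  mx <- filter2_valid(x, g); my <- filter2_valid(y, g)
  mxx <- filter2_valid(x * x, g); myy <- filter2_valid(y * y, g)
  mxy <- filter2_valid(x * y, g)
  vx <- mxx - mx^2; vy <- myy - my^2; cxy <- mxy - mx * my
  smap <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(smap)
}

#' Display window specification
#'
#' @param lo,hi window bounds on the `[0, 1]` intensity scale (`lo < hi`).
#'   The tissue window is 0.2-0.28; the lung window is 0-0.33.
#' @return list of class `ldct_window_spec`.
#' @export
window_spec <- function(lo = 0.2, hi = 0.28) {
  if (lo >= hi) stop("window requires lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "ldct_window_spec")
}

#' Apply a display window
#'
#' Linearly rescales `[lo, hi]` to `[0, 1]`, clipping outside. For display
#' and report rendering only.
#'
#' @param img image in `[0, 1]`.
#' @param w a [window_spec()].
#' @return windowed image in `[0, 1]`.
#' @export
apply_window <- function(img, w = window_spec()) {
  pmin(pmax((img - w$lo) / (w$hi - w$lo), 0), 1)
}

#' Evaluate predictions against ground truth
#'
#' Per-image and mean RMSE / PSNR / SSIM over aligned lists (for instance a
#' dataset's paired evaluation split).
#'
#' @param pred,truth lists of images of equal length and matching shapes.
#' @param max_i PSNR intensity maximum.
#' @param csv optional path: write the per-image table plus a footer row of
#'   means.
#' @param ... passed to [ssim()].
#' @return list of class `ldct_metric_report`: `per_image` data frame and
#'   `rmse`, `psnr`, `ssim`, `n_images` aggregates (means of per-image
#'   values; infinite per-image PSNRs are dropped from the mean with a
#'   warning).
#' @export
evaluate <- function(pred, truth, max_i = 1, csv = NULL, ...) {
  if (length(pred) != length(truth))
    stop(sprintf("length mismatch: %d predictions vs %d truths",
                 length(pred), length(truth)), call. = FALSE)
  per <- data.frame(
    image_id = seq_along(pred),
    rmse = vapply(seq_along(pred), function(i) rmse(pred[[i]], truth[[i]]), 0),
    psnr = vapply(seq_along(pred), function(i)
      suppressWarnings(psnr(pred[[i]], truth[[i]], max_i)), 0),
    ssim = vapply(seq_along(pred), function(i) ssim(pred[[i]], truth[[i]], ...), 0))
  pv <- per$psnr
  if (any(!is.finite(pv))) {
    warning("infinite per-image PSNR excluded from the mean")
    pv <- pv[is.finite(pv)]
  }
  rep_ <- structure(list(per_image = per,
                         rmse = mean(per$rmse),
                         psnr = if (length(pv)) mean(pv) else Inf,
                         ssim = mean(per$ssim),
                         n_images = length(pred)),
                    class = "ldct_metric_report")
  if (!is.null(csv)) {
    tab <- rbind(per, data.frame(image_id = NA, rmse = rep_$rmse,
                                 psnr = rep_$psnr, ssim = rep_$ssim))
    write.csv(tab, csv, row.names = FALSE)
  }
  rep_
}

#' @export
print.ldct_metric_report <- function(x, ...) {
  cat(sprintf("<ldct_metric_report> n=%d  RMSE %.4f  PSNR %.2f dB  SSIM %.4f\n",
              x$n_images, x$rmse, x$psnr, x$ssim))
  invisible(x)
}
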