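# The training objective: adversarial terms for both mappings, the
# cycle-consistency L1 term weighted by lambda, and a two-stage perceptual
# term, combined as
#   Loss = L_GAN(G, D_Y) + L_GAN(F, D_X) + lambda * L_cyc(G, F) + L_perc.
# Expectations are implemented as per-pixel (per-feature) means so values
# are stable across patch sizes.

LOG_EPS <- 1e-8

#' Loss configuration
#'
#' @param lambda_cyc cycle-consistency weight lambda (full-scale value 10).
#' @param adversarial_form `"log_bce"` for the literal log form of the
#'   minimax objective, or `"least_squares"` for the LSGAN variant (a
#'   stability option that deviates from the log form; flagged in logs).
#' @param perceptual_layers pooling stages of the extractor to compare
#'   (defaults: the second pooling stage, 128 channels at full width, and
#'   the last pooling stage, 512 channels).
#' @param perceptual_weights per-stage scalar weights.
#' @param adv_weight scalar applied to the generators' adversarial term
#'   during optimization (1 = the plain objective). Small-scale profiles
#'   lower it to keep the adversarial pull commensurate with the per-pixel
#'   cycle gradient; the logged loss decomposition is unaffected.
#' @return list of class `ldct_loss_config`.
#' @export
loss_config <- function(lambda_cyc = 10,
                        adversarial_form = c("log_bce", "least_squares"),
                        perceptual_layers = c("pool2", "pool5"),
                        perceptual_weights = c(1, 1),
                        adv_weight = 1) {
  adversarial_form <- match.arg(adversarial_form)
  if (lambda_cyc < 0) stop("lambda_cyc must be >= 0", call. = FALSE)
  if (length(perceptual_weights) != length(perceptual_layers))
    stop("perceptual_weights must match perceptual_layers", call. = FALSE)
  if (adv_weight < 0) stop("adv_weight must be >= 0", call. = FALSE)
  structure(list(lambda_cyc = lambda_cyc,
                 adversarial_form = adversarial_form,
                 perceptual_layers = perceptual_layers,
                 perceptual_weights = perceptual_weights,
                 adv_weight = adv_weight),
            class = "ldct_loss_config")
}

check_scores <- function(s, what) {
  if (any(!is.finite(s)) || any(s < 0 | s > 1))
    stop(sprintf("%s outside [0, 1]: discriminator contract violated", what),
         call. = FALSE)
  pmin(pmax(s, LOG_EPS), 1 - LOG_EPS)
}

#' Adversarial (minimax) objective value
#'
#' `E[log D(real)] + E[log(1 - D(fake))]`, averaged over the supplied
#' scores. The discriminator ascends this quantity; each generator descends
#' its own term.
#'
#' @param d_real,d_fake discriminator scores in (0, 1) (scalars or vectors;
#'   clamped at 1e-8 for stability).
#' @return scalar objective value (<= 0, maximum 0).
#' @export
adversarial_loss <- function(d_real, d_fake) {
  d_real <- check_scores(d_real, "d_real")
  d_fake <- check_scores(d_fake, "d_fake")
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' Cycle-consistency loss
#'
#' Mean absolute difference between each image and its reconstruction
#' through the opposite generator, summed over the two cycle directions.
#'
#' @param x,x_rec low-dose image and its reconstruction `F(G(x))`.
#' @param y,y_rec normal-dose image and its reconstruction `G(F(y))`.
#' @return non-negative scalar.
#' @export
cycle_loss <- function(x, x_rec, y, y_rec) {
  if (!identical(dim(as_hwc(x)), dim(as_hwc(x_rec))) ||
      !identical(dim(as_hwc(y)), dim(as_hwc(y_rec))))
    stop("cycle_loss: shape mismatch between image and reconstruction",
         call. = FALSE)
  mean(abs(x - x_rec)) + mean(abs(y - y_rec))
}

#' Perceptual loss
#'
#' Mean absolute difference of frozen deep features between each image and
#' its cycle reconstruction, summed over the configured extractor stages and
#' both cycle directions, weighted per stage.
#'
#' @param x,x_rec,y,y_rec images as in [cycle_loss()].
#' @param phi a [perceptual_extractor()].
#' @param cfg a [loss_config()].
#' @return non-negative scalar.
#' @export
perceptual_loss <- function(x, x_rec, y, y_rec, phi, cfg = loss_config()) {
  taps <- cfg$perceptual_layers
  fx <- perceptual_forward(phi, x, taps)$feats
  fxr <- perceptual_forward(phi, x_rec, taps)$feats
  fy <- perceptual_forward(phi, y, taps)$feats
  fyr <- perceptual_forward(phi, y_rec, taps)$feats
  total <- 0
  for (i in seq_along(taps)) {
    s <- taps[i]; w <- cfg$perceptual_weights[i]
    total <- total + w * (mean(abs(fx[[s]] - fxr[[s]])) +
                          mean(abs(fy[[s]] - fyr[[s]])))
  }
  total
}

#' Combine loss terms into a bundle
#'
#' @param l_gan_g,l_gan_f adversarial objective values for the two mappings.
#' @param l_cyc cycle-consistency value.
#' @param l_perc perceptual value.
#' @param cfg a [loss_config()] supplying lambda.
#' @return list of class `ldct_loss_bundle` with the four terms and
#'   `total = l_gan_g + l_gan_f + lambda * l_cyc + l_perc`.
#' @export
total_loss <- function(l_gan_g, l_gan_f, l_cyc, l_perc, cfg = loss_config()) {
  structure(list(l_gan_g = l_gan_g, l_gan_f = l_gan_f,
                 l_cyc = l_cyc, l_perc = l_perc,
                 lambda_cyc = cfg$lambda_cyc,
                 total = l_gan_g + l_gan_f + cfg$lambda_cyc * l_cyc + l_perc),
            class = "ldct_loss_bundle")
}

#' @export
print.ldct_loss_bundle <- function(x, ...) {
  cat(sprintf("<ldct_loss_bundle> gan_g=%.4f gan_f=%.4f cyc=%.4f perc=%.4f total=%.4f\n",
              x$l_gan_g, x$l_gan_f, x$l_cyc, x$l_perc, x$total))
  invisible(x)
}

## --- internal optimization-side losses and gradients -----------------------

# Discriminator loss (to MINIMIZE) and gradient w.r.t. the score maps
# (sigmoid probabilities for the log form, raw scores for least squares).
disc_loss_grad <- function(s_real, s_fake, form) {
  n_r <- length(s_real); n_f <- length(s_fake)
  if (form == "log_bce") {
    cr <- pmin(pmax(s_real, LOG_EPS), 1 - LOG_EPS)
    cf <- pmin(pmax(s_fake, LOG_EPS), 1 - LOG_EPS)
    loss <- -(mean(log(cr)) + mean(log(1 - cf)))
    d_real <- -1 / (cr * n_r)
    d_fake <- 1 / ((1 - cf) * n_f)
  } else {
    loss <- mean((s_real - 1)^2) + mean(s_fake^2)
    d_real <- 2 * (s_real - 1) / n_r
    d_fake <- 2 * s_fake / n_f
  }
  list(loss = loss, d_real = d_real, d_fake = d_fake)
}

# Generator-side adversarial loss (to MINIMIZE) and gradient w.r.t. the fake
# score map. For the log form the non-saturating -log D(fake) direction is
# used (same fixed points as the minimax term, usable gradients early on).
gen_adv_loss_grad <- function(s_fake, form) {
  n <- length(s_fake)
  if (form == "log_bce") {
    cf <- pmin(pmax(s_fake, LOG_EPS), 1 - LOG_EPS)
    list(loss = -mean(log(cf)), d_fake = -1 / (cf * n))
  } else {
    list(loss = mean((s_fake - 1)^2), d_fake = 2 * (s_fake - 1) / n)
  }
}

# d/d(rec) of mean(|rec - ref|)
l1_grad <- function(rec, ref) sign(rec - ref) / length(rec)
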