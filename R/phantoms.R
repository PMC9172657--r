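# Synthetic CT phantoms and physically motivated low-dose degradation.
# Phantoms are ellipse composites (Shepp-Logan-like) with optional
# low-intensity "lung" cavities; low dose is simulated in the sinogram
# domain: forward projection, Poisson photon statistics at the configured
# incident count plus Gaussian electronic noise, log conversion, and
# filtered back-projection. An image-domain Gaussian mode is kept as a fast
# fallback for quick tests.

#' Phantom specification
#'
#' @param image_size pixels per side (paper-scale slices are 512).
#' @param n_ellipses number of soft-tissue ellipses (0 gives a uniform
#'   background image).
#' @param intensity_range range the tissue attenuation values are drawn
#'   from, on the normalized `[0, 1]` scale.
#' @param include_lung_regions add two low-intensity cavities.
#' @param seed RNG seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return list of class `ldct_phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512L, n_ellipses = 6L,
                         intensity_range = c(0.3, 0.8),
                         include_lung_regions = TRUE, seed = 1L) {
  if (image_size < 2L) stop("image_size must be >= 2", call. = FALSE)
  if (n_ellipses < 0L) stop("n_ellipses must be >= 0", call. = FALSE)
  if (length(intensity_range) != 2L || any(intensity_range < 0) ||
      any(intensity_range > 1) || intensity_range[1] > intensity_range[2])
    stop("intensity_range must be an increasing pair inside [0, 1]",
         call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 n_ellipses = as.integer(n_ellipses),
                 intensity_range = intensity_range,
                 include_lung_regions = include_lung_regions,
                 seed = as.integer(seed)),
            class = "ldct_phantom_spec")
}

ellipse_mask <- function(xg, yg, cx, cy, a, b, phi) {
  dx <- xg - cx; dy <- yg - cy
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate a clean phantom slice
#'
#' Deterministic piecewise-smooth "normal-dose" image in `[0, 1]`: an oval
#' body on a dark background, painted tissue ellipses and (optionally) two
#' lung-like cavities, all inside the inscribed circle.
#'
#' @param spec a [phantom_spec()].
#' @return `image_size x image_size` matrix in `[0, 1]`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  n <- spec$image_size
  cc <- ((seq_len(n)) - (n + 1) / 2) / n
  yg <- matrix(cc, n, n)          # rows
  xg <- matrix(cc, n, n, byrow = TRUE)  # columns
  img <- matrix(0.02, n, n)
  if (spec$n_ellipses == 0L && !spec$include_lung_regions) return(img)
  with_seed(spec$seed, {
    body_phi <- runif(1, -0.15, 0.15)
    img[ellipse_mask(xg, yg, 0, 0, 0.44, 0.38, body_phi)] <- 0.35
    for (k in seq_len(spec$n_ellipses)) {
      cx <- runif(1, -0.22, 0.22); cy <- runif(1, -0.18, 0.18)
      a <- runif(1, 0.03, 0.14); b <- runif(1, 0.03, 0.14)
      phi <- runif(1, 0, pi)
      val <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
      m <- ellipse_mask(xg, yg, cx, cy, a, b, phi) &
        ellipse_mask(xg, yg, 0, 0, 0.44, 0.38, body_phi)
      img[m] <- val
    }
    if (spec$include_lung_regions) {
      for (sgn in c(-1, 1)) {
        m <- ellipse_mask(xg, yg, sgn * 0.17, runif(1, -0.05, 0.05),
                          0.11, 0.17, sgn * runif(1, 0, 0.2))
        img[m] <- 0.05
      }
    }
  })
  pmin(pmax(img, 0), 1)
}

#' Dose model for the low-dose simulator
#'
#' The default incident count (600 photons per detector bin) produces
#' clearly visible streak/quantum noise at desk scale; the companion
#' normal-dose regime uses 160/30 times this count (3200), mirroring the
#' tube-current ratio between a 30 mA low-dose and a 160 mA normal-dose
#' acquisition.
#'
#' @param photons_i0 incident photon count per detector bin (dose proxy;
#'   larger means higher dose).
#' @param n_angles projection angles for the forward model.
#' @param electronic_noise_sd additive Gaussian noise sd, in counts, in the
#'   sinogram domain.
#' @param attenuation_scale factor converting normalized line integrals to
#'   attenuation exponents.
#' @param noise_model `"sinogram"` for the physical Poisson+FBP pipeline;
#'   `"gaussian"` for fast image-domain white noise with sd
#'   `8 / sqrt(photons_i0)`.
#' @return list of class `ldct_dose_model`.
#' @export
dose_model <- function(photons_i0 = 600, n_angles = 120L,
                       electronic_noise_sd = 2,
                       attenuation_scale = 4,
                       noise_model = c("sinogram", "gaussian")) {
  noise_model <- match.arg(noise_model)
  if (photons_i0 <= 0) stop("photons_i0 must be > 0", call. = FALSE)
  if (n_angles < 2L) stop("n_angles must be >= 2", call. = FALSE)
  if (electronic_noise_sd < 0) stop("electronic_noise_sd must be >= 0", call. = FALSE)
  structure(list(photons_i0 = photons_i0, n_angles = as.integer(n_angles),
                 electronic_noise_sd = electronic_noise_sd,
                 attenuation_scale = attenuation_scale,
                 noise_model = noise_model),
            class = "ldct_dose_model")
}

#' Simulate a low-dose acquisition of a clean slice
#'
#' Forward-projects the clean image, corrupts the sinogram with Poisson
#' counts at `photons_i0` plus Gaussian electronic noise, log-converts, and
#' reconstructs by filtered back-projection; the result is clipped to
#' `[0, 1]`. Deterministic given the seed. Poisson draws switch to the
#' normal approximation above 1e7 expected counts.
#'
#' @param clean image matrix in `[0, 1]`.
#' @param dose a [dose_model()].
#' @param seed RNG seed for the noise draws.
#' @return degraded image, same size as `clean`, in `[0, 1]`.
#' @export
simulate_low_dose <- function(clean, dose = dose_model(), seed = 1L) {
  if (any(clean < 0 | clean > 1)) stop("clean image must lie in [0, 1]", call. = FALSE)
  if (dose$noise_model == "gaussian") {
    return(with_seed(seed, {
      noisy <- clean + rnorm(length(clean), 0, 8 / sqrt(dose$photons_i0))
      matrix(pmin(pmax(noisy, 0), 1), nrow(clean), ncol(clean))
    }))
  }
  sino <- radon_transform(clean, dose$n_angles)
  lambda <- dose$photons_i0 * exp(-dose$attenuation_scale * sino)
  counts <- with_seed(seed, {
    big <- lambda > 1e7
    out <- numeric(length(lambda))
    if (any(!big)) out[!big] <- rpois(sum(!big), lambda[!big])
    if (any(big)) out[big] <- lambda[big] + sqrt(lambda[big]) * rnorm(sum(big))
    if (dose$electronic_noise_sd > 0)
      out <- out + rnorm(length(out), 0, dose$electronic_noise_sd)
    out
  })
  counts <- pmax(counts, 0.5)
  p_hat <- -log(counts / dose$photons_i0) / dose$attenuation_scale
  dim(p_hat) <- dim(sino)
  recon <- fbp_reconstruct(p_hat)
  pmin(pmax(recon, 0), 1)
}

#' Extract sliding patches from an image
#'
#' All axis-aligned `patch_size` squares at offsets `0, stride, 2 stride,
#' ...` that fit inside the image, in row-major order.
#'
#' @param image matrix.
#' @param patch_size patch side in pixels.
#' @param stride offset step in pixels.
#' @return list of `patch_size x patch_size` matrices of length
#'   `(floor((H - p) / s) + 1) * (floor((W - p) / s) + 1)`.
#' @export
extract_patches <- function(image, patch_size = 256L, stride = 16L) {
  H <- nrow(image); W <- ncol(image)
  if (patch_size > H || patch_size > W)
    stop(sprintf("patch size %d exceeds image size %dx%d", patch_size, H, W),
         call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  ri <- seq(0L, H - patch_size, by = stride)
  ci <- seq(0L, W - patch_size, by = stride)
  out <- vector("list", length(ri) * length(ci))
  k <- 0L
  for (r in ri) for (cl in ci) {
    k <- k + 1L
    out[[k]] <- image[(r + 1L):(r + patch_size), (cl + 1L):(cl + patch_size)]
    attr(out[[k]], "offset") <- c(row = r, col = cl)
  }
  out
}

#' Build an unpaired two-domain patch dataset
#'
#' Domain X holds low-dose simulations of one phantom cohort; domain Y
#' holds normal-dose acquisitions (high-photon-count reconstructions, or
#' the clean phantoms themselves if `dose_y = NULL`) of a disjoint cohort;
#' both are independently shuffled. A held-out evaluation split (extra
#' slices from the X cohort) keeps noisy patches paired with their clean
#' counterparts -- the noiseless reconstruction for the sinogram noise
#' model, the phantom itself for the Gaussian model -- for metric
#' computation only; training never reads it.
#'
#' @param n_subjects_x,n_subjects_y phantom subjects per domain (>= 1).
#' @param slices_per_subject training slices per subject.
#' @param image_size slice side in pixels.
#' @param dose a [dose_model()] for the X (low-dose) domain.
#' @param dose_y dose model for the Y (normal-dose) domain; defaults to the
#'   X model with 160/30 times the photon count. `NULL` uses the clean
#'   phantom slices directly.
#' @param patch_size,stride patch extraction protocol.
#' @param n_eval_slices held-out paired slices per X subject (0 disables the
#'   evaluation split).
#' @param phantom template [phantom_spec()]; its seed is ignored (per-slice
#'   seeds are derived from `seed`).
#' @param subjects_x,subjects_y optional explicit subject ids; they must be
#'   disjoint (overlap would leak pairing across domains).
#' @param seed master RNG seed.
#' @return list of class `ldct_patch_dataset` with `domain_x`, `domain_y`,
#'   `patch_size`, `stride`, `eval` (list `x`, `clean`, `paired_index`) and
#'   a `manifest` data frame.
#' @export
build_unpaired_dataset <- function(n_subjects_x = 1L, n_subjects_y = 1L,
                                   slices_per_subject = 1L,
                                   image_size = 64L,
                                   dose = dose_model(),
                                   dose_y = ndct_dose(dose),
                                   patch_size = 32L, stride = 32L,
                                   n_eval_slices = 1L,
                                   phantom = phantom_spec(image_size = image_size),
                                   subjects_x = NULL, subjects_y = NULL,
                                   seed = 1L) {
  stopifnot(n_subjects_x >= 1L, n_subjects_y >= 1L, slices_per_subject >= 1L)
  if (is.null(subjects_x)) subjects_x <- seq_len(n_subjects_x)
  if (is.null(subjects_y)) subjects_y <- n_subjects_x + seq_len(n_subjects_y)
  if (length(intersect(subjects_x, subjects_y)) > 0L)
    stop("subjects_x and subjects_y overlap: cohorts must be disjoint (pairing leak)",
         call. = FALSE)
  slice_spec <- function(subject, slice) {
    sp <- phantom
    sp$image_size <- as.integer(image_size)
    sp$seed <- subseed(seed, subject * 100003L + slice)
    sp
  }
  manifest <- list()
  domain_x <- list()
  for (s in subjects_x) for (t in seq_len(slices_per_subject)) {
    clean <- make_phantom(slice_spec(s, t))
    noisy <- simulate_low_dose(clean, dose, seed = slice_spec(s, t)$seed + 1L)
    ps <- extract_patches(noisy, patch_size, stride)
    domain_x <- c(domain_x, ps)
    manifest[[length(manifest) + 1L]] <-
      data.frame(domain = "X", subject = s, slice = t, n_patches = length(ps))
  }
  domain_y <- list()
  for (s in subjects_y) for (t in seq_len(slices_per_subject)) {
    clean <- make_phantom(slice_spec(s, t))
    ndct <- if (is.null(dose_y)) clean
            else simulate_low_dose(clean, dose_y, seed = slice_spec(s, t)$seed + 2L)
    ps <- extract_patches(ndct, patch_size, stride)
    domain_y <- c(domain_y, ps)
    manifest[[length(manifest) + 1L]] <-
      data.frame(domain = "Y", subject = s, slice = t, n_patches = length(ps))
  }
  eval_split <- NULL
  if (n_eval_slices > 0L) {
    ex <- list(); ec <- list()
    for (s in subjects_x) for (t in slices_per_subject + seq_len(n_eval_slices)) {
      clean <- make_phantom(slice_spec(s, t))
      noisy <- simulate_low_dose(clean, dose, seed = slice_spec(s, t)$seed + 1L)
      ex <- c(ex, extract_patches(noisy, patch_size, stride))
      ec <- c(ec, extract_patches(clean_reference(clean, dose), patch_size, stride))
    }
    eval_split <- list(x = ex, clean = ec, paired_index = seq_along(ex))
  }
  with_seed(seed, {
    domain_x <- domain_x[sample.int(length(domain_x))]
    domain_y <- domain_y[sample.int(length(domain_y))]
  })
  structure(list(domain_x = domain_x, domain_y = domain_y,
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 dose = dose, eval = eval_split,
                 manifest = do.call(rbind, manifest), seed = seed),
            class = "ldct_patch_dataset")
}

#' Companion normal-dose model
#'
#' The same acquisition as `dose` with 160/30 times the incident photons.
#'
#' @param dose a [dose_model()].
#' @return a [dose_model()] for the normal-dose regime.
#' @export
ndct_dose <- function(dose = dose_model()) {
  d <- dose
  d$photons_i0 <- dose$photons_i0 * 160 / 30
  d
}

# Paired evaluation reference for a clean phantom slice under a dose model:
# the deterministic noiseless reconstruction for the sinogram pipeline (so
# paired comparisons measure noise, not shared discretization bias), the
# phantom itself for image-domain Gaussian noise.
clean_reference <- function(clean, dose = dose_model()) {
  if (dose$noise_model == "gaussian") return(clean)
  rec <- fbp_reconstruct(radon_transform(clean, dose$n_angles))
  pmin(pmax(rec, 0), 1)
}

#' @export
print.ldct_patch_dataset <- function(x, ...) {
  cat(sprintf("<ldct_patch_dataset> |X|=%d |Y|=%d patch=%d stride=%d eval=%d\n",
              length(x$domain_x), length(x$domain_y), x$patch_size, x$stride,
              if (is.null(x$eval)) 0L else length(x$eval$x)))
  invisible(x)
}

# Training-time sampler over the two unpaired domains: independent epoch
# shuffles of X and Y, deterministic in `seed`. Reads nothing but
# domain_x/domain_y.
dataset_sampler <- function(ds, seed = 1L) {
  nx <- length(ds$domain_x); ny <- length(ds$domain_y)
  if (nx == 0L || ny == 0L) stop("empty domain in dataset", call. = FALSE)
  ix <- integer(0); iy <- integer(0)
  px <- 0L; py <- 0L; ex <- 0L; ey <- 0L
  function() {
    if (px >= length(ix)) {
      ex <<- ex + 1L
      ix <<- with_seed(subseed(seed, ex * 2L), sample.int(nx))
      px <<- 0L
    }
    if (py >= length(iy)) {
      ey <<- ey + 1L
      iy <<- with_seed(subseed(seed, ey * 2L + 1L), sample.int(ny))
      py <<- 0L
    }
    px <<- px + 1L; py <<- py + 1L
    list(x = ds$domain_x[[ix[px]]], y = ds$domain_y[[iy[py]]])
  }
}
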