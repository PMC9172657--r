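# Cycle-consistent training loop for the two generators G (low->normal dose)
# and F (normal->low) and the two PatchGAN discriminators D_X, D_Y. Each
# step updates the discriminators first, then both generators on the
# adversarial + lambda * cycle + perceptual objective. Fully deterministic
# under a fixed seed and resumable from checkpoints.

#' Training configuration
#'
#' The `"paper"` profile carries the full-scale protocol: Adam, initial
#' learning rate 1e-5 decaying linearly between steps 100k and 700k down to
#' 1e-7, batch size 1, one million steps. The `"tiny"` profile is a
#' desk-scale protocol for CPU runs (hundreds of steps, conventional
#' CycleGAN-scale learning rate); every field can be overridden.
#'
#' @param profile `"paper"` or `"tiny"`.
#' @param ... field overrides (`lr_init`, `lr_final`, `decay_start_step`,
#'   `decay_end_step`, `total_steps`, `batch_size`, `beta1`, `beta2`,
#'   `d_lr_mult` (discriminator learning-rate multiplier, a standard
#'   stabilizer for adversarial training), `fake_pool_size` (history pool
#'   of past generated images shown to the discriminators; 0 disables,
#'   which is the full-scale default), `adv_warmup_steps` (the generators'
#'   adversarial term ramps linearly from 0 over this many steps while the
#'   discriminators train; 0 disables), `ema_decay` (exponential moving
#'   average of the generator weights used at inference; 0 disables),
#'   `checkpoint_every`, `seed`).
#' @return list of class `ldct_train_config`.
#' @export
train_config <- function(profile = c("paper", "tiny"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") {
    list(lr_init = 1e-5, lr_final = 1e-7,
         decay_start_step = 1e5, decay_end_step = 7e5, total_steps = 1e6,
         batch_size = 1L, beta1 = 0.9, beta2 = 0.999,
         d_lr_mult = 1, fake_pool_size = 0L, adv_warmup_steps = 0L,
         ema_decay = 0, checkpoint_every = 5e4, seed = 1L)
  } else {
    list(lr_init = 2e-4, lr_final = 2e-5,
         decay_start_step = 360, decay_end_step = 900, total_steps = 900,
         batch_size = 1L, beta1 = 0.9, beta2 = 0.999,
         d_lr_mult = 2, fake_pool_size = 25L, adv_warmup_steps = 0L,
         ema_decay = 0.995, checkpoint_every = 500, seed = 1L)
  }
  cfg <- modifyList(cfg, list(...))
  if (!(cfg$decay_start_step < cfg$decay_end_step &&
        cfg$decay_end_step <= cfg$total_steps))
    stop("need decay_start_step < decay_end_step <= total_steps", call. = FALSE)
  if (cfg$lr_final >= cfg$lr_init)
    stop("need lr_final < lr_init", call. = FALSE)
  cfg$profile <- profile
  structure(cfg, class = "ldct_train_config")
}

#' Piecewise-linear learning-rate schedule
#'
#' Constant at `lr_init` before `decay_start_step`, linear down to
#' `lr_final` at `decay_end_step`, constant thereafter.
#'
#' @param step non-negative step counter (vectorized).
#' @param cfg a [train_config()].
#' @return learning rate(s).
#' @export
lr_schedule <- function(step, cfg = train_config()) {
  frac <- (pmin(pmax(step, cfg$decay_start_step), cfg$decay_end_step) -
             cfg$decay_start_step) /
    (cfg$decay_end_step - cfg$decay_start_step)
  lr <- cfg$lr_init + frac * (cfg$lr_final - cfg$lr_init)
  # exact at and beyond the endpoints
  lr[step <= cfg$decay_start_step] <- cfg$lr_init
  lr[step >= cfg$decay_end_step] <- cfg$lr_final
  lr
}

#' Initialize a training state
#'
#' Builds G, F, D_X, D_Y, the frozen perceptual extractor and fresh Adam
#' moments, all seeded deterministically.
#'
#' @param train_cfg a [train_config()].
#' @param gen_cfg a [generator_config()] shared by G and F.
#' @param disc_cfg a [discriminator_config()] shared by D_X and D_Y.
#' @param loss_cfg a [loss_config()].
#' @param phi_width_scale width multiplier for the perceptual extractor.
#' @return list of class `ldct_train_state`.
#' @export
train_state_init <- function(train_cfg = train_config("tiny"),
                             gen_cfg = generator_config(),
                             disc_cfg = discriminator_config(),
                             loss_cfg = loss_config(),
                             phi_width_scale = 1 / 8) {
  seed <- train_cfg$seed
  G <- generator_init(gen_cfg, seed = subseed(seed, 1L))
  F_ <- generator_init(gen_cfg, seed = subseed(seed, 2L))
  Dx <- discriminator_init(disc_cfg, seed = subseed(seed, 3L))
  Dy <- discriminator_init(disc_cfg, seed = subseed(seed, 4L))
  phi <- perceptual_extractor(width_scale = phi_width_scale,
                              seed = subseed(seed, 5L))
  structure(list(step = 0L, G = G, F = F_, Dx = Dx, Dy = Dy, phi = phi,
                 adam = list(G = adam_init(G$params), F = adam_init(F_$params),
                             Dx = adam_init(Dx$params), Dy = adam_init(Dy$params)),
                 pool_x = list(), pool_y = list(),
                 G_ema = if (!is.null(train_cfg$ema_decay) &&
                             train_cfg$ema_decay > 0) G$params,
                 train_cfg = train_cfg, loss_cfg = loss_cfg,
                 lr = lr_schedule(0, train_cfg)),
            class = "ldct_train_state")
}

#' @export
print.ldct_train_state <- function(x, ...) {
  cat(sprintf("<ldct_train_state> step=%d lr=%.3g ablation=%s channels=%d\n",
              x$step, x$lr, x$G$config$ablation, x$G$config$channels))
  invisible(x)
}

# gradient of the perceptual term w.r.t. a reconstruction (ref fixed)
perc_grad <- function(phi, ref, rec, cfg) {
  taps <- cfg$perceptual_layers
  fref <- perceptual_forward(phi, ref, taps)$feats
  frec <- perceptual_forward(phi, rec, taps, want_cache = TRUE)
  loss <- 0
  dfeats <- list()
  for (i in seq_along(taps)) {
    s <- taps[i]; w <- cfg$perceptual_weights[i]
    diff <- frec$feats[[s]] - fref[[s]]
    loss <- loss + w * mean(abs(diff))
    dfeats[[s]] <- w * sign(diff) / length(diff)
  }
  drec <- perceptual_backward(phi, dfeats, frec$cache)
  list(loss = loss, drec = drec)
}

disc_update <- function(disc, astate, real, fake, form, lr, b1, b2) {
  fr <- discriminator_forward(disc, real)
  ff <- discriminator_forward(disc, fake)
  raw <- form == "least_squares"   # LSGAN regresses the raw score surface
  dl <- disc_loss_grad(if (raw) fr$logits else fr$out,
                       if (raw) ff$logits else ff$out, form)
  gr <- discriminator_backward(disc, dl$d_real, fr$cache, from_logits = raw)$grads
  gf <- discriminator_backward(disc, dl$d_fake, ff$cache, from_logits = raw)$grads
  g <- nested_map(`+`, gr, gf)
  up <- adam_update(disc$params, g, astate, lr, b1, b2)
  disc$params <- up$params
  list(disc = disc, astate = up$state, loss = dl$loss)
}

# History pool of generated images: with probability 1/2 the discriminator
# sees a stored past fake instead of the current one (swap-in), damping
# oscillation from chasing the newest generator output. Deterministic: the
# draws run on a step-derived RNG stream.
pool_swap <- function(pool, img, maxn, seed) {
  if (maxn <= 0L) return(list(img = img, pool = pool))
  if (length(pool) < maxn) {
    pool[[length(pool) + 1L]] <- img
    return(list(img = img, pool = pool))
  }
  with_seed(seed, {
    if (runif(1) < 0.5) {
      i <- sample.int(maxn, 1L)
      out <- pool[[i]]
      pool[[i]] <- img
      list(img = out, pool = pool)
    } else list(img = img, pool = pool)
  })
}

# adversarial gradient w.r.t. a generated image, through a (frozen) critic
adv_input_grad <- function(disc, fake, form) {
  ff <- discriminator_forward(disc, fake)
  raw <- form == "least_squares"
  gl <- gen_adv_loss_grad(if (raw) ff$logits else ff$out, form)
  dx <- discriminator_backward(disc, gl$d_fake, ff$cache, from_logits = raw)$dx
  list(loss = gl$loss, dx = dx)
}

#' One training step
#'
#' Runs both cycles on one unpaired image pair, updates the discriminators
#' and then both generators, advances the step counter and the learning
#' rate.
#'
#' @param state an `ldct_train_state`.
#' @param x low-dose patch (matrix).
#' @param y normal-dose patch (matrix), unpaired with `x`.
#' @return list `state` (updated) and `bundle` (the [total_loss()]
#'   decomposition logged for the step).
#' @export
train_step <- function(state, x, y) {
  cfgl <- state$loss_cfg
  form <- cfgl$adversarial_form
  lam <- cfgl$lambda_cyc
  b1 <- state$train_cfg$beta1; b2 <- state$train_cfg$beta2
  lr <- lr_schedule(state$step, state$train_cfg)
  x <- as_hwc(x); y <- as_hwc(y)

  ## forward: both cycles (caches kept for the generator update)
  fG1 <- generator_forward(state$G, x);  y_fake <- fG1$out
  fF1 <- generator_forward(state$F, y_fake); x_rec <- fF1$out
  fF2 <- generator_forward(state$F, y);  x_fake <- fF2$out
  fG2 <- generator_forward(state$G, x_fake); y_rec <- fG2$out

  ## discriminators first (on pooled fakes when the history pool is on)
  d_mult <- if (is.null(state$train_cfg$d_lr_mult)) 1 else state$train_cfg$d_lr_mult
  pool_n <- if (is.null(state$train_cfg$fake_pool_size)) 0L
            else state$train_cfg$fake_pool_size
  py_ <- pool_swap(state$pool_y, y_fake, pool_n,
                   subseed(state$train_cfg$seed, 3L + 2L * state$step))
  state$pool_y <- py_$pool
  px_ <- pool_swap(state$pool_x, x_fake, pool_n,
                   subseed(state$train_cfg$seed, 4L + 2L * state$step))
  state$pool_x <- px_$pool
  uy <- disc_update(state$Dy, state$adam$Dy, y, py_$img, form, lr * d_mult, b1, b2)
  state$Dy <- uy$disc; state$adam$Dy <- uy$astate
  ux <- disc_update(state$Dx, state$adam$Dx, x, px_$img, form, lr * d_mult, b1, b2)
  state$Dx <- ux$disc; state$adam$Dx <- ux$astate

  ## generator objective pieces
  aw <- if (is.null(cfgl$adv_weight)) 1 else cfgl$adv_weight
  warm <- state$train_cfg$adv_warmup_steps
  if (!is.null(warm) && warm > 0L) aw <- aw * min(1, state$step / warm)
  advG <- adv_input_grad(state$Dy, y_fake, form)
  advF <- adv_input_grad(state$Dx, x_fake, form)
  advG$dx <- aw * advG$dx
  advF$dx <- aw * advF$dx
  l_cyc <- mean(abs(x_rec - x)) + mean(abs(y_rec - y))
  px <- perc_grad(state$phi, x, x_rec, cfgl)
  py <- perc_grad(state$phi, y, y_rec, cfgl)
  l_perc <- px$loss + py$loss

  ## backward, x -> G -> F cycle
  d_x_rec <- lam * l1_grad(x_rec, x) + px$drec
  bF1 <- generator_backward(state$F, d_x_rec, fF1$cache)
  d_y_fake <- advG$dx + bF1$dx
  bG1 <- generator_backward(state$G, d_y_fake, fG1$cache)

  ## backward, y -> F -> G cycle
  d_y_rec <- lam * l1_grad(y_rec, y) + py$drec
  bG2 <- generator_backward(state$G, d_y_rec, fG2$cache)
  d_x_fake <- advF$dx + bG2$dx
  bF2 <- generator_backward(state$F, d_x_fake, fF2$cache)

  gG <- nested_map(`+`, bG1$grads, bG2$grads)
  gF <- nested_map(`+`, bF1$grads, bF2$grads)
  upG <- adam_update(state$G$params, gG, state$adam$G, lr, b1, b2)
  state$G$params <- upG$params; state$adam$G <- upG$state
  upF <- adam_update(state$F$params, gF, state$adam$F, lr, b1, b2)
  state$F$params <- upF$params; state$adam$F <- upF$state
  ed <- state$train_cfg$ema_decay
  if (!is.null(ed) && ed > 0) {
    state$G_ema <- nested_map(function(e, p) ed * e + (1 - ed) * p,
                              state$G_ema, state$G$params)
  }

  ## logged decomposition: the literal minimax objective values
  l_gan_g <- adversarial_loss(discriminator_forward(state$Dy, y, FALSE)$out,
                              discriminator_forward(state$Dy, y_fake, FALSE)$out)
  l_gan_f <- adversarial_loss(discriminator_forward(state$Dx, x, FALSE)$out,
                              discriminator_forward(state$Dx, x_fake, FALSE)$out)
  bundle <- total_loss(l_gan_g, l_gan_f, l_cyc, l_perc, cfgl)
  if (!all(vapply(bundle[c("l_gan_g", "l_gan_f", "l_cyc", "l_perc", "total")],
                  is.finite, TRUE))) {
    dump <- tempfile("ldct_nan_step_", fileext = ".rds")
    saveRDS(list(step = state$step, x = x, y = y, y_fake = y_fake,
                 x_rec = x_rec, x_fake = x_fake, y_rec = y_rec,
                 bundle = unclass(bundle)), dump)
    stop(sprintf("non-finite loss at step %d; tensors dumped to %s",
                 state$step, dump), call. = FALSE)
  }
  state$step <- state$step + 1L
  state$lr <- lr_schedule(state$step, state$train_cfg)
  list(state = state, bundle = bundle)
}

#' Save / load a training checkpoint
#'
#' The checkpoint stores the step counter, all network parameters, Adam
#' moments and configurations; loading reconstructs a state that continues
#' training exactly as the uninterrupted run would.
#'
#' @param state an `ldct_train_state`.
#' @param path file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the state.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "ldct_train_state"))
  state
}

#' Train the full cycle-consistent model on an unpaired dataset
#'
#' @param dataset an [build_unpaired_dataset()] dataset (both domains
#'   non-empty).
#' @param train_cfg a [train_config()].
#' @param gen_cfg,disc_cfg,loss_cfg network and loss configurations;
#'   defaults follow the dataset patch size.
#' @param phi_width_scale perceptual extractor width multiplier.
#' @param out_dir directory for checkpoints and the loss log.
#' @param resume_from optional checkpoint path to continue from.
#' @param verbose print progress every 50 steps.
#' @return path of the final checkpoint; the per-step loss log (columns
#'   step, l_gan_g, l_gan_f, l_cyc, l_perc, total, lr) is written to
#'   `loss_log.csv` in `out_dir` and attached as attribute `"log"`.
#' @export
train <- function(dataset, train_cfg = train_config("tiny"),
                  gen_cfg = NULL, disc_cfg = NULL, loss_cfg = NULL,
                  phi_width_scale = 1 / 8,
                  out_dir = tempfile("ldct_run_"), resume_from = NULL,
                  verbose = FALSE) {
  if (length(dataset$domain_x) == 0L || length(dataset$domain_y) == 0L)
    stop("dataset has an empty domain", call. = FALSE)
  ps <- dataset$patch_size
  if (is.null(gen_cfg))
    gen_cfg <- generator_config(channels = 16L, redcnn_layers = 3L,
                                unet_stages = 3L, input_size = ps,
                                residual = TRUE, clamp_output = TRUE)
  if (is.null(disc_cfg))
    disc_cfg <- discriminator_config(input_size = ps, base_channels = 16L)
  if (is.null(loss_cfg))
    loss_cfg <- loss_config(adversarial_form = "least_squares",
                            adv_weight = 4)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(resume_from)) {
    state <- load_checkpoint(resume_from)
    # continuing with the checkpoint's own protocol unless a config is
    # passed explicitly (e.g. to extend total_steps)
    if (!missing(train_cfg)) state$train_cfg <- train_cfg
  } else {
    state <- train_state_init(train_cfg, gen_cfg, disc_cfg, loss_cfg,
                              phi_width_scale)
  }
  sampler <- dataset_sampler(dataset, seed = subseed(state$train_cfg$seed, 17L))
  for (i in seq_len(state$step)) sampler()   # fast-forward on resume
  total <- state$train_cfg$total_steps
  log <- vector("list", max(0L, total - state$step))
  li <- 0L
  while (state$step < total) {
    b <- sampler()
    r <- train_step(state, b$x, b$y)
    state <- r$state
    li <- li + 1L
    log[[li]] <- data.frame(step = state$step, l_gan_g = r$bundle$l_gan_g,
                            l_gan_f = r$bundle$l_gan_f, l_cyc = r$bundle$l_cyc,
                            l_perc = r$bundle$l_perc, total = r$bundle$total,
                            lr = state$lr)
    if (verbose && state$step %% 50L == 0L)
      message(sprintf("step %d/%d  total=%.4f cyc=%.4f", state$step, total,
                      r$bundle$total, r$bundle$l_cyc))
    if (state$step %% state$train_cfg$checkpoint_every == 0L &&
        state$step < total)
      save_checkpoint(state, file.path(out_dir, sprintf("ckpt_%06d.rds", state$step)))
  }
  final <- file.path(out_dir, "ckpt_final.rds")
  save_checkpoint(state, final)
  logdf <- do.call(rbind, log[seq_len(li)])
  if (!is.null(logdf)) {
    logpath <- file.path(out_dir, "loss_log.csv")
    if (file.exists(logpath)) {
      old <- utils::read.csv(logpath)
      logdf <- rbind(old[old$step <= (total - li), , drop = FALSE], logdf)
    }
    write.csv(logdf, logpath, row.names = FALSE)
  }
  attr(final, "log") <- logdf
  final
}

#' Denoise images with a trained generator
#'
#' Applies G in inference mode (the exponential-moving-average weights when
#' the training profile tracked them). Inputs larger than the nominal
#' generator input are processed in overlapping tiles (half-tile stride)
#' and blended by averaging.
#'
#' @param images a single image matrix or a list of them.
#' @param checkpoint an `ldct_train_state` or a checkpoint path.
#' @param tile tile side; defaults to the generator's nominal input size.
#' @return denoised image(s), same shape(s) as the input.
#' @export
denoise <- function(images, checkpoint, tile = NULL) {
  state <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  gen <- state$G
  # inference uses the smoothed (EMA) generator when training tracked one
  if (!is.null(state$G_ema)) gen$params <- state$G_ema
  if (is.null(tile)) tile <- gen$config$input_size
  one <- function(img) {
    H <- nrow(img); W <- ncol(img)
    if (H <= tile && W <= tile) return(generate(gen, img))
    offs <- function(n) unique(c(seq(0L, n - tile, by = max(1L, tile %/% 2L)),
                                 n - tile))
    acc <- matrix(0, H, W); wt <- matrix(0, H, W)
    for (r in offs(H)) for (cl in offs(W)) {
      sub <- img[(r + 1L):(r + tile), (cl + 1L):(cl + tile)]
      out <- generate(gen, sub)
      acc[(r + 1L):(r + tile), (cl + 1L):(cl + tile)] <-
        acc[(r + 1L):(r + tile), (cl + 1L):(cl + tile)] + out
      wt[(r + 1L):(r + tile), (cl + 1L):(cl + tile)] <-
        wt[(r + 1L):(r + tile), (cl + 1L):(cl + tile)] + 1
    }
    acc / wt
  }
  if (is.list(images)) lapply(images, one) else one(images)
}
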