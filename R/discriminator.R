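# PatchGAN discriminator: a ladder of stride-2 4x4 convolutions reducing the
# input to a 4x4 single-channel sigmoid map of local "probability of being
# normal-dose" scores; the discriminator output is their mean.

#' Discriminator configuration
#'
#' The ladder has `n_stages` stride-2 convolutions (kernel 4, pad 1), so the
#' nominal input side is `4 * 2^n_stages`. Channel widths double each stage
#' from `base_channels`, capped at 512; the last stage maps to 1 channel and
#' is sigmoid-activated. LeakyReLU(0.2) between stages.
#'
#' @param input_size nominal square input side (must be `4 * 2^k`).
#' @param base_channels width of the first stage (full scale 64).
#' @return list of class `ldct_discriminator_config`.
#' @export
discriminator_config <- function(input_size = 256L, base_channels = 64L) {
  k <- log2(input_size / 4)
  if (input_size < 8L || k != round(k))
    stop(sprintf("input size %d cannot reach a 4x4 map; need 4*2^k with k >= 1",
                 input_size), call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 n_stages = as.integer(k),
                 base_channels = as.integer(base_channels)),
            class = "ldct_discriminator_config")
}

#' Build a discriminator with freshly initialized parameters
#'
#' @param config a [discriminator_config()].
#' @param seed integer seed for initialization.
#' @return list of class `ldct_discriminator`.
#' @export
discriminator_init <- function(config = discriminator_config(), seed = 1L) {
  ns <- config$n_stages
  widths <- pmin(config$base_channels * 2L^(seq_len(ns) - 1L), 512L)
  widths[ns] <- 1L
  with_seed(seed, {
    layers <- lapply(seq_len(ns), function(l)
      conv_layer(4L, 4L, if (l == 1L) 1L else widths[l - 1L], widths[l]))
    structure(list(config = config, params = list(layers = layers),
                   widths = widths),
              class = "ldct_discriminator")
  })
}

# Forward pass; `out` is the sigmoid probability map, `logits` the
# pre-sigmoid map (the raw-score surface used by the least-squares
# adversarial option).
discriminator_forward <- function(disc, x, want_cache = TRUE) {
  ns <- disc$config$n_stages
  x <- as_hwc(x)
  if (dim(x)[1] < 4L * 2L^ns || dim(x)[2] < 4L * 2L^ns)
    stop(sprintf("input %dx%d too small to reach a 4x4 map: minimum side is %d",
                 dim(x)[1], dim(x)[2], 4L * 2L^ns), call. = FALSE)
  caches <- vector("list", ns)
  act <- vector("list", ns)
  h <- x
  for (l in seq_len(ns)) {
    cv <- conv_fwd(h, disc$params$layers[[l]]$w, disc$params$layers[[l]]$b,
                   2L, 1L)
    if (l < ns) {
      a <- lrelu_fwd(cv$out)
      h <- a$out
      act[[l]] <- a$cache
    } else {
      logits <- cv$out
      a <- sigmoid_fwd(cv$out)
      h <- a$out
      act[[l]] <- a$cache
    }
    caches[[l]] <- cv$cache
  }
  list(out = h, logits = logits,
       cache = if (want_cache) list(convs = caches, act = act))
}

# `from_logits`: the upstream gradient is w.r.t. the pre-sigmoid map, so the
# final sigmoid is skipped on the way back.
discriminator_backward <- function(disc, dout, cache, from_logits = FALSE) {
  ns <- disc$config$n_stages
  g <- vector("list", ns)
  h <- dout
  for (l in rev(seq_len(ns))) {
    h <- if (l < ns) lrelu_bwd(h, cache$act[[l]])
         else if (from_logits) h
         else sigmoid_bwd(h, cache$act[[l]])
    bw <- conv_bwd(h, cache$convs[[l]])
    g[[l]] <- list(w = bw$dw, b = bw$db)
    h <- bw$dx
  }
  list(dx = h, grads = list(layers = g))
}

#' Score an image with the PatchGAN discriminator
#'
#' @param disc an [discriminator_init()] discriminator.
#' @param img single-channel image whose side is the configured nominal size
#'   (or larger, as long as it halves cleanly through all stages).
#' @return list of class `ldct_patch_scores`: `scores` (the sigmoid map,
#'   4x4 at nominal size) and `mean_score` (their arithmetic mean).
#' @export
score <- function(disc, img) {
  r <- discriminator_forward(disc, img, want_cache = FALSE)
  s <- r$out
  dim(s) <- dim(s)[1:2]
  structure(list(scores = s, mean_score = mean(s)),
            class = "ldct_patch_scores")
}

#' @export
print.ldct_patch_scores <- function(x, ...) {
  cat(sprintf("<ldct_patch_scores> %dx%d map, mean = %.4f\n",
              nrow(x$scores), ncol(x$scores), x$mean_score))
  invisible(x)
}
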