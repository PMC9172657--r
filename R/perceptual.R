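# Fixed (non-trained) convolutional feature extractor with VGG-16 topology:
# conv blocks of (2, 2, 3, 3, 3) 3x3 convolutions with widths
# (64, 128, 256, 512, 512) * width_scale, each followed by 2x2 max pooling.
# Perceptual features are tapped after the second pooling stage ("pool2",
# 128-channel at full width) and the last pooling stage ("pool5",
# 512-channel). Weights are drawn once from a fixed seed and never updated;
# grayscale inputs are replicated to the 3 input channels.

vgg_plan <- function(width_scale) {
  widths <- pmax(2L, as.integer(round(c(64, 128, 256, 512, 512) * width_scale)))
  list(blocks = c(2L, 2L, 3L, 3L, 3L), widths = widths)
}

#' Build a fixed perceptual feature extractor
#'
#' @param width_scale multiplier on the VGG-16 channel widths (1 = full; small
#'   scales keep the topology and tap points but shrink compute for
#'   desk-scale runs).
#' @param seed seed for the fixed random weights.
#' @return list of class `ldct_perceptual`. Its parameters are frozen by
#'   contract: nothing in the package ever writes to them.
#' @export
perceptual_extractor <- function(width_scale = 1, seed = 99L) {
  plan <- vgg_plan(width_scale)
  with_seed(seed, {
    layers <- list()
    cin <- 3L
    for (b in seq_along(plan$blocks)) {
      for (k in seq_len(plan$blocks[b])) {
        layers[[length(layers) + 1L]] <-
          c(conv_layer(3L, 3L, cin, plan$widths[b]), list(block = b))
        cin <- plan$widths[b]
      }
    }
    structure(list(layers = layers, plan = plan, width_scale = width_scale,
                   seed = seed),
              class = "ldct_perceptual")
  })
}

#' @export
print.ldct_perceptual <- function(x, ...) {
  cat(sprintf("<ldct_perceptual> VGG-16 topology, widths %s (frozen)\n",
              paste(x$plan$widths, collapse = "/")))
  invisible(x)
}

# Forward pass returning tapped feature maps; taps name pooling stages
# ("pool2", "pool5"). want_cache enables gradients w.r.t. the input image.
perceptual_forward <- function(phi, img, taps = c("pool2", "pool5"),
                               want_cache = FALSE) {
  img <- as_hwc(img)
  d <- dim(img)
  tap_block <- as.integer(sub("pool", "", taps))
  need <- 2L^max(tap_block)
  if (d[1] %% need != 0L || d[2] %% need != 0L)
    stop(sprintf("perceptual taps through pool%d need H, W divisible by %d (got %dx%d)",
                 max(tap_block), need, d[1], d[2]), call. = FALSE)
  h <- array(rep(img, 3L), c(d[1], d[2], 3L))
  feats <- setNames(vector("list", length(taps)), taps)
  caches <- list()
  li <- 0L
  for (b in seq_along(phi$plan$blocks)) {
    for (k in seq_len(phi$plan$blocks[b])) {
      li <- li + 1L
      cv <- conv_fwd(h, phi$layers[[li]]$w, phi$layers[[li]]$b, 1L, 1L)
      r <- relu_fwd(cv$out)
      if (want_cache) caches[[paste0("conv", li)]] <- list(conv = cv$cache, relu = r$cache)
      h <- r$out
    }
    mp <- maxpool_fwd(h)
    if (want_cache) caches[[paste0("pool", b)]] <- mp$cache
    h <- mp$out
    if (b %in% tap_block) feats[[paste0("pool", b)]] <- h
    if (b >= max(tap_block)) break
  }
  list(feats = feats, cache = if (want_cache) caches)
}

# Backward w.r.t. the input image only (phi is frozen). dfeats: named list of
# gradients for each tapped feature map.
perceptual_backward <- function(phi, dfeats, cache) {
  taps <- as.integer(sub("pool", "", names(dfeats)))
  last <- max(taps)
  h <- NULL
  li <- sum(phi$plan$blocks[seq_len(last)])
  for (b in rev(seq_len(last))) {
    tap_name <- paste0("pool", b)
    if (b %in% taps) {
      h <- if (is.null(h)) dfeats[[tap_name]] else h + dfeats[[tap_name]]
    }
    h <- maxpool_bwd(h, cache[[tap_name]])
    for (k in rev(seq_len(phi$plan$blocks[b]))) {
      h <- relu_bwd(h, cache[[paste0("conv", li)]]$relu)
      h <- conv_bwd_input_only(h, cache[[paste0("conv", li)]]$conv)
      li <- li - 1L
    }
  }
  # sum the 3 replicated channels back to grayscale
  dimg <- h[, , 1L, drop = FALSE] + h[, , 2L, drop = FALSE] + h[, , 3L, drop = FALSE]
  dimg
}

# input-gradient-only variant of conv_bwd (skips weight gradients)
conv_bwd_input_only <- function(dout, cache) {
  kd <- cache$kd; d <- cache$dimx
  n <- prod(dim(dout)[1:2])
  dmat <- t(matrix(dout, nrow = n, ncol = kd[4]))
  dcols <- cache$wmat %*% dmat
  dx <- cpp_col2im(dcols, d[1], d[2], d[3], kd[1], kd[2],
                   cache$stride, cache$pad)
  dim(dx) <- d
  dx
}
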