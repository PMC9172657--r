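# Adaptive feature-selection generator: three parallel feature extractors
# (residual encoder-decoder CNN, strided U-Net, pointwise 1x1 convolution)
# whose H x W x C outputs are fused per channel by selective-kernel (SK)
# attention, then projected back to a single-channel image.

#' Generator configuration
#'
#' @param channels branch feature width C (the full-scale model uses 64).
#' @param redcnn_layers number of convolutional layers in the RED-CNN branch
#'   (mirrored by the same number of deconvolutional layers; full scale 7).
#' @param redcnn_kernel RED-CNN kernel size (odd; default 3).
#' @param unet_stages number of stride-2 encoder stages in the U-Net branch
#'   (mirrored in the decoder; full scale 7). Reduced automatically, with a
#'   warning, when `input_size` cannot support the requested depth.
#' @param unet_kernel U-Net kernel size (default 4, stride 2).
#' @param reduction_dim dimension d of the compact SK feature; default
#'   `max(channels / 2, 8)`.
#' @param ablation one of `"full"`, `"redcnn_only"`, `"unet_only"`,
#'   `"concat_no_sk"`, `"no_conv1x1"` selecting the generator variant.
#' @param residual add the input image to the generator output (off by
#'   default; convergence aid for small-scale runs).
#' @param clamp_output clamp the generator output to the valid `[0, 1]`
#'   intensity range (exact subgradient). Keeps the adversarial game inside
#'   the image domain; used by the desk-scale profile.
#' @param input_size nominal square input size; used to validate/clamp
#'   `unet_stages`.
#' @return a list of class `ldct_generator_config`.
#' @export
generator_config <- function(channels = 64L, redcnn_layers = 7L,
                             redcnn_kernel = 3L, unet_stages = 7L,
                             unet_kernel = 4L, reduction_dim = NULL,
                             ablation = c("full", "redcnn_only", "unet_only",
                                          "concat_no_sk", "no_conv1x1"),
                             residual = FALSE, clamp_output = FALSE,
                             input_size = 256L) {
  ablation <- match.arg(ablation)
  if (channels < 1L || redcnn_layers < 1L || unet_stages < 1L)
    stop("channels, redcnn_layers and unet_stages must be >= 1", call. = FALSE)
  if (redcnn_kernel %% 2L != 1L)
    stop("redcnn_kernel must be odd", call. = FALSE)
  max_stages <- max(1L, floor(log2(input_size)) - 1L)
  if (unet_stages > max_stages) {
    warning(sprintf("unet_stages reduced from %d to %d for input size %d",
                    unet_stages, max_stages, input_size), call. = FALSE)
    unet_stages <- max_stages
  }
  if (is.null(reduction_dim)) reduction_dim <- max(channels %/% 2L, 8L)
  if (reduction_dim >= channels)
    warning(sprintf("reduction_dim (%d) >= channels (%d): compact feature is not compact",
                    reduction_dim, channels), call. = FALSE)
  structure(list(channels = as.integer(channels),
                 redcnn_layers = as.integer(redcnn_layers),
                 redcnn_kernel = as.integer(redcnn_kernel),
                 unet_stages = as.integer(unet_stages),
                 unet_kernel = as.integer(unet_kernel),
                 reduction_dim = as.integer(reduction_dim),
                 ablation = ablation, residual = residual,
                 clamp_output = clamp_output,
                 input_size = as.integer(input_size)),
            class = "ldct_generator_config")
}

active_branches <- function(cfg) {
  switch(cfg$ablation,
         full = c("redcnn", "unet", "conv1x1"),
         concat_no_sk = c("redcnn", "unet", "conv1x1"),
         no_conv1x1 = c("redcnn", "unet"),
         redcnn_only = "redcnn",
         unet_only = "unet")
}

#' Build a generator with freshly initialized parameters
#'
#' Weights are truncated-normal (sd 0.02, clipped at 2 sd), biases zero.
#'
#' @param config a [generator_config()].
#' @param seed integer seed controlling initialization.
#' @return a list of class `ldct_generator` with elements `config`, `params`.
#' @export
generator_init <- function(config = generator_config(), seed = 1L) {
  cfg <- config
  C <- cfg$channels
  with_seed(seed, {
    params <- list()
    br <- active_branches(cfg)
    if ("redcnn" %in% br) {
      k <- cfg$redcnn_kernel; L <- cfg$redcnn_layers
      params$redcnn <- list(
        convs = lapply(seq_len(L), function(l)
          conv_layer(k, k, if (l == 1L) 1L else C, C)),
        deconvs = lapply(seq_len(L), function(l)
          deconv_layer(k, k, C, C)))
    }
    if ("unet" %in% br) {
      k <- cfg$unet_kernel; D <- cfg$unet_stages
      params$unet <- list(
        encs = lapply(seq_len(D), function(l)
          conv_layer(k, k, if (l == 1L) 1L else C, C)),
        decs = lapply(seq_len(D), function(l)
          deconv_layer(k, k, C, if (l == 1L) C else 2L * C)))
    }
    if ("conv1x1" %in% br) params$conv1x1 <- conv_layer(1L, 1L, 1L, C)
    if (cfg$ablation %in% c("full", "no_conv1x1")) {
      nb <- length(br); d <- cfg$reduction_dim
      params$sk <- list(
        ws = init_w(c(d, C)), bs = numeric(d),
        gamma = rep(1, d), beta = numeric(d),
        heads = lapply(seq_len(nb), function(i) init_w(c(C, d))))
    }
    cin_final <- if (cfg$ablation == "concat_no_sk") 3L * C else C
    params$final <- conv_layer(1L, 1L, cin_final, 1L)
    structure(list(config = cfg, params = params), class = "ldct_generator")
  })
}

#' @export
print.ldct_generator <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<ldct_generator> ablation=%s channels=%d params=%d\n",
              x$config$ablation, x$config$channels, np))
  invisible(x)
}

## --- RED-CNN branch ---------------------------------------------------------

# Shortcut layout: deconv layer l receives the post-ReLU activation of conv
# layer (L - l), for every other l (those with (L - l) odd), added before the
# deconv ReLU.
redcnn_skip_source <- function(l, L) {
  k <- L - l
  if (k >= 1L && k %% 2L == 1L) k else NA_integer_
}

redcnn_fwd <- function(x, p, kernel) {
  pad <- (kernel - 1L) %/% 2L
  L <- length(p$convs)
  a <- list(as_hwc(x))                # a[[l+1]] = activation after conv l
  caches <- list(convs = vector("list", L), deconvs = vector("list", L),
                 relu_c = vector("list", L), relu_d = vector("list", L),
                 skips = integer(L))
  h <- a[[1L]]
  for (l in seq_len(L)) {
    cv <- conv_fwd(h, p$convs[[l]]$w, p$convs[[l]]$b, 1L, pad)
    r <- relu_fwd(cv$out)
    caches$convs[[l]] <- cv$cache
    caches$relu_c[[l]] <- r$cache
    h <- r$out
    a[[l + 1L]] <- h
  }
  for (l in seq_len(L)) {
    dv <- deconv_fwd(h, p$deconvs[[l]]$w, p$deconvs[[l]]$b, 1L, pad)
    z <- dv$out
    src <- redcnn_skip_source(l, L)
    caches$skips[l] <- if (is.na(src)) 0L else src
    if (!is.na(src)) z <- z + a[[src + 1L]]
    r <- relu_fwd(z)
    caches$deconvs[[l]] <- dv$cache
    caches$relu_d[[l]] <- r$cache
    h <- r$out
  }
  list(out = h, cache = caches)
}

redcnn_bwd <- function(dout, p, cache) {
  L <- length(p$convs)
  g <- list(convs = vector("list", L), deconvs = vector("list", L))
  skip_grads <- vector("list", L + 1L)   # gradient w.r.t. a[[k+1]]
  h <- dout
  for (l in rev(seq_len(L))) {
    h <- relu_bwd(h, cache$relu_d[[l]])
    src <- cache$skips[l]
    if (src > 0L) {
      sg <- skip_grads[[src + 1L]]
      skip_grads[[src + 1L]] <- if (is.null(sg)) h else sg + h
    }
    bw <- deconv_bwd(h, cache$deconvs[[l]])
    g$deconvs[[l]] <- list(w = bw$dw, b = bw$db)
    h <- bw$dx
  }
  for (l in rev(seq_len(L))) {
    sg <- skip_grads[[l + 1L]]
    if (!is.null(sg)) h <- h + sg
    h <- relu_bwd(h, cache$relu_c[[l]])
    bw <- conv_bwd(h, cache$convs[[l]])
    g$convs[[l]] <- list(w = bw$dw, b = bw$db)
    h <- bw$dx
  }
  list(dx = h, grads = g)
}

## --- U-Net branch -----------------------------------------------------------

unet_fwd <- function(x, p, kernel) {
  D <- length(p$encs)
  x <- as_hwc(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H %% 2L^D != 0L || W %% 2L^D != 0L)
    stop(sprintf("U-Net branch with %d stages needs H and W divisible by %d (got %dx%d)",
                 D, 2L^D, H, W), call. = FALSE)
  e <- vector("list", D)
  caches <- list(encs = vector("list", D), decs = vector("list", D),
                 relu_e = vector("list", D), relu_d = vector("list", D),
                 cat_ch = integer(D))
  h <- x
  for (l in seq_len(D)) {
    cv <- conv_fwd(h, p$encs[[l]]$w, p$encs[[l]]$b, 2L, 1L)
    r <- relu_fwd(cv$out)
    caches$encs[[l]] <- cv$cache; caches$relu_e[[l]] <- r$cache
    h <- r$out
    e[[l]] <- h
  }
  for (l in seq_len(D)) {
    if (l > 1L) {
      skip <- e[[D - l + 1L]]
      caches$cat_ch[l] <- dim(h)[3]
      h <- array(c(h, skip), c(dim(h)[1:2], dim(h)[3] + dim(skip)[3]))
    }
    dv <- deconv_fwd(h, p$decs[[l]]$w, p$decs[[l]]$b, 2L, 1L)
    r <- relu_fwd(dv$out)
    caches$decs[[l]] <- dv$cache; caches$relu_d[[l]] <- r$cache
    h <- r$out
  }
  list(out = h, cache = caches)
}

unet_bwd <- function(dout, p, cache) {
  D <- length(p$encs)
  g <- list(encs = vector("list", D), decs = vector("list", D))
  skip_grads <- vector("list", D)      # gradient w.r.t. e[[k]]
  h <- dout
  for (l in rev(seq_len(D))) {
    h <- relu_bwd(h, cache$relu_d[[l]])
    bw <- deconv_bwd(h, cache$decs[[l]])
    g$decs[[l]] <- list(w = bw$dw, b = bw$db)
    h <- bw$dx
    if (l > 1L) {
      nc <- cache$cat_ch[l]
      full <- dim(h)[3]
      skip_part <- h[, , (nc + 1L):full, drop = FALSE]
      k <- D - l + 1L
      sg <- skip_grads[[k]]
      skip_grads[[k]] <- if (is.null(sg)) skip_part else sg + skip_part
      h <- h[, , seq_len(nc), drop = FALSE]
    }
  }
  for (l in rev(seq_len(D))) {
    sg <- skip_grads[[l]]
    if (!is.null(sg)) h <- h + sg
    h <- relu_bwd(h, cache$relu_e[[l]])
    bw <- conv_bwd(h, cache$encs[[l]])
    g$encs[[l]] <- list(w = bw$dw, b = bw$db)
    h <- bw$dx
  }
  list(dx = h, grads = g)
}

## --- selective-kernel fusion ------------------------------------------------

sk_fwd <- function(Us, skp) {
  nb <- length(Us)
  d3 <- dim(Us[[1L]])
  U <- Reduce(`+`, Us)
  HW <- d3[1] * d3[2]; C <- d3[3]
  S <- colMeans(matrix(U, HW, C))
  zlin <- drop(skp$ws %*% S) + skp$bs
  fn <- featnorm_fwd(zlin, skp$gamma, skp$beta)
  Z <- pmax(fn$out, 0)
  logits <- vapply(skp$heads[seq_len(nb)], function(h) drop(h %*% Z),
                   numeric(C))                     # C x nb
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  Wt <- ex / rowSums(ex)                            # C x nb softmax weights
  V <- array(0, d3)
  for (k in seq_len(nb)) V <- V + Us[[k]] * rep(Wt[, k], each = HW)
  list(out = V,
       state = list(S = S, Z = Z, weights = Wt),
       cache = list(Us = Us, Wt = Wt, Z = Z, fn = fn$cache,
                    relu_mask = fn$out > 0, S = S, d3 = d3, nb = nb))
}

sk_bwd <- function(dV, skp, cache) {
  nb <- cache$nb; d3 <- cache$d3
  HW <- d3[1] * d3[2]; C <- d3[3]
  Us <- cache$Us; Wt <- cache$Wt
  dUs <- vector("list", nb)
  dWt <- matrix(0, C, nb)
  for (k in seq_len(nb)) {
    dUs[[k]] <- dV * rep(Wt[, k], each = HW)
    dWt[, k] <- colSums(matrix(dV * Us[[k]], HW, C))
  }
  # softmax backward, per channel across the nb branches
  dlogits <- Wt * (dWt - rowSums(dWt * Wt))
  dZ <- numeric(length(cache$Z))
  dheads <- vector("list", nb)
  for (k in seq_len(nb)) {
    dZ <- dZ + drop(crossprod(skp$heads[[k]], dlogits[, k]))
    dheads[[k]] <- outer(dlogits[, k], cache$Z)
  }
  dfn <- dZ * cache$relu_mask
  fb <- featnorm_bwd(dfn, cache$fn)
  dS <- drop(crossprod(skp$ws, fb$dv))
  dws <- outer(fb$dv, cache$S)
  dU <- array(rep(dS / HW, each = HW), d3)
  for (k in seq_len(nb)) dUs[[k]] <- dUs[[k]] + dU
  list(dUs = dUs,
       grads = list(ws = dws, bs = fb$dv, gamma = fb$dgamma, beta = fb$dbeta,
                    heads = dheads))
}

## --- full generator forward / backward -------------------------------------

generator_forward <- function(gen, x, want_cache = TRUE) {
  cfg <- gen$config; p <- gen$params
  x <- as_hwc(x)
  br <- active_branches(cfg)
  Us <- list(); caches <- list()
  if ("redcnn" %in% br) {
    r <- redcnn_fwd(x, p$redcnn, cfg$redcnn_kernel)
    Us <- c(Us, list(r$out)); caches$redcnn <- r$cache
  }
  if ("unet" %in% br) {
    u <- unet_fwd(x, p$unet, cfg$unet_kernel)
    Us <- c(Us, list(u$out)); caches$unet <- u$cache
  }
  if ("conv1x1" %in% br) {
    cc <- conv_fwd(x, p$conv1x1$w, p$conv1x1$b, 1L, 0L)
    Us <- c(Us, list(cc$out)); caches$conv1x1 <- cc$cache
  }
  sk_state <- NULL
  if (cfg$ablation %in% c("full", "no_conv1x1")) {
    sk <- sk_fwd(Us, p$sk)
    V <- sk$out; caches$sk <- sk$cache; sk_state <- sk$state
  } else if (cfg$ablation == "concat_no_sk") {
    V <- array(unlist(Us), c(dim(Us[[1L]])[1:2], 3L * cfg$channels))
    caches$nb_ch <- dim(Us[[1L]])[3]
  } else {
    V <- Us[[1L]]
  }
  fin <- conv_fwd(V, p$final$w, p$final$b, 1L, 0L)
  out <- fin$out
  if (cfg$residual) out <- out + x
  if (isTRUE(cfg$clamp_output)) {
    caches$clamp_mask <- out > 0 & out < 1
    out <- pmin(pmax(out, 0), 1)
  }
  caches$final <- fin$cache
  list(out = out, cache = if (want_cache) caches else NULL,
       sk_state = sk_state)
}

generator_backward <- function(gen, dout, cache) {
  cfg <- gen$config; p <- gen$params
  br <- active_branches(cfg)
  g <- list()
  if (isTRUE(cfg$clamp_output)) dout <- dout * cache$clamp_mask
  fb <- conv_bwd(dout, cache$final)
  g$final <- list(w = fb$dw, b = fb$db)
  dV <- fb$dx
  if (cfg$ablation %in% c("full", "no_conv1x1")) {
    sb <- sk_bwd(dV, p$sk, cache$sk)
    dUs <- sb$dUs
    g$sk <- sb$grads
  } else if (cfg$ablation == "concat_no_sk") {
    C <- cfg$channels
    dUs <- lapply(0:2, function(k) dV[, , (k * C + 1L):((k + 1L) * C), drop = FALSE])
  } else {
    dUs <- list(dV)
  }
  dx <- 0
  i <- 1L
  if ("redcnn" %in% br) {
    rb <- redcnn_bwd(dUs[[i]], p$redcnn, cache$redcnn)
    g$redcnn <- rb$grads; dx <- dx + rb$dx; i <- i + 1L
  }
  if ("unet" %in% br) {
    ub <- unet_bwd(dUs[[i]], p$unet, cache$unet)
    g$unet <- ub$grads; dx <- dx + ub$dx; i <- i + 1L
  }
  if ("conv1x1" %in% br) {
    cb <- conv_bwd(dUs[[i]], cache$conv1x1)
    g$conv1x1 <- list(w = cb$dw, b = cb$db); dx <- dx + cb$dx
  }
  if (cfg$residual) dx <- dx + dout
  # order grads to mirror gen$params exactly
  g <- g[names(gen$params)]
  list(dx = dx, grads = g)
}

## --- exported operation surface --------------------------------------------

#' Run a single branch of the generator
#'
#' These expose the three feature extractors individually; each maps a
#' single-channel image to an H x W x C feature map.
#'
#' @param x single-channel image (H x W matrix or H x W x 1 array).
#' @param gen an [generator_init()] generator whose config activates the
#'   branch.
#' @return an H x W x C array.
#' @export
red_cnn_branch <- function(x, gen) {
  if (is.null(gen$params$redcnn)) stop("RED-CNN branch not active", call. = FALSE)
  redcnn_fwd(x, gen$params$redcnn, gen$config$redcnn_kernel)$out
}

#' @rdname red_cnn_branch
#' @export
unet_branch <- function(x, gen) {
  if (is.null(gen$params$unet)) stop("U-Net branch not active", call. = FALSE)
  unet_fwd(x, gen$params$unet, gen$config$unet_kernel)$out
}

#' @rdname red_cnn_branch
#' @export
conv1x1_branch <- function(x, gen) {
  if (is.null(gen$params$conv1x1)) stop("1x1 branch not active", call. = FALSE)
  conv_fwd(as_hwc(x), gen$params$conv1x1$w, gen$params$conv1x1$b, 1L, 0L)$out
}

#' Global average pooling of a feature map
#'
#' Returns the per-channel spatial mean `S_c = mean(U[, , c])`.
#'
#' @param U an H x W x C feature map.
#' @return numeric vector of length C.
#' @export
global_avg_pool <- function(U) {
  U <- as_hwc(U)
  if (prod(dim(U)) == 0L) stop("empty feature map", call. = FALSE)
  d <- dim(U)
  colMeans(matrix(U, d[1] * d[2], d[3]))
}

#' Compact SK feature
#'
#' Projects the channel descriptor S to a length-d compact feature
#' Z = ReLU(norm(W_S S + b)), where norm standardizes over the d components
#' with learned gain/bias.
#'
#' @param S channel descriptor (length C).
#' @param sk the `sk` parameter block of a generator (`gen$params$sk`).
#' @return numeric vector of length d, non-negative.
#' @export
compact_feature <- function(S, sk) {
  zlin <- drop(sk$ws %*% S) + sk$bs
  pmax(featnorm_fwd(zlin, sk$gamma, sk$beta)$out, 0)
}

#' Per-channel branch-selection weights
#'
#' Softmax over the branch logit heads evaluated at the compact feature Z;
#' for every channel the weights sum to one.
#'
#' @param Z compact feature (length d).
#' @param sk the `sk` parameter block of a generator.
#' @return matrix C x n_branches of weights in (0, 1), rows summing to 1.
#' @export
branch_softmax <- function(Z, sk) {
  C <- nrow(sk$heads[[1L]])
  logits <- matrix(vapply(sk$heads, function(h) drop(h %*% Z), numeric(C)),
                   nrow = C)
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  ex / rowSums(ex)
}

#' Selective-kernel fusion of branch feature maps
#'
#' Fuses the branch outputs by element-wise sum, derives per-channel
#' selection weights from the pooled descriptor, and returns the weighted
#' combination `V[, , c] = a_c U1 + b_c U2 + c_c U3`.
#'
#' @param U1,U2,U3 H x W x C feature maps of identical shape (`U3` may be
#'   `NULL` for two-branch fusion).
#' @param sk the `sk` parameter block of a generator.
#' @return list with `V` (fused map) and `state` (list `S`, `Z`, `weights`).
#' @export
sk_fuse <- function(U1, U2, U3 = NULL, sk) {
  Us <- Filter(Negate(is.null), list(U1, U2, U3))
  dims <- lapply(Us, dim)
  for (i in seq_along(Us)[-1L])
    if (!identical(dims[[i]], dims[[1L]]))
      stop(sprintf("branch %d shape (%s) differs from branch 1 (%s)",
                   i, paste(dims[[i]], collapse = "x"),
                   paste(dims[[1L]], collapse = "x")), call. = FALSE)
  if (length(sk$heads) < length(Us))
    stop("sk parameters have fewer heads than branches", call. = FALSE)
  r <- sk_fwd(Us, sk)
  list(V = r$out, state = r$state)
}

#' Apply the generator to an image
#'
#' Runs the active branches, SK fusion (or the configured ablation variant)
#' and the final 1x1 projection; output has the same H x W as the input.
#'
#' @param gen an [generator_init()] generator.
#' @param x single-channel image.
#' @return denoised image, same dimensions as `x`.
#' @export
generate <- function(gen, x) {
  was_mat <- is.matrix(x)
  out <- generator_forward(gen, x, want_cache = FALSE)$out
  if (was_mat) dim(out) <- dim(out)[1:2]
  out
}
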