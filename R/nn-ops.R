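# Low-level neural-network primitives on H x W x C arrays (single image,
# batch size 1 throughout, matching the training protocol). Every forward
# returns list(out, cache); every backward takes the upstream gradient plus
# the cache and returns the input gradient and parameter gradients.

as_hwc <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

conv_out_size <- function(n, k, stride, pad) {
  num <- n + 2L * pad - k
  if (num < 0L || num %% stride != 0L)
    stop(sprintf(
      "spatial size %d incompatible with kernel %d, stride %d, pad %d (need (%d + %d - %d) divisible by %d)",
      n, k, stride, pad, n, 2L * pad, k, stride), call. = FALSE)
  num %/% stride + 1L
}

## --- convolution -----------------------------------------------------------

# w: array (kh, kw, Cin, Cout); b: length Cout. The patch matrix is
# output-position-major (n x kh*kw*Cin), so forward/backward are plain
# GEMMs with no explicit transposes.
conv_fwd <- function(x, w, b, stride = 1L, pad = 0L) {
  x <- as_hwc(x)
  d <- dim(x); kd <- dim(w)
  stopifnot(d[3] == kd[3])
  ho <- conv_out_size(d[1], kd[1], stride, pad)
  wo <- conv_out_size(d[2], kd[2], stride, pad)
  cols <- cpp_im2col(x, d[1], d[2], d[3], kd[1], kd[2], stride, pad)
  wmat <- matrix(w, nrow = kd[1] * kd[2] * kd[3], ncol = kd[4])
  out <- cols %*% wmat                      # n x Cout
  out <- out + rep(b, each = nrow(out))
  dim(out) <- c(ho, wo, kd[4])
  list(out = out, cache = list(cols = cols, wmat = wmat, dimx = d, kd = kd,
                               stride = stride, pad = pad))
}

conv_bwd <- function(dout, cache) {
  kd <- cache$kd; d <- cache$dimx
  n <- prod(dim(dout)[1:2])
  dmat <- matrix(dout, nrow = n, ncol = kd[4])      # n x Cout
  dw <- crossprod(cache$cols, dmat)
  dim(dw) <- kd
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, cache$wmat)             # n x kh*kw*Cin
  dx <- cpp_col2im(dcols, d[1], d[2], d[3], kd[1], kd[2],
                   cache$stride, cache$pad)
  dim(dx) <- d
  list(dx = dx, dw = dw, db = db)
}

## --- transposed convolution ------------------------------------------------

# w: array (kh, kw, Cout, Cin); output spatial size (H-1)*stride - 2*pad + k.
deconv_fwd <- function(x, w, b, stride = 1L, pad = 0L) {
  x <- as_hwc(x)
  d <- dim(x); kd <- dim(w)
  stopifnot(d[3] == kd[4])
  ho <- (d[1] - 1L) * stride - 2L * pad + kd[1]
  wo <- (d[2] - 1L) * stride - 2L * pad + kd[2]
  xmat <- matrix(x, nrow = d[1] * d[2], ncol = d[3]) # n x Cin
  wmat <- matrix(w, nrow = kd[1] * kd[2] * kd[3], ncol = kd[4])
  cols <- tcrossprod(xmat, wmat)                     # n x kh*kw*Cout
  out <- cpp_col2im(cols, ho, wo, kd[3], kd[1], kd[2], stride, pad)
  dim(out) <- c(ho, wo, kd[3])
  out <- out + rep(b, each = ho * wo)
  list(out = out, cache = list(xmat = xmat, wmat = wmat, dimx = d, kd = kd,
                               dimo = c(ho, wo, kd[3]),
                               stride = stride, pad = pad))
}

deconv_bwd <- function(dout, cache) {
  kd <- cache$kd; o <- cache$dimo
  dcols <- cpp_im2col(dout, o[1], o[2], o[3], kd[1], kd[2],
                      cache$stride, cache$pad)       # n x kh*kw*Cout
  dx <- dcols %*% cache$wmat                         # n x Cin
  dim(dx) <- cache$dimx
  dw <- crossprod(dcols, cache$xmat)
  dim(dw) <- kd
  db <- colSums(matrix(dout, prod(o[1:2]), o[3]))
  list(dx = dx, dw = dw, db = db)
}

## --- activations -----------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dout, cache) dout * cache

lrelu_fwd <- function(x, slope = 0.2) {
  m <- x > 0
  list(out = x * m + (slope * x) * !m, cache = list(m = m, slope = slope))
}
lrelu_bwd <- function(dout, cache)
  dout * cache$m + (cache$slope * dout) * !cache$m

sigmoid_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = s, cache = s)
}
sigmoid_bwd <- function(dout, cache) dout * cache * (1 - cache)

## --- 2x2 max pooling -------------------------------------------------------

maxpool_fwd <- function(x) {
  x <- as_hwc(x)
  d <- dim(x)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  cand <- array(NA_real_, c(d[1] / 2L, d[2] / 2L, d[3], 4L))
  cand[, , , 1L] <- x[i1, j1, , drop = FALSE]
  cand[, , , 2L] <- x[i1 + 1L, j1, , drop = FALSE]
  cand[, , , 3L] <- x[i1, j1 + 1L, , drop = FALSE]
  cand[, , , 4L] <- x[i1 + 1L, j1 + 1L, , drop = FALSE]
  do2 <- c(d[1] %/% 2L, d[2] %/% 2L, d[3])
  out <- array(cand[, , , 1L], do2)
  # deterministic tie-break: first of the four candidates in scan order
  arg <- array(1L, do2)
  for (k in 2:4) {
    ck <- array(cand[, , , k], do2)
    m <- ck > out
    arg[m] <- k
    out[m] <- ck[m]
  }
  list(out = out, cache = list(arg = arg, dimx = d))
}

maxpool_bwd <- function(dout, cache) {
  d <- cache$dimx
  dx <- array(0, d)
  arg <- cache$arg
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  for (k in 1:4) {
    di <- (k - 1L) %% 2L; dj <- (k - 1L) %/% 2L
    mask <- arg == k
    sub <- dx[i1 + di, j1 + dj, , drop = FALSE]
    sub[mask] <- sub[mask] + dout[mask]
    dx[i1 + di, j1 + dj, ] <- sub
  }
  dx
}

## --- vector feature normalization (for the SK compact feature) -------------

# Standardizes a length-d vector to zero mean / unit variance over its
# components, then applies a learned gain and bias. Degenerates gracefully
# at d = 1 (standardized value is 0).
featnorm_fwd <- function(v, gamma, beta, eps = 1e-5) {
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  inv <- 1 / sqrt(s2 + eps)
  vhat <- (v - mu) * inv
  list(out = gamma * vhat + beta,
       cache = list(vhat = vhat, inv = inv, gamma = gamma, n = length(v)))
}

featnorm_bwd <- function(dout, cache) {
  n <- cache$n; vhat <- cache$vhat
  dgamma <- dout * vhat
  dbeta <- dout
  dvhat <- dout * cache$gamma
  dv <- cache$inv * (dvhat - mean(dvhat) - vhat * mean(dvhat * vhat))
  list(dv = dv, dgamma = dgamma, dbeta = dbeta)
}

## --- parameter initialization ---------------------------------------------

# Truncated-normal (clipped at 2 sd) weights, zero biases.
init_w <- function(dims, sd = 0.02) {
  v <- rnorm(prod(dims), 0, sd)
  v <- pmin(pmax(v, -2 * sd), 2 * sd)
  array(v, dims)
}

conv_layer <- function(kh, kw, cin, cout, sd = 0.02) {
  list(w = init_w(c(kh, kw, cin, cout), sd), b = numeric(cout))
}

deconv_layer <- function(kh, kw, cout, cin, sd = 0.02) {
  list(w = init_w(c(kh, kw, cout, cin), sd), b = numeric(cout))
}

## --- nested-list parameter utilities ---------------------------------------

# Apply f(elementwise) across parallel nested lists of arrays.
nested_map <- function(f, ...) {
  ls <- list(...)
  x <- ls[[1L]]
  if (is.list(x)) {
    out <- lapply(seq_along(x), function(i)
      do.call(nested_map, c(list(f), lapply(ls, `[[`, i))))
    names(out) <- names(x)
    out
  } else {
    do.call(f, ls)
  }
}

nested_zero <- function(p) nested_map(function(x) x * 0, p)

nested_sumabs <- function(p) sum(vapply(rapply(p, function(x) sum(abs(x)),
                                               how = "unlist"), identity, 1.0))

# Adam optimizer over nested parameter lists.
adam_init <- function(params) {
  list(m = nested_zero(params), v = nested_zero(params), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nested_map(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- nested_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- nested_map(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

# Derive a well-spread 32-bit sub-seed from a master seed and a stream id,
# in double arithmetic to avoid integer overflow.
subseed <- function(seed, k) {
  as.integer((as.double(seed) * 1103515245 + as.double(k) * 12345 + 7) %%
               2147483629)
}

# Run a block of code with a private RNG stream, restoring the caller's
# RNG state afterwards. Used everywhere a `seed` argument appears.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
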