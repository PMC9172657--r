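# The layer primitives are the foundation of every network here, so they
# are validated against a plain-loop convolution oracle and central-
# difference gradients.

ns <- asNamespace("ldctgan")

test_that("conv forward matches the plain-loop oracle", {
  set.seed(11)
  cases <- list(list(k = 3L, s = 1L, p = 1L), list(k = 1L, s = 1L, p = 0L),
                list(k = 4L, s = 2L, p = 1L))
  for (cs in cases) {
    x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    w <- array(rnorm(cs$k * cs$k * 3 * 2), c(cs$k, cs$k, 3, 2))
    b <- rnorm(2)
    got <- ns$conv_fwd(x, w, b, cs$s, cs$p)$out
    want <- naive_conv2d(x, w, b, cs$s, cs$p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("conv/deconv/maxpool/featnorm gradients match finite differences", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.5, c(3, 3, 2, 3))
  b <- rnorm(3)
  fw <- ns$conv_fwd(x, w, b, 1L, 1L)
  bw <- ns$conv_bwd(cos(fw$out), fw$cache)
  f <- function(x, w, b) sum(sin(ns$conv_fwd(x, w, b, 1L, 1L)$out))
  expect_lt(max(abs(bw$dx - num_grad(function(z) f(z, w, b), x))), 1e-7)
  expect_lt(max(abs(bw$dw - num_grad(function(z) f(x, z, b), w))), 1e-7)
  expect_lt(max(abs(bw$db - num_grad(function(z) f(x, w, z), b))), 1e-7)

  wd <- array(rnorm(4 * 4 * 3 * 2) * 0.5, c(4, 4, 3, 2))
  bd <- rnorm(3)
  x2 <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  fd <- ns$deconv_fwd(x2, wd, bd, 2L, 1L)
  expect_equal(dim(fd$out), c(6L, 6L, 3L))
  bd2 <- ns$deconv_bwd(cos(fd$out), fd$cache)
  g <- function(x, w, b) sum(sin(ns$deconv_fwd(x, w, b, 2L, 1L)$out))
  expect_lt(max(abs(bd2$dx - num_grad(function(z) g(z, wd, bd), x2))), 1e-7)
  expect_lt(max(abs(bd2$dw - num_grad(function(z) g(x2, z, bd), wd))), 1e-7)
  expect_lt(max(abs(bd2$db - num_grad(function(z) g(x2, wd, z), bd))), 1e-7)

  x3 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  mp <- ns$maxpool_fwd(x3)
  dmp <- ns$maxpool_bwd(cos(mp$out), mp$cache)
  expect_lt(max(abs(dmp - num_grad(function(z)
    sum(sin(ns$maxpool_fwd(z)$out)), x3))), 1e-7)

  v <- rnorm(8); gam <- rnorm(8); bet <- rnorm(8)
  fn <- ns$featnorm_fwd(v, gam, bet)
  fb <- ns$featnorm_bwd(cos(fn$out), fn$cache)
  h <- function(v, g, b) sum(sin(ns$featnorm_fwd(v, g, b)$out))
  expect_lt(max(abs(fb$dv - num_grad(function(z) h(z, gam, bet), v))), 1e-7)
  expect_lt(max(abs(fb$dgamma - num_grad(function(z) h(v, z, bet), gam))), 1e-7)
  expect_lt(max(abs(fb$dbeta - num_grad(function(z) h(v, gam, z), bet))), 1e-7)
})

test_that("incompatible spatial sizes raise shape errors naming the divisibility", {
  x <- array(rnorm(5 * 5), c(5, 5, 1))
  w <- array(rnorm(4 * 4), c(4, 4, 1, 1))
  expect_error(ns$conv_fwd(x, w, 0, 2L, 1L), "divisible")
})

test_that("Adam first step moves each parameter by about lr against the gradient", {
  p <- list(a = matrix(c(1, -2, 3, 0.5), 2), b = c(0, 1))
  g <- list(a = matrix(c(0.3, -0.1, 2, -4), 2), b = c(1e-3, -5))
  st <- ns$adam_init(p)
  up <- ns$adam_update(p, g, st, lr = 0.01)
  delta <- unlist(up$params) - unlist(p)
  expect_equal(delta, -0.01 * sign(unlist(g)), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("with_seed isolates the caller's RNG stream", {
  set.seed(42)
  a <- rnorm(1)
  set.seed(42)
  invisible(ns$with_seed(7, rnorm(10)))
  expect_identical(rnorm(1), a)
  expect_identical(ns$with_seed(7, runif(3)), ns$with_seed(7, runif(3)))
})
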