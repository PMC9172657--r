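ns <- asNamespace("ldctgan")

small_gen <- function(ablation = "full", seed = 1L, channels = 8L,
                      residual = FALSE) {
  generator_init(generator_config(channels = channels, redcnn_layers = 2L,
                                  unet_stages = 2L, reduction_dim = 4L,
                                  ablation = ablation, residual = residual,
                                  input_size = 16L),
                 seed = seed)
}

test_that("branches produce H x W x C maps and vanish on zero input", {
  gen <- small_gen()
  x <- matrix(runif(256), 16, 16)
  expect_equal(dim(red_cnn_branch(x, gen)), c(16L, 16L, 8L))
  expect_equal(dim(unet_branch(x, gen)), c(16L, 16L, 8L))
  expect_equal(dim(conv1x1_branch(x, gen)), c(16L, 16L, 8L))
  z <- matrix(0, 16, 16)
  expect_true(all(red_cnn_branch(z, gen) == 0))   # zero biases, ReLU(0) = 0
  expect_true(all(unet_branch(z, gen) == 0))
})

test_that("U-Net bottleneck halves the input through every strided stage", {
  for (d in 2:4) {
    n <- 2L^(d + 1L)
    cfg <- generator_config(channels = 4L, redcnn_layers = 1L,
                            reduction_dim = 2L, unet_stages = d,
                            input_size = n)
    gen <- generator_init(cfg, seed = 2)
    x <- matrix(runif(n * n), n, n)
    enc <- gen$params$unet$encs
    h <- ns$as_hwc(x)
    for (l in seq_len(d))
      h <- ns$conv_fwd(h, enc[[l]]$w, enc[[l]]$b, 2L, 1L)$out
    expect_equal(dim(h)[1:2], c(n, n) / 2L^d)
    expect_equal(dim(unet_branch(x, gen))[1:2], c(n, n))
  }
  expect_error(unet_branch(matrix(0, 10, 10), small_gen()), "divisible")
})

test_that("the 1x1 branch is pointwise: permuting pixels permutes outputs", {
  gen <- small_gen()
  x <- matrix(runif(256), 16, 16)
  x2 <- x
  x2[1, 1] <- x[5, 7]; x2[5, 7] <- x[1, 1]
  o1 <- conv1x1_branch(x, gen); o2 <- conv1x1_branch(x2, gen)
  expect_equal(o1[1, 1, ], o2[5, 7, ])
  expect_equal(o1[5, 7, ], o2[1, 1, ])
  o1[1, 1, ] <- o2[1, 1, ]; o1[5, 7, ] <- o2[5, 7, ]
  expect_equal(o1, o2)
  # identity weights on one channel replicate the input exactly
  g1 <- generator_init(suppressWarnings(   # degenerate 1-channel config
    generator_config(channels = 1L, redcnn_layers = 1L, reduction_dim = 1L,
                     unet_stages = 1L, input_size = 16L)), seed = 1)
  g1$params$conv1x1$w[] <- 1
  g1$params$conv1x1$b[] <- 0
  expect_equal(conv1x1_branch(x, g1)[, , 1], x)
})

test_that("global average pooling is the exact spatial mean and is linear", {
  U <- array(2, c(4, 4, 3))
  expect_equal(global_avg_pool(U), c(2, 2, 2))
  U2 <- array(0, c(2, 2, 1)); U2[, , 1] <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(global_avg_pool(U2), 2.5)
  A <- array(runif(32), c(4, 4, 2)); B <- array(runif(32), c(4, 4, 2))
  expect_equal(global_avg_pool(A + B),
               global_avg_pool(A) + global_avg_pool(B))
})

test_that("the compact feature is non-negative with the configured dimension", {
  gen <- small_gen()
  for (i in 1:20) {
    S <- rnorm(8, sd = 3)
    Z <- compact_feature(S, gen$params$sk)
    expect_length(Z, 4L)
    expect_true(all(Z >= 0))
  }
})

test_that("branch softmax reproduces closed forms and always normalizes", {
  # zero heads -> equal logits -> uniform weights
  sk0 <- list(heads = list(matrix(0, 5, 2), matrix(0, 5, 2), matrix(0, 5, 2)))
  W <- branch_softmax(c(1, 2), sk0)
  expect_equal(unname(W), matrix(1 / 3, 5, 3))
  # logits (ln 2, 0, 0) -> (0.5, 0.25, 0.25)
  skl <- list(heads = list(matrix(log(2), 1, 1), matrix(0, 1, 1),
                           matrix(0, 1, 1)))
  expect_equal(as.numeric(branch_softmax(1, skl)), c(0.5, 0.25, 0.25))
  # normalization identity on random compact features
  gen <- small_gen()
  for (i in 1:100) {
    W <- branch_softmax(rnorm(4, sd = 4), gen$params$sk)
    expect_true(all(W > 0 & W < 1))
    expect_lt(max(abs(rowSums(W) - 1)), 1e-6)
  }
})

test_that("SK fusion selects, interpolates, and respects the convex envelope", {
  gen <- small_gen()
  sk <- gen$params$sk
  U1 <- array(runif(64 * 8), c(8, 8, 8))
  U2 <- array(runif(64 * 8), c(8, 8, 8))
  U3 <- array(runif(64 * 8), c(8, 8, 8))
  # forced degenerate selection: huge first-head logits -> V = U1
  skf <- sk
  skf$ws[] <- 0; skf$bs[] <- 1; skf$gamma[] <- 0; skf$beta[] <- 1
  skf$heads[[1]][] <- 60; skf$heads[[2]][] <- 0; skf$heads[[3]][] <- 0
  r <- sk_fuse(U1, U2, U3, sk = skf)
  expect_equal(r$V, U1, tolerance = 1e-8)
  # equal branches pass through unchanged for any weights (a+b+c = 1)
  r2 <- sk_fuse(U1, U1, U1, sk = sk)
  expect_equal(r2$V, U1, tolerance = 1e-12)
  # element-wise convex-combination bound against brute-force min/max
  for (i in 1:10) {
    A1 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    A2 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    A3 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    V <- sk_fuse(A1, A2, A3, sk = sk)$V
    lo <- pmin(A1, A2, A3); hi <- pmax(A1, A2, A3)
    expect_true(all(V >= lo - 1e-9 & V <= hi + 1e-9))
  }
  # state invariants: S is the pooled sum map, weights sum to one
  st <- r2$state
  expect_equal(st$S, global_avg_pool(U1 + U1 + U1))
  expect_lt(max(abs(rowSums(st$weights) - 1)), 1e-6)
  expect_error(sk_fuse(U1, U2, array(0, c(4, 4, 8)), sk = sk), "branch 3")
})

test_that("generate preserves shape, is deterministic, and honors ablations", {
  x <- matrix(runif(64 * 64), 64, 64)
  for (ab in c("full", "redcnn_only", "unet_only", "concat_no_sk",
               "no_conv1x1")) {
    gen <- generator_init(generator_config(channels = 8L, redcnn_layers = 2L,
                                           unet_stages = 2L, reduction_dim = 4L,
                                           ablation = ab, input_size = 64L),
                          seed = 5)
    out <- generate(gen, x)
    expect_equal(dim(out), dim(x))
    expect_true(all(is.finite(out)))
  }
  gen1 <- small_gen(seed = 9); gen2 <- small_gen(seed = 9)
  x16 <- matrix(runif(256), 16, 16)
  expect_identical(generate(gen1, x16), generate(gen2, x16))
})

test_that("inactive branches are dead: their parameters cannot affect the output", {
  gen <- small_gen("redcnn_only")
  expect_null(gen$params$unet)
  x <- matrix(runif(256), 16, 16)
  base <- generate(gen, x)
  gen$params$unet <- small_gen("full")$params$unet  # graft foreign weights
  expect_identical(generate(gen, x), base)
})

test_that("residual mode adds the input to the projection", {
  g0 <- small_gen(seed = 3)
  g1 <- small_gen(seed = 3, residual = TRUE)
  x <- matrix(runif(256), 16, 16)
  expect_equal(generate(g1, x), generate(g0, x) + x, tolerance = 1e-12)
})

test_that("generator_config warns on excessive depth and non-compact reduction", {
  expect_warning(generator_config(unet_stages = 7L, input_size = 32L),
                 "reduced")
  expect_warning(generator_config(channels = 8L, reduction_dim = 8L),
                 "not compact")
})
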