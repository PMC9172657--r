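test_that("the learning-rate schedule is the stated piecewise-linear function", {
  cfg <- train_config("paper")
  expect_equal(lr_schedule(0, cfg), 1e-5)
  expect_equal(lr_schedule(7e5, cfg), 1e-7)
  expect_equal(lr_schedule(9.9e5, cfg), 1e-7)
  expect_equal(lr_schedule(4e5, cfg), 5.05e-6)
  expect_error(train_config("paper", decay_end_step = 2e6), "decay")
  expect_error(train_config("paper", lr_final = 1e-4), "lr_final")
})

test_that("a step updates the generators but never the frozen extractor", {
  st <- micro_state(seed = 2)
  ds <- micro_dataset(seed = 3)
  r <- train_step(st, ds$domain_x[[1]], ds$domain_y[[1]])
  ns <- asNamespace("ldctgan")
  moved <- function(a, b) ns$nested_sumabs(ns$nested_map(`-`, a, b)) > 0
  expect_true(moved(r$state$G$params, st$G$params))
  expect_true(moved(r$state$F$params, st$F$params))
  expect_true(moved(r$state$Dx$params, st$Dx$params))
  expect_identical(r$state$phi, st$phi)
  expect_s3_class(r$bundle, "ldct_loss_bundle")
  expect_true(is.finite(r$bundle$total))
  expect_equal(r$state$step, 1L)
})

test_that("cycle and perceptual terms route no gradient into the discriminators", {
  ds <- micro_dataset(seed = 3)
  st0 <- micro_state(seed = 2)
  stA <- stB <- st0
  stA$loss_cfg <- loss_config(lambda_cyc = 0, perceptual_weights = c(0, 0),
                              adversarial_form = "least_squares")
  stB$loss_cfg <- loss_config(lambda_cyc = 10,
                              adversarial_form = "least_squares")
  rA <- train_step(stA, ds$domain_x[[1]], ds$domain_y[[1]])
  rB <- train_step(stB, ds$domain_x[[1]], ds$domain_y[[1]])
  # discriminator updates identical whatever the cycle/perceptual weights
  expect_identical(rA$state$Dx$params, rB$state$Dx$params)
  expect_identical(rA$state$Dy$params, rB$state$Dy$params)
  # generator updates are not
  expect_false(identical(rA$state$G$params, rB$state$G$params))
})

test_that("identically seeded runs are identical and checkpoints resume exactly", {
  ds <- micro_dataset(seed = 6)
  run <- function() {
    st <- micro_state(seed = 4)
    s <- asNamespace("ldctgan")$dataset_sampler(ds, seed = 4)
    traj <- numeric(0)
    for (i in 1:6) {
      b <- s()
      r <- train_step(st, b$x, b$y)
      st <- r$state
      traj <- c(traj, r$bundle$total)
    }
    list(st = st, traj = traj)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$traj, r2$traj)
  expect_identical(r1$st$G$params, r2$st$G$params)
  # checkpoint round-trip is bit-exact
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(r1$st, ck)
  expect_identical(load_checkpoint(ck)$G$params, r1$st$G$params)
})

test_that("train() resumes from a checkpoint onto the uninterrupted trajectory", {
  ds <- micro_dataset(seed = 6)
  out1 <- tempfile("full_"); out2 <- tempfile("half_")
  cfg10 <- train_config("tiny", seed = 3, total_steps = 10L,
                        decay_start_step = 5L, decay_end_step = 10L,
                        checkpoint_every = 5L)
  gcfg <- generator_config(channels = 8L, redcnn_layers = 2L, unet_stages = 2L,
                           reduction_dim = 4L, input_size = 32L,
                           residual = TRUE, clamp_output = TRUE)
  dcfg <- discriminator_config(32L, 8L)
  lcfg <- loss_config(adversarial_form = "least_squares")
  ck_full <- train(ds, cfg10, gcfg, dcfg, lcfg, phi_width_scale = 1 / 16,
                   out_dir = out1)
  log_full <- attr(ck_full, "log")
  # the periodic step-5 checkpoint of the same run restarts mid-schedule
  ck_res <- train(ds, out_dir = out2,
                  resume_from = file.path(out1, "ckpt_000005.rds"))
  log_res <- attr(ck_res, "log")
  expect_equal(log_res$total, log_full$total[6:10], tolerance = 1e-12)
  expect_identical(load_checkpoint(ck_res)$G$params,
                   load_checkpoint(ck_full)$G$params)
})

test_that("train() validates its dataset", {
  ds <- micro_dataset(seed = 6)
  ds$domain_y <- list()
  expect_error(train(ds), "empty")
})

test_that("non-finite activations abort the step with a diagnostic", {
  st <- micro_state(seed = 2)
  bad <- matrix(Inf, 32, 32)
  expect_error(train_step(st, bad, matrix(0.5, 32, 32)))
})

test_that("denoise preserves shape, is deterministic, and tiles seamlessly when trivial", {
  st <- micro_state(seed = 5)
  imgs <- list(matrix(runif(1024), 32, 32), matrix(runif(1024), 32, 32))
  o1 <- denoise(imgs, st)
  expect_equal(dim(o1[[1]]), c(32L, 32L))
  expect_identical(o1, denoise(imgs, st))
  # an input that fits in one tile takes the direct path bit-for-bit
  expect_identical(denoise(imgs[[1]], st, tile = 32L),
                   generate(st$G, imgs[[1]]))
  # larger inputs tile-and-blend (64 = 2x2 tiles of 32 with overlap)
  big <- matrix(runif(64 * 64), 64, 64)
  ob <- denoise(big, st, tile = 32L)
  expect_equal(dim(ob), c(64L, 64L))
  expect_true(all(is.finite(ob)))
})
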