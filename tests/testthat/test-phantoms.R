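ns <- asNamespace("ldctgan")

test_that("phantoms are deterministic, bounded, and structured", {
  sp <- phantom_spec(image_size = 64L, n_ellipses = 5L, seed = 7L)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  # no structures requested -> uniform background
  flat <- make_phantom(phantom_spec(image_size = 64L, n_ellipses = 0L,
                                    include_lung_regions = FALSE))
  expect_equal(length(unique(as.numeric(flat))), 1L)
  # background + body (+ tissue) give a multi-modal histogram
  h <- table(round(as.numeric(a), 3))
  modes <- h[h > 50]
  expect_gte(length(modes), 2L)
})

test_that("phantom_spec validates its fields", {
  expect_error(phantom_spec(image_size = 1), "image_size")
  expect_error(phantom_spec(n_ellipses = -1), "n_ellipses")
  expect_error(phantom_spec(intensity_range = c(0.9, 0.1)), "intensity_range")
})

test_that("patch extraction enumerates the sliding grid in row-major order", {
  img <- matrix(seq_len(64 * 64), 64, 64)
  ps <- extract_patches(img, 32L, 32L)
  expect_length(ps, 4L)
  expect_equal(ps[[1]], img[1:32, 1:32], ignore_attr = TRUE)
  # row-major: columns advance first
  expect_equal(ps[[2]], img[1:32, 33:64], ignore_attr = TRUE)
  expect_equal(ps[[4]], img[33:64, 33:64], ignore_attr = TRUE)
  # single exact fit returns the input
  one <- extract_patches(img, 64L, 16L)
  expect_length(one, 1L)
  expect_equal(one[[1]], img, ignore_attr = TRUE)
  expect_error(extract_patches(img, 128L, 16L), "128")
})

test_that("patch counts equal brute-force offset enumeration", {
  set.seed(3)
  for (i in 1:50) {
    H <- sample(10:70, 1); W <- sample(10:70, 1)
    p <- sample(3:min(H, W), 1); s <- sample(1:12, 1)
    img <- matrix(0, H, W)
    expect_length(extract_patches(img, p, s), naive_patch_count(H, W, p, s))
  }
})

test_that("the noiseless dose limit reproduces plain filtered back-projection", {
  ph <- make_phantom(phantom_spec(image_size = 48L, n_ellipses = 3L, seed = 2L))
  rec <- fbp_reconstruct(radon_transform(ph, 90L))
  rec <- pmin(pmax(rec, 0), 1)
  nl <- simulate_low_dose(ph, dose_model(photons_i0 = 1e12, n_angles = 90L,
                                         electronic_noise_sd = 0), seed = 1)
  expect_lt(max(abs(nl - rec)), 1e-3)
  # and the reconstruction itself is a faithful (if imperfect) inverse
  expect_gt(psnr(rec, ph), 25)
})

test_that("low-dose simulation is seed-deterministic and dose-monotone", {
  ph <- make_phantom(phantom_spec(image_size = 32L, n_ellipses = 3L, seed = 4L))
  d <- dose_model(photons_i0 = 800, n_angles = 60L)
  expect_identical(simulate_low_dose(ph, d, seed = 9),
                   simulate_low_dose(ph, d, seed = 9))
  ref <- ns$clean_reference(ph, d)
  noise_var <- function(i0) {
    dd <- dose_model(photons_i0 = i0, n_angles = 60L)
    mean(sapply(1:6, function(s)
      mean((simulate_low_dose(ph, dd, seed = s) - ref)^2)))
  }
  vs <- sapply(c(300, 2400, 2e4), noise_var)
  expect_true(all(diff(vs) < 0))
})

test_that("dose model rejects non-physical settings", {
  expect_error(dose_model(photons_i0 = 0), "photons_i0")
  expect_error(dose_model(n_angles = 1), "n_angles")
  expect_error(simulate_low_dose(matrix(2, 4, 4), dose_model()), "\\[0, 1\\]")
})

test_that("unpaired dataset construction honors counts, determinism and cohort disjointness", {
  ds <- build_unpaired_dataset(n_subjects_x = 1, n_subjects_y = 1,
                               slices_per_subject = 1, image_size = 64,
                               dose = dose_model(noise_model = "gaussian"),
                               patch_size = 32, stride = 32,
                               n_eval_slices = 0, seed = 3)
  expect_length(ds$domain_x, 4L)
  expect_length(ds$domain_y, 4L)
  ds2 <- build_unpaired_dataset(n_subjects_x = 1, n_subjects_y = 1,
                                slices_per_subject = 1, image_size = 64,
                                dose = dose_model(noise_model = "gaussian"),
                                patch_size = 32, stride = 32,
                                n_eval_slices = 0, seed = 3)
  expect_identical(ds, ds2)
  expect_error(build_unpaired_dataset(subjects_x = 1:2, subjects_y = 2:3,
                                      image_size = 32, patch_size = 32,
                                      n_eval_slices = 0),
               "disjoint")
})

test_that("the paired evaluation split exists only outside the training path", {
  ds <- micro_dataset(seed = 8)
  expect_length(ds$eval$x, 1L)
  expect_identical(ds$eval$paired_index, seq_along(ds$eval$x))
  # noise strictly degrades the paired patches
  p <- psnr(ds$eval$x[[1]], ds$eval$clean[[1]])
  expect_true(is.finite(p))
  # the training sampler reads only the two domains: stripping the eval
  # split leaves its stream untouched
  ds_strip <- ds
  ds_strip$eval <- NULL
  s1 <- ns$dataset_sampler(ds, seed = 4)
  s2 <- ns$dataset_sampler(ds_strip, seed = 4)
  for (i in 1:10) expect_identical(s1(), s2())
})
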