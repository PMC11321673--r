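test_that("degradation reproduces the hand-computed worked examples", {
  # unpolarized target J = 0.6 behind uniform smoke t = 0.5, A_inf = 0.8,
  # fully co-polarized ambient
  sc <- scene_truth(matrix(0.6, 4, 4), matrix(0.5, 4, 4),
                    ambient_total = 0.8, noise_sigma = 0)
  im <- degrade(sc)
  expect_equal(im$i0[1, 1], 0.55)
  expect_equal(im$i45[1, 1], 0.35)
  expect_equal(im$i90[1, 1], 0.15)
  expect_equal(im$i135[1, 1], 0.35)
  expect_equal(direct_pd(im)[1, 1], 0.4)   # = A_inf (1 - t)

  # pure smoke: t = 0 everywhere
  sc0 <- scene_truth(matrix(0.6, 4, 4), matrix(0, 4, 4),
                     ambient_total = 0.8, noise_sigma = 0)
  im0 <- degrade(sc0)
  expect_equal(im0$i0[1, 1], 0.8)
  expect_equal(im0$i45[1, 1], 0.4)
  expect_equal(im0$i90[1, 1], 0)
  expect_equal(im0$i135[1, 1], 0.4)

  # no smoke: every channel is half the unpolarized radiance
  sc1 <- scene_truth(matrix(0.6, 4, 4), matrix(1, 4, 4), noise_sigma = 0)
  im1 <- degrade(sc1)
  for (ch in c("i0", "i45", "i90", "i135")) {
    expect_equal(im1[[ch]], matrix(0.3, 4, 4))
  }
})

test_that("noise-free channels satisfy the Stokes consistency identity", {
  sc <- make_phantom_scene(c(24, 36), "tissue_texture", seed = 3,
                           ambient_dolp = 0.7, noise_sigma = 0)
  im <- degrade(sc)
  expect_equal(im$i0 + im$i90, im$i45 + im$i135, tolerance = 1e-9)
})

test_that("direct PD equals the analytic backscatter for co-polarized ambient", {
  tf <- make_transmission_field(c(16, 16), "smooth_noise", seed = 2,
                                t_min_truth = 0.1, t_max_truth = 0.9)
  sc <- scene_truth(matrix(0.4, 16, 16), tf, ambient_total = 0.7,
                    ambient_dolp = 1, noise_sigma = 0)
  im <- degrade(sc)
  expect_equal(direct_pd(im), 0.7 * (1 - tf), tolerance = 1e-12)
})

test_that("smoke-only pixels carry no target information", {
  t0 <- matrix(0, 8, 8)
  im_a <- degrade(scene_truth(matrix(0.1, 8, 8), t0, noise_sigma = 0))
  im_b <- degrade(scene_truth(matrix(0.9, 8, 8), t0, noise_sigma = 0))
  for (ch in c("i0", "i45", "i90", "i135")) {
    expect_identical(im_a[[ch]], im_b[[ch]])
  }
})

test_that("degradation with noise is reproducible under a fixed seed", {
  sc <- make_phantom_scene(c(16, 16), "tissue_texture", seed = 9,
                           noise_sigma = 0.01)
  expect_identical(degrade(sc), degrade(sc))
})

test_that("ambient polarization axis steers the channel split", {
  # vertically polarized ambient: the cross channel carries the smoke
  sc <- scene_truth(matrix(0.6, 4, 4), matrix(0, 4, 4), ambient_total = 0.8,
                    ambient_axis = 90, noise_sigma = 0)
  im <- degrade(sc)
  expect_equal(im$i0[1, 1], 0)
  expect_equal(im$i90[1, 1], 0.8)
  at <- ambient_truth(sc)
  expect_equal(unname(at), c(0, 0.4, 0.8, 0.4))
})

test_that("transmission fields honor kind, range and seed", {
  tc <- make_transmission_field(c(10, 12), "constant", value = 0.7)
  expect_identical(tc, matrix(0.7, 10, 12))

  tb1 <- make_transmission_field(c(32, 32), "blobs", seed = 5)
  tb2 <- make_transmission_field(c(32, 32), "blobs", seed = 5)
  expect_identical(tb1, tb2)
  # blob centers reach the configured floor, background stays near the top
  expect_equal(min(tb1), 0)
  expect_gt(max(tb1), 0.9)

  ts1 <- make_transmission_field(c(32, 32), "smooth_noise", seed = 1,
                                 t_min_truth = 0.2, t_max_truth = 0.8)
  expect_gte(min(ts1), 0.2)
  expect_lte(max(ts1), 0.8)
})

test_that("phantoms are deterministic with documented structure", {
  cc <- make_phantom(c(48, 72), "color_checker")
  expect_equal(dim(cc), c(48, 72, 3))
  # 24 constant patches: the top-left patch is constant over its block
  expect_equal(length(unique(as.vector(cc[1:12, 1:12, 1]))), 1L)
  patch_vals <- unique(round(as.vector(cc[, , 1]), 6))
  expect_lte(length(patch_vals), 24)

  rb <- make_phantom(c(50, 64), "resolution_bars")
  expect_true(is.matrix(rb))
  expect_setequal(unique(as.vector(rb)), c(0.1, 0.9))
  # finest band alternates every 2 columns
  bottom <- rb[50, ]
  expect_equal(bottom[1:4], c(0.1, 0.1, 0.9, 0.9))

  tt1 <- make_phantom(c(32, 32), "tissue_texture", seed = 4)
  tt2 <- make_phantom(c(32, 32), "tissue_texture", seed = 4)
  expect_identical(tt1, tt2)
  expect_true(all(tt1 >= 0 & tt1 <= 1))
})

test_that("shape and range violations are rejected", {
  expect_error(scene_truth(matrix(0.5, 4, 4), matrix(0.5, 5, 5)), "match")
  expect_error(scene_truth(matrix(0.5, 4, 4), matrix(2, 4, 4)), "\\[0, 1\\]")
  expect_error(scene_truth(matrix(0.5, 4, 4), matrix(0.5, 4, 4),
                           ambient_total = 0), "ambient_total")
  expect_error(polarized_images(matrix(0, 2, 2), matrix(0, 2, 2),
                                matrix(0, 2, 2), matrix(0, 3, 3)),
               "share one shape")
})
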