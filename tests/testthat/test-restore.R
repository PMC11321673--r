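pd_coeffs <- refined_pd_coefficients(canonical_fit)

const_images <- function(i0, i45, i90, i135) {
  polarized_images(matrix(i0, 3, 3), matrix(i45, 3, 3),
                   matrix(i90, 3, 3), matrix(i135, 3, 3))
}

test_that("direct PD subtracts channels and clamps at zero", {
  expect_equal(direct_pd(const_images(0.55, 0.3, 0.15, 0.3))[1, 1], 0.4)
  expect_equal(direct_pd(const_images(0.3, 0.3, 0.3, 0.3))[1, 1], 0)
  expect_equal(direct_pd(const_images(0.3, 0.5, 0.4, 0.5))[1, 1], 0)
})

test_that("refined PD evaluates the fitted channel weights", {
  im <- const_images(0.8, 0.5, 0.3, 0.6)
  expect_equal(refined_pd(im, pd_coeffs)[1, 1], 0.5889, tolerance = 1e-3)
  expect_equal(refined_pd(const_images(0, 0, 0, 0), pd_coeffs)[1, 1], 0)
  expect_equal(refined_pd(const_images(0.5, 0.5, 0.5, 0.5),
                          pd_coeffs)[1, 1], 0.2339, tolerance = 1e-3)
  # ambient clamp
  expect_equal(refined_pd(im, pd_coeffs, a_inf_co = 0.5)[1, 1], 0.5)
  expect_error(refined_pd(im, fit = canonical_fit), "unused|coeffs")
  expect_error(refined_pd_coefficients(
    fit_weight_vector(target_curve(), c(0, 30, 90))), "basis")
})

test_that("channel weights are derived from the coefficients", {
  w <- polarsmoke:::refined_pd_weights(pd_coeffs)
  expect_equal(unname(w), c(1 - pd_coeffs$a / 2, -pd_coeffs$b / 2,
                            -pd_coeffs$c / 2))
  expect_equal(unname(w), c(0.7182, 0.4471, -0.6975), tolerance = 1e-3)
})

test_that("ambient estimation recovers the generated airlight", {
  # pure smoke image: every pixel supports the estimate exactly
  sc0 <- scene_truth(matrix(0.6, 12, 12), matrix(0, 12, 12),
                     ambient_total = 0.8, noise_sigma = 0)
  im0 <- degrade(sc0)
  est <- estimate_ambient(im0, direct_pd(im0))
  expect_equal(unname(est$a_inf_pol), unname(ambient_truth(sc0)),
               tolerance = 1e-12)
  expect_equal(est$a_inf_co, 0.8)

  # scene with an embedded smoke-only region, automatic pooling
  sc <- make_phantom_scene(c(64, 64), "tissue_texture", seed = 21)
  im <- degrade(sc)
  est2 <- estimate_ambient(im, apply(direct_pd(im), c(1, 2), mean))
  expect_lt(max(abs(est2$a_inf_co - 0.8)) / 0.8, 0.02)

  # explicit ROI: plain masked means
  roi <- matrix(FALSE, 12, 12); roi[1:3, 1:3] <- TRUE
  est3 <- estimate_ambient(im0, direct_pd(im0), strategy = "roi", roi = roi)
  expect_equal(est3$a_inf_pol[["i45"]], mean(im0$i45[roi]))
  expect_error(estimate_ambient(im0, direct_pd(im0), strategy = "roi",
                                roi = matrix(FALSE, 12, 12)), "empty")
})

test_that("transmission map inverts the degradation model with clamping", {
  pd <- matrix(c(0, 0.25, 0.6, 0.1), 2, 2)
  tm <- transmission_map(pd, a_inf_co = 0.5, t_min = 0.05)
  expect_equal(tm$t[1, 1], 1)
  expect_equal(tm$t[2, 1], 0.5)
  expect_equal(tm$t[1, 2], 0.05)   # 1 - 0.6/0.5 < 0 -> floored
  expect_equal(tm$t[2, 2], 0.8)
  expect_error(transmission_map(pd, a_inf_co = 0), "a_inf_co")
})

test_that("single-channel restoration inverts the forward mixing", {
  t1 <- transmission_map(matrix(0, 2, 2), 0.5)   # t == 1
  img <- matrix(c(0.2, 0.5, 0.7, 0.9), 2, 2)
  expect_equal(restore_channel(img, t1, 0.8), img)
  t5 <- structure(list(t = matrix(0.5, 2, 2), t_min = 0.05),
                  class = "transmission_map")
  expect_equal(restore_channel(matrix(0.55, 2, 2), t5, 0.8)[1, 1], 0.3)
  # a pixel at the ambient level stays at the ambient level for any t
  expect_equal(restore_channel(matrix(0.8, 2, 2), t5, 0.8),
               matrix(0.8, 2, 2))
})

test_that("degrade then restore with oracle parameters is the identity", {
  tf <- make_transmission_field(c(24, 32), "blobs", t_min_truth = 0.3,
                                t_max_truth = 0.95, seed = 13)
  sc <- scene_truth(make_phantom(c(24, 32), "tissue_texture", seed = 13),
                    tf, noise_sigma = 0)
  out <- restore(degrade(sc), method = "POL", ambient = ambient_truth(sc),
                 t_min = 1e-6)
  clean_im <- degrade(scene_truth(sc$clean, matrix(1, 24, 32),
                                  noise_sigma = 0))
  expect_equal(out$transmission$t, array(rep(tf, 3), c(24, 32, 3)),
               tolerance = 1e-6)
  for (ch in c("j0", "j45", "j90", "j135")) {
    expect_equal(out[[ch]], clean_im[[sub("j", "i", ch)]], tolerance = 1e-6)
  }
  expect_equal(out$s0, clean_im$i0 + clean_im$i90, tolerance = 1e-6)
})

test_that("restoration deviation grows as transmission falls", {
  img <- matrix(0.7, 4, 4)
  devs <- vapply(c(0.9, 0.6, 0.4, 0.2), function(tv) {
    tm <- transmission_map(matrix(0.8 * (1 - tv), 4, 4), 0.8, t_min = 0.01)
    mean(abs(restore_channel(img, tm, 0.8) - img))
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
  # where the PD is zero the restoration is a no-op
  tm1 <- transmission_map(matrix(0, 4, 4), 0.8)
  expect_equal(restore_channel(img, tm1, 0.8), img)
})

test_that("transmission and ambient are recovered accurately over seeds", {
  errs <- vapply(1:8, function(s) {
    sc <- make_phantom_scene(c(64, 64), "tissue_texture", seed = s)
    out <- restore(degrade(sc), method = "POL")
    t_hat <- apply(out$transmission$t, c(1, 2), mean)
    c(t = sqrt(mean((t_hat - sc$transmission)^2)),
      a = max(abs(out$ambient$a_inf_co - 0.8)) / 0.8)
  }, numeric(2))
  expect_lt(max(errs["t", ]), 0.02)
  expect_lt(max(errs["a", ]), 0.02)
})

test_that("direct PD is exact for co-polarized ambient, refined PD wins when depolarized", {
  # smoke-only pixels expose the estimators directly
  t0 <- matrix(0, 6, 6)
  truth_a <- 0.8
  # P_A = 1: direct PD recovers A exactly, refined PD is biased
  im1 <- degrade(scene_truth(matrix(0.5, 6, 6), t0, ambient_total = truth_a,
                             ambient_dolp = 1, noise_sigma = 0))
  err_direct_1 <- abs(direct_pd(im1)[1, 1] - truth_a)
  err_refined_1 <- abs(refined_pd(im1, pd_coeffs)[1, 1] - truth_a)
  expect_lt(err_direct_1, 1e-12)
  expect_gt(err_refined_1, 0.01)
  # P_A = 0.5: refined PD is strictly closer (0.588 A vs 0.5 A)
  im5 <- degrade(scene_truth(matrix(0.5, 6, 6), t0, ambient_total = truth_a,
                             ambient_dolp = 0.5, noise_sigma = 0))
  expect_equal(direct_pd(im5)[1, 1] / truth_a, 0.5, tolerance = 1e-9)
  expect_equal(refined_pd(im5, pd_coeffs)[1, 1] / truth_a, 0.588,
               tolerance = 1e-3)
  for (pa in c(0.3, 0.5, 0.6)) {
    im <- degrade(scene_truth(matrix(0.5, 6, 6), t0, ambient_total = truth_a,
                              ambient_dolp = pa, noise_sigma = 0))
    expect_lt(abs(refined_pd(im, pd_coeffs)[1, 1] - truth_a),
              abs(direct_pd(im)[1, 1] - truth_a))
  }
})

test_that("RPOL restoration improves similarity to the clean scene", {
  sc <- make_phantom_scene(c(48, 72), "color_checker", seed = 11,
                           ambient_dolp = 0.7)
  im <- degrade(sc)
  out <- restore(im, method = "RPOL")
  smoky <- pmin(im$i0 + im$i90, 1)
  restored <- pmin(out$s0, 1)
  expect_gt(ssim(sc$clean, restored), ssim(sc$clean, smoky))
  g <- glance(out)
  expect_identical(g$method, "RPOL")
  expect_identical(g$ambient_strategy, "auto_percentile")
})

test_that("oracle ambient vectors are validated", {
  im <- const_images(0.5, 0.4, 0.3, 0.4)
  expect_error(restore(im, ambient = c(0.8, 0.4, 0.1, 0.4)), "named")
  out <- restore(im, method = "POL",
                 ambient = c(i0 = 0.8, i45 = 0.4, i90 = 0.1, i135 = 0.4))
  expect_s3_class(out, "restoration_result")
  expect_identical(out$ambient$strategy, "oracle")
})
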