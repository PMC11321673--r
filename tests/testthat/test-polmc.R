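smoke_medium <- function(mu_s) medium_spec(smoke_mie, mu_s = mu_s)

test_that("energy ledger closes and the run is seed-deterministic", {
  cfg <- sim_config(n_photons = 10000, seed = 3, n_grid = 50)
  g1 <- run_simulation(cfg, smoke_medium(0.62))
  g2 <- run_simulation(cfg, smoke_medium(0.62))
  led <- g1$ledger
  gap <- led[["launched"]] - sum(led[c("detected_top", "transmitted_bottom",
                                       "absorbed", "lost_side")])
  expect_lt(abs(gap) / led[["launched"]], 1e-6)
  expect_identical(g1$stokes, g2$stokes)
  expect_identical(g1$efd, g2$efd)
})

test_that("a clear slab over an absorbing surface sends everything down", {
  # index-matched, zero-albedo lower boundary absorbs the whole beam
  med <- medium_spec(smoke_mie, mu_s = 0, mu_a = 0, surface_index = 1,
                     diffuse_albedo = 0)
  g <- run_simulation(sim_config(n_photons = 2000, seed = 1, n_grid = 20), med)
  expect_equal(g$ledger[["detected_top"]], 0)
  expect_equal(g$ledger[["transmitted_bottom"]], 2000)
})

test_that("without scattering all detected photons carry the target tag", {
  med <- medium_spec(smoke_mie, mu_s = 0, mu_a = 0, surface_index = 1,
                     diffuse_albedo = 1)
  g <- run_simulation(sim_config(n_photons = 2000, seed = 2, n_grid = 20), med)
  expect_equal(sum(g$stokes[, , 1, 1]), 0)       # smoke-only accumulator empty
  expect_gt(sum(g$stokes[, , 1, 2]), 0)
})

test_that("detected per-pixel Stokes vectors stay physical", {
  g <- run_simulation(sim_config(n_photons = 20000, seed = 5, n_grid = 50),
                      smoke_medium(0.75))
  for (t in 1:2) {
    s <- g$stokes[, , , t]
    pol2 <- s[, , 2]^2 + s[, , 3]^2 + s[, , 4]^2
    expect_true(all(pol2 <= s[, , 1]^2 * (1 + 1e-9)))
    expect_true(all(s[, , 1] >= 0))
  }
})

test_that("S(theta) decreases with orientation angle for the simulated media", {
  for (mu in c(0.50, 0.62, 0.75)) {
    g <- run_simulation(sim_config(n_photons = 50000, seed = 1),
                        smoke_medium(mu))
    h <- efd_histogram(g, central_region(g))
    expect_lt(cor(h$theta, h$mass, method = "spearman"), 0)
    expect_true(all(h$mass >= 0))
    expect_lte(sum(h$mass), g$ledger[["detected_top"]] + 1e-9)
  }
})

test_that("forced zero-angle scattering leaves the photon state unchanged", {
  s <- scatter_photon(c(1, 1, 0, 0), smoke_mie, n = 1, seed = 1,
                      forced_theta = 0, forced_phi = 0)
  expect_equal(s$direction[1, ], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(s$stokes[1, ], c(1, 1, 0, 0), tolerance = 1e-9)
  # with a free azimuth the physical state is unchanged even though the
  # reference frame follows the sampled azimuth
  s2 <- scatter_photon(c(1, 1, 0, 0), smoke_mie, n = 5, seed = 2,
                       forced_theta = 0)
  expect_equal(s2$direction, matrix(rep(c(0, 0, 1), each = 5), 5),
               tolerance = 1e-12)
  dolp <- sqrt(s2$stokes[, 2]^2 + s2$stokes[, 3]^2 + s2$stokes[, 4]^2)
  expect_equal(dolp, rep(1, 5), tolerance = 1e-9)
})

test_that("Rayleigh scattering at 90 degrees fully polarizes unpolarized light", {
  mr <- compute_mie(particle_spec(0.02, 1.5 + 0i, 630), n_angles = 1801)
  s <- scatter_photon(c(1, 0, 0, 0), mr, n = 3, seed = 1,
                      forced_theta = pi / 2)
  dolp <- sqrt(s$stokes[, 2]^2 + s$stokes[, 3]^2)
  expect_equal(dolp, rep(1, 3), tolerance = 1e-3)
})

test_that("sampled angles follow the polarization-dependent joint density", {
  n <- 1e5
  s <- scatter_photon(c(1, 1, 0, 0), smoke_mie, n = n, seed = 42)
  tab <- smoke_mie$matrix_table
  th_br <- seq(0, pi, length.out = 19)
  ph_br <- seq(0, 2 * pi, length.out = 13)
  obs <- table(cut(s$theta, th_br), cut(s$phi, ph_br))
  thg <- seq(0, pi, length.out = 2001)
  s11 <- approx(deg2rad_t(tab$angle), tab$s11, thg)$y
  s12 <- approx(deg2rad_t(tab$angle), tab$s12, thg)$y
  expected <- outer(seq_len(18), seq_len(12), Vectorize(function(i, j) {
    thm <- thg >= th_br[i] & thg <= th_br[i + 1]
    phg <- seq(ph_br[j], ph_br[j + 1], length.out = 200)
    sum((s11 * sin(thg))[thm]) * diff(range(phg)) +
      sum((s12 * sin(thg))[thm]) * sum(cos(2 * phg)) * (phg[2] - phg[1])
  }))
  expected <- expected / sum(expected) * n
  keep <- expected > 5
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(chi, sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("surface interaction reproduces Fresnel reflectance", {
  n <- 40000
  # normal incidence on n = 1.5: R = ((1.5 - 1)/(1.5 + 1))^2 = 0.04
  s <- surface_interaction(c(1, 0, 0, 0), surface_index = 1.5, n = n,
                           seed = 7)
  r_hat <- mean(s$branch == 0)
  expect_equal(r_hat, 0.04, tolerance = 0.2)   # ~3 sigma of the binomial
  # grazing incidence reflects almost everything
  sg <- surface_interaction(c(1, 0, 0, 0), surface_index = 1.5, n = 2000,
                            seed = 8, direction = c(sqrt(1 - 1e-4), 0, 0.01))
  expect_gt(mean(sg$branch == 0), 0.9)
  # specular branch flips the vertical direction component
  sp <- s$direction[s$branch == 0, , drop = FALSE]
  expect_true(all(sp[, 3] == -1))
  # diffuse branch depolarizes and re-emits upward with reduced weight
  df <- which(s$branch == 1)
  expect_true(all(s$direction[df, 3] < 0))
  expect_true(all(s$stokes[df, 2:4] == 0))
  expect_true(all(s$weight[df] == 0.5))
})

test_that("electric-field bins follow the Q-folding rule", {
  expect_identical(classify_efd_bin(c(1, 1, 0, 0)), 1L)
  expect_identical(classify_efd_bin(c(1, -1, 0, 0)), 19L)
  expect_identical(classify_efd_bin(c(1, 0, 1, 0)), 10L)   # 45-degree bin
  expect_identical(classify_efd_bin(c(1, 0, -1, 0)), 10L)  # U sign folded
  expect_identical(classify_efd_bin(c(1, 0, 0, 0)), 10L)   # unpolarized
  expect_identical(classify_efd_bin(c(1, 0, 0, 1)), 10L)   # circular only
  m <- rbind(c(1, cos(deg2rad_t(10)), sin(deg2rad_t(10)), 0),
             c(1, cos(deg2rad_t(170)), sin(deg2rad_t(170)), 0))
  expect_identical(classify_efd_bin(m), c(2L, 18L))
  expect_error(classify_efd_bin(c(0, 0, 0, 0)), "I component")
})

test_that("the polarizer Mueller matrix obeys Malus' law", {
  expect_equal(drop(polarizer_mueller(0) %*% c(1, 0, 0, 0))[1], 0.5)
  for (th in c(0, 20, 45, 133)) {
    for (th0 in c(0, 30, 90)) {
      s_in <- c(1, cos(2 * deg2rad_t(th)), sin(2 * deg2rad_t(th)), 0)
      out <- drop(polarizer_mueller(th0) %*% s_in)
      expect_equal(out[1], cos(deg2rad_t(th0 - th))^2, tolerance = 1e-12)
    }
  }
  expect_equal(polarizer_mueller(30), polarizer_mueller(210),
               tolerance = 1e-12)
})

test_that("interval intensities act as an analyzer on the per-bin Stokes", {
  # one pixel, all mass in the 0-degree bin, fully co-polarized
  g <- manual_grid(list(`1` = c(2, 2, 0, 0)))
  expect_equal(interval_intensities(g, 0)$intensity[1], 2)
  expect_equal(interval_intensities(g, 90)$intensity[1], 0,
               tolerance = 1e-12)
  # uniform unpolarized bins: analyzed intensity independent of theta0
  gu <- manual_grid(rep(list(c(1, 0, 0, 0)), 19))
  for (th0 in c(0, 30, 45, 90)) {
    expect_equal(interval_intensities(gu, th0)$intensity, rep(0.5, 19))
  }
})

test_that("summed interval intensities equal analyzing the total Stokes", {
  g <- run_simulation(sim_config(n_photons = 20000, seed = 1),
                      smoke_medium(0.62))
  reg <- central_region(g)
  tot <- apply(g$stokes[, , , 1] + g$stokes[, , , 2], 3,
               function(m) sum(m[reg]))
  for (th0 in c(0, 30, 45, 90)) {
    direct <- drop(polarizer_mueller(th0)[1, ] %*% tot)
    expect_equal(sum(interval_intensities(g, th0, reg)$intensity), direct,
                 tolerance = 1e-9)
  }
})

test_that("histogram reconstruction matches the co/cross analyzers within 2%", {
  # the Q-only folding of the orientation bins preserves the information the
  # 0/90-degree analyzers use; oblique analyzers lose the U sign
  g <- run_simulation(sim_config(n_photons = 50000, seed = 1),
                      smoke_medium(0.62))
  reg <- central_region(g)
  h <- efd_histogram(g, reg)
  total <- sum(g$stokes[, , 1, 1][reg] + g$stokes[, , 1, 2][reg])
  for (th0 in c(0, 90)) {
    synth <- synthesize_intensity(h, th0)
    analyzed <- sum(interval_intensities(g, th0, reg)$intensity)
    expect_lt(abs(synth - analyzed) / total, 0.02)
  }
})

test_that("refined PD tracks the tagged backscatter truth better than direct PD", {
  g <- run_simulation(sim_config(n_photons = 50000, seed = 1),
                      smoke_medium(0.75))
  pc <- pd_curves(g, canonical_fit, central_region(g))
  expect_lte(sum(abs(pc$refined_pd - pc$truth)),
             sum(abs(pc$direct_pd - pc$truth)))
  # aggregate refined PD reproduces the closed form I0 - Icrog/2
  cf <- coef(canonical_fit)
  icrog_tot <- cf[[1]] * sum(pc$i0) + cf[[2]] * sum(pc$i45) +
    cf[[3]] * sum(pc$i90)
  expect_equal(sum(pc$refined_pd), sum(pc$i0) - icrog_tot / 2,
               tolerance = 1e-9)
})

test_that("a fully absorbed beam yields all-zero PD curves and truth", {
  med <- medium_spec(smoke_mie, mu_s = 0, mu_a = 0, surface_index = 1,
                     diffuse_albedo = 0)
  g <- run_simulation(sim_config(n_photons = 1000, seed = 1, n_grid = 20),
                      med)
  pc <- pd_curves(g, canonical_fit)
  expect_true(all(pc$direct_pd == 0))
  expect_true(all(pc$refined_pd == 0))
  expect_true(all(pc$truth == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(bin_width = 7), "divisible")
  expect_error(sim_config(n_photons = 0), "n_photons")
  expect_error(sim_config(source_stokes = c(1, 1, 1, 0)), "unphysical")
  expect_error(medium_spec(smoke_mie, mu_s = -1), "mu_s")
  expect_error(scatter_photon(c(1, 2, 0, 0), smoke_mie), "unphysical")
  expect_error(surface_interaction(c(1, 0, 0, 0),
                                   direction = c(0, 0, -1)), "downward")
  expect_error(pd_curves(run_simulation(sim_config(10, n_grid = 4),
                                        smoke_medium(0.5)),
                         fit = NULL), "pd_fit")
})
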