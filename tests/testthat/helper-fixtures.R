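# shared fixtures, computed once per test run

# large smoke particle (study conditions) probed at 630 nm
smoke_particle <- particle_spec(6.0, 1.57 + 0.43i, 630, density = 1.0e-6)
smoke_mie <- compute_mie(smoke_particle, n_angles = 1801)

# canonical weight-curve fit (19-point, 5-degree grid, basis {0, 45, 90})
canonical_fit <- fit_weight_vector()

# a synthetic mie_result with a prescribed matrix table (for CDF tests)
synthetic_mie <- function(angle, s11, s12 = NULL) {
  theta <- deg2rad_t(angle)
  norm <- 2 * pi * sum(diff(theta) * ((s11 * sin(theta))[-1] +
                                        (s11 * sin(theta))[-length(theta)]) / 2)
  s11 <- s11 / norm
  s12 <- if (is.null(s12)) rep(0, length(angle)) else s12 / norm
  structure(
    list(size_parameter = NA_real_, q_ext = NA_real_, q_sca = NA_real_,
         q_abs = NA_real_, asymmetry = NA_real_,
         matrix_table = tibble::tibble(angle = angle, s11 = s11, s12 = s12,
                                       s33 = s11, s34 = 0)),
    class = "mie_result")
}

deg2rad_t <- function(x) x * pi / 180

# detection_grid built by hand from a list of per-bin Stokes rows,
# placed in a single pixel, for exercising the analysis helpers
manual_grid <- function(bin_stokes, bin_width = 5) {
  nb <- 90 / bin_width + 1
  efd <- array(0, c(1, 1, nb, 4, 2))
  for (b in seq_along(bin_stokes)) {
    if (!is.null(bin_stokes[[b]])) efd[1, 1, b, , 1] <- bin_stokes[[b]]
  }
  stokes <- array(0, c(1, 1, 4, 2))
  stokes[1, 1, , 1] <- apply(efd[1, 1, , , 1, drop = FALSE], 4, sum)
  structure(
    list(stokes = stokes, efd = efd,
         ledger = c(launched = 1, detected_top = 1, transmitted_bottom = 0,
                    absorbed = 0, lost_side = 0),
         n_capped = 0L, bin_width = bin_width, n_bins_efd = nb,
         config = sim_config(n_photons = 1),
         medium = medium_spec(smoke_mie, mu_s = 0.62)),
    class = "detection_grid")
}
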