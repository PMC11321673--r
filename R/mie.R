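#' Define a spherical scattering particle
#'
#' Bundles the single-particle optical parameters used throughout the
#' transport model: the sphere diameter, its complex refractive index
#' relative to the host medium, the vacuum wavelength of the illumination,
#' and the particle number density of the bulk medium. The default values
#' describe a large surgical-smoke particle (6 um droplet/soot aggregate)
#' probed at 630 nm.
#'
#' @param diameter Sphere diameter in micrometres. Must be > 0.
#' @param index Complex refractive index relative to the host medium, e.g.
#'   `1.57 + 0.43i` for smoke. The imaginary part (absorption) must be >= 0.
#' @param wavelength Vacuum wavelength in nanometres. Must be > 0.
#' @param density Particle number density in particles per cubic micrometre
#'   (um^-3). Must be >= 0. Only used when converting single-particle cross
#'   sections into bulk attenuation coefficients.
#'
#' @return An object of class `particle_spec`.
#' @examples
#' particle_spec(6.0, 1.57 + 0.43i, 630, 1.0e-6)
#' @export
particle_spec <- function(diameter = 6.0, index = 1.57 + 0.43i,
                          wavelength = 630, density = 0) {
  index <- as.complex(index)
  if (!is.finite(diameter) || diameter <= 0) {
    stop_input("`diameter` must be a finite positive length (um), got %s", diameter)
  }
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop_input("`wavelength` must be a finite positive length (nm), got %s", wavelength)
  }
  if (!is.finite(Re(index)) || !is.finite(Im(index)) || Im(index) < 0) {
    stop_input("`index` must be finite with non-negative imaginary part")
  }
  if (!is.finite(density) || density < 0) {
    stop_input("`density` must be a finite non-negative number density (um^-3)")
  }
  structure(
    list(diameter = diameter, index = index, wavelength = wavelength,
         density = density),
    class = "particle_spec"
  )
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf(
    "<particle_spec> d = %g um, m = %g%+gi, lambda = %g nm, n = %g um^-3\n",
    x$diameter, Re(x$index), Im(x$index), x$wavelength, x$density))
  invisible(x)
}

#' Lorenz-Mie solution for a homogeneous sphere
#'
#' Computes the Mie coefficients for a single sphere and derives the
#' extinction, scattering and absorption efficiencies, the asymmetry
#' parameter g, and the angle-resolved scattering (Mueller) matrix entries
#' S11, S12, S33, S34 on a uniform polar-angle grid. The series is truncated
#' at the Wiscombe criterion `x + 4 x^(1/3) + 2` and the logarithmic
#' derivative is evaluated by downward recurrence, the standard numerically
#' stable scheme for absorbing spheres.
#'
#' S11 is normalized as a phase function: its integral over the full sphere
#' of directions equals 1, so that `2 * pi * integral(S11(theta) *
#' sin(theta))` is unity. The remaining matrix entries are scaled by the
#' same factor, preserving the ratios S12/S11 etc. that drive polarized
#' scattering.
#'
#' @param particle A [particle_spec()].
#' @param n_angles Number of points of the uniform angle grid on
#'   \[0, 180\] degrees (endpoints included). At least 19. The default
#'   (1801, i.e. 0.1 degree spacing) resolves the forward peak of large
#'   particles well enough for accurate cumulative-distribution inversion.
#'
#' @return An object of class `mie_result`: a list with `size_parameter`,
#'   `q_ext`, `q_sca`, `q_abs`, `asymmetry`, and `matrix_table`, a tibble
#'   with columns `angle` (degrees), `s11`, `s12`, `s33`, `s34`.
#' @examples
#' mie <- compute_mie(particle_spec(6.0, 1.57 + 0.43i, 630), n_angles = 361)
#' mie$q_ext
#' @export
compute_mie <- function(particle, n_angles = 1801) {
  stopifnot(inherits(particle, "particle_spec"))
  if (!is.numeric(n_angles) || length(n_angles) != 1 || !is.finite(n_angles) ||
      n_angles < 19) {
    stop_input("`n_angles` must be a single integer >= 19")
  }
  n_angles <- as.integer(n_angles)

  lambda_um <- particle$wavelength * 1e-3
  x <- pi * particle$diameter / lambda_um
  m <- particle$index

  series <- mie_series(m, x)
  an <- series$an
  bn <- series$bn
  nmax <- length(an)
  n <- seq_len(nmax)

  q_ext <- (2 / x^2) * sum((2 * n + 1) * Re(an + bn))
  q_sca <- (2 / x^2) * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))
  q_abs <- q_ext - q_sca

  # asymmetry parameter from the standard series
  g_num <- 0
  if (nmax > 1) {
    k <- seq_len(nmax - 1)
    g_num <- sum(k * (k + 2) / (k + 1) *
                   Re(an[k] * Conj(an[k + 1]) + bn[k] * Conj(bn[k + 1])))
  }
  g_num <- g_num + sum((2 * n + 1) / (n * (n + 1)) * Re(an * Conj(bn)))
  asymmetry <- (4 / (x^2 * q_sca)) * g_num

  theta <- seq(0, pi, length.out = n_angles)
  amp <- mie_amplitudes(an, bn, cos(theta))
  s11 <- 0.5 * (Mod(amp$S1)^2 + Mod(amp$S2)^2)
  s12 <- 0.5 * (Mod(amp$S2)^2 - Mod(amp$S1)^2)
  s33 <- Re(amp$S2 * Conj(amp$S1))
  s34 <- Im(amp$S2 * Conj(amp$S1))

  # normalize S11 to a phase function: solid-angle integral = 1
  norm <- 2 * pi * trapz(theta, s11 * sin(theta))
  s11 <- s11 / norm
  s12 <- s12 / norm
  s33 <- s33 / norm
  s34 <- s34 / norm

  structure(
    list(
      particle = particle,
      size_parameter = x,
      q_ext = q_ext,
      q_sca = q_sca,
      q_abs = q_abs,
      asymmetry = asymmetry,
      matrix_table = tibble::tibble(
        angle = rad2deg(theta), s11 = s11, s12 = s12, s33 = s33, s34 = s34)
    ),
    class = "mie_result"
  )
}

# Mie coefficients a_n, b_n (Bohren-Huffman recurrences).
mie_series <- function(m, x) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  mx <- m * x
  nmx <- max(nmax, ceiling(Mod(mx))) + 16

  # logarithmic derivative D_n(mx), downward recurrence; slot j holds D_{j-1}
  D <- complex(nmx + 1)
  for (i in nmx:1) {
    D[i] <- i / mx - 1 / (D[i + 1] + i / mx)
  }
  D <- D[seq_len(nmax) + 1]              # D_1 .. D_nmax

  an <- complex(nmax)
  bn <- complex(nmax)
  psi_nm1 <- cos(x)   # psi_0(x) = sin? see below: psi_{-1} = cos x, psi_0 = sin x
  psi_n <- sin(x)
  chi_nm1 <- -sin(x)
  chi_n <- cos(x)
  for (k in seq_len(nmax)) {
    psi_k <- (2 * k - 1) / x * psi_n - psi_nm1
    chi_k <- (2 * k - 1) / x * chi_n - chi_nm1
    # xi_n = psi_n - i*chi_n (outgoing-wave convention, Im(m) >= 0 absorbing)
    xi_k <- complex(real = psi_k, imaginary = -chi_k)
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    da <- D[k] / m + k / x
    db <- D[k] * m + k / x
    an[k] <- (da * psi_k - psi_n) / (da * xi_k - xi_n)
    bn[k] <- (db * psi_k - psi_n) / (db * xi_k - xi_n)
    psi_nm1 <- psi_n; psi_n <- psi_k
    chi_nm1 <- chi_n; chi_n <- chi_k
  }
  list(an = an, bn = bn)
}

# scattering amplitudes S1(mu), S2(mu) via pi_n/tau_n recurrences,
# vectorized over the angle grid
mie_amplitudes <- function(an, bn, mu) {
  nmax <- length(an)
  S1 <- complex(length(mu))
  S2 <- complex(length(mu))
  pi_nm1 <- rep(0, length(mu))   # pi_0
  pi_n <- rep(1, length(mu))     # pi_1
  for (k in seq_len(nmax)) {
    tau_n <- k * mu * pi_n - (k + 1) * pi_nm1
    fac <- (2 * k + 1) / (k * (k + 1))
    S1 <- S1 + fac * (an[k] * pi_n + bn[k] * tau_n)
    S2 <- S2 + fac * (an[k] * tau_n + bn[k] * pi_n)
    pi_next <- ((2 * k + 1) * mu * pi_n - (k + 1) * pi_nm1) / k
    pi_nm1 <- pi_n
    pi_n <- pi_next
  }
  list(S1 = S1, S2 = S2)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Bulk attenuation coefficient of a monodisperse particle medium
#'
#' Converts a single-particle Mie efficiency into the attenuation
#' coefficient of a medium of identical, independently scattering spheres:
#' `coefficient = density * efficiency * pi * d^2 / 4`, converted to
#' cm^-1. With the default extinction convention this is `n * C_ext`; with
#' `convention = "scattering"` it is `n * C_sca`.
#'
#' @param particle A [particle_spec()] carrying the number density.
#' @param mie A [compute_mie()] result for the same particle.
#' @param convention Which cross section to use, `"extinction"` (default)
#'   or `"scattering"`.
#'
#' @return Attenuation coefficient in cm^-1.
#' @examples
#' p <- particle_spec(6.0, 1.57 + 0.43i, 630, density = 1.0e-6)
#' m <- compute_mie(p, n_angles = 181)
#' bulk_coefficient(p, m)                 # ~0.62 cm^-1
#' @export
bulk_coefficient <- function(particle, mie,
                             convention = c("extinction", "scattering")) {
  stopifnot(inherits(particle, "particle_spec"), inherits(mie, "mie_result"))
  convention <- match.arg(convention)
  q <- switch(convention, extinction = mie$q_ext, scattering = mie$q_sca)
  cross_um2 <- q * pi * particle$diameter^2 / 4
  # um^-3 * um^2 = um^-1; 1 um^-1 = 1e4 cm^-1
  particle$density * cross_um2 * 1e4
}

#' Cumulative distribution of the scattering angle
#'
#' Integrates the S11 phase function over solid angle to the tabulated
#' cumulative distribution used for inverse-transform sampling of the polar
#' scattering angle in the Monte Carlo transport.
#'
#' @param mie A [compute_mie()] result.
#' @return A tibble with columns `angle` (degrees, same grid as the matrix
#'   table) and `cdf`, monotone non-decreasing from 0 at 0 degrees to
#'   exactly 1 at 180 degrees.
#' @examples
#' m <- compute_mie(particle_spec(0.2, 1.5 + 0i, 630), n_angles = 181)
#' tail(phase_cdf(m), 2)
#' @export
phase_cdf <- function(mie) {
  stopifnot(inherits(mie, "mie_result"))
  tab <- mie$matrix_table
  theta <- deg2rad(tab$angle)
  integrand <- 2 * pi * tab$s11 * sin(theta)
  n <- length(theta)
  steps <- (theta[-1] - theta[-n]) * (integrand[-1] + integrand[-n]) / 2
  cdf <- c(0, cumsum(steps))
  total <- cdf[n]
  if (!is.finite(total) || total <= 0) {
    stop("phase function is not normalizable (all-zero or non-finite S11)",
         call. = FALSE)
  }
  tibble::tibble(angle = tab$angle, cdf = cdf / total)
}

#' @export
print.mie_result <- function(x, ...) {
  cat(sprintf(
    paste0("<mie_result> x = %.4g, Q_ext = %.4g, Q_sca = %.4g, ",
           "Q_abs = %.4g, g = %.4g\n"),
    x$size_parameter, x$q_ext, x$q_sca, x$q_abs, x$asymmetry))
  cat(sprintf("  matrix table: %d angles on [0, 180] deg\n",
              nrow(x$matrix_table)))
  invisible(x)
}

#' @rdname compute_mie
#' @param x A `mie_result`.
#' @param ... Unused.
#' @export
tidy.mie_result <- function(x, ...) x$matrix_table

#' @rdname compute_mie
#' @export
glance.mie_result <- function(x, ...) {
  tibble::tibble(
    size_parameter = x$size_parameter,
    q_ext = x$q_ext, q_sca = x$q_sca, q_abs = x$q_abs,
    asymmetry = x$asymmetry,
    n_angles = nrow(x$matrix_table)
  )
}

#' @rdname compute_mie
#' @param object A `mie_result`.
#' @export
autoplot.mie_result <- function(object, ...) {
  tab <- tidyr::pivot_longer(object$matrix_table, -"angle",
                             names_to = "entry", values_to = "value")
  ggplot2::ggplot(tab, ggplot2::aes(.data$angle, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~entry, scales = "free_y") +
    ggplot2::labs(x = "scattering angle (deg)", y = NULL,
                  title = sprintf("Mie scattering matrix, x = %.3g",
                                  object$size_parameter))
}
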