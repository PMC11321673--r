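#' Describe the bi-layer smoke-over-surface medium
#'
#' The transport model is a plane-parallel slab of scattering smoke of given
#' depth above a smooth dielectric surface (the target/tissue). Photons
#' scatter inside the slab according to the single-particle Mie matrix and
#' interact with the lower boundary by polarization-resolved Fresnel
#' reflection plus depolarized Lambertian diffuse re-emission.
#'
#' @param mie A [compute_mie()] result supplying the scattering matrix.
#' @param mu_s Scattering coefficient of the slab in cm^-1.
#' @param mu_a Absorption coefficient in cm^-1.
#' @param depth Slab depth in cm.
#' @param surface_index Refractive index of the lower boundary.
#' @param diffuse_albedo Fraction of the weight transmitted through the
#'   Fresnel interface that re-emerges as depolarized Lambertian light; the
#'   remainder is absorbed below the surface.
#' @return An object of class `medium_spec`. The optical depth
#'   `(mu_s + mu_a) * depth` is available via `optical_depth()`.
#' @examples
#' m <- compute_mie(particle_spec(), n_angles = 361)
#' med <- medium_spec(m, mu_s = 0.62)
#' optical_depth(med)
#' @export
medium_spec <- function(mie, mu_s, mu_a = 0.01, depth = 8,
                        surface_index = 1.5, diffuse_albedo = 0.5) {
  stopifnot(inherits(mie, "mie_result"))
  if (!is.finite(depth) || depth <= 0) stop_input("`depth` must be > 0 (cm)")
  if (!is.finite(mu_s) || mu_s < 0) stop_input("`mu_s` must be >= 0 (cm^-1)")
  if (!is.finite(mu_a) || mu_a < 0) stop_input("`mu_a` must be >= 0 (cm^-1)")
  if (!is.finite(surface_index) || surface_index < 1) {
    stop_input("`surface_index` must be >= 1")
  }
  structure(
    list(mie = mie, mu_s = mu_s, mu_a = mu_a, depth = depth,
         surface_index = surface_index, diffuse_albedo = diffuse_albedo),
    class = "medium_spec")
}

#' @rdname medium_spec
#' @param medium A `medium_spec`.
#' @export
optical_depth <- function(medium) {
  stopifnot(inherits(medium, "medium_spec"))
  (medium$mu_s + medium$mu_a) * medium$depth
}

#' Configure a polarized Monte Carlo run
#'
#' @param n_photons Number of launched photons.
#' @param seed Integer seed; every photon gets an independent, reproducible
#'   random substream derived from it.
#' @param source_stokes Stokes vector of the pencil-beam source; the default
#'   `(1, 1, 0, 0)` is horizontal linear polarization along the lab x axis.
#' @param bin_width Width of the electric-field-direction bins in degrees;
#'   must divide 90. The default 5 degrees gives the 19 bins 0, 5, ..., 90.
#' @param plane_size Side length of the square detection plane in cm.
#' @param n_grid Detection plane sampling, `n_grid x n_grid` pixels.
#' @param roulette_threshold,roulette_survival Russian-roulette weight
#'   threshold and survival probability.
#' @param max_steps Safety cap on transport events per photon; reaching it
#'   books the remaining weight as absorbed (prevents non-termination in
#'   degenerate media).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_photons = 50000, seed = 1,
                       source_stokes = c(1, 1, 0, 0), bin_width = 5,
                       plane_size = 25, n_grid = 100,
                       roulette_threshold = 1e-4, roulette_survival = 0.1,
                       max_steps = 1e6) {
  if (!is.finite(n_photons) || n_photons < 1) {
    stop_input("`n_photons` must be >= 1")
  }
  if (90 %% bin_width != 0) stop_input("90 must be divisible by `bin_width`")
  if (length(source_stokes) != 4 || source_stokes[1] <= 0) {
    stop_input("`source_stokes` must be a Stokes 4-vector with I > 0")
  }
  if (sum(source_stokes[2:4]^2) > source_stokes[1]^2 * (1 + 1e-12)) {
    stop_input("`source_stokes` is unphysical (Q^2+U^2+V^2 > I^2)")
  }
  structure(
    list(n_photons = as.integer(n_photons), seed = as.integer(seed),
         source_stokes = source_stokes, bin_width = bin_width,
         plane_size = plane_size, n_grid = as.integer(n_grid),
         roulette_threshold = roulette_threshold,
         roulette_survival = roulette_survival,
         max_steps = as.integer(max_steps)),
    class = "sim_config")
}

mie_tables <- function(mie) {
  tab <- mie$matrix_table
  cdf <- phase_cdf(mie)
  list(theta = deg2rad(tab$angle), s11 = tab$s11, s12 = tab$s12,
       s33 = tab$s33, s34 = tab$s34, cdf = cdf$cdf)
}

#' Run the polarized Monte Carlo transport
#'
#' Launches a pencil beam perpendicular to the slab at the center of the
#' detection plane and traces Stokes-resolved photons until they exit
#' through the top (where they are detected on the sampling grid), are
#' absorbed, leave the detection plane, or are terminated by roulette.
#' Photons are tagged by whether they ever interacted with the lower
#' boundary; photons that never touched it constitute the backscattered
#' smoke component.
#'
#' @param config A [sim_config()].
#' @param medium A [medium_spec()].
#' @return An object of class `detection_grid` with elements `stokes`
#'   (array `n_grid x n_grid x 4 x 2`; last index 1 = smoke-only photons,
#'   2 = target-interacted), `efd` (array `n_grid x n_grid x n_bins x 4 x
#'   2` of per-electric-field-bin Stokes sums), `ledger` (energy bookkeeping
#'   in launched-photon weight units), and the configuration.
#' @examples
#' \donttest{
#' mie <- compute_mie(particle_spec(), n_angles = 721)
#' med <- medium_spec(mie, mu_s = 0.62)
#' grid <- run_simulation(sim_config(n_photons = 2000, seed = 7), med)
#' glance(grid)
#' }
#' @export
run_simulation <- function(config, medium) {
  stopifnot(inherits(config, "sim_config"), inherits(medium, "medium_spec"))
  tabs <- mie_tables(medium$mie)
  res <- cpp_run_simulation(
    n_photons = config$n_photons, seed = config$seed,
    theta = tabs$theta, s11 = tabs$s11, s12 = tabs$s12, s33 = tabs$s33,
    s34 = tabs$s34, cdf = tabs$cdf,
    mu_s = medium$mu_s, mu_a = medium$mu_a, depth = medium$depth,
    surface_index = medium$surface_index,
    diffuse_albedo = medium$diffuse_albedo,
    source_stokes = config$source_stokes,
    plane_half = config$plane_size / 2, nx = config$n_grid,
    bin_width = config$bin_width,
    roulette_threshold = config$roulette_threshold,
    roulette_survival = config$roulette_survival,
    max_steps = config$max_steps)
  if (res$n_capped > 0) {
    warning(sprintf("%d photon(s) hit the per-photon step cap; their weight was booked as absorbed",
                    res$n_capped), call. = FALSE)
  }
  structure(
    list(stokes = res$stokes, efd = res$efd,
         ledger = res$ledger, n_capped = res$n_capped,
         bin_width = config$bin_width, n_bins_efd = res$n_bins_efd,
         config = config, medium = medium),
    class = "detection_grid")
}

#' @export
print.detection_grid <- function(x, ...) {
  cat(sprintf("<detection_grid> %d x %d pixels, %d EFD bins of %g deg\n",
              dim(x$stokes)[1], dim(x$stokes)[2], x$n_bins_efd, x$bin_width))
  led <- x$ledger
  cat(sprintf("  ledger: detected %.4f, bottom %.4f, absorbed %.4f, side %.4f (of %g)\n",
              led[["detected_top"]], led[["transmitted_bottom"]],
              led[["absorbed"]], led[["lost_side"]], led[["launched"]]))
  invisible(x)
}

#' @rdname run_simulation
#' @param x,object A `detection_grid`.
#' @param ... Unused.
#' @export
glance.detection_grid <- function(x, ...) {
  led <- as.list(x$ledger)
  tibble::tibble(
    launched = led$launched, detected_top = led$detected_top,
    transmitted_bottom = led$transmitted_bottom, absorbed = led$absorbed,
    lost_side = led$lost_side,
    ledger_gap = led$launched -
      (led$detected_top + led$transmitted_bottom + led$absorbed +
         led$lost_side),
    n_photons = x$config$n_photons, mu_s = x$medium$mu_s,
    optical_depth = optical_depth(x$medium))
}

#' @rdname run_simulation
#' @export
autoplot.detection_grid <- function(object, ...) {
  img <- object$stokes[, , 1, 1] + object$stokes[, , 1, 2]
  df <- tidyr::expand_grid(x = seq_len(nrow(img)), y = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = log10(.data$intensity + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Detected intensity (log10)", fill = "log10 I")
}

#' Logical mask of the central detection-plane region
#'
#' @param grid A [run_simulation()] result.
#' @param size Side length in pixels of the centered square region.
#' @return A logical matrix matching the detection grid.
#' @export
central_region <- function(grid, size = 20) {
  stopifnot(inherits(grid, "detection_grid"))
  nx <- dim(grid$stokes)[1]
  size <- min(size, nx)
  lo <- floor((nx - size) / 2) + 1
  idx <- lo:(lo + size - 1)
  m <- matrix(FALSE, nx, nx)
  m[idx, idx] <- TRUE
  m
}

tag_index <- function(tags = c("all", "smoke_only", "target")) {
  tags <- match.arg(tags)
  switch(tags, all = 1:2, smoke_only = 1L, target = 2L)
}

# sum the per-EFD-bin Stokes vectors over a pixel region -> nbins x 4
efd_stokes_sums <- function(grid, region = NULL, tags = "all") {
  ti <- tag_index(tags)
  nb <- grid$n_bins_efd
  d <- dim(grid$efd)
  a <- grid$efd
  dim(a) <- c(d[1] * d[2], nb, 4, 2)
  mask <- if (is.null(region)) rep(TRUE, d[1] * d[2]) else as.vector(region)
  out <- matrix(0, nb, 4)
  for (t in ti) {
    for (k in 1:4) {
      sl <- a[mask, , k, t, drop = FALSE]
      out[, k] <- out[, k] + colSums(array(sl, dim(sl)[1:2]))
    }
  }
  out
}

#' Electric-field-direction histogram of detected light
#'
#' Bins the detected backscattered light by the orientation of its linear
#' polarization (from the Q component of the normalized Stokes vector,
#' folded into \[0, 90\] degrees) and returns the accumulated weight
#' `S(theta)` per bin.
#'
#' @param grid A [run_simulation()] result.
#' @param region Optional logical pixel mask (e.g. [central_region()]);
#'   `NULL` uses the whole plane.
#' @param tags Which photons to include: `"all"`, `"smoke_only"` (never
#'   touched the lower boundary) or `"target"`.
#' @return A tibble of class `efd_histogram` with columns `theta` (bin
#'   label, degrees) and `mass`.
#' @export
efd_histogram <- function(grid, region = NULL, tags = "all") {
  stopifnot(inherits(grid, "detection_grid"))
  sums <- efd_stokes_sums(grid, region, tags)
  out <- tibble::tibble(
    theta = (seq_len(grid$n_bins_efd) - 1) * grid$bin_width,
    mass = sums[, 1])
  class(out) <- c("efd_histogram", class(out))
  out
}

#' @export
autoplot.efd_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$theta, .data$mass)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "electric-field orientation (deg)",
                  y = "S(theta) (weight)",
                  title = "Electric-field-direction distribution")
}

#' Mueller matrix of an ideal linear polarizer
#'
#' @param theta0 Transmission-axis angle in degrees.
#' @return The 4x4 Mueller matrix.
#' @examples
#' polarizer_mueller(0) %*% c(1, 0, 0, 0)  # transmits half the intensity
#' @export
polarizer_mueller <- function(theta0) {
  c2 <- cos(2 * deg2rad(theta0))
  s2 <- sin(2 * deg2rad(theta0))
  0.5 * matrix(c(
    1, c2, s2, 0,
    c2, c2^2, c2 * s2, 0,
    s2, c2 * s2, s2^2, 0,
    0, 0, 0, 0), 4, 4, byrow = TRUE)
}

#' Per-bin analyzed intensities of the detected light
#'
#' Applies an ideal analyzer at `theta0` to the accumulated Stokes vector of
#' each electric-field-direction bin, giving the contribution of each bin to
#' the intensity a polarimetric camera channel at `theta0` would record.
#'
#' @inheritParams efd_histogram
#' @param theta0 Analyzer angle in degrees.
#' @return A tibble with columns `theta` (bin label) and `intensity`.
#' @export
interval_intensities <- function(grid, theta0, region = NULL, tags = "all") {
  stopifnot(inherits(grid, "detection_grid"))
  sums <- efd_stokes_sums(grid, region, tags)
  M <- polarizer_mueller(theta0)
  tibble::tibble(
    theta = (seq_len(grid$n_bins_efd) - 1) * grid$bin_width,
    intensity = drop(sums %*% M[1, ]))
}

#' Direct-PD, refined-PD and true backscatter curves per orientation bin
#'
#' For each electric-field-direction bin of the detected light this returns
#' the analyzed co/cross intensities, the direct polarization difference
#' `I0 - I90`, the refined polarization difference `I0 - Icrog / 2` built
#' from the fitted weight-curve coefficients (`Icrog = a I0 + b I45 +
#' c I90`), and the ground-truth backscattered component: the analyzed
#' intensity of photons that never interacted with the target surface.
#'
#' @inheritParams efd_histogram
#' @param fit A [fit_weight_vector()] result with basis \{0, 45, 90\}.
#' @return A tibble with columns `theta`, `s_theta`, `i0`, `i45`, `i90`,
#'   `direct_pd`, `refined_pd`, `truth`.
#' @export
pd_curves <- function(grid, fit, region = NULL) {
  stopifnot(inherits(grid, "detection_grid"))
  if (!inherits(fit, "pd_fit")) {
    stop_input("`fit` must be a pd_fit (see fit_weight_vector())")
  }
  cf <- refined_pd_coefficients(fit)
  i0 <- interval_intensities(grid, 0, region)$intensity
  i45 <- interval_intensities(grid, 45, region)$intensity
  i90 <- interval_intensities(grid, 90, region)$intensity
  icrog <- cf$a * i0 + cf$b * i45 + cf$c * i90
  truth <- interval_intensities(grid, 0, region, tags = "smoke_only")$intensity
  hist <- efd_histogram(grid, region)
  tibble::tibble(
    theta = hist$theta,
    s_theta = hist$mass,
    i0 = i0, i45 = i45, i90 = i90,
    direct_pd = i0 - i90,
    refined_pd = i0 - icrog / 2,
    truth = truth)
}

default_reference_axis <- function(direction) {
  ax <- c(1, 0, 0)
  e1 <- ax - sum(ax * direction) * direction
  if (sum(e1^2) < 1e-12) {
    ax <- c(0, 1, 0)
    e1 <- ax - sum(ax * direction) * direction
  }
  e1 / sqrt(sum(e1^2))
}

check_stokes <- function(stokes) {
  if (length(stokes) != 4 || stokes[1] <= 0) {
    stop_input("Stokes vector must have 4 components with I > 0")
  }
  if (sum(stokes[2:4]^2) > stokes[1]^2 * (1 + 1e-9)) {
    stop_input("unphysical Stokes vector: Q^2 + U^2 + V^2 > I^2")
  }
  invisible(stokes)
}

#' Sample single scattering events
#'
#' Draws `n` independent single-scatter outcomes for a photon in the given
#' state: the polar/azimuthal scattering angles from the joint density
#' proportional to `S11(theta) I + S12(theta) (Q cos 2phi + U sin 2phi)`,
#' and the rotated, scattered, renormalized Stokes vector. Useful for
#' validating the sampler; the transport loop calls the same compiled code.
#'
#' @param stokes Incident Stokes 4-vector (any positive intensity).
#' @param mie A [compute_mie()] result.
#' @param n Number of independent samples.
#' @param seed Seed.
#' @param direction Incident direction (unit 3-vector, default +z).
#' @param forced_theta,forced_phi Optionally pin the sampled angles
#'   (radians) instead of drawing them.
#' @return A list with `theta`, `phi` (radians), `direction`, `reference`
#'   and `stokes` (matrices, one row per sample).
#' @export
scatter_photon <- function(stokes, mie, n = 1, seed = 1,
                           direction = c(0, 0, 1),
                           forced_theta = NULL, forced_phi = NULL) {
  stopifnot(inherits(mie, "mie_result"))
  check_stokes(stokes)
  direction <- direction / sqrt(sum(direction^2))
  tabs <- mie_tables(mie)
  cpp_scatter_samples(
    u0 = direction, v0 = default_reference_axis(direction), S0 = stokes,
    theta = tabs$theta, s11 = tabs$s11, s12 = tabs$s12, s33 = tabs$s33,
    s34 = tabs$s34, cdf = tabs$cdf, n = as.integer(n), seed = seed,
    forced_theta = if (is.null(forced_theta)) -1 else forced_theta,
    forced_phi = if (is.null(forced_phi)) -1 else forced_phi)
}

#' Sample lower-boundary interactions
#'
#' Draws `n` independent interactions of a downward photon with the
#' dielectric target surface: polarization-resolved Fresnel specular
#' reflection (branch 0) or transmission followed by depolarized Lambertian
#' diffuse re-emission (branch 1).
#'
#' @param stokes Incident Stokes 4-vector.
#' @param surface_index Refractive index of the surface (>= 1).
#' @param diffuse_albedo Diffuse albedo of the backing.
#' @param n Number of samples.
#' @param seed Seed.
#' @param direction Incident direction (must point downward, uz > 0).
#' @return A list with `branch`, `direction`, `stokes`, `weight`, `alive`
#'   and the summed `transmitted_bottom` weight.
#' @export
surface_interaction <- function(stokes, surface_index = 1.5,
                                diffuse_albedo = 0.5, n = 1, seed = 1,
                                direction = c(0, 0, 1)) {
  check_stokes(stokes)
  direction <- direction / sqrt(sum(direction^2))
  if (direction[3] <= 0) {
    stop_input("`direction` must point downward toward the surface (uz > 0)")
  }
  cpp_surface_samples(
    u0 = direction, v0 = default_reference_axis(direction), S0 = stokes,
    surface_index = surface_index, diffuse_albedo = diffuse_albedo,
    n = as.integer(n), seed = seed)
}

#' Electric-field-direction bin of a Stokes vector
#'
#' Computes the linear-polarization orientation folded into \[0, 90\]
#' degrees as `0.5 * acos(Q / sqrt(Q^2 + U^2))` (so orientations psi and
#' 180 - psi share a bin) and assigns it to a bin of width `bin_width`.
#' A vector with no linear polarization is assigned to the 45-degree bin.
#'
#' @param stokes A Stokes 4-vector, or a matrix with one vector per row.
#' @param bin_width Bin width in degrees; must divide 90.
#' @return Integer bin index (1-based; bin `k` is labeled by orientation
#'   `(k - 1) * bin_width` degrees).
#' @examples
#' classify_efd_bin(c(1, 1, 0, 0))    # 1  (0-degree bin)
#' classify_efd_bin(c(1, -1, 0, 0))   # 19 (90-degree bin)
#' @export
classify_efd_bin <- function(stokes, bin_width = 5) {
  if (90 %% bin_width != 0) stop_input("90 must be divisible by `bin_width`")
  if (is.null(dim(stokes))) stokes <- matrix(stokes, nrow = 1)
  if (ncol(stokes) != 4) stop_input("`stokes` must have 4 columns")
  if (any(stokes[, 1] <= 0)) stop_input("Stokes I component must be > 0")
  nbins <- 90 / bin_width + 1
  lin <- sqrt(stokes[, 2]^2 + stokes[, 3]^2)
  theta <- ifelse(lin < 1e-12 * stokes[, 1], 45,
                  rad2deg(0.5 * acos(pmin(1, pmax(-1, stokes[, 2] / lin)))))
  # epsilon guards exact bin edges against floating-point round-down
  as.integer(pmin(floor(theta / bin_width + 1e-9), nbins - 1)) + 1L
}
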