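#' Bundle four linear polarization channel images
#'
#' Container for the four co-registered channels a division-of-focal-plane
#' or rotating-analyzer polarimetric camera records. Under 0-degree
#' (horizontal) illumination, `i0` is the co-polarized and `i90` the
#' cross-polarized channel. Channels are numeric arrays in \[0, 1\], either
#' `h x w` (grayscale) or `h x w x 3` (RGB), all of identical shape.
#'
#' @param i0,i45,i90,i135 Channel images.
#' @return An object of class `polarized_images`.
#' @export
polarized_images <- function(i0, i45, i90, i135) {
  chans <- list(i0 = i0, i45 = i45, i90 = i90, i135 = i135)
  d <- dim(i0) %||% length(i0)
  for (nm in names(chans)) {
    if (!is.numeric(chans[[nm]])) stop_input("channel `%s` must be numeric", nm)
    if (!identical(dim(chans[[nm]]) %||% length(chans[[nm]]), d)) {
      stop_input("all four channels must share one shape")
    }
  }
  structure(chans, class = "polarized_images")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.polarized_images <- function(x, ...) {
  d <- dim(x$i0) %||% length(x$i0)
  cat("<polarized_images> channels 0/45/90/135, shape",
      paste(d, collapse = " x "), "\n")
  invisible(x)
}

#' Describe a synthetic polarized-smoke scene
#'
#' Ground truth for the forward degradation model: a clean scene radiance,
#' a spatially varying transmission field, and a partially polarized
#' ambient (smoke) term. The ambient light is modeled as a Stokes vector
#' `A_inf * (1, P_A cos 2a, P_A sin 2a)` with degree of linear polarization
#' `P_A` and polarization axis `a`; `P_A = 1` emulates single-scattering
#' smoke whose backscatter is fully co-polarized, smaller values emulate
#' the depolarization produced by multiple scattering in dense smoke.
#'
#' @param clean Clean scene radiance, `h x w` or `h x w x 3` array in
#'   \[0, 1\].
#' @param transmission Transmission field `t(x)` in \[0, 1\], `h x w`.
#' @param ambient_total Ambient intensity at infinite optical depth,
#'   `A_inf` in (0, 1\].
#' @param ambient_dolp Degree of linear polarization `P_A` of the ambient
#'   term, in \[0, 1\].
#' @param ambient_axis Ambient polarization axis in degrees (default 0, the
#'   illumination axis).
#' @param target_dolp Degree of linear polarization of the target radiance
#'   (default 0: an unpolarized, depolarizing target).
#' @param target_axis Target polarization axis in degrees.
#' @param noise_sigma Standard deviation of additive Gaussian sensor noise,
#'   applied per analyzed channel before clipping.
#' @param seed Seed for the noise.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(clean, transmission, ambient_total = 0.8,
                        ambient_dolp = 1, ambient_axis = 0,
                        target_dolp = 0, target_axis = 0,
                        noise_sigma = 0.005, seed = 1) {
  d <- dim(clean)
  if (is.null(d) || !(length(d) %in% 2:3)) {
    stop_input("`clean` must be an h x w or h x w x 3 array")
  }
  if (!identical(dim(transmission), d[1:2])) {
    stop_input("`transmission` must match the spatial shape of `clean`")
  }
  if (any(transmission < 0 | transmission > 1)) {
    stop_input("`transmission` must lie in [0, 1]")
  }
  if (ambient_total <= 0 || ambient_total > 1) {
    stop_input("`ambient_total` must lie in (0, 1]")
  }
  if (ambient_dolp < 0 || ambient_dolp > 1) {
    stop_input("`ambient_dolp` must lie in [0, 1]")
  }
  structure(
    list(clean = clean, transmission = transmission,
         ambient_total = ambient_total, ambient_dolp = ambient_dolp,
         ambient_axis = ambient_axis, target_dolp = target_dolp,
         target_axis = target_axis, noise_sigma = noise_sigma, seed = seed),
    class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %s, A_inf = %g, P_A = %g, t in [%.3f, %.3f], sigma = %g\n",
    paste(dim(x$clean), collapse = " x "), x$ambient_total, x$ambient_dolp,
    min(x$transmission), max(x$transmission), x$noise_sigma))
  invisible(x)
}

# analyzed intensity of the Stokes triple (s0, s1, s2) through an ideal
# analyzer at angle theta (degrees)
analyze_stokes <- function(s0, s1, s2, theta) {
  th <- deg2rad(theta)
  0.5 * (s0 + s1 * cos(2 * th) + s2 * sin(2 * th))
}

#' Ambient channel intensities implied by a scene
#'
#' The per-channel ambient values `A_inf(pol)` that an ideal analyzer
#' records at infinite optical depth, i.e. the analyzed ambient Stokes
#' vector. These are the oracle values for ambient estimation.
#'
#' @param scene A [scene_truth()].
#' @return Named numeric vector with elements `i0`, `i45`, `i90`, `i135`.
#' @export
ambient_truth <- function(scene) {
  stopifnot(inherits(scene, "scene_truth"))
  s0 <- scene$ambient_total
  s1 <- scene$ambient_dolp * s0 * cos(2 * deg2rad(scene$ambient_axis))
  s2 <- scene$ambient_dolp * s0 * sin(2 * deg2rad(scene$ambient_axis))
  vapply(c(i0 = 0, i45 = 45, i90 = 90, i135 = 135),
         function(a) analyze_stokes(s0, s1, s2, a), numeric(1))
}

#' Apply the polarized degradation model
#'
#' Forward model of imaging through smoke: per pixel and color band the
#' captured Stokes vector is the transmission-weighted mixture
#' `t(x) * S_target + (1 - t(x)) * S_ambient`, and each analyzer channel
#' records `0.5 * (S0 + S1 cos 2theta + S2 sin 2theta)`. Additive Gaussian
#' sensor noise is injected after analysis and the channels are clipped to
#' \[0, 1\].
#'
#' @param scene A [scene_truth()].
#' @param noise Logical; set `FALSE` to produce the noise-free channels
#'   (exact Stokes consistency `I0 + I90 == I45 + I135`).
#' @return A [polarized_images()] set.
#' @examples
#' sc <- scene_truth(matrix(0.6, 8, 8), matrix(0.5, 8, 8),
#'                   ambient_total = 0.8, noise_sigma = 0)
#' degrade(sc)$i0[1, 1]  # 0.55
#' @export
degrade <- function(scene, noise = TRUE) {
  stopifnot(inherits(scene, "scene_truth"))
  d <- dim(scene$clean)
  nb <- if (length(d) == 3) d[3] else 1
  t_field <- scene$transmission

  a0 <- scene$ambient_total
  a1 <- scene$ambient_dolp * a0 * cos(2 * deg2rad(scene$ambient_axis))
  a2 <- scene$ambient_dolp * a0 * sin(2 * deg2rad(scene$ambient_axis))
  j1f <- scene$target_dolp * cos(2 * deg2rad(scene$target_axis))
  j2f <- scene$target_dolp * sin(2 * deg2rad(scene$target_axis))

  make_band <- function(j) {
    s0 <- j * t_field + a0 * (1 - t_field)
    s1 <- j * j1f * t_field + a1 * (1 - t_field)
    s2 <- j * j2f * t_field + a2 * (1 - t_field)
    lapply(c(0, 45, 90, 135), function(a) analyze_stokes(s0, s1, s2, a))
  }

  if (nb == 1) {
    bands <- list(make_band(scene$clean))
  } else {
    bands <- lapply(seq_len(nb), function(b) make_band(scene$clean[, , b]))
  }
  chan <- function(k) {
    if (nb == 1) return(bands[[1]][[k]])
    arr <- array(0, d)
    for (b in seq_len(nb)) arr[, , b] <- bands[[b]][[k]]
    arr
  }
  out <- lapply(1:4, chan)
  if (noise && scene$noise_sigma > 0) {
    set.seed(scene$seed)
    out <- lapply(out, function(img) {
      img + array(rnorm(length(img), sd = scene$noise_sigma),
                  dim(img) %||% length(img))
    })
  }
  out <- lapply(out, function(img) pmax(pmin(img, 1), 0))
  polarized_images(out[[1]], out[[2]], out[[3]], out[[4]])
}

#' Generate a synthetic transmission field
#'
#' @param shape Integer vector `c(h, w)`.
#' @param kind `"constant"`, `"blobs"` (smoke plumes: Gaussian blobs where
#'   transmission drops to `t_min_truth`, background near `t_max_truth`) or
#'   `"smooth_noise"` (low-pass-filtered Gaussian noise rescaled to the
#'   range).
#' @param value Value for `kind = "constant"`.
#' @param t_min_truth,t_max_truth Range of the generated field. The default
#'   `t_min_truth = 0` makes blob centers pure smoke (no target signal),
#'   which is what ambient-light estimators exploit.
#' @param n_blobs Number of blobs.
#' @param smoothness Gaussian kernel standard deviation, in pixels, for
#'   `"smooth_noise"` (and blob radius scale for `"blobs"`).
#' @param seed Seed; fields are bit-reproducible given the seed.
#' @return An `h x w` matrix in \[`t_min_truth`, `t_max_truth`\].
#' @export
make_transmission_field <- function(shape, kind = c("blobs", "constant",
                                                    "smooth_noise"),
                                    value = 0.7, t_min_truth = 0,
                                    t_max_truth = 0.95, n_blobs = 3,
                                    smoothness = NULL, seed = 1) {
  kind <- match.arg(kind)
  h <- shape[1]; w <- shape[2]
  if (kind == "constant") {
    return(matrix(value, h, w))
  }
  set.seed(seed)
  if (kind == "blobs") {
    sigma <- smoothness %||% (min(h, w) / 6)
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), w), h, w)
    field <- matrix(0, h, w)
    cx <- runif(n_blobs, 0.15 * w, 0.85 * w)
    cy <- runif(n_blobs, 0.15 * h, 0.85 * h)
    sc <- runif(n_blobs, 0.6, 1.4) * sigma
    for (b in seq_len(n_blobs)) {
      field <- pmax(field,
                    exp(-((xs - cx[b])^2 + (ys - cy[b])^2) / (2 * sc[b]^2)))
    }
    # force full depth at the strongest blob so a pure-smoke region exists
    field <- field / max(field)
    t_field <- t_max_truth - (t_max_truth - t_min_truth) * field
  } else {
    sigma <- smoothness %||% (min(h, w) / 10)
    noise <- matrix(rnorm(h * w), h, w)
    sm <- gaussian_blur(noise, sigma)
    sm <- (sm - min(sm)) / (max(sm) - min(sm))
    t_field <- t_min_truth + (t_max_truth - t_min_truth) * sm
  }
  pmax(pmin(t_field, t_max_truth), t_min_truth)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    h <- nrow(m); w <- ncol(m)
    mp <- m[c(rep(1, r), seq_len(h), rep(h, r)), ]
    out <- matrix(0, h, w)
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[i:(i + h - 1), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Generate a deterministic test phantom
#'
#' Emulates the physical test targets used on the desk: a 24-patch color
#' checker, a resolution-bar target, and a soft tissue-like texture.
#'
#' @param shape Integer vector `c(h, w)`.
#' @param kind `"color_checker"` (4 x 6 grid of constant RGB patches),
#'   `"resolution_bars"` (grayscale vertical bar groups of increasing
#'   spatial frequency) or `"tissue_texture"` (reddish low-frequency
#'   texture).
#' @param seed Seed (used by `"tissue_texture"` only).
#' @return An `h x w` matrix or `h x w x 3` array in \[0, 1\].
#' @export
make_phantom <- function(shape, kind = c("color_checker", "resolution_bars",
                                         "tissue_texture"), seed = 1) {
  kind <- match.arg(kind)
  h <- shape[1]; w <- shape[2]
  if (kind == "color_checker") {
    cols <- color_checker_patches()
    img <- array(0, c(h, w, 3))
    rows <- 4; colsn <- 6
    for (r in seq_len(rows)) {
      for (cc in seq_len(colsn)) {
        ri <- (floor((r - 1) * h / rows) + 1):floor(r * h / rows)
        ci <- (floor((cc - 1) * w / colsn) + 1):floor(cc * w / colsn)
        patch <- cols[(r - 1) * colsn + cc, ]
        for (b in 1:3) img[ri, ci, b] <- patch[b]
      }
    }
    return(img)
  }
  if (kind == "resolution_bars") {
    img <- matrix(0.1, h, w)
    periods <- c(32, 16, 8, 4, 2)
    band_h <- floor(h / length(periods))
    x <- seq_len(w)
    for (i in seq_along(periods)) {
      ri <- ((i - 1) * band_h + 1):min(i * band_h, h)
      bars <- 0.1 + 0.8 * (((x - 1) %/% periods[i]) %% 2)
      img[ri, ] <- matrix(bars, length(ri), w, byrow = TRUE)
    }
    return(img)
  }
  set.seed(seed)
  base <- gaussian_blur(matrix(rnorm(h * w), h, w), min(h, w) / 12)
  base <- (base - min(base)) / (max(base) - min(base))
  img <- array(0, c(h, w, 3))
  img[, , 1] <- 0.35 + 0.45 * base
  img[, , 2] <- 0.15 + 0.25 * base
  img[, , 3] <- 0.12 + 0.20 * base
  pmax(pmin(img, 1), 0)
}

# 24 documented constant sRGB patch values (rows top-left to bottom-right)
color_checker_patches <- function() {
  matrix(c(
    0.45, 0.31, 0.26,   0.76, 0.58, 0.51,   0.38, 0.48, 0.61,
    0.34, 0.42, 0.26,   0.52, 0.50, 0.69,   0.40, 0.74, 0.67,
    0.85, 0.49, 0.17,   0.28, 0.36, 0.65,   0.76, 0.33, 0.38,
    0.36, 0.24, 0.42,   0.62, 0.73, 0.25,   0.89, 0.63, 0.18,
    0.16, 0.24, 0.58,   0.28, 0.58, 0.29,   0.69, 0.19, 0.23,
    0.93, 0.78, 0.13,   0.73, 0.34, 0.58,   0.03, 0.52, 0.63,
    0.95, 0.95, 0.95,   0.78, 0.78, 0.78,   0.63, 0.63, 0.63,
    0.48, 0.48, 0.48,   0.33, 0.33, 0.33,   0.19, 0.19, 0.19),
    nrow = 24, ncol = 3, byrow = TRUE)
}

#' Convenience constructor for a full synthetic scene
#'
#' Builds a [scene_truth()] from a phantom radiance and a generated
#' transmission field with the package's default smoke parameters.
#'
#' @inheritParams make_phantom
#' @param t_kind Transmission field kind, see [make_transmission_field()].
#' @param ... Passed to [scene_truth()] (e.g. `ambient_total`,
#'   `ambient_dolp`, `noise_sigma`).
#' @return A [scene_truth()].
#' @examples
#' sc <- make_phantom_scene(c(48, 72), seed = 7)
#' imgs <- degrade(sc)
#' @export
make_phantom_scene <- function(shape, kind = "color_checker",
                               t_kind = "blobs", seed = 1, ...) {
  clean <- make_phantom(shape, kind, seed = seed)
  t_field <- make_transmission_field(shape, t_kind, seed = seed)
  scene_truth(clean, t_field, seed = seed, ...)
}
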