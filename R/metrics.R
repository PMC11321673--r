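#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(max_value^2 / MSE)` in decibels. Identical images have
#' infinite PSNR; the returned value is `Inf` in that case.
#'
#' @param reference,test Images of identical shape.
#' @param max_value Peak signal value (1 for float images in \[0, 1\], 255
#'   for 8-bit integers).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0.5, 4, 4), matrix(0.6, 4, 4))  # 20 dB
#' @export
psnr <- function(reference, test, max_value = 1) {
  if (!identical(dim(reference) %||% length(reference),
                 dim(test) %||% length(test))) {
    stop_input("`reference` and `test` must have identical shape")
  }
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the standard parameters: 11 x 11 Gaussian window
#' with sigma 1.5, stability constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`
#' with `K1 = 0.01`, `K2 = 0.03`. Multi-band images are scored per band and
#' averaged. Local statistics are evaluated on the valid interior (no
#' padding).
#'
#' @param reference,test Images of identical shape with values in
#'   \[0, `max_value`\].
#' @param max_value Dynamic range L.
#' @param k1,k2 Stability constants.
#' @param window_size,sigma Gaussian window parameters.
#' @return Mean SSIM in \[-1, 1\]; 1 only for identical images.
#' @export
ssim <- function(reference, test, max_value = 1, k1 = 0.01, k2 = 0.03,
                 window_size = 11, sigma = 1.5) {
  if (!identical(dim(reference) %||% length(reference),
                 dim(test) %||% length(test))) {
    stop_input("`reference` and `test` must have identical shape")
  }
  if (length(dim(reference)) == 3) {
    vals <- vapply(seq_len(dim(reference)[3]), function(b) {
      ssim(reference[, , b], test[, , b], max_value, k1, k2, window_size,
           sigma)
    }, numeric(1))
    return(mean(vals))
  }
  if (min(dim(reference)) < window_size) {
    stop_input("image smaller than the %d-pixel SSIM window", window_size)
  }
  c1 <- (k1 * max_value)^2
  c2 <- (k2 * max_value)^2
  w <- gaussian_window(window_size, sigma)
  mu1 <- conv2_valid(reference, w)
  mu2 <- conv2_valid(test, w)
  s11 <- conv2_valid(reference^2, w) - mu1^2
  s22 <- conv2_valid(test^2, w) - mu2^2
  s12 <- conv2_valid(reference * test, w) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

gaussian_window <- function(size, sigma) {
  r <- (size - 1) / 2
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 'valid' convolution with a 1-D kernel applied along both axes
conv2_valid <- function(img, k) {
  n <- length(k)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h - n + 1, w)
  for (i in seq_len(n)) {
    out <- out + k[i] * img[i:(i + h - n), , drop = FALSE]
  }
  out2 <- matrix(0, h - n + 1, w - n + 1)
  for (i in seq_len(n)) {
    out2 <- out2 + k[i] * out[, i:(i + w - n), drop = FALSE]
  }
  out2
}

#' CIEDE2000 color difference
#'
#' Mean perceptual color difference Delta E00 between two sRGB images:
#' pixels are decoded with the standard sRGB transfer function, converted
#' to CIELAB under the D65 white point (2-degree observer), and compared
#' with the CIE 2000 formula including the rotation term.
#'
#' @param reference,test `h x w x 3` sRGB images in \[0, 1\].
#' @return Mean Delta E00 (>= 0, 0 only for identical colors).
#' @export
ciede2000 <- function(reference, test) {
  for (img in list(reference, test)) {
    if (length(dim(img)) != 3 || dim(img)[3] != 3) {
      stop_input("ciede2000 requires h x w x 3 sRGB inputs")
    }
  }
  if (!identical(dim(reference), dim(test))) {
    stop_input("`reference` and `test` must have identical shape")
  }
  lab1 <- srgb_to_lab(reference)
  lab2 <- srgb_to_lab(test)
  mean(delta_e00(lab1, lab2))
}

srgb_to_lab <- function(img) {
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  grDevices::convertColor(px, from = "sRGB", to = "Lab")
}

#' CIE 2000 color difference between Lab colors
#'
#' Vectorized Delta E00 for matrices of CIELAB triples (columns L, a, b).
#' Exposed so the formula can be verified directly against the published
#' reference pairs.
#'
#' @param lab1,lab2 Numeric matrices with columns L, a, b.
#' @param kl,kc,kh Parametric weighting factors (all 1 for reference
#'   conditions).
#' @return Numeric vector of Delta E00 values.
#' @export
delta_e00 <- function(lab1, lab2, kl = 1, kc = 1, kh = 1) {
  lab1 <- matrix(lab1, ncol = 3)
  lab2 <- matrix(lab2, ncol = 3)
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
                ifelse(abs(dh) <= 180, dh,
                       ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(deg2rad(dhp) / 2)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
                ifelse(abs(h1p - h2p) <= 180, hsum / 2,
                       ifelse(hsum < 360, (hsum + 360) / 2,
                              (hsum - 360) / 2)))
  T_ <- 1 - 0.17 * cos(deg2rad(hbp - 30)) + 0.24 * cos(deg2rad(2 * hbp)) +
    0.32 * cos(deg2rad(3 * hbp + 6)) - 0.20 * cos(deg2rad(4 * hbp - 63))
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  Rc <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  Sl <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  Sc <- 1 + 0.045 * Cbp
  Sh <- 1 + 0.015 * Cbp * T_
  Rt <- -sin(deg2rad(2 * dtheta)) * Rc

  sqrt((dLp / (kl * Sl))^2 + (dCp / (kc * Sc))^2 + (dHp / (kh * Sh))^2 +
         Rt * (dCp / (kc * Sc)) * (dHp / (kh * Sh)))
}

#' Full-reference quality report
#'
#' Computes PSNR, SSIM and (for RGB input) mean CIEDE2000 of a test image
#' against its clean reference.
#'
#' @param reference,test Images of identical shape.
#' @param max_value Dynamic range.
#' @return A tibble of class `quality_report` with columns `psnr`, `ssim`
#'   and `ciede2000` (`NA` for grayscale input).
#' @examples
#' sc <- make_phantom_scene(c(32, 48), seed = 2, noise_sigma = 0)
#' smoky <- degrade(sc)
#' quality_report(sc$clean, smoky$i0 + smoky$i90)
#' @export
quality_report <- function(reference, test, max_value = 1) {
  de <- if (length(dim(reference)) == 3 && dim(reference)[3] == 3) {
    ciede2000(reference, test)
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    psnr = psnr(reference, test, max_value),
    ssim = ssim(reference, test, max_value),
    ciede2000 = de)
  class(out) <- c("quality_report", class(out))
  out
}
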