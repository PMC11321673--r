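#' Read an image file
#'
#' Reads TIFF or PNG images into numeric arrays in \[0, 1\] (integer data
#' are normalized by their bit depth).
#'
#' @param path File path; format inferred from the extension.
#' @return An `h x w` matrix or `h x w x bands` array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_input("unsupported image format: .%s (TIFF or PNG expected)", ext))
  img
}

#' Write an image file
#'
#' Writes a numeric array in \[0, 1\] as 8- or 16-bit TIFF or PNG. Values
#' are quantized to the requested depth; integer data written and re-read
#' round-trip bit-identically, floats round-trip to within one quantization
#' step.
#'
#' @param path Output path; format inferred from the extension.
#' @param data Image array, values in \[0, 1\].
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, data, bit_depth = 16) {
  if (!bit_depth %in% c(8, 16)) stop_input("`bit_depth` must be 8 or 16")
  if (any(data < 0 | data > 1)) {
    stop_input("image data must lie in [0, 1] before writing")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(data, path, bits.per.sample = bit_depth),
    png = png::writePNG(data, path),  # PNG output is 8-bit
    stop_input("unsupported image format: .%s (TIFF or PNG expected)", ext))
  invisible(path)
}

#' Split a division-of-focal-plane mosaic into polarization channels
#'
#' A DoFP sensor samples the four analyzer orientations on a 2 x 2 mosaic
#' of micro-polarizers. `"superpixel"` mode subsamples each orientation to
#' a half-resolution channel; `"bilinear"` mode interpolates each
#' orientation back to full resolution.
#'
#' @param raw Single-band mosaic image with even width and height.
#' @param layout 2 x 2 matrix assigning analyzer angles to the mosaic
#'   positions; must be a permutation of 0, 45, 90, 135. The default
#'   `rbind(c(90, 45), c(135, 0))` is the common commercial layout.
#' @param mode `"superpixel"` or `"bilinear"`.
#' @return A [polarized_images()] set.
#' @export
demosaic <- function(raw, layout = rbind(c(90, 45), c(135, 0)),
                     mode = c("superpixel", "bilinear")) {
  mode <- match.arg(mode)
  if (length(dim(raw)) != 2) stop_input("`raw` must be a single-band matrix")
  h <- nrow(raw); w <- ncol(raw)
  if (h %% 2 != 0 || w %% 2 != 0) {
    stop_input("mosaic dimensions must be even, got %d x %d", h, w)
  }
  if (!identical(dim(layout), c(2L, 2L)) ||
      !setequal(as.vector(layout), c(0, 45, 90, 135))) {
    stop_input("`layout` must be a 2 x 2 permutation of 0, 45, 90, 135")
  }
  chans <- list()
  for (dr in 1:2) {
    for (dc in 1:2) {
      sub <- raw[seq(dr, h, by = 2), seq(dc, w, by = 2)]
      if (mode == "bilinear") {
        sub <- dofp_upsample(sub, h, w, dr, dc)
      }
      chans[[paste0("i", layout[dr, dc])]] <- sub
    }
  }
  polarized_images(chans$i0, chans$i45, chans$i90, chans$i135)
}

# bilinear re-expansion of one orientation's sparse lattice to full
# resolution: place samples on their mosaic sites, then interpolate the
# missing rows/columns (edge replication outside the lattice)
dofp_upsample <- function(sub, h, w, dr, dc) {
  rows_half <- approx_axis(seq(dr, h, by = 2), h)
  cols_half <- approx_axis(seq(dc, w, by = 2), w)
  # separable linear interpolation via weights on the subsampled grid
  interp1 <- function(m, ax) {
    lo <- m[ax$i0, , drop = FALSE]
    hi <- m[ax$i1, , drop = FALSE]
    lo * (1 - ax$f) + hi * ax$f
  }
  out <- interp1(sub, rows_half)
  out <- t(interp1(t(out), cols_half))
  out
}

# mapping from full-resolution coordinates to bracketing sample indices
approx_axis <- function(sites, n_full) {
  xi <- seq_len(n_full)
  pos <- (xi - sites[1]) / 2 + 1      # fractional index into the lattice
  pos <- pmin(length(sites), pmax(1, pos))
  i0 <- floor(pos)
  f <- pos - i0
  i1 <- pmin(length(sites), i0 + 1)
  list(i0 = i0, i1 = i1, f = matrix(f, nrow = n_full, ncol = 1)[, 1])
}

#' Build a DoFP mosaic from four channels
#'
#' Inverse of [demosaic()] in `"superpixel"` mode; useful for synthesizing
#' raw sensor frames from the forward model.
#'
#' @param images A [polarized_images()] set of half-resolution channels.
#' @param layout As in [demosaic()].
#' @return A full-resolution single-band mosaic matrix.
#' @export
mosaic <- function(images, layout = rbind(c(90, 45), c(135, 0))) {
  stopifnot(inherits(images, "polarized_images"))
  h <- nrow(images$i0) * 2L
  w <- ncol(images$i0) * 2L
  raw <- matrix(0, h, w)
  for (dr in 1:2) {
    for (dc in 1:2) {
      raw[seq(dr, h, by = 2), seq(dc, w, by = 2)] <-
        images[[paste0("i", layout[dr, dc])]]
    }
  }
  raw
}
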