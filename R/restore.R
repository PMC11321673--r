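#' Refined-PD channel weights from a weight-curve fit
#'
#' Converts the fitted amplitude coefficients `(a, b, c)` of the
#' cosine-squared basis at \{0, 45, 90\} degrees into the closed-form pixel
#' weights of the refined polarization difference. The synthesized cleaner
#' orthogonal channel is `Icrog = a I0 + b I45 + c I90`; treating its mean
#' orientation density as the `S(90)` estimate gives
#' `PD' = I0 - Icrog / 2 = (1 - a/2) I0 - (b/2) I45 - (c/2) I90`.
#'
#' @param fit A [fit_weight_vector()] result whose basis is
#'   \{0, 45, 90\} degrees.
#' @return An object of class `refined_pd_coefficients` with elements `a`,
#'   `b`, `c` and derived weights `w0`, `w45`, `w90`.
#' @examples
#' refined_pd_coefficients(fit_weight_vector())
#' @export
refined_pd_coefficients <- function(fit) {
  stopifnot(inherits(fit, "pd_fit"))
  if (!identical(sort(as.numeric(fit$basis_angles)), c(0, 45, 90))) {
    stop_input("refined PD weights require the basis {0, 45, 90} degrees")
  }
  cf <- fit$coefficients[order(fit$basis_angles)]
  structure(
    list(a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]),
         fit = fit),
    class = "refined_pd_coefficients")
}

#' @export
print.refined_pd_coefficients <- function(x, ...) {
  w <- refined_pd_weights(x)
  cat(sprintf("<refined_pd_coefficients> a = %.4f, b = %.4f, c = %.4f\n",
              x$a, x$b, x$c))
  cat(sprintf("  channel weights: w0 = %.4f, w45 = %.4f, w90 = %.4f\n",
              w[1], w[2], w[3]))
  invisible(x)
}

# weights are always derived, never stored
refined_pd_weights <- function(coeffs) {
  c(w0 = 1 - coeffs$a / 2, w45 = -coeffs$b / 2, w90 = -coeffs$c / 2)
}

#' Direct polarization difference
#'
#' The classic backscatter estimator `PD(x) = I_co(x) - I_cro(x)`, clamped
#' below at zero (a negative polarization difference has no physical
#' interpretation under the degradation model and is noise).
#'
#' @param images A [polarized_images()] set.
#' @param co_channel Name of the co-polarized channel (`"i0"` under the
#'   default horizontal illumination; its orthogonal channel is used as
#'   cross).
#' @return An image (same shape as the channels).
#' @export
direct_pd <- function(images, co_channel = "i0") {
  stopifnot(inherits(images, "polarized_images"))
  cross <- c(i0 = "i90", i45 = "i135", i90 = "i0", i135 = "i45")[[co_channel]]
  pmax(images[[co_channel]] - images[[cross]], 0)
}

#' Refined polarization difference
#'
#' Backscatter estimator corrected for the leakage of multiply scattered
#' (randomly oriented) backscatter into the cross-polarized channel:
#' `PD'(x) = (1 - a/2) I0 - (b/2) I45 - (c/2) I90` with the fitted weight
#' coefficients. Clamped to \[0, `a_inf_co`\] when an ambient level is
#' supplied, else to \[0, 1\].
#'
#' @param images A [polarized_images()] set.
#' @param coeffs A [refined_pd_coefficients()] object.
#' @param a_inf_co Optional co-polarized ambient level used as the upper
#'   clamp.
#' @return An image.
#' @export
refined_pd <- function(images, coeffs, a_inf_co = NULL) {
  stopifnot(inherits(images, "polarized_images"))
  if (!inherits(coeffs, "refined_pd_coefficients")) {
    stop_input("`coeffs` must come from refined_pd_coefficients()")
  }
  w <- refined_pd_weights(coeffs)
  pd <- w[["w0"]] * images$i0 + w[["w45"]] * images$i45 +
    w[["w90"]] * images$i90
  hi <- a_inf_co %||% 1
  pmax(pmin(pd, hi), 0)
}

#' Estimate the ambient light level per channel
#'
#' The ambient (airlight) channel intensities `A_inf(pol)` are estimated
#' from pixels dominated by smoke. Strategy `"auto_percentile"` pools the
#' pixels whose polarization-difference value is in the top `q` percent
#' (default 1 percent) -- under the degradation model these are the pixels
#' with the lowest transmission -- and takes per-channel means. Strategy
#' `"roi"` averages over a user-supplied mask of a smoke-only region.
#'
#' @param images A [polarized_images()] set.
#' @param pd A polarization-difference image ([direct_pd()] or
#'   [refined_pd()]), same spatial shape as the channels.
#' @param strategy `"auto_percentile"` or `"roi"`.
#' @param q Top percentile (percent) for `"auto_percentile"`.
#' @param roi Logical mask for `"roi"`.
#' @param co_channel Co-polarized channel name.
#' @return An object of class `ambient_estimate`: list with `a_inf_pol`
#'   (named per-channel vector or per-band matrix), `a_inf_co`, `strategy`
#'   and the pooled `support` mask.
#' @export
estimate_ambient <- function(images, pd,
                             strategy = c("auto_percentile", "roi"),
                             q = 1, roi = NULL, co_channel = "i0") {
  stopifnot(inherits(images, "polarized_images"))
  strategy <- match.arg(strategy)
  sp_dim <- (dim(images$i0) %||% length(images$i0))[1:2]
  pd_sp <- if (length(dim(pd)) == 3) apply(pd, c(1, 2), mean) else pd
  if (!identical(dim(pd_sp), sp_dim)) {
    stop_input("`pd` must match the spatial shape of the channels")
  }
  if (strategy == "auto_percentile") {
    thr <- stats::quantile(pd_sp, 1 - q / 100, names = FALSE)
    support <- pd_sp >= thr
  } else {
    if (is.null(roi) || !is.logical(roi) || !identical(dim(roi), sp_dim)) {
      stop_input("`roi` must be a logical mask matching the image shape")
    }
    support <- roi
  }
  if (!any(support)) stop_input("ambient support is empty")

  band_mean <- function(img) {
    if (length(dim(img)) == 3) {
      vapply(seq_len(dim(img)[3]),
             function(b) mean(img[, , b][support]), numeric(1))
    } else {
      mean(img[support])
    }
  }
  a_inf <- vapply(c("i0", "i45", "i90", "i135"),
                  function(ch) band_mean(images[[ch]]),
                  numeric(length(band_mean(images$i0))))
  structure(
    list(a_inf_pol = a_inf,
         a_inf_co = if (is.matrix(a_inf)) a_inf[, co_channel]
                    else a_inf[[co_channel]],
         strategy = strategy, support = support, co_channel = co_channel),
    class = "ambient_estimate")
}

#' @export
print.ambient_estimate <- function(x, ...) {
  cat("<ambient_estimate>", x$strategy, "over", sum(x$support), "pixels\n")
  if (is.matrix(x$a_inf_pol)) {
    print(round(x$a_inf_pol, 4))
  } else {
    print(round(x$a_inf_pol, 4))
  }
  invisible(x)
}

#' Transmission map from a polarization difference
#'
#' Inverts the degradation model: `t(x) = 1 - PD(x) / A_inf(co)`, clipped
#' to \[`t_min`, 1\]. The floor keeps the later division of the restoration
#' step well conditioned where the smoke is optically thick.
#'
#' @param pd Polarization-difference image.
#' @param a_inf_co Co-polarized ambient level (> 0); scalar or one value
#'   per color band.
#' @param t_min Transmission floor.
#' @return An object of class `transmission_map`: list with the clipped
#'   image `t` and `t_min`.
#' @export
transmission_map <- function(pd, a_inf_co, t_min = 0.05) {
  if (any(!is.finite(a_inf_co)) || any(a_inf_co <= 0)) {
    stop_input("`a_inf_co` must be > 0")
  }
  if (length(dim(pd)) == 3) {
    nb <- dim(pd)[3]
    a <- if (length(a_inf_co) == 1) rep(a_inf_co, nb) else a_inf_co
    t_img <- pd
    for (b in seq_len(nb)) t_img[, , b] <- 1 - pd[, , b] / a[b]
  } else {
    t_img <- 1 - pd / a_inf_co[1]
  }
  structure(list(t = pmax(pmin(t_img, 1), t_min), t_min = t_min),
            class = "transmission_map")
}

#' Restore one polarized channel
#'
#' Inverts the degradation model for a single analyzer channel:
#' `J_pol(x) = (I_pol(x) - A_inf(pol)) / t(x) + A_inf(pol)`, clipped to
#' \[0, 1\].
#'
#' @param i_pol Captured channel image.
#' @param t A [transmission_map()] (or a bare transmission image).
#' @param a_inf_pol Ambient level of this channel; scalar or per band.
#' @return Restored channel image.
#' @export
restore_channel <- function(i_pol, t, a_inf_pol) {
  t_img <- if (inherits(t, "transmission_map")) t$t else t
  if (length(dim(i_pol)) == 3 && length(dim(t_img)) == 2) {
    t_img <- array(rep(t_img, dim(i_pol)[3]), dim(i_pol))
  }
  if (length(dim(i_pol)) == 3 && length(a_inf_pol) == dim(i_pol)[3]) {
    a <- aperm(array(a_inf_pol, c(dim(i_pol)[3], dim(i_pol)[1:2])),
               c(2, 3, 1))
  } else {
    a <- a_inf_pol[1]
  }
  pmax(pmin((i_pol - a) / t_img + a, 1), 0)
}

#' Desmoke a polarized image set
#'
#' The full restoration pipeline: backscatter estimation by direct PD
#' (`method = "POL"`) or refined PD (`method = "RPOL"`), ambient-light
#' estimation (or oracle override), transmission-map inversion, and
#' channel-by-channel restoration of all four analyzer channels, band by
#' band for RGB input. The recombined intensity `S0 = J_co + J_cro` is the
#' headline desmoked image.
#'
#' @param images A [polarized_images()] set.
#' @param method `"POL"` (direct PD) or `"RPOL"` (refined PD).
#' @param fit A [fit_weight_vector()] result; required for `"RPOL"`.
#'   Defaults to the fit on the canonical 19-point grid.
#' @param ambient `NULL` for automatic estimation, an
#'   [estimate_ambient()] result, or a named numeric vector
#'   `c(i0 =, i45 =, i90 =, i135 =)` of oracle ambient channel values
#'   (see [ambient_truth()]).
#' @param ambient_strategy,ambient_q,ambient_roi Passed to
#'   [estimate_ambient()] when `ambient` is `NULL`.
#' @param t_min Transmission floor.
#' @param co_channel Co-polarized channel under the illumination axis.
#' @return An object of class `restoration_result` with the restored
#'   channels `j0`, `j45`, `j90`, `j135`, the recombined `s0`
#'   (`= j_co + j_cro`), the intermediate `pd` and `transmission`, the
#'   `ambient` used, and the method/parameter snapshot.
#' @examples
#' sc <- make_phantom_scene(c(32, 48), seed = 3, noise_sigma = 0)
#' out <- restore(degrade(sc), method = "RPOL")
#' glance(out)
#' @export
restore <- function(images, method = c("RPOL", "POL"), fit = NULL,
                    ambient = NULL, ambient_strategy = "auto_percentile",
                    ambient_q = 1, ambient_roi = NULL, t_min = 0.05,
                    co_channel = "i0") {
  stopifnot(inherits(images, "polarized_images"))
  method <- match.arg(method)

  coeffs <- NULL
  if (method == "RPOL") {
    fit <- fit %||% fit_weight_vector()
    coeffs <- refined_pd_coefficients(fit)
    pd <- refined_pd(images, coeffs)
  } else {
    pd <- direct_pd(images, co_channel)
  }

  if (is.null(ambient)) {
    ambient <- estimate_ambient(images, pd, strategy = ambient_strategy,
                                q = ambient_q, roi = ambient_roi,
                                co_channel = co_channel)
  } else if (is.numeric(ambient)) {
    if (is.null(names(ambient)) ||
        !all(c("i0", "i45", "i90", "i135") %in% names(ambient))) {
      stop_input("numeric `ambient` must be named i0/i45/i90/i135")
    }
    ambient <- structure(
      list(a_inf_pol = ambient[c("i0", "i45", "i90", "i135")],
           a_inf_co = ambient[[co_channel]], strategy = "oracle",
           support = NULL, co_channel = co_channel),
      class = "ambient_estimate")
  } else if (!inherits(ambient, "ambient_estimate")) {
    stop_input("`ambient` must be NULL, a named numeric vector, or an ambient_estimate")
  }

  a_pol <- ambient$a_inf_pol
  a_co <- ambient$a_inf_co
  get_a <- function(ch) if (is.matrix(a_pol)) a_pol[, ch] else a_pol[[ch]]

  # clamp the PD to the physically admissible range before inversion
  pd_cl <- if (length(dim(pd)) == 3 && length(a_co) > 1) {
    arr <- pd
    for (b in seq_along(a_co)) arr[, , b] <- pmax(pmin(pd[, , b], a_co[b]), 0)
    arr
  } else {
    pmax(pmin(pd, max(a_co)), 0)
  }
  t_map <- transmission_map(pd_cl, a_co, t_min = t_min)

  js <- lapply(c("i0", "i45", "i90", "i135"), function(ch) {
    restore_channel(images[[ch]], t_map, get_a(ch))
  })
  names(js) <- c("j0", "j45", "j90", "j135")
  cross <- c(i0 = "j90", i45 = "j135", i90 = "j0", i135 = "j45")
  co_j <- sub("^i", "j", co_channel)
  s0 <- js[[co_j]] + js[[cross[[co_channel]]]]

  structure(
    c(js,
      list(s0 = s0, pd = pd_cl, transmission = t_map, ambient = ambient,
           method = method, coefficients = coeffs,
           params = list(t_min = t_min, co_channel = co_channel))),
    class = "restoration_result")
}

#' @export
print.restoration_result <- function(x, ...) {
  cat(sprintf("<restoration_result> method %s, t_min %g, ambient via %s\n",
              x$method, x$params$t_min, x$ambient$strategy))
  invisible(x)
}

#' @rdname restore
#' @param x,object A `restoration_result`.
#' @param ... Unused.
#' @export
glance.restoration_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    a_inf_co = mean(x$ambient$a_inf_co),
    mean_t = mean(x$transmission$t),
    min_t = min(x$transmission$t),
    mean_pd = mean(x$pd),
    t_min = x$params$t_min,
    ambient_strategy = x$ambient$strategy)
}

#' @rdname restore
#' @export
autoplot.restoration_result <- function(object, ...) {
  to_gray <- function(img) if (length(dim(img)) == 3) {
    apply(img, c(1, 2), mean)
  } else img
  panels <- list(`restored S0` = to_gray(object$s0) / 2,
                 `PD` = to_gray(object$pd),
                 `transmission` = object$transmission$t |> to_gray())
  df <- purrr::imap_dfr(panels, function(img, nm) {
    g <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
    g$value <- img[cbind(g$row, g$col)]
    g$panel <- nm
    g
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
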