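#' Malus-law weight curve of an analyzer direction
#'
#' The contribution of linearly polarized light with electric-field
#' orientation `theta` to the intensity transmitted by an ideal analyzer at
#' `theta0` is `cos^2(theta0 - theta)` (Malus' law). These cosine-squared
#' curves are both the rows of the weight matrix relating analyzed
#' intensities to the electric-field-direction decomposition and the basis
#' functions of the refined-PD curve fit.
#'
#' @param theta0 Analyzer direction in degrees.
#' @param grid Orientation sample angles in degrees.
#' @return A tibble of class `weight_curve` with columns `theta` and
#'   `value`, and attribute `theta0`.
#' @examples
#' weight_curve(45)$value[10]  # = 1 at theta = 45
#' @export
weight_curve <- function(theta0, grid = seq(0, 90, by = 5)) {
  out <- tibble::tibble(theta = grid,
                        value = cos(deg2rad(theta0 - grid))^2)
  attr(out, "theta0") <- theta0
  class(out) <- c("weight_curve", class(out))
  out
}

#' Target weight curve for a cleaner orthogonal polarization
#'
#' Piecewise-linear target curve used to synthesize an orthogonal
#' polarization channel with the backscatter-dominated orientations
#' suppressed: zero on \[0, 45\] degrees (where the backscattered component
#' concentrates under 0-degree illumination) and rising linearly as
#' `theta/45 - 1` on \[45, 90\] degrees, reaching 1 at 90 degrees (the
#' orientation orthogonal to the illumination).
#'
#' @param grid Sample angles in degrees, all within \[0, 90\].
#' @return A tibble of class `target_curve` with columns `theta`, `value`.
#' @examples
#' target_curve(c(0, 45, 67.5, 90))$value  # 0, 0, 0.5, 1
#' @export
target_curve <- function(grid = seq(0, 90, by = 5)) {
  if (any(!is.finite(grid)) || any(grid < 0) || any(grid > 90)) {
    stop_input("`grid` must lie within [0, 90] degrees")
  }
  out <- tibble::tibble(theta = grid,
                        value = ifelse(grid <= 45, 0, grid / 45 - 1))
  class(out) <- c("target_curve", class(out))
  out
}

#' Fit cosine-squared weight curves to a target curve
#'
#' Least-squares fit of the target curve by a linear combination of
#' Malus-law basis curves `cos^2(theta0_k - theta)` at the chosen analyzer
#' directions. The model is linear in the amplitude coefficients, so the
#' solution is the closed-form linear least-squares solution; no iterative
#' optimizer is involved. With the default basis \{0, 45, 90\} degrees and
#' the default 19-point 5-degree grid the coefficients are the fixed
#' constants of the refined-PD estimator.
#'
#' @param target A data frame with columns `theta` (degrees) and `value`,
#'   typically from [target_curve()]. Its `theta` column is the fitting
#'   grid.
#' @param basis_angles Analyzer directions (degrees) of the basis curves.
#'   At least three distinct directions modulo 180 are required; more than
#'   three cosine-squared curves are always linearly dependent (they span
#'   only \{1, cos 2 theta, sin 2 theta\}) and raise an error naming the
#'   dependent angles.
#'
#' @return An object of class `pd_fit` with elements `coefficients` (named
#'   by basis angle), `basis_angles`, `grid`, `target`, `fitted`,
#'   `residuals`, `sse` and `r_square`.
#' @examples
#' fit <- fit_weight_vector(target_curve())
#' coef(fit)          # a, b, c of the refined PD
#' glance(fit)        # SSE and R-squared
#' @export
fit_weight_vector <- function(target = target_curve(),
                              basis_angles = c(0, 45, 90)) {
  if (!is.data.frame(target) || !all(c("theta", "value") %in% names(target))) {
    stop_input("`target` must be a data frame with columns `theta` and `value`")
  }
  grid <- target$theta
  y <- target$value
  p <- length(basis_angles)
  if (p < 3) stop_input("at least three basis angles are required")
  if (length(grid) < p) {
    stop_input("fitting grid must have at least as many samples as coefficients")
  }
  X <- vapply(basis_angles,
              function(a) cos(deg2rad(a - grid))^2,
              numeric(length(grid)))
  qrX <- qr(X)
  if (qrX$rank < p) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dep <- basis_angles[setdiff(seq_len(p), keep)]
    stop_input(
      "basis is rank-deficient on this grid: curve(s) at %s deg are linear combinations of the others (cos^2 curves span only a 3-dimensional space)",
      paste(dep, collapse = ", "))
  }
  coefs <- qr.coef(qrX, y)
  names(coefs) <- paste0("theta0_", basis_angles)
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(coefficients = coefs,
         basis_angles = basis_angles,
         grid = grid,
         target = y,
         fitted = fitted,
         residuals = resid,
         sse = sse,
         r_square = 1 - sse / sst),
    class = "pd_fit")
}

#' @export
coef.pd_fit <- function(object, ...) object$coefficients

#' @export
print.pd_fit <- function(x, ...) {
  cat("<pd_fit> weight-vector fit\n")
  cat("  basis (deg):", paste(x$basis_angles, collapse = ", "), "\n")
  cat("  coefficients:", paste(sprintf("%.4f", x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  SSE = %.4f, R-square = %.4f on %d grid points\n",
              x$sse, x$r_square, length(x$grid)))
  invisible(x)
}

#' @rdname fit_weight_vector
#' @param x,object A `pd_fit`.
#' @param ... Unused.
#' @export
tidy.pd_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 basis_angle = x$basis_angles,
                 estimate = unname(x$coefficients))
}

#' @rdname fit_weight_vector
#' @export
glance.pd_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, r.squared = x$r_square,
                 n_basis = length(x$basis_angles), n_grid = length(x$grid))
}

#' @rdname fit_weight_vector
#' @export
autoplot.pd_fit <- function(object, ...) {
  grid_fine <- seq(min(object$grid), max(object$grid), by = 0.5)
  df <- dplyr::bind_rows(
    tibble::tibble(theta = object$grid, value = object$target,
                   curve = "target"),
    tibble::tibble(theta = grid_fine,
                   value = evaluate_fitted_curve(object, grid_fine),
                   curve = "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(.data$theta, .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$curve == "target", ]) +
    ggplot2::labs(x = "electric-field orientation (deg)", y = "weight",
                  title = "Weight-vector curve fit")
}

#' Evaluate a fitted weight curve
#'
#' Evaluates `sum_k coef_k * cos^2(theta0_k - theta)` at arbitrary angles.
#' The curve has period 180 degrees.
#'
#' @param fit A [fit_weight_vector()] result.
#' @param theta Angles in degrees.
#' @return Numeric vector of curve values.
#' @export
evaluate_fitted_curve <- function(fit, theta) {
  stopifnot(inherits(fit, "pd_fit"))
  X <- vapply(fit$basis_angles,
              function(a) cos(deg2rad(a - theta))^2,
              numeric(length(theta)))
  drop(X %*% fit$coefficients)
}

#' Weight matrix of the discrete electric-field decomposition
#'
#' Matrix `M` with `M[i, j] = cos^2((theta0_i - theta_j))` relating the
#' vector of analyzed intensities at discrete analyzer directions to the
#' vector of intensities of discrete electric-field orientations,
#' `I = M %*% S`. The rows are Malus-law weight curves, so `M` is symmetric
#' with unit diagonal and numerical rank 3 (rows lie in the span of
#' \{1, cos 2 theta, sin 2 theta\}), which is why the decomposition cannot
#' be inverted directly and a prior is needed.
#'
#' @param step Angle step in degrees; must divide 90.
#' @param span Two-element range of directions in degrees (default 0 to 90).
#' @return A symmetric matrix with dimnames giving the angles.
#' @examples
#' M <- build_weight_matrix(step = 5)
#' qr(M)$rank  # 3
#' @export
build_weight_matrix <- function(step = 1, span = c(0, 90)) {
  if (length(span) != 2 || span[1] >= span[2]) {
    stop_input("`span` must be an increasing two-element angle range")
  }
  if ((span[2] - span[1]) %% step != 0) {
    stop_input("`step` must divide the span (%g deg)", span[2] - span[1])
  }
  angles <- seq(span[1], span[2], by = step)
  M <- outer(angles, angles, function(i, j) cos(deg2rad(i - j))^2)
  dimnames(M) <- list(angles, angles)
  M
}

#' Synthesize an analyzed intensity from an orientation histogram
#'
#' Given the intensities `S(theta)` of discrete electric-field orientations,
#' computes the intensity an ideal analyzer at `theta0` would transmit:
#' `sum_theta S(theta) * cos^2(theta0 - theta)`.
#'
#' @param hist A data frame with columns `theta` (degrees) and `mass`
#'   (non-negative intensities), e.g. from [efd_histogram()].
#' @param theta0 Analyzer direction(s) in degrees.
#' @return Numeric vector, one intensity per `theta0`.
#' @export
synthesize_intensity <- function(hist, theta0) {
  if (!is.data.frame(hist) || !all(c("theta", "mass") %in% names(hist)) ||
      nrow(hist) == 0) {
    stop_input("`hist` must be a non-empty data frame with columns `theta`, `mass`")
  }
  vapply(theta0,
         function(a) sum(hist$mass * cos(deg2rad(a - hist$theta))^2),
         numeric(1))
}
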