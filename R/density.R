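#' Cell density from the characteristic frequency
#'
#' The mean cell area follows from the characteristic frequency as
#' `A = alpha / f*^2` (px2), where `alpha` is a dimensionless shape
#' factor: 1 for a square lattice, `2/sqrt(3) ~ 1.15` for a perfect
#' hexagonal one (the densest possible packing, so real mosaics satisfy
#' `alpha < 1.15`; irregular mosaics may fall below 1). The endothelial
#' cell density is then `delta = f*^2 / alpha` per px2, converted to
#' mm^-2 with the lateral sampling density. With no calibration data,
#' `alpha = 1` is the customary default; calibrated clinical values for
#' the ring-enhanced estimator fall just below 1.
#'
#' @param f_star characteristic frequency in px^-1, or a
#'   `char_frequency` from [estimate_f_star()].
#' @param alpha shape factor (dimensionless).
#' @param sampling_um_per_px lateral sampling density, micrometer per
#'   pixel.
#' @return Object of class `density_estimate`: list with `f_star`,
#'   `alpha`, `sampling_um_per_px`, `mean_cell_area_px2`,
#'   `mean_cell_area_um2` and `density_mm2`.
#' @examples
#' d <- density_from_fstar(1 / 25, alpha = 1, sampling_um_per_px = 0.557)
#' round(d$density_mm2)   # 5158 cells per mm2
#' @export
density_from_fstar <- function(f_star, alpha = 1,
                               sampling_um_per_px = 0.557) {
  f <- fstar_value(f_star)
  if (!is.finite(f) || f <= 0 || f > 0.5)
    stop("f_star must lie in (0, 0.5] px^-1")
  if (alpha <= 0) stop("alpha must be positive")
  if (sampling_um_per_px <= 0) stop("sampling must be positive")
  area_px2 <- alpha / f^2
  area_um2 <- area_px2 * sampling_um_per_px^2
  structure(
    list(f_star = f, alpha = alpha,
         sampling_um_per_px = sampling_um_per_px,
         mean_cell_area_px2 = area_px2,
         mean_cell_area_um2 = area_um2,
         density_mm2 = 1e6 / area_um2),
    class = "density_estimate"
  )
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(
    "<density_estimate> %.0f cells/mm2 (mean cell area %.1f um2; f* = %.5f px^-1, alpha = %.3f)\n",
    x$density_mm2, x$mean_cell_area_um2, x$f_star, x$alpha))
  invisible(x)
}

#' Leave-one-out calibration of the shape factor alpha
#'
#' Given a training set of images with known ground-truth density
#' (`n_eval` cells in an evaluation area of `A_eval` px2) and an
#' estimated characteristic frequency per image, the per-image shape
#' factor is `alpha_j = f*_j^2 / delta_j` (with `delta_j` in cells per
#' px2). Held-out calibration assigns each image the arithmetic mean of
#' the other images' `alpha_j`, and reports the resulting relative
#' density error `(delta_est - delta_gt) / delta_gt`.
#'
#' @param f_stars numeric vector of characteristic frequencies (px^-1),
#'   or a list of `char_frequency` objects.
#' @param density_gt_px2 ground-truth densities, cells per px2
#'   (`n_eval / A_eval`).
#' @return data.frame with one row per image: `f_star`,
#'   `density_gt_px2`, `alpha_self` (that image's own ratio), `alpha`
#'   (held-out calibration), `density_est_px2`, `rel_error`.
#' @export
calibrate_alpha <- function(f_stars, density_gt_px2) {
  f <- vapply(if (is.list(f_stars)) f_stars else as.list(f_stars),
              fstar_value, numeric(1))
  d <- as.numeric(density_gt_px2)
  if (length(f) != length(d)) stop("f_stars and densities differ in length")
  if (any(!is.finite(f)) || any(f <= 0))
    stop("all training images need a valid f* estimate")
  if (any(d <= 0)) stop("ground-truth densities must be positive")
  n <- length(f)
  alpha_self <- f^2 / d
  alpha <- if (n == 1) alpha_self else
    (sum(alpha_self) - alpha_self) / (n - 1)
  d_est <- f^2 / alpha
  data.frame(
    f_star = f, density_gt_px2 = d, alpha_self = alpha_self,
    alpha = alpha, density_est_px2 = d_est,
    rel_error = (d_est - d) / d
  )
}

#' Ground-truth density of a phantom or ground truth object, cells/px2
#'
#' Convenience accessor: `n_eval / A_eval` with `A_eval` the rasterized
#' evaluation polygon area.
#'
#' @param truth an `endo_ground_truth` or `mosaic_phantom`.
#' @param dim image dimensions, needed when `truth$dim` is absent.
#' @return density in cells per px2.
#' @export
truth_density_px2 <- function(truth, dim = NULL) {
  if (inherits(truth, "mosaic_phantom")) truth <- truth$truth
  stopifnot(inherits(truth, "endo_ground_truth"))
  dim <- truth$dim %||% dim
  if (is.null(dim)) stop("image dimensions unknown")
  truth$n_eval / sum(polygon_mask(truth$polygon, dim))
}
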