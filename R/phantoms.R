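#' Band-limited lattice phantom
#'
#' Generates the classic synthetic test pattern for spectral density
#' estimation: a periodic mosaic of bright cells separated by dark
#' 1-pixel lines, low-pass filtered so that only spatial frequencies
#' below `band_limit_factor` times the lattice fundamental survive.
#' For a square lattice with cell side `s` the characteristic frequency
#' is `1/s` px^-1 and the shape factor `alpha = 1`; for a hexagonal
#' lattice with distance `s` across flats it is `2/(sqrt(3) s)` px^-1
#' and `alpha = 2/sqrt(3) ~ 1.15`.
#'
#' Cells are axis-aligned with a lattice site at the image corner;
#' hexagons are flat-topped. The gray levels of the binary pattern
#' before filtering are 210 (cells) and 40 (lines); after filtering the
#' image is linearly rescaled to use the full 8-bit range.
#'
#' @param pattern `"square"` or `"hexagonal"`.
#' @param size_px edge length of the square image, pixels.
#' @param side_to_side_px cell width: square side, or hexagon distance
#'   across flats. Must satisfy `size_px >= 4 * side_to_side_px`.
#' @param band_limit_factor isotropic low-pass cutoff, as a multiple of
#'   the lattice fundamental frequency.
#' @return Object of class `lattice_phantom`: list with `image` (8-bit
#'   grayscale matrix, rows = y), `pattern`, `size_px`,
#'   `side_to_side_px`, `true_f_star` (px^-1) and `true_alpha`.
#' @examples
#' ph <- make_lattice("hexagonal", 350, 25)
#' ph$true_f_star * 350   # ~16.17: the ring sits at bin 16
#' @export
make_lattice <- function(pattern = c("square", "hexagonal"),
                         size_px = 350L, side_to_side_px = 25,
                         band_limit_factor = 3) {
  pattern <- match.arg(pattern)
  n <- as.integer(size_px)
  s <- side_to_side_px
  if (n < 4 * s) stop("size_px must be at least 4 * side_to_side_px")

  if (pattern == "square") {
    true_f <- 1 / s
    true_alpha <- 1
    xy <- 0:(n - 1)
    dark <- outer((xy %% s) < 1, (xy %% s) < 1, "|")  # rows = y, cols = x
  } else {
    true_f <- 2 / (sqrt(3) * s)
    true_alpha <- 2 / sqrt(3)
    centers <- hex_lattice_points(spacing = s, xlim = c(-2 * s, n + 2 * s),
                                  ylim = c(-2 * s, n + 2 * s))
    vr <- voronoi_render_cpp(n, n, centers, 1)
    dark <- vr$boundary
  }
  img <- matrix(210, n, n)
  img[dark] <- 40
  img <- band_limit(img, cutoff = band_limit_factor * true_f)

  structure(
    list(image = img, pattern = pattern, size_px = n,
         side_to_side_px = s, true_f_star = true_f,
         true_alpha = true_alpha),
    class = "lattice_phantom"
  )
}

# isotropic hard low-pass in the Fourier domain, then rescale to [0, 255]
band_limit <- function(img, cutoff) {
  n <- nrow(img)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) / n     # unshifted DFT frequencies
  keep <- outer(f^2, f^2, "+") < cutoff^2
  sp <- stats::fft(img) * keep
  out <- Re(stats::fft(sp, inverse = TRUE)) / length(img)
  out <- (out - min(out)) / (max(out) - min(out)) * 255
  round(out)
}

# flat-top hexagonal (triangular) lattice points with nearest-neighbor
# distance `spacing`; one point at the origin. Returns (x, y) matrix.
hex_lattice_points <- function(spacing, xlim, ylim) {
  h <- sqrt(3) / 2 * spacing                # column pitch in x
  jr <- floor(xlim[1] / h):ceiling(xlim[2] / h)
  ir <- floor(ylim[1] / spacing - 1):ceiling(ylim[2] / spacing + 1)
  g <- expand.grid(i = ir, j = jr)
  x <- g$j * h
  y <- (g$i + (g$j %% 2) / 2) * spacing
  ok <- x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2]
  cbind(x = x[ok], y = y[ok])
}

#' @export
print.lattice_phantom <- function(x, ...) {
  cat(sprintf(
    "<lattice_phantom> %s, %d x %d px, cell %g px, f* = %.5f px^-1, alpha = %.4f\n",
    x$pattern, x$size_px, x$size_px, x$side_to_side_px, x$true_f_star,
    x$true_alpha))
  invisible(x)
}

# Simulation-calibrated map from lattice jitter (displacement radius as
# a fraction of the lattice spacing) to the coefficient of variation of
# Voronoi cell area: mean measured CV over 3 seeds on 600 px mosaics at
# 2000 cells/mm2 (see the methods vignette for the protocol). Monotone;
# interpolated linearly in both directions.
.cv_cal <- list(
  jitter = c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8),
  cv     = c(0, 0.0217, 0.0429, 0.0650, 0.0875, 0.1369, 0.1901,
             0.2444, 0.2933, 0.3261, 0.3552)
)

size_cv_from_jitter <- function(jitter) {
  stats::approx(.cv_cal$jitter, .cv_cal$cv, xout = jitter, rule = 2)$y
}

#' @rdname make_mosaic
#' @param size_cv target coefficient of variation of cell area
#'   (fraction, e.g. 0.25 for 25 %).
#' @export
jitter_for_size_cv <- function(size_cv) {
  if (size_cv < 0) stop("size_cv must be >= 0")
  if (size_cv == 0) return(0)
  if (size_cv > max(.cv_cal$cv))
    stop("requested size_cv larger than attainable by lattice jitter (max ",
         round(max(.cv_cal$cv), 2), ")")
  stats::approx(.cv_cal$cv, .cv_cal$jitter, xout = size_cv)$y
}

#' Synthetic endothelium mosaic with ground truth
#'
#' Emulates a confocal image of corneal endothelium: a Voronoi mosaic of
#' a jittered hexagonal point process, rendered as bright cells separated
#' by dark boundary lines, with additive Gaussian noise and a
#' multiplicative low-frequency illumination gradient. All randomness
#' derives from the single `seed` argument. The exact cell geometry is
#' returned as ground truth: a label image, one marker point strictly
#' inside each complete cell, and an evaluation polygon outlining the
#' union of the complete cells (cells not touching the image border),
#' mirroring the marker-plus-outline ground truth drawn by an expert on
#' clinical images.
#'
#' Cell size variability is controlled either directly through `jitter`
#' (displacement radius of lattice points, as a fraction of the lattice
#' spacing) or through `size_cv`, which is converted to a jitter via a
#' simulation-calibrated mapping ([jitter_for_size_cv()]).
#'
#' @param size_px image edge length, pixels.
#' @param density_mm2 target cell density, cells per mm2.
#' @param sampling_um_per_px lateral sampling density, micrometer per
#'   pixel (0.557 for the slit-scanning confocal instrument the defaults
#'   model).
#' @param jitter displacement radius as a fraction of lattice spacing;
#'   overrides `size_cv` when given.
#' @param boundary_width_px width of the dark intercellular lines:
#'   pixels within half this distance of a Voronoi edge are boundary.
#' @param noise_sd additive Gaussian noise standard deviation (gray
#'   levels).
#' @param illumination_amplitude relative amplitude of the multiplicative
#'   linear illumination gradient (0 disables it).
#' @param cell_intensity,boundary_intensity,intensity_sd mean gray level
#'   of cells and boundaries, and the between-cell intensity spread.
#' @param seed integer seed; identical seeds give identical phantoms.
#' @return Object of class `mosaic_phantom`: list with `image` (8-bit
#'   grayscale matrix), `truth_labels` (integer label matrix, boundary
#'   pixels 0), `truth_markers` (one `(x, y)` row per complete cell,
#'   0-based pixel coordinates), `truth` (an `endo_ground_truth` with the
#'   markers and evaluation polygon), `cells` (per-cell table: label,
#'   area in px2, centroid, completeness) and `params`.
#' @examples
#' ph <- make_mosaic(size_px = 300, seed = 1)
#' nrow(ph$cells)                      # cells visible in the frame
#' @export
make_mosaic <- function(size_px = 500L, density_mm2 = 2000,
                        sampling_um_per_px = 0.557,
                        size_cv = 0.25, jitter = NULL,
                        boundary_width_px = 2, noise_sd = 8,
                        illumination_amplitude = 0.15,
                        cell_intensity = 190, boundary_intensity = 60,
                        intensity_sd = 4, seed) {
  if (missing(seed)) stop("an explicit `seed` is required")
  n <- as.integer(size_px)
  area_mm2 <- (n * sampling_um_per_px / 1000)^2
  n_target <- density_mm2 * area_mm2
  if (n_target < 10)
    stop("parameters yield fewer than 10 cells; increase size or density")
  if (is.null(jitter)) jitter <- jitter_for_size_cv(size_cv)

  a <- sqrt(2 * (n^2 / n_target) / sqrt(3))   # lattice spacing, px
  withr::local_seed(seed)

  centers <- hex_lattice_points(a, c(-2 * a, n + 2 * a), c(-2 * a, n + 2 * a))
  # fixed fractional phase: keeps Voronoi edges of the unjittered lattice
  # clear of the frame border (an exact alignment no real mosaic shows)
  centers <- centers + rep(c(0.293, 0.407) * a, each = nrow(centers))
  if (jitter > 0) {
    m <- nrow(centers)
    r <- jitter * a * sqrt(runif(m))
    th <- runif(m, 0, 2 * pi)
    centers <- centers + cbind(r * cos(th), r * sin(th))
  }
  vr <- voronoi_render_cpp(n, n, centers, boundary_width_px)
  part <- vr$labels                          # full partition, no 0s
  boundary <- vr$boundary

  # compact region table over cells visible in the frame
  present <- sort(unique(as.vector(part)))
  relab <- integer(max(present))
  relab[present] <- seq_along(present)
  part <- matrix(relab[part], n, n)
  k <- length(present)

  interior <- part
  interior[boundary] <- 0L                   # truth label image

  idx <- seq_len(n * n)
  yy <- (idx - 1) %% n                       # 0-based y (row)
  xx <- (idx - 1) %/% n                      # 0-based x (col)
  pix_by_cell <- split(idx, as.vector(part))
  area_px <- tabulate(interior, nbins = k)   # boundary pixels excluded

  on_border <- logical(k)
  bmask <- yy == 0 | yy == n - 1 | xx == 0 | xx == n - 1
  on_border[unique(as.vector(part)[bmask])] <- TRUE
  complete <- !on_border & area_px > 0

  centroid <- t(vapply(pix_by_cell, function(p) {
    c(mean(xx[p]), mean(yy[p]))
  }, numeric(2)))

  # marker: interior (non-boundary) pixel of the cell nearest its centroid
  markers <- t(vapply(seq_len(k), function(l) {
    p <- pix_by_cell[[l]]
    p <- p[!boundary[p]]
    if (length(p) == 0) return(c(NA_real_, NA_real_))
    d <- (xx[p] - centroid[l, 1])^2 + (yy[p] - centroid[l, 2])^2
    c(xx[p[which.min(d)]], yy[p[which.min(d)]])
  }, numeric(2)))

  # evaluation region: union of complete cells (their full Voronoi extent)
  eval_mask <- matrix(complete[part], n, n)
  polygon <- trace_mask_contour(eval_mask)
  truth <- new_ground_truth(markers[complete, , drop = FALSE], polygon,
                            dim = c(n, n))

  # rendering: per-cell base intensity, dark lines, illumination, noise
  base_int <- pmax(pmin(rnorm(k, cell_intensity, intensity_sd), 255), 0)
  img <- matrix(base_int[part], n, n)
  img[boundary] <- boundary_intensity
  if (illumination_amplitude > 0) {
    phi <- runif(1, 0, 2 * pi)
    ramp <- outer((yy[seq_len(n)] / (n - 1) - 0.5) * sin(phi),
                  rep(1, n)) +
            outer(rep(1, n), ((0:(n - 1)) / (n - 1) - 0.5) * cos(phi))
    img <- img * (1 + illumination_amplitude * ramp)
  }
  if (noise_sd > 0) img <- img + rnorm(n * n, 0, noise_sd)
  img <- round(pmax(pmin(img, 255), 0))

  cells <- data.frame(
    label = seq_len(k), area_px = area_px,
    centroid_x = centroid[, 1], centroid_y = centroid[, 2],
    marker_x = markers[, 1], marker_y = markers[, 2],
    complete = complete
  )
  structure(
    list(image = img, truth_labels = interior,
         truth_markers = markers[complete, , drop = FALSE],
         truth = truth, cells = cells,
         params = list(size_px = n, density_mm2 = density_mm2,
                       sampling_um_per_px = sampling_um_per_px,
                       size_cv = size_cv, jitter = jitter,
                       boundary_width_px = boundary_width_px,
                       noise_sd = noise_sd,
                       illumination_amplitude = illumination_amplitude,
                       seed = seed, lattice_spacing_px = a,
                       n_cells_target = n_target)),
    class = "mosaic_phantom"
  )
}

#' @export
print.mosaic_phantom <- function(x, ...) {
  cat(sprintf(
    "<mosaic_phantom> %d x %d px, %d cells in frame (%d complete), jitter %.3f, seed %d\n",
    x$params$size_px, x$params$size_px, nrow(x$cells),
    sum(x$cells$complete), x$params$jitter, x$params$seed))
  invisible(x)
}

# outer contour of a single-component binary mask, as an (x, y) polygon
# in 0-based pixel coordinates (vertices are boundary pixel centers)
trace_mask_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(t(mask * 1)))
  if (length(oc) == 0) stop("empty evaluation mask")
  poly <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  colnames(poly) <- c("x", "y")
  poly
}
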