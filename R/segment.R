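#' Stochastic watershed parameters
#'
#' The segmentation has three tunable parameters plus the repetition
#' count: `u`, the range of the uniform noise added at every repetition
#' (gray levels); `k_sigma`, the PDF smoothing size relative to the cell
#' size (`sigma_PDF = k_sigma / f*`); `k_h`, the depth of local minima
#' to suppress (`h = k_h * m / sigma_PDF`); and `m`, the number of
#' seeded-watershed repetitions. The defaults are the values found
#' optimal by leave-one-out training on clinical confocal images
#' (`u = 30`, `k_sigma = 0.17`, `k_h = 0.002`, `m = 100`); `alpha` is
#' the shape factor used when converting `f*` to a seed count and is
#' taken as 1 at the seeding stage.
#'
#' @param u noise range, gray levels (>= 0).
#' @param k_sigma relative smoothing size (> 0).
#' @param k_h relative H-minima depth (>= 0).
#' @param m repetitions (>= 1).
#' @param alpha shape factor for seeding.
#' @return list of class `stowa_params`.
#' @export
stowa_params <- function(u = 30, k_sigma = 0.17, k_h = 0.002, m = 100L,
                         alpha = 1) {
  stopifnot(u >= 0, k_sigma > 0, k_h >= 0, m >= 1, alpha > 0)
  structure(list(u = u, k_sigma = k_sigma, k_h = k_h, m = as.integer(m),
                 alpha = alpha),
            class = "stowa_params")
}

#' @export
print.stowa_params <- function(x, ...) {
  cat(sprintf("<stowa_params> u = %g, k_sigma = %g, k_h = %g, m = %d, alpha = %g\n",
              x$u, x$k_sigma, x$k_h, x$m, x$alpha))
  invisible(x)
}

#' Expected number of cells in an image
#'
#' `n_seeds = A_I * f*^2 / alpha`, the image area times the spectral
#' density estimate, rounded to the nearest integer (at least 1).
#'
#' @param image_area_px2 image area in px2.
#' @param f_star characteristic frequency (px^-1) or `char_frequency`.
#' @param alpha shape factor.
#' @return integer seed count.
#' @examples
#' n_seeds_from_fstar(350^2, 1 / 25)   # 196 cells of area 625 px2
#' @export
n_seeds_from_fstar <- function(image_area_px2, f_star, alpha = 1) {
  f <- fstar_value(f_star)
  stopifnot(image_area_px2 > 0, f > 0, alpha > 0)
  max(1L, as.integer(round(image_area_px2 * f^2 / alpha)))
}

#' Randomly placed hexagonal seed grid
#'
#' Seeds are the points of a hexagonal grid with edge length
#' `t = sqrt(2/(3 sqrt(3)) * A_I / n_seeds)` (one grid point per hexagon
#' of edge `t`, so the seed density matches the requested cell density),
#' given a rotation drawn uniformly from `[0, 2 pi)` and a translation
#' uniform over one grid cell. Points falling outside the image are
#' dropped. Randomness is taken from the current RNG state.
#'
#' @param dim image dimensions `c(rows, cols)`.
#' @param n_seeds requested seed density, seeds per image.
#' @return matrix of seed coordinates `(x, y)`, 0-based, continuous.
#' @export
hex_seed_grid <- function(dim, n_seeds) {
  stopifnot(n_seeds >= 1)
  nr <- dim[1]; nc <- dim[2]
  t_edge <- sqrt(2 / (3 * sqrt(3)) * (nr * nc) / n_seeds)
  a <- sqrt(3) * t_edge                    # point spacing of the grid
  theta <- runif(1, 0, 2 * pi)
  # basis vectors of the rotated lattice
  v1 <- a * c(cos(theta), sin(theta))
  v2 <- a * c(cos(theta + pi / 3), sin(theta + pi / 3))
  shift <- runif(2)                        # translation within one cell
  ctr <- c(nc - 1, nr - 1) / 2
  rad <- sqrt(sum((c(nc, nr) / 2)^2)) + a
  krange <- ceiling(rad / a * 1.3) + 1
  k <- expand.grid(i = -krange:krange, j = -krange:krange)
  x <- ctr[1] + (k$i + shift[1]) * v1[1] + (k$j + shift[2]) * v2[1]
  y <- ctr[2] + (k$i + shift[1]) * v1[2] + (k$j + shift[2]) * v2[2]
  ok <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  structure(cbind(x = x[ok], y = y[ok]), t_edge = t_edge)
}

#' Seeded watershed
#'
#' Floods a topographic surface (high values = ridges; for endothelium
#' images, the inverted image) from labeled seeds, the only minima of
#' the flooded relief, producing exactly one 4-connected region per seed
#' label separated by watershed lines (label 0). Ties in the flooding
#' order are broken first-in-first-out, so the result is deterministic.
#'
#' @param surface numeric matrix.
#' @param seeds either an integer matrix of seed labels (same size as
#'   `surface`, 0 = no seed) or a matrix of `(x, y)` seed coordinates
#'   (0-based; each point becomes its own label).
#' @return integer label matrix; 0 marks watershed lines.
#' @export
seeded_watershed <- function(surface, seeds) {
  surface <- as_gray_matrix(surface)
  if (is.matrix(seeds) && ncol(seeds) == 2 &&
      !all(dim(seeds) == dim(surface))) {
    seeds <- seeds_to_labels(seeds, dim(surface))
  }
  storage.mode(seeds) <- "integer"
  if (!any(seeds > 0)) stop("at least one seed is required")
  seeded_watershed_cpp(surface, seeds)
}

# rasterize seed points to a label image; points sharing a pixel merge
seeds_to_labels <- function(pts, dim) {
  i <- round(pts[, 2]) + 1
  j <- round(pts[, 1]) + 1
  ok <- !is.na(i) & !is.na(j) & i >= 1 & i <= dim[1] & j >= 1 & j <= dim[2]
  i <- i[ok]; j <- j[ok]
  m <- matrix(0L, dim[1], dim[2])
  lin <- cbind(i, j)
  keep <- !duplicated(lin)
  m[lin[keep, , drop = FALSE]] <- seq_len(sum(keep))
  m
}

#' Boundary-occurrence map (PDF) of the stochastic watershed
#'
#' Runs `m` repetitions of the seeded watershed on the inverted image.
#' Each repetition adds uniform noise in `[0, u]` to the (floating
#' point) inverted image and places a freshly randomized hexagonal seed
#' grid; the watershed-line pixels of the resulting segmentation
#' increment a per-pixel counter. The count map — between 0 and `m`
#' everywhere — estimates the likelihood that a pixel belongs to a cell
#' boundary.
#'
#' @param image grayscale image matrix (bright cells, dark boundaries).
#' @param params [stowa_params()].
#' @param f_star characteristic frequency used to derive the seed count
#'   via [n_seeds_from_fstar()]; ignored when `n_seeds` is given.
#' @param n_seeds explicit seed count (overrides `f_star`).
#' @param seed master seed; per-repetition streams are derived from it.
#' @param seeds optional fixed seed points (`(x, y)` matrix) used for
#'   every repetition instead of a fresh random grid; diagnostic use.
#' @return Object of class `pdf_map`: list with `counts` (integer
#'   matrix), `m`, `n_seeds` and `params`.
#' @export
build_pdf <- function(image, params = stowa_params(), f_star = NULL,
                      n_seeds = NULL, seed = 1L, seeds = NULL) {
  img <- as_gray_matrix(image)
  stopifnot(inherits(params, "stowa_params"))
  if (is.null(n_seeds)) {
    if (is.null(f_star) && is.null(seeds))
      stop("either f_star, n_seeds or fixed seeds are required")
    n_seeds <- if (is.null(seeds))
      n_seeds_from_fstar(length(img), f_star, params$alpha)
    else nrow(seeds)
  }
  inv <- max(img) - img
  counts <- matrix(0L, nrow(img), ncol(img))
  withr::local_seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, params$m)
  for (r in seq_len(params$m)) {
    set.seed(rep_seeds[r])
    surf <- inv
    if (params$u > 0)
      surf <- surf + runif(length(surf), 0, params$u)
    pts <- seeds %||% hex_seed_grid(dim(img), n_seeds)
    if (nrow(pts) == 0) next
    lab <- seeded_watershed_cpp(surf, seeds_to_labels(pts, dim(img)))
    counts <- counts + (lab == 0L)
  }
  structure(list(counts = counts, m = params$m, n_seeds = n_seeds,
                 params = params),
            class = "pdf_map")
}

#' @export
print.pdf_map <- function(x, ...) {
  cat(sprintf("<pdf_map> %d x %d, m = %d repetitions, %d seeds/rep, max count %d\n",
              nrow(x$counts), ncol(x$counts), x$m, x$n_seeds, max(x$counts)))
  invisible(x)
}

#' Extract a segmentation from a PDF
#'
#' Smooths the boundary-occurrence counts with a Gaussian kernel of size
#' `sigma_PDF = k_sigma / f*`, suppresses local minima shallower than
#' `h = k_h * m / sigma_PDF` with the H-minima transform, and applies
#' the classical watershed (flooding from all remaining regional
#' minima).
#'
#' @param pdf a [build_pdf()] result.
#' @param params [stowa_params()] (defaults to those stored in `pdf`).
#' @param f_star characteristic frequency (px^-1) or `char_frequency`.
#' @return integer label matrix, watershed lines = 0.
#' @export
pdf_to_labels <- function(pdf, params = NULL, f_star) {
  stopifnot(inherits(pdf, "pdf_map"))
  params <- params %||% pdf$params
  f <- fstar_value(f_star)
  stopifnot(f > 0)
  sigma <- params$k_sigma / f
  sm <- EBImage::gblur(pdf$counts + 0, sigma = sigma)
  h <- params$k_h * pdf$m / sigma
  if (h > 0) sm <- hminima(sm, h)
  seeds <- regional_minima_cpp(sm)
  seeded_watershed_cpp(sm, seeds)
}

#' H-minima transform
#'
#' Suppresses all regional minima of depth less than `h`, by erosion
#' reconstruction of `x + h` over `x` (computed through the dual
#' dilation reconstruction).
#'
#' @param x numeric matrix.
#' @param h minimum depth to preserve.
#' @return numeric matrix.
#' @export
hminima <- function(x, h) {
  stopifnot(h >= 0)
  if (h == 0) return(x)
  -reconstruct_dilate_cpp(-(x + h), -x)
}

#' Re-estimate the characteristic frequency from a PDF
#'
#' The boundary-occurrence map is a clean rendition of the cell mosaic
#' (no illumination gradient, no texture), so running the ring-enhanced
#' spectral estimator on it yields a robust `f*` even when the estimate
#' from the original image was poor. Used to set the PDF smoothing size.
#'
#' @param pdf a [build_pdf()] result.
#' @return a `char_frequency` (method `"modeRMrec"`).
#' @export
refine_fstar_from_pdf <- function(pdf) {
  stopifnot(inherits(pdf, "pdf_map"))
  estimate_f_star(pdf$counts + 0, method = "modeRMrec")
}

#' Re-align segmentation boundaries with the image
#'
#' The watershed of the smoothed PDF follows ridges of a blurred image,
#' which may be displaced from the true boundaries. This step shrinks
#' every region by 20 % — keeping the pixels `x` with
#' `D_c(x) / (D_c(x) + D_b(x)) < 0.8`, where `D_c` is the Euclidean
#' distance to the region's center of mass (or to the region pixel
#' nearest it, if the centroid falls outside the region) and `D_b` the
#' Euclidean distance to the region boundary — and uses the shrunken
#' regions as seeds for a seeded watershed of the original image,
#' inverted and lightly smoothed (Gaussian, `sigma = 2`). Regions whose
#' shrunken marker would be empty keep their full extent as seed. The
#' number of regions is preserved.
#'
#' @param image the original grayscale image.
#' @param labels integer label matrix from [pdf_to_labels()].
#' @param sigma smoothing of the inverted image before re-flooding.
#' @return integer label matrix, watershed lines = 0.
#' @export
correct_borders <- function(image, labels, sigma = 2) {
  img <- as_gray_matrix(image)
  lab <- as_labels(labels)
  stopifnot(all(dim(img) == dim(lab)))
  k <- max(lab)
  if (k == 0) stop("no regions to correct")

  # distance to the region boundary: watershed lines and image edge
  inside <- lab != 0L
  padded <- matrix(0, nrow(lab) + 2, ncol(lab) + 2)
  padded[2:(nrow(lab) + 1), 2:(ncol(lab) + 1)] <- inside
  db <- EBImage::distmap(padded)[2:(nrow(lab) + 1), 2:(ncol(lab) + 1)]

  idx <- which(inside)
  yy <- (idx - 1) %% nrow(lab)
  xx <- (idx - 1) %/% nrow(lab)
  lv <- lab[idx]
  present <- sort(unique(lv))
  li <- match(lv, present)                 # index into per-region vectors
  cx <- as.numeric(tapply(xx, li, mean))
  cy <- as.numeric(tapply(yy, li, mean))
  d2c <- (xx - cx[li])^2 + (yy - cy[li])^2

  # centroid outside its (non-convex) region: use nearest region pixel
  ci <- cbind(round(cy) + 1, round(cx) + 1)
  bad <- which(lab[ci] != present)
  for (l in bad) {
    sel <- li == l
    p <- which(sel)[which.min(d2c[sel])]
    d2c[sel] <- (xx[sel] - xx[p])^2 + (yy[sel] - yy[p])^2
  }

  dc <- sqrt(d2c)
  keep <- dc / (dc + db[idx]) < 0.8
  seeds <- matrix(0L, nrow(lab), ncol(lab))
  seeds[idx[keep]] <- lv[keep]
  empty <- !(present %in% lv[keep])
  if (any(empty)) {
    sel <- li %in% which(empty)
    seeds[idx[sel]] <- lv[sel]             # keep the full extent as seed
  }
  surf <- EBImage::gblur(max(img) - img, sigma = sigma)
  seeded_watershed_cpp(surf, seeds)
}

#' Fully automatic cell segmentation
#'
#' The complete pipeline: estimate the characteristic frequency with the
#' ring-enhanced spectral estimator; derive the seed count (`alpha = 1`);
#' build the stochastic-watershed boundary map ([build_pdf()]);
#' re-estimate `f*` from that map (more robust than the image estimate);
#' extract the segmentation by smoothing, H-minima suppression and
#' classical watershed ([pdf_to_labels()]); and re-align the boundaries
#' with the unsmoothed image ([correct_borders()]).
#'
#' @param image grayscale image matrix (or phantom).
#' @param params [stowa_params()].
#' @param sampling_um_per_px lateral sampling density (recorded in the
#'   result; the segmentation itself works in pixels).
#' @param seed master seed for the stochastic components.
#' @param f_star optional known characteristic frequency, bypassing the
#'   spectral estimate.
#' @param n_seeds optional explicit seed count, bypassing the density
#'   estimate for seeding only.
#' @param refine_fstar re-estimate `f*` from the PDF before smoothing
#'   (recommended). If the re-estimate fails, the initial value is kept.
#' @param border_correction run the final boundary re-alignment.
#' @param keep_pdf retain the PDF in the returned object.
#' @return Object of class `endo_segmentation`: list with `labels`
#'   (integer matrix, boundary = 0), `f_star_initial`, `f_star_used`
#'   (the value that set the smoothing), `n_seeds`, `params`,
#'   `sampling_um_per_px`, `seed` and (optionally) `pdf`.
#' @export
segment_cells <- function(image, params = stowa_params(),
                          sampling_um_per_px = 0.557, seed = 1L,
                          f_star = NULL, n_seeds = NULL,
                          refine_fstar = TRUE, border_correction = TRUE,
                          keep_pdf = FALSE) {
  img <- as_gray_matrix(image)
  stopifnot(inherits(params, "stowa_params"))
  f0 <- if (is.null(f_star)) estimate_f_star(img, "modeRMrec")
        else f_star
  if (is.null(n_seeds))
    n_seeds <- n_seeds_from_fstar(length(img), f0, params$alpha)
  pdf <- build_pdf(img, params, n_seeds = n_seeds, seed = seed)
  f_used <- f0
  if (refine_fstar) {
    f_used <- tryCatch(refine_fstar_from_pdf(pdf), endo_no_ring = function(e) {
      message("PDF re-estimation found no ring; keeping the initial f*")
      f0
    })
  }
  lab <- pdf_to_labels(pdf, params, f_used)
  if (border_correction) lab <- correct_borders(img, lab)
  structure(
    list(labels = lab, f_star_initial = fstar_value(f0),
         f_star_used = fstar_value(f_used), n_seeds = n_seeds,
         params = params, sampling_um_per_px = sampling_um_per_px,
         seed = seed, pdf = if (keep_pdf) pdf else NULL),
    class = "endo_segmentation"
  )
}

#' @export
print.endo_segmentation <- function(x, ...) {
  cat(sprintf(
    "<endo_segmentation> %d x %d, %d regions (f* = %.5f px^-1, %d seeds/rep, m = %d)\n",
    nrow(x$labels), ncol(x$labels), max(x$labels), x$f_star_used,
    x$n_seeds, x$params$m))
  invisible(x)
}

# plain integer label matrix from whatever callers hand us
as_labels <- function(x) {
  if (inherits(x, "endo_segmentation")) x <- x$labels
  if (is.list(x) && !is.null(x$labels)) x <- x$labels
  if (!is.matrix(x)) stop("expected a label matrix")
  storage.mode(x) <- "integer"
  x
}
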