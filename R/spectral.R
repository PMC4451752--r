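#' 2-D frequency spectrum of a grayscale image
#'
#' Computes the magnitude of the discrete Fourier transform on a square
#' working frame, DC-centered. Non-square images are reduced to their
#' largest centered square crop, which keeps the radial frequency bins
#' isotropic.
#'
#' @param image numeric matrix (rows = y, columns = x), or an object with
#'   an `$image` field such as a phantom.
#' @return An object of class `spectrum2d`: a list with `magnitude` (the
#'   DC-centered magnitude spectrum, a square matrix), `size` (the frame
#'   width N in pixels) and `dc` (the 1-based row/column index of the DC
#'   sample, `floor(N/2) + 1`).
#' @seealso [radial_project()], [enhance_ring()], [estimate_f_star()]
#' @export
spectrum2d <- function(image) {
  img <- as_gray_matrix(image)
  n <- min(dim(img))
  if (n < 4L) stop("image too small for spectral analysis")
  r0 <- floor((nrow(img) - n) / 2)
  c0 <- floor((ncol(img) - n) / 2)
  img <- img[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n), drop = FALSE]
  mag <- fftshift2(Mod(stats::fft(img)))
  structure(
    list(magnitude = mag, size = n, dc = floor(n / 2) + 1L),
    class = "spectrum2d"
  )
}

# swap quadrants so that DC ends up at (floor(N/2)+1, floor(N/2)+1)
fftshift2 <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  ri <- c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))
  ci <- c((floor(m / 2) + 1):m, seq_len(floor(m / 2)))
  x[ri, ci, drop = FALSE]
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("<spectrum2d> %d x %d, DC at index %d (1-based)%s\n",
              x$size, x$size, x$dc,
              if (isTRUE(x$ring_enhanced)) ", ring-enhanced" else ""))
  invisible(x)
}

#' Radial projection of a 2-D spectrum
#'
#' Projects the 2-D spectrum onto radial frequency bins
#' `f = {0, 1/N, 2/N, ..., 1/2}` px^-1. Each 2-D sample is assigned to
#' the bin nearest its radial frequency; samples beyond 1/2 px^-1 (the
#' frame corners) fall into the last bin. Per bin, values are aggregated
#' as the mean of the magnitude, the maximum of the magnitude, or the
#' mean of the power (squared magnitude).
#'
#' @param spec a [spectrum2d()] object.
#' @param aggregate one of `"mean_magnitude"`, `"max_magnitude"`,
#'   `"mean_power"`.
#' @return An object of class `radial_profile`: list with `bins`
#'   (frequencies in px^-1), `values`, `counts` (samples per bin), `n`
#'   (frame width) and `aggregate`.
#' @export
radial_project <- function(spec,
                           aggregate = c("mean_magnitude", "max_magnitude",
                                         "mean_power")) {
  stopifnot(inherits(spec, "spectrum2d"))
  aggregate <- match.arg(aggregate)
  n <- spec$size
  vals <- spec$magnitude
  if (length(vals) == 0) stop("empty spectrum")
  if (aggregate == "mean_power") vals <- vals^2
  ctr <- floor(n / 2)                       # 0-based index of DC
  fx <- (seq_len(n) - 1 - ctr) / n
  r <- sqrt(outer(fx^2, fx^2, "+"))         # radial frequency of samples
  nb <- floor(n / 2) + 1L                   # bins 0 .. floor(N/2)
  bin <- pmin(as.integer(round(r * n)), nb - 1L) + 1L
  counts <- tabulate(bin, nbins = nb)
  if (aggregate == "max_magnitude") {
    values <- rep(-Inf, nb)
    ord <- order(bin)
    values[unique(bin[ord])] <-
      vapply(split(as.vector(vals)[ord], bin[ord]), max, numeric(1))
    values[values == -Inf] <- 0
  } else {
    sums <- vapply(split(as.vector(vals), bin), sum, numeric(1))
    values <- numeric(nb)
    values[as.integer(names(sums))] <- sums
    values <- values / pmax(counts, 1L)
  }
  structure(
    list(bins = (0:(nb - 1L)) / n, values = values, counts = counts,
         n = n, aggregate = aggregate),
    class = "radial_profile"
  )
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %s, %d bins (N = %d)\n",
              x$aggregate, length(x$bins), x$n))
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, ...) {
  data.frame(frequency = x$bins, value = x$values, count = x$counts)
}

#' Locate local maxima of a radial profile with sub-bin refinement
#'
#' Finds local maxima of the profile, excluding the DC bin, and refines
#' the position and height of each by fitting a parabola through the
#' three consecutive samples around the maximum. A sample is a local
#' maximum if it is strictly larger than its left neighbor and at least
#' as large as its right neighbor (ties resolve toward lower frequency).
#' The refined position is clamped to within half a bin of the integer
#' maximum.
#'
#' @param profile a [radial_project()] result, or a plain numeric vector
#'   of per-bin values (bin width then taken as 1).
#' @return data.frame with one row per peak, in increasing frequency
#'   order: `bin` (0-based integer bin), `position` (refined, in bins),
#'   `frequency` (refined, px^-1; `NA` for plain vectors), `height`
#'   (refined profile height).
#' @export
find_peaks <- function(profile) {
  if (inherits(profile, "radial_profile")) {
    v <- profile$values
    n <- profile$n
  } else {
    v <- as.numeric(profile)
    n <- NA_integer_
  }
  nb <- length(v)
  if (nb < 3) stop("profile too short")
  # candidate interior maxima, 0-based bins 1 .. nb-2
  i <- 2:(nb - 1)
  is_max <- v[i] > v[i - 1] & v[i] >= v[i + 1]
  idx <- i[is_max]
  if (length(idx) == 0) stop_no_ring()
  refine <- function(k) {
    y1 <- v[k - 1]; y2 <- v[k]; y3 <- v[k + 1]
    a <- (y1 - 2 * y2 + y3) / 2
    b <- (y3 - y1) / 2
    off <- if (a == 0) 0 else max(-0.5, min(0.5, -b / (2 * a)))
    height <- a * off^2 + b * off + y2
    c(position = (k - 1) + off, height = height)
  }
  ref <- t(vapply(idx, refine, c(position = 0, height = 0)))
  data.frame(
    bin = idx - 1L,
    position = ref[, "position"],
    frequency = if (is.na(n)) NA_real_ else ref[, "position"] / n,
    height = ref[, "height"]
  )
}

#' Enhance the spectral ring by removing the central peak
#'
#' The DC peak of the magnitude spectrum decays slowly and can drown the
#' ring produced by the repetitive cell mosaic. This operation removes
#' the central peak together with its full tail, using dilation by
#' reconstruction: a seed image equal to the magnitude at the DC sample
#' and zero elsewhere is iteratively dilated with the elementary
#' 4-neighbor structuring element, clipped under the magnitude after
#' every step, until stability. The reconstruction equals the central
#' peak with its monotone tail but without the ring; subtracting it
#' yields a spectrum in which the ring stands alone. The construction is
#' a high-pass filter tailored to the image at hand, with no parameter.
#'
#' @param spec a [spectrum2d()] object.
#' @return A `spectrum2d` whose `magnitude` is the enhanced spectrum
#'   (non-negative everywhere, exactly 0 at DC), with `ring_enhanced =
#'   TRUE` and the reconstruction stored as `background`.
#' @export
enhance_ring <- function(spec) {
  stopifnot(inherits(spec, "spectrum2d"))
  mag <- spec$magnitude
  seed <- matrix(0, nrow(mag), ncol(mag))
  seed[spec$dc, spec$dc] <- mag[spec$dc, spec$dc]
  bg <- reconstruct_dilate_cpp(seed, mag)
  structure(
    list(magnitude = mag - bg, size = spec$size, dc = spec$dc,
         ring_enhanced = TRUE, background = bg),
    class = "spectrum2d"
  )
}

#' Estimate the characteristic frequency of the cell mosaic
#'
#' The characteristic frequency `f*` (px^-1) is the radius of the ring in
#' the 2-D frequency spectrum produced by the repetitive cell pattern;
#' `lambda = 1/f*` is the characteristic cell width in pixels. Seven
#' estimators are available:
#'
#' * `"modeRM"`: highest refined peak of the radial mean of the magnitude
#'   spectrum.
#' * `"1stRM"`: first (lowest-frequency) peak of the radial mean.
#' * `"2ndRMAX"`: second peak of the radial maximum of the magnitude.
#' * `"modePS"`: highest peak of the radial mean of the power spectrum
#'   (no smoothing applied).
#' * `"meanPS"`, `"medianPS"`: weighted mean / weighted median frequency
#'   of the radial mean of the power spectrum treated as a distribution
#'   over bins, after zeroing the first `n_highpass` bins (a high-pass
#'   filter; required for these two methods).
#' * `"modeRMrec"` (recommended, parameter-free): highest refined peak of
#'   the radial mean of the ring-enhanced spectrum ([enhance_ring()]).
#'
#' @param image numeric matrix, phantom, or a `spectrum2d`.
#' @param method estimator name, see above.
#' @param n_highpass number of low-frequency bins (counted from and
#'   including bin 0) to zero before `meanPS`/`medianPS`.
#' @return Object of class `char_frequency`: list with `f_star` (px^-1),
#'   `bin_index` (nearest integer bin), `method`, `peak_value`, `n`
#'   (frame width) and `lambda_px = 1/f_star`.
#' @examples
#' ph <- make_lattice("square", 350, 25)
#' fs <- estimate_f_star(ph, "modeRMrec")
#' fs$f_star * 350   # close to 14: one cell every 25 px
#' @export
estimate_f_star <- function(image,
                            method = c("modeRMrec", "modeRM", "1stRM",
                                       "2ndRMAX", "modePS", "meanPS",
                                       "medianPS"),
                            n_highpass = NULL) {
  method <- match.arg(method)
  spec <- if (inherits(image, "spectrum2d")) image else spectrum2d(image)
  need_hp <- method %in% c("meanPS", "medianPS")
  if (need_hp && is.null(n_highpass))
    stop("methods meanPS and medianPS require `n_highpass`")

  if (need_hp) {
    prof <- radial_project(spec, "mean_power")
    w <- prof$values
    nhp <- as.integer(n_highpass)
    if (nhp < 0) stop("`n_highpass` must be >= 0")
    w[seq_len(min(nhp, length(w)))] <- 0
    if (all(w <= 0)) stop("high-pass filter removed the whole profile")
    f <- prof$bins
    if (method == "meanPS") {
      fstar <- sum(f * w) / sum(w)
    } else {
      cw <- cumsum(w) / sum(w)
      fstar <- f[which(cw >= 0.5)[1]]
    }
    peak_value <- w[which.min(abs(f - fstar))]
    bin_index <- as.integer(round(fstar * prof$n))
    return(new_char_frequency(fstar, bin_index, method, peak_value, prof$n))
  }

  if (method == "modeRMrec") {
    prof <- radial_project(enhance_ring(spec), "mean_magnitude")
    pk <- find_peaks(prof)
    best <- pk[which.max(pk$height), ]
  } else if (method == "modeRM") {
    pk <- find_peaks(radial_project(spec, "mean_magnitude"))
    best <- pk[which.max(pk$height), ]
  } else if (method == "1stRM") {
    pk <- find_peaks(radial_project(spec, "mean_magnitude"))
    best <- pk[1, ]
  } else if (method == "2ndRMAX") {
    pk <- find_peaks(radial_project(spec, "max_magnitude"))
    if (nrow(pk) < 2)
      stop_no_ring("2ndRMAX requires at least two peaks in the radial maximum")
    best <- pk[2, ]
  } else {  # modePS
    pk <- find_peaks(radial_project(spec, "mean_power"))
    best <- pk[which.max(pk$height), ]
  }
  new_char_frequency(best$frequency, as.integer(best$bin), method,
                     best$height, spec$size)
}

new_char_frequency <- function(f_star, bin_index, method, peak_value, n) {
  if (!is.finite(f_star) || f_star <= 0 || f_star > 0.5)
    stop_no_ring(sprintf("estimated frequency %.4g px^-1 is outside (0, 1/2]",
                         f_star))
  structure(
    list(f_star = f_star, bin_index = bin_index, method = method,
         peak_value = peak_value, n = n, lambda_px = 1 / f_star),
    class = "char_frequency"
  )
}

#' @export
print.char_frequency <- function(x, ...) {
  cat(sprintf(
    "<char_frequency> f* = %.5f px^-1 (bin %d of N = %d), lambda = %.2f px, method = %s\n",
    x$f_star, x$bin_index, x$n, x$lambda_px, x$method))
  invisible(x)
}

# numeric f* from either a number or a char_frequency
fstar_value <- function(f) {
  if (inherits(f, "char_frequency")) f$f_star else as.numeric(f)
}
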