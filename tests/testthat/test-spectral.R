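test_that("radial projection partitions every spectrum sample into one bin", {
  for (n in c(31, 32, 350)) {
    sp <- spectrum2d(matrix(runif(n * n), n, n))
    pr <- radial_project(sp)
    expect_length(pr$bins, floor(n / 2) + 1)
    expect_true(all(diff(pr$bins) > 0))
    expect_equal(sum(pr$counts), n * n)
    expect_equal(pr$bins[length(pr$bins)], floor(n / 2) / n)
  }
})

test_that("a constant image has all spectral energy at DC", {
  pr <- radial_project(spectrum2d(matrix(7, 64, 64)))
  expect_gt(pr$values[1], 0)
  expect_equal(pr$values[-1], rep(0, length(pr$values) - 1))
})

test_that("a pure cosine of period 25 px in a 350 px frame peaks at bin 14", {
  x <- outer(rep(1, 350), cos(2 * pi * (0:349) / 25))
  pr <- radial_project(spectrum2d(x), "mean_magnitude")
  expect_equal(which.max(pr$values[-1]), 14)
})

test_that("parabolic refinement matches the closed form and a least-squares fit", {
  # single interior maximum
  pk <- find_peaks(c(9, 1, 2, 1, 0, 0))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$bin, 2)
  # symmetric triple refines exactly to the central bin
  pk <- find_peaks(c(9, 0, 3, 5, 3, 0))
  expect_equal(pk$position[which.max(pk$height)], 3)
  # (3, 5, 4) at bins 9, 10, 11: vertex of the 3-point parabola
  v <- c(10, rep(0, 8), 3, 5, 4, rep(0, 3))
  pk <- find_peaks(v)
  expect_equal(pk$position, 10 - (4 - 3) / (2 * (3 + 4 - 10)))
  ora <- quad_vertex(c(9, 10, 11), c(3, 5, 4))
  expect_equal(pk$position, ora[1], tolerance = 1e-10)
  expect_equal(pk$height, ora[2], tolerance = 1e-10)
  # monotone profiles have no interior peak
  expect_error(find_peaks(c(9, 5, 4, 3, 2, 1)), class = "endo_no_ring")
  # refinement never strays more than half a bin
  set.seed(1)
  for (i in 1:50) {
    v <- runif(21)
    pk <- tryCatch(find_peaks(v), endo_no_ring = function(e) NULL)
    if (is.null(pk)) next
    expect_true(all(abs(pk$position - pk$bin) <= 0.5))
  }
})

test_that("ring enhancement equals the iterate-until-stable definition", {
  set.seed(42)
  for (i in 1:5) {
    n <- 32
    mag <- matrix(runif(n * n, 0, 100), n, n)
    dc <- floor(n / 2) + 1
    mag[dc, dc] <- max(mag) * 2            # DC dominates, as in real spectra
    sp <- structure(list(magnitude = mag, size = n, dc = dc),
                    class = "spectrum2d")
    out <- enhance_ring(sp)
    seed <- matrix(0, n, n); seed[dc, dc] <- mag[dc, dc]
    expect_identical(out$background, naive_reconstruct(seed, mag))
    expect_identical(out$magnitude, mag - out$background)
  }
})

test_that("ring enhancement removes the DC tail and keeps an isolated ring", {
  # radially non-increasing spectrum: reconstruction swallows everything
  n <- 33; dc <- 17
  d <- sqrt(outer((1:n - dc)^2, (1:n - dc)^2, "+"))
  mono <- 100 * exp(-d / 4)
  sp <- structure(list(magnitude = mono, size = n, dc = dc),
                  class = "spectrum2d")
  out <- enhance_ring(sp)
  expect_equal(max(abs(out$magnitude)), 0)

  # a ring brighter than the local tail survives; the peak does not
  ring <- mono + 50 * exp(-(d - 10)^2)
  sp$magnitude <- ring
  out <- enhance_ring(sp)
  expect_equal(out$magnitude[dc, dc], 0)
  expect_true(all(out$magnitude >= 0))
  expect_true(all(out$magnitude <= ring + 1e-12))
  on_ring <- abs(d - 10) < 0.5
  expect_gt(mean(out$magnitude[on_ring]), 10)
  # the reconstructed background decreases along rays from DC. On the
  # discrete grid, paths crossing the moat off-axis can deliver slightly
  # higher values just past it, so the monotonicity of the continuous
  # operator holds only up to a small discretization slack.
  bg <- out$background
  slack <- 0.05 * max(bg)
  for (ray in list(bg[dc, dc:n], bg[dc, dc:1], bg[dc:n, dc], bg[dc:1, dc]))
    expect_true(all(diff(ray) <= slack))
})

test_that("mode-type estimators locate the lattice frequency within one bin", {
  for (pat in c("square", "hexagonal")) {
    ph <- make_lattice(pat, 350, 25)
    want <- round(ph$true_f_star * 350)
    for (m in c("modeRM", "modePS", "modeRMrec")) {
      fs <- estimate_f_star(ph, m)
      expect_lte(abs(fs$bin_index - want), 1,
                 label = sprintf("%s on %s (bin %d vs %d)", m, pat,
                                 fs$bin_index, want))
    }
  }
})

test_that("estimates land on the analytic bins of the 350/25 lattices", {
  fs <- estimate_f_star(make_lattice("square", 350, 25), "modeRMrec")
  expect_equal(fs$bin_index, 14)
  expect_equal(fs$f_star, 14 / 350, tolerance = 0.02)
  fh <- estimate_f_star(make_lattice("hexagonal", 350, 25), "modeRMrec")
  expect_equal(fh$bin_index, 16)
})

test_that("doubling the cell size halves the estimated frequency", {
  f1 <- estimate_f_star(make_lattice("square", 350, 25), "modeRMrec")$f_star
  f2 <- estimate_f_star(make_lattice("square", 350, 50), "modeRMrec")$f_star
  expect_equal(f2 / f1, 0.5, tolerance = 1.5 / (350 * f1))  # bin resolution
})

test_that("power-spectrum distribution estimators respect the high-pass filter", {
  ph <- make_lattice("square", 350, 25)
  expect_error(estimate_f_star(ph, "meanPS"), "n_highpass")
  f_mean <- estimate_f_star(ph, "meanPS", n_highpass = 3)
  f_med <- estimate_f_star(ph, "medianPS", n_highpass = 5)
  expect_gt(f_mean$f_star, 0)
  expect_gt(f_med$f_star, 0)
  # zeroing every bin leaves an empty distribution
  expect_error(estimate_f_star(ph, "medianPS", n_highpass = 176))
})

test_that("2ndRMAX needs two peaks and fails cleanly otherwise", {
  # a spectrum with a single off-DC maximum leaves 2ndRMAX nothing to use
  n <- 33; dc <- 17
  d <- sqrt(outer((1:n - dc)^2, (1:n - dc)^2, "+"))
  sp <- structure(list(magnitude = 100 * exp(-(d - 6)^2), size = n, dc = dc),
                  class = "spectrum2d")
  expect_error(estimate_f_star(sp, "2ndRMAX"), class = "endo_no_ring")
  # on a two-ring spectrum it takes the second ring
  sp$magnitude <- 100 * exp(-(d - 4)^2) + 60 * exp(-(d - 10)^2)
  fs <- estimate_f_star(sp, "2ndRMAX")
  expect_equal(fs$bin_index, 10)
})

test_that("the frequency estimate is invariant to linear gray rescaling", {
  ph <- make_mosaic(size_px = 300, seed = 14)
  f1 <- estimate_f_star(ph$image, "modeRMrec")$f_star
  f2 <- estimate_f_star(ph$image * 0.5 + 40, "modeRMrec")$f_star
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("non-square images are analyzed on the largest centered square", {
  ph <- make_lattice("square", 350, 25)
  wide <- cbind(ph$image, ph$image[, 1:40])   # 350 x 390
  fs <- estimate_f_star(wide, "modeRMrec")
  expect_equal(fs$n, 350)
  expect_equal(fs$bin_index, 14)
})
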