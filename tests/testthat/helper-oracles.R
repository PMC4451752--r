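# Independent oracles used by the tests. These deliberately re-derive
# results by brute force, never through the code paths they check.

# grayscale dilation with the elementary cross (origin + 4 neighbors),
# via shifted copies padded with -Inf
dilate4 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  up <- rbind(x[-1, , drop = FALSE], rep(-Inf, nc))
  dn <- rbind(rep(-Inf, nc), x[-nr, , drop = FALSE])
  lf <- cbind(x[, -1, drop = FALSE], rep(-Inf, nr))
  rt <- cbind(rep(-Inf, nr), x[, -nc, drop = FALSE])
  pmax(x, up, dn, lf, rt)
}

# naive dilation by reconstruction: iterate geodesic dilation to stability
naive_reconstruct <- function(seed, mask) {
  j <- pmin(seed, mask)
  repeat {
    jn <- pmin(dilate4(j), mask)
    if (identical(jn, j)) return(j)
    j <- jn
  }
}

# least-squares quadratic through three points, returning the vertex
quad_vertex <- function(x, y) {
  fit <- stats::lm(y ~ x + I(x^2))
  b <- stats::coef(fit)
  vx <- -b[2] / (2 * b[3])
  unname(c(vx, b[1] + b[2] * vx + b[3] * vx^2))
}

# fixture cache: expensive phantoms/segmentations shared across tests
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# the mosaic set used by the robustness experiments (~150 cells each)
mosaic_set <- function(n = 5) {
  fixture(paste0("mosaic_set_", n), lapply(seq_len(n), function(s) {
    make_mosaic(size_px = 500L, seed = 1000 + s)
  }))
}

# true characteristic frequency of a mosaic phantom under alpha = 1,
# i.e. the frequency whose density estimate matches the ground truth
true_fstar <- function(ph) sqrt(truth_density_px2(ph))

# optimal seed count from the ground truth (image area times truth density)
opt_seeds <- function(ph) {
  round(prod(dim(ph$image)) * truth_density_px2(ph))
}
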