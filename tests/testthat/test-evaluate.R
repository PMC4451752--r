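# 9-cell toy: a 30 x 30 frame of 10 x 10 cells, polygon covering it all
toy_labels <- function() {
  lab <- matrix(0L, 30, 30)
  ids <- 0L
  for (bi in 0:2) for (bj in 0:2) {
    ids <- ids + 1L
    lab[(bi * 10 + 1):(bi * 10 + 10), (bj * 10 + 1):(bj * 10 + 10)] <- ids
  }
  lab
}

toy_truth <- function() {
  centers <- expand.grid(x = c(4.5, 14.5, 24.5), y = c(4.5, 14.5, 24.5))
  new_ground_truth(as.matrix(centers),
                   cbind(c(-0.5, 29.5, 29.5, -0.5),
                         c(-0.5, -0.5, 29.5, 29.5)),
                   dim = c(30L, 30L))
}

test_that("polygon rasterization follows the even-odd pixel-center rule", {
  m <- polygon_mask(cbind(c(-0.5, 29.5, 29.5, -0.5),
                          c(-0.5, -0.5, 29.5, 29.5)), c(30, 30))
  expect_true(all(m))
  m <- polygon_mask(cbind(c(1.5, 4.5, 4.5, 1.5), c(1.5, 1.5, 3.5, 3.5)),
                    c(8, 8))
  expect_equal(sum(m), 6)                     # x in {2, 3, 4}, y in {2, 3}
  expect_true(all(which(m, arr.ind = TRUE)[, 1] %in% c(3, 4)))
})

test_that("a perfect segmentation scores p = r = F = 1", {
  sc <- score_segmentation(toy_labels(), toy_truth())
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$F, 1)
})

test_that("merging one pair of cells gives the enumerated toy score", {
  lab <- toy_labels()
  lab[lab == 2L] <- 1L                        # merge a vertical pair
  sc <- score_segmentation(lab, toy_truth())
  expect_equal(sc$n_total, 8)
  expect_equal(sc$n_corr, 7)
  expect_equal(sc$precision, 7 / 8)
  expect_equal(sc$recall, 7 / 9)
  expect_equal(sc$F, 2 * (7 / 8) * (7 / 9) / ((7 / 8) + (7 / 9)))
  expect_equal(sc$F, 0.8235, tolerance = 1e-4)
})

test_that("splitting every cell halves precision and leaves recall intact", {
  lab <- toy_labels()
  half <- matrix(rep(rep(c(0L, 1L), c(5, 5)), each = 30), 30, 30)
  split <- lab * 2L - half                     # each cell -> two 5 x 10 halves
  sc <- score_segmentation(split, toy_truth())
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1 / 2)
  expect_equal(sc$F, 2 / 3)
})

test_that("regions outside or barely overlapping the region are ignored", {
  lab <- toy_labels()
  # polygon covering only the left two columns of cells
  truth <- new_ground_truth(
    as.matrix(expand.grid(x = c(4.5, 14.5), y = c(4.5, 14.5, 24.5))),
    cbind(c(-0.5, 19.5, 19.5, -0.5), c(-0.5, -0.5, 29.5, 29.5)),
    dim = c(30L, 30L))
  sc <- score_segmentation(lab, truth)
  # the right-hand column (labels 7:9) lies fully outside and is ignored
  expect_equal(sc$n_total, 6)
  expect_equal(sc$F, 1)
})

test_that("scores are invariant to region relabeling", {
  lab <- toy_labels()
  perm <- sample(9)
  lab2 <- lab
  lab2[lab > 0] <- perm[lab[lab > 0]]
  s1 <- score_segmentation(lab, toy_truth())
  s2 <- score_segmentation(lab2, toy_truth())
  expect_equal(s1[c("n_total", "n_corr", "precision", "recall", "F")],
               s2[c("n_total", "n_corr", "precision", "recall", "F")])
})

test_that("F stays within [0, 1] and is zero only without correct regions", {
  sc <- score_segmentation(toy_labels(), toy_truth())
  expect_true(sc$F >= 0 && sc$F <= 1)
  # a single region swallowing everything: no region has exactly 1 marker
  lab <- matrix(1L, 30, 30)
  sc <- score_segmentation(lab, toy_truth())
  expect_equal(sc$n_corr, 0)
  expect_equal(sc$F, 0)
})

test_that("the trainer honors symmetry and degenerate grids", {
  ph <- make_mosaic(size_px = 250, density_mm2 = 2500, noise_sd = 4,
                    illumination_amplitude = 0, seed = 321)
  grid1 <- data.frame(u = 30, k_sigma = 0.17, k_h = 0.002)
  tr <- train_parameters(list(ph, ph), list(ph$truth, ph$truth),
                         grid1, m = 10, master_seed = 5)
  # single-triple grid: that triple is returned for every image
  expect_equal(tr$per_image$k_sigma, c(0.17, 0.17))
  expect_equal(tr$per_image$u, c(30, 30))

  # two identical images: identical leave-one-out parameters
  grid2 <- rbind(grid1, data.frame(u = 30, k_sigma = 0.5, k_h = 0.002))
  tr2 <- train_parameters(list(ph, ph), list(ph$truth, ph$truth),
                          grid2, m = 10, master_seed = 5)
  expect_equal(tr2$per_image$k_sigma[1], tr2$per_image$k_sigma[2])
  expect_true(all(c("mean_F", "F_1", "F_2") %in% names(tr2$surface)))
})
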