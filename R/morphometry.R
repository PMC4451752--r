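#' Clinical morphometry from a cell segmentation
#'
#' Computes the three standard clinical measures from a label image:
#'
#' * **cell density**, the inverse of the mean cell area, in mm^-2;
#' * **polymegathism**, the coefficient of variation of cell area
#'   (population standard deviation over mean), in %;
#' * **pleomorphism**, the percentage of cells with exactly six
#'   neighbors, in %.
#'
#' Regions touching the image border are partially imaged and are
#' discarded from all three measures, but still count as neighbors of
#' the retained cells (they bound them even if unmeasured). Two regions
#' are neighbors iff they touch a common boundary (0-labeled) pixel,
#' reaching through the boundary line (robust to lines up to ~3 px
#' wide). Cell area is the label support, excluding the boundary
#' pixels.
#'
#' @param labels integer label matrix (0 = boundary) or
#'   [segment_cells()] result.
#' @param sampling_um_per_px lateral sampling density, micrometer per
#'   pixel.
#' @return Object of class `morphometry_report`: list with
#'   `n_cells_used`, `density_mm2`, `polymegathism_pct`,
#'   `pleomorphism_pct`, `mean_cell_area_um2` and `cells` (per-cell
#'   table: label, area in px2 and um2, neighbor count, border flag).
#' @examples
#' ph <- make_mosaic(size_px = 300, noise_sd = 0, seed = 7)
#' measure_morphometry(ph$truth_labels, 0.557)
#' @export
measure_morphometry <- function(labels, sampling_um_per_px = 0.557) {
  lab <- as_labels(labels)
  if (sampling_um_per_px <= 0) stop("sampling must be positive")
  k <- max(lab)
  if (k < 1) stop("no regions in the label image")
  area_px <- tabulate(lab, nbins = k)

  on_border <- logical(k)
  edge <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  on_border[unique(edge[edge > 0])] <- TRUE

  pairs <- neighbor_pairs_cpp(lab)
  nn <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = k)

  keep <- !on_border & area_px > 0
  if (sum(keep) < 2) stop("fewer than 2 usable (non-border) cells")

  area_um2 <- area_px * sampling_um_per_px^2
  a <- area_um2[keep]
  mean_area <- mean(a)
  cv <- sqrt(mean((a - mean_area)^2)) / mean_area        # population sd
  structure(
    list(
      n_cells_used = sum(keep),
      density_mm2 = 1e6 / mean_area,
      polymegathism_pct = 100 * cv,
      pleomorphism_pct = 100 * mean(nn[keep] == 6),
      mean_cell_area_um2 = mean_area,
      cells = data.frame(label = seq_len(k), area_px2 = area_px,
                         area_um2 = area_um2, n_neighbors = nn,
                         border_touching = on_border)[area_px > 0, ]
    ),
    class = "morphometry_report"
  )
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf(
    paste0("<morphometry_report> %d cells: density %.0f /mm2, ",
           "polymegathism %.1f %%, pleomorphism %.1f %%\n"),
    x$n_cells_used, x$density_mm2, x$polymegathism_pct,
    x$pleomorphism_pct))
  invisible(x)
}

#' Per-region summary of a label image
#'
#' @param labels integer label matrix (0 = boundary).
#' @return data.frame with `label`, `area_px2`, `centroid_x`,
#'   `centroid_y` (0-based) and `border_touching`.
#' @export
region_table <- function(labels) {
  lab <- as_labels(labels)
  k <- max(lab)
  idx <- which(lab > 0)
  lv <- lab[idx]
  yy <- (idx - 1) %% nrow(lab)
  xx <- (idx - 1) %/% nrow(lab)
  on_border <- logical(k)
  edge <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  on_border[unique(edge[edge > 0])] <- TRUE
  data.frame(
    label = sort(unique(lv)),
    area_px2 = tabulate(lv, nbins = k)[sort(unique(lv))],
    centroid_x = as.numeric(tapply(xx, lv, mean)),
    centroid_y = as.numeric(tapply(yy, lv, mean)),
    border_touching = on_border[sort(unique(lv))]
  )
}
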