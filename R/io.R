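#' Read a grayscale image
#'
#' Reads an 8-bit (or 16-bit) grayscale TIFF or PNG into a numeric
#' matrix on the 0-255 scale (rows = y, columns = x, origin top-left).
#' Multi-channel images are averaged to grayscale.
#'
#' @param path file path; format chosen by extension.
#' @return numeric matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img * 255
}

#' Write a grayscale image
#'
#' @param image numeric matrix on the 0-255 scale (values are clipped),
#'   or an integer matrix with `scale` given explicitly.
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @param bits 8 or 16 bits per sample.
#' @param scale full-scale value of `image` (default 255 for 8 bit).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, bits = 8L, scale = 255) {
  img <- pmax(pmin(as_gray_matrix(image) / scale, 1), 0)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits)),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Write a label image as 16-bit grayscale TIFF
#'
#' Boundary pixels (label 0) map to 0; labels are stored verbatim in the
#' 16-bit range.
#'
#' @param labels label matrix or [segment_cells()] result.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  lab <- as_labels(labels)
  if (max(lab) > 65535) stop("more than 65535 regions")
  write_gray_image(lab, path, bits = 16L, scale = 65535)
}

#' Read a label image written by [write_label_map()]
#'
#' @param path `.tif` path.
#' @return integer label matrix.
#' @export
read_label_map <- function(path) {
  lab <- round(read_gray_image(path) / 255 * 65535)
  storage.mode(lab) <- "integer"
  lab
}

#' Write ground truth as plain columnar text
#'
#' A simple two-section text format: a `[markers]` section with one
#' `x y` pair per cell and a `[polygon]` section with the evaluation
#' outline vertices, all 0-based pixel coordinates.
#'
#' @param truth an [new_ground_truth()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "endo_ground_truth"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[markers]", con)
  utils::write.table(truth$markers, con, row.names = FALSE,
                     col.names = FALSE)
  writeLines("[polygon]", con)
  utils::write.table(truth$polygon, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param path input path.
#' @param dim optional image dimensions `c(rows, cols)`.
#' @return an `endo_ground_truth`.
#' @export
read_ground_truth <- function(path, dim = NULL) {
  lines <- readLines(path)
  im <- which(lines == "[markers]")
  ip <- which(lines == "[polygon]")
  if (length(im) != 1 || length(ip) != 1 || ip < im)
    stop("malformed ground truth file: ", path)
  parse_block <- function(block) {
    block <- block[nzchar(trimws(block))]
    do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                          function(v) as.numeric(v[1:2])))
  }
  markers <- parse_block(lines[(im + 1):(ip - 1)])
  polygon <- parse_block(lines[(ip + 1):length(lines)])
  new_ground_truth(markers, polygon, dim = dim)
}

#' Pipeline run configuration
#'
#' Bundles everything a full run needs; the defaults reproduce the
#' recommended configuration (ring-enhanced spectral estimator with PDF
#' re-estimation, `u = 30`, `k_sigma = 0.17`, `k_h = 0.002`, `m = 100`,
#' `alpha = 1`, 0.557 micrometer per pixel).
#'
#' @param image path to the input image (8-bit grayscale TIFF/PNG).
#' @param out_dir directory for all outputs.
#' @param params [stowa_params()].
#' @param sampling_um_per_px lateral sampling density.
#' @param seed master seed.
#' @param method spectral estimator for the initial `f*`.
#' @param refine_fstar,border_correction pipeline switches, see
#'   [segment_cells()].
#' @param crop optional crop rectangle `c(x0, y0, width, height)`
#'   (0-based), applied before analysis; stands in for the manual
#'   cropping of the dark image borders.
#' @param write_pdf also write the boundary-occurrence map.
#' @return list of class `endo_run_config`.
#' @export
run_config <- function(image, out_dir = ".", params = stowa_params(),
                       sampling_um_per_px = 0.557, seed = 1L,
                       method = "modeRMrec", refine_fstar = TRUE,
                       border_correction = TRUE, crop = NULL,
                       write_pdf = TRUE) {
  structure(
    list(image = image, out_dir = out_dir, params = params,
         sampling_um_per_px = sampling_um_per_px, seed = seed,
         method = method, refine_fstar = refine_fstar,
         border_correction = border_correction, crop = crop,
         write_pdf = write_pdf),
    class = "endo_run_config"
  )
}

#' Run the full quantification pipeline on one image
#'
#' Reads the image, estimates the characteristic frequency, segments
#' the cells with the stochastic watershed, measures the morphometry,
#' and writes the artifacts to `out_dir`: `labels.tif` (16-bit label
#' image), optionally `pdf.tif`, `report.json` (morphometry + density
#' estimates) and `run_record.json` (configuration, seed and package
#' version, sufficient to reproduce the run).
#'
#' @param config an [run_config()] object.
#' @return the [measure_morphometry()] report, invisibly, with the
#'   segmentation attached as attribute `"segmentation"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "endo_run_config"))
  img <- read_gray_image(config$image)
  if (!is.null(config$crop)) {
    cr <- config$crop
    img <- img[(cr[2] + 1):(cr[2] + cr[4]), (cr[1] + 1):(cr[1] + cr[3])]
  }
  fs <- estimate_f_star(img, config$method)
  seg <- segment_cells(img, params = config$params,
                       sampling_um_per_px = config$sampling_um_per_px,
                       seed = config$seed, f_star = fs,
                       refine_fstar = config$refine_fstar,
                       border_correction = config$border_correction,
                       keep_pdf = TRUE)
  rep <- measure_morphometry(seg, config$sampling_um_per_px)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  write_label_map(seg, outp("labels.tif"))
  if (config$write_pdf)
    write_gray_image(seg$pdf$counts, outp("pdf.tif"), bits = 16L,
                     scale = 65535)
  spectral <- density_from_fstar(fs, alpha = 1, config$sampling_um_per_px)
  jsonlite::write_json(
    list(n_cells_used = rep$n_cells_used,
         density_mm2 = rep$density_mm2,
         polymegathism_pct = rep$polymegathism_pct,
         pleomorphism_pct = rep$pleomorphism_pct,
         spectral_density_mm2 = spectral$density_mm2,
         f_star_px = seg$f_star_used),
    outp("report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(rep$cells, outp("cells.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(image = config$image, crop = config$crop,
         method = config$method,
         params = unclass(config$params),
         sampling_um_per_px = config$sampling_um_per_px,
         seed = config$seed, refine_fstar = config$refine_fstar,
         border_correction = config$border_correction,
         package_version = as.character(utils::packageVersion("endomosaic"))),
    outp("run_record.json"), auto_unbox = TRUE, digits = NA)
  attr(rep, "segmentation") <- seg
  invisible(rep)
}

#' Write a phantom to disk
#'
#' Writes the raster as an 8-bit image and, for mosaics, the ground
#' truth sidecar next to it.
#'
#' @param phantom a [make_lattice()] or [make_mosaic()] result.
#' @param image_path image output path (`.png`/`.tif`).
#' @param truth_path optional ground truth path (mosaics only).
#' @return `image_path`, invisibly.
#' @export
write_phantom <- function(phantom, image_path, truth_path = NULL) {
  write_gray_image(phantom$image, image_path)
  if (!is.null(truth_path)) {
    if (!inherits(phantom, "mosaic_phantom"))
      stop("only mosaic phantoms carry ground truth")
    write_ground_truth(phantom$truth, truth_path)
  }
  invisible(image_path)
}
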