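# Raster input/output and dataset loading.

#' Read a grayscale image
#'
#' Reads PNG or TIFF and returns an integer matrix of intensities in
#' 0..255. Color images are converted with the standard luma weights
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel is ignored.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix (rows = image rows from the top).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such image file: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' for '%s' (use PNG or TIFF)",
                 ext, path)))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] >= 3L) {
      x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      x <- x[, , 1L]
    }
  }
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Write a grayscale image as PNG
#'
#' @param image Numeric matrix with intensities in 0..255.
#' @param path Output path (`.png`).
#' @export
write_gray_image <- function(image, path) {
  if (!is.matrix(image)) stop("image must be a matrix")
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Load a class-per-directory image dataset
#'
#' Reads every PNG/TIFF under one subdirectory per class (the layout wood
#' stereogram collections are distributed in) and checks that all images
#' share the same dimensions, naming the first offending file otherwise.
#'
#' @param dir Dataset root; each subdirectory is a class.
#' @return List with `images`, `labels` (factor of subdirectory names) and
#'   `ids` (paths relative to `dir`), as accepted by
#'   [extract_feature_table()].
#' @export
load_image_dataset <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such dataset directory: '%s'", dir))
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) {
    stop(sprintf("'%s' has no class subdirectories", dir))
  }
  images <- list(); labels <- character(0); ids <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(dir, cl),
                             pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (fp in files) {
      img <- read_gray_image(fp)
      rel <- file.path(cl, basename(fp))
      if (length(images) > 0L && !identical(dim(img), dim(images[[1L]]))) {
        stop(sprintf(
          "image '%s' is %dx%d but '%s' is %dx%d; all images must share one size",
          rel, nrow(img), ncol(img), ids[1L],
          nrow(images[[1L]]), ncol(images[[1L]])))
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl)
      ids <- c(ids, rel)
    }
  }
  if (length(images) == 0L) stop(sprintf("no images found under '%s'", dir))
  list(images = images, labels = factor(labels), ids = ids)
}

#' Write / read a feature table as tab-delimited text
#'
#' The header records the column layout (`label`, `id`, then
#' `m<index>.<feature>` in bank order), so downstream consumers never have
#' to guess the feature-vector layout.
#'
#' @param table Data frame from [extract_feature_table()].
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such feature table: '%s'", path))
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
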