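# Image and report I/O: 8-bit grayscale PNG/TIFF/JPEG reading, 0/255 PNG
# mask writing, and JSON reports.

#' Read a grayscale image as an 8-bit integer matrix
#'
#' Supports PNG, TIFF and (when the jpeg package is installed) JPEG. Color
#' images are converted to grayscale by channel averaging; intensities are
#' scaled to integer gray levels 0-255.
#'
#' @param path Image file path.
#' @return Integer matrix with values in 0-255.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the jpeg package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3L, dim(x)[3]), drop = FALSE], c(1, 2), mean)
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Write a grayscale image or binary mask as 8-bit PNG
#'
#' Masks (0/1) are written as 0/255; images already in 0-255 are written
#' unchanged.
#'
#' @param image Numeric matrix: a 0/1 mask or 0-255 grayscale image.
#' @param path Output PNG path.
#' @export
write_gray_png <- function(image, path) {
  v <- as.matrix(image)
  if (max(v) <= 1) v <- v * 255
  png::writePNG(v / 255, path)
  invisible(path)
}

#' Write a metrics or prediction report as JSON
#'
#' @param report Named list of scalar metrics / vectors.
#' @param path Output JSON path.
#' @export
write_report_json <- function(report, path) {
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}

#' Write a phantom dataset to a directory
#'
#' Images and ground-truth masks are written as PNGs and labels as a
#' `labels.csv` with columns `filename,label`.
#'
#' @param samples List of `phantom_sample` objects.
#' @param dir Output directory (created if needed).
#' @export
write_phantom_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    img_name <- sprintf("phantom_%03d.png", i)
    write_gray_png(s$image, file.path(dir, img_name))
    write_gray_png(s$tumor_mask, file.path(dir, sprintf("mask_%03d.png", i)))
    data.frame(filename = img_name, label = s$label)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}
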