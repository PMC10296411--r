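# Histogram of Oriented Gradients, written out in full: central-difference
# gradients, magnitude-weighted orientation voting with linear bin
# interpolation, L2-hys block normalization, and a fixed output-dimension
# contract.

#' Feature vector container
#'
#' @param values Numeric vector of finite feature values.
#' @param source One of `"hog"`, `"deep"`, `"fused"`.
#' @return Object of class `feature_vector` with `values`, `source`, `dim`.
#' @export
feature_vector <- function(values, source = c("hog", "deep", "fused")) {
  source <- match.arg(source)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("feature vector is empty")
  if (!all(is.finite(values))) stop("feature values must be finite")
  structure(list(values = values, source = source, dim = length(values)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<%s feature vector, dim %d>\n", x$source, x$dim))
  invisible(x)
}

#' HOG extractor configuration
#'
#' Defaults follow the descriptor contract used throughout the package:
#' 9 unsigned orientation bins over 0-180 degrees, 4-pixel cells, 2x2-cell
#' blocks advanced with a 4-pixel stride, and an output fixed at exactly
#' 1236 features (the raw 6x6x36 = 1296 block layout on a 28x28 resize is
#' truncated to the contract dimension).
#'
#' @param n_bins Number of orientation bins (default 9).
#' @param cell_size Cell side in pixels.
#' @param block_size Block side in cells (default 2 for 2x2 blocks).
#' @param block_stride Block stride in pixels (default 4; must be a multiple
#'   of `cell_size`).
#' @param resize_to Side of the square working image the input is resized to.
#' @param signed If `FALSE` (default) orientations are folded to `[0, 180)`.
#' @param target_dim Exact output dimensionality (default 1236); the raw
#'   descriptor is zero-padded or truncated to this length.
#' @param epsilon Normalization floor guarding empty blocks.
#' @param clip L2-hys clipping value (default 0.2).
#' @return Object of class `hog_config`.
#' @export
hog_config <- function(n_bins = 9L, cell_size = 4L, block_size = 2L,
                       block_stride = 4L, resize_to = 28L, signed = FALSE,
                       target_dim = 1236L, epsilon = 1e-6, clip = 0.2) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (target_dim < 1L) stop("target_dim must be positive")
  if (block_stride %% cell_size != 0L)
    stop("block_stride must be a multiple of cell_size")
  if (signed) stop("only the unsigned 0-180 degree range is supported")
  structure(
    list(n_bins = as.integer(n_bins), cell_size = as.integer(cell_size),
         block_size = as.integer(block_size),
         block_stride = as.integer(block_stride),
         resize_to = as.integer(resize_to), signed = signed,
         target_dim = as.integer(target_dim), epsilon = epsilon, clip = clip),
    class = "hog_config"
  )
}

#' Image gradients for HOG
#'
#' Central differences in the interior, one-sided differences at borders.
#' Magnitude is `sqrt(ix^2 + iy^2)`; orientation is the gradient angle folded
#' to `[0, 180)` degrees (unsigned), with vertical gradients (`ix = 0`)
#' mapping to 90 degrees and zero-magnitude pixels assigned orientation 0.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return List with `magnitude` and `orientation` matrices.
#' @export
hog_gradients <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be a matrix of at least 3 x 3 pixels")
  img <- `storage.mode<-`(image, "double")
  nr <- nrow(img)
  nc <- ncol(img)
  gx <- matrix(0, nr, nc)  # along columns (x direction)
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]
  gx[, nc] <- img[, nc] - img[, nc - 1]
  gy <- matrix(0, nr, nc)  # along rows (y direction)
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]
  gy[nr, ] <- img[nr, ] - img[nr - 1, ]
  mag <- sqrt(gx^2 + gy^2)
  ori <- (atan2(gy, gx) * 180 / pi) %% 180
  ori[mag == 0] <- 0
  list(magnitude = mag, orientation = ori)
}

#' Raw per-cell orientation histograms
#'
#' Magnitude-weighted orientation voting with linear interpolation between
#' the two nearest bin centers (wrapping at 180 degrees), before any block
#' normalization. Exposed so the voting can be validated against a direct
#' per-pixel loop.
#'
#' @param image Numeric matrix (already at working resolution; not resized).
#' @param config An [hog_config()].
#' @return Array `n_cells_row x n_cells_col x n_bins` of histogram votes.
#' @export
hog_cell_histograms <- function(image, config = hog_config()) {
  g <- hog_gradients(image)
  cs <- config$cell_size
  nb <- config$n_bins
  n_cr <- nrow(image) %/% cs
  n_cc <- ncol(image) %/% cs
  if (n_cr < 1L || n_cc < 1L) stop("image smaller than one cell")
  keep_r <- seq_len(n_cr * cs)
  keep_c <- seq_len(n_cc * cs)
  mag <- g$magnitude[keep_r, keep_c]
  ori <- g$orientation[keep_r, keep_c]
  bw <- 180 / nb
  x <- ori / bw - 0.5
  b0 <- floor(x)
  frac <- x - b0
  bin_lo <- (as.integer(b0) %% nb)
  bin_hi <- ((as.integer(b0) + 1L) %% nb)
  w_lo <- as.vector(mag * (1 - frac))
  w_hi <- as.vector(mag * frac)
  row_idx <- (seq_len(n_cr * cs) - 1L) %/% cs          # 0-based cell row
  col_idx <- (seq_len(n_cc * cs) - 1L) %/% cs
  cell_of <- outer(row_idx, col_idx * n_cr, "+")        # 0-based cell id
  key_lo <- as.vector(cell_of) * nb + bin_lo + 1L
  key_hi <- as.vector(cell_of) * nb + bin_hi + 1L
  h <- numeric(n_cr * n_cc * nb)
  acc <- rowsum(c(w_lo, w_hi), c(key_lo, key_hi))
  h[as.integer(rownames(acc))] <- acc[, 1]
  aperm(array(h, dim = c(nb, n_cr, n_cc)), c(2, 3, 1))
}

#' HOG descriptor of an image
#'
#' Resizes the image to `config$resize_to`, computes per-cell orientation
#' histograms, normalizes overlapping blocks with L2-hys (L2-normalize, clip
#' at `config$clip`, renormalize), concatenates block descriptors in
#' row-major order, and pads with zeros or truncates to exactly
#' `config$target_dim` values. The output dimension is therefore independent
#' of the input image size.
#'
#' @param image Numeric grayscale matrix.
#' @param config An [hog_config()].
#' @return A `feature_vector` with `source = "hog"`, all values in `[0, 1]`.
#' @export
hog_features <- function(image, config = hog_config()) {
  img <- resize_gray(image, config$resize_to)
  cells <- hog_cell_histograms(img, config)
  n_cr <- dim(cells)[1]
  n_cc <- dim(cells)[2]
  bs <- config$block_size
  stride_cells <- config$block_stride %/% config$cell_size
  starts_r <- seq(1L, n_cr - bs + 1L, by = stride_cells)
  starts_c <- seq(1L, n_cc - bs + 1L, by = stride_cells)
  eps <- config$epsilon
  out <- vector("list", length(starts_r) * length(starts_c))
  k <- 0L
  for (i in starts_r) {
    for (j in starts_c) {
      v <- as.vector(aperm(cells[i:(i + bs - 1L), j:(j + bs - 1L), ,
                                 drop = FALSE], c(3, 2, 1)))
      v <- v / sqrt(sum(v^2) + eps^2)
      v <- pmin(v, config$clip)
      v <- v / sqrt(sum(v^2) + eps^2)
      k <- k + 1L
      out[[k]] <- v
    }
  }
  raw <- unlist(out)
  td <- config$target_dim
  vals <- if (length(raw) >= td) raw[seq_len(td)] else c(raw, numeric(td - length(raw)))
  feature_vector(vals, source = "hog")
}

#' Resize a grayscale matrix to a square side
#'
#' Bilinear resize used for the working resolutions of the HOG and residual
#' backbones (no-op when the image is already the target size).
#'
#' @param image Numeric matrix.
#' @param side Target side in pixels.
#' @return `side x side` numeric matrix.
#' @export
resize_gray <- function(image, side) {
  img <- `storage.mode<-`(as.matrix(image), "double")
  if (nrow(img) == side && ncol(img) == side) return(img)
  as.matrix(EBImage::resize(EBImage::Image(img), w = side, h = side))
}
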