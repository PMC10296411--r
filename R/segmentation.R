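# Segmentation stage: mayfly-optimized Kapur thresholds -> label map ->
# tumor-region mask, plus Tanimoto / Dice overlap and area metrics.

#' 8-connected component labeling of a binary mask
#'
#' Labels connected sets of foreground pixels using 8-connectivity (edges and
#' corners). Implemented as a connected-component search on the pixel
#' adjacency graph.
#'
#' @param mask Binary (logical or 0/1) matrix.
#' @return Integer matrix of the same shape; 0 for background, components
#'   numbered from 1 in decreasing size order.
#' @export
label_components <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  fg <- which(m == 1L)
  out <- matrix(0L, nrow(m), ncol(m))
  if (length(fg) == 0L) return(out)
  nr <- nrow(m)
  nc <- ncol(m)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]
    c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- m[nb] == 1L
    edges <- rbind(edges, cbind(id[fg[ok][keep]], id[nb[keep]]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)
  # renumber by decreasing size, ties by first appearance
  ord <- order(-comp$csize, seq_along(comp$csize))
  relabel <- integer(length(comp$csize))
  relabel[ord] <- seq_along(ord)
  out[fg] <- relabel[comp$membership]
  out
}

#' Segment a grayscale image by mayfly-optimized Kapur thresholding
#'
#' Maximizes Kapur's multilevel entropy over `n_classes - 1` thresholds with
#' the mayfly optimizer, assigns each pixel its intensity class, picks the
#' tumor-candidate class as the one whose mean intensity is farthest from the
#' global foreground mean (tumors are hyper- or hypo-intense), and keeps its
#' largest 8-connected component as the tumor mask.
#'
#' @param image Integer-valued grayscale matrix in `[0, levels - 1]`.
#' @param n_classes Number of intensity classes (default 4: background, two
#'   tissue modes, tumor).
#' @param config Optional [mfo_config()] for the threshold search.
#' @param seed Seed used when `config` is `NULL`.
#' @param levels Number of gray levels (default 256).
#' @return An object of class `segmentation_result`: list with `thresholds`,
#'   `label_map` (classes `0..n_classes-1`), `tumor_mask` (0/1 matrix),
#'   `tumor_class`, `objective_value` and `degenerate` flag. A single-valued
#'   image yields an empty mask, `degenerate = TRUE` and a warning.
#' @export
segment_image <- function(image, n_classes = 4L, config = NULL, seed = 1L,
                          levels = 256L) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  empty <- matrix(0L, nrow(image), ncol(image))
  if (length(unique(as.vector(image))) < 2L) {
    warning("degenerate image with a single gray level; empty tumor mask")
    return(structure(
      list(thresholds = integer(0), label_map = empty, tumor_mask = empty,
           tumor_class = NA_integer_, objective_value = NA_real_,
           degenerate = TRUE),
      class = "segmentation_result"))
  }
  hist <- compute_histogram(image, levels)
  opt <- optimize_thresholds(hist, n_classes, config = config, seed = seed)
  thr <- opt$thresholds
  # level t belongs to the upper class: class = #(thresholds <= pixel)
  label_map <- matrix(findInterval(as.vector(image), thr),
                      nrow(image), ncol(image))
  tumor_class <- .pick_tumor_class(image, label_map, n_classes)
  if (is.na(tumor_class)) {
    tumor_mask <- empty
  } else {
    comp <- label_components(label_map == tumor_class)
    tumor_mask <- matrix(as.integer(comp == 1L), nrow(image), ncol(image))
  }
  structure(
    list(thresholds = thr, label_map = label_map, tumor_mask = tumor_mask,
         tumor_class = tumor_class, objective_value = opt$score$value,
         degenerate = FALSE),
    class = "segmentation_result"
  )
}

# Tumor-candidate class: among non-background classes (label > 0), the class
# whose mean intensity is farthest from the mean over all non-background
# pixels. The darkest class is treated as background.
.pick_tumor_class <- function(image, label_map, n_classes) {
  fg <- label_map > 0L
  if (!any(fg)) return(NA_integer_)
  fg_mean <- mean(image[fg])
  cand <- sort(unique(label_map[fg]))
  dists <- vapply(cand, function(k) {
    abs(mean(image[label_map == k]) - fg_mean)
  }, numeric(1))
  cand[which.max(dists)]
}

#' @export
print.segmentation_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate segmentation (single gray level): empty tumor mask\n")
  } else {
    cat("Kapur/MFO segmentation: thresholds",
        paste(x$thresholds, collapse = ", "),
        sprintf("(entropy %.4f nats); tumor class %d, %d mask pixels\n",
                x$objective_value, x$tumor_class, sum(x$tumor_mask)))
  }
  invisible(x)
}

.check_masks <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  list(a = a > 0, b = b > 0)
}

#' Tanimoto (Jaccard) overlap between two binary masks
#'
#' `|A∩B| / |A∪B|`; defined as 1 when both masks are empty. Ranges from 0
#' to 1.
#'
#' @param mask_a,mask_b Binary matrices of equal shape.
#' @return Scalar overlap coefficient.
#' @export
tanimoto <- function(mask_a, mask_b) {
  m <- .check_masks(mask_a, mask_b)
  uni <- sum(m$a | m$b)
  if (uni == 0L) return(1)
  sum(m$a & m$b) / uni
}

#' Dice overlap index between two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`; defined as 1 when both masks are empty. Always at
#' least as large as [tanimoto()].
#'
#' @inheritParams tanimoto
#' @return Scalar overlap coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(mask_a, mask_b) {
  m <- .check_masks(mask_a, mask_b)
  denom <- sum(m$a) + sum(m$b)
  if (denom == 0L) return(1)
  2 * sum(m$a & m$b) / denom
}

#' Mask area in physical units
#'
#' @param mask Binary matrix.
#' @param pixel_area Physical area of one pixel (default 1).
#' @return List with `area = n_pixels * pixel_area` and `n_pixels`.
#' @export
mask_area <- function(mask, pixel_area = 1) {
  n <- sum(mask > 0)
  list(area = n * pixel_area, n_pixels = as.integer(n))
}

#' Segmentation quality report against a ground-truth mask
#'
#' @param pred Predicted binary tumor mask.
#' @param truth Ground-truth binary mask.
#' @param pixel_area Physical pixel area for the area metric.
#' @return List with `tc` (Tanimoto), `doi` (Dice), `area` and `n_pixels` of
#'   the predicted mask.
#' @export
segmentation_metrics <- function(pred, truth, pixel_area = 1) {
  a <- mask_area(pred, pixel_area)
  list(tc = tanimoto(pred, truth), doi = dice_overlap(pred, truth),
       area = a$area, n_pixels = a$n_pixels)
}
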