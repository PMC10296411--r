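# Synthetic brain phantoms: an elliptical "brain" of concentric tissue zones
# on a dark background, one compact hyper- or hypo-intense tumor blob with a
# known ground-truth mask, and class labels that are a deterministic function
# of tumor shape, location quadrant and intensity polarity — so every
# pipeline stage can be exercised and scored without real MRI data.

#' Phantom generator specification
#'
#' Intensity layout: background 0 outside an elliptical brain region;
#' `n_tissue_modes` concentric zones at `mode_means`; one tumor blob at
#' `tumor_intensity`; additive Gaussian noise of sd `noise_sigma` inside the
#' brain, rounded and clipped to `[0, 255]`. The tumor intensity must be at
#' least `contrast_margin` gray levels away from every tissue mean, so the
#' tumor forms its own histogram mode.
#'
#' @param image_side Square image side in pixels (default 256).
#' @param n_tissue_modes Number of tissue intensity zones (default 3).
#' @param mode_means Gray-level means of the tissue zones (length
#'   `n_tissue_modes`).
#' @param mode_sigma Unused placeholder kept for symmetry with `noise_sigma`
#'   (tissue zones share the global noise level).
#' @param tumor_intensity Tumor gray level; above the tissue means for a
#'   hyper-intense tumor, below for hypo-intense.
#' @param tumor_radius_range Two-vector of minimum and maximum tumor radius
#'   in pixels.
#' @param tumor_shape `"disc"`, `"ellipse"` or `"lobed"` (three-lobed
#'   irregular outline).
#' @param tumor_quadrant Placement region: `"lower-center"`, `"upper-left"`
#'   or `"upper-right"`.
#' @param noise_sigma Gaussian noise sd in gray levels (default 4; 0 gives a
#'   noise-free phantom with exactly `n_tissue_modes + 2` distinct values).
#' @param contrast_margin Minimum tumor-to-tissue mean separation in gray
#'   levels (default 30).
#' @param seed Seed; phantoms are byte-identical under a fixed seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_side = 256L, n_tissue_modes = 3L,
                         mode_means = c(100, 130, 160), mode_sigma = 4,
                         tumor_intensity = 250,
                         tumor_radius_range = c(12, 22),
                         tumor_shape = c("disc", "ellipse", "lobed"),
                         tumor_quadrant = c("lower-center", "upper-left",
                                            "upper-right"),
                         noise_sigma = 4, contrast_margin = 30, seed = 1L) {
  tumor_shape <- match.arg(tumor_shape)
  tumor_quadrant <- match.arg(tumor_quadrant)
  if (length(mode_means) != n_tissue_modes)
    stop("mode_means must have n_tissue_modes entries")
  if (any(mode_means < 0 | mode_means > 255) ||
      tumor_intensity < 0 || tumor_intensity > 255)
    stop("gray levels must lie in [0, 255]")
  if (any(abs(tumor_intensity - mode_means) < contrast_margin))
    stop("tumor intensity within contrast_margin of a tissue mode; ",
         "infeasible phantom contrast")
  structure(
    list(image_side = as.integer(image_side),
         n_tissue_modes = as.integer(n_tissue_modes),
         mode_means = mode_means, mode_sigma = mode_sigma,
         tumor_intensity = tumor_intensity,
         tumor_radius_range = tumor_radius_range,
         tumor_shape = tumor_shape, tumor_quadrant = tumor_quadrant,
         noise_sigma = noise_sigma, contrast_margin = contrast_margin,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# label rule: shape, quadrant and polarity co-vary; shape indexes the class
.phantom_classes <- function() {
  list(
    list(label = 0L, name = "pituitary-like", shape = "disc",
         quadrant = "lower-center", intensity = 250),
    list(label = 1L, name = "glioma-like", shape = "lobed",
         quadrant = "upper-left", intensity = 220),
    list(label = 2L, name = "meningioma-like", shape = "ellipse",
         quadrant = "upper-right", intensity = 40)
  )
}

.label_from_spec <- function(spec) {
  for (cl in .phantom_classes()) {
    if (cl$shape == spec$tumor_shape) return(list(label = cl$label, name = cl$name))
  }
  stop("unknown tumor shape")
}

.tumor_blob <- function(spec, center, radius, angle, phase) {
  side <- spec$image_side
  r <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  dr <- r - center[1]
  dc <- cc - center[2]
  switch(spec$tumor_shape,
    disc = dr^2 + dc^2 <= radius^2,
    ellipse = {
      u <- cos(angle) * dr + sin(angle) * dc
      v <- -sin(angle) * dr + cos(angle) * dc
      (u / radius)^2 + (v / (0.6 * radius))^2 <= 1
    },
    lobed = {
      theta <- atan2(dc, dr)
      rad <- radius * (1 + 0.3 * sin(3 * theta + phase))
      dr^2 + dc^2 <= rad^2
    })
}

#' Generate one brain phantom
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom_sample`: list with `image` (integer
#'   matrix in 0-255), `tumor_mask` (0/1 ground truth), `label` (0, 1 or 2),
#'   `label_name` and `spec_used`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  side <- spec$image_side
  ctr <- (side + 1) / 2
  a_r <- 0.42 * side
  a_c <- 0.34 * side
  r <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  ellip <- ((r - ctr) / a_r)^2 + ((cc - ctr) / a_c)^2
  brain <- ellip <= 1
  # concentric tissue zones from the normalized elliptical radius
  zone <- pmin(floor(sqrt(pmax(ellip, 0)) * spec$n_tissue_modes) + 1L,
               spec$n_tissue_modes)
  img <- matrix(0, side, side)
  img[brain] <- spec$mode_means[zone[brain]]

  # tumor placement: rejection-sample a center in the requested quadrant
  # until the blob lies strictly inside the brain ellipse
  radius <- stats::runif(1, spec$tumor_radius_range[1],
                         spec$tumor_radius_range[2])
  angle <- stats::runif(1, 0, pi)
  phase <- stats::runif(1, 0, 2 * pi)
  box <- switch(spec$tumor_quadrant,
    "lower-center" = list(r = c(0.55, 0.75), c = c(0.40, 0.60)),
    "upper-left" = list(r = c(0.25, 0.45), c = c(0.28, 0.45)),
    "upper-right" = list(r = c(0.25, 0.45), c = c(0.55, 0.72)))
  mask <- NULL
  for (try in seq_len(200)) {
    center <- c(stats::runif(1, box$r[1], box$r[2]) * side,
                stats::runif(1, box$c[1], box$c[2]) * side)
    cand <- .tumor_blob(spec, center, radius, angle, phase)
    if (any(cand) && all(brain[cand])) {
      mask <- cand
      break
    }
  }
  if (is.null(mask)) stop("could not place tumor inside the brain ellipse")
  img[mask] <- spec$tumor_intensity

  if (spec$noise_sigma > 0) {
    noise <- matrix(stats::rnorm(side * side, sd = spec$noise_sigma),
                    side, side)
    img[brain] <- img[brain] + noise[brain]
  }
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), side, side)
  lab <- .label_from_spec(spec)
  structure(
    list(image = img, tumor_mask = matrix(as.integer(mask), side, side),
         label = lab$label, label_name = lab$name, spec_used = spec),
    class = "phantom_sample"
  )
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("Phantom %dx%d: label %d (%s), %s tumor of %d pixels\n",
              nrow(x$image), ncol(x$image), x$label, x$label_name,
              x$spec_used$tumor_shape, sum(x$tumor_mask)))
  invisible(x)
}

#' Generate a balanced labeled phantom dataset
#'
#' Cycles through the three phantom classes (disc / lower-center /
#' hyper-intense; lobed / upper-left / hyper-intense; ellipse / upper-right /
#' hypo-intense), deriving one sub-seed per sample from the master seed, so
#' the dataset is exactly balanced and fully reproducible.
#'
#' @param n_per_class Samples per class (>= 1).
#' @param spec_template A [phantom_spec()] supplying everything except the
#'   per-class shape, quadrant, intensity and the per-sample seed.
#' @param seed Master seed.
#' @return List of `phantom_sample` objects of length `3 * n_per_class`.
#' @export
generate_dataset <- function(n_per_class, spec_template = phantom_spec(),
                             seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  classes <- .phantom_classes()
  n_total <- n_per_class * length(classes)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  lapply(seq_len(n_total), function(i) {
    cl <- classes[[((i - 1L) %% length(classes)) + 1L]]
    sp <- spec_template
    sp$tumor_shape <- cl$shape
    sp$tumor_quadrant <- cl$quadrant
    sp$tumor_intensity <- cl$intensity
    sp$seed <- sub_seeds[i]
    generate_phantom(sp)
  })
}
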