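# End-to-end pipeline: segment each image with mayfly-optimized Kapur
# thresholds, extract HOG + deep features from the tumor region, fuse and
# entropy-select them, standardize, and train / apply the BiLSTM classifier.

#' Pipeline configuration
#'
#' Collects the per-stage settings used by [pipeline_fit()] and
#' [pipeline_predict()].
#'
#' @param n_classes_seg Intensity classes for segmentation. The default, 5,
#'   matches the default phantom layout: background + 3 tissue zones + tumor,
#'   one Kapur class each.
#' @param mfo_iterations Mayfly iterations per image for the threshold
#'   search.
#' @param hog A [hog_config()].
#' @param backbone A [residual_backbone_spec()].
#' @param fusion A [fusion_config()].
#' @param bilstm_hidden,bilstm_seq_len,bilstm_fc,dropout_rate BiLSTM shape
#'   parameters (see [bilstm_spec()]).
#' @param train A [train_config()] (Adam, learning rate 0.001, batch 32).
#' @param seed Master seed; per-image segmentation seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_classes_seg = 5L, mfo_iterations = 60L,
                            hog = hog_config(),
                            backbone = residual_backbone_spec(),
                            fusion = fusion_config(),
                            bilstm_hidden = 100L, bilstm_seq_len = 100L,
                            bilstm_fc = 50L, dropout_rate = 0.5,
                            train = train_config(), seed = 1L) {
  structure(
    list(n_classes_seg = as.integer(n_classes_seg),
         mfo_iterations = as.integer(mfo_iterations),
         hog = hog, backbone = backbone, fusion = fusion,
         bilstm_hidden = as.integer(bilstm_hidden),
         bilstm_seq_len = as.integer(bilstm_seq_len),
         bilstm_fc = as.integer(bilstm_fc), dropout_rate = dropout_rate,
         train = train, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Segment images and extract fused features
#'
#' For each image: Kapur/mayfly segmentation, masking of the image by the
#' tumor mask (tumor region kept, everything else zeroed; the full image is
#' used as a fallback when the mask comes back empty), HOG and deep feature
#' extraction on the masked image, and concatenation (deep first).
#'
#' @param images List of grayscale integer matrices, or of `phantom_sample`
#'   objects.
#' @param config A [pipeline_config()].
#' @param masks Optional list of precomputed binary masks, bypassing
#'   segmentation (e.g. ground truth for ablation).
#' @return List with `features` (samples x P matrix), `segmentations` (list
#'   of `segmentation_result` or NULL when `masks` given) and `parts`.
#' @export
pipeline_features <- function(images, config = pipeline_config(),
                              masks = NULL) {
  imgs <- lapply(images, function(s) {
    if (inherits(s, "phantom_sample")) s$image else s
  })
  weights <- backbone_weights(config$backbone)
  segs <- vector("list", length(imgs))
  rows <- vector("list", length(imgs))
  parts <- NULL
  for (i in seq_along(imgs)) {
    img <- imgs[[i]]
    if (is.null(masks)) {
      cfg <- mfo_config(
        bounds = rbind(rep(1, config$n_classes_seg - 1L),
                       rep(255, config$n_classes_seg - 1L)),
        n_iterations = config$mfo_iterations,
        seed = as.integer((as.numeric(config$seed) * 1000 + i) %% 2147483647))
      seg <- segment_image(img, n_classes = config$n_classes_seg,
                           config = cfg)
      segs[[i]] <- seg
      mask <- seg$tumor_mask
    } else {
      mask <- masks[[i]]
    }
    masked <- if (sum(mask) > 0) img * (mask > 0) else img
    fh <- hog_features(masked, config$hog)
    fd <- deep_features(masked, config$backbone, weights = weights)
    fused <- concat_features(fd, fh)
    parts <- fused$parts
    rows[[i]] <- fused$values
  }
  list(features = do.call(rbind, rows), segmentations = segs, parts = parts)
}

#' Fit the full detection pipeline on labeled images
#'
#' Runs [pipeline_features()], scores the fused features by batch entropy,
#' keeps the top `config$fusion$select_n`, standardizes the selected features
#' on the training batch, and trains the BiLSTM classifier.
#'
#' @param images Training images (or `phantom_sample` list; labels then
#'   default to the phantom labels).
#' @param labels Class labels (0-based or 1-based); optional for phantom
#'   samples.
#' @param config A [pipeline_config()].
#' @return Object of class `tumor_pipeline` holding the fitted classifier
#'   together with every transform needed at prediction time (selected
#'   indices, standardization statistics, stage configs) plus the training
#'   `loss_trace` and `segmentations`.
#' @export
pipeline_fit <- function(images, labels = NULL, config = pipeline_config()) {
  if (is.null(labels)) {
    labels <- vapply(images, function(s) {
      if (!inherits(s, "phantom_sample"))
        stop("labels must be given for raw images")
      s$label
    }, integer(1))
  }
  feats <- pipeline_features(images, config)
  scores <- entropy_scores(feats$features, config$fusion)
  idx <- selection_indices(scores, config$fusion$select_n)
  xsel <- feats$features[, idx, drop = FALSE]
  mu <- colMeans(xsel)
  sdv <- apply(xsel, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xstd <- sweep(sweep(xsel, 2, mu, "-"), 2, sdv, "/")
  spec <- bilstm_spec(input_dim = length(idx),
                      seq_len = config$bilstm_seq_len,
                      hidden_units = config$bilstm_hidden,
                      fc_units = config$bilstm_fc,
                      dropout_rate = config$dropout_rate,
                      n_classes = length(unique(labels)),
                      seed = config$seed)
  model <- build_bilstm(spec)
  fit <- train_bilstm(model, xstd, labels, config$train)
  structure(
    list(model = fit$model, loss_trace = fit$loss_trace,
         selected_indices = idx, entropy_scores = scores,
         feature_mean = mu, feature_sd = sdv, config = config,
         segmentations = feats$segmentations,
         label_levels = sort(unique(labels))),
    class = "tumor_pipeline"
  )
}

#' Apply a fitted pipeline to new images
#'
#' @param pipeline A [pipeline_fit()] result.
#' @param images Images or `phantom_sample` list.
#' @return List with `labels` (predicted, on the training label scale),
#'   `probs` (class probability matrix) and `segmentations`.
#' @export
pipeline_predict <- function(pipeline, images) {
  stopifnot(inherits(pipeline, "tumor_pipeline"))
  feats <- pipeline_features(images, pipeline$config)
  xsel <- feats$features[, pipeline$selected_indices, drop = FALSE]
  xstd <- sweep(sweep(xsel, 2, pipeline$feature_mean, "-"),
                2, pipeline$feature_sd, "/")
  probs <- predict_bilstm(pipeline$model, xstd)
  pred <- pipeline$label_levels[max.col(probs, ties.method = "first")]
  list(labels = pred, probs = probs, segmentations = feats$segmentations)
}

#' @export
print.tumor_pipeline <- function(x, ...) {
  cat(sprintf(paste0("Fitted tumor pipeline: %d selected features, ",
                     "%d training epochs (final loss %.4f)\n"),
              length(x$selected_indices), length(x$loss_trace),
              if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)]
              else NA_real_))
  invisible(x)
}
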