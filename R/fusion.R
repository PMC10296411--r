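# Fusion stage: concatenate deep and HOG descriptors into a single vector,
# score every feature by the Shannon entropy of its distribution, and keep
# the highest-entropy subset.

#' Fusion / selection configuration
#'
#' @param select_n Number of features retained by [select_features()]
#'   (default 1126).
#' @param normalization_constant Scalar multiplying every entropy score
#'   (default 1).
#' @param probability_model How the per-feature probability distribution is
#'   formed: `"histogram-over-batch"` (default) bins the feature's values
#'   across the batch into `n_hist_bins` equal-width bins;
#'   `"softmax-over-sample"` applies a softmax to the feature's values across
#'   the batch.
#' @param n_hist_bins Bin count for the histogram model (default 16).
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(select_n = 1126L, normalization_constant = 1,
                          probability_model = c("histogram-over-batch",
                                                "softmax-over-sample"),
                          n_hist_bins = 16L) {
  probability_model <- match.arg(probability_model)
  if (select_n < 1L) stop("select_n must be >= 1")
  structure(
    list(select_n = as.integer(select_n),
         normalization_constant = normalization_constant,
         probability_model = probability_model,
         n_hist_bins = as.integer(n_hist_bins)),
    class = "fusion_config"
  )
}

#' Concatenate deep and HOG feature vectors
#'
#' Deep features first, then HOG, so the fused length is `P = m + D`.
#'
#' @param f_res `feature_vector` from [deep_features()] (length `m`).
#' @param f_hog `feature_vector` from [hog_features()] (length `D`).
#' @return A `fused_vector`: list with `values`, `dim`, `parts` (named
#'   lengths of the deep and HOG segments), `selected_indices` (NULL before
#'   selection) and `entropy_scores` (NULL before scoring).
#' @export
concat_features <- function(f_res, f_hog) {
  va <- if (inherits(f_res, "feature_vector")) f_res$values else as.numeric(f_res)
  vb <- if (inherits(f_hog, "feature_vector")) f_hog$values else as.numeric(f_hog)
  if (length(va) == 0L || length(vb) == 0L) stop("empty feature vector")
  structure(
    list(values = c(va, vb), dim = length(va) + length(vb),
         parts = c(deep = length(va), hog = length(vb)),
         selected_indices = NULL, entropy_scores = NULL),
    class = "fused_vector"
  )
}

#' @export
print.fused_vector <- function(x, ...) {
  cat(sprintf("<fused feature vector, dim %d (deep %d + hog %d)%s>\n",
              x$dim, x$parts[["deep"]], x$parts[["hog"]],
              if (is.null(x$selected_indices)) ""
              else sprintf(", %d selected", length(x$selected_indices))))
  invisible(x)
}

.batch_matrix <- function(batch) {
  if (is.matrix(batch)) return(batch)
  if (is.list(batch)) {
    return(do.call(rbind, lapply(batch, function(v) {
      if (inherits(v, "fused_vector") || inherits(v, "feature_vector")) v$values
      else as.numeric(v)
    })))
  }
  stop("batch must be a matrix (samples x features) or a list of vectors")
}

#' Per-feature entropy scores over a batch
#'
#' For each feature a probability distribution is formed per
#' `config$probability_model` and scored by
#' `-normalization_constant * sum(p * log(p))` (nats, non-negative). A
#' feature constant across the batch scores 0 under the histogram model.
#'
#' @param batch Samples-by-features matrix, or list of
#'   `fused_vector`/numeric rows.
#' @param config A [fusion_config()].
#' @return Numeric vector of one score per feature.
#' @export
entropy_scores <- function(batch, config = fusion_config()) {
  m <- .batch_matrix(batch)
  if (config$probability_model == "histogram-over-batch" && nrow(m) < 2L)
    stop("histogram-over-batch scoring needs at least 2 samples")
  N <- config$normalization_constant
  if (config$probability_model == "histogram-over-batch") {
    nb <- config$n_hist_bins
    apply(m, 2, function(v) {
      rng <- range(v)
      if (rng[1] == rng[2]) return(0)
      # equal-width bins over the observed range; right-closed top bin
      bin <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * nb) + 1L, nb)
      p <- tabulate(bin, nbins = nb) / length(v)
      -N * .plogp(p)
    })
  } else {
    apply(m, 2, function(v) {
      e <- exp(v - max(v))
      p <- e / sum(e)
      -N * .plogp(p)
    })
  }
}

#' Keep the highest-entropy features
#'
#' Retains the `config$select_n` features with the largest scores, preserving
#' their original order; ties are broken toward the lower index. With
#' `select_n >= dim` the vector is returned unchanged (selection is therefore
#' idempotent).
#'
#' @param fused A `fused_vector`.
#' @param scores Per-feature scores from [entropy_scores()] (length
#'   `fused$dim`).
#' @param config A [fusion_config()].
#' @return A `fused_vector` with `values` restricted to the selected
#'   features, `selected_indices` (increasing, unique) and `entropy_scores`
#'   filled in.
#' @export
select_features <- function(fused, scores, config = fusion_config()) {
  stopifnot(inherits(fused, "fused_vector"))
  if (length(scores) != fused$dim)
    stop("scores length must match fused dimension")
  idx <- selection_indices(scores, config$select_n)
  fused$values <- fused$values[idx]
  fused$dim <- length(idx)
  fused$selected_indices <- idx
  fused$entropy_scores <- scores[idx]
  fused
}

#' Indices of the top-scoring features
#'
#' @param scores Per-feature scores.
#' @param select_n Number to keep (capped at `length(scores)`).
#' @return Strictly increasing integer indices.
#' @export
selection_indices <- function(scores, select_n) {
  n <- min(select_n, length(scores))
  sort(order(-scores, seq_along(scores))[seq_len(n)])
}
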