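# Pre-activation residual embedding backbone: a small seeded convolutional
# network in ResNet-V2 style (normalization and nonlinearity BEFORE each
# convolution, parameter-free identity shortcuts), pooled into a fixed-length
# deep feature vector. The default network is untrained: its value here is a
# stable, seeded random projection of local image structure, not a
# classification model.

#' Residual backbone specification
#'
#' Each block applies instance normalization -> ReLU -> 3x3 convolution ->
#' instance normalization -> ReLU -> 1x1 convolution on the residual branch,
#' plus an identity shortcut. The stem replicates the `[0, 1]`-scaled image
#' across `channels` feature maps (parameter-free), so with all convolution
#' weights zero the whole network reduces to the shortcut path. The embedding
#' is the global average pool over the final channels, hence
#' `embedding_dim = channels`.
#'
#' @param n_blocks Number of residual blocks (default 2).
#' @param channels Channel width, constant across blocks (identity shortcuts
#'   require it); equals the embedding dimension.
#' @param embedding_dim Output dimensionality; must equal `channels`.
#' @param input_side Side of the square working image (default 32).
#' @param seed Seed for the weight draw; fixes the embedding map.
#' @param pretrained If `TRUE`, weights are loaded from `weights_file`
#'   instead of being drawn.
#' @param weights_file Path to an `.rds` weight list (only with
#'   `pretrained = TRUE`).
#' @return Object of class `residual_backbone_spec`.
#' @export
residual_backbone_spec <- function(n_blocks = 2L, channels = 64L,
                                   embedding_dim = channels,
                                   input_side = 32L, seed = 1L,
                                   pretrained = FALSE, weights_file = NULL) {
  if (embedding_dim != channels)
    stop("embedding_dim must equal channels: the embedding is the global ",
         "average pool over the final channels and identity shortcuts keep ",
         "the width constant")
  structure(
    list(n_blocks = as.integer(n_blocks), channels = as.integer(channels),
         embedding_dim = as.integer(embedding_dim),
         input_side = as.integer(input_side), seed = as.integer(seed),
         pretrained = pretrained, weights_file = weights_file),
    class = "residual_backbone_spec"
  )
}

#' Backbone weights
#'
#' Draws He-initialized convolution kernels under `spec$seed`, or loads a
#' user-supplied weight file when `spec$pretrained` is `TRUE` (no weights are
#' downloaded or shipped).
#'
#' @param spec A [residual_backbone_spec()].
#' @return List of per-block weight lists (`w3`: 3x3 kernels, `w1`: 1x1
#'   kernels, biases `b3`, `b1`).
#' @export
backbone_weights <- function(spec) {
  if (isTRUE(spec$pretrained)) {
    if (is.null(spec$weights_file) || !file.exists(spec$weights_file))
      stop("pretrained = TRUE but weights_file is missing: ",
           spec$weights_file)
    return(readRDS(spec$weights_file))
  }
  set.seed(spec$seed)
  C <- spec$channels
  lapply(seq_len(spec$n_blocks), function(b) {
    list(
      w3 = array(stats::rnorm(3 * 3 * C * C, sd = sqrt(2 / (9 * C))),
                 dim = c(3, 3, C, C)),
      b3 = numeric(C),
      w1 = array(stats::rnorm(C * C, sd = sqrt(2 / C)), dim = c(1, 1, C, C)),
      b1 = numeric(C)
    )
  })
}

# Multi-channel 2-D convolution with "same" zero padding via im2col + GEMM.
# x: H x W x Cin array; w: k x k x Cin x Cout.
.conv2d <- function(x, w, bias = NULL) {
  H <- dim(x)[1]
  W <- dim(x)[2]
  Cin <- dim(x)[3]
  k <- dim(w)[1]
  Cout <- dim(w)[4]
  pad <- (k - 1L) %/% 2L
  if (pad > 0L) {
    xp <- array(0, dim = c(H + 2 * pad, W + 2 * pad, Cin))
    xp[(pad + 1):(pad + H), (pad + 1):(pad + W), ] <- x
  } else {
    xp <- x
  }
  cols <- matrix(0, H * W, k * k * Cin)
  wm <- matrix(0, k * k * Cin, Cout)
  blk <- 0L
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      slab <- xp[dy:(dy + H - 1L), dx:(dx + W - 1L), , drop = FALSE]
      cols[, blk + seq_len(Cin)] <- matrix(slab, H * W, Cin)
      wm[blk + seq_len(Cin), ] <- matrix(w[dy, dx, , ], Cin, Cout)
      blk <- blk + Cin
    }
  }
  out <- cols %*% wm
  if (!is.null(bias)) out <- sweep(out, 2, bias, "+")
  array(out, dim = c(H, W, Cout))
}

# Per-channel instance normalization over the spatial plane.
.instance_norm <- function(x, eps = 1e-5) {
  C <- dim(x)[3]
  for (c in seq_len(C)) {
    v <- x[, , c]
    x[, , c] <- (v - mean(v)) / sqrt(stats::var(as.vector(v)) * (length(v) - 1) / length(v) + eps)
  }
  x
}

#' Deep embedding of an image through the residual backbone
#'
#' Resizes the image, scales it to `[0, 1]`, replicates it across channels,
#' applies the pre-activation residual blocks and global-average-pools the
#' result. Deterministic given `spec$seed`.
#'
#' @param image Numeric grayscale matrix (8-bit 0-255 or already in
#'   `[0, 1]`).
#' @param spec A [residual_backbone_spec()].
#' @param weights Optional weight list overriding [backbone_weights()]
#'   (used, e.g., to probe the shortcut path with zeroed kernels).
#' @return A `feature_vector` with `source = "deep"` and
#'   `dim = spec$embedding_dim`.
#' @export
deep_features <- function(image, spec = residual_backbone_spec(),
                          weights = NULL) {
  if (is.null(weights)) weights <- backbone_weights(spec)
  img <- resize_gray(image, spec$input_side)
  if (max(img) > 1) img <- img / 255
  C <- spec$channels
  x <- array(img, dim = c(nrow(img), ncol(img), C))  # replicated stem
  for (blk in weights) {
    h <- .instance_norm(x)
    h[h < 0] <- 0
    h <- .conv2d(h, blk$w3, blk$b3)
    h <- .instance_norm(h)
    h[h < 0] <- 0
    h <- .conv2d(h, blk$w1, blk$b1)
    x <- x + h
  }
  emb <- apply(x, 3, mean)
  feature_vector(emb, source = "deep")
}
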