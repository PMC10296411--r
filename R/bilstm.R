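# Bidirectional LSTM classifier over fused feature vectors. The flat fused
# vector is reshaped into a fixed-length sequence, run through a forward and
# a backward LSTM whose per-step outputs are concatenated, max-pooled over
# time, and passed through a ReLU fully-connected layer, dropout, and a
# softmax output. Training is plain backpropagation-through-time with the
# Adam update, all written out in matrix form.

#' BiLSTM architecture specification
#'
#' The layer stack is: feature input reshaped to `seq_len` steps of
#' `input_per_step = ceiling(input_dim / seq_len)` values (zero-padded) ->
#' forward LSTM -> backward LSTM (per-step outputs concatenated) ->
#' max pooling over time -> fully-connected + ReLU (`fc_units`) -> dropout ->
#' fully-connected softmax over `n_classes`.
#'
#' @param input_dim Length of the (selected) fused feature vector.
#' @param seq_len Number of time steps the vector is reshaped into
#'   (default 100).
#' @param hidden_units LSTM hidden size per direction (default 100).
#' @param fc_units Fully-connected layer width (default 50).
#' @param dropout_rate Dropout probability, active only in training
#'   (default 0.5).
#' @param n_classes Number of output classes (default 3).
#' @param seed Seed for parameter initialization.
#' @return Object of class `bilstm_spec`.
#' @export
bilstm_spec <- function(input_dim, seq_len = 100L, hidden_units = 100L,
                        fc_units = 50L, dropout_rate = 0.5, n_classes = 3L,
                        seed = 1L) {
  if (input_dim < 1L) stop("input_dim must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(
    list(input_dim = as.integer(input_dim), seq_len = as.integer(seq_len),
         input_per_step = as.integer(ceiling(input_dim / seq_len)),
         hidden_units = as.integer(hidden_units),
         fc_units = as.integer(fc_units), dropout_rate = dropout_rate,
         n_classes = as.integer(n_classes), seed = as.integer(seed)),
    class = "bilstm_spec"
  )
}

.glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Build a BiLSTM model with seeded initial parameters
#'
#' Gate order within the `4 * hidden` weight blocks is input, forget, cell,
#' output; forget-gate biases start at 1.
#'
#' @param spec A [bilstm_spec()].
#' @return Object of class `bilstm_model` (spec + parameter list).
#' @export
build_bilstm <- function(spec) {
  stopifnot(inherits(spec, "bilstm_spec"))
  set.seed(spec$seed)
  H <- spec$hidden_units
  d <- spec$input_per_step
  init_dir <- function() {
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1
    list(W = .glorot(d, 4 * H), U = .glorot(H, 4 * H), b = b)
  }
  params <- list(
    fwd = init_dir(), bwd = init_dir(),
    W1 = .glorot(2 * H, spec$fc_units), b1 = numeric(spec$fc_units),
    W2 = .glorot(spec$fc_units, spec$n_classes), b2 = numeric(spec$n_classes)
  )
  structure(list(spec = spec, params = params), class = "bilstm_model")
}

#' @export
print.bilstm_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("BiLSTM classifier: %d features -> %d x %d sequence -> ",
                     "2 x %d hidden -> max pool -> FC %d -> %d classes\n"),
              s$input_dim, s$seq_len, s$input_per_step, s$hidden_units,
              s$fc_units, s$n_classes))
  invisible(x)
}

# Reshape a batch of flat vectors (n x input_dim) into a stacked step matrix
# ((n * seq_len) x d) where rows (t-1)*n + 1..n hold step t.
.stack_steps <- function(x, spec) {
  n <- nrow(x)
  d <- spec$input_per_step
  T <- spec$seq_len
  pad <- matrix(0, n, T * d)
  pad[, seq_len(ncol(x))] <- x
  xs <- matrix(0, n * T, d)
  for (t in seq_len(T)) {
    xs[(t - 1L) * n + seq_len(n), ] <- pad[, (t - 1L) * d + seq_len(d)]
  }
  xs
}

# One-direction LSTM pass over stacked steps; order is the step visiting
# sequence (1..T forward, T..1 backward). Returns per-step hidden states and
# the cache needed for BPTT.
.lstm_forward <- function(xs, par, n, T, order) {
  H <- ncol(par$U)  / 4L
  zx <- xs %*% par$W
  h <- matrix(0, n, H)
  cc <- matrix(0, n, H)
  cache <- vector("list", T)
  hs <- vector("list", T)
  for (t in order) {
    rows <- (t - 1L) * n + seq_len(n)
    z <- sweep(zx[rows, , drop = FALSE] + h %*% par$U, 2, par$b, "+")
    ig <- 1 / (1 + exp(-z[, 1:H, drop = FALSE]))
    fg <- 1 / (1 + exp(-z[, (H + 1):(2 * H), drop = FALSE]))
    gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    og <- 1 / (1 + exp(-z[, (3 * H + 1):(4 * H), drop = FALSE]))
    c_new <- fg * cc + ig * gg
    tc <- tanh(c_new)
    cache[[t]] <- list(i = ig, f = fg, g = gg, o = og, tc = tc,
                       c_prev = cc, h_prev = h)
    cc <- c_new
    h <- og * tc
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# Full forward pass. Returns probabilities plus every intermediate needed by
# the backward pass.
.bilstm_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  p <- model$params
  n <- nrow(x)
  T <- spec$seq_len
  H <- spec$hidden_units
  xs <- .stack_steps(x, spec)
  fwd <- .lstm_forward(xs, p$fwd, n, T, seq_len(T))
  bwd <- .lstm_forward(xs, p$bwd, n, T, rev(seq_len(T)))
  # max pooling over time on the concatenated per-step outputs
  M <- matrix(-Inf, n, 2 * H)
  amax <- matrix(1L, n, 2 * H)
  for (t in seq_len(T)) {
    hc <- cbind(fwd$hs[[t]], bwd$hs[[t]])
    upd <- hc > M
    M[upd] <- hc[upd]
    amax[upd] <- t
  }
  Z1 <- sweep(M %*% p$W1, 2, p$b1, "+")
  A <- pmax(Z1, 0)
  if (training && spec$dropout_rate > 0) {
    keep <- 1 - spec$dropout_rate
    mask <- matrix((stats::runif(length(A)) < keep) / keep, nrow(A), ncol(A))
  } else {
    mask <- NULL
  }
  D <- if (is.null(mask)) A else A * mask
  logits <- sweep(D %*% p$W2, 2, p$b2, "+")
  e <- exp(logits - apply(logits, 1, max))
  probs <- e / rowSums(e)
  list(probs = probs, xs = xs, fwd = fwd, bwd = bwd, M = M, amax = amax,
       Z1 = Z1, A = A, mask = mask, D = D, n = n)
}

# BPTT through one direction given per-step pooled gradients dh_pool (list
# over t of n x H matrices).
.lstm_backward <- function(xs, par, cache, dh_pool, n, T, order) {
  H <- ncol(par$U) / 4L
  gW <- matrix(0, nrow(par$W), ncol(par$W))
  gU <- matrix(0, H, 4 * H)
  gb <- numeric(4 * H)
  dz_stack <- matrix(0, n * T, 4 * H)
  dh_next <- matrix(0, n, H)
  dc_next <- matrix(0, n, H)
  for (t in rev(order)) {
    cc <- cache[[t]]
    dh <- dh_pool[[t]] + dh_next
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do * cc$o * (1 - cc$o))
    dz_stack[(t - 1L) * n + seq_len(n), ] <- dz
    gU <- gU + crossprod(cc$h_prev, dz)
    gb <- gb + colSums(dz)
    dh_next <- dz %*% t(par$U)
  }
  gW <- crossprod(xs, dz_stack)
  list(W = gW, U = gU, b = gb)
}

# Gradients of the mean cross-entropy loss for one batch.
.bilstm_backward <- function(model, fw, y) {
  spec <- model$spec
  p <- model$params
  n <- fw$n
  T <- spec$seq_len
  H <- spec$hidden_units
  dlogits <- fw$probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits / n
  gW2 <- crossprod(fw$D, dlogits)
  gb2 <- colSums(dlogits)
  dD <- dlogits %*% t(p$W2)
  dA <- if (is.null(fw$mask)) dD else dD * fw$mask
  dZ1 <- dA * (fw$Z1 > 0)
  gW1 <- crossprod(fw$M, dZ1)
  gb1 <- colSums(dZ1)
  dM <- dZ1 %*% t(p$W1)
  # route pooled gradients back to the arg-max time steps
  dh_f <- vector("list", T)
  dh_b <- vector("list", T)
  for (t in seq_len(T)) {
    d_t <- dM * (fw$amax == t)
    dh_f[[t]] <- d_t[, seq_len(H), drop = FALSE]
    dh_b[[t]] <- d_t[, H + seq_len(H), drop = FALSE]
  }
  gf <- .lstm_backward(fw$xs, p$fwd, fw$fwd$cache, dh_f, n, T, seq_len(T))
  gb_dir <- .lstm_backward(fw$xs, p$bwd, fw$bwd$cache, dh_b, n, T,
                           rev(seq_len(T)))
  list(fwd = gf, bwd = gb_dir, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Training configuration
#'
#' Defaults are the pipeline's stated training hyperparameters: Adam with
#' learning rate 0.001 and batch size 32.
#'
#' @param epochs Number of passes over the training data.
#' @param optimizer Only `"adam"` is supported.
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Seed fixing shuffling and dropout draws.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, optimizer = "adam",
                         learning_rate = 0.001, batch_size = 32L,
                         seed = 1L) {
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is supported")
  structure(
    list(epochs = as.integer(epochs), optimizer = optimizer,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# flatten/unflatten parameter lists for the Adam state
.flatten_grads <- function(g) {
  c(as.vector(g$fwd$W), as.vector(g$fwd$U), g$fwd$b,
    as.vector(g$bwd$W), as.vector(g$bwd$U), g$bwd$b,
    as.vector(g$W1), g$b1, as.vector(g$W2), g$b2)
}

.flatten_params <- function(p) {
  .flatten_grads(list(fwd = p$fwd, bwd = p$bwd, W1 = p$W1, b1 = p$b1,
                      W2 = p$W2, b2 = p$b2))
}

.unflatten_params <- function(v, p) {
  take <- function(n) {
    out <- v[seq_len(n)]
    v <<- v[-seq_len(n)]
    out
  }
  for (dir in c("fwd", "bwd")) {
    p[[dir]]$W <- matrix(take(length(p[[dir]]$W)), nrow(p[[dir]]$W))
    p[[dir]]$U <- matrix(take(length(p[[dir]]$U)), nrow(p[[dir]]$U))
    p[[dir]]$b <- take(length(p[[dir]]$b))
  }
  p$W1 <- matrix(take(length(p$W1)), nrow(p$W1))
  p$b1 <- take(length(p$b1))
  p$W2 <- matrix(take(length(p$W2)), nrow(p$W2))
  p$b2 <- take(length(p$b2))
  p
}

#' Train a BiLSTM classifier
#'
#' Mini-batch cross-entropy training with the Adam update. Deterministic
#' given `config$seed` and the data order; with `epochs = 0` the model is
#' returned unchanged.
#'
#' @param model A [build_bilstm()] model.
#' @param x Samples-by-features numeric matrix (or list of fused vectors).
#' @param y Integer class labels in `1..n_classes` (or 0-based; detected).
#' @param config A [train_config()].
#' @return List with the trained `model` and `loss_trace` (mean cross-entropy
#'   per epoch).
#' @export
train_bilstm <- function(model, x, y, config = train_config()) {
  stopifnot(inherits(model, "bilstm_model"))
  x <- .batch_matrix(x)
  y <- .canon_labels(y, model$spec$n_classes)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class")
  if (config$epochs == 0L) {
    return(list(model = model, loss_trace = numeric(0)))
  }
  set.seed(config$seed)
  n <- nrow(x)
  theta <- .flatten_params(model$params)
  m1 <- numeric(length(theta))
  m2 <- numeric(length(theta))
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  step <- 0L
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- .bilstm_forward(model, xb, training = TRUE)
      pr <- pmax(fw$probs[cbind(seq_along(yb), yb)], 1e-12)
      losses[bi] <- -mean(log(pr))
      g <- .flatten_grads(.bilstm_backward(model, fw, yb))
      step <- step + 1L
      m1 <- b1 * m1 + (1 - b1) * g
      m2 <- b2 * m2 + (1 - b2) * g^2
      mh <- m1 / (1 - b1^step)
      vh <- m2 / (1 - b2^step)
      theta <- theta - config$learning_rate * mh / (sqrt(vh) + eps)
      model$params <- .unflatten_params(theta, model$params)
    }
    trace[ep] <- mean(losses)
  }
  list(model = model, loss_trace = trace)
}

.canon_labels <- function(y, n_classes) {
  y <- as.integer(y)
  if (min(y) == 0L) y <- y + 1L
  if (any(y < 1L) || any(y > n_classes)) stop("labels outside 1..n_classes")
  y
}

#' Class probabilities for new samples
#'
#' @param model A (trained) `bilstm_model`.
#' @param x Samples-by-features matrix or list of fused vectors.
#' @return Matrix `n x n_classes` of softmax probabilities (rows sum to 1).
#' @export
predict_bilstm <- function(model, x) {
  x <- .batch_matrix(x)
  .bilstm_forward(model, x, training = FALSE)$probs
}
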