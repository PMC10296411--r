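make_separable <- function(n_per_class, dim = 12, seed = 1, spread = 0.3) {
  set.seed(seed)
  centers <- rbind(c(rep(3, dim / 2), rep(0, dim / 2)),
                   c(rep(0, dim / 2), rep(3, dim / 2)),
                   rep(-3, dim))
  y <- rep(1:3, each = n_per_class)
  x <- centers[y, ] + matrix(rnorm(3 * n_per_class * dim, sd = spread),
                             ncol = dim)
  list(x = x, y = y)
}

test_that("model construction is seeded with the specified layer shapes", {
  spec <- bilstm_spec(input_dim = 1126, seq_len = 100, hidden_units = 100,
                      fc_units = 50, n_classes = 3, seed = 7)
  expect_equal(spec$input_per_step, 12L)  # ceiling(1126 / 100), zero-padded
  m1 <- build_bilstm(spec)
  m2 <- build_bilstm(spec)
  expect_identical(m1$params, m2$params)
  # reshaped input -> forward LSTM -> backward LSTM -> max pool -> FC+ReLU
  # -> dropout -> softmax FC
  for (dir in c("fwd", "bwd")) {
    expect_equal(dim(m1$params[[dir]]$W), c(12, 400))
    expect_equal(dim(m1$params[[dir]]$U), c(100, 400))
    expect_equal(length(m1$params[[dir]]$b), 400)
  }
  expect_equal(dim(m1$params$W1), c(200, 50))   # pooled 2H concatenation
  expect_equal(dim(m1$params$W2), c(50, 3))
})

test_that("softmax outputs are normalized probabilities", {
  spec <- bilstm_spec(input_dim = 20, seq_len = 5, hidden_units = 6,
                      fc_units = 4, n_classes = 3, seed = 2)
  m <- build_bilstm(spec)
  set.seed(3)
  p <- predict_bilstm(m, matrix(rnorm(8 * 20), 8, 20))
  expect_equal(dim(p), c(8, 3))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
})

test_that("analytic gradients match finite differences", {
  spec <- bilstm_spec(input_dim = 10, seq_len = 4, hidden_units = 5,
                      fc_units = 4, dropout_rate = 0, n_classes = 3, seed = 2)
  m <- build_bilstm(spec)
  set.seed(11)
  x <- matrix(rnorm(6 * 10), 6, 10)
  y <- c(1, 2, 3, 1, 2, 3)
  fw <- mayflyseg:::.bilstm_forward(m, x, training = FALSE)
  g <- mayflyseg:::.flatten_grads(mayflyseg:::.bilstm_backward(m, fw, y))
  theta <- mayflyseg:::.flatten_params(m$params)
  loss_at <- function(th) {
    m2 <- m
    m2$params <- mayflyseg:::.unflatten_params(th, m$params)
    f <- mayflyseg:::.bilstm_forward(m2, x, training = FALSE)
    -mean(log(f$probs[cbind(1:6, y)]))
  }
  idx <- sample(length(theta), 25)
  num <- sapply(idx, function(j) {
    e <- 1e-5
    tp <- theta; tp[j] <- tp[j] + e
    tm <- theta; tm[j] <- tm[j] - e
    (loss_at(tp) - loss_at(tm)) / (2 * e)
  })
  expect_lt(max(abs(num - g[idx])), 1e-7)
})

test_that("training is deterministic, finite, and inert at zero epochs", {
  d <- make_separable(8, seed = 5)
  spec <- bilstm_spec(input_dim = 12, seq_len = 4, hidden_units = 8,
                      fc_units = 6, n_classes = 3, seed = 1)
  m <- build_bilstm(spec)
  cfg <- train_config(epochs = 5, seed = 9)
  f1 <- train_bilstm(m, d$x, d$y, cfg)
  f2 <- train_bilstm(m, d$x, d$y, cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$model$params, f2$model$params)
  expect_true(all(is.finite(f1$loss_trace)))
  expect_equal(length(f1$loss_trace), 5)

  f0 <- train_bilstm(m, d$x, d$y, train_config(epochs = 0))
  expect_identical(f0$model$params, m$params)
  expect_length(f0$loss_trace, 0)

  expect_error(train_bilstm(m, d$x, rep(1, nrow(d$x)), cfg), "single class")
  expect_error(train_config(optimizer = "sgd"), "adam")
  expect_equal(train_config()$learning_rate, 0.001)
  expect_equal(train_config()$batch_size, 32L)
})

test_that("the network can overfit a small separable three-class set", {
  d <- make_separable(20, seed = 7)  # 60 samples
  spec <- bilstm_spec(input_dim = 12, seq_len = 4, hidden_units = 8,
                      fc_units = 6, dropout_rate = 0, n_classes = 3, seed = 3)
  fit <- train_bilstm(build_bilstm(spec), d$x, d$y,
                      train_config(epochs = 200, seed = 4))
  pred <- max.col(predict_bilstm(fit$model, d$x))
  expect_equal(mean(pred == d$y), 1.0)
})

test_that("confusion-count metrics reproduce hand-computed values", {
  m <- binary_metrics(tp = 9, fp = 1, fn = 1, tn = 9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$f1, 0.9)
  z <- binary_metrics(0, 0, 0, 10)
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
})

test_that("rank AUC matches the all-pairs concordance oracle", {
  expect_equal(rank_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1.0)
  expect_true(is.na(rank_auc(1:4, rep(TRUE, 4))))
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:30, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # with ties
    pos <- runif(n) < 0.4
    if (sum(pos) == 0 || sum(pos) == n) next
    expect_equal(rank_auc(scores, pos), oracle_pair_auc(scores, pos),
                 tolerance = 1e-12)
  }
  # invariance to strictly monotone score transformation
  set.seed(5)
  s <- rnorm(40)
  pos <- runif(40) < 0.5
  expect_equal(rank_auc(exp(2 * s) + 3, pos), rank_auc(s, pos))
})

test_that("evaluation reports are internally consistent", {
  set.seed(31)
  n <- 60
  y <- sample(1:3, n, replace = TRUE)
  raw <- matrix(runif(n * 3), n, 3)
  probs <- raw / rowSums(raw)
  rep_ <- evaluate_predictions(probs, y)
  expect_equal(sum(rep_$confusion), n)
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / n)
  for (k in 1:3) {
    pc <- rep_$per_class[k, ]
    if (pc$precision + pc$recall > 0) {
      expect_equal(pc$f1,
                   2 * pc$precision * pc$recall / (pc$precision + pc$recall),
                   tolerance = 1e-12)
    }
    expect_equal(pc$auc, oracle_pair_auc(probs[, k], y == k),
                 tolerance = 1e-12)
  }
  expect_error(evaluate_predictions(probs[0, , drop = FALSE], integer(0)),
               "empty")
})
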