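test_that("histogram construction counts pixels and normalizes", {
  h <- compute_histogram(matrix(c(0, 0, 255, 255), 2, 2))
  expect_equal(h$probs[1], 0.5)
  expect_equal(h$probs[256], 0.5)
  expect_equal(sum(h$probs), 1)
  expect_equal(h$total_pixels, 4)

  hc <- compute_histogram(matrix(7, 3, 3))
  expect_equal(hc$probs[8], 1)
  expect_equal(sum(hc$probs[-8]), 0)

  set.seed(123)
  img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  hr <- compute_histogram(img)
  expect_equal(sum(hr$counts), 4096)
  expect_equal(sum(hr$probs), 1, tolerance = 1e-12)
  expect_equal(hr$counts[42], sum(img == 41))  # direct count, 0-based level 41
})

test_that("histogram rejects empty and out-of-range input", {
  expect_error(compute_histogram(matrix(numeric(0), 0, 0)), "empty")
  expect_error(compute_histogram(matrix(300, 2, 2)), "range")
  expect_error(compute_histogram(matrix(-1, 2, 2)), "range")
  expect_error(compute_histogram(matrix(1.5, 2, 2)), "integer")
})

test_that("histograms round-trip through JSON", {
  h <- random_histogram(5)
  h2 <- histogram_from_json(histogram_to_json(h))
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$probs, h$probs)
  expect_equal(h2$levels, h$levels)
})

test_that("class entropy matches closed forms and the summation oracle", {
  hu <- histogram_from_counts(rep(1, 256))
  ce <- class_entropy(hu, 0, 127)
  expect_equal(ce$mass, 0.5)
  expect_equal(ce$entropy, log(128), tolerance = 1e-12)

  hs <- histogram_from_counts(c(rep(0, 10), 5, rep(0, 245)))
  expect_equal(class_entropy(hs, 0, 255)$entropy, 0)
  expect_equal(class_entropy(hs, 30, 40)$entropy, 0)  # empty class convention
  expect_equal(class_entropy(hs, 30, 40)$mass, 0)

  for (seed in 1:5) {
    h <- random_histogram(seed)
    set.seed(seed + 100)
    lo <- sample(0:200, 1)
    hi <- lo + sample(1:55, 1)
    got <- class_entropy(h, lo, hi)
    exp <- oracle_class_entropy(h$probs, lo, hi)
    expect_equal(got$entropy, exp$entropy, tolerance = 1e-10)
    expect_equal(got$mass, exp$mass, tolerance = 1e-12)
  }
  expect_error(class_entropy(hu, 10, 5), "lo")
})

test_that("Kapur objective composes class entropies and hits closed forms", {
  hu <- histogram_from_counts(rep(1, 256))
  expect_equal(kapur_objective(hu, 128)$value, 2 * log(128), tolerance = 1e-10)

  hs <- histogram_from_counts(c(rep(0, 99), 12, rep(0, 156)))
  expect_equal(kapur_objective(hs, c(50, 150))$value, 0)

  for (seed in 1:5) {
    h <- random_histogram(seed + 10)
    set.seed(seed)
    thr <- sort(sample(1:255, 3))
    sc <- kapur_objective(h, thr)
    lo <- c(0, thr)
    hi <- c(thr - 1, 255)
    parts <- mapply(function(a, b) class_entropy(h, a, b)$entropy, lo, hi)
    expect_equal(sc$value, sum(parts), tolerance = 1e-10)
    expect_equal(sc$per_class_entropies, unname(parts), tolerance = 1e-10)
    expect_equal(sum(sc$class_masses), 1, tolerance = 1e-12)
  }
})

test_that("Kapur objective validates thresholds", {
  hu <- histogram_from_counts(rep(1, 256))
  expect_error(kapur_objective(hu, c(10, 10)), "increasing")
  expect_error(kapur_objective(hu, 0), "1, L-1|\\[1")
  expect_error(kapur_objective(hu, 256), "1, L-1|\\[1")
})

test_that("entropy bounds hold and the objective ignores total pixel count", {
  for (seed in 1:10) {
    h <- random_histogram(seed + 20)
    set.seed(seed)
    n <- sample(2:4, 1)
    thr <- sort(sample(1:255, n - 1))
    v <- kapur_objective(h, thr)$value
    expect_gte(v, 0)
    expect_lte(v, n * log(256))
    h10 <- histogram_from_counts(h$counts * 10)
    expect_equal(kapur_objective(h10, thr)$value, v, tolerance = 1e-10)
  }
})

test_that("exhaustive bilevel search equals a plain scan over all thresholds", {
  for (seed in c(3, 17)) {
    h <- random_histogram(seed)
    got <- exhaustive_best_thresholds(h, 2)
    vals <- sapply(1:255, function(t) kapur_objective(h, t)$value)
    expect_equal(got$score$value, max(vals), tolerance = 1e-12)
    expect_equal(got$thresholds, which.max(vals))
  }
})

test_that("two-spike histogram: maximum entropy keeps both spikes together", {
  counts <- numeric(256)
  counts[51] <- 10   # level 50
  counts[201] <- 10  # level 200
  h <- histogram_from_counts(counts)
  got <- exhaustive_best_thresholds(h, 2)
  # splitting the spikes yields two zero-entropy singletons; keeping them in
  # one class scores ln 2, so the optimum is the smallest such threshold
  expect_equal(got$score$value, log(2), tolerance = 1e-12)
  expect_equal(got$thresholds, 1L)
  expect_equal(kapur_objective(h, 51)$value, 0)
})

test_that("exhaustive trilevel search matches an independent double loop", {
  set.seed(77)
  x <- c(round(rnorm(800, 60, 8)), round(rnorm(800, 130, 10)),
         round(rnorm(800, 210, 7)))
  x <- x[x >= 0 & x <= 255]
  h <- histogram_from_counts(tabulate(x + 1, nbins = 256))
  got <- exhaustive_best_thresholds(h, 3)
  exp <- oracle_best_pair(h)
  expect_equal(got$score$value, exp$value, tolerance = 1e-12)
  expect_equal(got$thresholds, as.integer(exp$thresholds))
})

test_that("exhaustive search rejects unsupported class counts", {
  h <- random_histogram(1)
  expect_error(exhaustive_best_thresholds(h, 5), "2, 3, 4")
  expect_error(exhaustive_best_thresholds(h, 1), "2, 3, 4")
})
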