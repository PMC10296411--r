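# Independent brute-force oracles and small fixture builders shared across
# the suite. Each oracle is written as a direct transliteration of the
# defining formula, deliberately ignoring the package's vectorized paths.

# random 256-bin histogram with a few dominant intensity clusters
random_histogram <- function(seed, levels = 256L) {
  set.seed(seed)
  counts <- stats::rpois(levels, lambda = 2)
  n_clusters <- sample(2:4, 1)
  centers <- sample.int(levels, n_clusters)
  for (c in centers) {
    x <- round(stats::rnorm(2000, mean = c - 1, sd = stats::runif(1, 3, 12)))
    x <- x[x >= 0 & x <= levels - 1]
    counts <- counts + tabulate(x + 1L, nbins = levels)
  }
  histogram_from_counts(counts, levels)
}

# term-by-term class entropy: -sum (p/w) log (p/w)
oracle_class_entropy <- function(probs, lo, hi) {
  p <- probs[(lo + 1):(hi + 1)]
  w <- sum(p)
  if (w <= 0) return(list(entropy = 0, mass = 0))
  h <- 0
  for (pi in p) if (pi > 0) h <- h - (pi / w) * log(pi / w)
  list(entropy = h, mass = w)
}

# exhaustive n=3 search as an independently coded double loop
oracle_best_pair <- function(hist) {
  L <- hist$levels
  best <- -Inf
  arg <- NULL
  for (t1 in 1:(L - 2)) {
    for (t2 in (t1 + 1):(L - 1)) {
      v <- class_entropy(hist, 0, t1 - 1)$entropy +
        class_entropy(hist, t1, t2 - 1)$entropy +
        class_entropy(hist, t2, L - 1)$entropy
      if (v > best) {
        best <- v
        arg <- c(t1, t2)
      }
    }
  }
  list(thresholds = arg, value = best)
}

# per-pixel HOG cell voting loop with linear bin interpolation
oracle_cell_histograms <- function(image, config) {
  g <- hog_gradients(image)
  cs <- config$cell_size
  nb <- config$n_bins
  n_cr <- nrow(image) %/% cs
  n_cc <- ncol(image) %/% cs
  out <- array(0, dim = c(n_cr, n_cc, nb))
  bw <- 180 / nb
  for (r in seq_len(n_cr * cs)) {
    for (c in seq_len(n_cc * cs)) {
      m <- g$magnitude[r, c]
      if (m == 0) next
      o <- g$orientation[r, c]
      x <- o / bw - 0.5
      b0 <- floor(x)
      frac <- x - b0
      lo <- (b0 %% nb) + 1
      hi <- ((b0 + 1) %% nb) + 1
      cr <- (r - 1) %/% cs + 1
      cc_ <- (c - 1) %/% cs + 1
      out[cr, cc_, lo] <- out[cr, cc_, lo] + m * (1 - frac)
      out[cr, cc_, hi] <- out[cr, cc_, hi] + m * frac
    }
  }
  out
}

# all-pairs concordance AUC (ties count one half)
oracle_pair_auc <- function(scores, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

# per-feature histogram entropy by direct summation
oracle_entropy_score <- function(v, n_bins, N = 1) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  bin <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1, n_bins)
  h <- 0
  for (b in seq_len(n_bins)) {
    p <- sum(bin == b) / length(v)
    if (p > 0) h <- h - p * log(p)
  }
  N * h
}

# random binary mask
random_mask <- function(seed, side = 12, p = 0.4) {
  set.seed(seed)
  matrix(as.integer(stats::runif(side * side) < p), side, side)
}
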