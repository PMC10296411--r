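# Kapur's maximum-entropy thresholding: histogram construction, the entropy
# objective for bilevel/multilevel thresholds, and an exhaustive-search oracle.

#' Gray-level histogram of an image
#'
#' Counts pixel intensities of an integer-valued grayscale image and normalizes
#' them into a probability distribution, the domain on which Kapur's entropy
#' objective is defined.
#'
#' @param image Numeric matrix (or array/vector) of integer gray levels in
#'   `[0, levels - 1]`.
#' @param levels Number of gray levels `L` (default 256 for 8-bit images).
#' @return An object of class `kapur_histogram`: a list with `counts`
#'   (integer vector of length `levels`), `probs` (probabilities summing to 1),
#'   `total_pixels` and `levels`.
#' @examples
#' h <- compute_histogram(matrix(c(0, 0, 255, 255), 2, 2))
#' h$probs[c(1, 256)]
#' @export
compute_histogram <- function(image, levels = 256L) {
  levels <- as.integer(levels)
  if (length(image) == 0L) stop("image is empty")
  v <- as.vector(image)
  if (anyNA(v)) stop("image contains NA values")
  if (any(v != floor(v))) stop("image must contain integer gray levels")
  if (min(v) < 0 || max(v) > levels - 1L)
    stop("pixel values out of range [0, ", levels - 1L, "]")
  counts <- tabulate(as.integer(v) + 1L, nbins = levels)
  histogram_from_counts(counts, levels)
}

#' Build a histogram object from raw bin counts
#'
#' @param counts Non-negative integer vector of per-level counts.
#' @param levels Number of gray levels; defaults to `length(counts)`.
#' @return A `kapur_histogram` object.
#' @export
histogram_from_counts <- function(counts, levels = length(counts)) {
  counts <- as.numeric(counts)
  if (length(counts) != levels) stop("length(counts) must equal levels")
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("histogram has no mass")
  structure(
    list(counts = counts, probs = counts / total,
         total_pixels = total, levels = as.integer(levels)),
    class = "kapur_histogram"
  )
}

#' @export
print.kapur_histogram <- function(x, ...) {
  cat("Gray-level histogram:", x$levels, "levels,",
      format(x$total_pixels, big.mark = ","), "pixels,",
      sum(x$counts > 0), "non-empty bins\n")
  invisible(x)
}

#' Serialize a histogram to JSON
#'
#' @param hist A `kapur_histogram`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
histogram_to_json <- function(hist, path = NULL) {
  stopifnot(inherits(hist, "kapur_histogram"))
  js <- jsonlite::toJSON(list(counts = hist$counts, levels = hist$levels),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a histogram back from JSON
#'
#' @param json JSON string or path to a JSON file written by
#'   [histogram_to_json()].
#' @return A `kapur_histogram`.
#' @export
histogram_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  histogram_from_counts(x$counts, x$levels)
}

# sum of p*log(p) with the 0*log(0) = 0 convention
.plogp <- function(p) {
  pos <- p > 0
  sum(p[pos] * log(p[pos]))
}

#' Shannon entropy of one intensity class
#'
#' Entropy (in nats) of the histogram restricted to levels `lo..hi` and
#' renormalized by the class mass, the per-class term of Kapur's objective.
#' An empty class (zero mass) contributes entropy 0 by convention.
#'
#' @param hist A `kapur_histogram`.
#' @param lo,hi Inclusive 0-based gray-level bounds, `0 <= lo <= hi <= L-1`.
#' @return A list with `entropy` (nats) and `mass` (class probability).
#' @export
class_entropy <- function(hist, lo, hi) {
  stopifnot(inherits(hist, "kapur_histogram"))
  L <- hist$levels
  if (lo > hi) stop("lo must not exceed hi")
  if (lo < 0 || hi > L - 1L) stop("class bounds outside [0, L-1]")
  p <- hist$probs[(lo + 1L):(hi + 1L)]
  mass <- sum(p)
  if (mass <= 0) return(list(entropy = 0, mass = 0))
  # -sum((p/w) log(p/w)) = log(w) - (1/w) sum p log p
  list(entropy = log(mass) - .plogp(p) / mass, mass = mass)
}

.validate_thresholds <- function(thresholds, L) {
  t <- as.integer(thresholds)
  if (length(t) < 1L) stop("at least one threshold required")
  if (any(t != thresholds)) stop("thresholds must be integers")
  if (any(t < 1L) || any(t > L - 1L)) stop("thresholds must lie in [1, L-1]")
  if (length(t) > 1L && any(diff(t) <= 0L))
    stop("thresholds must be strictly increasing")
  t
}

#' Kapur's multilevel entropy objective
#'
#' Sum of the class entropies induced by a threshold vector. A threshold `t`
#' assigns level `t` to the upper class, so `n-1` thresholds induce the
#' half-open classes `[0, t1), [t1, t2), ..., [t_{n-1}, L)`. Kapur's rule
#' selects the thresholds that maximize this sum.
#'
#' @param hist A `kapur_histogram`.
#' @param thresholds Strictly increasing integer vector in `[1, L-1]`.
#' @return An object of class `kapur_score`: list with `value` (nats),
#'   `per_class_entropies` and `class_masses` (each of length
#'   `length(thresholds) + 1`).
#' @export
kapur_objective <- function(hist, thresholds) {
  stopifnot(inherits(hist, "kapur_histogram"))
  L <- hist$levels
  t <- .validate_thresholds(thresholds, L)
  lo <- c(0L, t)
  hi <- c(t - 1L, L - 1L)
  ents <- numeric(length(lo))
  masses <- numeric(length(lo))
  for (k in seq_along(lo)) {
    ce <- class_entropy(hist, lo[k], hi[k])
    ents[k] <- ce$entropy
    masses[k] <- ce$mass
  }
  structure(
    list(value = sum(ents), per_class_entropies = ents,
         class_masses = masses, thresholds = t),
    class = "kapur_score"
  )
}

#' @export
print.kapur_score <- function(x, ...) {
  cat("Kapur entropy", format(x$value, digits = 6), "nats at thresholds",
      paste(x$thresholds, collapse = ", "), "\n")
  invisible(x)
}

# Cumulative tables enabling O(1) class entropies: for 0-based levels a..b,
# mass = cp[b+2]-cp[a+1] and sum p log p = cs[b+2]-cs[a+1].
.kapur_tables <- function(hist) {
  p <- hist$probs
  pl <- ifelse(p > 0, p * log(p), 0)
  list(cp = c(0, cumsum(p)), cs = c(0, cumsum(pl)), L = hist$levels)
}

# Class entropy from cumulative tables, vectorized over (lo, hi)
.class_entropy_fast <- function(tab, lo, hi) {
  w <- tab$cp[hi + 2L] - tab$cp[lo + 1L]
  s <- tab$cs[hi + 2L] - tab$cs[lo + 1L]
  out <- ifelse(w > 0, log(pmax(w, .Machine$double.xmin)) - s / w, 0)
  out[w <= 0] <- 0
  out
}

# Objective value only (fast path used by the optimizer); thresholds assumed
# valid.
.kapur_value_fast <- function(tab, thresholds) {
  lo <- c(0L, thresholds)
  hi <- c(thresholds - 1L, tab$L - 1L)
  sum(.class_entropy_fast(tab, lo, hi))
}

#' Exhaustive search for globally optimal Kapur thresholds
#'
#' Enumerates every valid threshold vector for `n_classes` in {2, 3, 4} and
#' returns the one maximizing [kapur_objective()]. Ties are broken by the
#' lexicographically smallest threshold vector. Serves as the ground-truth
#' oracle for the mayfly optimizer.
#'
#' @param hist A `kapur_histogram`.
#' @param n_classes Number of intensity classes (2, 3 or 4).
#' @return List with `thresholds` (integer vector of length `n_classes - 1`)
#'   and `score` (a `kapur_score`).
#' @export
exhaustive_best_thresholds <- function(hist, n_classes) {
  stopifnot(inherits(hist, "kapur_histogram"))
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% 2:4)
    stop("exhaustive search supports n_classes in {2, 3, 4}")
  L <- hist$levels
  tab <- .kapur_tables(hist)
  if (n_classes == 2L) {
    t1 <- 1:(L - 1L)
    vals <- .class_entropy_fast(tab, rep(0L, length(t1)), t1 - 1L) +
      .class_entropy_fast(tab, t1, rep(L - 1L, length(t1)))
    best <- which.max(vals)  # first maximum = smallest t
    thr <- t1[best]
  } else if (n_classes == 3L) {
    h_first <- .class_entropy_fast(tab, rep(0L, L - 1L), 0:(L - 2L))  # [0,t1)
    h_last <- .class_entropy_fast(tab, 1:(L - 1L), rep(L - 1L, L - 1L))
    best_val <- -Inf
    thr <- NULL
    for (t1 in 1:(L - 2L)) {
      t2 <- (t1 + 1L):(L - 1L)
      vals <- h_first[t1] +
        .class_entropy_fast(tab, rep(t1, length(t2)), t2 - 1L) +
        h_last[t2]
      j <- which.max(vals)
      if (vals[j] > best_val) {
        best_val <- vals[j]
        thr <- c(t1, t2[j])
      }
    }
  } else {
    h_first <- .class_entropy_fast(tab, rep(0L, L - 1L), 0:(L - 2L))
    h_last <- .class_entropy_fast(tab, 1:(L - 1L), rep(L - 1L, L - 1L))
    best_val <- -Inf
    thr <- NULL
    for (t1 in 1:(L - 3L)) {
      for (t2 in (t1 + 1L):(L - 2L)) {
        t3 <- (t2 + 1L):(L - 1L)
        vals <- h_first[t1] +
          .class_entropy_fast(tab, t1, t2 - 1L) +
          .class_entropy_fast(tab, rep(t2, length(t3)), t3 - 1L) +
          h_last[t3]
        j <- which.max(vals)
        if (vals[j] > best_val) {
          best_val <- vals[j]
          thr <- c(t1, t2, t3[j])
        }
      }
    }
  }
  list(thresholds = as.integer(thr), score = kapur_objective(hist, thr))
}
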