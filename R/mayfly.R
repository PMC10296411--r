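# Mayfly optimization (MFO): a swarm metaheuristic with paired male/female
# populations, nuptial-dance exploration for the best male, and convex
# crossover mating. Used here to maximize Kapur's entropy over threshold
# vectors, but written as a general continuous maximizer over a bounded box.

#' Configuration for the mayfly optimizer
#'
#' @param bounds 2 x d numeric matrix; row 1 lower, row 2 upper bounds per
#'   dimension (a 2-vector is treated as a single dimension).
#' @param n_males,n_females Swarm sizes; the algorithm pairs agents, so the
#'   two must be equal.
#' @param n_iterations Number of optimization rounds.
#' @param a1,a2 Male attraction coefficients toward the personal and global
#'   best positions.
#' @param a3 Female attraction coefficient toward the paired male.
#' @param beta Visibility exponent of the `exp(-beta * r^2)` attraction
#'   decay, with `r` measured on the box-normalized scale (coordinate
#'   differences divided by the per-dimension bound range) so the decay is
#'   invariant to the units of the search box.
#' @param dance Nuptial-dance amplitude of the best male (random velocity
#'   kick sustaining exploration).
#' @param fl Random-walk amplitude for females whose paired male is not
#'   fitter.
#' @param gravity Velocity damping factor in (0, 1].
#' @param dance_damp,fl_damp Per-iteration multiplicative reduction of the
#'   `dance` and `fl` amplitudes, in (0, 1].
#' @param mutation_prob Per-coordinate probability that an offspring gene is
#'   mutated after mating (0 disables mutation).
#' @param mutation_sigma Mutation step standard deviation as a fraction of
#'   the per-dimension bound range.
#' @param seed Integer seed controlling every random draw.
#' @return An object of class `mfo_config`.
#' @export
mfo_config <- function(bounds,
                       n_males = 20L, n_females = 20L, n_iterations = 100L,
                       a1 = 1.0, a2 = 1.5, a3 = 1.5, beta = 2,
                       dance = 5, fl = 1, gravity = 0.8,
                       dance_damp = 0.99, fl_damp = 0.99,
                       mutation_prob = 0.5, mutation_sigma = 0.2,
                       seed = 1L) {
  if (is.vector(bounds) && length(bounds) == 2L) bounds <- matrix(bounds, 2, 1)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L) stop("bounds must be a 2 x d matrix (lower; upper)")
  if (any(bounds[1, ] >= bounds[2, ])) stop("lower bounds must be < upper")
  if (n_males != n_females)
    stop("mayfly optimization uses equal numbers of male and female agents")
  for (nm in c("gravity", "dance_damp", "fl_damp")) {
    v <- get(nm)
    if (v <= 0 || v > 1) stop(nm, " must lie in (0, 1]")
  }
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("mutation_prob must lie in [0, 1]")
  if (mutation_sigma < 0) stop("mutation_sigma must be non-negative")
  structure(
    list(bounds = bounds, n_males = as.integer(n_males),
         n_females = as.integer(n_females),
         n_iterations = as.integer(n_iterations),
         a1 = a1, a2 = a2, a3 = a3, beta = beta, dance = dance, fl = fl,
         gravity = gravity, dance_damp = dance_damp, fl_damp = fl_damp,
         mutation_prob = mutation_prob, mutation_sigma = mutation_sigma,
         seed = as.integer(seed)),
    class = "mfo_config"
  )
}

#' Write / read an optimizer configuration
#'
#' Round-trips an [mfo_config()] through JSON or YAML, chosen by file
#' extension.
#'
#' @param config An `mfo_config`.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_mfo_config` returns the reconstructed `mfo_config`.
#' @export
write_mfo_config <- function(config, path) {
  stopifnot(inherits(config, "mfo_config"))
  x <- unclass(config)
  x$bounds <- list(lower = config$bounds[1, ], upper = config$bounds[2, ])
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

#' @rdname write_mfo_config
#' @export
read_mfo_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::fromJSON(path)
  bounds <- rbind(unlist(x$bounds$lower), unlist(x$bounds$upper))
  mfo_config(bounds = bounds, n_males = x$n_males, n_females = x$n_females,
             n_iterations = x$n_iterations, a1 = x$a1, a2 = x$a2, a3 = x$a3,
             beta = x$beta, dance = x$dance, fl = x$fl, gravity = x$gravity,
             dance_damp = x$dance_damp, fl_damp = x$fl_damp,
             mutation_prob = x$mutation_prob,
             mutation_sigma = x$mutation_sigma, seed = x$seed)
}

.clamp <- function(x, bounds) {
  for (j in seq_len(ncol(x))) {
    x[, j] <- pmin(pmax(x[, j], bounds[1, j]), bounds[2, j])
  }
  x
}

.eval_rows <- function(x, objective) {
  apply(x, 1L, objective)
}

#' Initialize a mayfly population
#'
#' Draws male and female positions uniformly inside the bounded box under
#' `config$seed`, sets velocities to zero and evaluates personal and global
#' bests. The caller's RNG state is advanced deterministically.
#'
#' @param config An [mfo_config()].
#' @param objective Function mapping a position vector to a finite value to
#'   MAXIMIZE.
#' @return An object of class `mayfly_population`.
#' @export
mfo_initialize <- function(config, objective) {
  stopifnot(inherits(config, "mfo_config"))
  set.seed(config$seed)
  d <- ncol(config$bounds)
  nm <- config$n_males
  nf <- config$n_females
  rand_box <- function(n) {
    m <- matrix(stats::runif(n * d), n, d)
    sweep(sweep(m, 2, config$bounds[2, ] - config$bounds[1, ], "*"),
          2, config$bounds[1, ], "+")
  }
  male_pos <- rand_box(nm)
  female_pos <- rand_box(nf)
  m_fit <- .eval_rows(male_pos, objective)
  f_fit <- .eval_rows(female_pos, objective)
  bad <- which(!is.finite(c(m_fit, f_fit)))
  if (length(bad)) {
    pts <- rbind(male_pos, female_pos)
    stop("objective is non-finite at initial point (",
         paste(format(pts[bad[1], ], digits = 6), collapse = ", "), ")")
  }
  all_fit <- c(m_fit, f_fit)
  all_pos <- rbind(male_pos, female_pos)
  gb <- which.max(all_fit)
  structure(
    list(male_positions = male_pos, female_positions = female_pos,
         male_velocities = matrix(0, nm, d),
         female_velocities = matrix(0, nf, d),
         male_fitness = m_fit, female_fitness = f_fit,
         pbest_positions = male_pos, pbest_values = m_fit,
         global_best = list(position = all_pos[gb, ], value = all_fit[gb]),
         dance_cur = config$dance, fl_cur = config$fl, iteration = 0L),
    class = "mayfly_population"
  )
}

#' Convex crossover mating of two mayflies
#'
#' Each child coordinate is the convex combination of the parents' coordinates
#' with mixing number `P`; for `P` in `[0, 1]` children lie on the segment
#' between the parents.
#'
#' @param male,female Numeric parent vectors of equal length.
#' @param P Mixing number (drawn from a truncated Gaussian during
#'   optimization).
#' @return List with `child1 = P*male + (1-P)*female` and
#'   `child2 = P*female + (1-P)*male`.
#' @export
mfo_mate <- function(male, female, P) {
  if (length(male) != length(female)) stop("parent dimensions differ")
  list(child1 = P * male + (1 - P) * female,
       child2 = P * female + (1 - P) * male)
}

# one draw from N(0.5, 0.1) truncated to [0, 1] via inverse-CDF
.rtrunc_p <- function() {
  lo <- stats::pnorm(0, 0.5, 0.1)
  hi <- stats::pnorm(1, 0.5, 0.1)
  stats::qnorm(stats::runif(1, lo, hi), 0.5, 0.1)
}

#' One iteration of the mayfly optimizer
#'
#' Updates male velocities toward personal/global bests with
#' `exp(-beta * r^2)` attraction (the best male instead performs a nuptial
#' dance), female velocities toward their rank-paired male when he is fitter
#' (random walk otherwise), moves and clamps positions, mates the top half of
#' ranked pairs, applies range-scaled Gaussian mutation to offspring genes
#' with probability `mutation_prob`, replaces the worst agents with the
#' offspring, refreshes bests, and damps the dance/random-walk amplitudes.
#'
#' @param pop A `mayfly_population`.
#' @param config The [mfo_config()] used at initialization.
#' @param objective The objective being maximized.
#' @return The updated `mayfly_population`; its `global_best$value` never
#'   decreases.
#' @export
mfo_step <- function(pop, config, objective) {
  stopifnot(inherits(pop, "mayfly_population"), inherits(config, "mfo_config"))
  bounds <- config$bounds
  d <- ncol(bounds)
  nm <- config$n_males
  g <- config$gravity
  gbest <- pop$global_best$position
  # attraction distances are measured on the box-normalized scale so the
  # exp(-beta * r^2) visibility term is invariant to the bounds' units
  rng <- bounds[2, ] - bounds[1, ]

  # --- male velocity updates ---
  best_male <- which.max(pop$male_fitness)
  mp <- pop$male_positions
  mv <- pop$male_velocities
  dp <- pop$pbest_positions - mp
  dg <- sweep(-mp, 2, gbest, "+")
  rp2 <- rowSums(sweep(dp, 2, rng, "/")^2)
  rg2 <- rowSums(sweep(dg, 2, rng, "/")^2)
  mv <- g * mv +
    config$a1 * exp(-config$beta * rp2) * dp +
    config$a2 * exp(-config$beta * rg2) * dg
  mv[best_male, ] <- g * pop$male_velocities[best_male, ] +
    pop$dance_cur * stats::runif(d, -1, 1)

  # --- female velocity updates: rank-paired with males ---
  m_rank <- order(pop$male_fitness, decreasing = TRUE)
  f_rank <- order(pop$female_fitness, decreasing = TRUE)
  fp <- pop$female_positions
  fv <- pop$female_velocities
  for (k in seq_len(nm)) {
    i_m <- m_rank[k]
    i_f <- f_rank[k]
    if (pop$male_fitness[i_m] > pop$female_fitness[i_f]) {
      dmf <- mp[i_m, ] - fp[i_f, ]
      fv[i_f, ] <- g * fv[i_f, ] +
        config$a3 * exp(-config$beta * sum((dmf / rng)^2)) * dmf
    } else {
      fv[i_f, ] <- g * fv[i_f, ] + pop$fl_cur * stats::runif(d, -1, 1)
    }
  }

  # --- position update (loc(t+1) = loc(t) + v(t+1)) and clamping ---
  mp <- .clamp(mp + mv, bounds)
  fp <- .clamp(fp + fv, bounds)
  m_fit <- .eval_rows(mp, objective)
  f_fit <- .eval_rows(fp, objective)

  # personal bests (males)
  improved <- m_fit > pop$pbest_values
  pop$pbest_positions[improved, ] <- mp[improved, , drop = FALSE]
  pop$pbest_values[improved] <- m_fit[improved]

  # --- mating: top half of ranked pairs; offspring replace worst agents ---
  m_rank <- order(m_fit, decreasing = TRUE)
  f_rank <- order(f_fit, decreasing = TRUE)
  n_pairs <- nm %/% 2L
  if (n_pairs >= 1L) {
    worst_m <- rev(m_rank)  # ascending fitness
    worst_f <- rev(f_rank)
    mutate <- function(child) {
      hit <- stats::runif(d) < config$mutation_prob
      if (any(hit)) {
        child[hit] <- child[hit] +
          stats::rnorm(sum(hit), 0, config$mutation_sigma * rng[hit])
      }
      child
    }
    for (k in seq_len(n_pairs)) {
      off <- mfo_mate(mp[m_rank[k], ], fp[f_rank[k], ], .rtrunc_p())
      c1 <- pmin(pmax(mutate(off$child1), bounds[1, ]), bounds[2, ])
      c2 <- pmin(pmax(mutate(off$child2), bounds[1, ]), bounds[2, ])
      i_m <- worst_m[k]
      i_f <- worst_f[k]
      mp[i_m, ] <- c1
      mv[i_m, ] <- 0
      m_fit[i_m] <- objective(c1)
      fp[i_f, ] <- c2
      fv[i_f, ] <- 0
      f_fit[i_f] <- objective(c2)
      if (m_fit[i_m] > pop$pbest_values[i_m]) {
        pop$pbest_positions[i_m, ] <- c1
        pop$pbest_values[i_m] <- m_fit[i_m]
      }
    }
  }

  # --- global best (elitist: never degrades) ---
  all_fit <- c(m_fit, f_fit)
  all_pos <- rbind(mp, fp)
  j <- which.max(all_fit)
  if (all_fit[j] > pop$global_best$value) {
    pop$global_best <- list(position = all_pos[j, ], value = all_fit[j])
  }

  pop$male_positions <- mp
  pop$female_positions <- fp
  pop$male_velocities <- mv
  pop$female_velocities <- fv
  pop$male_fitness <- m_fit
  pop$female_fitness <- f_fit
  pop$dance_cur <- pop$dance_cur * config$dance_damp
  pop$fl_cur <- pop$fl_cur * config$fl_damp
  pop$iteration <- pop$iteration + 1L
  pop
}

#' Run the mayfly optimizer
#'
#' Initializes a population under `config$seed` and iterates [mfo_step()]
#' for `config$n_iterations` rounds, recording the global best value after
#' each round.
#'
#' @param config An [mfo_config()].
#' @param objective Function to maximize over the bounded box.
#' @return List with `best_position`, `best_value`, `trace` (per-iteration
#'   best values, monotone non-decreasing) and the final `population`.
#' @export
mfo_optimize <- function(config, objective) {
  pop <- mfo_initialize(config, objective)
  trace <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    pop <- mfo_step(pop, config, objective)
    trace[it] <- pop$global_best$value
  }
  list(best_position = pop$global_best$position,
       best_value = pop$global_best$value,
       trace = trace, population = pop)
}

#' Decode a continuous position into a valid threshold vector
#'
#' The optimizer searches a relaxed continuous box; gray-level thresholds are
#' recovered by sorting, rounding, clamping to `[1, L-1]` and resolving
#' duplicates by incrementing (shifting down from the top if the upper bound
#' is hit), so the Kapur objective is well defined everywhere.
#'
#' @param x Numeric position vector.
#' @param levels Number of gray levels `L`.
#' @return Strictly increasing integer thresholds in `[1, L-1]`.
#' @export
decode_thresholds <- function(x, levels = 256L) {
  L <- as.integer(levels)
  n <- length(x)
  if (n > L - 1L) stop("more thresholds than available gray levels")
  t <- sort(round(x))
  t <- pmin(pmax(t, 1), L - 1L)
  if (n > 1L) {
    for (i in 2:n) if (t[i] <= t[i - 1L]) t[i] <- t[i - 1L] + 1L
    if (t[n] > L - 1L) {
      t[n] <- L - 1L
      for (i in (n - 1L):1L) if (t[i] >= t[i + 1L]) t[i] <- t[i + 1L] - 1L
    }
  }
  as.integer(t)
}

#' Maximize the Kapur objective over thresholds with the mayfly optimizer
#'
#' @param hist A [compute_histogram()] result.
#' @param n_classes Number of intensity classes (`n_classes - 1` thresholds).
#' @param config Optional [mfo_config()]; defaults to the package defaults on
#'   the box `[1, L-1]^d` with the given `seed`.
#' @param seed Seed used when `config` is `NULL`.
#' @return List with `thresholds`, `score` (a `kapur_score`) and the raw
#'   optimizer result `mfo`.
#' @export
optimize_thresholds <- function(hist, n_classes, config = NULL, seed = 1L) {
  stopifnot(inherits(hist, "kapur_histogram"))
  L <- hist$levels
  d <- as.integer(n_classes) - 1L
  if (d < 1L) stop("n_classes must be at least 2")
  if (is.null(config)) {
    config <- mfo_config(bounds = rbind(rep(1, d), rep(L - 1, d)), seed = seed)
  }
  tab <- .kapur_tables(hist)
  obj <- function(x) .kapur_value_fast(tab, decode_thresholds(x, L))
  res <- mfo_optimize(config, obj)
  thr <- decode_thresholds(res$best_position, L)
  list(thresholds = thr, score = kapur_objective(hist, thr), mfo = res)
}
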