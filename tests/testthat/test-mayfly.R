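sphere <- function(x) -sum((x - 0.3)^2)  # maximum 0 at 0.3 in every dim

test_that("configuration validates swarm symmetry and bounds", {
  expect_error(mfo_config(bounds = c(0, 1), n_males = 5, n_females = 6),
               "equal numbers")
  expect_error(mfo_config(bounds = rbind(c(1, 0), c(0, 1))), "lower")
  expect_error(mfo_config(bounds = c(0, 1), gravity = 0), "gravity")
  cfg <- mfo_config(bounds = c(0, 1))
  expect_s3_class(cfg, "mfo_config")
  expect_equal(ncol(cfg$bounds), 1)
})

test_that("configuration round-trips through JSON and YAML", {
  cfg <- mfo_config(bounds = rbind(c(0, -2), c(1, 5)), n_males = 7,
                    n_females = 7, n_iterations = 13, dance = 2.5, seed = 42)
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_mfo_config(cfg, path)
    cfg2 <- read_mfo_config(path)
    expect_equal(cfg2$bounds, cfg$bounds, ignore_attr = TRUE)
    expect_equal(cfg2[setdiff(names(cfg2), "bounds")],
                 cfg[setdiff(names(cfg), "bounds")])
  }
})

test_that("initialization is seeded, in-bounds, and evaluates bests", {
  cfg <- mfo_config(bounds = rbind(c(0, 0), c(1, 1)), n_males = 20,
                    n_females = 20, seed = 7)
  p1 <- mfo_initialize(cfg, sphere)
  p2 <- mfo_initialize(cfg, sphere)
  expect_identical(p1, p2)
  expect_true(all(p1$male_positions >= 0 & p1$male_positions <= 1))
  expect_true(all(p1$female_positions >= 0 & p1$female_positions <= 1))
  expect_true(all(p1$male_velocities == 0))
  direct <- max(c(apply(p1$male_positions, 1, sphere),
                  apply(p1$female_positions, 1, sphere)))
  expect_equal(p1$global_best$value, direct)
  expect_error(mfo_initialize(cfg, function(x) NaN), "non-finite")
})

test_that("mating is a convex crossover of the parents", {
  expect_equal(mfo_mate(c(1, 2), c(3, 4), 1),
               list(child1 = c(1, 2), child2 = c(3, 4)))
  expect_equal(mfo_mate(c(1, 2), c(3, 4), 0),
               list(child1 = c(3, 4), child2 = c(1, 2)))
  expect_equal(mfo_mate(c(0, 0), c(2, 4), 0.5),
               list(child1 = c(1, 2), child2 = c(1, 2)))
  expect_error(mfo_mate(c(1, 2), c(1, 2, 3), 0.5), "dimensions")
  set.seed(1)
  for (i in 1:20) {
    m <- runif(3, -5, 5)
    f <- runif(3, -5, 5)
    P <- runif(1)
    off <- mfo_mate(m, f, P)
    expect_true(all(off$child1 >= pmin(m, f) - 1e-12 &
                    off$child1 <= pmax(m, f) + 1e-12))
    expect_true(all(off$child2 >= pmin(m, f) - 1e-12 &
                    off$child2 <= pmax(m, f) + 1e-12))
  }
})

test_that("a lone best male at the optimum with no dance stays put", {
  cfg <- mfo_config(bounds = rbind(c(0, 0), c(1, 1)), n_males = 1,
                    n_females = 1, dance = 0, seed = 3)
  pop <- mfo_initialize(cfg, sphere)
  pop$male_positions[1, ] <- c(0.3, 0.3)
  pop$male_velocities[1, ] <- 0
  pop$male_fitness[1] <- sphere(c(0.3, 0.3))
  pop$pbest_positions[1, ] <- c(0.3, 0.3)
  pop$pbest_values[1] <- pop$male_fitness[1]
  pop$global_best <- list(position = c(0.3, 0.3), value = 0)
  pop$dance_cur <- 0
  stepped <- mfo_step(pop, cfg, sphere)
  expect_equal(stepped$male_positions[1, ], c(0.3, 0.3))
  expect_equal(stepped$global_best$value, 0)
})

test_that("the global best never degrades and positions respect bounds", {
  cfg <- mfo_config(bounds = rbind(c(-2, -2, -2), c(2, 2, 2)), seed = 11,
                    n_iterations = 30)
  pop <- mfo_initialize(cfg, sphere)
  prev <- pop$global_best$value
  for (i in 1:30) {
    pop <- mfo_step(pop, cfg, sphere)
    expect_gte(pop$global_best$value, prev)
    prev <- pop$global_best$value
    expect_true(all(pop$male_positions >= -2 & pop$male_positions <= 2))
    expect_true(all(pop$female_positions >= -2 & pop$female_positions <= 2))
  }
})

test_that("optimization is deterministic and its trace monotone", {
  cfg <- mfo_config(bounds = rbind(c(-1, -1), c(1, 1)), n_iterations = 40,
                    seed = 5)
  r1 <- mfo_optimize(cfg, sphere)
  r2 <- mfo_optimize(cfg, sphere)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
  expect_equal(length(r1$trace), 40)
  expect_true(all(diff(r1$trace) >= 0))
  expect_equal(r1$best_value, r1$trace[40])

  rc <- mfo_optimize(mfo_config(bounds = c(0, 1), n_iterations = 5, seed = 1),
                     function(x) 4.25)
  expect_equal(rc$trace, rep(4.25, 5))
  expect_equal(rc$best_value, 4.25)
})

test_that("the swarm converges on the 2-D sphere maximization", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- mfo_config(bounds = rbind(c(-5, -5), c(5, 5)), seed = seed)
    r <- mfo_optimize(cfg, function(x) -sum(x^2))
    if (r$best_value > -1e-3) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("threshold decoding yields valid strictly increasing integers", {
  expect_equal(decode_thresholds(c(200.4, 10.6, 99.9)), c(11L, 100L, 200L))
  expect_equal(decode_thresholds(c(50.2, 50.4, 49.8)), c(50L, 51L, 52L))
  expect_equal(decode_thresholds(c(-10, 300)), c(1L, 255L))
  expect_equal(decode_thresholds(c(254.9, 255.2, 255.4)), c(253L, 254L, 255L))
  set.seed(8)
  for (i in 1:50) {
    t <- decode_thresholds(runif(sample(1:4, 1), -20, 280))
    expect_true(all(t >= 1 & t <= 255))
    if (length(t) > 1) expect_true(all(diff(t) > 0))
  }
})

test_that("mayfly search recovers exhaustive Kapur optima on histograms", {
  # bilevel search is exact; trilevel search may rarely miss (the acceptance
  # suite enforces the full 20-seed >= 90% criterion)
  hits3 <- 0
  for (seed in 1:5) {
    h <- random_histogram(seed + 40)
    got2 <- optimize_thresholds(h, 2, seed = seed)
    ex2 <- exhaustive_best_thresholds(h, 2)
    expect_lte(abs(got2$score$value - ex2$score$value), 1e-9)
    ex3 <- exhaustive_best_thresholds(h, 3)
    got3 <- optimize_thresholds(h, 3, seed = seed)
    if (abs(got3$score$value - ex3$score$value) <= 1e-9) hits3 <- hits3 + 1
  }
  expect_gte(hits3, 4)
})
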