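test_that("phantom spec validates its geometry and intensity settings", {
  expect_error(phantom_spec(mode_means = c(100, 130)), "n_tissue_modes")
  expect_error(phantom_spec(tumor_intensity = 300), "255")
  expect_error(phantom_spec(tumor_intensity = 150, contrast_margin = 80),
               "contrast")
  s <- phantom_spec(seed = 1)
  expect_equal(s$image_side, 256L)
  expect_equal(s$mode_means, c(100, 130, 160))
  expect_equal(s$noise_sigma, 4)
  expect_equal(s$contrast_margin, 30)
})

test_that("phantom generation is deterministic and well-ranged", {
  p1 <- generate_phantom(phantom_spec(seed = 17))
  p2 <- generate_phantom(phantom_spec(seed = 17))
  expect_identical(p1, p2)
  expect_equal(dim(p1$image), c(256, 256))
  expect_true(is.integer(p1$image))
  expect_true(all(p1$image >= 0 & p1$image <= 255))
  expect_true(all(p1$tumor_mask %in% c(0L, 1L)))
  p3 <- generate_phantom(phantom_spec(seed = 18))
  expect_false(identical(p1$image, p3$image))
})

test_that("a noise-free phantom has exactly the designed intensity levels", {
  spec <- phantom_spec(seed = 23, noise_sigma = 0)
  p <- generate_phantom(spec)
  vals <- sort(unique(as.vector(p$image)))
  # background 0, three tissue modes, one tumor intensity
  expect_equal(length(vals), spec$n_tissue_modes + 2L)
  expect_true(all(spec$mode_means %in% vals))
  expect_true(0 %in% vals)
  # every tumor pixel carries the spec tumor intensity
  tum <- unique(p$image[p$tumor_mask == 1])
  expect_equal(tum, spec$tumor_intensity)
  expect_true(all(abs(tum - spec$mode_means) >= spec$contrast_margin))
})

test_that("tumor masks are plausibly sized single blobs strictly inside the brain", {
  for (seed in c(3, 8, 51)) {
    spec <- phantom_spec(seed = seed)
    p <- generate_phantom(spec)
    n <- sum(p$tumor_mask)
    expect_gte(n, pi * spec$tumor_radius_range[1]^2 * 0.5)
    expect_lte(n, pi * (2.4 * spec$tumor_radius_range[2])^2)
    lab <- label_components(p$tumor_mask)
    expect_equal(max(lab), 1L)                     # one connected lesion
    expect_true(all(p$image[p$tumor_mask == 1] > 0))
    expect_true(all(p$tumor_mask[p$image == 0] == 0))  # never in background
    # and never on the image border
    expect_true(all(p$tumor_mask[c(1, 256), ] == 0))
    expect_true(all(p$tumor_mask[, c(1, 256)] == 0))
  }
})

test_that("the three lesion classes differ in shape, quadrant and intensity", {
  cls <- list(
    list(shape = "disc", quadrant = "lower-center", intensity = 250,
         label = 0L),
    list(shape = "lobed", quadrant = "upper-left", intensity = 220,
         label = 1L),
    list(shape = "ellipse", quadrant = "upper-right", intensity = 40,
         label = 2L))
  ps <- lapply(seq_along(cls), function(i) {
    generate_phantom(phantom_spec(seed = 100 + i,
                                  tumor_shape = cls[[i]]$shape,
                                  tumor_quadrant = cls[[i]]$quadrant,
                                  tumor_intensity = cls[[i]]$intensity))
  })
  for (i in seq_along(ps)) {
    expect_equal(ps[[i]]$label, cls[[i]]$label)
    m <- mean(ps[[i]]$image[ps[[i]]$tumor_mask == 1])
    expect_lt(abs(m - cls[[i]]$intensity), 3)  # noise-level deviation only
  }
  # quadrant placement: tumor centroid lands in the requested region
  cent <- t(vapply(ps, function(p) {
    colMeans(which(p$tumor_mask == 1, arr.ind = TRUE))
  }, numeric(2)))
  expect_gt(cent[1, 1], 128)   # pituitary-like: lower half
  expect_lt(cent[2, 1], 128)   # glioma-like: upper left
  expect_lt(cent[2, 2], 128)
  expect_lt(cent[3, 1], 128)   # meningioma-like: upper right
  expect_gt(cent[3, 2], 128)
})

test_that("dataset generation is balanced, interleaved, and seeded", {
  d1 <- generate_dataset(5, seed = 99)
  d2 <- generate_dataset(5, seed = 99)
  expect_equal(length(d1), 15)
  labels <- vapply(d1, `[[`, integer(1), "label")
  expect_equal(as.vector(table(labels)), c(5, 5, 5))
  expect_equal(labels[1:3], c(0L, 1L, 2L))
  expect_identical(lapply(d1, `[[`, "image"), lapply(d2, `[[`, "image"))
  d3 <- generate_dataset(5, seed = 100)
  expect_false(identical(d1[[1]]$image, d3[[1]]$image))
  # phantoms within one dataset are mutually distinct
  expect_false(identical(d1[[1]]$image, d1[[4]]$image))
  expect_error(generate_dataset(0, seed = 1), "n_per_class")
})
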