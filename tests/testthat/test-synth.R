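# Synthetic H&E-like image generator: determinism, geometry, style
# separation, splits.

test_that("rendering is bit-identical under a fixed seed", {
  st <- synth_style()
  a <- generate_image(st, 64, 64, 123)
  b <- generate_image(st, 64, 64, 123)
  expect_identical(a$image, b$image)
  expect_identical(a$centers, b$centers)
  c_ <- generate_image(st, 64, 64, 124)
  expect_false(identical(a$image, c_$image))
})

test_that("a zero-count style renders pure background", {
  st <- synth_style(nucleus_count_range = c(0, 0))
  s <- generate_image(st, 64, 64, 5)
  expect_equal(nrow(s$centers), 0)
  expect_equal(dim(s$image), c(64, 64, 3))
})

test_that("non-overlapping placement respects pairwise radii sums", {
  st <- synth_style(nucleus_count_range = c(20, 20), overlap_fraction = 0,
                    radius_range = c(3, 6))
  s <- generate_image(st, 256, 256, 11)
  expect_equal(nrow(s$centers), 20)
  d <- as.matrix(dist(s$centers))
  diag(d) <- Inf
  # radii are not exposed per nucleus; the guaranteed lower bound is twice
  # the minimum radius
  expect_true(all(d[upper.tri(d)] >= 2 * 3))
  expect_true(all(s$centers >= 0 & s$centers <= 255))
})

test_that("nuclei are darker than the background", {
  st <- synth_style()
  for (seed in 1:5) {
    s <- generate_image(st, 64, 64, seed)
    if (nrow(s$centers) == 0) next
    lum <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    at_centers <- lum[round(s$centers) + 1]
    expect_lt(mean(at_centers), mean(lum))
  }
})

test_that("style radius too large for the image is rejected", {
  st <- synth_style(radius_range = c(40, 40))
  expect_error(generate_image(st, 64, 64, 1), "radius")
})

test_that("datasets derive per-sample seeds deterministically", {
  st <- synth_style()
  d1 <- generate_dataset(st, 4, 64, 64, 99)
  d2 <- generate_dataset(st, 4, 64, 64, 99)
  expect_identical(lapply(d1, `[[`, "image"), lapply(d2, `[[`, "image"))
  seeds <- vapply(d1, `[[`, integer(1), "seed")
  expect_equal(length(unique(seeds)), 4)
})

test_that("the half/half + 20% split is disjoint with the stated sizes", {
  d <- generate_dataset(synth_style(), 10, 64, 64, 3)
  sp <- split_dataset(d, 17)
  expect_equal(length(sp$test), 5)
  expect_equal(length(sp$train), 4)
  expect_equal(length(sp$val), 1)
  ids <- function(x) vapply(x, `[[`, integer(1), "seed")
  all_ids <- c(ids(sp$train), ids(sp$val), ids(sp$test))
  expect_equal(length(unique(all_ids)), 10)
})

test_that("styles with different nucleus colors are separable", {
  stA <- synth_style(style_id = "A", nucleus_color = c(90, 60, 140))
  stB <- synth_style(style_id = "B", nucleus_color = c(40, 110, 60),
                     background_color = c(215, 205, 230))
  corpA <- generate_dataset(stA, 25, 64, 64, 1)
  corpB <- generate_dataset(stB, 25, 64, 64, 2)
  feat <- function(s) vapply(1:3, function(ch) mean(s$image[, , ch]),
                             numeric(1))
  fA <- t(vapply(corpA, feat, numeric(3)))
  fB <- t(vapply(corpB, feat, numeric(3)))
  muA <- colMeans(fA[1:10, ]); muB <- colMeans(fB[1:10, ])
  classify <- function(f)
    if (sum((f - muA)^2) < sum((f - muB)^2)) "A" else "B"
  preds <- c(apply(fA[11:25, ], 1, classify), apply(fB[11:25, ], 1, classify))
  truth <- rep(c("A", "B"), each = 15)
  expect_gt(mean(preds == truth), 0.9)
})

test_that("multi-style corpora group correctly and reject duplicates", {
  sts <- list(synth_style(style_id = "a"), synth_style(style_id = "b"),
              synth_style(style_id = "c"))
  corp <- generate_multistyle_corpus(sts, 4, 64, 64, 5)
  expect_equal(names(corp), c("a", "b", "c"))
  expect_equal(vapply(corp, length, integer(1)), c(a = 4L, b = 4L, c = 4L))
  corp2 <- generate_multistyle_corpus(sts, 4, 64, 64, 5)
  expect_identical(corp, corp2)
  expect_error(
    generate_multistyle_corpus(list(synth_style(style_id = "a"),
                                    synth_style(style_id = "a")),
                               2, 64, 64, 1),
    "duplicate")
  expect_error(generate_multistyle_corpus(sts[1], 2, 64, 64, 1))
})

test_that("centers always lie inside the image", {
  st <- synth_style(overlap_fraction = 0.5)
  for (seed in 1:8) {
    s <- generate_image(st, 64, 96, seed)
    if (nrow(s$centers) == 0) next
    expect_true(all(s$centers[, 1] >= 0 & s$centers[, 1] <= 63))
    expect_true(all(s$centers[, 2] >= 0 & s$centers[, 2] <= 95))
  }
})
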