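# Patch pipeline (crop / normalize / augment), optimizer contracts,
# freezing during fine-tuning, determinism.

test_that("crops are aligned with the gold map and reproducible", {
  s <- generate_image(synth_style(), 96, 96, 21)
  cfg <- desk_config(patch_size = 64, patches_per_image = 4, seed = 1)
  enc <- proximity_params()
  full <- proximity_map(s$centers, 96, 96, enc)
  set.seed(5)
  ps <- crop_patches(s, cfg, enc, map = full)
  expect_length(ps, 4)
  for (p in ps) {
    expect_equal(dim(p$image), c(64, 64, 3))
    expect_equal(dim(p$label), c(64, 64))
    expect_equal(p$ybar, mean(full$values))
    # locate the crop by matching the label against the full map
    found <- FALSE
    for (r0 in 1:33) for (c0 in 1:33) {
      if (identical(full$values[r0:(r0 + 63), c0:(c0 + 63)], p$label)) {
        expect_equal(s$image[r0:(r0 + 63), c0:(c0 + 63), ], p$image)
        found <- TRUE; break
      }
      if (found) break
    }
    expect_true(found)
  }
  set.seed(5)
  ps2 <- crop_patches(s, cfg, enc, map = full)
  expect_identical(ps, ps2)
})

test_that("patch-size-equal-to-image crops are the identity", {
  s <- generate_image(synth_style(), 64, 64, 3)
  cfg <- desk_config(patch_size = 64, patches_per_image = 1)
  p <- crop_patches(s, cfg)[[1]]
  expect_equal(p$image, s$image)
  expect_equal(p$label, proximity_map(s$centers, 64, 64)$values)
})

test_that("normalization gives zero mean / unit sd and affine invariance", {
  set.seed(2)
  x <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  n <- normalize_patch(x)
  for (ch in 1:3) {
    expect_equal(mean(n[, , ch]), 0, tolerance = 1e-12)
    expect_equal(sd(n[, , ch]), 1, tolerance = 1e-12)
  }
  expect_equal(normalize_patch(3.7 * x + 12), n, tolerance = 1e-9)
  const <- array(42, c(8, 8, 3))
  expect_true(all(normalize_patch(const) == 0))
})

test_that("augmentation applies one transform to both pair members", {
  s <- generate_image(synth_style(), 64, 64, 9)
  lab <- proximity_map(s$centers, 64, 64)$values
  img <- s$image
  # mark the label argmax in the image so co-movement is observable
  am <- which(lab == max(lab), arr.ind = TRUE)[1, ]
  img[am[1], am[2], ] <- c(-1000, -1000, -1000)
  for (seed in 1:10) {
    a <- augment(img, lab, seed = seed, shift_max = 5)
    am2_img <- which(a$image[, , 1] == -1000, arr.ind = TRUE)
    am2_lab <- which(a$label == max(a$label), arr.ind = TRUE)
    expect_equal(unname(am2_img[1, ]), unname(am2_lab[1, ]))
  }
  # identity draw: no shift, no elastic, dihedral element may still act;
  # check zero elastic magnitude leaves values intact under k=0 draws
  reps <- replicate(20, {
    a <- augment(img, lab, shift_max = 0, elastic_magnitude = 0)
    identical(dim(a$image), dim(img))
  })
  expect_true(all(reps))
})

test_that("an explicit identity transform leaves the pair unchanged", {
  s <- generate_image(synth_style(), 48, 48, 2)
  lab <- proximity_map(s$centers, 48, 48)$values
  # find a seed whose dihedral draw is the identity
  for (seed in 1:50) {
    set.seed(seed)
    k <- sample(0:3, 1); flip <- runif(1) < 0.5
    if (k == 0 && !flip) {
      a <- augment(s$image, lab, seed = seed, shift_max = 0,
                   elastic_magnitude = 0)
      expect_equal(a$image, s$image)
      expect_equal(a$label, lab)
      break
    }
  }
})

test_that("elastic distortion is smooth and zero magnitude is exact", {
  s <- generate_image(synth_style(), 64, 64, 30)
  lab <- proximity_map(s$centers, 64, 64)$values
  a0 <- augment(s$image, lab, seed = 3, shift_max = 0,
                elastic_magnitude = 0)
  a1 <- augment(s$image, lab, seed = 3, shift_max = 0,
                elastic_magnitude = 4)
  expect_equal(dim(a1$label), dim(lab))
  expect_false(identical(a0$label, a1$label))
})

test_that("a lambda=0 all-background batch produces exactly zero gradients", {
  net <- tiny_net()
  set.seed(11)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  gold <- array(0, c(32, 32, 2))
  fw <- net_forward(net, x, train = TRUE)
  lp0 <- loss_params(lam = 0)
  gout <- array(0, c(32, 32, 2))
  for (n in 1:2) gout[, , n] <-
    proxidet:::weighted_mse_grad(fw$out[, , n], gold[, , n], lp0, ybar = 0)
  grads <- net_backward(net, fw, gout)
  for (nm in names(grads)) expect_true(all(grads[[nm]] == 0))
  # with lambda = 5 and a positive image-level ybar the gradient is live
  lp5 <- loss_params(lam = 5)
  for (n in 1:2) gout[, , n] <-
    proxidet:::weighted_mse_grad(fw$out[, , n], gold[, , n], lp5, ybar = 0.2)
  grads5 <- net_backward(net, fw, gout)
  expect_gt(max(abs(grads5[["out.conv2.w"]])), 0)
})

test_that("short training runs are reproducible and reduce the loss", {
  sp <- with(list(), {
    corpus <- generate_dataset(micro_style(), 14, 32, 32, 44)
    list(train = corpus[1:10], val = corpus[11:14])
  })
  cfg <- desk_config(patch_size = 32, max_iterations = 40, eval_every = 20,
                     seed = 9)
  run <- function() {
    set.seed(1)
    net <- build_network(tiny_spec())
    train(net, data_source(sp$train), sp$val, cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$params, f2$network$params)
  expect_lt(mean(tail(f1$history$loss, 5)), f1$history$loss[1])
})

test_that("fine-tuning honors frozen blocks bit-for-bit", {
  corpus <- generate_dataset(micro_style(), 8, 32, 32, 55)
  cfg <- desk_config(patch_size = 32, max_iterations = 8, eval_every = 8,
                     seed = 2)
  set.seed(3)
  base <- build_network(tiny_spec())
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(base, ck)
  ft <- fine_tune(ck, data_source(corpus[1:6]), corpus[7:8], cfg,
                  frozen_blocks = 2)
  frozen_names <- names(base$params)[base$pblock <= 2]
  live_names <- setdiff(names(base$params), frozen_names)
  for (nm in frozen_names)
    expect_identical(ft$network$params[[nm]], base$params[[nm]])
  changed <- vapply(live_names, function(nm)
    !identical(ft$network$params[[nm]], base$params[[nm]]), logical(1))
  expect_true(any(changed))
  # frozen batch-norm running moments are held fixed too
  for (nm in names(base$running))
    if (base$pblock[[paste0(nm, ".g")]] <= 2)
      expect_identical(ft$network$running[[nm]], base$running[[nm]])
  # spec mismatch is rejected
  expect_error(fine_tune(ck, data_source(corpus[1:6]), corpus[7:8], cfg,
                         spec = tiny_spec(base_width = 8)),
               "spec")
  # frozen_blocks = 0 updates everything trainable
  ft0 <- fine_tune(ck, data_source(corpus[1:6]), corpus[7:8], cfg,
                   frozen_blocks = 0)
  w_changed <- vapply(names(base$params), function(nm)
    !identical(ft0$network$params[[nm]], base$params[[nm]]), logical(1))
  expect_true(mean(w_changed[grepl("\\.w$", names(base$params))]) > 0.9)
})

test_that("auxiliary subsampling selects round(f*N) samples under seed", {
  corpus <- generate_dataset(micro_style(), 20, 32, 32, 66)
  src <- data_source(corpus, "auxiliary", fraction = 0.3)
  s1 <- proxidet:::subsample_source(src, 5)
  s2 <- proxidet:::subsample_source(src, 5)
  expect_length(s1, 6)
  expect_identical(s1, s2)
  s3 <- proxidet:::subsample_source(src, 6)
  expect_false(identical(
    vapply(s1, `[[`, integer(1), "seed"),
    vapply(s3, `[[`, integer(1), "seed")))
  expect_length(proxidet:::subsample_source(
    data_source(corpus, fraction = 1), 5), 20)
})
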