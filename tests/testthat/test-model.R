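# Architecture contracts: pixel-to-pixel sizes (including the odd-size
# floor/pad path), determinism, freezing, parameter counting.

test_that("output spatial size equals input size, odd sizes included", {
  set.seed(1)
  net <- build_network(network_spec(base_width = 4, depth = 4,
                                    dropout_rate = 0, min_input = 32))
  for (hw in list(c(33, 33), c(64, 64), c(75, 75), c(101, 101),
                  c(75, 101))) {
    x <- array(rnorm(hw[1] * hw[2] * 3), c(hw[1], hw[2], 3, 1))
    out <- net_forward(net, x, train = FALSE)$out
    expect_equal(dim(out), c(hw[1], hw[2], 1))
    expect_true(all(is.finite(out)))
  }
})

test_that("repeated evaluation-mode passes are identical", {
  net <- tiny_net()
  set.seed(2)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  o1 <- net_forward(net, x, train = FALSE)$out
  o2 <- net_forward(net, x, train = FALSE)$out
  expect_identical(o1, o2)
})

test_that("specs that downsample below 1 px are rejected at build", {
  expect_error(build_network(network_spec(base_width = 4, depth = 4,
                                          min_input = 8)),
               "non-positive")
  expect_error(network_spec(base_width = 2))
  expect_error(network_spec(depth = 1))
})

test_that("channel doubling shows up in the parameter count", {
  set.seed(3)
  n8 <- build_network(network_spec(base_width = 8, min_input = 32))
  n16 <- build_network(network_spec(base_width = 16, min_input = 32))
  # a mid-depth convolution quadruples exactly when the width doubles
  expect_equal(length(n16$params[["d2.conv2.w"]]),
               4 * length(n8$params[["d2.conv2.w"]]))
  r <- count_parameters(n16) / count_parameters(n8)
  expect_gt(r, 3); expect_lt(r, 4.5)
  # same spec twice gives the same count
  set.seed(4)
  n8b <- build_network(network_spec(base_width = 8, min_input = 32))
  expect_equal(count_parameters(n8b), count_parameters(n8))
})

test_that("freezing excludes leading blocks from counting and updates", {
  net <- tiny_net()
  expect_equal(count_parameters(freeze_blocks(net, 0), trainable_only = TRUE),
               count_parameters(net))
  nb <- n_blocks(net)
  expect_equal(nb, 2 * 2 + 2)
  counts <- vapply(0:nb, function(k)
    count_parameters(freeze_blocks(net, k), trainable_only = TRUE),
    numeric(1))
  expect_true(all(diff(counts) < 0))
  expect_equal(counts[nb + 1], 0)
  expect_error(freeze_blocks(net, nb + 1), "0\\.\\.")
  expect_error(freeze_blocks(net, -1))
})

test_that("gradients reach every non-frozen weight on a real batch", {
  net <- tiny_net()
  set.seed(5)
  x <- array(rnorm(24 * 24 * 3 * 2), c(24, 24, 3, 2))
  gold <- array(runif(24 * 24 * 2), c(24, 24, 2))
  fw <- net_forward(net, x, train = TRUE)
  gout <- array(0, c(24, 24, 2))
  for (n in 1:2) gout[, , n] <-
    proxidet:::weighted_mse_grad(fw$out[, , n], gold[, , n], loss_params())
  grads <- net_backward(net, fw, gout)
  # conv biases are provably cancelled by the following batch norm, so the
  # flow check covers weights and batch-norm parameters
  for (nm in names(grads)) {
    if (grepl("\\.w$", nm) || grepl("\\.(g)$", nm) || nm == "out.conv2.b")
      expect_gt(max(abs(grads[[nm]])), 0)
  }
})

test_that("the sigmoid head bounds outputs by the scale", {
  set.seed(6)
  net <- build_network(tiny_spec(sigmoid_head = TRUE, output_scale = 5))
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  out <- net_forward(net, x, train = FALSE)$out
  expect_true(all(out > 0 & out < 5))
})
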