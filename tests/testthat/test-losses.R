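# Weighted MSE, its closed-form last-layer gradient under the sigmoid
# head, and the target/auxiliary combination.

test_that("weighted MSE matches a hand-computed elementwise oracle", {
  gold <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  pred <- matrix(c(0.5, 0.1, 0, 0), 2, 2, byrow = TRUE)
  lp <- loss_params(lam = 5)
  # ybar = 0.25, weights {2.25, 1.25, ...}: ((2.25*.25 + 1.25*.01)/2)/4
  expect_equal(weighted_mse(pred, gold, lp), 0.071875)
  lp_unnorm <- loss_params(lam = 5, normalize_by_pixels = FALSE)
  expect_equal(weighted_mse(pred, gold, lp_unnorm), 0.2875)
})

test_that("zero residuals or all-zero gold give exactly zero loss", {
  set.seed(1)
  g <- matrix(runif(64) * 5, 8, 8)
  expect_equal(weighted_mse(g, g, loss_params()), 0)
  z <- matrix(0, 8, 8)
  p <- matrix(rnorm(64), 8, 8)
  # the trivial-solution pathology: with ybar = 0 every weight vanishes
  expect_equal(weighted_mse(p, z, loss_params(lam = 5)), 0)
  expect_equal(weighted_mse(p, z, loss_params(lam = 0)), 0)
  # but a positive image-level ybar keeps background crops penalized
  expect_gt(weighted_mse(p, z, loss_params(lam = 5), ybar = 0.1), 0)
})

test_that("loss is non-negative and zero only where weights allow", {
  set.seed(2)
  for (i in 1:10) {
    g <- matrix(pmax(rnorm(36), 0), 6, 6)
    o <- g + matrix(rnorm(36, sd = 0.1), 6, 6)
    expect_gte(weighted_mse(o, g, loss_params(lam = runif(1, 0, 10))), 0)
  }
})

test_that("background errors are penalized more as lambda grows", {
  g <- matrix(0, 10, 10); g[5, 5] <- 5       # sparse gold
  o <- matrix(0.3, 10, 10)                   # uniform wrong prediction
  lams <- c(0, 0.5, 5, 50)
  losses <- vapply(lams, function(l)
    weighted_mse(o, g, loss_params(lam = l)), numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("closed-form sigmoid-head gradient matches finite differences", {
  set.seed(5)
  lp <- loss_params(lam = 5)
  for (trial in 1:5) {
    z <- matrix(rnorm(64), 8, 8)
    g <- matrix(pmax(rnorm(64, 0.3, 0.4), 0), 8, 8)
    o <- plogis(z)
    an <- last_layer_gradient(o, g, lp, z)
    eps <- 1e-6
    for (idx in sample(64, 6)) {
      zp <- z; zp[idx] <- z[idx] + eps
      zm <- z; zm[idx] <- z[idx] - eps
      fd <- (weighted_mse(plogis(zp), g, lp) -
               weighted_mse(plogis(zm), g, lp)) / (2 * eps)
      expect_equal(an[idx], fd, tolerance = 1e-5)
    }
  }
  # zero residual and all-zero gold both give a zero gradient
  z <- matrix(rnorm(16), 4, 4)
  expect_equal(last_layer_gradient(plogis(z), plogis(z), lp, z),
               matrix(0, 4, 4))
  expect_equal(last_layer_gradient(plogis(z), matrix(0, 4, 4), lp, z),
               matrix(0, 4, 4))
})

test_that("combined loss is the gamma-weighted sum", {
  expect_equal(combined_loss(0.2, 0.3, loss_params(gamma = 1)), 0.5)
  expect_equal(combined_loss(0.2, 0.3, loss_params(gamma = 5)), 1.3)
  expect_equal(combined_loss(0.7, 0, loss_params(gamma = 3)), 2.1)
  # linear in each argument
  lp <- loss_params(gamma = 2.5)
  expect_equal(combined_loss(2 * 0.2, 0.3, lp) - combined_loss(0, 0.3, lp),
               2 * (combined_loss(0.2, 0.3, lp) - combined_loss(0, 0.3, lp)))
  expect_error(combined_loss(-0.1, 0.3, lp))
  expect_error(combined_loss(Inf, 0.3, lp))
})

test_that("shape mismatches are rejected", {
  expect_error(weighted_mse(matrix(0, 2, 3), matrix(0, 3, 2)), "shape")
  expect_error(last_layer_gradient(matrix(0, 2, 2), matrix(0, 2, 2),
                                   loss_params(), matrix(0, 3, 3)),
               "shape")
})
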