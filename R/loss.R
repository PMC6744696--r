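#' Loss parameters for proximity regression
#'
#' @param lam region-weight control (>= 0). Each pixel's squared residual
#'   is weighted by `y + lam * ybar`, where `y` is the gold value and
#'   `ybar` the mean gold value of the source image. With `lam = 0` the
#'   background (gold 0) carries no weight, which admits the all-zero
#'   trivial solution; positive `lam` penalizes it.
#' @param gamma balance weight between target and auxiliary data sources
#'   (> 0); 1 corresponds to naive pooling.
#' @param normalize_by_pixels divide the per-image loss by the number of
#'   pixels (default TRUE, as used for training).
#' @return an object of class `loss_params`.
#' @export
loss_params <- function(lam = 5, gamma = 1, normalize_by_pixels = TRUE) {
  stopifnot(is.numeric(lam), length(lam) == 1, is.finite(lam), lam >= 0,
            is.numeric(gamma), length(gamma) == 1, is.finite(gamma), gamma > 0,
            is.logical(normalize_by_pixels), length(normalize_by_pixels) == 1)
  structure(list(lam = lam, gamma = gamma,
                 normalize_by_pixels = normalize_by_pixels),
            class = "loss_params")
}

# Per-pixel weights y + lam * ybar. ybar defaults to the mean of the gold
# map itself; training passes the mean of the full source image's map so
# that all-background crops of annotated images still carry weight.
loss_weights <- function(gold, params, ybar = NULL) {
  if (is.null(ybar)) ybar <- mean(gold)
  gold + params$lam * ybar
}

#' Weighted mean squared error between predicted and gold proximity maps
#'
#' Computes `(1/2) * sum((y + lam*ybar) * (o - y)^2)`, optionally divided
#' by the pixel count. The weight vanishes on background pixels when
#' `lam = 0`, so errors there are not penalized; `lam > 0` adds a uniform
#' penalty proportional to the image's mean gold value, which suppresses
#' the all-zero trivial solution on sparse maps.
#'
#' @param prediction,gold numeric matrices of equal size (or
#'   `proximity_map` objects).
#' @param params a [loss_params()] object.
#' @param ybar optional override for the mean gold value (used when `gold`
#'   is a crop of a larger annotated image).
#' @return scalar loss.
#' @export
weighted_mse <- function(prediction, gold, params = loss_params(), ybar = NULL) {
  o <- map_values(prediction); y <- map_values(gold)
  if (!all(dim(o) == dim(y))) stop("prediction and gold shapes differ")
  w <- loss_weights(y, params, ybar)
  l <- 0.5 * sum(w * (o - y)^2)
  if (params$normalize_by_pixels) l <- l / length(y)
  l
}

# Gradient of weighted_mse with respect to the prediction.
weighted_mse_grad <- function(prediction, gold, params = loss_params(),
                              ybar = NULL) {
  o <- map_values(prediction); y <- map_values(gold)
  if (!all(dim(o) == dim(y))) stop("prediction and gold shapes differ")
  g <- loss_weights(y, params, ybar) * (o - y)
  if (params$normalize_by_pixels) g <- g / length(y)
  g
}

#' Analytic last-layer gradient for the sigmoid-head configuration
#'
#' For a network whose last layer applies a sigmoid to the pre-activation
#' `z` (so the prediction is `o = sigmoid(z)`), the derivative of the
#' weighted MSE with respect to `z` is
#' `(y + lam*ybar) * (o - y) * a * (1 - a)` with `a = sigmoid(z)`.
#' This closed form serves as an oracle against the backpropagated
#' gradient.
#'
#' @param prediction predicted map `o` (sigmoid output).
#' @param gold gold proximity map.
#' @param params a [loss_params()] object.
#' @param preactivation matrix `z` of last-layer inputs, same size.
#' @param ybar optional mean-gold override (see [weighted_mse()]).
#' @return matrix of per-pixel derivatives.
#' @export
last_layer_gradient <- function(prediction, gold, params = loss_params(),
                                preactivation, ybar = NULL) {
  o <- map_values(prediction); y <- map_values(gold)
  z <- map_values(preactivation)
  if (!all(dim(o) == dim(y)) || !all(dim(z) == dim(y)))
    stop("shape mismatch")
  a <- plogis(z)
  g <- loss_weights(y, params, ybar) * (o - y) * a * (1 - a)
  if (params$normalize_by_pixels) g <- g / length(y)
  g
}

#' Combine target and auxiliary losses
#'
#' Returns `gamma * target_loss + auxiliary_loss`. With `gamma = 1` this is
#' naive pooling of the two sources; large `gamma` asymptotically ignores
#' the auxiliary source.
#'
#' @param target_loss,auxiliary_loss finite non-negative scalars.
#' @param params a [loss_params()] object supplying `gamma`.
#' @return scalar combined loss.
#' @export
combined_loss <- function(target_loss, auxiliary_loss, params = loss_params()) {
  stopifnot(is.finite(target_loss), is.finite(auxiliary_loss),
            target_loss >= 0, auxiliary_loss >= 0)
  params$gamma * target_loss + auxiliary_loss
}

#' @importFrom stats plogis
NULL
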