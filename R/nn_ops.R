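# Primitive differentiable operations on (H, W, C, N) arrays.
# Convolutions delegate to src/conv_ops.cpp (im2col + GEMM); batch norm,
# ELU, dropout and shape ops are plain R. Padding convention: `pt`/`pl`
# zeros on top/left only; the output size is chosen by the caller and
# out-of-range taps on the bottom/right read zero implicitly.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

conv_out_size <- function(H, k, stride, pt) {
  # largest Ho with (Ho-1)*stride + k - pt <= max(H, needed); we fix the
  # three configurations used by the network explicitly for clarity
  if (stride == 1L) H else (H %/% 2L)
}

op_conv_f <- function(x, w, b, k, stride, pt, pl) {
  d <- dim(x)
  Ho <- if (stride == 1L) d[1] else d[1] %/% 2L
  Wo <- if (stride == 1L) d[2] else d[2] %/% 2L
  if (k == 1L && stride == 2L) {
    # offset-1 subsampling projection: operates on x cropped by the caller
    Ho <- (d[1] - 1L) %/% 2L + 1L
    Wo <- (d[2] - 1L) %/% 2L + 1L
  }
  conv_fwd_cpp(x, w, b, k, stride, pt, pl, Ho, Wo)
}

op_conv_b <- function(x, w, gy, k, stride, pt, pl) {
  conv_bwd_cpp(x, w, gy, k, stride, pt, pl)
}

op_tconv_f <- function(x, w, b, s) tconv_fwd_cpp(x, w, b, s)
op_tconv_b <- function(x, w, gy, s) tconv_bwd_cpp(x, w, gy, s)

# Batch normalization over (H, W, N) per channel.
# Returns y plus the cache needed for the backward pass; in train mode also
# the updated running moments (biased variance).
op_bn_f <- function(x, gamma, beta, run, train) {
  if (train) {
    s <- bn_stats_cpp(x)
    m <- s$mean; v <- s$var
    run <- list(m = (1 - BN_MOMENTUM) * run$m + BN_MOMENTUM * m,
                v = (1 - BN_MOMENTUM) * run$v + BN_MOMENTUM * v)
  } else {
    m <- run$m; v <- run$v
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  r <- bn_fwd_cpp(x, gamma, beta, m, invstd)
  list(y = r$y, run = run,
       cache = list(xhat = r$xhat, invstd = invstd, train = train))
}

op_bn_b <- function(cache, gamma, gy) {
  r <- bn_bwd_cpp(cache$xhat, gamma, cache$invstd, gy, cache$train)
  list(gx = r$gx, ggamma = r$ggamma, gbeta = r$gbeta)
}

op_elu_f <- function(x, alpha) elu_fwd_cpp(x, alpha)

op_elu_b <- function(y, alpha, gy) elu_bwd_cpp(y, alpha, gy)

op_dropout_mask <- function(n, rate) {
  (runif(n) >= rate) / (1 - rate)
}

op_pad_br_f <- function(x, Ht, Wt) {
  d <- dim(x)
  if (d[1] == Ht && d[2] == Wt) return(x)
  out <- array(0, c(Ht, Wt, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  out
}

op_pad_br_b <- function(gy, H, W) {
  d <- dim(gy)
  if (d[1] == H && d[2] == W) return(gy)
  gy[seq_len(H), seq_len(W), , , drop = FALSE]
}

op_crop_offset_f <- function(x) {
  # drop the first row and column (aligns the 1x1 stride-2 shortcut
  # projection with the floor(H/2) size rule of the strided 3x3 conv)
  d <- dim(x)
  x[2:d[1], 2:d[2], , , drop = FALSE]
}

op_crop_offset_b <- function(gy, H, W) {
  d <- dim(gy)
  out <- array(0, c(H, W, d[3], d[4]))
  out[2:H, 2:W, , ] <- gy
  out
}

op_concat_f <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

op_concat_b <- function(gy, C1) {
  d <- dim(gy)
  list(ga = gy[, , seq_len(C1), , drop = FALSE],
       gb = gy[, , (C1 + 1):d[3], , drop = FALSE])
}
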