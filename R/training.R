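# Patch sampling, normalization, augmentation and the SGD training loop
# with validation-driven learning-rate decay, fine-tuning with block
# freezing and mixed target/auxiliary training.

#' Training configuration
#'
#' Defaults follow the reference training recipe (SGD with Nesterov
#' momentum, learning rate 0.01 decayed by 10 on validation plateaus of
#' `patience` iterations down to a floor of 1e-4, weight decay 1e-6,
#' batches of 4 images with four 200x200 patches each). [desk_config()]
#' provides a small-scale profile for CPU experiments.
#'
#' @param lr initial learning rate.
#' @param momentum Nesterov momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param batch_size images per iteration.
#' @param max_iterations training iterations.
#' @param lr_decay_factor divide `lr` by this on a validation plateau.
#' @param patience iterations without validation improvement before decay.
#' @param lr_floor do not decay below this learning rate.
#' @param patch_size square patch side in pixels.
#' @param patches_per_image patches cropped per sampled image (fresh each
#'   iteration).
#' @param snapshot_every keep a parameter snapshot every so many
#'   iterations (the last snapshot is retained on divergence).
#' @param eval_every evaluate validation F1 every so many iterations.
#' @param xi_grid thresholds scanned when selecting the validation xi.
#' @param radius gold-region radius for validation matching.
#' @param min_distance local-maxima neighborhood for detection.
#' @param shift_max maximum augmentation shift in pixels.
#' @param elastic_magnitude elastic-distortion displacement magnitude in
#'   pixels (0 disables).
#' @param elastic_spacing control-point spacing of the elastic field.
#' @param aux_batch_fraction fraction of each batch drawn from the
#'   auxiliary source when one is present.
#' @param seed master seed for sampling, augmentation, dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 1e-6,
                         batch_size = 4, max_iterations = 1e5,
                         lr_decay_factor = 10, patience = 1e4,
                         lr_floor = 1e-4, patch_size = 200,
                         patches_per_image = 4, snapshot_every = 2000,
                         eval_every = 1000,
                         xi_grid = seq(0.1, 0.9, by = 0.1),
                         radius = 16, min_distance = 6,
                         shift_max = 8, elastic_magnitude = 0,
                         elastic_spacing = 32,
                         aux_batch_fraction = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(lr > 0, momentum >= 0, momentum < 1, weight_decay >= 0,
            batch_size >= 1, max_iterations >= 1, lr_decay_factor > 1,
            patience >= 1, lr_floor > 0, patch_size >= 8,
            patches_per_image >= 1, aux_batch_fraction > 0,
            aux_batch_fraction < 1)
  structure(cfg, class = "train_config")
}

#' Desk-scale training profile
#'
#' Small configuration for single-CPU experiments on 64x64 synthetic
#' images: whole-image "patches", short schedule, frequent validation.
#' Arguments override the profile.
#'
#' @param ... overrides passed to [train_config()].
#' @return a `train_config`.
#' @export
desk_config <- function(...) {
  defaults <- list(patch_size = 64, patches_per_image = 1,
                   max_iterations = 1200, eval_every = 200,
                   snapshot_every = 400, patience = 600,
                   shift_max = 4)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

#' Declare a training data source
#'
#' @param samples list of annotated samples (`synth_sample` or lists with
#'   `image` and `centers`).
#' @param role "target" or "auxiliary".
#' @param fraction subsampling fraction in (0, 1]; `round(fraction * N)`
#'   samples are selected deterministically under the training seed.
#' @return object of class `data_source`.
#' @export
data_source <- function(samples, role = c("target", "auxiliary"),
                        fraction = 1) {
  role <- match.arg(role)
  stopifnot(length(samples) >= 1, fraction > 0, fraction <= 1)
  structure(list(samples = samples, role = role, fraction = fraction),
            class = "data_source")
}

#' Crop aligned image / proximity-map patches
#'
#' Crops `patches_per_image` random square patches from an annotated image
#' together with the matching crop of its gold proximity map. Images
#' smaller than the patch size are reflect-padded first (the map is padded
#' identically). Each returned pair carries `ybar`, the mean of the *full*
#' image's gold map, which the weighted loss uses so that all-background
#' crops of annotated images still contribute.
#'
#' @param sample a `synth_sample` or list with `image` and `centers`.
#' @param config a [train_config()].
#' @param encoding a [proximity_params()] used to build the gold map.
#' @param map optional precomputed gold map for the full image.
#' @return list of pairs: each `list(image, label, ybar)`.
#' @export
crop_patches <- function(sample, config, encoding = proximity_params(),
                         map = NULL) {
  img <- sample$image
  H <- dim(img)[1]; W <- dim(img)[2]
  if (is.null(map))
    map <- proximity_map(sample$centers, H, W, encoding)
  mv <- map_values(map)
  ybar <- mean(mv)
  ps <- config$patch_size
  if (H < ps || W < ps) {
    img <- reflect_pad(img, max(H, ps), max(W, ps))
    mvp <- array(mv, c(H, W, 1))
    mv <- reflect_pad(mvp, max(H, ps), max(W, ps))[, , 1]
    H <- dim(img)[1]; W <- dim(img)[2]
  }
  lapply(seq_len(config$patches_per_image), function(i) {
    r0 <- if (H > ps) sample.int(H - ps + 1L, 1L) else 1L
    c0 <- if (W > ps) sample.int(W - ps + 1L, 1L) else 1L
    list(image = img[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L), , drop = FALSE],
         label = mv[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)],
         ybar = ybar)
  })
}

#' Standardize an image patch per channel
#'
#' Subtracts the per-channel mean and divides by the per-channel standard
#' deviation computed on the patch itself; constant channels map to zero
#' (epsilon guard).
#'
#' @param patch `H x W x 3` numeric array.
#' @return standardized array of the same shape.
#' @export
normalize_patch <- function(patch) {
  stopifnot(length(dim(patch)) == 3)
  out <- array(0, dim(patch))
  for (ch in seq_len(dim(patch)[3])) {
    v <- patch[, , ch]
    out[, , ch] <- (v - mean(v)) / max(sd(v), 1e-8)
  }
  out
}

rot90m <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

apply_dihedral <- function(x, k, flip) {
  f <- function(m) {
    if (flip) m <- m[, ncol(m):1, drop = FALSE]
    rot90m(m, k)
  }
  if (length(dim(x)) == 2) return(f(x))
  out <- NULL
  for (ch in seq_len(dim(x)[3])) {
    r <- f(x[, , ch])
    if (is.null(out)) out <- array(0, c(dim(r), dim(x)[3]))
    out[, , ch] <- r
  }
  out
}

shift_reflect <- function(x, dr, dc) {
  d2 <- length(dim(x)) == 2
  if (d2) dim(x) <- c(dim(x), 1)
  H <- dim(x)[1]; W <- dim(x)[2]
  ri <- abs(seq_len(H) - dr - 1) %% (2 * H - 2) + 1
  ri[ri > H] <- 2 * H - ri[ri > H]
  ci <- abs(seq_len(W) - dc - 1) %% (2 * W - 2) + 1
  ci[ci > W] <- 2 * W - ci[ci > W]
  out <- x[ri, ci, , drop = FALSE]
  if (d2) dim(out) <- dim(out)[1:2]
  out
}

bilinear_sample <- function(m, rr, cc) {
  H <- nrow(m); W <- ncol(m)
  rr <- pmin(pmax(rr, 1), H); cc <- pmin(pmax(cc, 1), W)
  r0 <- pmin(floor(rr), H - 1); c0 <- pmin(floor(cc), W - 1)
  fr <- rr - r0; fc <- cc - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Jointly augment an image patch and its label patch
#'
#' Applies the same geometric transform to both members of an aligned
#' image / proximity-map pair: a random element of the 8-fold dihedral
#' group (right-angle rotations and mirroring), an integer shift with
#' reflect padding, and optionally a smooth elastic distortion (a random
#' displacement field on a coarse control grid, bilinearly upsampled and
#' applied identically to both members). Zero shift and zero elastic
#' magnitude with the identity dihedral draw leave the pair unchanged.
#'
#' @param image `H x W x C` array.
#' @param label `H x W` matrix.
#' @param seed optional seed for the transform draw (uses the current RNG
#'   stream when NULL).
#' @param shift_max maximum absolute shift in pixels.
#' @param elastic_magnitude elastic displacement magnitude in pixels.
#' @param elastic_spacing control-point spacing in pixels.
#' @return list with transformed `image` and `label`.
#' @export
augment <- function(image, label, seed = NULL, shift_max = 0,
                    elastic_magnitude = 0, elastic_spacing = 32) {
  run <- function() {
    k <- sample(0:3, 1)
    flip <- runif(1) < 0.5
    image <- apply_dihedral(image, k, flip)
    label <- apply_dihedral(label, k, flip)
    if (shift_max > 0) {
      dr <- sample(-shift_max:shift_max, 1)
      dc <- sample(-shift_max:shift_max, 1)
      image <- shift_reflect(image, dr, dc)
      label <- shift_reflect(label, dr, dc)
    }
    if (elastic_magnitude > 0) {
      H <- dim(label)[1]; W <- dim(label)[2]
      cells <- max(2L, ceiling(max(H, W) / elastic_spacing))
      dr <- low_freq_field(H, W, cells) * elastic_magnitude
      dc <- low_freq_field(H, W, cells) * elastic_magnitude
      rr <- c(row(label) + dr); cc <- c(col(label) + dc)
      for (ch in seq_len(dim(image)[3]))
        image[, , ch] <- bilinear_sample(image[, , ch], rr, cc)
      label[] <- bilinear_sample(label, rr, cc)
    }
    list(image = image, label = label)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# --- optimizer -------------------------------------------------------------

sgd_init <- function(net) lapply(net$params, function(p) p * 0)

# SGD with Nesterov momentum and decoupled-from-frozen weight decay
sgd_step <- function(net, grads, vel, lr, momentum, weight_decay) {
  frozen <- net$frozen
  for (nm in names(net$params)) {
    if (net$pblock[[nm]] <= frozen) next
    g <- grads[[nm]] + weight_decay * net$params[[nm]]
    vel[[nm]] <- momentum * vel[[nm]] + g
    net$params[[nm]] <- net$params[[nm]] -
      lr * (g + momentum * vel[[nm]])
  }
  list(net = net, vel = vel)
}

# --- training loop ---------------------------------------------------------

subsample_source <- function(src, seed) {
  n <- length(src$samples)
  k <- max(1L, round(src$fraction * n))
  if (k >= n) return(src$samples)
  idx <- with_seed(seed, sort(sample.int(n, k)))
  src$samples[idx]
}

# assemble one batch: returns list(x (ps,ps,3,N), labels (ps,ps,N),
# ybars (N), is_target (N))
make_batch <- function(samples, maps, picks, config, encoding) {
  ps <- config$patch_size
  pairs <- list()
  for (i in picks) {
    pi <- crop_patches(samples[[i]], config, encoding, maps[[i]])
    for (p in pi) {
      a <- augment(p$image, p$label, shift_max = config$shift_max,
                   elastic_magnitude = config$elastic_magnitude,
                   elastic_spacing = config$elastic_spacing)
      pairs[[length(pairs) + 1]] <-
        list(image = normalize_patch(a$image), label = a$label,
             ybar = p$ybar)
    }
  }
  N <- length(pairs)
  x <- array(0, c(ps, ps, 3, N)); y <- array(0, c(ps, ps, N))
  ybars <- numeric(N)
  for (j in seq_len(N)) {
    x[, , , j] <- pairs[[j]]$image
    y[, , j] <- pairs[[j]]$label
    ybars[j] <- pairs[[j]]$ybar
  }
  list(x = x, y = y, ybars = ybars)
}

#' Train the regression network
#'
#' Runs the stochastic-gradient loop with per-iteration dynamic patch
#' cropping, joint augmentation and per-patch standardization. Validation
#' F1 (at the best threshold on the validation grid) is evaluated
#' periodically; when it fails to improve for `patience` iterations the
#' learning rate is divided by `lr_decay_factor`, never dropping below
#' `lr_floor`. When an auxiliary source is present, each batch mixes both
#' sources and the total loss is `gamma * L_target + L_aux` with both
#' partial sums normalized by the full batch size (so `gamma = 1` is
#' exactly naive pooling). A non-finite loss aborts training and restores
#' the last snapshot.
#'
#' @param network a `proxi_net` (possibly with frozen blocks).
#' @param target a [data_source()] with role "target" (or a plain list of
#'   samples).
#' @param val list of validation samples.
#' @param config a [train_config()].
#' @param lparams a [loss_params()] (supplies `lam` and `gamma`).
#' @param encoding a [proximity_params()]; its scale should match the
#'   network's `output_scale`.
#' @param auxiliary optional [data_source()] with role "auxiliary".
#' @param verbose print progress lines.
#' @return list with `network` (trained), `history` (data.frame:
#'   iteration, loss, lr, val_f1), `best_xi` (validation-selected
#'   threshold), `val_f1` (final validation F1).
#' @export
train <- function(network, target, val, config = train_config(),
                  lparams = loss_params(), encoding = proximity_params(),
                  auxiliary = NULL, verbose = FALSE) {
  stopifnot(inherits(network, "proxi_net"))
  if (!inherits(target, "data_source")) target <- data_source(target)
  stopifnot(length(val) >= 1)
  set.seed(config$seed)
  tgt <- subsample_source(target, config$seed + 1L)
  aux <- if (!is.null(auxiliary)) {
    stopifnot(inherits(auxiliary, "data_source"))
    subsample_source(auxiliary, config$seed + 2L)
  }
  enc_map <- function(s) proximity_map(s$centers, dim(s$image)[1],
                                       dim(s$image)[2], encoding)
  tmaps <- lapply(tgt, enc_map)
  amaps <- if (!is.null(aux)) lapply(aux, enc_map)
  vel <- sgd_init(network)
  lr <- config$lr
  it_max <- as.integer(config$max_iterations)
  hist_it <- integer(0); hist_loss <- numeric(0)
  hist_lr <- numeric(0); hist_f1 <- numeric(0)
  best_f1 <- -Inf; best_xi <- config$xi_grid[1]
  last_improve <- 0L
  snapshot <- network
  n_t <- if (is.null(aux)) config$batch_size
         else max(1L, config$batch_size -
                    round(config$batch_size * config$aux_batch_fraction))
  n_a <- if (is.null(aux)) 0L else max(1L, config$batch_size - n_t)
  for (it in seq_len(it_max)) {
    picks_t <- sample.int(length(tgt), n_t, replace = n_t > length(tgt))
    bt <- make_batch(tgt, tmaps, picks_t, config, encoding)
    if (!is.null(aux)) {
      picks_a <- sample.int(length(aux), n_a, replace = n_a > length(aux))
      ba <- make_batch(aux, amaps, picks_a, config, encoding)
      x <- array(0, c(dim(bt$x)[1:3], dim(bt$x)[4] + dim(ba$x)[4]))
      x[, , , seq_len(dim(bt$x)[4])] <- bt$x
      x[, , , dim(bt$x)[4] + seq_len(dim(ba$x)[4])] <- ba$x
      scale_i <- c(rep(lparams$gamma, dim(bt$x)[4]),
                   rep(1, dim(ba$x)[4]))
      y <- array(c(bt$y, ba$y), c(dim(bt$y)[1:2],
                                  dim(bt$y)[3] + dim(ba$y)[3]))
      ybars <- c(bt$ybars, ba$ybars)
    } else {
      x <- bt$x; y <- bt$y; ybars <- bt$ybars
      scale_i <- rep(1, dim(x)[4])
    }
    N <- dim(x)[4]
    fw <- net_forward(network, x, train = TRUE)
    network$running <- fw$running
    loss <- 0
    gout <- array(0, dim(y))
    for (j in seq_len(N)) {
      loss <- loss + scale_i[j] *
        weighted_mse(fw$out[, , j], y[, , j], lparams, ybar = ybars[j])
      gout[, , j] <- scale_i[j] *
        weighted_mse_grad(fw$out[, , j], y[, , j], lparams,
                          ybar = ybars[j])
    }
    loss <- loss / N; gout <- gout / N
    if (!is.finite(loss)) {
      warning("non-finite loss at iteration ", it,
              "; restoring last snapshot")
      network <- snapshot
      break
    }
    grads <- net_backward(network, fw, gout)
    st <- sgd_step(network, grads, vel, lr, config$momentum,
                   config$weight_decay)
    network <- st$net; vel <- st$vel
    f1_here <- NA_real_
    if (it %% config$eval_every == 0 || it == it_max) {
      vmaps <- lapply(val, function(s) predict_map(network, s))
      curve <- pr_curve(network, val, config$xi_grid, config$radius,
                        config$min_distance, maps = vmaps)
      f1_here <- max(curve$f1)
      xi_here <- max(curve$xi[curve$f1 >= f1_here - 1e-12])
      if (f1_here > best_f1 + 1e-12) {
        best_f1 <- f1_here; best_xi <- xi_here; last_improve <- it
      } else if (it - last_improve >= config$patience) {
        if (lr / config$lr_decay_factor >= config$lr_floor) {
          lr <- lr / config$lr_decay_factor
          if (verbose) message(sprintf("it %d: lr decayed to %g", it, lr))
        }
        last_improve <- it
      }
      if (verbose)
        message(sprintf("it %d  loss %.5f  lr %g  val F1 %.4f (xi %.2f)",
                        it, loss, lr, f1_here, xi_here))
    }
    if (it %% config$snapshot_every == 0) snapshot <- network
    hist_it <- c(hist_it, it); hist_loss <- c(hist_loss, loss)
    hist_lr <- c(hist_lr, lr); hist_f1 <- c(hist_f1, f1_here)
  }
  list(network = network,
       history = data.frame(iteration = hist_it, loss = hist_loss,
                            lr = hist_lr, val_f1 = hist_f1),
       best_xi = best_xi, val_f1 = best_f1)
}

#' Fine-tune a trained network on a target dataset
#'
#' Starts from an existing network (or checkpoint file), optionally
#' freezes the first `frozen_blocks` blocks, and trains on the target
#' source.
#'
#' @param base a trained `proxi_net` or a checkpoint path saved with
#'   [save_checkpoint()].
#' @param target,val,config,lparams,encoding,auxiliary,verbose as in
#'   [train()].
#' @param frozen_blocks number of leading blocks to freeze (default 0 =
#'   fine-tune the entire network).
#' @param spec optional `network_spec` to validate the checkpoint against;
#'   a mismatch is rejected.
#' @return as [train()].
#' @export
fine_tune <- function(base, target, val, config = train_config(),
                      frozen_blocks = 0, lparams = loss_params(),
                      encoding = proximity_params(), auxiliary = NULL,
                      spec = NULL, verbose = FALSE) {
  net <- if (is.character(base)) load_checkpoint(base)$network else base
  stopifnot(inherits(net, "proxi_net"))
  if (!is.null(spec) && !identical(unclass(net$spec), unclass(spec)))
    stop("checkpoint network spec does not match the requested spec")
  net <- freeze_blocks(net, frozen_blocks)
  train(net, target, val, config, lparams, encoding, auxiliary, verbose)
}
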