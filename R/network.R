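#' Network architecture hyperparameters
#'
#' Describes the fully convolutional regression network: a one-convolution
#' input transition, `depth` residual downsampling blocks (stride-2 first
#' convolution, channels doubling except at the deepest block), `depth`
#' residual upsampling blocks (kernel-2/stride-2 transposed convolution,
#' concatenation skip from the mirrored downsampling block, zero-padding
#' on the bottom/right when floor-division made sizes asymmetric), a
#' multi-context aggregation path (transposed convolutions applied to every
#' downsampled output, projected to a common width and summed), and a
#' two-convolution output transition producing a single-channel map of the
#' input's spatial size. Blocks are indexed 1..(2*depth + 2) from input to
#' output for freezing.
#'
#' @param base_width channel count after the input transition (>= 4;
#'   default 32; the desk-scale test profile uses 8).
#' @param depth residual blocks per path (>= 2, default 4).
#' @param dropout_rate dropout after the convolutions of the last two
#'   downsampling blocks (training only; default 0.5).
#' @param elu_alpha ELU saturation hyperparameter (default 1).
#' @param output_scale the value regressed at an annotated center; must
#'   match the proximity encoding scale (default 5).
#' @param sigmoid_head if TRUE the last layer applies
#'   `output_scale * sigmoid(z)` instead of a linear map. The linear head
#'   is the default; the sigmoid head exists as the configuration for
#'   which the closed-form last-layer gradient holds.
#' @param min_input declared minimum input size in pixels; the build is
#'   rejected if `depth` downsamplings starting from it reach a
#'   non-positive feature size.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(base_width = 32, depth = 4, dropout_rate = 0.5,
                         elu_alpha = 1, output_scale = 5,
                         sigmoid_head = FALSE, min_input = 32) {
  stopifnot(base_width >= 4, depth >= 2,
            dropout_rate >= 0, dropout_rate < 1,
            elu_alpha > 0, output_scale > 0, min_input >= 4)
  structure(list(base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 dropout_rate = dropout_rate, elu_alpha = elu_alpha,
                 output_scale = output_scale,
                 sigmoid_head = isTRUE(sigmoid_head),
                 min_input = as.integer(min_input)),
            class = "network_spec")
}

#' Number of freezable blocks of a network or spec
#' @param x a `network_spec` or built network.
#' @return integer block count (`2 * depth + 2`).
#' @export
n_blocks <- function(x) {
  spec <- if (inherits(x, "proxi_net")) x$spec else x
  2L * spec$depth + 2L
}

# channel plan: down_ch[j] = output channels of downsampling block j
down_channels <- function(spec) {
  w <- spec$base_width
  ch <- w * 2^seq_len(spec$depth)
  ch[spec$depth] <- ch[spec$depth - 1]
  as.integer(ch)
}

#' Build the regression network
#'
#' Initializes all parameters (He-normal convolution weights, zero biases,
#' unit-gain batch norm) using R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param spec a [network_spec()].
#' @return object of class `proxi_net`: parameter list, per-parameter block
#'   index, batch-norm running moments, and frozen-block count (0).
#' @export
build_network <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$min_input %/% 2^spec$depth < 1)
    stop(sprintf(
      "spec rejected: %d downsamplings of the declared minimum input %d px reach a non-positive size",
      spec$depth, spec$min_input))
  P <- list(); blk <- integer(); run <- list()
  he <- function(fan_in, nr, nc) {
    matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  add_conv <- function(name, cin, cout, k, block) {
    P[[paste0(name, ".w")]] <<- he(k * k * cin, k * k * cin, cout)
    P[[paste0(name, ".b")]] <<- numeric(cout)
    blk[paste0(name, ".w")] <<- block; blk[paste0(name, ".b")] <<- block
  }
  add_tconv <- function(name, cin, cout, s, block) {
    P[[paste0(name, ".w")]] <<- he(cin, cin, s * s * cout)
    P[[paste0(name, ".b")]] <<- numeric(cout)
    blk[paste0(name, ".w")] <<- block; blk[paste0(name, ".b")] <<- block
  }
  add_bn <- function(name, c, block) {
    P[[paste0(name, ".g")]] <<- rep(1, c)
    P[[paste0(name, ".b")]] <<- numeric(c)
    blk[paste0(name, ".g")] <<- block; blk[paste0(name, ".b")] <<- block
    run[[name]] <<- list(m = numeric(c), v = rep(1, c))
  }
  nd <- spec$depth; w <- spec$base_width
  dch <- down_channels(spec)
  # block 1: input transition
  add_conv("b1.conv", 3L, w, 3L, 1L); add_bn("b1.bn", w, 1L)
  # downsampling blocks
  cin <- w
  for (j in seq_len(nd)) {
    b <- 1L + j; nm <- paste0("d", j); cout <- dch[j]
    add_conv(paste0(nm, ".conv1"), cin, cout, 3L, b)
    add_bn(paste0(nm, ".bn1"), cout, b)
    add_conv(paste0(nm, ".conv2"), cout, cout, 3L, b)
    add_bn(paste0(nm, ".bn2"), cout, b)
    add_conv(paste0(nm, ".proj"), cin, cout, 1L, b)
    add_bn(paste0(nm, ".bnp"), cout, b)
    cin <- cout
  }
  # upsampling blocks; block j consumes the skip from down level nd - j
  for (j in seq_len(nd)) {
    b <- 1L + nd + j; nm <- paste0("u", j)
    cskip <- if (j == nd) w else dch[nd - j]
    add_tconv(paste0(nm, ".tconv"), cin, cskip, 2L, b)
    add_bn(paste0(nm, ".bnt"), cskip, b)
    add_conv(paste0(nm, ".conv1"), 2L * cskip, cskip, 3L, b)
    add_bn(paste0(nm, ".bn1"), cskip, b)
    add_conv(paste0(nm, ".conv2"), cskip, cskip, 3L, b)
    add_bn(paste0(nm, ".bn2"), cskip, b)
    add_conv(paste0(nm, ".proj"), 2L * cskip, cskip, 1L, b)
    add_bn(paste0(nm, ".bnp"), cskip, b)
    cin <- cskip
  }
  # multi-context aggregation + output transition: final block
  bo <- 2L * nd + 2L
  add_conv("mc.id", w, w, 1L, bo); add_bn("mc.bnid", w, bo)
  for (j in seq_len(nd)) {
    add_tconv(paste0("mc.t", j), dch[j], w, 2L^j, bo)
    add_bn(paste0("mc.bnt", j), w, bo)
  }
  add_conv("out.conv1", w, w, 3L, bo); add_bn("out.bn1", w, bo)
  add_conv("out.conv2", w, 1L, 3L, bo)
  structure(list(spec = spec, params = P, pblock = blk, running = run,
                 frozen = 0L),
            class = "proxi_net")
}

#' Freeze the first k blocks of a network
#'
#' Parameters of blocks `1..k` are excluded from gradient updates and their
#' batch-norm layers keep using (and stop updating) their running moments.
#'
#' @param network a `proxi_net`.
#' @param k number of leading blocks to freeze, `0 <= k <= n_blocks()`.
#' @return the network with `frozen = k`.
#' @export
freeze_blocks <- function(network, k) {
  stopifnot(inherits(network, "proxi_net"))
  k <- as.integer(k)
  if (k < 0 || k > n_blocks(network))
    stop(sprintf("k must be in 0..%d", n_blocks(network)))
  network$frozen <- k
  network
}

#' Count network parameters
#'
#' @param network a `proxi_net`.
#' @param trainable_only if TRUE, exclude parameters in frozen blocks.
#' @return integer total.
#' @export
count_parameters <- function(network, trainable_only = FALSE) {
  stopifnot(inherits(network, "proxi_net"))
  keep <- rep(TRUE, length(network$params))
  if (trainable_only)
    keep <- network$pblock[names(network$params)] > network$frozen
  sum(vapply(network$params[keep], length, integer(1)))
}

# which bn layer belongs to which block (derived from its gamma entry)
bn_block <- function(net, name) net$pblock[[paste0(name, ".g")]]

# ---------------------------------------------------------------------------
# forward: hand-wired topology recorded on a tape; backward replays it.

tape_env <- function() {
  e <- new.env(parent = emptyenv())
  e$vals <- list(); e$tape <- list(); e$n <- 0L
  e
}

emit <- function(te, op, ins, y, name = NULL, aux = NULL, saved = NULL) {
  te$n <- te$n + 1L
  id <- te$n
  te$vals[[id]] <- y
  te$tape[[id]] <- list(op = op, ins = ins, out = id, name = name,
                        aux = aux, saved = saved)
  id
}

#' Forward pass of the network
#'
#' @param net a `proxi_net`.
#' @param x input array of dim `(H, W, 3, N)` (already normalized).
#' @param train logical; training mode enables dropout and batch-statistics
#'   normalization (except in frozen blocks) and updates running moments.
#' @return list with `out` (array `(H, W, N)` of predicted maps), `tape`
#'   (for [net_backward()]), and `running` (updated moments; assign back to
#'   the network when training).
#' @export
net_forward <- function(net, x, train = FALSE) {
  stopifnot(inherits(net, "proxi_net"), length(dim(x)) == 4, dim(x)[3] == 3)
  spec <- net$spec; nd <- spec$depth
  P <- net$params; run <- net$running
  te <- tape_env()
  ea <- spec$elu_alpha

  conv <- function(id, name, k, stride, pt, pl) {
    force(id)
    y <- op_conv_f(te$vals[[id]], P[[paste0(name, ".w")]],
                   P[[paste0(name, ".b")]], k, stride, pt, pl)
    emit(te, "conv", id, y, name,
         aux = list(k = k, stride = stride, pt = pt, pl = pl))
  }
  tconv <- function(id, name, s) {
    force(id)
    y <- op_tconv_f(te$vals[[id]], P[[paste0(name, ".w")]],
                    P[[paste0(name, ".b")]], s)
    emit(te, "tconv", id, y, name, aux = list(s = s))
  }
  bn <- function(id, name) {
    force(id)
    tr <- train && bn_block(net, name) > net$frozen
    r <- op_bn_f(te$vals[[id]], P[[paste0(name, ".g")]],
                 P[[paste0(name, ".b")]], run[[name]], tr)
    if (tr) run[[name]] <<- r$run
    emit(te, "bn", id, r$y, name, saved = r$cache)
  }
  elu <- function(id) {
    force(id)
    y <- op_elu_f(te$vals[[id]], ea)
    emit(te, "elu", id, y)
  }
  dropout <- function(id) {
    force(id)
    if (!train || spec$dropout_rate <= 0) return(id)
    v <- te$vals[[id]]
    mask <- array(op_dropout_mask(length(v), spec$dropout_rate), dim(v))
    emit(te, "dropout", id, v * mask, saved = list(mask = mask))
  }
  pad_to <- function(id, Ht, Wt) {
    force(id)
    v <- te$vals[[id]]; d <- dim(v)
    if (d[1] == Ht && d[2] == Wt) return(id)
    emit(te, "pad", id, op_pad_br_f(v, Ht, Wt),
         aux = list(H = d[1], W = d[2]))
  }
  crop_off <- function(id) {
    force(id)
    v <- te$vals[[id]]; d <- dim(v)
    emit(te, "crop", id, op_crop_offset_f(v), aux = list(H = d[1], W = d[2]))
  }
  concat <- function(ida, idb) {
    force(ida); force(idb)
    a <- te$vals[[ida]]; b <- te$vals[[idb]]
    emit(te, "concat", c(ida, idb), op_concat_f(a, b),
         aux = list(C1 = dim(a)[3]))
  }
  addv <- function(ida, idb) {
    force(ida); force(idb)
    emit(te, "add", c(ida, idb), te$vals[[ida]] + te$vals[[idb]])
  }

  xin <- emit(te, "input", integer(0), x)
  # block 1
  cur <- elu(bn(conv(xin, "b1.conv", 3L, 1L, 1L, 1L), "b1.bn"))
  feats <- integer(nd + 1L); feats[1] <- cur
  # downsampling path
  for (j in seq_len(nd)) {
    nm <- paste0("d", j)
    drop_here <- j >= nd - 1L
    h <- elu(bn(conv(cur, paste0(nm, ".conv1"), 3L, 2L, 1L, 1L),
                paste0(nm, ".bn1")))
    if (drop_here) h <- dropout(h)
    h <- bn(conv(h, paste0(nm, ".conv2"), 3L, 1L, 1L, 1L),
            paste0(nm, ".bn2"))
    if (drop_here) h <- dropout(h)
    sc <- bn(conv(crop_off(cur), paste0(nm, ".proj"), 1L, 2L, 0L, 0L),
             paste0(nm, ".bnp"))
    cur <- elu(addv(h, sc))
    feats[j + 1L] <- cur
  }
  # upsampling path
  for (j in seq_len(nd)) {
    nm <- paste0("u", j)
    skip <- feats[nd - j + 1L]
    sdim <- dim(te$vals[[skip]])
    h <- elu(bn(tconv(cur, paste0(nm, ".tconv"), 2L), paste0(nm, ".bnt")))
    h <- pad_to(h, sdim[1], sdim[2])
    cat_id <- concat(h, skip)
    r <- elu(bn(conv(cat_id, paste0(nm, ".conv1"), 3L, 1L, 1L, 1L),
                paste0(nm, ".bn1")))
    r <- bn(conv(r, paste0(nm, ".conv2"), 3L, 1L, 1L, 1L),
            paste0(nm, ".bn2"))
    sc <- bn(conv(cat_id, paste0(nm, ".proj"), 1L, 1L, 0L, 0L),
             paste0(nm, ".bnp"))
    cur <- elu(addv(r, sc))
  }
  # multi-context aggregation: project every downsampled output back to
  # full resolution and sum with the projected upsampling-path output
  H <- dim(x)[1]; W <- dim(x)[2]
  mc <- bn(conv(cur, "mc.id", 1L, 1L, 0L, 0L), "mc.bnid")
  for (j in seq_len(nd)) {
    t <- bn(tconv(feats[j + 1L], paste0("mc.t", j), 2L^j),
            paste0("mc.bnt", j))
    mc <- addv(mc, pad_to(t, H, W))
  }
  mc <- elu(mc)
  # output transition
  o <- elu(bn(conv(mc, "out.conv1", 3L, 1L, 1L, 1L), "out.bn1"))
  o <- conv(o, "out.conv2", 3L, 1L, 1L, 1L)
  if (spec$sigmoid_head) {
    z <- te$vals[[o]]
    a <- plogis(z)
    o <- emit(te, "sigscale", o, spec$output_scale * a,
              saved = list(a = a))
  }
  out <- te$vals[[o]]
  out_dim <- dim(out)
  dim(out) <- c(out_dim[1], out_dim[2], out_dim[4])
  list(out = out, tape = te, out_id = o, running = run)
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param net the `proxi_net` used in the forward pass.
#' @param fw result of `net_forward(..., train = TRUE)`.
#' @param gout gradient of the loss w.r.t. the network output, array
#'   `(H, W, N)`.
#' @return named list of gradients, one entry per parameter (frozen blocks
#'   included; the optimizer skips them).
#' @export
net_backward <- function(net, fw, gout) {
  te <- fw$tape
  P <- net$params
  ea <- net$spec$elu_alpha
  gvals <- vector("list", te$n)
  grads <- list()
  d_out <- dim(te$vals[[fw$out_id]])
  dim(gout) <- d_out
  gvals[[fw$out_id]] <- gout
  acc <- function(id, g) {
    gvals[[id]] <<- if (is.null(gvals[[id]])) g else gvals[[id]] + g
  }
  gacc <- function(nm, g) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) g else grads[[nm]] + g
  }
  for (i in rev(seq_len(te$n))) {
    e <- te$tape[[i]]
    g <- gvals[[i]]
    if (is.null(g) || e$op == "input") next
    switch(e$op,
      conv = {
        r <- op_conv_b(te$vals[[e$ins]], P[[paste0(e$name, ".w")]], g,
                       e$aux$k, e$aux$stride, e$aux$pt, e$aux$pl)
        gacc(paste0(e$name, ".w"), r$gw)
        gacc(paste0(e$name, ".b"), r$gb)
        acc(e$ins, r$gx)
      },
      tconv = {
        r <- op_tconv_b(te$vals[[e$ins]], P[[paste0(e$name, ".w")]], g,
                        e$aux$s)
        gacc(paste0(e$name, ".w"), r$gw)
        gacc(paste0(e$name, ".b"), r$gb)
        acc(e$ins, r$gx)
      },
      bn = {
        r <- op_bn_b(e$saved, P[[paste0(e$name, ".g")]], g)
        gacc(paste0(e$name, ".g"), r$ggamma)
        gacc(paste0(e$name, ".b"), r$gbeta)
        acc(e$ins, r$gx)
      },
      elu = acc(e$ins, op_elu_b(te$vals[[i]], ea, g)),
      dropout = acc(e$ins, g * e$saved$mask),
      pad = acc(e$ins, op_pad_br_b(g, e$aux$H, e$aux$W)),
      crop = acc(e$ins, op_crop_offset_b(g, e$aux$H, e$aux$W)),
      concat = {
        r <- op_concat_b(g, e$aux$C1)
        acc(e$ins[1], r$ga); acc(e$ins[2], r$gb)
      },
      add = { acc(e$ins[1], g); acc(e$ins[2], g) },
      sigscale = {
        a <- e$saved$a
        acc(e$ins, g * net$spec$output_scale * a * (1 - a))
      },
      stop("unknown op: ", e$op)
    )
  }
  # ensure every parameter has a gradient entry
  for (nm in names(P)) if (is.null(grads[[nm]])) grads[[nm]] <- P[[nm]] * 0
  grads
}

#' @export
print.proxi_net <- function(x, ...) {
  cat(sprintf(
    "proxi_net: base_width %d, depth %d, %d blocks, %d parameters (%d frozen blocks)\n",
    x$spec$base_width, x$spec$depth, n_blocks(x), count_parameters(x),
    x$frozen))
  invisible(x)
}
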