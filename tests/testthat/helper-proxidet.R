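# Shared fixtures and independent oracles used across the suite.

# tiny architecture for fast CPU checks
tiny_spec <- function(...) {
  args <- utils::modifyList(list(base_width = 4, depth = 2,
                                 dropout_rate = 0, min_input = 8),
                            list(...))
  do.call(network_spec, args)
}

tiny_net <- function(seed = 7, ...) {
  set.seed(seed)
  build_network(tiny_spec(...))
}

# brute-force minimum-cost assignment by enumerating all injections of
# rows into columns (n <= m required)
brute_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 7)
  best <- Inf
  cols <- seq_len(m)
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) { best <<- min(best, acc); return() }
    for (j in cols[!used]) {
      used[j] <- TRUE
      rec(i + 1L, used, acc + cost[i, j])
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# exhaustive local-maxima scan: suppression + per-pixel neighborhood check
# + plateau merge, written independently of detect()
brute_detect <- function(v, xi, min_distance) {
  mx <- max(v)
  if (mx <= 0) return(matrix(numeric(0), 0, 2))
  proc <- v
  proc[proc < xi * mx] <- 0
  H <- nrow(proc); W <- ncol(proc)
  md <- ceiling(min_distance)
  mask <- outer((-md:md)^2, (-md:md)^2, "+") <= min_distance^2
  mask[md + 1, md + 1] <- FALSE
  padded <- matrix(-Inf, H + 2 * md, W + 2 * md)
  padded[md + seq_len(H), md + seq_len(W)] <- proc
  cand <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (proc[i, j] <= 0) next
    win <- padded[i:(i + 2 * md), j:(j + 2 * md)]
    if (proc[i, j] >= max(win[mask])) cand[i, j] <- TRUE
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), 0, 2))
  n <- nrow(idx)
  comp <- seq_len(n)
  if (n > 1) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (proc[idx[a, , drop = FALSE]] == proc[idx[b, , drop = FALSE]] &&
          sum((idx[a, ] - idx[b, ])^2) <= min_distance^2) {
        old <- comp[b]; comp[comp == old] <- comp[a]
      }
    }
  }
  pts <- t(vapply(split(seq_len(n), comp), function(g)
    colMeans(idx[g, , drop = FALSE]) - 1, numeric(2)))
  unname(pts)
}

# random smooth positive map (sum of Gaussian bumps + smooth background)
random_bumpy_map <- function(H, W, n_bumps, seed) {
  set.seed(seed)
  v <- matrix(0, H, W)
  for (b in seq_len(n_bumps)) {
    cr <- runif(1, 2, H - 3); cc <- runif(1, 2, W - 3)
    s <- runif(1, 1.5, 4); amp <- runif(1, 0.5, 2)
    d2 <- outer((seq_len(H) - 1 - cr)^2, (seq_len(W) - 1 - cc)^2, "+")
    v <- v + amp * exp(-d2 / (2 * s^2))
  }
  v
}

# compare two point sets irrespective of order
expect_same_points <- function(a, b, tol = 1e-8) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a) == 0) return(invisible())
  oa <- order(round(a[, 1], 6), round(a[, 2], 6))
  ob <- order(round(b[, 1], 6), round(b[, 2], 6))
  expect_equal(unname(a[oa, , drop = FALSE]),
               unname(b[ob, , drop = FALSE]), tolerance = tol)
}

# sparse style that fits 32x32 micro images
micro_style <- function(...) {
  synth_style(nucleus_count_range = c(2, 4), radius_range = c(2.5, 4), ...)
}

# desk-scale study conditions: the corpus every end-to-end check uses
desk_corpus <- function(seed, n_images = 210, size = 64) {
  corpus <- generate_dataset(synth_style(), n_images, size, size, seed)
  split_dataset(corpus, seed + 1)
}
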