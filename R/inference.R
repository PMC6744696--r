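# Full-image prediction and nucleus localization by suppression +
# local-maxima extraction.

#' Predict a proximity map for one image
#'
#' Applies the same per-channel standardization used in training and runs a
#' single full-image forward pass (no sliding window); the output has the
#' input's spatial size. Images smaller than `2^depth` pixels in either
#' dimension are reflect-padded for the pass and cropped back; images
#' smaller than 8 px are rejected.
#'
#' @param network a trained `proxi_net`.
#' @param image `H x W x 3` array (0..255 or any numeric range; grayscale
#'   `H x W` is replicated to 3 channels with a warning) or a
#'   `synth_sample`.
#' @return a `proximity_map` with the predicted `values` (no encoding
#'   params).
#' @export
predict_map <- function(network, image) {
  stopifnot(inherits(network, "proxi_net"))
  if (is.list(image) && !is.null(image$image)) image <- image$image
  if (length(dim(image)) == 2) {
    warning("grayscale input replicated to 3 channels")
    image <- array(rep(image, 3), c(dim(image), 3))
  }
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < 8 || W < 8) stop("image smaller than the 8 px floor")
  x <- normalize_patch(image)
  floor_px <- 2^network$spec$depth
  Hp <- max(H, floor_px); Wp <- max(W, floor_px)
  if (Hp > H || Wp > W) x <- reflect_pad(x, Hp, Wp)
  dim(x) <- c(dim(x)[1], dim(x)[2], 3, 1)
  fw <- net_forward(network, x, train = FALSE)
  vals <- fw$out[seq_len(H), seq_len(W), 1]
  structure(list(values = vals, params = NULL), class = "proximity_map")
}

#' @export
predict.proxi_net <- function(object, image, ...) predict_map(object, image)

#' Localize nuclei on a predicted proximity map
#'
#' Values below `xi * max(map)` are suppressed (set to 0); the remaining
#' pixels are scanned for local maxima: a detection is a pixel whose value
#' is positive and not smaller than every neighbor within `min_distance`
#' (Euclidean). Connected plateaus of equal value collapse to their
#' centroid. The threshold is relative to the map's own maximum, so
#' detection is invariant to positive rescaling of the map.
#'
#' @param map a `proximity_map` or numeric matrix.
#' @param xi suppression threshold fraction in `[0, 1]`.
#' @param min_distance neighborhood radius in pixels (default 6).
#' @return a `detection_set`: list with `points` (n x 2 matrix of
#'   (row, col)), `scores` (map values at the peaks), `xi`.
#' @export
detect <- function(map, xi, min_distance = 6) {
  v <- map_values(map)
  if (!all(is.finite(v))) stop("map must be finite")
  if (xi < 0 || xi > 1) stop("xi must be in [0, 1]")
  mx <- max(v)
  empty <- structure(list(points = matrix(numeric(0), 0, 2),
                          scores = numeric(0), xi = xi),
                     class = "detection_set")
  if (mx <= 0) return(empty)
  proc <- v
  proc[proc < xi * mx] <- 0
  H <- nrow(proc); W <- ncol(proc)
  md <- as.integer(ceiling(min_distance))
  offs <- expand.grid(di = -md:md, dj = -md:md)
  offs <- offs[offs$di^2 + offs$dj^2 <= min_distance^2 &
                 !(offs$di == 0 & offs$dj == 0), ]
  pad <- matrix(-Inf, H + 2 * md, W + 2 * md)
  pad[md + seq_len(H), md + seq_len(W)] <- proc
  ismax <- proc > 0
  for (r in seq_len(nrow(offs))) {
    sh <- pad[md + offs$di[r] + seq_len(H), md + offs$dj[r] + seq_len(W)]
    ismax <- ismax & (proc >= sh)
    if (!any(ismax)) break
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  # collapse plateaus: candidates within min_distance of each other with
  # equal value belong to one peak; take the component centroid
  n <- nrow(idx)
  vals_c <- proc[idx]
  comp <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (vals_c[i] == vals_c[j] &&
            sum((idx[i, ] - idx[j, ])^2) <= min_distance^2) {
          old <- comp[j]; comp[comp == old] <- comp[i]
        }
      }
    }
  }
  groups <- split(seq_len(n), comp)
  pts <- t(vapply(groups, function(g)
    colMeans(idx[g, , drop = FALSE]) - 1, numeric(2)))
  scores <- vapply(groups, function(g) vals_c[g[1]], numeric(1))
  ord <- order(-scores, pts[, 1], pts[, 2])
  structure(list(points = unname(pts[ord, , drop = FALSE]),
                 scores = unname(scores[ord]), xi = xi),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("detection_set: %d points (xi = %.3g)\n",
              nrow(x$points), x$xi))
  invisible(x)
}

# reflect-pad an (H, W, C) array on the bottom/right to (Ht, Wt)
reflect_pad <- function(x, Ht, Wt) {
  H <- dim(x)[1]; W <- dim(x)[2]
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(Ht)]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(Wt)]
  x[ri, ci, , drop = FALSE]
}
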