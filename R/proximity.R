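#' Proximity-map encoding parameters
#'
#' Parameters of the exponential proximity encoding that turns point
#' annotations into dense regression targets. A pixel at Euclidean distance
#' `D` from its nearest annotated center receives the value
#' `scale * (exp(alpha * (1 - D/d)) - 1) / (exp(alpha) - 1)` when `D <= d`
#' and 0 otherwise, so the encoded value is exactly `scale` on a center and
#' decays to 0 continuously at distance `d`.
#'
#' @param alpha decay control (dimensionless, > 0). Larger values
#'   concentrate the mass near the center.
#' @param d distance threshold in pixels (> 0); pixels farther than `d`
#'   from every center are 0.
#' @param scale multiplicative factor applied to the encoded values (> 0);
#'   training regresses the scaled values directly.
#' @return an object of class `proximity_params`.
#' @export
proximity_params <- function(alpha = 3, d = 15, scale = 5) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(d), length(d) == 1, is.finite(d),
            is.numeric(scale), length(scale) == 1, is.finite(scale))
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (d <= 0) stop("'d' must be > 0")
  if (scale <= 0) stop("'scale' must be > 0")
  structure(list(alpha = alpha, d = d, scale = scale),
            class = "proximity_params")
}

#' Encode point annotations as a proximity map
#'
#' For every pixel, computes the exact Euclidean distance to the nearest
#' annotated center (pixel centers at integer 0-based coordinates, centers
#' real-valued) and applies the exponential proximity encoding. Pixels
#' farther than `params$d` from all centers are exactly 0; an empty center
#' list yields an all-zero map.
#'
#' @param centers a 2-column matrix (or an empty / NULL value) of
#'   real-valued `(row, col)` center coordinates, 0-based.
#' @param height,width map size in pixels.
#' @param params a [proximity_params()] object.
#' @return a `proximity_map` object: list with `values` (height x width
#'   matrix) and `params`.
#' @export
proximity_map <- function(centers, height, width, params = proximity_params()) {
  stopifnot(inherits(params, "proximity_params"),
            height >= 1, width >= 1)
  centers <- as_centers(centers)
  if (nrow(centers) > 0) {
    if (!all(is.finite(centers))) stop("centers must be finite")
    if (any(centers[, 1] < 0) || any(centers[, 1] > height - 1) ||
        any(centers[, 2] < 0) || any(centers[, 2] > width - 1))
      stop("centers must lie inside the image bounds [0, height-1] x [0, width-1]")
  }
  vals <- matrix(0, height, width)
  if (nrow(centers) > 0) {
    d <- params$d
    # distances are only needed where they can be <= d: update windows
    dist2 <- matrix(Inf, height, width)
    win <- ceiling(d) + 1L
    for (i in seq_len(nrow(centers))) {
      cr <- centers[i, 1]; cc <- centers[i, 2]
      r0 <- max(0L, floor(cr) - win); r1 <- min(height - 1L, ceiling(cr) + win)
      c0 <- max(0L, floor(cc) - win); c1 <- min(width - 1L, ceiling(cc) + win)
      rr <- r0:r1; cc2 <- c0:c1
      d2 <- outer((rr - cr)^2, (cc2 - cc)^2, "+")
      sub <- dist2[rr + 1L, cc2 + 1L, drop = FALSE]
      dist2[rr + 1L, cc2 + 1L] <- pmin(sub, d2)
    }
    D <- sqrt(dist2)
    inside <- is.finite(D) & D <= d
    vals[inside] <- params$scale *
      expm1(params$alpha * (1 - D[inside] / d)) / expm1(params$alpha)
  }
  structure(list(values = vals, params = params), class = "proximity_map")
}

#' Mean value of a proximity map
#'
#' Arithmetic mean over all pixels; this is the per-image quantity that the
#' weighted regression loss uses to balance the contribution of individual
#' images.
#'
#' @param map a `proximity_map` object or a plain numeric matrix.
#' @return a scalar.
#' @export
mean_proximity <- function(map) {
  v <- map_values(map)
  if (length(v) == 0) stop("map is empty")
  mean(v)
}

map_values <- function(map) {
  if (inherits(map, "proximity_map")) map$values
  else if (is.matrix(map)) map
  else stop("expected a 'proximity_map' or a numeric matrix")
}

# Normalize centers input to an n x 2 numeric matrix of (row, col).
as_centers <- function(centers) {
  if (is.null(centers) || length(centers) == 0)
    return(matrix(numeric(0), 0, 2))
  if (is.data.frame(centers)) centers <- as.matrix(centers)
  if (!is.matrix(centers) || ncol(centers) != 2)
    stop("centers must be an n x 2 matrix of (row, col) coordinates")
  storage.mode(centers) <- "double"
  centers
}

#' @export
print.proximity_map <- function(x, ...) {
  cat(sprintf("proximity_map: %d x %d, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Write / read a proximity map as 32-bit float TIFF
#'
#' Values are stored in units of `scale` (i.e. divided by it) so that gold
#' maps occupy exactly `[0, 1]`; values outside `[0, scale]` are clipped
#' with a warning on write.
#'
#' @param map a `proximity_map` or numeric matrix.
#' @param path output file path.
#' @param scale value of one stored unit (default: the map's own encoding
#'   scale, else 1).
#' @return `read_proximity_tiff` returns a numeric matrix of map values.
#' @export
write_proximity_tiff <- function(map, path, scale = NULL) {
  v <- map_values(map)
  if (is.null(scale))
    scale <- if (inherits(map, "proximity_map")) map$params$scale else 1
  u <- v / scale
  if (min(u) < 0 || max(u) > 1) {
    warning("values outside [0, scale] clipped on write")
    u <- pmin(pmax(u, 0), 1)
  }
  tiff::writeTIFF(u, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_proximity_tiff
#' @export
read_proximity_tiff <- function(path, scale = 1) {
  u <- tiff::readTIFF(path)
  if (length(dim(u)) == 3) u <- u[, , 1]
  u * scale
}
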