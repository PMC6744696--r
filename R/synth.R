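# Seeded generator of H&E-like synthetic microscopy tiles with known
# nucleus centers. Nuclei are anti-aliased filled ellipses with random
# orientation, per-nucleus color jitter and a radial intensity falloff,
# rendered over a textured eosin-pink background; a configurable fraction
# of nuclei is placed touching an existing nucleus.

#' Synthetic image style ("organ" emulation)
#'
#' A style bundles the appearance statistics of one synthetic dataset:
#' nucleus density, size and shape ranges, hematoxylin-like nucleus color,
#' eosin-like background, and an overlap (touching) fraction. Distinct
#' styles play the role of distinct organs in cross-dataset and
#' mixed-dataset training experiments.
#'
#' @param style_id label for the style.
#' @param nucleus_count_range integer interval `c(min, max)` of nuclei per
#'   image.
#' @param radius_range semi-major axis range in pixels (min >= 2).
#' @param eccentricity_range range in `[0, 1)`; the semi-minor axis is
#'   `a * sqrt(1 - e^2)`.
#' @param nucleus_color RGB triple in 0..255 (dark purple by default).
#' @param color_jitter per-nucleus uniform color jitter amplitude.
#' @param background_color RGB triple in 0..255 (pink by default).
#' @param texture_amplitude amplitude of the low-frequency background
#'   texture (0..255 scale).
#' @param overlap_fraction fraction in `[0, 1]` of nuclei placed adjacent
#'   to (touching) an already placed nucleus.
#' @param noise_sd per-channel additive Gaussian noise sd (0..255 scale).
#' @param clutter_count_range integer interval of background clutter
#'   elements per image: soft hue-shifted smudges (stromal debris) that
#'   darken the background without being nuclei and are not annotated.
#' @param clutter_strength blend strength of clutter in `[0, 1)`; 0
#'   disables clutter.
#' @return object of class `synth_style`.
#' @export
synth_style <- function(style_id = "style1",
                        nucleus_count_range = c(4L, 9L),
                        radius_range = c(3, 6),
                        eccentricity_range = c(0, 0.6),
                        nucleus_color = c(90, 60, 140),
                        color_jitter = 20,
                        background_color = c(235, 185, 205),
                        texture_amplitude = 14,
                        overlap_fraction = 0.2,
                        noise_sd = 4,
                        clutter_count_range = c(3L, 8L),
                        clutter_strength = 0.45) {
  stopifnot(length(nucleus_count_range) == 2,
            nucleus_count_range[1] <= nucleus_count_range[2],
            nucleus_count_range[1] >= 0,
            length(radius_range) == 2, radius_range[1] >= 2,
            radius_range[1] <= radius_range[2],
            length(eccentricity_range) == 2,
            eccentricity_range[1] >= 0, eccentricity_range[2] < 1,
            length(nucleus_color) == 3, all(nucleus_color >= 0),
            all(nucleus_color <= 255),
            length(background_color) == 3, all(background_color >= 0),
            all(background_color <= 255),
            overlap_fraction >= 0, overlap_fraction <= 1,
            noise_sd >= 0, texture_amplitude >= 0, color_jitter >= 0,
            length(clutter_count_range) == 2,
            clutter_count_range[1] >= 0,
            clutter_count_range[1] <= clutter_count_range[2],
            clutter_strength >= 0, clutter_strength < 1)
  structure(list(style_id = as.character(style_id),
                 nucleus_count_range = as.integer(nucleus_count_range),
                 radius_range = as.numeric(radius_range),
                 eccentricity_range = as.numeric(eccentricity_range),
                 nucleus_color = as.numeric(nucleus_color),
                 color_jitter = as.numeric(color_jitter),
                 background_color = as.numeric(background_color),
                 texture_amplitude = as.numeric(texture_amplitude),
                 overlap_fraction = as.numeric(overlap_fraction),
                 noise_sd = as.numeric(noise_sd),
                 clutter_count_range = as.integer(clutter_count_range),
                 clutter_strength = as.numeric(clutter_strength)),
            class = "synth_style")
}

# run expr with a private, seeded RNG stream; restores the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smooth low-frequency field in [-1, 1], bilinear upsample of a coarse grid
low_freq_field <- function(height, width, cells = 6L) {
  g <- matrix(runif((cells + 1L)^2, -1, 1), cells + 1L, cells + 1L)
  ri <- seq(0, cells, length.out = height)
  ci <- seq(0, cells, length.out = width)
  r0 <- pmin(floor(ri), cells - 1L); c0 <- pmin(floor(ci), cells - 1L)
  fr <- ri - r0; fc <- ci - c0
  a <- g[cbind(rep(r0 + 1L, width), rep(c0 + 1L, each = height))]
  b <- g[cbind(rep(r0 + 2L, width), rep(c0 + 1L, each = height))]
  cc <- g[cbind(rep(r0 + 1L, width), rep(c0 + 2L, each = height))]
  d <- g[cbind(rep(r0 + 2L, width), rep(c0 + 2L, each = height))]
  fr <- rep(fr, width); fc <- rep(fc, each = height)
  v <- a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) +
    cc * (1 - fr) * fc + d * fr * fc
  matrix(v, height, width)
}

#' Generate one synthetic annotated image
#'
#' Rendering is fully determined by `(style, height, width, seed)`:
#' calling twice with the same arguments yields bit-identical pixels and
#' identical center lists. Centers are real-valued `(row, col)`, 0-based,
#' and always inside the image. With `overlap_fraction = 0` nuclei are
#' placed with pairwise center distance at least the sum of their
#' semi-major axes (rejection sampling).
#'
#' @param style a [synth_style()].
#' @param height,width image size in pixels (>= 32).
#' @param seed integer seed.
#' @return object of class `synth_sample`: list with `image`
#'   (height x width x 3 integer array, 0..255), `centers` (n x 2 matrix of
#'   (row, col)), `style_id`, `seed`.
#' @export
generate_image <- function(style, height, width, seed) {
  stopifnot(inherits(style, "synth_style"), height >= 32, width >= 32)
  if (max(style$radius_range) > min(height, width) / 2)
    stop("style radius_range exceeds half the image size; use larger images or smaller nuclei")
  with_seed(seed, {
    n <- if (style$nucleus_count_range[1] == style$nucleus_count_range[2])
      style$nucleus_count_range[1]
    else sample(style$nucleus_count_range[1]:style$nucleus_count_range[2], 1)
    # nucleus geometry
    a <- runif(max(n, 0), style$radius_range[1], style$radius_range[2])
    ecc <- runif(max(n, 0), style$eccentricity_range[1],
                 style$eccentricity_range[2])
    b <- a * sqrt(1 - ecc^2)
    theta <- runif(max(n, 0), 0, pi)
    n_overlap <- if (n > 0) rbinom(1, n, style$overlap_fraction) else 0L
    centers <- matrix(numeric(0), 0, 2)
    margin <- a + 1
    place_free <- function(i, centers) {
      if (height - 1 - margin[i] <= margin[i] ||
          width - 1 - margin[i] <= margin[i])
        stop("image too small for the style's nucleus radii")
      for (try in 1:300) {
        r <- runif(1, margin[i], height - 1 - margin[i])
        cl <- runif(1, margin[i], width - 1 - margin[i])
        ok <- TRUE
        if (nrow(centers) > 0) {
          dd <- sqrt((centers[, 1] - r)^2 + (centers[, 2] - cl)^2)
          ok <- all(dd >= a[seq_len(nrow(centers))] + a[i] + 0.5)
        }
        if (ok) return(c(r, cl))
      }
      stop("could not place ", i, " non-overlapping nuclei; reduce counts or radii")
    }
    if (n > 0) {
      for (i in seq_len(n)) {
        if (i > 1 && i > n - n_overlap) {
          # touching nucleus: perturb an existing center
          j <- sample(i - 1L, 1)
          ang <- runif(1, 0, 2 * pi)
          dist <- (a[i] + a[j]) * runif(1, 0.55, 0.95)
          r <- min(max(centers[j, 1] + dist * sin(ang), 1), height - 2)
          cl <- min(max(centers[j, 2] + dist * cos(ang), 1), width - 2)
          centers <- rbind(centers, c(r, cl))
        } else {
          centers <- rbind(centers, place_free(i, centers))
        }
      }
    }
    # background: per-channel base color modulated by shared low-freq texture
    tex <- low_freq_field(height, width)
    img <- array(0, c(height, width, 3))
    for (ch in 1:3)
      img[, , ch] <- style$background_color[ch] + style$texture_amplitude * tex
    # background clutter: soft hue-shifted smudges, darker than stroma but
    # not annotated as nuclei (rendered beneath them)
    if (style$clutter_strength > 0 && style$clutter_count_range[2] > 0) {
      n_cl <- if (style$clutter_count_range[1] == style$clutter_count_range[2])
        style$clutter_count_range[1]
      else sample(style$clutter_count_range[1]:style$clutter_count_range[2], 1)
      cl_col_base <- 0.45 * style$nucleus_color + 0.55 * style$background_color
      for (i in seq_len(n_cl)) {
        cr <- runif(1, 0, height - 1); cc <- runif(1, 0, width - 1)
        ca <- runif(1, 3, 10); cb <- runif(1, 3, 10)
        th <- runif(1, 0, pi)
        strength <- style$clutter_strength * runif(1, 0.5, 1)
        cl_col <- cl_col_base + runif(3, -15, 15)
        ext <- ceiling(max(ca, cb)) + 2L
        r0 <- max(0L, floor(cr) - ext); r1 <- min(height - 1L, ceiling(cr) + ext)
        c0 <- max(0L, floor(cc) - ext); c1 <- min(width - 1L, ceiling(cc) + ext)
        rr <- r0:r1; cc2 <- c0:c1
        dy <- outer(rr - cr, rep(1, length(cc2)))
        dx <- outer(rep(1, length(rr)), cc2 - cc)
        u <- (dy * cos(th) + dx * sin(th)) / ca
        v <- (-dy * sin(th) + dx * cos(th)) / cb
        cov <- strength * exp(-2 * (u^2 + v^2))
        for (ch in 1:3) {
          sub <- img[rr + 1L, cc2 + 1L, ch]
          img[rr + 1L, cc2 + 1L, ch] <- sub * (1 - cov) + cl_col[ch] * cov
        }
      }
    }
    # render nuclei: anti-aliased ellipse coverage + radial falloff
    if (n > 0) {
      rows <- 0:(height - 1)
      for (i in seq_len(n)) {
        col_i <- style$nucleus_color +
          runif(3, -style$color_jitter, style$color_jitter)
        ext <- ceiling(a[i]) + 2L
        r0 <- max(0L, floor(centers[i, 1]) - ext)
        r1 <- min(height - 1L, ceiling(centers[i, 1]) + ext)
        c0 <- max(0L, floor(centers[i, 2]) - ext)
        c1 <- min(width - 1L, ceiling(centers[i, 2]) + ext)
        rr <- r0:r1; cc <- c0:c1
        dy <- outer(rr - centers[i, 1], rep(1, length(cc)))
        dx <- outer(rep(1, length(rr)), cc - centers[i, 2])
        u <- (dy * cos(theta[i]) + dx * sin(theta[i])) / a[i]
        v <- (-dy * sin(theta[i]) + dx * cos(theta[i])) / b[i]
        rho <- sqrt(u^2 + v^2)
        # coverage: 1 inside, linear fade over ~1 px at the rim
        edge_px <- 1 / min(a[i], b[i])
        cov <- pmin(pmax((1 + edge_px - rho) / edge_px, 0), 1)
        shade <- 0.75 + 0.45 * pmin(rho, 1)^2  # darker core, lighter rim
        for (ch in 1:3) {
          sub <- img[rr + 1L, cc + 1L, ch]
          img[rr + 1L, cc + 1L, ch] <-
            sub * (1 - cov) + (col_i[ch] * shade) * cov
        }
      }
    }
    noise <- array(rnorm(length(img), 0, style$noise_sd), dim(img))
    img <- round(pmin(pmax(img + noise, 0), 255))
    storage.mode(img) <- "integer"
    structure(list(image = img, centers = centers,
                   style_id = style$style_id, seed = seed),
              class = "synth_sample")
  })
}

#' Generate a seeded dataset of synthetic images
#'
#' Per-sample seeds are derived deterministically from the master seed, so
#' the corpus is identical across runs.
#'
#' @param style a [synth_style()].
#' @param n_images number of images (>= 1).
#' @param height,width image size.
#' @param seed master seed.
#' @return list of `synth_sample` objects.
#' @export
generate_dataset <- function(style, n_images, height, width, seed) {
  stopifnot(n_images >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_images))
  lapply(seq_len(n_images), function(i)
    generate_image(style, height, width, seeds[i]))
}

#' Split a dataset into disjoint train / validation / test sets
#'
#' The images are split into two halves (train+validation vs test), then a
#' fraction of the training half is held out for validation.
#'
#' @param samples list of samples (or anything indexable).
#' @param seed split seed.
#' @param test_fraction fraction used for testing (default 0.5).
#' @param val_fraction fraction *of the training half* used for validation
#'   (default 0.2).
#' @return list with `train`, `val`, `test` (pairwise disjoint).
#' @export
split_dataset <- function(samples, seed, test_fraction = 0.5,
                          val_fraction = 0.2) {
  n <- length(samples)
  stopifnot(n >= 2)
  idx <- with_seed(seed, sample.int(n))
  n_test <- round(n * test_fraction)
  test_i <- idx[seq_len(n_test)]
  rest <- idx[-seq_len(n_test)]
  n_val <- max(1L, round(length(rest) * val_fraction))
  val_i <- rest[seq_len(n_val)]
  train_i <- rest[-seq_len(n_val)]
  list(train = samples[train_i], val = samples[val_i], test = samples[test_i])
}

#' Generate corpora for several styles
#'
#' Independent seeded corpora per style, supporting target-versus-auxiliary
#' pooling experiments across synthetic "organs".
#'
#' @param styles list of [synth_style()] objects with distinct `style_id`s
#'   (>= 2 styles).
#' @param n_per_style images per style.
#' @param height,width image size.
#' @param seed master seed.
#' @return named list mapping `style_id` to a list of `synth_sample`s.
#' @export
generate_multistyle_corpus <- function(styles, n_per_style, height, width,
                                       seed) {
  stopifnot(length(styles) >= 2)
  ids <- vapply(styles, function(s) s$style_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate style_ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      length(styles)))
  out <- lapply(seq_along(styles), function(i)
    generate_dataset(styles[[i]], n_per_style, height, width, seeds[i]))
  names(out) <- ids
  out
}

#' @export
print.synth_sample <- function(x, ...) {
  cat(sprintf("synth_sample [%s]: %d x %d, %d nuclei, seed %d\n",
              x$style_id, dim(x$image)[1], dim(x$image)[2],
              nrow(x$centers), x$seed))
  invisible(x)
}

#' @importFrom stats rbinom
NULL
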