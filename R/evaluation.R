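# Detection evaluation: Hungarian one-to-one matching of detections to
# annotations within a gold-region radius, precision/recall/F1, mean
# localization distance, PR curves and validation-based threshold
# selection.

# Minimum-cost linear sum assignment (Jonker-Volgenant shortest augmenting
# path with potentials, O(n^2 m)). cost: n x m matrix with n <= m.
# Returns for each row the assigned column.
lsap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      uj <- which(used) - 1L            # columns (0-based) in the tree
      rows <- p[uj + 1L]
      u[rows] <- u[rows] + delta
      v[uj + 1L] <- v[uj + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Match detections to annotations with the Hungarian algorithm
#'
#' Detections within `radius` pixels of an annotation are candidate
#' matches, with cost equal to the Euclidean distance; pairs farther apart
#' get a large sentinel cost. The minimum-total-cost one-to-one assignment
#' is computed; assigned pairs at distance `<= radius` are true positives,
#' remaining detections are false positives and remaining annotations
#' false negatives.
#'
#' @param detections a `detection_set` or an n x 2 matrix of (row, col)
#'   points.
#' @param annotations m x 2 matrix of gold-standard (row, col) centers.
#' @param radius gold-region radius in pixels (default 16).
#' @return a `match_report`: `tp` data.frame (detection, annotation,
#'   distance), `fp` (detection indices), `fn` (annotation indices),
#'   `radius`, and the counts.
#' @export
match_detections <- function(detections, annotations, radius = 16) {
  stopifnot(radius > 0)
  det <- if (inherits(detections, "detection_set")) detections$points
         else as_centers(detections)
  ann <- as_centers(annotations)
  nd <- nrow(det); na <- nrow(ann)
  tp <- data.frame(detection = integer(0), annotation = integer(0),
                   distance = numeric(0))
  if (nd > 0 && na > 0) {
    D <- sqrt(outer(det[, 1], ann[, 1], "-")^2 +
                outer(det[, 2], ann[, 2], "-")^2)
    sentinel <- (max(nd, na) + 1) * (radius + 1)
    cost <- ifelse(D <= radius, D, sentinel)
    if (nd <= na) {
      a <- lsap(cost)
      pairs <- cbind(seq_len(nd), a)
    } else {
      a <- lsap(t(cost))
      pairs <- cbind(a, seq_len(na))
    }
    keep <- D[pairs] <= radius
    pairs <- pairs[keep, , drop = FALSE]
    tp <- data.frame(detection = pairs[, 1], annotation = pairs[, 2],
                     distance = D[pairs])
  }
  structure(list(tp = tp,
                 fp = setdiff(seq_len(nd), tp$detection),
                 fn = setdiff(seq_len(na), tp$annotation),
                 radius = radius,
                 n_detections = nd, n_annotations = na),
            class = "match_report")
}

#' Detection metrics from a match report
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1,
#' and the mean Euclidean distance over true-positive pairs. Conventions
#' for degenerate cases: with neither detections nor annotations all three
#' are 1; otherwise an empty denominator yields 0. `mean_ed` is `NA` when
#' there are no true positives.
#'
#' @param report a `match_report` from [match_detections()].
#' @return a `metric_summary`: list with `precision`, `recall`, `f1`,
#'   `mean_ed`, `tp`, `fp`, `fn`.
#' @export
metrics <- function(report) {
  stopifnot(inherits(report, "match_report"))
  tp <- nrow(report$tp); fp <- length(report$fp); fn <- length(report$fn)
  if (report$n_detections == 0 && report$n_annotations == 0) {
    p <- r <- f1 <- 1
  } else {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  structure(list(precision = p, recall = r, f1 = f1,
                 mean_ed = if (tp > 0) mean(report$tp$distance) else NA_real_,
                 tp = tp, fp = fp, fn = fn),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("P %.4f  R %.4f  F1 %.4f  mean ED %s  (TP %d FP %d FN %d)\n",
              x$precision, x$recall, x$f1,
              ifelse(is.na(x$mean_ed), "NA", sprintf("%.3f", x$mean_ed)),
              x$tp, x$fp, x$fn))
  invisible(x)
}

# evaluate pooled counts for a fixed xi over predicted maps + annotations
pooled_metrics_at_xi <- function(maps, annotations, xi, radius,
                                 min_distance = 6) {
  tp <- fp <- fn <- 0L; dists <- numeric(0)
  for (i in seq_along(maps)) {
    rep_i <- match_detections(detect(maps[[i]], xi, min_distance),
                              annotations[[i]], radius)
    tp <- tp + nrow(rep_i$tp); fp <- fp + length(rep_i$fp)
    fn <- fn + length(rep_i$fn)
    dists <- c(dists, rep_i$tp$distance)
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
       mean_ed = if (length(dists)) mean(dists) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' Precision-recall curve over a threshold grid
#'
#' For each `xi` in the grid, detections are recomputed on every sample's
#' predicted map and TP/FP/FN counts are pooled over the samples
#' (micro-averaging) to give one precision/recall point.
#'
#' @param network a trained `proxi_net`.
#' @param samples list of `synth_sample`s (or lists with `image` and
#'   `centers`).
#' @param xi_grid numeric vector of thresholds in `[0, 1]`.
#' @param radius gold-region radius (default 16).
#' @param min_distance local-maxima neighborhood radius (default 6).
#' @param maps optional precomputed predicted maps (recycled across `xi`,
#'   avoids redundant forward passes).
#' @return data.frame with columns `xi`, `precision`, `recall`, `f1`.
#' @export
pr_curve <- function(network, samples, xi_grid, radius = 16,
                     min_distance = 6, maps = NULL) {
  stopifnot(length(xi_grid) >= 1)
  xi_grid <- sort(xi_grid)
  if (is.null(maps))
    maps <- lapply(samples, function(s) predict_map(network, s))
  anns <- lapply(samples, function(s) s$centers)
  rows <- lapply(xi_grid, function(xi) {
    m <- pooled_metrics_at_xi(maps, anns, xi, radius, min_distance)
    data.frame(xi = xi, precision = m$precision, recall = m$recall,
               f1 = m$f1)
  })
  do.call(rbind, rows)
}

#' Select the detection threshold on a validation set
#'
#' Returns the grid value of `xi` with the best pooled validation F1
#' score; ties are broken toward the larger threshold.
#'
#' @inheritParams pr_curve
#' @return the selected `xi` (scalar).
#' @export
select_xi <- function(network, samples, xi_grid, radius = 16,
                      min_distance = 6, maps = NULL) {
  stopifnot(length(samples) >= 1)
  curve <- pr_curve(network, samples, xi_grid, radius, min_distance, maps)
  best <- max(curve$f1)
  max(curve$xi[curve$f1 >= best - 1e-12])
}

#' Aggregate metric summaries across datasets
#'
#' @param summaries list of `metric_summary` objects (>= 1).
#' @return data.frame with one row per metric (`precision`, `recall`,
#'   `f1`, `mean_ed`) and columns `mean`, `sd` (sample standard deviation;
#'   0 for a single summary).
#' @export
aggregate_metrics <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  get <- function(f) vapply(summaries, function(s) s[[f]], numeric(1))
  mets <- c("precision", "recall", "f1", "mean_ed")
  out <- data.frame(
    metric = mets,
    mean = vapply(mets, function(f) mean(get(f)), numeric(1)),
    sd = vapply(mets, function(f)
      if (length(summaries) > 1) sd(get(f)) else 0, numeric(1)),
    row.names = NULL)
  out
}
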