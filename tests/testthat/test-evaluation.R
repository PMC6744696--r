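# Hungarian matching against the exhaustive assignment oracle, metric
# conventions, PR curves and threshold selection.

test_that("matching handles the canonical single-pair cases", {
  r <- match_detections(rbind(c(10, 10)), rbind(c(10, 10)), radius = 16)
  expect_equal(nrow(r$tp), 1)
  expect_equal(r$tp$distance, 0)
  # a detection 17 px away from the only annotation is not matched
  r2 <- match_detections(rbind(c(10, 27)), rbind(c(10, 10)), radius = 16)
  expect_equal(nrow(r2$tp), 0)
  expect_equal(r2$fp, 1L)
  expect_equal(r2$fn, 1L)
})

test_that("matching picks the minimum-cost assignment", {
  ann <- rbind(c(10, 10), c(30, 30))
  det <- rbind(c(12, 10), c(29, 31), c(50, 50))
  r <- match_detections(det, ann, radius = 16)
  expect_equal(nrow(r$tp), 2)
  expect_equal(sort(r$tp$distance), sort(c(2, sqrt(2))))
  expect_equal(r$fp, 3L)
  expect_equal(length(r$fn), 0)
})

test_that("hungarian equals exhaustive minimum cost on small instances", {
  set.seed(42)
  for (trial in 1:60) {
    nd <- sample(0:7, 1); na <- sample(0:7, 1)
    det <- cbind(runif(nd, 0, 40), runif(nd, 0, 40))
    ann <- cbind(runif(na, 0, 40), runif(na, 0, 40))
    radius <- runif(1, 5, 20)
    r <- match_detections(det, ann, radius)
    # count conservation
    expect_equal(nrow(r$tp) + length(r$fn), na)
    expect_equal(nrow(r$tp) + length(r$fp), nd)
    expect_true(all(r$tp$distance <= radius))
    if (nd > 0 && na > 0) {
      D <- sqrt(outer(det[, 1], ann[, 1], "-")^2 +
                  outer(det[, 2], ann[, 2], "-")^2)
      sentinel <- (max(nd, na) + 1) * (radius + 1)
      cost <- ifelse(D <= radius, D, sentinel)
      best <- if (nd <= na) brute_assignment_cost(cost)
              else brute_assignment_cost(t(cost))
      got <- sum(r$tp$distance) +
        sentinel * (min(nd, na) - nrow(r$tp))
      expect_equal(got, best, tolerance = 1e-9)
    }
  }
})

test_that("matching is invariant to the ordering of the point lists", {
  set.seed(7)
  det <- cbind(runif(6, 0, 30), runif(6, 0, 30))
  ann <- cbind(runif(5, 0, 30), runif(5, 0, 30))
  r1 <- match_detections(det, ann, 10)
  p <- sample(6); q <- sample(5)
  r2 <- match_detections(det[p, ], ann[q, ], 10)
  expect_equal(nrow(r1$tp), nrow(r2$tp))
  expect_equal(sort(r1$tp$distance), sort(r2$tp$distance))
})

test_that("metrics implement the printed formulas and conventions", {
  # TP 8, FP 2, FN 2
  set.seed(8)
  ann <- cbind(seq(5, 75, by = 10), rep(10, 8))
  det <- rbind(ann + 0.5, c(60, 60), c(70, 70))
  ann <- rbind(ann, c(40, 80), c(50, 90))
  m <- metrics(match_detections(det, ann, 16))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  # degenerate conventions
  m0 <- metrics(match_detections(matrix(numeric(0), 0, 2),
                                 rbind(c(1, 1)), 16))
  expect_equal(c(m0$precision, m0$recall, m0$f1), c(0, 0, 0))
  m1 <- metrics(match_detections(matrix(numeric(0), 0, 2),
                                 matrix(numeric(0), 0, 2), 16))
  expect_equal(c(m1$precision, m1$recall, m1$f1), c(1, 1, 1))
  mp <- metrics(match_detections(rbind(c(3, 3)), rbind(c(3, 3)), 16))
  expect_equal(mp$f1, 1)
  expect_equal(mp$mean_ed, 0)
})

test_that("pr_curve pools counts and recall decreases with xi", {
  # use gold maps as perfect predictions, plus one corrupted map
  samples <- lapply(1:4, function(i) generate_image(synth_style(), 64, 64, i))
  maps <- lapply(samples, function(s)
    proximity_map(s$centers, 64, 64))
  curve <- pr_curve(NULL, samples, xi_grid = seq(0.1, 0.9, by = 0.2),
                    radius = 16, min_distance = 4, maps = maps)
  expect_equal(nrow(curve), 5)
  expect_true(all(diff(curve$recall) <= 1e-12))
  # one-element grid equals pooled metrics at that xi
  c1 <- pr_curve(NULL, samples, 0.5, 16, 4, maps = maps)
  pm <- proxidet:::pooled_metrics_at_xi(maps,
    lapply(samples, `[[`, "centers"), 0.5, 16, 4)
  expect_equal(c1$precision, pm$precision)
  expect_equal(c1$recall, pm$recall)
})

test_that("select_xi maximizes grid F1 with ties toward larger xi", {
  samples <- lapply(1:3, function(i) generate_image(synth_style(), 64, 64, 10 + i))
  maps <- lapply(samples, function(s) proximity_map(s$centers, 64, 64))
  grid <- seq(0.1, 0.9, by = 0.1)
  xi <- select_xi(NULL, samples, grid, 16, 4, maps = maps)
  curve <- pr_curve(NULL, samples, grid, 16, 4, maps = maps)
  expect_equal(max(curve$f1[abs(curve$xi - xi) < 1e-9]), max(curve$f1))
  # exhaustive check: no grid point does better
  expect_true(all(curve$f1 <= curve$f1[abs(curve$xi - xi) < 1e-9] + 1e-12))
  # ties: gold maps give perfect detection at every xi here -> largest wins
  if (max(curve$f1) == 1 && min(curve$f1) == 1) expect_equal(xi, 0.9)
  expect_equal(select_xi(NULL, samples, 0.35, 16, 4, maps = maps), 0.35)
})

test_that("aggregate reports mean and sample sd per metric", {
  ms <- lapply(c(0.8, 0.9, 0.85), function(f)
    structure(list(precision = f, recall = f - 0.05, f1 = f - 0.02,
                   mean_ed = 2 * f, tp = 1, fp = 1, fn = 1),
              class = "metric_summary"))
  ag <- aggregate_metrics(ms)
  expect_equal(ag$mean[ag$metric == "precision"], mean(c(0.8, 0.9, 0.85)))
  expect_equal(ag$sd[ag$metric == "precision"], sd(c(0.8, 0.9, 0.85)))
  ag1 <- aggregate_metrics(ms[1])
  expect_true(all(ag1$sd == 0))
  ag2 <- aggregate_metrics(ms[c(1, 1)])
  expect_true(all(ag2$sd == 0))
})
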