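# Config-driven experiment orchestration: synthesize corpora, train
# (optionally with an auxiliary source / fine-tuning), select the
# detection threshold on validation data, evaluate on held-out test
# images, and write all artifacts with a hash manifest.

default_experiment_config <- function() {
  list(
    seed = 1L,
    network = list(base_width = 8, depth = 4, dropout_rate = 0.5,
                   output_scale = 5),
    encoding = list(alpha = 3, d = 15, scale = 5),
    loss = list(lam = 5, gamma = 1),
    training = list(profile = "desk"),
    evaluation = list(radius = 16, min_distance = 6,
                      xi_grid = seq(0.1, 0.9, by = 0.1)),
    data = list(synthetic = list(height = 64, width = 64, n_images = 60,
                                 style = list(style_id = "target")))
  )
}

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_experiment_config(), config)
  if (!is.null(cfg$network$output_scale) &&
      cfg$network$output_scale != cfg$encoding$scale)
    stop("config inconsistency: network output_scale must equal encoding scale")
  cfg
}

# YAML sequences with mixed numeric types arrive as lists; flatten them
flatten_cfg <- function(cfg) lapply(cfg, function(x)
  if (is.list(x) && !is.list(x[[1]])) unlist(x) else x)

build_style <- function(style_cfg) do.call(synth_style, flatten_cfg(style_cfg))

build_train_config <- function(tcfg, ecfg, seed) {
  tcfg <- flatten_cfg(tcfg)
  profile <- tcfg$profile %||% "paper"
  tcfg$profile <- NULL
  tcfg$seed <- tcfg$seed %||% seed
  tcfg$radius <- tcfg$radius %||% ecfg$radius
  tcfg$min_distance <- tcfg$min_distance %||% ecfg$min_distance
  if (!is.null(ecfg$xi_grid)) tcfg$xi_grid <- unlist(ecfg$xi_grid)
  if (profile == "desk") do.call(desk_config, tcfg)
  else do.call(train_config, tcfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment end to end
#'
#' Generates the seeded synthetic corpus described in the config (target
#' and optionally auxiliary styles), splits it into disjoint
#' train/validation/test sets, trains the network (optionally fine-tuning
#' from a base checkpoint and/or mixing an auxiliary source under the
#' loss-balance weight gamma), selects the detection threshold on the
#' validation set, evaluates on the test set, and writes checkpoint,
#' logs, detections, report, PR curve, the resolved config and a hash
#' manifest into `out_dir`.
#'
#' @param config path to a YAML config or an equivalent named list.
#' @param out_dir output directory (created; pre-existing artifacts are
#'   overwritten).
#' @param verbose print progress.
#' @return (invisibly) a list with `report`, `network`, `history`.
#' @export
run_experiment <- function(config, out_dir, verbose = FALSE) {
  cfg <- resolve_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  enc <- do.call(proximity_params, cfg$encoding)
  lp <- do.call(loss_params, cfg$loss)
  tc <- build_train_config(cfg$training, cfg$evaluation, cfg$seed)
  sy <- cfg$data$synthetic
  style <- build_style(sy$style)
  corpus <- generate_dataset(style, sy$n_images, sy$height, sy$width,
                             cfg$seed)
  sp <- split_dataset(corpus, cfg$seed + 1L,
                      sy$split$test_fraction %||% 0.5,
                      sy$split$val_fraction %||% 0.2)
  aux_src <- NULL
  if (!is.null(cfg$data$auxiliary)) {
    au <- cfg$data$auxiliary
    aux_corpus <- generate_dataset(build_style(au$style),
                                   au$n_images %||% sy$n_images,
                                   sy$height, sy$width, cfg$seed + 1000L)
    aux_src <- data_source(aux_corpus, "auxiliary",
                           au$fraction %||% 1)
  }
  set.seed(cfg$seed)
  net <- build_network(do.call(network_spec, cfg$network))
  fit <- if (!is.null(cfg$base_checkpoint))
    fine_tune(cfg$base_checkpoint, data_source(sp$train), sp$val, tc,
              frozen_blocks = cfg$frozen_blocks %||% 0, lparams = lp,
              encoding = enc, auxiliary = aux_src, verbose = verbose)
  else
    train(net, data_source(sp$train), sp$val, tc, lp, enc,
          auxiliary = aux_src, verbose = verbose)
  xi <- fit$best_xi
  ev <- cfg$evaluation
  test_maps <- lapply(sp$test, function(s) predict_map(fit$network, s))
  pooled <- pooled_metrics_at_xi(test_maps,
                                 lapply(sp$test, function(s) s$centers),
                                 xi, ev$radius, ev$min_distance)
  curve <- pr_curve(fit$network, sp$test, unlist(ev$xi_grid), ev$radius,
                    ev$min_distance, maps = test_maps)
  dets <- lapply(test_maps, detect, xi = xi,
                 min_distance = ev$min_distance)
  ids <- sprintf("test_%03d", seq_along(dets))
  write_annotations(stats::setNames(lapply(dets, `[[`, "points"), ids),
                    file.path(out_dir, "detections.csv"),
                    stats::setNames(lapply(dets, `[[`, "scores"), ids))
  write_annotations(stats::setNames(lapply(sp$test, `[[`, "centers"), ids),
                    file.path(out_dir, "annotations.csv"))
  report <- list(
    seed = cfg$seed, selected_xi = xi, val_f1 = fit$val_f1,
    test = pooled,
    n_train = length(sp$train), n_val = length(sp$val),
    n_test = length(sp$test))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(curve, file.path(out_dir, "pr_curve.csv"), row.names = FALSE)
  write.csv(fit$history, file.path(out_dir, "history.csv"),
            row.names = FALSE)
  save_checkpoint(fit$network, file.path(out_dir, "checkpoint.rds"),
                  enc, cfg$seed)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  write_manifest(out_dir)
  invisible(list(report = report, network = fit$network,
                 history = fit$history))
}

#' @importFrom stats setNames
NULL
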