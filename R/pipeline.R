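#' Default run configuration
#'
#' All tunables of the end-to-end pipeline in one validated list: amide-I
#' mask threshold (0.30 AU), baseline anchors, classifier settings, phantom
#' parameters for the simulated train/validation pair, the ROC operating
#' point (Pfa 0.10) and the master seed. Unknown keys in an override are
#' rejected.
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    rows = 64L, cols = 64L, snr = 500, boundary_mixing = TRUE,
    n_fibrosis = 2L, n_foci = 3L, focus_radius = 5,
    threshold = 0.30, anchors = default_anchors(),
    k_per_class = 5L, priors = NULL, weights = "auc",
    likelihood = "gaussian", posterior_threshold = 0.5,
    pfa_target = 0.10, band = 1236,
    expand_metrics = FALSE, seed = 1L, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  stopifnot(cfg$threshold > 0, cfg$pfa_target >= 0, cfg$pfa_target <= 1,
            cfg$k_per_class >= 1, cfg$posterior_threshold >= 0,
            cfg$posterior_threshold <= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys of [run_config()].
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$anchors)) vals$anchors <- lapply(vals$anchors, as.numeric)
  do.call(run_config, vals)
}

#' Run the full simulate-to-render pipeline
#'
#' Executes the stage sequence simulate (train + validation phantoms) ->
#' preprocess -> features -> train -> classify -> evaluate -> render, writing
#' every artifact, the resolved configuration and a log to `out_dir`.
#' Re-running with the same configuration and seed reproduces all numeric
#' artifacts bit-exact.
#'
#' Artifacts written: validation cube (`validation_cube`, ENVI pair), mask
#' and truth rasters, model JSON, class map raster, confusion CSV, per-class
#' Pd at the configured Pfa CSV, ROC CSVs, rejection-report JSON, band and
#' class-map PNGs with legend CSV, resolved config YAML, `run_log.txt`.
#'
#' @param config a [run_config()]; `out_dir` must be set.
#' @return (invisibly) a list with the fitted model, evaluation tables and
#'   artifact paths.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$out_dir)) stop("config$out_dir must be set", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  logf <- out("run_log.txt")
  cat("", file = logf)
  t_all <- proc.time()[3]
  stage_times <- c()
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  stage <- local({
    t_last <- proc.time()[3]
    function(name) {
      t_now <- proc.time()[3]
      stage_times[name] <<- t_now - t_last
      t_last <<- t_now
      log_line("stage %-12s %8.2f s", name, stage_times[name])
    }
  })
  run_stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    stage(name)
    res
  }

  cfg_plain <- unclass(config)
  cfg_yaml <- out("config.yaml")
  yaml::write_yaml(cfg_plain[!vapply(cfg_plain, is.null, logical(1))], cfg_yaml)
  log_line("config hash %s; seed %d; irheart %s",
           substr(paste(tools::md5sum(cfg_yaml)), 1, 12), config$seed,
           as.character(utils::packageVersion("irheart")))

  library_ <- default_class_library()
  mk_spec <- function(seed) phantom_spec(
    rows = config$rows, cols = config$cols, snr = config$snr,
    boundary_mixing = config$boundary_mixing, n_fibrosis = config$n_fibrosis,
    n_foci = config$n_foci, focus_radius = config$focus_radius, seed = seed)
  sim <- run_stage("simulate", {
    train <- synth_phantom(mk_spec(config$seed), library_)
    valid <- synth_phantom(mk_spec(config$seed + 1L), library_)
    write_cube(valid$cube, out("validation_cube"))
    write_label_raster(valid$truth$labels, out("validation_truth"))
    list(train = train, valid = valid)
  })

  defs <- default_metric_library(expand = config$expand_metrics)
  pp <- run_stage("preprocess", {
    tr <- preprocess_cube(sim$train$cube, config$threshold, config$anchors)
    va <- preprocess_cube(sim$valid$cube, config$threshold, config$anchors)
    list(train = tr, valid = va)
  })
  log_line("masked-out pixels: train %d, validation %d",
           sum(!pp$train$mask$keep), sum(!pp$valid$mask$keep))

  feats <- run_stage("features", {
    list(train = compute_features(pp$train$cube, pp$train$mask, defs),
         valid = compute_features(pp$valid$cube, pp$valid$mask, defs))
  })

  model <- run_stage("train", {
    m <- ir_bayes(feats$train, sim$train$truth$labels, metric_library = defs,
                  k_per_class = config$k_per_class, priors = config$priors,
                  likelihood = config$likelihood, weights = config$weights,
                  posterior_threshold = config$posterior_threshold)
    write_model(m, out("model.json"))
    m
  })

  cls <- run_stage("classify", {
    post <- posterior_map(feats$valid, model)
    pred <- classify_map(post, pp$valid$mask, model)
    write_label_raster(pred, out("class_map"))
    list(post = post, pred = pred)
  })
  log_line("unclassified among kept pixels: %d",
           sum(cls$pred == 0L & pp$valid$mask$keep))

  ev <- run_stage("evaluate", {
    truth <- sim$valid$truth$labels
    conf <- confusion(cls$pred, truth, pp$valid$mask)
    utils::write.csv(round(conf$percent, 4), out("confusion_percent.csv"))
    utils::write.csv(conf$counts, out("confusion_counts.csv"))
    pd <- data.frame(class = character(), pd = numeric(), auc = numeric())
    for (cc in 1:5) {
      curve <- roc_one_vs_rest(cls$post, cc, truth, pp$valid$mask)
      utils::write.csv(curve$points, out(sprintf("roc_class%d.csv", cc)),
                       row.names = FALSE)
      pd <- rbind(pd, data.frame(class = class_name(cc),
                                 pd = pd_at_pfa(curve, config$pfa_target),
                                 auc = curve$auc))
    }
    utils::write.csv(pd, out("pd_at_pfa.csv"), row.names = FALSE)
    rej <- rejection_report(cls$pred)
    jsonlite::write_json(unclass(rej), out("rejection_report.json"),
                         auto_unbox = TRUE, digits = I(17))
    list(confusion = conf, pd_table = pd, rejection = rej)
  })

  run_stage("render", {
    write_gray_png(band_image(sim$valid$cube, config$band, pp$valid$mask,
                              config$anchors), out("band_1236.png"))
    img <- class_image(cls$pred)
    write_rgb_png(img, out("class_map.png"))
    utils::write.csv(attr(img, "legend"), out("class_map_legend.csv"),
                     row.names = FALSE)
    NULL
  })
  log_line("total %.2f s", proc.time()[3] - t_all)
  invisible(list(model = model, confusion = ev$confusion,
                 pd_table = ev$pd_table, rejection = ev$rejection,
                 pred = cls$pred, out_dir = config$out_dir))
}
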