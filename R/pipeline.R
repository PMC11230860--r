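#' End-to-end pipeline stages with file-based provenance
#'
#' Four stages mirror a full study run: `run_generate()` writes the synthetic
#' training tables and screening library; `run_train()` fits the three
#' per-target models and reports their held-out test metrics; `run_screen()`
#' ranks the library by ensemble score; `run_validate()` produces the
#' balanced-resampling threshold-sweep table. Every stage echoes its
#' configuration, seeds and the package version to a JSON provenance record,
#' and all tabular outputs are deterministic CSV. A thin command-line wrapper
#' over these functions ships in `inst/scripts/mpnnscreen.R`.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Defaults mirror the study design: 1000 balanced repetitions, thresholds
#' 0.5/0.6/0.7/0.8/0.9/0.95, a 70/10/20 stratified split, the 1024/1024/512
#' head with learning rate 0.001 and batch size 128, and the study-sized
#' synthetic populations. Stage seeds are derived from the single master
#' seed.
#'
#' @param out_dir directory for all stage outputs.
#' @param seed master seed.
#' @param scale proportional size factor passed to [synthetic_spec()].
#' @param epochs training epochs (see [model_config()]).
#' @param n_reps balanced-resampling repetitions.
#' @param thresholds threshold sweep.
#' @param spec,model,split,screen optional pre-built configuration objects
#'   overriding the derived defaults.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "mpnnscreen_run", seed = 101L,
                            scale = 1, epochs = 100L, n_reps = 1000L,
                            thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95),
                            spec = NULL, model = NULL, split = NULL,
                            screen = NULL) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    spec = spec %||% synthetic_spec(seed = derive_seed(seed, "generate"),
                                    scale = scale),
    model = model %||% model_config(epochs = epochs,
                                    seed = derive_seed(seed, "model")),
    split = split %||% split_config(seed = derive_seed(seed, "splitcfg")),
    screen = screen %||% screening_config(),
    n_reps = as.integer(n_reps),
    thresholds = thresholds
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `out_dir`, `seed`, `scale`, `epochs`, `n_reps`,
#' `thresholds`, `threshold`. Anything omitted keeps its default; overrides
#' are echoed in the stage provenance records.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("out_dir", "seed", "scale", "epochs",
                                  "n_reps", "thresholds"))]
  cfg <- do.call(pipeline_config, args)
  if (!is.null(y$threshold)) cfg$screen <- screening_config(y$threshold)
  cfg
}

.provenance <- function(config, stage, extra = list()) {
  c(list(stage = stage,
         package = "mpnnscreen",
         version = as.character(utils::packageVersion("mpnnscreen")),
         timestamp = format(Sys.time(), tz = "UTC"),
         seed = config$seed),
    extra)
}

.stage_paths <- function(config) {
  targets <- names(config$spec$motif_per_target)
  list(
    train_csv = file.path(config$out_dir,
                          sprintf("train_%s.csv", targets)),
    screen_csv = file.path(config$out_dir, "screen_library.csv"),
    sidecar = file.path(config$out_dir, "synthetic_spec.json"),
    models = file.path(config$out_dir, sprintf("model_%s.rds", targets)),
    loss_logs = file.path(config$out_dir, sprintf("loss_%s.csv", targets)),
    test_metrics = file.path(config$out_dir, "test_metrics.csv"),
    ranked = file.path(config$out_dir, "screen_ranked.csv"),
    screen_summary = file.path(config$out_dir, "screen_summary.json"),
    validation = file.path(config$out_dir, "validation_table.csv"),
    validation_json = file.path(config$out_dir, "validation_report.json")
  )
}

#' @rdname pipeline
#' @param config a [pipeline_config()].
#' @return `run_generate()`: the written file paths, invisibly.
#' @export
run_generate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    io_error(sprintf("cannot create output directory '%s'", config$out_dir))
  p <- .stage_paths(config)
  targets <- names(config$spec$motif_per_target)
  for (k in seq_along(targets)) {
    tr <- rbind(generate_actives(config$spec, targets[k]),
                generate_decoys(config$spec, targets[k]))
    write_molecule_table(tr, p$train_csv[k])
  }
  lib <- generate_screening_library(config$spec)
  write_molecule_table(lib, p$screen_csv)
  write_spec_sidecar(config$spec, p$sidecar)
  jsonlite::write_json(.provenance(config, "generate",
                                   list(files = c(p$train_csv, p$screen_csv))),
                       file.path(config$out_dir, "generate_provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' @rdname pipeline
#' @param quiet suppress training progress.
#' @return `run_train()`: list with `models` (named list) and `metrics`
#'   (data.frame rows per target, columns AUROC/AUPRC/F1), invisibly.
#' @export
run_train <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- .stage_paths(config)
  targets <- names(config$spec$motif_per_target)
  models <- list()
  metrics <- data.frame(target = targets, AUROC = NA_real_, AUPRC = NA_real_,
                        F1 = NA_real_)
  for (k in seq_along(targets)) {
    if (!file.exists(p$train_csv[k]))
      io_error(sprintf("training table not found: %s (run_generate first?)",
                       p$train_csv[k]))
    rec <- read_molecule_table(p$train_csv[k])
    ds <- assemble_training_set(rec[rec$label == 1L, ],
                                rec[rec$label == 0L, ], targets[k])
    sp <- split_dataset(ds, config$split)
    mdl <- train_model(sp$train, sp$valid, config$model, quiet = quiet)
    save_model(mdl, p$models[k])
    utils::write.csv(mdl$history, p$loss_logs[k], row.names = FALSE)
    m <- evaluate_model_on_test(mdl, sp$test,
                                threshold = config$screen$threshold)
    metrics$AUROC[k] <- m$auroc
    metrics$AUPRC[k] <- m$auprc
    metrics$F1[k] <- m$f1
    models[[targets[k]]] <- mdl
  }
  utils::write.csv(metrics, p$test_metrics, row.names = FALSE)
  jsonlite::write_json(.provenance(config, "train",
                                   list(files = c(p$models, p$test_metrics))),
                       file.path(config$out_dir, "train_provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(models = models, metrics = metrics))
}

.load_stage_models <- function(config) {
  p <- .stage_paths(config)
  targets <- names(config$spec$motif_per_target)
  models <- list()
  for (k in seq_along(targets)) {
    if (!file.exists(p$models[k]))
      io_error(sprintf("model artifact not found: %s (run_train first?)",
                       p$models[k]))
    models[[targets[k]]] <- load_model(p$models[k])
  }
  models
}

#' @rdname pipeline
#' @param models optional named list of trained models (otherwise loaded from
#'   the stage artifacts).
#' @return `run_screen()`: the ranked score table, invisibly.
#' @export
run_screen <- function(config, models = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- .stage_paths(config)
  if (!file.exists(p$screen_csv))
    io_error(sprintf("screening library not found: %s", p$screen_csv))
  models <- models %||% .load_stage_models(config)
  lib <- read_molecule_table(p$screen_csv)
  ranked <- screen_library(models, lib, config$screen)
  utils::write.csv(ranked, p$ranked, row.names = FALSE)
  jsonlite::write_json(c(.provenance(config, "screen"),
                         attr(ranked, "summary")),
                       p$screen_summary, auto_unbox = TRUE, digits = NA)
  invisible(ranked)
}

#' @rdname pipeline
#' @param ranked optional ranked score table from [run_screen()] (otherwise
#'   read from the stage CSV).
#' @return `run_validate()`: the `resampling_report`, invisibly.
#' @export
run_validate <- function(config, ranked = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- .stage_paths(config)
  if (is.null(ranked)) {
    if (!file.exists(p$ranked))
      io_error(sprintf("ranked screen table not found: %s", p$ranked))
    ranked <- utils::read.csv(p$ranked, stringsAsFactors = FALSE)
  }
  if (!"label" %in% names(ranked))
    format_error("ranked table lacks ground-truth labels")
  report <- balanced_resampling_validation(
    ranked, thresholds = config$thresholds, n_reps = config$n_reps,
    seed = derive_seed(config$seed, "validate"))
  utils::write.csv(as.data.frame(report), p$validation, row.names = FALSE)
  jsonlite::write_json(
    c(.provenance(config, "validate"),
      list(n_reps = report$n_reps, n_sample = report$n_sample,
           counts = report$counts,
           metrics_of_mean_counts = report$metrics_of_mean_counts,
           mean_of_metrics = report$mean_of_metrics,
           n_excluded = report$n_excluded)),
    p$validation_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
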