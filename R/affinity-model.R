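#' Per-target binding likelihood models
#'
#' Each target gets its own predictor: a directed message-passing encoder over
#' the molecular graph followed by a feed-forward head with hidden widths
#' 1024/1024/512, a sigmoid output bounded to \[0, 1\], trained with
#' minibatch MSE against binary activity labels (learning rate 0.001, batch
#' size 128; the study regime is 100 epochs). The 70/10/20
#' train/validation/test split is stratified by label, and the parameters from
#' the epoch with the lowest validation loss are retained.
#'
#' @name affinity_model
NULL

#' Model architecture and training configuration
#'
#' @param hidden_layers feed-forward head widths; default `c(1024, 1024, 512)`.
#' @param epochs training epochs; the study regime is 100 (the packaged
#'   synthetic benchmark uses 30, which saturates on the constructed signal).
#' @param learning_rate Adam learning rate, default 0.001.
#' @param batch_size minibatch size, default 128.
#' @param loss only `"mse"` is supported (the study's choice).
#' @param mp_depth message-passing steps, default 3.
#' @param mp_hidden message/hidden dimension of the encoder, default 64.
#' @param seed seed controlling weight initialisation and shuffling.
#' @param select `"best_valid"` (retain the epoch with lowest validation
#'   loss) or `"last"`.
#' @return an object of class `model_config`.
#' @export
model_config <- function(hidden_layers = c(1024L, 1024L, 512L),
                         epochs = 100L, learning_rate = 0.001,
                         batch_size = 128L, loss = "mse",
                         mp_depth = 3L, mp_hidden = 64L, seed = 1L,
                         select = c("best_valid", "last")) {
  select <- match.arg(select)
  if (any(hidden_layers <= 0) || length(hidden_layers) < 1L)
    config_error("'hidden_layers' must be positive widths")
  if (epochs < 1L) config_error("'epochs' must be >= 1")
  if (learning_rate <= 0) config_error("'learning_rate' must be positive")
  if (batch_size < 1L) config_error("'batch_size' must be >= 1")
  if (!identical(loss, "mse")) config_error("only loss = 'mse' is supported")
  if (mp_depth < 1L || mp_hidden < 1L)
    config_error("'mp_depth' and 'mp_hidden' must be >= 1")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), loss = loss,
                 mp_depth = as.integer(mp_depth),
                 mp_hidden = as.integer(mp_hidden),
                 seed = as.integer(seed), select = select),
            class = "model_config")
}

#' Train/validation/test split configuration
#'
#' @param fractions named fractions summing to 1; default 70/10/20.
#' @param seed split seed.
#' @param stratified stratify by label (default TRUE; avoids degenerate class
#'   ratios in small balanced datasets).
#' @return an object of class `split_config`.
#' @export
split_config <- function(fractions = c(train = 0.7, valid = 0.1, test = 0.2),
                         seed = 1L, stratified = TRUE) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    config_error("'fractions' must be three nonnegative numbers summing to 1")
  names(fractions) <- c("train", "valid", "test")
  stopifnot_flag(stratified, "stratified")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratified = stratified), class = "split_config")
}

.make_labeled <- function(records, target) {
  rownames(records) <- NULL
  structure(list(records = records, target = target),
            class = "labeled_dataset")
}

# floor each split's share, remainder to train
.split_sizes <- function(n, fractions) {
  sz <- floor(n * fractions)
  sz["train"] <- sz["train"] + (n - sum(sz))
  sz
}

#' Partition a labeled dataset into train/validation/test
#'
#' Sizes are the floored fractions of the input with the remainder assigned to
#' the training split (so 400 molecules yield 280/40/80 and 302 yield
#' 212/30/60). With stratification the rule is applied within each label
#' class. The partition is disjoint, covers the input, and is deterministic
#' for a fixed seed.
#'
#' @param dataset a [labeled_dataset()].
#' @param cfg a [split_config()].
#' @return a list of three `labeled_dataset`s: `train`, `valid`, `test`.
#' @export
split_dataset <- function(dataset, cfg = split_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(cfg, "split_config"))
  rec <- dataset$records
  n <- nrow(rec)
  if (n < 10L) split_error("dataset too small to split (need >= 10 molecules)")
  assign_split <- function(idx) {
    sz <- .split_sizes(length(idx), cfg$fractions)
    idx <- idx[sample.int(length(idx))]
    split(idx, rep(c("train", "valid", "test"), sz[c("train", "valid", "test")]))
  }
  parts <- with_seed(derive_seed(cfg$seed, "split"), {
    if (cfg$stratified) {
      by_class <- split(seq_len(n), rec$label)
      merged <- list(train = integer(0), valid = integer(0), test = integer(0))
      for (cls in by_class) {
        p <- assign_split(cls)
        for (nm in names(merged))
          merged[[nm]] <- c(merged[[nm]], p[[nm]] %||% integer(0))
      }
      merged
    } else assign_split(seq_len(n))
  })
  if (cfg$stratified) {
    classes <- unique(rec$label)
    for (nm in c("train", "valid", "test")) {
      if (cfg$fractions[nm] > 0 &&
          !all(classes %in% rec$label[parts[[nm]]]))
        split_error(sprintf(
          "stratified split '%s' received 0 items of a label class", nm))
    }
  }
  lapply(parts[c("train", "valid", "test")], function(idx)
    .make_labeled(rec[sort(idx), , drop = FALSE], dataset$target))
}

# featurize every record; training data must be fully parseable
.featurize_records <- function(records, spec = feature_spec()) {
  graphs <- parse_smiles_batch(records$smiles, allow_invalid = FALSE)
  lapply(graphs, featurize, spec = spec)
}

#' Train one target's binding likelihood model
#'
#' Runs exactly `cfg$epochs` epochs of minibatch Adam on the MSE between the
#' sigmoid-bounded prediction and the 0/1 labels, recording the full per-epoch
#' loss history. With `select = "best_valid"` the returned parameters are
#' those of the epoch with the lowest validation loss.
#'
#' @param train,valid [labeled_dataset()]s; `valid` may be `NULL`, in which
#'   case the last epoch's parameters are returned.
#' @param cfg a [model_config()].
#' @param quiet suppress per-epoch progress messages.
#' @return an object of class `trained_target_model` with fields `target`,
#'   `params`, `config`, `feature_spec`, `history` (epoch, train_loss,
#'   valid_loss), `seeds`.
#' @export
train_model <- function(train, valid = NULL, cfg = model_config(),
                        quiet = TRUE) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(cfg, "model_config"))
  rec <- train$records
  if (nrow(rec) == 0L) training_error("empty training set")
  if (length(unique(rec$label)) < 2L)
    training_error("training set must contain both classes")
  fspec <- feature_spec()
  feats <- .featurize_records(rec, fspec)
  y <- as.numeric(rec$label)
  vbatch <- NULL
  vy <- NULL
  if (!is.null(valid) && nrow(valid$records) > 0L) {
    vfeats <- .featurize_records(valid$records, fspec)
    vbatch <- mpnn_batch(vfeats)
    vy <- as.numeric(valid$records$label)
  }
  params <- mpnn_init_params(fspec$d_atom, fspec$d_bond, cfg$mp_hidden,
                             cfg$hidden_layers,
                             seed = derive_seed(cfg$seed, "init"))
  state <- adam_init(params)
  n <- length(y)
  history <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                        valid_loss = NA_real_)
  best <- list(loss = Inf, params = params, epoch = 0L)
  shuffle_seed <- derive_seed(cfg$seed, "shuffle")
  for (ep in seq_len(cfg$epochs)) {
    idx <- with_seed(shuffle_seed + ep, sample.int(n))
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      bi <- idx[s:min(s + cfg$batch_size - 1L, n)]
      batch <- mpnn_batch(feats[bi])
      fw <- mpnn_forward(params, batch, cfg$mp_depth, keep_cache = TRUE)
      loss <- mean((fw$scores - y[bi])^2)
      if (!is.finite(loss))
        training_error(sprintf("non-finite training loss at epoch %d", ep),
                       epoch = ep)
      ep_loss <- ep_loss + loss * length(bi)
      grads <- mpnn_backward(params, batch, fw$cache, y[bi], cfg$mp_depth)
      upd <- adam_step(params, grads, state, cfg$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    history$train_loss[ep] <- ep_loss / n
    if (!is.null(vbatch)) {
      vs <- mpnn_forward(params, vbatch, cfg$mp_depth)$scores
      vloss <- mean((vs - vy)^2)
      history$valid_loss[ep] <- vloss
      if (vloss < best$loss)
        best <- list(loss = vloss, params = params, epoch = ep)
    }
    if (!quiet)
      message(sprintf("epoch %3d  train %.5f  valid %s", ep,
                      history$train_loss[ep],
                      ifelse(is.null(vbatch), "-",
                             sprintf("%.5f", history$valid_loss[ep]))))
  }
  final <- if (cfg$select == "best_valid" && !is.null(vbatch)) best$params
           else params
  structure(list(target = train$target, params = final, config = cfg,
                 feature_spec = fspec, history = history,
                 best_epoch = if (!is.null(vbatch)) best$epoch else cfg$epochs,
                 seeds = list(init = derive_seed(cfg$seed, "init"),
                              shuffle = shuffle_seed)),
            class = "trained_target_model")
}

#' @export
print.trained_target_model <- function(x, ...) {
  cat(sprintf(
    "<trained_target_model> target %s: depth %d, dim %d, head %s; %d epochs (kept epoch %d)\n",
    x$target, x$config$mp_depth, x$config$mp_hidden,
    paste(x$config$hidden_layers, collapse = "/"),
    x$config$epochs, x$best_epoch))
  invisible(x)
}

#' Score molecules with a trained model
#'
#' Returns one binding likelihood in \[0, 1\] per molecule, in input order.
#' Unparseable SMILES score `NA` and are reported in the `rejects` attribute
#' (indices) rather than raising. Scores are independent of batching.
#'
#' @param object a `trained_target_model`.
#' @param newdata a [labeled_dataset()], a molecule records data.frame, or a
#'   character vector of SMILES.
#' @param batch_size scoring chunk size (memory control only; results are
#'   identical for any value).
#' @param ... unused.
#' @return numeric vector of scores in \[0, 1\].
#' @export
predict.trained_target_model <- function(object, newdata, batch_size = 512L,
                                         ...) {
  smiles <- if (inherits(newdata, "labeled_dataset")) newdata$records$smiles
    else if (is.data.frame(newdata)) newdata$smiles
    else as.character(newdata)
  fspec <- feature_spec()
  if (!identical(object$feature_spec$version, fspec$version))
    incompat_error(sprintf(
      "model featurization '%s' does not match current vocabulary '%s'",
      object$feature_spec$version, fspec$version))
  n <- length(smiles)
  scores <- rep(NA_real_, n)
  if (n == 0L) return(scores)
  graphs <- parse_smiles_batch(smiles, allow_invalid = TRUE)
  ok <- which(!vapply(graphs, is.null, logical(1)))
  if (length(ok)) {
    feats <- lapply(graphs[ok], featurize, spec = fspec)
    scores[ok] <- .predict_features(object, feats, batch_size)
  }
  attr(scores, "rejects") <- setdiff(seq_len(n), ok)
  scores
}

# score pre-featurized molecules (shared across models during screening)
.predict_features <- function(model, feats, batch_size = 512L) {
  out <- numeric(length(feats))
  for (s in seq(1L, length(feats), by = batch_size)) {
    sel <- s:min(s + batch_size - 1L, length(feats))
    batch <- mpnn_batch(feats[sel])
    out[sel] <- mpnn_forward(model$params, batch,
                             model$config$mp_depth)$scores
  }
  out
}

.model_format <- "mpnnscreen_model"
.model_format_version <- 1L

#' Persist / restore a trained model
#'
#' The artifact is a single file carrying a format tag, the package version,
#' the configuration, the featurization vocabularies, the training history and
#' the weights. `load_model()` validates the tag and featurization version and
#' raises an explicit error on mismatch or a truncated/corrupt file;
#' `load_model(save_model(m))` predicts identically to `m`.
#'
#' @param model a `trained_target_model`.
#' @param path file path.
#' @return `path` (save) or the restored `trained_target_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_target_model"))
  saveRDS(list(format = .model_format, format_version = .model_format_version,
               package_version = as.character(utils::packageVersion("mpnnscreen")),
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  obj <- tryCatch(readRDS(path), error = function(e)
    io_error(sprintf("cannot read model artifact '%s': %s", path,
                     conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, .model_format) ||
      is.null(obj$model))
    io_error(sprintf("'%s' is not a model artifact", path))
  if (!identical(obj$format_version, .model_format_version))
    incompat_error(sprintf("model artifact format version %s not supported",
                           obj$format_version))
  model <- structure(obj$model, class = "trained_target_model")
  if (!identical(model$feature_spec$version, feature_spec()$version))
    incompat_error(sprintf(
      "artifact featurization '%s' does not match current vocabulary '%s'",
      model$feature_spec$version, feature_spec()$version))
  model
}
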