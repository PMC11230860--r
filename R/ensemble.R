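#' Three-target ensemble scoring and library screening
#'
#' The ensemble score of a molecule is the unweighted arithmetic mean of its
#' three per-target binding likelihoods,
#' `(Score(SERT) + Score(D2) + Score(NMDA)) / 3`,
#' and a molecule is called positive when the score reaches the decision
#' threshold (0.5 by default; the boundary is inclusive, so a score exactly at
#' the threshold is positive — relevant when comparing threshold sweeps).
#'
#' @name ensemble
NULL

#' Screening decision threshold
#'
#' @param threshold decision threshold in \[0, 1\], default 0.5.
#' @return an object of class `screening_config`.
#' @export
screening_config <- function(threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    config_error("'threshold' must be a single number in [0, 1]")
  structure(list(threshold = threshold), class = "screening_config")
}

#' Ensemble score: mean of the three per-target scores
#'
#' Exact arithmetic mean; no imputation — a missing sub-score is an error.
#' Vectorized over molecules.
#'
#' @param score_sert,score_d2,score_nmda numeric vectors in \[0, 1\], equal
#'   length.
#' @return numeric vector of ensemble scores in \[0, 1\].
#' @examples
#' ensemble_score(0.2, 0.5, 0.8)  # 0.5
#' @export
ensemble_score <- function(score_sert, score_d2, score_nmda) {
  if (length(score_sert) != length(score_d2) ||
      length(score_d2) != length(score_nmda))
    config_error("the three score vectors must have equal length")
  s <- cbind(score_sert, score_d2, score_nmda)
  if (anyNA(s))
    config_error("missing sub-score: ensemble requires all three target scores")
  if (any(s < 0 | s > 1))
    config_error("scores must lie in [0, 1]")
  unname((score_sert + score_d2 + score_nmda) / 3)
}

#' Binarize a score at the decision threshold
#'
#' Positive iff `score >= threshold` (boundary inclusive).
#'
#' @param score numeric scores in \[0, 1\].
#' @param cfg a [screening_config()].
#' @return integer vector of 0/1 predictions.
#' @export
classify <- function(score, cfg = screening_config()) {
  stopifnot(inherits(cfg, "screening_config"))
  if (any(!is.na(score) & (score < 0 | score > 1)))
    config_error("scores must lie in [0, 1]")
  as.integer(score >= cfg$threshold)
}

#' Screen a compound library with the three-target ensemble
#'
#' Scores every molecule with each per-target model, averages into the
#' ensemble score, classifies at the threshold, and ranks descending by
#' ensemble score (ties broken by molecule id, stable). Unparseable SMILES are
#' excluded from the ranking and reported in the `rejects` attribute.
#'
#' @param models named list of three `trained_target_model`s with identical
#'   featurization vocabularies.
#' @param library molecule records data.frame.
#' @param cfg a [screening_config()].
#' @return a data.frame `id, smiles, score_<target>..., ensemble, prediction`
#'   sorted by descending ensemble score, with attributes `rejects` (excluded
#'   records) and `summary` (n, n_positive, fraction_positive, threshold).
#' @export
screen_library <- function(models, library, cfg = screening_config()) {
  if (length(models) != 3L || is.null(names(models)))
    config_error("'models' must be a named list of three trained models")
  for (m in models) {
    stopifnot(inherits(m, "trained_target_model"))
    if (!identical(m$feature_spec$version,
                   models[[1]]$feature_spec$version))
      incompat_error("models have incompatible featurization vocabularies")
  }
  if (nrow(library) == 0L) {
    out <- data.frame(id = character(0), smiles = character(0))
    for (nm in names(models)) out[[paste0("score_", tolower(nm))]] <- numeric(0)
    out$ensemble <- numeric(0)
    out$prediction <- integer(0)
    attr(out, "rejects") <- library
    attr(out, "summary") <- list(n = 0L, n_positive = 0L,
                                 fraction_positive = NA_real_,
                                 threshold = cfg$threshold)
    return(out)
  }
  # parse and featurize once, score with all three models on shared features
  graphs <- parse_smiles_batch(library$smiles, allow_invalid = TRUE)
  parseable <- which(!vapply(graphs, is.null, logical(1)))
  fspec <- feature_spec()
  feats <- lapply(graphs[parseable], featurize, spec = fspec)
  score_mat <- matrix(NA_real_, nrow(library), length(models))
  for (k in seq_along(models)) {
    m <- models[[k]]
    if (!identical(m$feature_spec$version, fspec$version))
      incompat_error(sprintf(
        "model featurization '%s' does not match current vocabulary '%s'",
        m$feature_spec$version, fspec$version))
    if (length(parseable))
      score_mat[parseable, k] <- .predict_features(m, feats)
  }
  ok <- stats::complete.cases(score_mat)
  out <- data.frame(id = library$id[ok], smiles = library$smiles[ok],
                    stringsAsFactors = FALSE)
  for (k in seq_along(models))
    out[[paste0("score_", tolower(names(models)[k]))]] <- score_mat[ok, k]
  out$ensemble <- ensemble_score(score_mat[ok, 1], score_mat[ok, 2],
                                 score_mat[ok, 3])
  out$prediction <- classify(out$ensemble, cfg)
  if ("label" %in% names(library)) out$label <- library$label[ok]
  out <- out[order(-out$ensemble, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- library[!ok, , drop = FALSE]
  attr(out, "summary") <- list(
    n = nrow(out), n_positive = sum(out$prediction),
    fraction_positive = mean(out$prediction), threshold = cfg$threshold)
  out
}
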