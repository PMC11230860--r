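#' Synthetic active/decoy populations with known ground truth
#'
#' The real study data (BindingDB actives, DUD-E decoys, DrugBank inhibitor
#' annotations, Drug Repurposing Hub library) are not deposited, so this
#' module generates SMILES populations carrying the same statistical
#' structure: per-target actives that all share a target-specific substructure
#' motif, decoys guaranteed to contain no motif, and a heavily imbalanced
#' external screening library disjoint from the training data. Molecules are
#' assembled by attaching random alkyl/oxy decorations to either a motif
#' scaffold (actives) or a motif-free scaffold pool (decoys); since every
#' default motif contains a nitrogen or sulfur atom and every decoration and
#' decoy scaffold is built from carbon and oxygen only, motif-freedom of
#' negatives holds by construction and is re-checked independently in the test
#' suite by exhaustive substructure matching.
#'
#' @name synthetic_data
NULL

# decoration fragments: carbon/oxygen only, so they can never create a
# nitrogen- or sulfur-bearing motif
.frag_starters <- c("C", "CC", "CCC", "CCO", "OC", "CC(C)", "CC(=O)",
                    "CCOC", "OCC", "CC(C)C")
.frag_units <- c("C", "O", "CC", "C(C)", "C(=O)", "CO", "OC")
.decoy_cores <- c("c1ccccc1", "C1CCCCC1", "C1CCOC1", "c1ccoc1", "C1CCCC1",
                  "CCCCC", "CC(C)CC", "c1ccc2ccccc2c1", "C1CCCCCC1",
                  "CC1CCCCC1")

#' Specification of the synthetic study populations
#'
#' Default sizes mirror the study design: SERT and D2 train on 200 actives
#' (Ki at most 10 nM) vs. 200 decoys, NMDA on 152 actives vs. 150 decoys, and
#' the external screen holds 154 positives against 5744 negatives. `scale`
#' shrinks every count proportionally for fast exploratory runs.
#'
#' @param n_actives named integer vector, actives per target.
#' @param n_decoys named integer vector, decoys per target.
#' @param n_screen_pos,n_screen_neg external screening library composition.
#' @param motif_per_target named character vector of SMILES substructure
#'   motifs, one per target; defaults are three distinct heteroaromatic ring
#'   systems (indole / pyridine / thiophene) so the three models learn three
#'   different functions.
#' @param ki_range_active,ki_range_inactive Ki sampling intervals in nM;
#'   actives are strictly more potent (active upper bound must not exceed the
#'   inactive lower bound). Ki is sampled log-uniformly.
#' @param screen_motif_weights relative frequency with which each target's
#'   motif appears among screen positives (defaults proportional to the
#'   109/65/18 SERT/D2/NMDA inhibitor annotation counts the screen emulates;
#'   a positive may carry several motifs, mirroring multi-target drugs).
#' @param seed master seed; generation is a pure function of (spec, seed).
#' @param scale multiplies all counts (rounded).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_actives = c(SERT = 200L, D2 = 200L, NMDA = 152L),
                           n_decoys = c(SERT = 200L, D2 = 200L, NMDA = 150L),
                           n_screen_pos = 154L,
                           n_screen_neg = 5744L,
                           motif_per_target = c(SERT = "c1ccc2[nH]ccc2c1",
                                                D2 = "c1ccncc1",
                                                NMDA = "c1ccsc1"),
                           ki_range_active = c(0.1, 10),
                           ki_range_inactive = c(1000, 1e5),
                           screen_motif_weights = c(SERT = 109, D2 = 65,
                                                    NMDA = 18),
                           seed = 101L,
                           scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    config_error("'scale' must be a single positive number")
  rescale <- function(x) {
    y <- as.integer(round(x * scale))
    y[x > 0 & y < 1L] <- 1L   # a positive request never scales to zero
    names(y) <- names(x)
    y
  }
  targets <- names(motif_per_target)
  if (is.null(targets) || any(!nzchar(targets)))
    config_error("'motif_per_target' must be a named character vector")
  expand <- function(x, what) {
    if (any(is.na(x)) || any(x < 0))
      config_error(sprintf("'%s' must be nonnegative", what))
    if (is.null(names(x))) {
      if (length(x) == 1L) x <- stats::setNames(rep(x, length(targets)), targets)
      else config_error(sprintf("'%s' must be named per target", what))
    }
    if (!all(targets %in% names(x)))
      config_error(sprintf("'%s' must cover every target", what))
    rescale(x[targets])
  }
  n_actives <- expand(n_actives, "n_actives")
  n_decoys <- expand(n_decoys, "n_decoys")
  if (length(n_screen_pos) != 1L || length(n_screen_neg) != 1L ||
      is.na(n_screen_pos) || is.na(n_screen_neg) ||
      n_screen_pos < 0 || n_screen_neg < 0)
    config_error("screen counts must be single nonnegative numbers")
  if (length(ki_range_active) != 2L || length(ki_range_inactive) != 2L ||
      any(ki_range_active <= 0) || any(ki_range_inactive <= 0) ||
      diff(ki_range_active) < 0 || diff(ki_range_inactive) < 0)
    config_error("Ki ranges must be positive increasing intervals (nM)")
  if (ki_range_active[2] > ki_range_inactive[1])
    config_error("actives must be strictly more potent: ki_range_active upper bound must not exceed ki_range_inactive lower bound")
  for (t in targets) {
    ok <- tryCatch({parse_smiles(motif_per_target[[t]]); TRUE},
                   ms_parse_error = function(e) FALSE)
    if (!ok) config_error(sprintf("invalid motif SMILES for target %s: '%s'",
                                  t, motif_per_target[[t]]))
  }
  w <- screen_motif_weights
  if (is.null(names(w)) || !all(targets %in% names(w)) || any(w < 0))
    config_error("'screen_motif_weights' must be named per target, nonnegative")
  structure(list(
    n_actives = n_actives, n_decoys = n_decoys,
    n_screen_pos = as.integer(round(n_screen_pos * scale)),
    n_screen_neg = as.integer(round(n_screen_neg * scale)),
    motif_per_target = motif_per_target,
    ki_range_active = as.numeric(ki_range_active),
    ki_range_inactive = as.numeric(ki_range_inactive),
    screen_motif_weights = w[targets],
    seed = as.integer(seed), scale = scale
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  cat("  targets:", paste(sprintf("%s (%d act / %d dec, motif %s)",
                                  names(x$motif_per_target), x$n_actives,
                                  x$n_decoys, x$motif_per_target),
                          collapse = "; "), "\n")
  cat(sprintf("  screen: %d positives / %d negatives; seed %d\n",
              x$n_screen_pos, x$n_screen_neg, x$seed))
  invisible(x)
}

# random decoration chain: starter then 0..3 growth units
.random_decoration <- function(n, allow_empty = FALSE) {
  k <- sample.int(4L, n, replace = TRUE) - 1L
  starters <- if (allow_empty)
    sample(c(.frag_starters, ""), n, replace = TRUE)
  else sample(.frag_starters, n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    if (!nzchar(starters[i])) return("")
    units <- if (k[i] > 0L) sample(.frag_units, k[i], replace = TRUE) else
      character(0)
    paste0(starters[i], paste0(units, collapse = ""))
  }, character(1))
}

# Build n unique, valid molecules around the core strings produced by
# cores_fn(m), excluding any canonical SMILES in `exclude`. Pure function of
# the RNG state. Raises a generation error when the combinatorial pool cannot
# supply the request.
.build_unique <- function(n, cores_fn, exclude = character(0),
                          max_rounds = 60L) {
  if (n == 0L) return(character(0))
  seen <- character(0)
  out <- character(0)
  rounds <- 0L
  while (length(out) < n) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      generation_error(sprintf(
        "could not generate %d unique molecules disjoint from the exclusion set (got %d)",
        n, length(out)))
    m <- max(16L, 2L * (n - length(out)))
    cand <- paste0(.random_decoration(m), cores_fn(m),
                   .random_decoration(m, allow_empty = TRUE))
    can <- canonical_smiles(cand)
    ok <- !is.na(can) & !duplicated(can) & !can %in% seen & !can %in% exclude
    seen <- c(seen, can[ok])
    out <- c(out, cand[ok])
  }
  out[seq_len(n)]
}

.sample_ki <- function(n, range) {
  10^stats::runif(n, log10(range[1]), log10(range[2]))
}

#' Generate the active set for one target
#'
#' Every active embeds the target's motif as a substructure and carries a Ki
#' sampled log-uniformly inside `ki_range_active`, so the whole set passes the
#' study's activity filter. Deterministic for a fixed spec.
#'
#' @param spec a [synthetic_spec()].
#' @param target a key of `spec$motif_per_target`.
#' @return molecule records data.frame, `label = 1`.
#' @export
generate_actives <- function(spec, target) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!target %in% names(spec$motif_per_target))
    config_error(sprintf("unknown target '%s'", target))
  n <- spec$n_actives[[target]]
  if (n == 0L) return(.empty_records())
  core <- spec$motif_per_target[[target]]
  with_seed(derive_seed(spec$seed, paste0("actives:", target)), {
    smi <- .build_unique(n, function(m) rep(core, m))
    ki <- .sample_ki(n, spec$ki_range_active)
  })
  data.frame(id = sprintf("%s_act_%04d", target, seq_len(n)), smiles = smi,
             target = target, ki_nM = ki, label = 1L,
             stringsAsFactors = FALSE)
}

#' Generate motif-free decoys
#'
#' Decoys emulate guaranteed non-binders: none contains any target's motif
#' (their scaffolds and decorations carry no nitrogen or sulfur, while every
#' motif does). Ki, where reported, falls in the inactive range.
#'
#' @param spec a [synthetic_spec()].
#' @param target optional target name selecting the per-target decoy count and
#'   stream; required when `spec$n_decoys` differs across targets.
#' @return molecule records data.frame, `label = 0`.
#' @export
generate_decoys <- function(spec, target = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(target)) {
    if (length(unique(spec$n_decoys)) > 1L)
      config_error("per-target decoy counts differ; supply 'target'")
    target <- names(spec$n_decoys)[1]
  }
  if (!target %in% names(spec$n_decoys))
    config_error(sprintf("unknown target '%s'", target))
  n <- spec$n_decoys[[target]]
  if (n == 0L) return(.empty_records())
  with_seed(derive_seed(spec$seed, paste0("decoys:", target)), {
    smi <- .build_unique(n, function(m) sample(.decoy_cores, m, replace = TRUE))
    ki <- .sample_ki(n, spec$ki_range_inactive)
  })
  data.frame(id = sprintf("%s_dec_%04d", target, seq_len(n)), smiles = smi,
             target = target, ki_nM = ki, label = 0L,
             stringsAsFactors = FALSE)
}

# canonical SMILES of every training molecule a spec generates
.training_canonical <- function(spec) {
  cans <- lapply(names(spec$motif_per_target), function(t) {
    c(canonical_smiles(generate_actives(spec, t)$smiles),
      canonical_smiles(generate_decoys(spec, t)$smiles))
  })
  unique(unlist(cans))
}

#' Generate the imbalanced external screening library
#'
#' Positives bear one or more target motifs (multi-motif molecules emulate
#' multi-target inhibitors; per-motif frequencies follow
#' `spec$screen_motif_weights`), negatives are motif-free. No molecule of the
#' library coincides (by canonical SMILES) with any training molecule the same
#' spec generates; the library is shuffled and ground-truth labels retained.
#'
#' @param spec a [synthetic_spec()].
#' @return molecule records data.frame with `label` 1/0; for positives the
#'   `target` column lists the motifs carried, separated by ";".
#' @export
generate_screening_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  exclude <- if (spec$n_screen_pos + spec$n_screen_neg > 0L)
    .training_canonical(spec) else character(0)
  targets <- names(spec$motif_per_target)
  # per-motif membership probability: weights normalized to ~1.25 expected
  # motifs per positive (192 inhibitor annotations over 154 unique drugs in
  # the population this emulates), independent of scale
  w <- spec$screen_motif_weights
  p <- pmin(w / sum(w) * 1.25, 1)

  pos <- .empty_records()
  if (spec$n_screen_pos > 0L) {
    with_seed(derive_seed(spec$seed, "screen:pos"), {
      memb <- matrix(FALSE, spec$n_screen_pos, length(targets),
                     dimnames = list(NULL, targets))
      for (i in seq_len(spec$n_screen_pos)) {
        repeat {
          m <- stats::runif(length(targets)) < p
          if (any(m)) break
        }
        memb[i, ] <- m
      }
      combos <- apply(memb, 1L, function(m)
        paste(spec$motif_per_target[targets[m]], collapse = "C"))
      smi <- .build_unique(spec$n_screen_pos,
                           function(m) sample(combos, m, replace = TRUE),
                           exclude = exclude)
    })
    # record which motifs each built molecule actually carries
    carried <- vapply(smi, function(s) {
      hits <- targets[vapply(targets, function(t)
        grepl(spec$motif_per_target[[t]], s, fixed = TRUE), logical(1))]
      paste(hits, collapse = ";")
    }, character(1), USE.NAMES = FALSE)
    pos <- data.frame(id = sprintf("scr_pos_%04d", seq_len(spec$n_screen_pos)),
                      smiles = smi, target = carried, ki_nM = NA_real_,
                      label = 1L, stringsAsFactors = FALSE)
  }
  neg <- .empty_records()
  if (spec$n_screen_neg > 0L) {
    with_seed(derive_seed(spec$seed, "screen:neg"), {
      smi <- .build_unique(spec$n_screen_neg,
                           function(m) sample(.decoy_cores, m, replace = TRUE),
                           exclude = c(exclude, canonical_smiles(pos$smiles)))
    })
    neg <- data.frame(id = sprintf("scr_neg_%04d", seq_len(spec$n_screen_neg)),
                      smiles = smi, target = NA_character_, ki_nM = NA_real_,
                      label = 0L, stringsAsFactors = FALSE)
  }
  lib <- rbind(pos, neg)
  if (nrow(lib) > 1L)
    lib <- with_seed(derive_seed(spec$seed, "screen:shuffle"),
                     lib[sample.int(nrow(lib)), , drop = FALSE])
  rownames(lib) <- NULL
  lib
}

#' Write a synthetic spec provenance sidecar
#'
#' Echoes the spec (counts, motifs, Ki ranges, seed, scale) to JSON next to
#' generated datasets so a run can be reproduced exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_spec_sidecar <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
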