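#' Molecule tables, activity filtering and training-set assembly
#'
#' Molecule collections are plain data frames with the columns `id`, `smiles`,
#' `target`, `ki_nM`, `label` (`ki_nM` in nanomolar; `label` 1 = active,
#' 0 = inactive; either may be `NA` when unknown). A labeled training dataset
#' wraps such a table, requiring every label present and canonical-SMILES
#' uniqueness.
#'
#' @name chem_io
NULL

.ki_unit_factor <- c(pM = 1e-3, nM = 1, uM = 1e3, `µM` = 1e3,
                     mM = 1e6, M = 1e9)

.empty_records <- function() {
  data.frame(id = character(0), smiles = character(0), target = character(0),
              ki_nM = numeric(0), label = integer(0), stringsAsFactors = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Canonical form via OpenBabel's canonical SMILES writer; used for duplicate
#' detection and train/validation disjointness checks, since the same molecule
#' admits many SMILES spellings. Unparseable entries canonicalize to `NA`.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, same length and order.
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  idx <- which(ok)
  if (!length(idx)) return(out)
  input <- paste0(paste(smiles[idx], seq_along(idx)), collapse = "\n")
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(input, "\n")),
    error = function(e) NULL
  )
  lines <- if (is.null(res)) character(0) else
    strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2L) p[2] else NA_character_, character(1))))
  keep <- !is.na(pos) & pos >= 1L & pos <= length(idx)
  out[idx[pos[keep]]] <- trimws(can[keep])
  # entries OpenBabel silently dropped (invalid) stay NA; if counts mismatch
  # badly, fall back to per-molecule canonicalization for unresolved slots
  unresolved <- idx[is.na(out[idx])]
  for (k in unresolved) {
    r <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles[k], "\n")),
      error = function(e) NULL
    )
    if (!is.null(r)) {
      v <- trimws(strsplit(r, "\t", fixed = TRUE)[[1]][1])
      if (nzchar(v)) out[k] <- v
    }
  }
  out
}

#' Read a molecule table from CSV
#'
#' Reads a comma-separated table with a header row, maps columns per
#' `dialect`, validates every SMILES, and normalizes Ki values to nanomolar
#' when a units column is mapped. Rows whose SMILES does not parse are
#' dropped, reported in a warning with their row numbers, and counted in the
#' `dropped_rows` attribute.
#'
#' @param path CSV file path.
#' @param dialect named list mapping the canonical fields `id`, `smiles` and
#'   optionally `target`, `ki`, `label`, `units` to column names in the file.
#' @return a molecule records data.frame (see [chem_io]).
#' @export
read_molecule_table <- function(path,
                                dialect = list(id = "id", smiles = "smiles",
                                               target = "target",
                                               ki = "ki_nM", label = "label")) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in c("id", "smiles"))
    if (is.null(dialect[[f]]) || !dialect[[f]] %in% names(df)) {
      if (nrow(df) == 0L && ncol(df) <= 1L) break
      format_error(sprintf("mandatory column '%s' (mapped to field '%s') missing",
                           dialect[[f]] %||% f, f))
    }
  if (nrow(df) == 0L) {
    warning("empty molecule table: ", path)
    out <- .empty_records()
    attr(out, "dropped_rows") <- integer(0)
    return(out)
  }
  get_col <- function(f, default) {
    cn <- dialect[[f]]
    if (!is.null(cn) && cn %in% names(df)) df[[cn]] else default
  }
  ki <- suppressWarnings(as.numeric(get_col("ki", rep(NA_real_, nrow(df)))))
  units <- get_col("units", NULL)
  if (!is.null(units)) {
    fac <- .ki_unit_factor[as.character(units)]
    if (anyNA(fac[!is.na(ki)]))
      format_error(sprintf("unknown Ki unit(s): %s",
                           paste(unique(units[is.na(fac)]), collapse = ", ")))
    ki <- ki * fac
  }
  rec <- data.frame(
    id = as.character(get_col("id", NA_character_)),
    smiles = as.character(get_col("smiles", NA_character_)),
    target = as.character(get_col("target", rep(NA_character_, nrow(df)))),
    ki_nM = ki,
    label = suppressWarnings(as.integer(get_col("label",
                                                rep(NA_integer_, nrow(df))))),
    stringsAsFactors = FALSE
  )
  graphs <- parse_smiles_batch(rec$smiles, allow_invalid = TRUE)
  bad <- which(vapply(graphs, is.null, logical(1)))
  if (length(bad)) {
    warning(sprintf("dropped %d row(s) with unparseable SMILES (rows: %s)",
                    length(bad), paste(bad, collapse = ", ")))
    rec <- rec[-bad, , drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(rec, "dropped_rows") <- bad
  rec
}

#' Write a molecule table to CSV
#'
#' Writes `id,smiles,target,ki_nM,label` with a header, byte-reproducibly for
#' identical inputs.
#'
#' @param records molecule records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(records, path) {
  cols <- c("id", "smiles", "target", "ki_nM", "label")
  for (cl in cols) if (!cl %in% names(records))
    format_error(sprintf("records lack column '%s'", cl))
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Write / read the one-molecule-per-line SMILES format
#'
#' Lines are `smiles<TAB>id`.
#' @param records molecule records data.frame.
#' @param path file path.
#' @return `path` (write) or a records data.frame (read).
#' @export
write_smiles_file <- function(records, path) {
  writeLines(paste(records$smiles, records$id, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_smiles_file
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.empty_records())
  parts <- strsplit(lines, "[ \t]+")
  out <- .empty_records()[rep(1L, 0L), ]
  out <- data.frame(
    id = vapply(parts, function(p) if (length(p) >= 2L) p[2] else NA_character_,
                character(1)),
    smiles = vapply(parts, `[`, character(1), 1L),
    target = NA_character_, ki_nM = NA_real_, label = NA_integer_,
    stringsAsFactors = FALSE
  )
  out
}

#' Filter records by inhibition constant
#'
#' Keeps exactly the records whose `ki_nM` is present and `<= ki_threshold_nM`
#' (boundary inclusive: a compound measured exactly at the threshold counts as
#' active). Records without a Ki are excluded and counted in the
#' `n_missing_ki` attribute. Order is preserved.
#'
#' @param records molecule records data.frame.
#' @param ki_threshold_nM positive threshold in nM (e.g. 10 for SERT/D2
#'   actives, 12 for NMDA actives).
#' @return the surviving records, original order.
#' @export
filter_actives <- function(records, ki_threshold_nM) {
  if (!is.numeric(ki_threshold_nM) || length(ki_threshold_nM) != 1L ||
      is.na(ki_threshold_nM) || ki_threshold_nM <= 0)
    config_error("'ki_threshold_nM' must be a single positive number")
  missing_ki <- is.na(records$ki_nM)
  keep <- !missing_ki & records$ki_nM <= ki_threshold_nM
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_ki") <- sum(missing_ki)
  out
}

#' A labeled per-target training dataset
#'
#' @param records molecule records with every `label` present in `{0, 1}` and
#'   no duplicate canonical SMILES.
#' @param target the target name the dataset trains against.
#' @return an object of class `labeled_dataset` (fields `records`, `target`).
#' @export
labeled_dataset <- function(records, target) {
  if (anyNA(records$label) || !all(records$label %in% c(0L, 1L)))
    format_error("labeled_dataset requires every label present in {0, 1}")
  can <- canonical_smiles(records$smiles)
  if (anyDuplicated(can))
    format_error("duplicate canonical SMILES within dataset")
  records$canonical <- can
  structure(list(records = records, target = target),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> target %s: %d molecules (%d active, %d inactive)\n",
              x$target, nrow(x$records), sum(x$records$label == 1L),
              sum(x$records$label == 0L)))
  invisible(x)
}

#' Assemble actives and decoys into a labeled training dataset
#'
#' Actives are labeled 1 and decoys 0. Duplicates within a class (by canonical
#' SMILES) are removed with a count recorded in the `n_duplicates_removed`
#' attribute; a molecule appearing in both classes is a contradiction and
#' raises a conflict error naming it.
#'
#' @param actives,decoys molecule records data.frames.
#' @param target target name.
#' @return a [labeled_dataset()].
#' @export
assemble_training_set <- function(actives, decoys, target) {
  if (nrow(actives) == 0L || nrow(decoys) == 0L)
    config_error("both actives and decoys must be non-empty")
  a <- actives; a$label <- 1L
  d <- decoys;  d$label <- 0L
  a$canonical <- canonical_smiles(a$smiles)
  d$canonical <- canonical_smiles(d$smiles)
  dup_a <- duplicated(a$canonical)
  dup_d <- duplicated(d$canonical)
  a <- a[!dup_a, , drop = FALSE]
  d <- d[!dup_d, , drop = FALSE]
  clash <- intersect(a$canonical, d$canonical)
  if (length(clash)) {
    ids <- c(a$id[match(clash[1], a$canonical)],
             d$id[match(clash[1], d$canonical)])
    conflict_error(sprintf(
      "molecule present in both classes: canonical SMILES '%s' (ids %s)",
      clash[1], paste(ids, collapse = ", ")), smiles = clash)
  }
  rec <- rbind(a[, c("id", "smiles", "target", "ki_nM", "label")],
               d[, c("id", "smiles", "target", "ki_nM", "label")])
  rec$target <- target
  rownames(rec) <- NULL
  ds <- labeled_dataset(rec, target)
  attr(ds, "n_duplicates_removed") <- sum(dup_a) + sum(dup_d)
  ds
}

#' Check train / external-validation disjointness
#'
#' The external screening library must share no molecule with the training
#' data. Returns the canonical SMILES present in both; an empty result is a
#' pass. The caller decides whether collisions are fatal.
#'
#' @param train a [labeled_dataset()] or molecule records data.frame.
#' @param external molecule records data.frame.
#' @return character vector of colliding canonical SMILES (possibly empty),
#'   with a `collisions` attribute giving the external ids involved.
#' @export
assert_disjoint <- function(train, external) {
  tr <- if (inherits(train, "labeled_dataset")) train$records else train
  tcan <- tr$canonical %||% canonical_smiles(tr$smiles)
  ecan <- canonical_smiles(external$smiles)
  clash <- intersect(tcan, ecan)
  structure(clash,
            collisions = external$id[ecan %in% clash])
}
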