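#' Molecular graphs and MPNN input features
#'
#' SMILES strings are parsed (via OpenBabel through ChemmineR) into a heavy-atom
#' molecular graph, then encoded into the four-block input the message-passing
#' encoder consumes: an atom feature matrix, a directed-arc (bond) feature
#' matrix, the incoming-arc table of every atom, and the feeding-arc table of
#' every directed arc. Each chemical bond is expanded into two directed arcs so
#' that message passing is directional.
#'
#' @name mol_graph
NULL

# SDF V2000 charge field codes -> formal charge
.charge_code <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

#' Fixed featurization vocabularies
#'
#' Atom block: one-hot element over C/N/O/S/F/Cl/Br/I/P/other, one-hot
#' heavy-atom degree 0-5, one-hot formal charge clipped to \[-2, 2\], an
#' aromatic flag, and a one-hot hybridization class (sp/sp2/sp3/other).
#' Bond block: one-hot order (single/double/triple/aromatic), a conjugation
#' flag and an in-ring flag. Models record the vocabulary they were trained
#' with and refuse to score molecules featurized under a different one.
#'
#' @return a list with the vocabularies, the derived dimensions `d_atom` and
#'   `d_bond`, and a `version` string.
#' @export
feature_spec <- function() {
  list(
    elements    = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "other"),
    degrees     = 0:5,
    charges     = -2:2,
    hybridizations = c("sp", "sp2", "sp3", "other"),
    bond_orders = c("single", "double", "triple", "aromatic"),
    d_atom      = 10L + 6L + 5L + 1L + 4L,
    d_bond      = 4L + 1L + 1L,
    version     = "mpnnscreen-fv1"
  )
}

#' Parse a SMILES string into a molecular graph
#'
#' Hydrogens are implicit; only heavy atoms appear. Aromaticity and ring
#' membership are perceived from the parsed structure; hybridization is
#' classified from bond orders (sp for a triple bond or two cumulated doubles,
#' sp2 for aromatic or one double, sp3 otherwise).
#'
#' @param smiles a single SMILES string.
#' @return an object of class `mol_graph`: a list with `atoms` (data.frame:
#'   element, degree, formal_charge, aromatic, hybridization), `bonds`
#'   (data.frame: a1, a2, order, aromatic, conjugated, in_ring), `smiles`,
#'   `n_atoms`, `n_bonds`.
#' @examples
#' g <- parse_smiles("CC(=O)OC1=CC=CC=C1C(=O)O")  # aspirin
#' g$n_atoms  # 13 heavy atoms
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    parse_error("SMILES must be a single non-empty string", smiles = smiles)
  single <- .single_atom_graph(smiles)
  if (!is.null(single)) return(single)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m1"))),
    error = function(e) NULL
  )
  if (is.null(sdf) || !ChemmineR::validSDF(sdf[1]))
    parse_error(sprintf("invalid SMILES: '%s'", smiles), smiles = smiles)
  .sdf_to_graph(sdf[[1]], smiles)
}

# Parse many SMILES at once. Returns a list of mol_graph; unparseable entries
# are NULL when allow_invalid, otherwise a parse error is raised naming the
# first offender. The batch path through OpenBabel is much faster than
# per-molecule calls; it falls back to per-molecule parsing only when the
# batch contains an invalid string.
parse_smiles_batch <- function(smiles, allow_invalid = FALSE) {
  n <- length(smiles)
  if (n == 0L) return(list())
  ok_shape <- is.character(smiles) & !is.na(smiles) & nzchar(smiles)
  graphs <- vector("list", n)
  for (k in which(ok_shape)) {
    sg <- .single_atom_graph(smiles[k])
    if (!is.null(sg)) {
      graphs[[k]] <- sg
      ok_shape[k] <- FALSE   # handled; keep out of the SDF batch
    }
  }
  idx <- which(ok_shape)
  if (length(idx)) {
    nm <- paste0("m", idx)
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[idx], nm))),
      error = function(e) NULL
    )
    if (!is.null(sdf) && length(sdf) == length(idx)) {
      valid <- ChemmineR::validSDF(sdf)
      for (k in seq_along(idx)) {
        if (valid[k])
          graphs[[idx[k]]] <- .sdf_to_graph(sdf[[k]], smiles[idx[k]])
      }
    } else {
      for (k in idx) {
        graphs[[k]] <- tryCatch(parse_smiles(smiles[k]), ms_parse_error =
                                  function(e) NULL)
      }
    }
  }
  bad <- vapply(graphs, is.null, logical(1))
  if (any(bad) && !allow_invalid)
    parse_error(sprintf("invalid SMILES: '%s'", smiles[which(bad)[1]]),
                smiles = smiles[which(bad)[1]])
  graphs
}

# Single-heavy-atom molecules (e.g. "C", "[O-]") cannot round-trip through
# the SDF route; build their one-node graph directly. Returns NULL when the
# SMILES is not a lone atom.
.single_atom_graph <- function(smiles) {
  m <- regmatches(smiles, regexec(
    "^\\[?([A-Z][a-z]?)(H[0-9]*)?([+-][0-9]*)?\\]?$", smiles))[[1]]
  if (length(m) == 0L) return(NULL)
  if (grepl("[\\[\\]]", smiles) && !grepl("^\\[.*\\]$", smiles)) return(NULL)
  element <- m[2]
  chg <- m[4]
  charge <- if (!nzchar(chg)) 0L else {
    mag <- sub("^[+-]", "", chg)
    as.integer(paste0(substr(chg, 1, 1), if (nzchar(mag)) mag else "1"))
  }
  atoms <- data.frame(element = element, degree = 0L,
                      formal_charge = charge, aromatic = FALSE,
                      hybridization = "sp3", stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                      aromatic = logical(0), conjugated = logical(0),
                      in_ring = logical(0))
  structure(list(atoms = atoms, bonds = bonds, smiles = smiles,
                 n_atoms = 1L, n_bonds = 0L), class = "mol_graph")
}

.sdf_to_graph <- function(sdf, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  n_atoms <- nrow(ab)
  if (is.null(n_atoms) || n_atoms < 1L)
    parse_error(sprintf("SMILES '%s' yields an empty molecule", smiles),
                smiles = smiles)
  element <- sub("_.*$", "", rownames(ab))
  chg_code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else
    integer(n_atoms)
  charge <- unname(.charge_code[as.character(chg_code)])
  charge[is.na(charge)] <- 0L

  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        aromatic = logical(0), conjugated = logical(0),
                        in_ring = logical(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    bonds$aromatic <- FALSE
    bonds$in_ring <- FALSE
  }
  n_bonds <- nrow(bonds)

  aromatic_atom <- logical(n_atoms)
  if (n_bonds > 0L) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, arom = TRUE, type = "all")),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    ring_list <- rg$RINGS %||% list()
    arom_flags <- rg$AROMATIC %||% logical(0)
    # bond lookup key: unordered atom pair
    key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    for (ri in seq_along(ring_list)) {
      members <- match(ring_list[[ri]], rownames(ab))
      if (anyNA(members)) next
      nxt <- c(members[-1], members[1])
      bk <- paste(pmin(members, nxt), pmax(members, nxt))
      hit <- match(bk, key)
      hit <- hit[!is.na(hit)]
      bonds$in_ring[hit] <- TRUE
      if (isTRUE(arom_flags[ri])) {
        bonds$aromatic[hit] <- TRUE
        aromatic_atom[members] <- TRUE
      }
    }
  }

  degree <- integer(n_atoms)
  n_double <- integer(n_atoms)
  n_triple <- integer(n_atoms)
  if (n_bonds > 0L) {
    degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n_atoms)
    dbl <- c(bonds$a1[bonds$order == 2L & !bonds$aromatic],
             bonds$a2[bonds$order == 2L & !bonds$aromatic])
    tri <- c(bonds$a1[bonds$order == 3L], bonds$a2[bonds$order == 3L])
    n_double <- tabulate(dbl, nbins = n_atoms)
    n_triple <- tabulate(tri, nbins = n_atoms)
  }
  hybrid <- ifelse(aromatic_atom, "sp2",
            ifelse(n_triple > 0L | n_double >= 2L, "sp",
            ifelse(n_double == 1L, "sp2", "sp3")))

  if (n_bonds > 0L) {
    # an endpoint is unsaturated if aromatic or carrying a multiple bond
    unsat <- aromatic_atom | n_double > 0L | n_triple > 0L
    multi <- bonds$order >= 2L | bonds$aromatic
    # conjugation: aromatic bonds, or any bond joining two unsaturated
    # centres where at least one side's unsaturation is external to the bond
    ext_unsat <- function(a, b_ord) {
      (n_double[a] + n_triple[a] - as.integer(b_ord >= 2L)) > 0L |
        aromatic_atom[a]
    }
    bonds$conjugated <- bonds$aromatic |
      (unsat[bonds$a1] & unsat[bonds$a2] &
         (ext_unsat(bonds$a1, bonds$order) | ext_unsat(bonds$a2, bonds$order)))
  }

  atoms <- data.frame(element = element, degree = degree,
                      formal_charge = charge, aromatic = aromatic_atom,
                      hybridization = hybrid, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, bonds = bonds, smiles = smiles,
                 n_atoms = n_atoms, n_bonds = n_bonds),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds\n",
              x$smiles, x$n_atoms, x$n_bonds))
  invisible(x)
}

.one_hot <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Encode a molecular graph into MPNN input features
#'
#' Produces the four blocks consumed by the message-passing encoder. Every
#' chemical bond is expanded into two directed arcs (arc `2k-1` runs
#' `a1 -> a2` of bond `k`, arc `2k` is its reverse); both arcs carry the
#' bond's feature row. Elements outside the vocabulary map to the catch-all
#' "other" slot (counted in attribute `n_other_elements`), never an error.
#'
#' @param graph a [parse_smiles()] result.
#' @param spec the featurization vocabularies, [feature_spec()].
#' @return an object of class `graph_features`: `atom_features`
#'   (n_atoms x d_atom), `bond_features` (2 n_bonds x d_bond), `atom_neighbors`
#'   (per atom, indices of incoming arcs), `bond_neighbors` (per arc, arcs
#'   feeding its source atom excluding its own reverse), plus `src`, `dst`,
#'   `rev` arc tables and the originating sizes.
#' @export
featurize <- function(graph, spec = feature_spec()) {
  stopifnot(inherits(graph, "mol_graph"))
  at <- graph$atoms
  n <- graph$n_atoms

  el_idx <- match(at$element, spec$elements)
  n_other <- sum(is.na(el_idx))
  el_idx[is.na(el_idx)] <- match("other", spec$elements)
  deg_idx <- match(pmin(pmax(at$degree, 0L), 5L), spec$degrees)
  chg_idx <- match(pmin(pmax(at$formal_charge, -2L), 2L), spec$charges)
  hyb <- at$hybridization
  hyb[!hyb %in% spec$hybridizations] <- "other"
  hyb_idx <- match(hyb, spec$hybridizations)

  atom_features <- cbind(
    .one_hot(el_idx, length(spec$elements)),
    .one_hot(deg_idx, length(spec$degrees)),
    .one_hot(chg_idx, length(spec$charges)),
    as.numeric(at$aromatic),
    .one_hot(hyb_idx, length(spec$hybridizations))
  )

  b <- graph$bonds
  nb <- graph$n_bonds
  if (nb > 0L) {
    ord <- ifelse(b$aromatic, "aromatic",
                  c("single", "double", "triple")[pmin(b$order, 3L)])
    ord_idx <- match(ord, spec$bond_orders)
    bf1 <- cbind(.one_hot(ord_idx, length(spec$bond_orders)),
                 as.numeric(b$conjugated), as.numeric(b$in_ring))
    bond_features <- bf1[rep(seq_len(nb), each = 2L), , drop = FALSE]
    src <- as.integer(rbind(b$a1, b$a2))
    dst <- as.integer(rbind(b$a2, b$a1))
    rev <- as.integer(rbind(seq_len(nb) * 2L, seq_len(nb) * 2L - 1L))
  } else {
    bond_features <- matrix(0, 0L, spec$d_bond)
    src <- dst <- rev <- integer(0)
  }
  n_arcs <- 2L * nb

  atom_neighbors <- split(seq_len(n_arcs), factor(dst, levels = seq_len(n)))
  names(atom_neighbors) <- NULL
  bond_neighbors <- lapply(seq_len(n_arcs), function(a) {
    inc <- atom_neighbors[[src[a]]]
    inc[inc != rev[a]]
  })

  structure(list(atom_features = atom_features,
                 bond_features = bond_features,
                 atom_neighbors = atom_neighbors,
                 bond_neighbors = bond_neighbors,
                 src = src, dst = dst, rev = rev,
                 n_atoms = n, n_bonds = nb,
                 spec_version = spec$version),
            class = "graph_features",
            n_other_elements = n_other)
}
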