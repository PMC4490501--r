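# Scaffold grouping: Bemis-Murcko framework extraction, partition of a
# dataset into scaffold groups (minimum size 15 by default), random 2:1
# train/test split, and mean-Tanimoto group assignment for queries.

#' Extract the Bemis-Murcko framework of a molecule
#'
#' Terminal atoms are pruned iteratively until only ring systems and the
#' linkers between them remain; the framework is canonicalized to a
#' SMILES string. Acyclic molecules return the canonical SMILES of the
#' whole structure.
#'
#' @param mol a Molecule.
#' @return canonical framework SMILES (character scalar).
#' @export
extractScaffold <- function(mol) {
  keep <- murckoAtoms(mol)
  if (length(keep) == 0 || length(keep) == nAtoms(mol))
    return(canonicalSmiles(mol))
  sub <- inducedSubMolecule(mol, keep)
  canonicalSmiles(sub)
}

# Atom indices of the Murcko framework: iteratively delete degree-1 atoms
# (molecules without rings shrink to nothing; handled by the caller),
# then re-attach atoms multiply bonded to a framework atom (exocyclic
# carbonyls and the like stay part of the framework, the usual
# convention).
murckoAtoms <- function(mol) {
  n <- nAtoms(mol)
  alive <- rep(TRUE, n)
  b <- mol@bonds
  repeat {
    deg <- integer(n)
    for (i in seq_len(nrow(b))) {
      if (alive[b$a1[i]] && alive[b$a2[i]]) {
        deg[b$a1[i]] <- deg[b$a1[i]] + 1L
        deg[b$a2[i]] <- deg[b$a2[i]] + 1L
      }
    }
    drop <- which(alive & deg <= 1L)
    if (length(drop) == 0 || sum(alive) == 0) break
    alive[drop] <- FALSE
  }
  if (any(alive)) {
    for (i in seq_len(nrow(b))) {
      if (b$order[i] >= 2L && xor(alive[b$a1[i]], alive[b$a2[i]]))
        alive[b$a1[i]] <- alive[b$a2[i]] <- TRUE
    }
  }
  which(alive)
}

# Substructure induced by an atom subset (indices remapped). Bonds to
# stripped side chains are replaced by hydrogens so the framework is a
# proper closed-valence structure.
inducedSubMolecule <- function(mol, keep) {
  map <- match(seq_len(nAtoms(mol)), keep)
  b <- mol@bonds
  sel <- !is.na(map[b$a1]) & !is.na(map[b$a2])
  atoms <- mol@atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  lost <- b[xor(is.na(map[b$a1]), is.na(map[b$a2])), , drop = FALSE]
  for (i in seq_len(nrow(lost))) {
    kept <- if (is.na(map[lost$a1[i]])) lost$a2[i] else lost$a1[i]
    atoms$nH[map[kept]] <- atoms$nH[map[kept]] + lost$order[i]
  }
  confs <- lapply(mol@conformers, function(cf) cf[keep, , drop = FALSE])
  Molecule(id = paste0(mol@id, "_scaffold"), atoms = atoms,
           bonds = data.frame(a1 = map[b$a1[sel]], a2 = map[b$a2[sel]],
                              order = b$order[sel]),
           conformers = confs)
}

#' Partition molecules into scaffold groups
#'
#' Equivalence classes under identical canonical Bemis-Murcko framework.
#' Classes smaller than \code{minSize} go to the unassigned pool. Group
#' ids are assigned by descending size, ties by lexicographic framework
#' string.
#'
#' @param mols list of Molecule.
#' @param minSize minimum retained group size (default 15).
#' @return a \code{GroupedDataset}.
#' @export
partitionByScaffold <- function(mols, minSize = 15L) {
  stopifnot(length(mols) >= 1)
  ids <- vapply(mols, molId, character(1))
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  scaf <- vapply(mols, extractScaffold, character(1))
  classes <- split(ids, scaf)
  sizes <- lengths(classes)
  keep <- names(classes)[sizes >= minSize]
  if (length(keep) == 0)
    stop("no groups: every scaffold class has fewer than ", minSize,
         " members")
  ord <- order(-sizes[keep], keep)
  keep <- keep[ord]
  groups <- lapply(seq_along(keep), function(g)
    list(group_id = g, skeleton = keep[g],
         member_ids = unname(classes[[keep[g]]])))
  unassigned <- unname(unlist(classes[setdiff(names(classes), keep)]))
  if (is.null(unassigned)) unassigned <- character(0)
  new("GroupedDataset", groups = groups, unassigned = unassigned,
      split = character(0))
}

#' Random train/test split
#'
#' Uniform random split at the requested ratio (2:1 by default, the
#' train:test counts within one compound of the exact ratio), reported
#' with the activity range and median of both partitions so comparability
#' can be checked.
#'
#' @param mols list of Molecule.
#' @param ratio train:test ratio as a single number (default 2 for 2:1).
#' @param seed integer seed.
#' @return named character vector ("train"/"test") by molecule id, with a
#'   \code{summary} attribute (range and median of pIC50 per partition).
#' @export
splitTrainTest <- function(mols, ratio = 2, seed = 1L) {
  stopifnot(length(mols) >= 3)
  ids <- vapply(mols, molId, character(1))
  n <- length(ids)
  nTrain <- round(n * ratio / (ratio + 1))
  flags <- withSeed(seed, {
    trainIdx <- sample(n, nTrain)
    out <- rep("test", n)
    out[trainIdx] <- "train"
    out
  })
  names(flags) <- ids
  act <- vapply(mols, activity, numeric(1))
  summ <- lapply(c(train = "train", test = "test"), function(f) {
    a <- act[flags == f & is.finite(act)]
    if (length(a) == 0) return(c(min = NA, median = NA, max = NA))
    c(min = min(a), median = stats::median(a), max = max(a))
  })
  attr(flags, "summary") <- summ
  flags
}

#' Assign a query molecule to a scaffold group by mean Tanimoto similarity
#'
#' Returns the group with the highest mean fingerprint Tanimoto between
#' the query and the group's members; ties break to the lowest group id.
#'
#' @param query a Molecule (fingerprint computed if absent).
#' @param groupFps named list (by group id) of lists of member bit sets.
#' @return list with \code{group_id} (integer) and \code{mean_tc}.
#' @export
assignGroup <- function(query, groupFps) {
  qfp <- fingerprint(query)
  means <- vapply(groupFps, function(fps)
    mean(vapply(fps, function(f) tanimoto(qfp, f), numeric(1))),
    numeric(1))
  gids <- as.integer(names(groupFps))
  best <- which(means == max(means))
  pick <- best[which.min(gids[best])]
  list(group_id = gids[pick], mean_tc = unname(means[pick]))
}

# Convenience: per-group fingerprint lists from molecules + grouping.
groupFingerprints <- function(mols, grouped) {
  ids <- vapply(mols, molId, character(1))
  out <- list()
  for (g in grouped@groups) {
    fps <- lapply(g$member_ids, function(id)
      fingerprint(mols[[match(id, ids)]]))
    out[[as.character(g$group_id)]] <- fps
  }
  out
}
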