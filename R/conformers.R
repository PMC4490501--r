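# Conformer ensemble generation: deterministic torsion driving around
# rotatable bonds from an embedded starting geometry, followed by
# best-fit-RMSD pruning (retained pairs differ by more than the cutoff,
# 1.00 A by default). This implements a generic "diverse low-strain
# ensemble" contract: candidate geometries with atom clashes are rejected,
# no force-field energies are computed.

# Atoms on the `b` side of bond (a, b) (the side rotated by a torsion).
movingSide <- function(mol, a, b) {
  g <- molGraph(mol)
  eid <- igraph::get_edge_ids(g, c(a, b))
  g2 <- igraph::delete_edges(g, eid)
  comp <- igraph::components(g2)$membership
  which(comp == comp[as.character(b)])
}

hasClash <- function(mol, conf, minDist = 1.2) {
  n <- nrow(conf)
  if (n < 4) return(FALSE)
  d <- as.matrix(stats::dist(conf))
  bonded <- matrix(FALSE, n, n)
  b <- mol@bonds
  bonded[cbind(b$a1, b$a2)] <- TRUE
  bonded[cbind(b$a2, b$a1)] <- TRUE
  # 1-3 neighbours are geometrically close by construction; skip them too
  nb <- neighborList(mol)
  for (i in seq_len(n)) for (j in nb[[i]]) bonded[i, nb[[j]]] <- TRUE
  diag(bonded) <- TRUE
  any(d[!bonded] < minDist)
}

#' Generate a deduplicated conformer ensemble
#'
#' Starting from the molecule's first conformer (generated by the SMILES
#' reader or supplied in the SDF), torsion angles of all rotatable bonds
#' are driven through staggered offsets in a deterministic seeded order.
#' Candidates with steric clashes are discarded; retained conformers
#' differ pairwise by heavy-atom best-fit RMSD greater than
#' \code{rmsdCutoff}.
#'
#' @param mol a Molecule with at least one conformer.
#' @param maxCount maximum conformers to retain (default 32).
#' @param rmsdCutoff redundancy cutoff in Angstrom (default 1.00).
#' @param seed integer seed making the search order reproducible.
#' @param maxCandidates cap on generated candidate geometries.
#' @return the Molecule carrying 1..maxCount conformers.
#' @export
generateConformers <- function(mol, maxCount = 32L, rmsdCutoff = 1.00,
                               seed = 1L, maxCandidates = 200L) {
  stopifnot(maxCount >= 1)
  if (length(mol@conformers) == 0)
    stop("conformer embedding failed for molecule '", mol@id,
         "': no starting geometry")
  base <- mol@conformers[[1]]
  rb <- rotatableBonds(mol)$bonds
  candidates <- genTorsionCandidates(mol, base, rb, seed, maxCandidates)
  kept <- pruneByRmsd(candidates, rmsdCutoff, maxCount)
  mol@conformers <- stats::setNames(kept,
    paste0("conf", seq_along(kept)))
  validObject(mol)
  mol
}

# Enumerate torsion-offset combinations (0, +120, -120 degrees per
# rotatable bond) in a seeded random order, base geometry first.
genTorsionCandidates <- function(mol, base, rb, seed, maxCandidates) {
  nrot <- nrow(rb)
  if (nrot == 0) return(list(base))
  offsets <- c(0, 2 * pi / 3, -2 * pi / 3)
  ncomb <- min(3^nrot, 3^10)
  combos <- seq_len(ncomb) - 1L
  withSeed(seed, {
    ord <- c(1L, 1L + sample(ncomb - 1L))
    combos <- combos[ord]
    out <- list(base)
    for (code in combos[-1]) {
      if (length(out) >= maxCandidates) break
      conf <- base
      cc <- code
      ok <- TRUE
      for (r in seq_len(min(nrot, 10L))) {
        k <- cc %% 3L; cc <- cc %/% 3L
        if (k == 0L) next
        a <- rb$a1[r]; bx <- rb$a2[r]
        side <- movingSide(mol, a, bx)
        axis <- conf[bx, ] - conf[a, ]
        if (sum(axis^2) < 1e-12) { ok <- FALSE; break }
        conf[side, ] <- rotateAboutAxis(conf[side, , drop = FALSE],
                                        conf[a, ], axis, offsets[k + 1L])
      }
      if (ok && !hasClash(mol, conf)) out[[length(out) + 1L]] <- conf
    }
    out
  })
}

# Greedy first-fit pruning: keep a candidate iff its best-fit RMSD to every
# already-retained conformer exceeds the cutoff. Candidates are processed
# in a canonical order (lexicographic rounded coordinates), so the
# retained set does not depend on input order.
pruneByRmsd <- function(candidates, rmsdCutoff, maxCount = Inf) {
  keys <- vapply(candidates, function(cf)
    paste(sprintf("%.4f", cf), collapse = ","), character(1))
  candidates <- candidates[order(keys)]
  kept <- list()
  for (cf in candidates) {
    if (length(kept) >= maxCount) break
    redundant <- any(vapply(kept, function(k)
      bestFitRmsd(cf, k) <= rmsdCutoff, logical(1)))
    if (!redundant) kept[[length(kept) + 1L]] <- cf
  }
  if (length(kept) == 0) kept <- candidates[1]
  kept
}
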