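# Connection-table helpers: graphs, rings, hydrogen placement, and the
# OpenBabel bridge (SDF text round-trip, SMARTS matching, properties).

molGraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = data.frame(from = mol@bonds$a1, to = mol@bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nAtoms(mol))))
}

# Adjacency list (heavy atoms).
neighborList <- function(mol) {
  n <- nAtoms(mol)
  nb <- vector("list", n)
  b <- mol@bonds
  for (i in seq_len(nrow(b))) {
    nb[[b$a1[i]]] <- c(nb[[b$a1[i]]], b$a2[i])
    nb[[b$a2[i]]] <- c(nb[[b$a2[i]]], b$a1[i])
  }
  nb
}

bondOrderLookup <- function(mol) {
  b <- mol@bonds
  key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
  stats::setNames(b$order, key)
}

bondOrderOf <- function(lookup, i, j) {
  unname(lookup[paste(min(i, j), max(i, j))])
}

# Smallest rings: for every bond, the shortest cycle through it (the bond
# plus the shortest path between its atoms with the bond removed),
# deduplicated. Girth-bounded SSSR-style perception, adequate for typical
# drug-like ring systems.
findRings <- function(mol, maxSize = 7L) {
  if (nrow(mol@bonds) == 0) return(list())
  g <- molGraph(mol)
  b <- mol@bonds
  seen <- character(0)
  rings <- list()
  for (r in seq_len(nrow(b))) {
    i <- b$a1[r]; j <- b$a2[r]
    eid <- igraph::get_edge_ids(g, c(i, j))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(i), to = as.character(j))$vpath[[1]])
    if (length(sp) == 0) next
    ring <- as.integer(igraph::as_ids(sp))
    if (length(ring) < 3 || length(ring) > maxSize) next
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- ring  # already ordered along the cycle
  }
  rings
}

# Order ring atom indices along the cycle by walking adjacency.
orderRing <- function(mol, ringAtoms) {
  nb <- neighborList(mol)
  inRing <- ringAtoms
  cur <- inRing[1]; prev <- NA_integer_
  out <- cur
  while (length(out) < length(inRing)) {
    nxt <- setdiff(intersect(nb[[cur]], inRing),
                   c(prev, out[-length(out)]))
    if (length(nxt) == 0) return(ringAtoms)  # fallback: unordered
    prev <- cur; cur <- nxt[1]; out <- c(out, cur)
  }
  out
}

# A ring is aromatic when its double-bond count matches the Hueckel-like
# Kekule pattern (3 for 6-rings, 2 for 5-rings) and non-sp2 positions are
# lone-pair heteroatoms. Conservative; covers the standard aromatics.
ringIsAromatic <- function(mol, ring) {
  sz <- length(ring)
  if (!sz %in% c(5L, 6L)) return(FALSE)
  lk <- bondOrderLookup(mol)
  dbl <- 0L
  hasDouble <- logical(sz)
  for (i in seq_len(sz)) {
    j <- if (i == sz) 1L else i + 1L
    o <- bondOrderOf(lk, ring[i], ring[j])
    if (is.na(o)) return(FALSE)
    if (o == 2L) {
      dbl <- dbl + 1L
      hasDouble[i] <- TRUE
      hasDouble[j] <- TRUE
    }
  }
  need <- if (sz == 6L) 3L else 2L
  if (dbl != need) return(FALSE)
  el <- mol@atoms$element[ring]
  bare <- !hasDouble
  all(el[bare] %in% c("N", "O", "S"))
}

# Mark aromatic atoms from ring perception; returns the molecule with the
# atom table's aromatic column refreshed and the aromatic rings attached.
perceiveAromaticity <- function(mol) {
  rings <- findRings(mol)
  arom <- logical(nAtoms(mol))
  aromRings <- list()
  for (r in rings) {
    if (ringIsAromatic(mol, r)) {
      arom[r] <- TRUE
      aromRings[[length(aromRings) + 1L]] <- r
    }
  }
  mol@atoms$aromatic <- arom | mol@atoms$aromatic
  list(mol = mol, rings = aromRings)
}

aromaticRings <- function(mol) perceiveAromaticity(mol)$rings

# Standard valences used to place implicit hydrogens when importing
# structures that lack explicit counts.
standardValence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                     Br = 1, I = 1, B = 3, Si = 4)

# Approximate positions for the attached hydrogens of heavy atom `i`:
# distributed on directions away from the mean of the neighbours, 1.0 A
# bond length. Adequate for SMARTS export, donor vectors and donor-H
# rasterization; not a force-field geometry.
hydrogenPositions <- function(mol, conf, i) {
  nh <- mol@atoms$nH[i]
  if (nh == 0) return(matrix(numeric(0), 0, 3))
  p <- conf[i, ]
  nb <- neighborList(mol)[[i]]
  if (length(nb) == 0) {
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    away <- unitVector(p - colMeans(conf[nb, , drop = FALSE]))
    if (sqrt(sum(away^2)) < 1e-8) away <- c(0, 0, 1)
    # spread several H around the away direction
    ortho <- unitVector(pracmaNull(away))
    dirs <- rbind(away,
                  unitVector(away * 0.5 + ortho * 0.87),
                  unitVector(away * 0.5 - ortho * 0.87),
                  unitVector(c(away[2], -away[1], away[3])))
  }
  # position = heavy atom + 1.0 A along each direction
  sweep(dirs[seq_len(nh), , drop = FALSE] * 1.0, 2, p, `+`)
}

# Any vector orthogonal to v.
pracmaNull <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitVector(c(v[2] * a[3] - v[3] * a[2],
               v[3] * a[1] - v[1] * a[3],
               v[1] * a[2] - v[2] * a[1]))
}

# ---- SDF text export ------------------------------------------------------

fmt10 <- function(x) formatC(x, format = "f", digits = 4, width = 10)

#' Serialize a Molecule to an SDF (V2000) text block
#'
#' Explicit hydrogens are appended at generated positions so that
#' substructure patterns with hydrogen-count constraints match correctly
#' downstream.
#'
#' @param mol a Molecule.
#' @param confIdx conformer to export (a zero matrix is used when the
#'   molecule has no conformer yet).
#' @param explicitH append generated hydrogen atoms (default TRUE).
#' @return a single character scalar (molfile + "$$$$").
#' @export
molToSdfText <- function(mol, confIdx = 1L, explicitH = TRUE) {
  n <- nAtoms(mol)
  conf <- if (length(mol@conformers) >= confIdx && confIdx >= 1)
    mol@conformers[[confIdx]] else matrix(0, n, 3)
  el <- mol@atoms$element
  hxyz <- matrix(numeric(0), 0, 3); hpar <- integer(0)
  if (explicitH) {
    for (i in seq_len(n)) {
      hp <- hydrogenPositions(mol, conf, i)
      if (nrow(hp)) {
        hxyz <- rbind(hxyz, hp)
        hpar <- c(hpar, rep(i, nrow(hp)))
      }
    }
  }
  natoms <- n + nrow(hxyz)
  nbonds <- nrow(mol@bonds) + length(hpar)
  lines <- c(mol@id, "  combiphore", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     natoms, nbonds))
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%s%s%s %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      fmt10(conf[i, 1]), fmt10(conf[i, 2]), fmt10(conf[i, 3]), el[i]))
  for (i in seq_len(nrow(hxyz)))
    lines <- c(lines, sprintf("%s%s%s %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      fmt10(hxyz[i, 1]), fmt10(hxyz[i, 2]), fmt10(hxyz[i, 3]), "H"))
  b <- mol@bonds
  for (i in seq_len(nrow(b)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$a1[i], b$a2[i],
                              b$order[i]))
  for (i in seq_along(hpar))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", hpar[i], n + i, 1L))
  chg <- which(mol@atoms$charge != 0)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, mol@atoms$charge[grp]),
               collapse = "")))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  paste0(paste(lines, collapse = "\n"), "\n")
}

# ---- OpenBabel bridge -----------------------------------------------------

obNamespace <- function() getNamespace("ChemmineOB")

#' Match SMARTS patterns against a Molecule
#'
#' Runs OpenBabel SMARTS matching on the exported structure (explicit
#' hydrogens included) and returns, per pattern, the list of unique matches
#' as heavy-atom index vectors (hydrogen hits are dropped).
#'
#' @param mol a Molecule.
#' @param patterns character vector of SMARTS.
#' @return named list (by pattern) of lists of integer vectors.
#' @export
matchSmarts <- function(mol, patterns) {
  ns <- obNamespace()
  sdf <- molToSdfText(mol)
  nheavy <- nAtoms(mol)
  out <- stats::setNames(vector("list", length(patterns)), patterns)
  ChemmineOB::forEachMol("SDF", sdf, function(obmol) {
    for (p in patterns) {
      sp <- ns$OBSmartsPattern()
      if (!ns$OBSmartsPattern_Init(sp, p))
        stop("invalid SMARTS pattern: ", p)
      ns$OBSmartsPattern_Match(sp, obmol)
      umap <- ns$OBSmartsPattern_GetUMapList(sp)
      res <- lapply(umap, function(ix) {
        ix <- as.integer(ix)
        ix[ix <= nheavy]
      })
      out[[p]] <<- res[lengths(res) > 0]
    }
    invisible(NULL)
  })
  out
}

#' Canonical SMILES of a Molecule (via OpenBabel)
#'
#' @param mol a Molecule.
#' @return canonical SMILES string.
#' @export
canonicalSmiles <- function(mol) {
  smi <- ChemmineOB::convertFormat("SDF", "CAN", molToSdfText(mol))
  strsplit(trimws(smi), "[ \t]")[[1]][1]
}

#' Physicochemical properties of a Molecule (via OpenBabel)
#'
#' @param mol a Molecule.
#' @return named list: MW, logP, HBD, HBA, TPSA.
#' @export
molProperties <- function(mol) {
  p <- NULL
  ChemmineOB::forEachMol("SDF", molToSdfText(mol), function(obmol) {
    p <<- ChemmineOB::prop_OB(obmol)
    invisible(NULL)
  })
  list(MW = as.numeric(p$MW), logP = as.numeric(p$logP),
       HBD = as.numeric(p$HBD), HBA = as.numeric(p$HBA2),
       TPSA = as.numeric(p$TPSA))
}

#' Count rotatable bonds
#'
#' Single acyclic bonds between two non-terminal heavy atoms, excluding
#' amide C-N bonds.
#'
#' @param mol a Molecule.
#' @return list with \code{count} and \code{bonds} (data.frame a1, a2).
#' @export
rotatableBonds <- function(mol) {
  b <- mol@bonds
  if (nrow(b) == 0)
    return(list(count = 0L, bonds = data.frame(a1 = integer(0),
                                               a2 = integer(0))))
  deg <- tabulate(c(b$a1, b$a2), nbins = nAtoms(mol))
  rings <- findRings(mol, maxSize = 12L)
  inRingBond <- function(i, j) {
    any(vapply(rings, function(r) {
      pos <- match(c(i, j), r)
      all(!is.na(pos))
    }, logical(1)))
  }
  lk <- bondOrderLookup(mol)
  amide <- function(i, j) {
    # C(=O)-N single bond
    el <- mol@atoms$element
    for (ord in list(c(i, j), c(j, i))) {
      ci <- ord[1]; ni <- ord[2]
      if (el[ci] == "C" && el[ni] == "N") {
        nb <- neighborList(mol)[[ci]]
        if (any(el[nb] == "O" &
                vapply(nb, function(x) identical(bondOrderOf(lk, ci, x), 2L),
                       logical(1)) & el[nb] == "O")) return(TRUE)
      }
    }
    FALSE
  }
  keep <- logical(nrow(b))
  for (r in seq_len(nrow(b))) {
    i <- b$a1[r]; j <- b$a2[r]
    keep[r] <- b$order[r] == 1L && deg[i] > 1L && deg[j] > 1L &&
      !inRingBond(i, j) && !amide(i, j)
  }
  list(count = sum(keep), bonds = b[keep, c("a1", "a2"), drop = FALSE])
}
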