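# Common pharmacophore hypothesis (CPH) search. k-point pharmacophores
# (k = 4, 5, 6) of all highly active ligands are enumerated, encoded as
# canonically ordered inter-site distance vectors, and co-located in
# distance space by a recursive partition (cells halved from a 4 A
# initial width down to 1 A final cells, with registration to neighbour
# cells within 0.5 A to avoid boundary misses). A cell populated by
# enough distinct actives yields one hypothesis whose sites come from a
# contributing reference ligand.

# Canonical ordering of a k-subset of sites: sort by feature letter, ties
# broken by each site's sorted distance profile to the other selected
# sites (lexicographic), then by site index.
canonicalSiteOrder <- function(types, dmat) {
  k <- length(types)
  profiles <- lapply(seq_len(k), function(i) sort(dmat[i, -i]))
  keys <- vapply(seq_len(k), function(i)
    paste(types[i], paste(sprintf("%012.6f", profiles[[i]]),
                          collapse = ","), sprintf("%04d", i)),
    character(1))
  order(keys)
}

#' Enumerate k-point pharmacophores of a site set
#'
#' All C(n, k) combinations, each reported with its sorted feature label
#' and canonically ordered inter-site distance vector.
#'
#' @param sites list of PharmacophoreSite.
#' @param k number of points.
#' @return list of lists: \code{label}, \code{dvec}, \code{siteIdx}
#'   (indices into \code{sites}, in canonical order). Empty when
#'   \code{length(sites) < k}.
#' @export
enumeratePharmacophores <- function(sites, k) {
  n <- length(sites)
  if (n < k) return(list())
  pos <- sitePositions(sites)
  types <- siteTypes(sites)
  combos <- utils::combn(n, k, simplify = FALSE)
  lapply(combos, function(ix) {
    sub <- pos[ix, , drop = FALSE]
    dmat <- as.matrix(stats::dist(sub))
    ord <- canonicalSiteOrder(types[ix], dmat)
    ix <- ix[ord]
    dmat <- dmat[ord, ord]
    list(label = paste(sort(types[ix]), collapse = ""),
         dvec = dmat[upper.tri(dmat)],
         siteIdx = ix)
  })
}

# Register a distance vector to its final partition cell and to every
# neighbour cell within `tol`; the expansion is capped, closest-to-
# boundary dimensions first.
cellKeys <- function(dvec, width, tol, maxCells = 256L) {
  base <- floor(dvec / width)
  frac <- dvec / width - base
  alts <- lapply(seq_along(dvec), function(d) {
    ks <- base[d]
    if (frac[d] < tol / width) ks <- c(ks, base[d] - 1)
    if (frac[d] > 1 - tol / width) ks <- c(ks, base[d] + 1)
    ks
  })
  # expand dimensions nearest a boundary first, under the cap
  nAlt <- lengths(alts)
  ordDims <- order(-(nAlt > 1), pmin(frac, 1 - frac))
  grids <- list(base)
  for (d in ordDims) {
    if (nAlt[d] == 1) next
    if (length(grids) * nAlt[d] > maxCells) break
    grids <- unlist(lapply(grids, function(g) {
      lapply(alts[[d]], function(v) { g[d] <- v; g })
    }), recursive = FALSE)
  }
  unique(vapply(grids, function(g) paste(g, collapse = ":"), character(1)))
}

#' Find common pharmacophore hypotheses among active ligands
#'
#' @param actives list of Molecule, each with at least one conformer and a
#'   finite activity (the reference ligand is the highest-pIC50
#'   contributor of a surviving cell).
#' @param k points per pharmacophore (4, 5 or 6).
#' @param mustMatch number of distinct actives that must co-locate in one
#'   cell. Default \code{NULL}: first all actives, then (if nothing is
#'   found) the smallest count exceeding two-thirds of the actives.
#' @param dMin final partition cell width in Angstrom (default 1).
#' @param neighborTol neighbour-registration tolerance in Angstrom
#'   (default 0.5).
#' @return list of \code{Hypothesis}, deterministically ordered, with a
#'   \code{mustMatch} attribute recording the threshold actually used.
#' @export
findCommonPharmacophores <- function(actives, k, mustMatch = NULL,
                                     dMin = 1.0, neighborTol = 0.5) {
  stopifnot(length(actives) >= 2, k %in% 4:6)
  nAct <- length(actives)
  entries <- list()   # one per (active, conformer, combo)
  siteCache <- vector("list", nAct)
  for (a in seq_len(nAct)) {
    mol <- actives[[a]]
    siteCache[[a]] <- vector("list", max(1L, length(mol@conformers)))
    for (ci in seq_along(mol@conformers)) {
      sites <- cachedSites(mol, ci)
      siteCache[[a]][[ci]] <- sites
      for (ph in enumeratePharmacophores(sites, k)) {
        ph$active <- a; ph$conf <- ci
        entries[[length(entries) + 1L]] <- ph
      }
    }
  }
  if (length(entries) == 0)
    stop("no common pharmacophore: no ligand offers ", k, " sites")
  thresholds <- if (!is.null(mustMatch)) mustMatch else {
    fb <- floor(2 * nAct / 3) + 1L   # exceeds two-thirds, less than all
    unique(c(nAct, min(fb, nAct - 1L)))
  }
  thresholds <- thresholds[thresholds >= 2]
  labels <- vapply(entries, `[[`, character(1), "label")
  for (mm in thresholds) {
    hyps <- searchCells(entries, labels, actives, siteCache, mm, dMin,
                        neighborTol)
    if (length(hyps) > 0) {
      attr(hyps, "mustMatch") <- mm
      return(hyps)
    }
  }
  stop("no common pharmacophore found for k = ", k,
       " even at the two-thirds match threshold")
}

searchCells <- function(entries, labels, actives, siteCache, mustMatch,
                        dMin, neighborTol) {
  acts <- vapply(actives, activity, numeric(1))
  ids <- vapply(actives, molId, character(1))
  out <- list()
  for (lab in sort(unique(labels))) {
    sel <- which(labels == lab)
    # which actives carry this label at all
    if (length(unique(vapply(entries[sel], `[[`, numeric(1), "active")))
        < mustMatch) next
    cellMap <- new.env(parent = emptyenv())
    for (ei in sel) {
      for (key in cellKeys(entries[[ei]]$dvec, dMin, neighborTol)) {
        cellMap[[key]] <- c(cellMap[[key]], ei)
      }
    }
    seenRef <- character(0)
    for (key in sort(ls(cellMap))) {
      eis <- cellMap[[key]]
      whichAct <- vapply(entries[eis], `[[`, numeric(1), "active")
      if (length(unique(whichAct)) < mustMatch) next
      # reference ligand: contributing active with highest pIC50
      uAct <- unique(whichAct)
      refA <- uAct[order(-acts[uAct], ids[uAct])][1]
      refEis <- eis[whichAct == refA]
      # among the reference's combos in this cell, the one closest to the
      # cell's member centroid
      ctr <- colMeans(do.call(rbind,
        lapply(entries[eis], `[[`, "dvec")))
      dd <- vapply(entries[refEis], function(e)
        sum((e$dvec - ctr)^2), numeric(1))
      refE <- entries[[refEis[which.min(dd)]]]
      refKey <- paste(refA, refE$conf, paste(refE$siteIdx, collapse = ","))
      if (refKey %in% seenRef) next
      seenRef <- c(seenRef, refKey)
      out[[length(out) + 1L]] <- buildHypothesis(
        actives[[refA]], refE, siteCache[[refA]][[refE$conf]],
        nMatched = length(unique(whichAct)))
    }
  }
  if (length(out) == 0) return(out)
  ord <- order(vapply(out, function(h) paste(h@label, h@referenceId,
    paste(sprintf("%.4f", h@distances[upper.tri(h@distances)]),
          collapse = ",")), character(1)))
  out[ord]
}

buildHypothesis <- function(refMol, entry, sites, nMatched) {
  selSites <- sites[entry$siteIdx]
  pos <- sitePositions(selSites)
  dmat <- as.matrix(stats::dist(pos))
  dimnames(dmat) <- NULL
  new("Hypothesis",
      k = as.integer(length(selSites)), sites = selSites,
      label = entry$label, referenceId = molId(refMol),
      referenceConformer = refMol@conformers[[entry$conf]],
      referenceMol = refMol,
      distances = dmat,
      nActivesMatched = as.integer(nMatched))
}
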