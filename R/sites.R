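# Pharmacophore site perception: hydrogen-bond acceptors (A) and donors
# (D) at heavy-atom positions with direction vectors, aromatic rings (R)
# at centroids with normals, hydrophobic groups (H) at fragment centroids,
# and charged groups (N/P) at group centroids. A/D/N/P are driven by the
# shipped substructure pattern set; R and H are perceived from the ring
# system and the nonpolar fragment structure.

#' Construct a PharmacophoreSite
#' @param type feature letter (A, D, H, N, P, R).
#' @param position xyz (Angstrom).
#' @param direction optional unit xyz.
#' @param atoms defining heavy-atom indices.
#' @return a \code{PharmacophoreSite}.
#' @export
PharmacophoreSite <- function(type, position, direction = numeric(0),
                              atoms = integer(0)) {
  if (length(direction) == 3) direction <- unitVector(direction)
  new("PharmacophoreSite", type = type, position = as.numeric(position),
      direction = as.numeric(direction), atoms = as.integer(atoms))
}

setMethod("show", "PharmacophoreSite", function(object) {
  cat(sprintf("%s site at (%.2f, %.2f, %.2f)%s\n", object@type,
              object@position[1], object@position[2], object@position[3],
              if (length(object@direction)) " [directed]" else ""))
})

# Direction pointing away from the bonded neighbours (lone-pair / X-H
# proxy); NULL when undefined.
awayDirection <- function(mol, conf, i) {
  nb <- neighborList(mol)[[i]]
  if (length(nb) == 0) return(NULL)
  v <- conf[i, ] - colMeans(conf[nb, , drop = FALSE])
  if (sqrt(sum(v^2)) < 1e-8) return(NULL)
  unitVector(v)
}

ringNormal <- function(coords) {
  c0 <- sweep(coords, 2, colMeans(coords))
  sv <- svd(c0)
  unitVector(sv$v[, 3])
}

# Hydrophobic fragments: connected components of aliphatic carbons with no
# polar (N, O, charged) neighbour, plus halogens. Aromatic carbons belong
# to R sites and are excluded.
hydrophobicFragments <- function(mol) {
  el <- mol@atoms$element
  nb <- neighborList(mol)
  polarNbr <- vapply(seq_len(nAtoms(mol)), function(i)
    any(el[nb[[i]]] %in% c("N", "O")) ||
      any(mol@atoms$charge[nb[[i]]] != 0), logical(1))
  isHyd <- (el == "C" & !mol@atoms$aromatic & !polarNbr &
              mol@atoms$charge == 0) |
    el %in% c("F", "Cl", "Br", "I")
  idx <- which(isHyd)
  if (length(idx) == 0) return(list())
  g <- molGraph(mol)
  sub <- igraph::induced_subgraph(g, as.character(idx))
  comp <- igraph::components(sub)$membership
  split(as.integer(igraph::V(sub)$name), comp)
}

#' Perceive pharmacophore sites on a conformer
#'
#' @param mol a Molecule.
#' @param conf conformer coordinate matrix (default: first conformer).
#' @return list of \code{PharmacophoreSite} (possibly empty).
#' @export
perceiveSites <- function(mol, conf = conformer(mol)) {
  stopifnot(nrow(conf) == nAtoms(mol))
  ar <- atomRoles(mol)
  sites <- list()
  addSite <- function(s) sites[[length(sites) + 1L]] <<- s
  # charged groups first so their atoms are excluded from A/D
  chargedAtoms <- integer(0)
  for (f in c("N", "P")) {
    seen <- character(0)
    for (m in ar$matches[[f]]) {
      key <- paste(sort(m), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      pos <- colMeans(conf[m, , drop = FALSE])
      addSite(PharmacophoreSite(f, pos, atoms = m))
      chargedAtoms <- union(chargedAtoms, m)
    }
  }
  accAtoms <- setdiff(unique(unlist(ar$matches$A)), chargedAtoms)
  for (i in accAtoms) {
    dir <- awayDirection(mol, conf, i)
    addSite(PharmacophoreSite("A", conf[i, ],
      direction = if (is.null(dir)) numeric(0) else dir, atoms = i))
  }
  donAtoms <- setdiff(unique(unlist(ar$matches$D)), chargedAtoms)
  for (i in donAtoms) {
    dir <- awayDirection(mol, conf, i)
    addSite(PharmacophoreSite("D", conf[i, ],
      direction = if (is.null(dir)) numeric(0) else dir, atoms = i))
  }
  for (ring in aromaticRings(mol)) {
    coords <- conf[ring, , drop = FALSE]
    addSite(PharmacophoreSite("R", colMeans(coords),
      direction = ringNormal(coords), atoms = ring))
  }
  for (frag in hydrophobicFragments(mol)) {
    addSite(PharmacophoreSite("H", colMeans(conf[frag, , drop = FALSE]),
                              atoms = frag))
  }
  sites
}

siteTypes <- function(sites) vapply(sites, function(s) s@type, character(1))

sitePositions <- function(sites) {
  do.call(rbind, lapply(sites, function(s) s@position))
}
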