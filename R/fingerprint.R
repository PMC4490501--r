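# Circular functional-class fingerprint (FCFP4-analogue) and Tanimoto
# similarity. Atom roles (acceptor, donor, ionizable, aromatic, halogen)
# come from the shipped substructure pattern set, so the fingerprint sees
# pharmacophoric roles rather than element identities; environments of
# diameter 4 (radius 0..2) are hashed into a 2048-bit space.

.patternCache <- new.env(parent = emptyenv())

#' Shipped feature pattern set
#'
#' Reads the editable SMARTS pattern config (feature, mode, smarts).
#' Override the file via \code{options(combiphore.featurePatterns = path)}.
#'
#' @return data.frame with columns feature, mode, smarts.
#' @export
featurePatterns <- function() {
  path <- getOption("combiphore.featurePatterns",
    system.file("extdata", "feature_patterns.json",
                package = "combiphore"))
  key <- paste0("pat:", path)
  if (!is.null(.patternCache[[key]])) return(.patternCache[[key]])
  pat <- jsonlite::fromJSON(path)
  .patternCache[[key]] <- pat
  pat
}

#' van der Waals radius table
#'
#' @return named numeric vector of radii (Angstrom) by element; unknown
#'   elements fall back to 1.70.
#' @export
vdwRadii <- function() {
  path <- getOption("combiphore.vdwRadii",
    system.file("extdata", "vdw_radii.csv", package = "combiphore"))
  key <- paste0("vdw:", path)
  if (!is.null(.patternCache[[key]])) return(.patternCache[[key]])
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  r <- stats::setNames(tab$radius, tab$element)
  .patternCache[[key]] <- r
  r
}

vdwRadiusOf <- function(elements) {
  r <- vdwRadii()[elements]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Match the full pattern set once and return per-feature match lists plus
# per-atom role flags.
atomRoles <- function(mol) {
  pat <- featurePatterns()
  matches <- matchSmarts(mol, unique(pat$smarts))
  n <- nAtoms(mol)
  roles <- data.frame(
    acceptor = logical(n), donor = logical(n), neg = logical(n),
    pos = logical(n), aromatic = mol@atoms$aromatic,
    halogen = mol@atoms$element %in% c("F", "Cl", "Br", "I"))
  featMatches <- list(A = list(), D = list(), N = list(), P = list())
  for (i in seq_len(nrow(pat))) {
    f <- pat$feature[i]
    for (m in matches[[pat$smarts[i]]]) {
      featMatches[[f]] <- c(featMatches[[f]], list(m))
      col <- switch(f, A = "acceptor", D = "donor", N = "neg", P = "pos")
      roles[[col]][m] <- TRUE
    }
  }
  list(roles = roles, matches = featMatches)
}

# Deterministic integer hashing (polynomial accumulation mod a prime well
# below 2^31, so plain double arithmetic stays exact).
.hp <- 2147483629
hashMix <- function(values) {
  h <- 17
  for (v in values) h <- (h * 1000003 + (v %% .hp)) %% .hp
  h
}

#' Compute the circular functional-class fingerprint of a molecule
#'
#' Radius 0..2 (diameter 4) neighbourhood environments over six atom
#' roles, hashed to a 2048-bit space. Deterministic and invariant to atom
#' input order.
#'
#' @param mol a Molecule.
#' @param nBits hash space size (default 2048).
#' @return sorted integer vector of set bit ids in [0, nBits).
#' @export
computeFingerprint <- function(mol, nBits = 2048L) {
  rl <- atomRoles(mol)$roles
  n <- nAtoms(mol)
  inv <- rl$acceptor * 1 + rl$donor * 2 + rl$neg * 4 + rl$pos * 8 +
    rl$aromatic * 16 + rl$halogen * 32
  nb <- neighborList(mol)
  lk <- bondOrderLookup(mol)
  codes <- vapply(seq_len(n), function(i) hashMix(c(1, inv[i])),
                  numeric(1))
  allCodes <- codes
  h <- codes
  for (r in 1:2) {
    newH <- numeric(n)
    for (i in seq_len(n)) {
      nbrs <- nb[[i]]
      if (length(nbrs) == 0) {
        newH[i] <- hashMix(c(r + 1, h[i]))
      } else {
        pairCodes <- sort(vapply(nbrs, function(j)
          hashMix(c(bondOrderOf(lk, i, j), h[j])), numeric(1)))
        newH[i] <- hashMix(c(r + 1, h[i], pairCodes))
      }
    }
    h <- newH
    allCodes <- c(allCodes, h)
  }
  sort(unique(as.integer(allCodes %% nBits)))
}

#' Attach fingerprints to molecules
#'
#' @param mols list of Molecule.
#' @return the list, every element carrying its fingerprint.
#' @export
addFingerprints <- function(mols) {
  lapply(mols, function(m) {
    if (length(m@fingerprint) == 0)
      m@fingerprint <- computeFingerprint(m)
    m
  })
}

#' Tanimoto coefficient between two bit sets
#'
#' |intersection| / |union|. Two empty sets are defined as similarity 0
#' (with a warning): the mathematically undefined case must not create
#' spurious dispatch ties.
#'
#' @param a,b integer vectors of set bit ids.
#' @return number in [0, 1].
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    warning("Tanimoto of two empty bit sets defined as 0")
    return(0)
  }
  length(intersect(a, b)) / length(union(a, b))
}
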