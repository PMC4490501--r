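#' @import methods
NULL

#' Molecule: connection table, conformers, activity, fingerprint
#'
#' Central small-molecule container. Heavy atoms only are stored explicitly;
#' attached hydrogens are kept as per-atom counts. Conformers are named
#' n-by-3 coordinate matrices in Angstrom. Activity, when present, is a
#' pIC50 (-log10 of the molar IC50).
#'
#' @slot id character compound identifier.
#' @slot atoms data.frame with columns \code{element}, \code{charge},
#'   \code{aromatic}, \code{nH} (one row per heavy atom).
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{order}
#'   (1, 2, 3; Kekule convention, aromatic rings alternate 1/2).
#' @slot conformers list of numeric matrices (nAtoms x 3), named.
#' @slot activity numeric pIC50, \code{NA_real_} when unknown.
#' @slot fingerprint integer vector of sorted fingerprint bit ids
#'   (length 0 = not yet computed).
#' @exportClass Molecule
setClass("Molecule",
  slots = c(
    id          = "character",
    atoms       = "data.frame",
    bonds       = "data.frame",
    conformers  = "list",
    activity    = "numeric",
    fingerprint = "integer"
  ),
  prototype = list(
    id = "", atoms = data.frame(), bonds = data.frame(),
    conformers = list(), activity = NA_real_, fingerprint = integer(0)
  )
)

setValidity("Molecule", function(object) {
  msgs <- character(0)
  n <- nrow(object@atoms)
  if (n < 1) msgs <- c(msgs, "molecule must have at least 1 heavy atom")
  req <- c("element", "charge", "aromatic", "nH")
  if (!all(req %in% names(object@atoms)))
    msgs <- c(msgs, "atoms must have columns element, charge, aromatic, nH")
  if (nrow(object@bonds) > 0) {
    if (!all(c("a1", "a2", "order") %in% names(object@bonds)))
      msgs <- c(msgs, "bonds must have columns a1, a2, order")
    else {
      idx <- c(object@bonds$a1, object@bonds$a2)
      if (any(idx < 1 | idx > n))
        msgs <- c(msgs, "bond references an invalid atom index")
    }
  }
  for (cf in object@conformers) {
    if (!is.matrix(cf) || nrow(cf) != n || ncol(cf) != 3)
      msgs <- c(msgs, "each conformer must be an nAtoms x 3 matrix")
    else if (!all(is.finite(cf)))
      msgs <- c(msgs, "conformer coordinates must be finite")
  }
  if (length(object@activity) != 1)
    msgs <- c(msgs, "activity must have length 1")
  else if (!is.na(object@activity) && !is.finite(object@activity))
    msgs <- c(msgs, "activity, when present, must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Molecule
#'
#' @param id compound identifier.
#' @param atoms data.frame (element, charge, aromatic, nH).
#' @param bonds data.frame (a1, a2, order).
#' @param conformers list of nAtoms x 3 coordinate matrices.
#' @param activity pIC50 or NA.
#' @param fingerprint optional integer bit-id vector.
#' @return a \code{Molecule}.
#' @export
Molecule <- function(id, atoms, bonds, conformers = list(),
                     activity = NA_real_, fingerprint = integer(0)) {
  atoms$element  <- as.character(atoms$element)
  atoms$charge   <- as.integer(atoms$charge)
  atoms$aromatic <- as.logical(atoms$aromatic)
  atoms$nH       <- as.integer(atoms$nH)
  if (nrow(bonds) > 0) {
    bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.integer(bonds$order)
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  conformers <- lapply(conformers, function(cf) {
    cf <- as.matrix(cf); storage.mode(cf) <- "double"
    dimnames(cf) <- NULL
    cf
  })
  new("Molecule", id = as.character(id), atoms = atoms, bonds = bonds,
      conformers = conformers, activity = as.numeric(activity),
      fingerprint = as.integer(fingerprint))
}

#' Pharmacophore site
#'
#' One perceived chemical feature with a position and, for directional
#' features (A, D, R), a unit direction vector.
#'
#' @slot type single letter in A, D, H, N, P, R.
#' @slot position numeric xyz in Angstrom.
#' @slot direction numeric xyz unit vector, or length 0 when undirected.
#' @slot atoms integer indices of the heavy atoms defining the site.
#' @exportClass PharmacophoreSite
setClass("PharmacophoreSite",
  slots = c(type = "character", position = "numeric",
            direction = "numeric", atoms = "integer"))

setValidity("PharmacophoreSite", function(object) {
  msgs <- character(0)
  if (!object@type %in% c("A", "D", "H", "N", "P", "R"))
    msgs <- c(msgs, "feature type must be one of A, D, H, N, P, R")
  if (length(object@position) != 3 || !all(is.finite(object@position)))
    msgs <- c(msgs, "position must be a finite xyz triple")
  if (length(object@direction) > 0) {
    if (length(object@direction) != 3)
      msgs <- c(msgs, "direction must be an xyz triple")
    else if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
      msgs <- c(msgs, "direction must be a unit vector")
  }
  if (length(msgs)) msgs else TRUE
})

#' Common pharmacophore hypothesis
#'
#' A k-point pharmacophore taken from a reference ligand conformer, with
#' its inter-site distance matrix and survival-score components.
#'
#' @slot k number of sites (4, 5 or 6).
#' @slot sites list of \code{PharmacophoreSite}.
#' @slot label sorted feature string, e.g. "ARRR".
#' @slot referenceId id of the contributing reference ligand.
#' @slot referenceConformer coordinates of the reference ligand conformer
#'   (heavy atoms) used for volume scoring.
#' @slot referenceMol the reference \code{Molecule} (atom table needed for
#'   volume scoring radii); may be NULL after deserialization.
#' @slot distances k x k symmetric matrix in Angstrom.
#' @slot scoreComponents named numeric (alignment, vector, volume).
#' @slot survival numeric survival score.
#' @slot nActivesMatched integer.
#' @exportClass Hypothesis
setClass("Hypothesis",
  slots = c(
    k = "integer", sites = "list", label = "character",
    referenceId = "character", referenceConformer = "matrix",
    referenceMol = "ANY", distances = "matrix",
    scoreComponents = "numeric", survival = "numeric",
    nActivesMatched = "integer"
  ),
  prototype = list(scoreComponents = c(alignment = NA_real_,
    vector = NA_real_, volume = NA_real_), survival = NA_real_,
    nActivesMatched = NA_integer_, referenceMol = NULL))

setValidity("Hypothesis", function(object) {
  msgs <- character(0)
  if (!object@k %in% 4:6) msgs <- c(msgs, "k must be 4, 5 or 6")
  if (length(object@sites) != object@k)
    msgs <- c(msgs, "number of sites must equal k")
  lab <- strsplit(object@label, "")[[1]]
  if (is.unsorted(lab)) msgs <- c(msgs, "label letters must be sorted")
  d <- object@distances
  if (!all(dim(d) == c(object@k, object@k)))
    msgs <- c(msgs, "distances must be k x k")
  else {
    if (max(abs(d - t(d))) > 1e-9 || any(abs(diag(d)) > 1e-9))
      msgs <- c(msgs, "distances must be symmetric with zero diagonal")
  }
  if (length(msgs)) msgs else TRUE
})

#' Grid specification for atom-based QSAR
#'
#' @slot origin numeric xyz of the grid corner (Angstrom).
#' @slot spacing cube edge, default 1 Angstrom.
#' @slot extents integer cube counts per axis.
#' @slot channels character vector of atom-type labels.
#' @exportClass GridSpec
setClass("GridSpec",
  slots = c(origin = "numeric", spacing = "numeric",
            extents = "integer", channels = "character"),
  prototype = list(spacing = 1,
                   channels = c("D", "H", "N", "P", "W", "X")))

setValidity("GridSpec", function(object) {
  msgs <- character(0)
  if (object@spacing <= 0) msgs <- c(msgs, "spacing must be positive")
  if (length(object@extents) != 3 || any(object@extents < 1))
    msgs <- c(msgs, "extents must be three positive counts")
  if (length(msgs)) msgs else TRUE
})

#' Fitted atom-based grid QSAR model
#'
#' Sparse per-bit partial-least-squares regression coefficients over
#' (cube, channel) occupancy bits, with training statistics.
#'
#' @slot grid a \code{GridSpec}.
#' @slot bits character ids ("ix:iy:iz:channel") of bits seen in training.
#' @slot coefficients numeric, parallel to \code{bits}.
#' @slot intercept numeric.
#' @slot nFactors integer PLS factor count (3).
#' @slot stats named numeric: r2, sd, f, p, stability, q2_loo.
#' @slot hypothesisRef character id of the hypothesis used for alignment.
#' @exportClass QsarModel
setClass("QsarModel",
  slots = c(grid = "GridSpec", bits = "character",
            coefficients = "numeric", intercept = "numeric",
            nFactors = "integer", stats = "numeric",
            hypothesisRef = "character"))

setValidity("QsarModel", function(object) {
  msgs <- character(0)
  if (length(object@bits) != length(object@coefficients))
    msgs <- c(msgs, "one coefficient per training bit required")
  if (length(msgs)) msgs else TRUE
})

#' Scaffold-grouped dataset with train/test split
#'
#' @slot groups list of lists (group_id, skeleton, member_ids).
#' @slot unassigned character ids in below-threshold scaffold classes.
#' @slot split named character vector ("train"/"test") by molecule id.
#' @exportClass GroupedDataset
setClass("GroupedDataset",
  slots = c(groups = "list", unassigned = "character", split = "character"),
  prototype = list(groups = list(), unassigned = character(0),
                   split = character(0)))

setValidity("GroupedDataset", function(object) {
  ids <- c(unlist(lapply(object@groups, `[[`, "member_ids")),
           object@unassigned)
  if (anyDuplicated(ids))
    "molecule ids must be unique across groups and unassigned"
  else TRUE
})

#' Combinatorial pharmacophore QSAR model
#'
#' One (hypothesis, QSAR model) pair per scaffold group plus the training
#' fingerprints backing the mean-Tanimoto dispatch rule.
#'
#' @slot entries named list (by group id) of lists with elements
#'   \code{hypothesis}, \code{qsar}, \code{fingerprints},
#'   \code{trainingIds}, \code{trainingMean}.
#' @slot dispatch list of dispatch parameters (fingerprint kind, tie rule).
#' @exportClass CombinatorialModel
setClass("CombinatorialModel",
  slots = c(entries = "list", dispatch = "list"),
  prototype = list(dispatch = list(fingerprint = "fcfp4-2048",
                                   tie = "lowest-group-id")))

setValidity("CombinatorialModel", function(object) {
  if (length(object@entries) < 1) return("at least one group entry required")
  ok <- vapply(object@entries, function(e) {
    is(e$hypothesis, "Hypothesis") && is(e$qsar, "QsarModel") &&
      all(is.finite(e$qsar@stats[c("r2", "sd", "f")]))
  }, logical(1))
  if (!all(ok)) "every entry needs a hypothesis and a finite-stats model"
  else TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d heavy atoms, %d bonds, %d conformer(s)",
              object@id, nrow(object@atoms), nrow(object@bonds),
              length(object@conformers)))
  if (!is.na(object@activity))
    cat(sprintf(", pIC50 = %.2f", object@activity))
  cat("\n")
})

setMethod("show", "Hypothesis", function(object) {
  cat(sprintf("Hypothesis %s (k = %d) from '%s'", object@label, object@k,
              object@referenceId))
  if (!is.na(object@survival))
    cat(sprintf(", survival = %.3f (%d actives matched)",
                object@survival, object@nActivesMatched))
  cat("\n")
})

setMethod("show", "QsarModel", function(object) {
  cat(sprintf("QsarModel: %d occupied bits, %d PLS factors\n",
              length(object@bits), object@nFactors))
  s <- object@stats
  cat(sprintf("  R2 = %.3f  SD = %.3f  F = %.1f  p = %.2g  Q2(LOO) = %.3f  stability = %.3f\n",
              s["r2"], s["sd"], s["f"], s["p"], s["q2_loo"], s["stability"]))
})

setMethod("show", "GroupedDataset", function(object) {
  cat(sprintf("GroupedDataset: %d group(s), %d unassigned\n",
              length(object@groups), length(object@unassigned)))
  for (g in object@groups)
    cat(sprintf("  group %d: %d members\n", g$group_id,
                length(g$member_ids)))
})

setMethod("show", "CombinatorialModel", function(object) {
  cat(sprintf("CombinatorialModel: %d group model(s)\n",
              length(object@entries)))
  for (gid in names(object@entries)) {
    e <- object@entries[[gid]]
    cat(sprintf("  group %s: hypothesis %s, R2 = %.3f\n", gid,
                e$hypothesis@label, e$qsar@stats["r2"]))
  }
})

# ---- accessors ------------------------------------------------------------

#' @describeIn Molecule compound id
#' @param mol a Molecule
#' @export
molId <- function(mol) mol@id

#' @describeIn Molecule heavy-atom table
#' @export
atomTable <- function(mol) mol@atoms

#' @describeIn Molecule bond table
#' @export
bondTable <- function(mol) mol@bonds

#' @describeIn Molecule number of heavy atoms
#' @export
nAtoms <- function(mol) nrow(mol@atoms)

#' @describeIn Molecule conformer list
#' @export
conformers <- function(mol) mol@conformers

#' @describeIn Molecule a single conformer coordinate matrix
#' @param i conformer index
#' @export
conformer <- function(mol, i = 1L) mol@conformers[[i]]

#' @describeIn Molecule activity (pIC50)
#' @export
activity <- function(mol) mol@activity

#' Set the activity (pIC50) of a Molecule
#' @param mol a Molecule
#' @param value pIC50
#' @export
`activity<-` <- function(mol, value) {
  mol@activity <- as.numeric(value); validObject(mol); mol
}

#' @describeIn Molecule fingerprint bit ids (computing if absent)
#' @export
fingerprint <- function(mol) {
  if (length(mol@fingerprint) == 0) computeFingerprint(mol) else
    mol@fingerprint
}
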