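# JSON serialization of the model objects (grouped datasets, hypotheses,
# QSAR models, the combinatorial model). Fingerprints serialize as sorted
# integer lists; grids as origin/spacing/extents; coefficients as sparse
# (bit, value) pairs.

molToList <- function(mol) {
  list(id = mol@id, atoms = mol@atoms, bonds = mol@bonds,
       conformers = lapply(mol@conformers, unclass),
       activity = mol@activity, fingerprint = mol@fingerprint)
}

molFromList <- function(x) {
  Molecule(id = x$id, atoms = rowsToDf(x$atoms),
           bonds = rowsToDf(x$bonds),
           conformers = lapply(x$conformers, rowsToMatrix),
           activity = if (is.null(x$activity)) NA_real_ else
             as.numeric(x$activity),
           fingerprint = as.integer(unlist(x$fingerprint)))
}

siteToList <- function(s) {
  list(type = s@type, xyz = s@position,
       dir = if (length(s@direction)) s@direction else NULL,
       atoms = s@atoms)
}

siteFromList <- function(x) {
  PharmacophoreSite(x$type, as.numeric(unlist(x$xyz)),
                    direction = if (is.null(x$dir)) numeric(0) else
                      as.numeric(unlist(x$dir)),
                    atoms = as.integer(unlist(x$atoms)))
}

# list of JSON row-objects -> data.frame / numeric matrix
rowsToDf <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v))))
}

rowsToMatrix <- function(rows, ncol = 3) {
  if (is.matrix(rows)) return(rows)
  t(vapply(rows, function(r) as.numeric(unlist(r)), numeric(ncol)))
}

hypothesisToList <- function(h) {
  list(k = h@k, label = h@label, reference_id = h@referenceId,
       sites = lapply(h@sites, siteToList),
       distances = h@distances,
       reference_conformer = h@referenceConformer,
       reference_mol = if (is.null(h@referenceMol)) NULL else
         molToList(h@referenceMol),
       scores = as.list(h@scoreComponents),
       survival = h@survival, n_actives_matched = h@nActivesMatched)
}

hypothesisFromList <- function(x) {
  k <- as.integer(x$k)
  scores <- vapply(x$scores, function(v)
    if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  new("Hypothesis", k = k, label = x$label,
      referenceId = x$reference_id,
      sites = lapply(x$sites, siteFromList),
      distances = rowsToMatrix(x$distances, ncol = k),
      referenceConformer = rowsToMatrix(x$reference_conformer),
      referenceMol = if (is.null(x$reference_mol)) NULL else
        molFromList(x$reference_mol),
      scoreComponents = scores,
      survival = if (is.null(x$survival)) NA_real_ else
        as.numeric(x$survival),
      nActivesMatched = if (is.null(x$n_actives_matched)) NA_integer_
        else as.integer(x$n_actives_matched))
}

qsarToList <- function(q) {
  list(grid = list(origin = q@grid@origin, spacing = q@grid@spacing,
                   extents = q@grid@extents,
                   channels = q@grid@channels),
       bits = q@bits, coefficients = q@coefficients,
       intercept = q@intercept, n_factors = q@nFactors,
       stats = as.list(q@stats), hypothesis_ref = q@hypothesisRef)
}

qsarFromList <- function(x) {
  new("QsarModel",
      grid = new("GridSpec",
                 origin = as.numeric(unlist(x$grid$origin)),
                 spacing = as.numeric(x$grid$spacing),
                 extents = as.integer(unlist(x$grid$extents)),
                 channels = as.character(unlist(x$grid$channels))),
      bits = as.character(unlist(x$bits)),
      coefficients = as.numeric(unlist(x$coefficients)),
      intercept = as.numeric(x$intercept),
      nFactors = as.integer(x$n_factors),
      stats = vapply(x$stats, function(v)
        if (is.null(v)) NA_real_ else as.numeric(v), numeric(1)),
      hypothesisRef = x$hypothesis_ref)
}

#' Serialize a CombinatorialModel to JSON
#'
#' @param model a \code{CombinatorialModel}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeCombinatorialModel <- function(model, path) {
  obj <- list(
    format = "combiphore-model-1",
    dispatch = model@dispatch,
    entries = lapply(model@entries, function(e) list(
      hypothesis = hypothesisToList(e$hypothesis),
      qsar = qsarToList(e$qsar),
      fingerprints = e$fingerprints,
      training_ids = e$trainingIds,
      training_mean = e$trainingMean)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a CombinatorialModel from JSON
#'
#' @param path file written by \code{writeCombinatorialModel}.
#' @return a \code{CombinatorialModel}.
#' @export
readCombinatorialModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(obj$entries, function(e) list(
    hypothesis = hypothesisFromList(e$hypothesis),
    qsar = qsarFromList(e$qsar),
    fingerprints = lapply(e$fingerprints, function(f)
      as.integer(unlist(f))),
    trainingIds = as.character(unlist(e$training_ids)),
    trainingMean = as.numeric(e$training_mean)))
  new("CombinatorialModel", entries = entries,
      dispatch = lapply(obj$dispatch, unlist))
}

#' Serialize a GroupedDataset to JSON
#'
#' @param grouped a \code{GroupedDataset}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGroupedDataset <- function(grouped, path) {
  obj <- list(
    groups = lapply(grouped@groups, function(g) list(
      group_id = g$group_id, skeleton_smiles = g$skeleton,
      member_ids = g$member_ids)),
    unassigned = grouped@unassigned,
    split = as.list(grouped@split))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
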