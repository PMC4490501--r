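# Structure input: SMILES (one per line or tabular), SDF V2000, and
# activity tables (CSV). Parsing of the standard formats is delegated to
# ChemmineR / OpenBabel; this file only converts their containers into
# Molecule objects and does the activity bookkeeping.

#' Convert an IC50 in nM to pIC50
#'
#' pIC50 = 9 - log10(IC50[nM]), i.e. -log10 of the molar IC50.
#'
#' @param ic50 IC50 value(s).
#' @param units "nM" (default) or "uM" or "M".
#' @return pIC50 value(s).
#' @export
pIC50FromIC50 <- function(ic50, units = c("nM", "uM", "M")) {
  units <- match.arg(units)
  nM <- switch(units, nM = ic50, uM = ic50 * 1e3, M = ic50 * 1e9)
  9 - log10(nM)
}

# Effective valence for implicit-H assignment, with common charge cases.
effectiveValence <- function(element, charge) {
  v <- standardValence[element]
  v[is.na(v)] <- 0
  v <- v + ifelse(element == "N" & charge > 0, 1, 0)
  v <- v + ifelse(element %in% c("O", "S") & charge < 0, -1, 0)
  v <- v + ifelse(element == "C" & charge != 0, -1, 0)
  pmax(v, 0)
}

# Build a Molecule from a ChemmineR SDF object plus the raw molfile lines
# (needed for M CHG, which the block representation drops). Explicit
# hydrogens are folded into per-atom counts.
molFromSDF <- function(sdf, rawLines = NULL, id = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  xyz <- ab[, 1:3, drop = FALSE]
  n <- length(el)
  a1 <- integer(0); a2 <- integer(0); ord <- integer(0)
  if (!is.null(bb) && nrow(bb) > 0) {
    a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
    ord <- as.integer(bb[, 3])
  }
  charge <- integer(n)
  if (!is.null(rawLines)) {
    for (ln in grep("^M  CHG", rawLines, value = TRUE)) {
      toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)),
                                  "[ ]+")[[1]])
      cnt <- toks[1]
      for (kk in seq_len(cnt)) {
        charge[toks[2 * kk]] <- toks[2 * kk + 1]
      }
    }
  }
  heavy <- which(el != "H")
  hmap <- match(seq_len(n), heavy)
  nH <- integer(length(heavy))
  keep <- logical(length(a1))
  for (i in seq_along(a1)) {
    hi <- el[a1[i]] == "H"; hj <- el[a2[i]] == "H"
    if (hi && hj) next
    if (hi || hj) {
      heavyAtom <- if (hi) a2[i] else a1[i]
      nH[hmap[heavyAtom]] <- nH[hmap[heavyAtom]] + 1L
    } else keep[i] <- TRUE
  }
  atoms <- data.frame(element = el[heavy], charge = charge[heavy],
                      aromatic = FALSE, nH = nH,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = hmap[a1[keep]], a2 = hmap[a2[keep]],
                      order = pmin(ord[keep], 3L))
  hadExplicitH <- any(el == "H")
  mol <- Molecule(id = if (is.null(id)) "mol" else id, atoms = atoms,
                  bonds = bonds,
                  conformers = list(input = xyz[heavy, , drop = FALSE]))
  if (!hadExplicitH) {
    ordSum <- numeric(nrow(atoms))
    for (i in seq_len(nrow(bonds))) {
      ordSum[bonds$a1[i]] <- ordSum[bonds$a1[i]] + bonds$order[i]
      ordSum[bonds$a2[i]] <- ordSum[bonds$a2[i]] + bonds$order[i]
    }
    mol@atoms$nH <- as.integer(pmax(0, effectiveValence(atoms$element,
      atoms$charge) - ordSum))
  }
  mol <- perceiveAromaticity(mol)$mol
  validObject(mol)
  mol
}

# SMILES -> Molecule through OpenBabel 3D generation. Returns NULL (with a
# warning) when the string cannot be parsed or embedded.
molFromSmiles <- function(smiles, id, gen3d = TRUE) {
  opts <- if (gen3d) data.frame(names = "gen3d", args = "") else NULL
  sdfTxt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF",
      paste0(smiles, " ", id, "\n"), options = opts),
    error = function(e) "")
  if (!nzchar(trimws(sdfTxt))) {
    warning("could not parse SMILES for '", id, "', record skipped")
    return(NULL)
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdfTxt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  if (length(sdfset) == 0) {
    warning("could not parse SMILES for '", id, "', record skipped")
    return(NULL)
  }
  raw <- as(ChemmineR::read.SDFstr(tf), "list")[[1]]
  tryCatch(molFromSDF(sdfset[[1]], rawLines = raw, id = id),
           error = function(e) {
             warning("could not convert '", id, "': ", conditionMessage(e))
             NULL
           })
}

#' Read molecules from a file
#'
#' Supported formats: \code{"sdf"} (V2000, coordinates kept as the input
#' conformer), \code{"smiles-table"} (one SMILES per line, optionally
#' followed by an id; 3D coordinates generated), and \code{"activity-csv"}
#' (CSV with header \code{id, smiles, ic50_nM} or \code{id, smiles, pic50}).
#' IC50 values are converted to pIC50 = 9 - log10(IC50[nM]). Records that
#' fail to parse are skipped with a warning; the number skipped is attached
#' as attribute \code{"skipped"}.
#'
#' @param path file path.
#' @param format one of "sdf", "smiles-table", "activity-csv".
#' @param ic50Units units for an ic50 column ("nM" default).
#' @param gen3d generate 3D coordinates for SMILES input (default TRUE).
#' @return list of \code{Molecule} with attribute \code{skipped}.
#' @export
readMolecules <- function(path,
                          format = c("sdf", "smiles-table", "activity-csv"),
                          ic50Units = "nM", gen3d = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  skipped <- 0L
  mols <- list()
  if (format == "sdf") {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    rawAll <- as(ChemmineR::read.SDFstr(path), "list")
    for (i in seq_along(sdfset)) {
      hdr <- ChemmineR::header(sdfset[[i]])
      id <- unname(hdr["Molecule_Name"])
      if (!nzchar(id)) id <- paste0("mol", i)
      m <- tryCatch(molFromSDF(sdfset[[i]], rawLines = rawAll[[i]], id = id),
                    error = function(e) {
                      warning("skipping record ", i, ": ",
                              conditionMessage(e))
                      NULL
                    })
      if (is.null(m)) skipped <- skipped + 1L else
        mols[[length(mols) + 1L]] <- m
    }
  } else if (format == "smiles-table") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      id <- if (length(toks) >= 2) toks[2] else paste0("S", i)
      m <- molFromSmiles(toks[1], id, gen3d = gen3d)
      if (is.null(m)) skipped <- skipped + 1L else
        mols[[length(mols) + 1L]] <- m
    }
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    if (!all(c("id", "smiles") %in% names(tab)))
      stop("activity table must have columns id, smiles and ",
           "ic50_nm or pic50")
    hasIc50 <- "ic50_nm" %in% names(tab)
    hasP <- "pic50" %in% names(tab)
    if (!hasIc50 && !hasP)
      stop("activity table must have an ic50_nM or pic50 column")
    for (i in seq_len(nrow(tab))) {
      m <- molFromSmiles(tab$smiles[i], as.character(tab$id[i]),
                         gen3d = gen3d)
      if (is.null(m)) { skipped <- skipped + 1L; next }
      act <- if (hasP) as.numeric(tab$pic50[i]) else
        pIC50FromIC50(as.numeric(tab$ic50_nm[i]), units = ic50Units)
      if (!is.finite(act)) {
        warning("non-finite activity for '", tab$id[i], "', record skipped")
        skipped <- skipped + 1L; next
      }
      activity(m) <- act
      mols[[length(mols) + 1L]] <- m
    }
  }
  if (length(mols) == 0)
    stop("no valid records in ", path)
  attr(mols, "skipped") <- skipped
  mols
}

#' Write molecules to an SDF file
#'
#' @param mols list of Molecule.
#' @param path output path.
#' @param allConformers write every conformer (default: first only).
#' @return invisibly, the path.
#' @export
writeSdf <- function(mols, path, allConformers = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    idx <- if (allConformers) seq_along(m@conformers) else 1L
    if (length(m@conformers) == 0) idx <- 1L
    for (i in idx) cat(molToSdfText(m, confIdx = i), file = con)
  }
  invisible(path)
}

#' Classify a pIC50 into activity bands
#'
#' pIC50 greater than 7.0 is "active", less than 5.0 "inactive", the
#' in-between values (boundaries included) "moderate".
#'
#' @param pIC50 finite numeric vector.
#' @return character vector of labels.
#' @export
classifyActivity <- function(pIC50) {
  stopifnot(all(is.finite(pIC50)))
  ifelse(pIC50 > 7.0, "active", ifelse(pIC50 < 5.0, "inactive", "moderate"))
}
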