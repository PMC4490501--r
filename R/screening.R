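# Decoy-set validation (enrichment factors, EF curve) and the virtual
# screening pipeline: Lipinski filter -> conformer generation ->
# combinatorial prediction -> ranking.

#' Enrichment factor
#'
#' EF = (Hits_s / N_s) / (Hits_t / N_t): the active rate in the selected
#' front fraction of a ranked list relative to the active rate in the
#' whole database. Computed in exact rational form (single final
#' division).
#'
#' @param hitsS actives in the selected fraction.
#' @param nS compounds in the selected fraction.
#' @param hitsT actives in the whole database.
#' @param nT compounds in the whole database.
#' @return the enrichment factor.
#' @export
enrichmentFactor <- function(hitsS, nS, hitsT, nT) {
  if (nS == 0) stop("selected fraction is empty (nS = 0)")
  stopifnot(hitsS >= 0, hitsS <= nS, nS <= nT, hitsT > 0, hitsT <= nT)
  (hitsS * nT) / (nS * hitsT)
}

#' Enrichment-factor curve of a ranked list
#'
#' For each fraction phi, the first \code{ceiling(phi * nT)} records are
#' selected and the EF computed from the actives they contain. Records
#' must arrive ranked (scores non-increasing); ties keep the stable input
#' order.
#'
#' @param ranked data.frame with columns \code{id}, \code{score},
#'   \code{is_active} (logical), ordered by decreasing score.
#' @param fractions fractions in (0, 1] (default 1, 2, 5, 10, 100
#'   percent).
#' @return list: \code{fractions}, \code{ef_values}, \code{hits_t},
#'   \code{n_t}.
#' @export
efCurve <- function(ranked, fractions = c(0.01, 0.02, 0.05, 0.10, 1.0)) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  nT <- nrow(ranked)
  hitsT <- sum(ranked$is_active)
  if (hitsT == 0) stop("no actives in the ranked list")
  efs <- vapply(fractions, function(phi) {
    nS <- ceiling(phi * nT)
    hitsS <- sum(ranked$is_active[seq_len(nS)])
    enrichmentFactor(hitsS, nS, hitsT, nT)
  }, numeric(1))
  list(fractions = fractions, ef_values = efs, hits_t = hitsT, n_t = nT)
}

#' Lipinski rule-of-five filter
#'
#' Evaluates MW <= 500, logP <= 5, H-bond donors <= 5 and H-bond
#' acceptors <= 10 (properties via OpenBabel). A compound passes with at
#' most one violation (the customary reading); \code{strict = TRUE}
#' requires zero violations.
#'
#' @param mols list of Molecule.
#' @param strict zero-violation mode (default FALSE).
#' @return list: \code{passing} (list of Molecule), \code{violations}
#'   (named integer vector by id).
#' @export
lipinskiFilter <- function(mols, strict = FALSE) {
  viol <- integer(length(mols))
  names(viol) <- vapply(mols, molId, character(1))
  for (i in seq_along(mols)) {
    p <- molProperties(mols[[i]])
    viol[i] <- sum(p$MW > 500, p$logP > 5, p$HBD > 5, p$HBA > 10)
  }
  limit <- if (strict) 0L else 1L
  list(passing = mols[viol <= limit], violations = viol)
}

#' Screen a compound library with a combinatorial model
#'
#' Pipeline: Lipinski filter, conformer generation, combinatorial
#' prediction per compound, removal of unmatched compounds and of
#' predictions at or below \code{activityMin}, descending sort (stable
#' under ties) and truncation to \code{topN}. The stage at which each
#' compound was dropped is logged in the \code{"provenance"} attribute.
#'
#' @param model a \code{CombinatorialModel}.
#' @param library list of Molecule.
#' @param activityMin minimum predicted pIC50 retained (default 5.0).
#' @param topN ranked-list length (default 100).
#' @param generateConfs run conformer generation on each passing compound
#'   (default FALSE; molecules usually arrive with conformers).
#' @param lipinski apply the rule-of-five pre-filter (default TRUE).
#' @return data.frame (id, group_id, mean_tc, score) ranked by
#'   decreasing score, with attribute \code{"provenance"}.
#' @export
screenLibrary <- function(model, library, activityMin = 5.0, topN = 100L,
                          generateConfs = FALSE, lipinski = TRUE) {
  stopifnot(length(library) >= 1)
  prov <- stats::setNames(rep("ranked", length(library)),
                          vapply(library, molId, character(1)))
  pool <- library
  if (lipinski) {
    lf <- lipinskiFilter(pool)
    dropped <- setdiff(names(prov), vapply(lf$passing, molId,
                                           character(1)))
    prov[dropped] <- "lipinski"
    pool <- lf$passing
  }
  rows <- list()
  for (m in pool) {
    if (generateConfs) m <- generateConformers(m)
    pr <- predictCombinatorial(model, m)
    if (!pr$matched) { prov[molId(m)] <- "unmatched"; next }
    if (pr$predicted <= activityMin) {
      prov[molId(m)] <- "below-threshold"; next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = molId(m), group_id = pr$group_id, mean_tc = pr$mean_tc,
      score = pr$predicted)
  }
  if (length(rows) == 0) {
    warning("screening produced an empty ranked list")
    out <- data.frame(id = character(0), group_id = integer(0),
                      mean_tc = numeric(0), score = numeric(0))
    attr(out, "provenance") <- prov
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$score)   # stable in R: ties keep input order
  out <- out[ord, , drop = FALSE]
  if (nrow(out) > topN) {
    prov[out$id[-seq_len(topN)]] <- "beyond-top-n"
    out <- out[seq_len(topN), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "provenance") <- prov
  out
}

#' Assemble a property-matched decoy set
#'
#' Per active, up to \code{ratio} candidates within the property windows
#' (MW, logP, donors, acceptors, rotatable bonds) and below the Tanimoto
#' bound to every active are selected; the result is deduplicated. When
#' candidates run short the available ones are returned with a warning.
#'
#' @param actives list of Molecule.
#' @param candidates list of candidate Molecule.
#' @param ratio decoys per active (default 36).
#' @param tcMax Tanimoto exclusion bound (default 0.75).
#' @param windows named tolerances: MW, logP, HBD, HBA, RotB.
#' @return list of selected decoy Molecules.
#' @export
makeDecoySet <- function(actives, candidates, ratio = 36L, tcMax = 0.75,
                         windows = c(MW = 40, logP = 1, HBD = 1,
                                     HBA = 1, RotB = 1)) {
  actProps <- lapply(actives, molProperties)
  actRotB <- vapply(actives, function(m) rotatableBonds(m)$count,
                    integer(1))
  actFps <- lapply(actives, fingerprint)
  candProps <- lapply(candidates, molProperties)
  candRotB <- vapply(candidates, function(m) rotatableBonds(m)$count,
                     integer(1))
  candFps <- lapply(candidates, fingerprint)
  candIds <- vapply(candidates, molId, character(1))
  maxTc <- vapply(candFps, function(f)
    max(vapply(actFps, function(a) tanimoto(a, f), numeric(1))),
    numeric(1))
  selected <- character(0)
  for (ai in seq_along(actives)) {
    ap <- actProps[[ai]]
    okProp <- vapply(seq_along(candidates), function(ci) {
      cp <- candProps[[ci]]
      abs(cp$MW - ap$MW) <= windows["MW"] &&
        abs(cp$logP - ap$logP) <= windows["logP"] &&
        abs(cp$HBD - ap$HBD) <= windows["HBD"] &&
        abs(cp$HBA - ap$HBA) <= windows["HBA"] &&
        abs(candRotB[ci] - actRotB[ai]) <= windows["RotB"]
    }, logical(1))
    eligible <- which(okProp & maxTc < tcMax & !candIds %in% selected)
    take <- eligible[seq_len(min(ratio, length(eligible)))]
    selected <- c(selected, candIds[take])
  }
  if (length(selected) < ratio * length(actives))
    warning("only ", length(selected), " of ", ratio * length(actives),
            " requested decoys available")
  candidates[match(selected, candIds)]
}
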