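# Combinatorial model construction and Tc-dispatched prediction: per
# scaffold group, CPH search over k = 4, 5, 6 on the highly active
# members, survival scoring and clustering, alignment of all members,
# QSAR fitting per surviving hypothesis, and selection of the best model
# by the statistic ranking. A query is predicted by exactly one group
# model, the group with the highest mean fingerprint Tanimoto.

#' Select the best (hypothesis, model) candidate
#'
#' Lexicographic ranking: highest training r2, then highest stability,
#' then highest F, then lowest p.
#'
#' @param candidates list of lists with elements \code{hypothesis} and
#'   \code{qsar}.
#' @return the winning candidate.
#' @export
selectBestModel <- function(candidates) {
  if (length(candidates) == 0) stop("no model candidates to select from")
  keys <- vapply(candidates, function(cd) {
    s <- cd$qsar@stats
    stab <- if (is.na(s["stability"])) -Inf else s["stability"]
    c(s["r2"], stab, s["f"], -s["p"])
  }, numeric(4))
  best <- 1L
  for (i in seq_along(candidates)[-1]) {
    for (d in 1:4) {
      if (keys[d, i] > keys[d, best] + 1e-12) { best <- i; break }
      if (keys[d, i] < keys[d, best] - 1e-12) break
    }
  }
  candidates[[best]]
}

#' Build the combinatorial pharmacophore QSAR model
#'
#' Per retained scaffold group: common pharmacophore search over the
#' highly active members (pIC50 > 7) for each k, scoring, filtering and
#' clustering to representative hypotheses; alignment of all group
#' members to each representative; PLS QSAR fit on the aligned occupancy
#' bits; and selection of the best candidate by the statistic ranking.
#' Groups failing any stage are dropped with a logged reason.
#'
#' @param mols list of Molecule with conformers and activities (the
#'   training set).
#' @param grouped a \code{GroupedDataset} over those molecules.
#' @param kValues pharmacophore sizes to search (default 4:6).
#' @param maxHypothesesPerGroup cap on QSAR candidates per group
#'   (top-survival representatives, default 3).
#' @param nFactors PLS factors (default 3).
#' @param seed seed for the stability resampling.
#' @param verbose print per-group progress.
#' @return a \code{CombinatorialModel}; attribute \code{"report"} holds a
#'   per-group stats table, attribute \code{"dropped"} the failures.
#' @export
buildCombinatorial <- function(mols, grouped, kValues = 4:6,
                               maxHypothesesPerGroup = 3L,
                               nFactors = 3L, seed = 1L,
                               verbose = FALSE) {
  ids <- vapply(mols, molId, character(1))
  entries <- list()
  dropped <- list()
  report <- list()
  for (g in grouped@groups) {
    gid <- as.character(g$group_id)
    members <- mols[match(g$member_ids, ids)]
    acts <- vapply(members, activity, numeric(1))
    if (length(members) < 5 ||
        sum(classifyActivity(acts) == "active") < 2) {
      dropped[[gid]] <- "fewer than 5 members or fewer than 2 actives"
      next
    }
    actives <- members[classifyActivity(acts) == "active"]
    hyps <- list()
    for (k in kValues) {
      hk <- tryCatch(findCommonPharmacophores(actives, k),
                     error = function(e) list())
      hyps <- c(hyps, hk)
    }
    if (length(hyps) == 0) {
      dropped[[gid]] <- "no common pharmacophore"
      next
    }
    hyps <- lapply(hyps, scoreHypothesis, actives = actives)
    reps <- filterAndCluster(hyps)
    if (length(reps) == 0) {
      dropped[[gid]] <- "no hypothesis survived filtering"
      next
    }
    reps <- reps[seq_len(min(length(reps), maxHypothesesPerGroup))]
    candidates <- list()
    for (h in reps) {
      cand <- tryCatch(
        fitGroupQsar(members, h, nFactors = nFactors, seed = seed),
        error = function(e) NULL)
      if (!is.null(cand)) candidates[[length(candidates) + 1L]] <- cand
    }
    if (length(candidates) == 0) {
      dropped[[gid]] <- "QSAR fit failed for every hypothesis"
      next
    }
    best <- selectBestModel(candidates)
    fps <- lapply(members, fingerprint)
    entries[[gid]] <- list(
      hypothesis = best$hypothesis, qsar = best$qsar,
      fingerprints = fps, trainingIds = g$member_ids,
      trainingMean = mean(acts[best$matchedIdx]),
      matchedIds = g$member_ids[best$matchedIdx])
    s <- best$qsar@stats
    report[[gid]] <- data.frame(
      group_id = g$group_id, n_members = length(members),
      n_actives = length(actives), hypothesis = best$hypothesis@label,
      k = best$hypothesis@k, n_matched = length(best$matchedIdx),
      r2 = s[["r2"]], sd = s[["sd"]], f = s[["f"]], p = s[["p"]],
      stability = s[["stability"]], q2_loo = s[["q2_loo"]])
    if (verbose)
      message("group ", gid, ": ", best$hypothesis@label,
              " r2 = ", round(s[["r2"]], 3))
  }
  if (length(entries) == 0)
    stop("no models built: every group failed")
  model <- new("CombinatorialModel", entries = entries,
               dispatch = list(fingerprint = "fcfp4-2048",
                               tie = "lowest-group-id"))
  attr(model, "report") <- do.call(rbind, report)
  attr(model, "dropped") <- dropped
  model
}

# Align every member to the hypothesis and fit the QSAR on the matched
# ones. Returns NULL-able candidate (hypothesis, qsar, matchedIdx).
fitGroupQsar <- function(members, hyp, nFactors = 3L, seed = 1L) {
  aligns <- lapply(members, alignToHypothesis, hyp = hyp)
  okIdx <- which(vapply(aligns, function(a) isTRUE(a$matched), logical(1)))
  if (length(okIdx) < nFactors + 2)
    stop("too few members match the hypothesis")
  coords <- lapply(aligns[okIdx], `[[`, "alignedConformer")
  grid <- buildGrid(coords)
  bitList <- lapply(okIdx, function(i)
    computeOccupancy(members[[i]], aligns[[i]]$alignedConformer, grid))
  acts <- vapply(members[okIdx], activity, numeric(1))
  qsar <- fitQsar(bitList, acts, grid, nFactors = nFactors,
                  hypothesisRef = paste0(hyp@label, "/", hyp@referenceId),
                  statsSeed = seed)
  list(hypothesis = hyp, qsar = qsar, matchedIdx = okIdx)
}

#' Predict a query compound with the combinatorial model
#'
#' The query is dispatched to the group with the highest mean Tanimoto
#' between its fingerprint and the group's training fingerprints, aligned
#' to that group's hypothesis, and (when the alignment matches) predicted
#' by that group's QSAR model. Unmatched queries return
#' \code{matched = FALSE} and no activity, unless \code{fallback} is
#' enabled (then the next-best groups are tried in mean-Tc order).
#'
#' @param model a \code{CombinatorialModel}.
#' @param query a Molecule with at least one conformer.
#' @param fallback try further groups when the dispatched one fails to
#'   match (default FALSE, the strict one-model rule).
#' @return list: \code{group_id}, \code{matched}, \code{mean_tc},
#'   \code{predicted} (NA when unmatched), \code{trainingMean} of the
#'   dispatched group.
#' @export
predictCombinatorial <- function(model, query, fallback = FALSE) {
  qfp <- fingerprint(query)
  gids <- names(model@entries)
  means <- vapply(model@entries, function(e)
    mean(vapply(e$fingerprints, function(f) tanimoto(qfp, f),
                numeric(1))), numeric(1))
  ord <- order(-means, as.integer(gids))
  tryOrder <- if (fallback) ord else ord[1]
  for (oi in tryOrder) {
    e <- model@entries[[oi]]
    al <- alignToHypothesis(query, e$hypothesis)
    if (isTRUE(al$matched)) {
      pred <- predictQsarConformer(e$qsar, query, al$alignedConformer)
      return(list(group_id = as.integer(gids[oi]), matched = TRUE,
                  mean_tc = unname(means[oi]), predicted = pred,
                  trainingMean = e$trainingMean))
    }
  }
  oi <- ord[1]
  list(group_id = as.integer(gids[oi]), matched = FALSE,
       mean_tc = unname(means[oi]), predicted = NA_real_,
       trainingMean = model@entries[[oi]]$trainingMean)
}
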