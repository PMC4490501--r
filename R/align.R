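# Alignment of ligands onto hypotheses: exhaustive type-respecting site
# mapping with distance-consistency pruning, optimal rigid superposition
# per mapping (Kabsch), and the three score components (alignment,
# vector/directionality, volume overlap) combined into the survival score.

# Site perception is pure but costly (one substructure-matching pass per
# call); alignment revisits the same conformers many times, so results
# are memoised on (id, conformer index, coordinate checksum).
.siteCache <- new.env(parent = emptyenv())

cachedSites <- function(mol, ci) {
  conf <- mol@conformers[[ci]]
  key <- paste(mol@id, ci, nrow(conf),
               format(sum(conf), digits = 12),
               format(sum(conf * conf), digits = 12))
  hit <- .siteCache[[key]]
  if (!is.null(hit)) return(hit)
  if (length(ls(.siteCache)) > 20000) rm(list = ls(.siteCache),
                                         envir = .siteCache)
  val <- perceiveSites(mol, conf)
  .siteCache[[key]] <- val
  val
}

#' Align a molecule to a hypothesis
#'
#' Over all conformers and all injective type-respecting mappings of
#' hypothesis sites to ligand sites, finds the least-squares rigid
#' superposition (rotation + translation, no scaling) minimizing the site
#' point RMSD. A ligand is \code{matched} when the best RMSD is below
#' \code{rmsdMax} and the directional (vector) score exceeds
#' \code{vectorMin}.
#'
#' @param mol a Molecule with at least one conformer.
#' @param hyp a \code{Hypothesis}.
#' @param rmsdMax site RMSD threshold in Angstrom (default 1.2).
#' @param vectorMin directional score threshold on the [0,1] cosine scale
#'   (default 0.5).
#' @param maxMappings combinatorial guard (default 1e5).
#' @return list: \code{matched}, \code{reason}, \code{siteRmsd},
#'   \code{distRmsd} (inter-site-distance RMSD to the reference),
#'   \code{vectorScore}, \code{volumeScore}, \code{mapping},
#'   \code{conformer} (index), \code{rotation}, \code{translation},
#'   \code{alignedConformer} (transformed heavy-atom coordinates).
#' @export
alignToHypothesis <- function(mol, hyp, rmsdMax = 1.2, vectorMin = 0.5,
                              maxMappings = 1e5) {
  stopifnot(length(mol@conformers) >= 1)
  hpos <- sitePositions(hyp@sites)
  htypes <- siteTypes(hyp@sites)
  k <- hyp@k
  best <- NULL
  nTried <- 0L
  for (ci in seq_along(mol@conformers)) {
    conf <- mol@conformers[[ci]]
    sites <- cachedSites(mol, ci)
    if (length(sites) == 0) next
    stypes <- siteTypes(sites)
    cand <- lapply(htypes, function(tt) which(stypes == tt))
    if (any(lengths(cand) == 0)) next
    spos <- sitePositions(sites)
    hd <- as.matrix(stats::dist(hpos))
    sd_ <- as.matrix(stats::dist(spos))
    # depth-first enumeration with pairwise-distance pruning
    res <- new.env(parent = emptyenv())
    res$best <- best; res$n <- nTried
    recurse <- function(level, chosen) {
      if (res$n >= maxMappings) return()
      if (level > k) {
        res$n <- res$n + 1L
        fit <- kabsch(spos[chosen, , drop = FALSE], hpos)
        if (is.null(res$best) || fit$rmsd < res$best$siteRmsd) {
          res$best <- list(siteRmsd = fit$rmsd, mapping = chosen,
                           conformer = ci, rotation = fit$rotation,
                           translation = fit$translation, sites = sites)
        }
        return()
      }
      for (s in cand[[level]]) {
        if (s %in% chosen) next
        ok <- TRUE
        for (prev in seq_len(level - 1L)) {
          if (abs(sd_[chosen[prev], s] - hd[prev, level]) >
              2 * rmsdMax + 1.0) { ok <- FALSE; break }
        }
        if (ok) recurse(level + 1L, c(chosen, s))
      }
    }
    recurse(1L, integer(0))
    best <- res$best; nTried <- res$n
  }
  if (is.null(best))
    return(list(matched = FALSE, reason = "no feature match",
                siteRmsd = NA_real_, distRmsd = NA_real_,
                vectorScore = NA_real_, volumeScore = NA_real_))
  conf <- mol@conformers[[best$conformer]]
  aligned <- applyTransform(conf, best$rotation, best$translation)
  mapped <- best$sites[best$mapping]
  # inter-site distance RMSD to the reference hypothesis
  mpos <- sitePositions(mapped)
  md <- as.matrix(stats::dist(mpos))
  hd <- hyp@distances
  distRmsd <- sqrt(mean((md[upper.tri(md)] - hd[upper.tri(hd)])^2))
  vs <- vectorScore(hyp@sites, mapped, best$rotation)
  vol <- volumeScore(mol, aligned, hyp)
  matched <- is.finite(best$siteRmsd) && best$siteRmsd < rmsdMax &&
    (is.na(vs) || vs > vectorMin)
  list(matched = matched,
       reason = if (matched) "ok" else "thresholds",
       siteRmsd = best$siteRmsd, distRmsd = distRmsd,
       vectorScore = vs, volumeScore = vol,
       mapping = best$mapping, conformer = best$conformer,
       rotation = best$rotation, translation = best$translation,
       alignedConformer = aligned)
}

# Mean cosine alignment of paired direction vectors, mapped to [0, 1].
# Ring normals are sign-ambiguous, so R pairs use |cos|. Pairs where
# either side lacks a direction are skipped; NA when nothing is paired.
vectorScore <- function(hypSites, mappedSites, rotation) {
  vals <- numeric(0)
  for (i in seq_along(hypSites)) {
    hv <- hypSites[[i]]@direction
    lv <- mappedSites[[i]]@direction
    if (length(hv) != 3 || length(lv) != 3) next
    lvr <- as.numeric(lv %*% rotation)
    cs <- sum(hv * lvr)
    if (hypSites[[i]]@type == "R") cs <- abs(cs)
    vals <- c(vals, (cs + 1) / 2)
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

# Shared / union van der Waals volume between the aligned conformer and
# the hypothesis reference ligand, by voxel counting (1 A voxels by
# default: grid approximation, adequate for a [0,1] overlap score).
volumeScore <- function(mol, alignedConf, hyp, voxel = 1.0) {
  refMol <- hyp@referenceMol
  if (is.null(refMol)) return(NA_real_)
  refConf <- hyp@referenceConformer
  rA <- vdwRadiusOf(mol@atoms$element)
  rB <- vdwRadiusOf(refMol@atoms$element)
  lo <- pmin(apply(alignedConf, 2, min) - max(rA),
             apply(refConf, 2, min) - max(rB))
  hi <- pmax(apply(alignedConf, 2, max) + max(rA),
             apply(refConf, 2, max) + max(rB))
  gx <- seq(lo[1] + voxel / 2, hi[1], by = voxel)
  gy <- seq(lo[2] + voxel / 2, hi[2], by = voxel)
  gz <- seq(lo[3] + voxel / 2, hi[3], by = voxel)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  inA <- voxelsInside(pts, alignedConf, rA)
  inB <- voxelsInside(pts, refConf, rB)
  un <- sum(inA | inB)
  if (un == 0) return(0)
  sum(inA & inB) / un
}

voxelsInside <- function(pts, coords, radii) {
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(coords))) {
    d2 <- (pts[, 1] - coords[i, 1])^2 + (pts[, 2] - coords[i, 2])^2 +
      (pts[, 3] - coords[i, 3])^2
    inside <- inside | d2 <= radii[i]^2
  }
  inside
}

#' Score a hypothesis against the active ligands
#'
#' Aligns every active; the survival score is the weighted sum of the
#' alignment score (1 - RMSD/rmsdMax, floored at 0), the vector score and
#' the volume score, averaged over matched actives. Default weights are
#' all 1. Zero matched actives gives survival 0 with a flag.
#'
#' @param hyp a \code{Hypothesis}.
#' @param actives list of Molecule.
#' @param weights named numeric (alignment, vector, volume).
#' @param rmsdMax,vectorMin alignment thresholds.
#' @return the Hypothesis with survival, score components and
#'   \code{nActivesMatched} filled in; attribute \code{"matches"} carries
#'   the per-active alignment results.
#' @export
scoreHypothesis <- function(hyp, actives,
                            weights = c(alignment = 1, vector = 1,
                                        volume = 1),
                            rmsdMax = 1.2, vectorMin = 0.5) {
  matches <- lapply(actives, alignToHypothesis, hyp = hyp,
                    rmsdMax = rmsdMax, vectorMin = vectorMin)
  names(matches) <- vapply(actives, molId, character(1))
  ok <- vapply(matches, function(m) isTRUE(m$matched), logical(1))
  if (!any(ok)) {
    hyp@survival <- 0
    hyp@scoreComponents <- c(alignment = 0, vector = 0, volume = 0)
    hyp@nActivesMatched <- 0L
    attr(hyp, "matches") <- matches
    attr(hyp, "zeroMatched") <- TRUE
    return(hyp)
  }
  comp <- vapply(matches[ok], function(m) {
    sAlign <- max(0, 1 - m$siteRmsd / rmsdMax)
    sVec <- if (is.na(m$vectorScore)) 1 else m$vectorScore
    sVol <- if (is.na(m$volumeScore)) 0 else m$volumeScore
    c(alignment = sAlign, vector = sVec, volume = sVol)
  }, numeric(3))
  means <- rowMeans(comp)
  hyp@scoreComponents <- means
  hyp@survival <- sum(weights[names(means)] * means)
  hyp@nActivesMatched <- sum(ok)
  attr(hyp, "matches") <- matches
  hyp
}

#' Filter scored hypotheses and cluster to representatives
#'
#' Per-active matches failing the vector (> 0.5) or inter-site distance
#' RMSD (< 1.2 A) criteria are discarded before ranking; the top 10
#' percent by survival score are kept; the keepers are clustered by
#' complete linkage on distance-vector dissimilarity (within feature
#' label) and one top-survival representative per cluster is returned.
#'
#' @param hyps list of scored Hypothesis (from \code{scoreHypothesis}).
#' @param keepFraction fraction kept after ranking (default 0.10).
#' @param vectorMin per-match vector score threshold (default 0.5).
#' @param rmsdMax per-match distance RMSD threshold (default 1.2).
#' @param clusterHeight complete-linkage cut height in Angstrom
#'   (default 1.0, the partition cell width).
#' @return list of representative Hypothesis objects, best first.
#' @export
filterAndCluster <- function(hyps, keepFraction = 0.10, vectorMin = 0.5,
                             rmsdMax = 1.2, clusterHeight = 1.0) {
  if (length(hyps) == 0) return(list())
  # re-average survival over matches passing the per-match filters
  hyps <- lapply(hyps, function(h) {
    matches <- attr(h, "matches")
    if (is.null(matches)) return(h)
    ok <- vapply(matches, function(m) {
      isTRUE(m$matched) &&
        (is.na(m$vectorScore) || m$vectorScore > vectorMin) &&
        is.finite(m$distRmsd) && m$distRmsd < rmsdMax
    }, logical(1))
    if (sum(ok) == 0) { h@survival <- 0; h@nActivesMatched <- 0L; return(h) }
    comp <- vapply(matches[ok], function(m) {
      c(alignment = max(0, 1 - m$siteRmsd / rmsdMax),
        vector = if (is.na(m$vectorScore)) 1 else m$vectorScore,
        volume = if (is.na(m$volumeScore)) 0 else m$volumeScore)
    }, numeric(3))
    h@scoreComponents <- rowMeans(comp)
    h@survival <- sum(rowMeans(comp))
    h@nActivesMatched <- as.integer(sum(ok))
    h
  })
  surv <- vapply(hyps, function(h) h@survival, numeric(1))
  nKeep <- max(1L, ceiling(keepFraction * length(hyps)))
  keep <- order(-surv)[seq_len(min(nKeep, length(hyps)))]
  kept <- hyps[keep]
  # cluster within feature label on distance-vector dissimilarity
  labs <- vapply(kept, function(h) h@label, character(1))
  reps <- list()
  for (lab in unique(labs)) {
    sub <- kept[labs == lab]
    if (length(sub) == 1) { reps <- c(reps, sub); next }
    dv <- do.call(rbind, lapply(sub, function(h)
      h@distances[upper.tri(h@distances)]))
    hc <- stats::hclust(stats::dist(dv), method = "complete")
    cl <- stats::cutree(hc, h = clusterHeight)
    for (cc in unique(cl)) {
      members <- sub[cl == cc]
      ms <- vapply(members, function(h) h@survival, numeric(1))
      reps <- c(reps, members[which.max(ms)])
    }
  }
  reps[order(-vapply(reps, function(h) h@survival, numeric(1)))]
}
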