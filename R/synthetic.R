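# Synthetic fixture generator with known ground truth. Each scaffold
# group is a tri-aryl template (two linked benzenes plus a third ring on
# a one-atom bridge) carrying a formyl acceptor: the planted 4-point
# pharmacophore is the carbonyl acceptor plus the three ring centroids
# (label ARRR, a scalene arrangement so the site mapping is unambiguous).
# Groups differ by the bridge element (CH2 / O / NH -> distinct
# Bemis-Murcko frameworks) and by a constant tag substituent (distinct
# fingerprints). Members differ by a 3-slot substituent lattice; the
# activity is exactly linear in the member's occupancy bits under a
# per-group weight map concentrated on the slot substituent cubes, plus
# Gaussian noise. Every member is randomly rigidly transformed so the
# pipeline's alignment genuinely has work to do; the generator-frame
# conformer, noise, transform and weights are all stored as truth.

RING_R <- 1.39    # aromatic C-C ring radius
BL_CC <- 1.48     # single bond between sp2 carbons
BL_SUB <- c(C = 1.51, O = 1.43, N = 1.40, F = 1.35, S = 1.77, Cl = 1.74)

ringCoords <- function(center, a0deg, radius = RING_R, pucker = 0) {
  t(vapply(0:5, function(i) {
    a <- (a0deg + 60 * i) * pi / 180
    center + c(radius * cos(a), radius * sin(a),
               pucker * (-1)^i)
  }, numeric(3)))
}

aromaticRingBonds <- function(offset) {
  data.frame(a1 = offset + c(1, 2, 3, 4, 5, 6),
             a2 = offset + c(2, 3, 4, 5, 6, 1),
             order = c(1L, 2L, 1L, 2L, 1L, 2L))
}

# Substituent slot definitions per group: attachment core atom, element
# chain, and the activity weight (pIC50 per fully occupied slot).
groupSlotTable <- function(g) {
  slots <- list(
    list( # group 1
      list(attach = 4L,  chain = "C", weight = 0.7),
      list(attach = 11L, chain = "O", weight = -1.6),
      list(attach = 15L, chain = "N", weight = -1.4)),
    list( # group 2
      list(attach = 5L,  chain = "O", weight = 0.7),
      list(attach = 12L, chain = "C", weight = -1.6),
      list(attach = 16L, chain = "F", weight = -1.4)),
    list( # group 3
      list(attach = 6L,  chain = "N", weight = 0.7),
      list(attach = 8L,  chain = "C", weight = -1.6),
      list(attach = 19L, chain = "O", weight = -1.4)))
  slots[[(g - 1L) %% 3L + 1L]]
}

subNH <- c(C = 3L, O = 1L, N = 2L, F = 0L)

# Core template shared by all groups: ring1 (atoms 1-6, centroid origin),
# ring2 (7-12, centroid (4.30, 0, 0)), bridge atom 13, ring3 (14-19,
# centroid (-2.87, 4.97, 0)), formyl C 20 / O 21.
groupCore <- function(g) {
  gg <- (g - 1L) %% 3L + 1L
  bridgeEl <- c("C", "O", "N")[gg]
  # ring3 is benzene / pyridine / pyrazine by group: the aza positions
  # keep the ring centroid (the planted R site) but give each family a
  # clearly distinct fingerprint neighbourhood
  ring3El <- rep("C", 6)
  if (gg == 2L) ring3El[5] <- "N"            # atom 18
  if (gg == 3L) ring3El[c(2, 5)] <- "N"      # atoms 15, 18 (para)
  c1 <- c(0, 0, 0); c2 <- c(4.30, 0, 0); c3 <- c(-2.87, 4.9707, 0)
  coords <- rbind(
    ringCoords(c1, 0), ringCoords(c2, 180),
    c(-1.435, 2.4855, 0),
    ringCoords(c3, -60),
    c(7.17, 0, 0),
    c(7.785, 1.0652, 0))
  el <- c(rep("C", 12), bridgeEl, ring3El, "C", "O")
  arom <- c(rep(TRUE, 12), FALSE, rep(TRUE, 6), FALSE, FALSE)
  ring3H <- ifelse(ring3El == "N", 0L, 1L)
  ring3H[1] <- 0L                   # atom 14 links the bridge
  nH <- c(0L, 1L, 0L, 1L, 1L, 1L,   # ring1: 1 links ring2, 3 links bridge
          0L, 1L, 1L, 0L, 1L, 1L,   # ring2: 7 links ring1, 10 formyl
          switch(bridgeEl, C = 2L, O = 0L, N = 1L),
          ring3H,
          1L, 0L)                   # formyl CH=O
  bonds <- rbind(
    aromaticRingBonds(0L), aromaticRingBonds(6L),
    data.frame(a1 = 13L, a2 = c(3L, 14L), order = 1L)[, c("a1", "a2",
                                                          "order")],
    aromaticRingBonds(13L),
    data.frame(a1 = c(1L, 10L, 20L), a2 = c(7L, 20L, 21L),
               order = c(1L, 1L, 2L)))
  list(atoms = data.frame(element = el, charge = 0L, aromatic = arom,
                          nH = nH, stringsAsFactors = FALSE),
       coords = coords, bonds = bonds,
       centroids = rbind(c1, c2, c3), bridgeEl = bridgeEl)
}

# Constant per-group tag substituent at ring3 position 17 (distinct
# fingerprint environments across groups).
groupTag <- function(g, core) {
  dir <- unitVector(core$coords[17L, ] - c(-2.87, 4.9707, 0))
  base <- core$coords[17L, ]
  gg <- (g - 1L) %% 3L + 1L
  if (gg == 1L) {          # acetyl
    rot <- function(v, th) c(cos(th) * v[1] - sin(th) * v[2],
                             sin(th) * v[1] + cos(th) * v[2], 0)
    cc <- base + BL_CC * dir
    list(atoms = data.frame(element = c("C", "O", "C"), charge = 0L,
                            aromatic = FALSE, nH = c(0L, 0L, 3L)),
         coords = rbind(cc,
                        cc + 1.23 * rot(dir, pi / 3),
                        cc + 1.51 * rot(dir, -pi / 3)),
         attach = 17L,
         bonds = data.frame(a1 = c(0L, 1L, 1L), a2 = c(1L, 2L, 3L),
                            order = c(1L, 2L, 1L)))
  } else if (gg == 2L) {   # chloro
    list(atoms = data.frame(element = "Cl", charge = 0L,
                            aromatic = FALSE, nH = 0L),
         coords = matrix(base + BL_SUB["Cl"] * dir, 1),
         attach = 17L,
         bonds = data.frame(a1 = 0L, a2 = 1L, order = 1L))
  } else {                 # ethyl
    list(atoms = data.frame(element = c("C", "C"), charge = 0L,
                            aromatic = FALSE, nH = c(2L, 3L)),
         coords = rbind(base + BL_SUB["C"] * dir,
                        base + (BL_SUB["C"] + 1.53) * dir),
         attach = 17L,
         bonds = data.frame(a1 = c(0L, 1L), a2 = c(1L, 2L), order = 1L))
  }
}

slotGeometry <- function(slot, core) {
  att <- slot$attach
  ringCentroid <- if (att <= 6L) core$centroids[1, ] else
    if (att <= 12L) core$centroids[2, ] else core$centroids[3, ]
  dir <- unitVector(core$coords[att, ] - ringCentroid)
  el <- slot$chain
  list(atoms = data.frame(element = el, charge = 0L, aromatic = FALSE,
                          nH = subNH[[el]]),
       coords = matrix(core$coords[att, ] + BL_SUB[[el]] * dir, 1),
       attach = att,
       bonds = data.frame(a1 = 0L, a2 = 1L, order = 1L))
}

# Assemble a member molecule: core + tag + the present slots. `pieces`
# bond tables use 0 for "the attachment core atom".
assembleMolecule <- function(id, core, pieces, jitter = NULL) {
  atoms <- core$atoms
  coords <- core$coords
  bonds <- core$bonds
  for (p in pieces) {
    off <- nrow(atoms)
    atoms$nH[p$attach] <- 0L
    atoms <- rbind(atoms, p$atoms)
    coords <- rbind(coords, p$coords)
    pb <- p$bonds
    a1 <- ifelse(pb$a1 == 0L, p$attach, pb$a1 + off)
    a2 <- ifelse(pb$a2 == 0L, p$attach, pb$a2 + off)
    bonds <- rbind(bonds, data.frame(a1 = a1, a2 = a2, order = pb$order))
  }
  if (!is.null(jitter)) coords <- coords + jitter(nrow(coords))
  Molecule(id = id, atoms = atoms, bonds = bonds,
           conformers = list(gen = coords))
}

#' Specification for the synthetic ground-truth dataset
#'
#' Defaults define the package's reference study conditions: 3 scaffold
#' groups of 20 members, a planted 4-point ARRR pharmacophore, slot
#' weights spanning the active (> 7) and inactive (< 5) pIC50 regimes,
#' Gaussian activity noise of 0.2 pIC50 units, coordinate jitter within
#' 0.3 Angstrom, and a 36:1 decoy ratio.
#'
#' @param nGroups number of scaffold families (default 3).
#' @param membersPerGroup compounds per family (default 20).
#' @param kPlanted planted pharmacophore size (4; the template plants
#'   ARRR).
#' @param noiseSd activity noise sd in pIC50 units (default 0.2).
#' @param activityBase intercept pIC50 of the unsubstituted member
#'   (default 7.6).
#' @param jitterMax per-coordinate uniform jitter bound (default 0.15,
#'   i.e. atom displacement within ~0.26 A).
#' @param decoyRatio decoys per compound for the decoy pool (default 36).
#' @param seed integer seed.
#' @return a list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(nGroups = 3L, membersPerGroup = 20L,
                          kPlanted = 4L, noiseSd = 0.2,
                          activityBase = 7.6, jitterMax = 0.15,
                          decoyRatio = 36L, seed = 42L) {
  stopifnot(nGroups >= 1, membersPerGroup >= 1, kPlanted == 4L,
            noiseSd >= 0, jitterMax >= 0)
  structure(list(nGroups = as.integer(nGroups),
                 membersPerGroup = as.integer(membersPerGroup),
                 kPlanted = 4L, plantedLabel = "ARRR",
                 noiseSd = noiseSd, activityBase = activityBase,
                 jitterMax = jitterMax, decoyRatio = as.integer(decoyRatio),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate the synthetic ground-truth dataset
#'
#' See \code{\link{syntheticSpec}} for the study conditions. Molecule
#' structures (atom and bond tables, substituent configurations) depend
#' only on the spec's sizes, not on the seed; jitter, noise and the
#' per-member rigid transforms are drawn from the seed.
#'
#' @param spec a \code{SyntheticSpec}.
#' @return list with \code{molecules} (Molecule list, activities set,
#'   one conformer each in an arbitrary world frame) and \code{truth}
#'   (per-group template, grid, planted sites, weight map; per-member
#'   generator-frame conformer, config, noise and transform).
#' @export
generateDataset <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    molecules <- list()
    truth <- list(spec = spec, groups = list(), members = list())
    for (g in seq_len(spec$nGroups)) {
      gt <- groupTruth(g, spec)
      truth$groups[[g]] <- gt
      for (i in seq_len(spec$membersPerGroup)) {
        config <- configBits((i - 1L) %% 8L)
        id <- sprintf("g%d_m%02d", g, i)
        jit <- function(n) matrix(stats::runif(3 * n, -spec$jitterMax,
                                               spec$jitterMax), n, 3)
        pieces <- c(list(gt$tag), gt$slotGeoms[config])
        mol <- assembleMolecule(id, gt$core, pieces, jitter = jit)
        genConf <- mol@conformers[[1]]
        bits <- computeOccupancy(mol, genConf, gt$grid)
        noise <- stats::rnorm(1, 0, spec$noiseSd)
        act <- spec$activityBase +
          sum(gt$weights[intersect(bits, names(gt$weights))]) + noise
        R <- randomRotation()
        tr <- stats::runif(3, -5, 5)
        mol@conformers <- list(world = applyTransform(genConf, R, tr))
        activity(mol) <- act
        molecules[[length(molecules) + 1L]] <- mol
        truth$members[[id]] <- list(
          id = id, group = g, config = which(config),
          genConformer = genConf, noise = noise, activity = act,
          rotation = R, translation = tr)
      }
    }
    list(molecules = molecules, truth = truth)
  })
}

configBits <- function(code) {
  c(bitwAnd(code, 1L) > 0L, bitwAnd(code, 2L) > 0L,
    bitwAnd(code, 4L) > 0L)
}

# Per-group ground truth: template (all slots present), generator grid,
# planted sites, and the per-bit weight map (each slot's weight spread
# uniformly over the cubes its substituent occupies in the unjittered
# template).
groupTruth <- function(g, spec) {
  core <- groupCore(g)
  tag <- groupTag(g, core)
  slots <- groupSlotTable(g)
  slotGeoms <- lapply(slots, slotGeometry, core = core)
  template <- assembleMolecule(sprintf("g%d_template", g), core,
                               c(list(tag), slotGeoms))
  tmplConf <- template@conformers[[1]]
  grid <- buildGrid(list(tmplConf))
  typing <- assignAtomTypes(template)
  nCore <- nrow(core$atoms) + nrow(tag$atoms)
  weights <- numeric(0)
  # The weight support is inflated by twice the jitter bound so that a
  # jittered member sphere always stays inside its slot's support; the
  # per-bit weight is normalized by the unpadded template cube count, so
  # a member's slot contribution is weight * (its cube count / the
  # template's), i.e. the nominal weight up to rasterization noise.
  # Support of a slot's weight: cubes its eroded sphere intersects (so
  # every jitter-displaced member sphere still covers them) minus cubes
  # any other atom's inflated sphere can reach (so the shared core and
  # absent slots never collect weight). A member present at the slot
  # then contributes exactly the nominal slot weight.
  pad <- sqrt(3) * spec$jitterMax
  nAll <- nAtoms(template)
  slotSupports <- vector("list", length(slotGeoms))
  for (s in seq_along(slotGeoms)) {
    idx <- nCore + s   # one heavy atom per slot, appended in order
    bitsEro <- computeOccupancy(template, tmplConf, grid,
                                typing = typing, atomSubset = idx,
                                radiusPad = -pad)
    othersPad <- computeOccupancy(template, tmplConf, grid,
                                  typing = typing,
                                  atomSubset = setdiff(seq_len(nAll), idx),
                                  radiusPad = pad)
    support <- setdiff(bitsEro, othersPad)
    if (length(support) == 0) next
    w <- rep(slots[[s]]$weight / length(support), length(support))
    names(w) <- support
    weights <- c(weights, w)
    slotSupports[[s]] <- support
  }
  # merge duplicated bits (overlapping slot spheres) by summing
  weights <- tapply(weights, names(weights), sum)
  weights <- stats::setNames(as.numeric(weights), names(weights))
  plantedPos <- rbind(A = core$coords[21L, ], R1 = core$centroids[1, ],
                      R2 = core$centroids[2, ], R3 = core$centroids[3, ])
  pd <- as.matrix(stats::dist(plantedPos))
  list(group = g, core = core, tag = tag, slots = slots,
       slotGeoms = slotGeoms, template = template, grid = grid,
       weights = weights, slotSupports = slotSupports,
       plantedLabel = spec$plantedLabel,
       plantedSites = plantedPos, plantedDistances = pd,
       intercept = spec$activityBase)
}

#' Recompute activities from the stored truth
#'
#' Ground-truth regeneration: intercept + weight map applied to the
#' occupancy bits of the stored generator-frame conformer, plus the
#' stored noise. Matches the generated activities to machine precision.
#'
#' @param dataset result of \code{generateDataset}.
#' @return named numeric vector of recomputed activities by member id.
#' @export
regenerateActivities <- function(dataset) {
  truth <- dataset$truth
  out <- numeric(0)
  ids <- vapply(dataset$molecules, molId, character(1))
  for (id in ids) {
    mb <- truth$members[[id]]
    gt <- truth$groups[[mb$group]]
    mol <- dataset$molecules[[match(id, ids)]]
    bits <- computeOccupancy(mol, mb$genConformer, gt$grid)
    out[id] <- gt$intercept +
      sum(gt$weights[intersect(bits, names(gt$weights))]) + mb$noise
  }
  out
}

#' Generate a property-matched decoy pool
#'
#' Decoys reuse the dataset's ring/formyl building blocks (similar size,
#' lipophilicity and H-bonding counts) but carry only two aromatic rings
#' -- the third ring position is a saturated carbocycle -- so the planted
#' A + 3-ring-centroid arrangement cannot be matched. Each decoy is
#' verified to have fingerprint Tanimoto below \code{tcMax} to every
#' dataset member; failing draws are resampled.
#'
#' @param dataset result of \code{generateDataset}.
#' @param ratio decoys per dataset compound (default: the spec's 36).
#' @param tcMax similarity exclusion bound (default 0.75).
#' @param seed seed (default: spec seed + 1).
#' @return list of decoy Molecules (ids "decoy0001", ...).
#' @export
generateDecoyPool <- function(dataset, ratio = NULL, tcMax = 0.75,
                              seed = NULL) {
  spec <- dataset$truth$spec
  if (is.null(ratio)) ratio <- spec$decoyRatio
  if (is.null(seed)) seed <- spec$seed + 1L
  nWant <- ratio * length(dataset$molecules)
  if (nWant == 0) return(list())
  memberFps <- lapply(dataset$molecules, fingerprint)
  withSeed(seed, {
    out <- vector("list", nWant)
    made <- 0L; attempt <- 0L
    while (made < nWant && attempt < nWant * 6L) {
      attempt <- attempt + 1L
      mol <- buildDecoy(sprintf("decoy%04d", made + 1L), spec)
      fp <- computeFingerprint(mol)
      maxTc <- max(vapply(memberFps, function(f) tanimoto(fp, f),
                          numeric(1)))
      if (maxTc >= tcMax) next
      mol@fingerprint <- fp
      made <- made + 1L
      out[[made]] <- mol
    }
    if (made < nWant)
      warning("only ", made, " of ", nWant, " decoys generated")
    out[seq_len(made)]
  })
}

# One decoy: benzene-CH2-benzene with a formyl on ring B and a saturated
# six-ring where the members carry their third aromatic ring, decorated
# with random small substituents. Uses the current RNG.
buildDecoy <- function(id, spec) {
  cA <- c(0, 0, 0); cB <- c(5.74, 0, 0); cS <- c(-2.87, 4.9707, 0)
  coords <- rbind(
    ringCoords(cA, 0), ringCoords(cB, 180),
    c(2.87, 0, 0),                     # CH2 between the aryls
    c(-1.435, 2.4855, 0),              # CH2 to the saturated ring
    ringCoords(cS, -60, radius = 1.47, pucker = 0.25),
    c(8.61, 0, 0), c(9.225, 1.0652, 0))
  el <- c(rep("C", 12), "C", "C", rep("C", 6), "C", "O")
  arom <- c(rep(TRUE, 12), rep(FALSE, 10))
  nH <- c(0L, 1L, 0L, 1L, 1L, 1L,      # ringA: 1 links CH2a, 3 CH2b
          0L, 1L, 1L, 0L, 1L, 1L,      # ringB: 7 links CH2a, 10 formyl
          2L, 2L,
          1L, 2L, 2L, 2L, 2L, 2L,      # saturated ring, 15 links CH2b
          1L, 0L)
  bonds <- rbind(
    aromaticRingBonds(0L), aromaticRingBonds(6L),
    data.frame(a1 = c(13L, 13L, 14L, 14L),
               a2 = c(1L, 7L, 3L, 15L), order = 1L),
    data.frame(a1 = 14L + c(1, 2, 3, 4, 5, 6),
               a2 = 14L + c(2, 3, 4, 5, 6, 1), order = 1L),
    data.frame(a1 = c(10L, 21L), a2 = c(21L, 22L), order = c(1L, 2L)))
  atoms <- data.frame(element = el, charge = 0L, aromatic = arom,
                      nH = nH, stringsAsFactors = FALSE)
  core <- list(atoms = atoms, coords = coords, bonds = bonds,
               centroids = rbind(cA, cB, cS))
  # random decoration: 0-3 substituents on the free aryl positions
  freePos <- c(2L, 4L, 5L, 6L, 8L, 9L, 11L, 12L)
  nSub <- sample(0:3, 1)
  pieces <- list()
  if (nSub > 0) {
    pos <- sample(freePos, nSub)
    for (att in pos) {
      elSub <- sample(c("C", "O", "F", "N"), 1)
      ringCentroid <- if (att <= 6L) cA else cB
      dir <- unitVector(coords[att, ] - ringCentroid)
      pieces[[length(pieces) + 1L]] <- list(
        atoms = data.frame(element = elSub, charge = 0L,
                           aromatic = FALSE, nH = subNH[[elSub]]),
        coords = matrix(coords[att, ] + BL_SUB[[elSub]] * dir, 1),
        attach = att,
        bonds = data.frame(a1 = 0L, a2 = 1L, order = 1L))
    }
  }
  jit <- function(n) matrix(stats::runif(3 * n, -spec$jitterMax,
                                         spec$jitterMax), n, 3)
  assembleMolecule(id, core, pieces, jitter = jit)
}
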