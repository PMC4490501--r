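# Atom-based grid 3D-QSAR. Aligned conformers are rasterized onto 1 A
# cubes: each atom is a van der Waals sphere under one of six atom-type
# channels (D donor, H hydrophobic/nonpolar, N negative ionic, P positive
# ionic, W electron-withdrawing incl. acceptors, X miscellaneous); a bit
# (cube, channel) is 1 when the sphere intersects the cube. Activities
# are regressed on the binary descriptors by partial least squares with
# three factors; each bit receives a regression coefficient for the
# favorable/unfavorable coefficient map.

QSAR_CHANNELS <- c("D", "H", "N", "P", "W", "X")

#' Assign QSAR atom types
#'
#' Pattern-driven typing with precedence N > P > D > W > H > X over the
#' heavy atoms. W (electron-withdrawing) covers hydrogen-bond acceptor
#' atoms and halogens; H covers nonpolar carbons (aromatic included) and
#' sulfur without polar neighbours; X is the catch-all.
#'
#' @param mol a Molecule.
#' @return list with \code{types} (character per heavy atom) and
#'   \code{radii} (van der Waals radii, Angstrom).
#' @export
assignAtomTypes <- function(mol) {
  ar <- atomRoles(mol)
  n <- nAtoms(mol)
  el <- mol@atoms$element
  # ionic typing applies to the heteroatoms of the charged group, not the
  # carbon skeleton the pattern spans
  negAtoms <- setdiff(unique(unlist(ar$matches$N)), which(el == "C"))
  posAtoms <- setdiff(unique(unlist(ar$matches$P)), which(el == "C"))
  donAtoms <- unique(unlist(ar$matches$D))
  accAtoms <- unique(unlist(ar$matches$A))
  types <- rep("X", n)
  isC <- el == "C"
  types[isC] <- "H"   # carbons default to hydrophobic
  types[el %in% c("F", "Cl", "Br", "I")] <- "W"
  types[el == "S"] <- "H"
  types[accAtoms] <- "W"
  types[donAtoms] <- "D"
  types[posAtoms] <- "P"
  types[negAtoms] <- "N"
  list(types = types, radii = vdwRadiusOf(el))
}

#' Build a grid covering aligned conformers
#'
#' Extents cover all supplied coordinate matrices plus the maximum van
#' der Waals radius as padding; the origin snaps to the integer lattice
#' so that translation by a whole cube shifts indices exactly.
#'
#' @param coordList list of n x 3 matrices.
#' @param spacing cube edge (default 1 Angstrom).
#' @param padding extra margin (default: max vdW radius + 0.5).
#' @return a \code{GridSpec}.
#' @export
buildGrid <- function(coordList, spacing = 1.0, padding = NULL) {
  all <- do.call(rbind, coordList)
  if (is.null(padding)) padding <- max(vdwRadii()) + 0.5
  lo <- floor((apply(all, 2, min) - padding) / spacing) * spacing
  hi <- ceiling((apply(all, 2, max) + padding) / spacing) * spacing
  new("GridSpec", origin = lo, spacing = spacing,
      extents = as.integer(round((hi - lo) / spacing)),
      channels = QSAR_CHANNELS)
}

# Cubes intersected by a sphere: candidate index ranges per axis, then an
# exact sphere-box test (squared distance from the centre to the nearest
# point of each cube).
sphereCubes <- function(center, radius, grid) {
  sp <- grid@spacing
  o <- grid@origin
  loIdx <- pmax(floor((center - radius - o) / sp), 0)
  hiIdx <- pmin(ceiling((center + radius - o) / sp) - 1, grid@extents - 1)
  if (any(hiIdx < loIdx)) return(matrix(integer(0), 0, 3))
  ix <- seq(loIdx[1], hiIdx[1]); iy <- seq(loIdx[2], hiIdx[2])
  iz <- seq(loIdx[3], hiIdx[3])
  cand <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))
  cubeLo <- sweep(cand * sp, 2, o, `+`)
  cubeHi <- cubeLo + sp
  nearest <- pmin(pmax(matrix(center, nrow(cand), 3, byrow = TRUE),
                       cubeLo), cubeHi)
  d2 <- rowSums(sweep(nearest, 2, center)^2)
  cand[d2 <= radius^2, , drop = FALSE]
}

#' Compute the binary occupancy descriptor of an aligned conformer
#'
#' A bit (cube, channel) is set when an atom of that channel's type has
#' its van der Waals sphere intersecting the cube (any overlap). Donor
#' hydrogens are rasterized at radius 1.2 A under channel D; other
#' hydrogens are implicit. Atoms outside the grid contribute no bits.
#'
#' @param mol the Molecule (for elements / hydrogen counts).
#' @param conf aligned conformer coordinates.
#' @param grid a \code{GridSpec}.
#' @param typing result of \code{assignAtomTypes(mol)} (recomputed when
#'   NULL).
#' @param atomSubset optional atom indices to rasterize (default: all).
#' @param radiusPad additive padding on every sphere radius (used by the
#'   synthetic generator to build jitter-tolerant weight supports).
#' @return character vector of set bit ids "ix:iy:iz:channel"
#'   (0-based cube indices).
#' @export
computeOccupancy <- function(mol, conf, grid, typing = NULL,
                             atomSubset = NULL, radiusPad = 0) {
  if (nAtoms(mol) == 0 || nrow(conf) == 0) return(character(0))
  if (is.null(typing)) typing <- assignAtomTypes(mol)
  if (is.null(atomSubset)) atomSubset <- seq_len(nAtoms(mol))
  bits <- character(0)
  for (i in atomSubset) {
    cubes <- sphereCubes(conf[i, ], typing$radii[i] + radiusPad, grid)
    if (nrow(cubes))
      bits <- c(bits, paste0(cubes[, 1], ":", cubes[, 2], ":",
                             cubes[, 3], ":", typing$types[i]))
    if (typing$types[i] == "D" && mol@atoms$nH[i] > 0) {
      hp <- hydrogenPositions(mol, conf, i)
      for (hh in seq_len(nrow(hp))) {
        cubes <- sphereCubes(hp[hh, ], 1.2 + radiusPad, grid)
        if (nrow(cubes))
          bits <- c(bits, paste0(cubes[, 1], ":", cubes[, 2], ":",
                                 cubes[, 3], ":D"))
      }
    }
  }
  sort(unique(bits))
}

# ---- PLS ------------------------------------------------------------------

# PLS1 (NIPALS) on centered, unscaled data. Returns the regression vector
# in the original predictor space plus the intercept. Factors beyond the
# data rank contribute nothing (zero-norm weight vectors stop the loop).
plsFit <- function(X, y, nFactors = 3L) {
  n <- nrow(X); p <- ncol(X)
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2, xbar); f <- y - ybar
  W <- matrix(0, p, 0); P <- matrix(0, p, 0); Q <- numeric(0)
  Tm <- matrix(0, n, 0)
  for (a in seq_len(nFactors)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- crossprod(E, t) / tt
    q <- sum(f * t) / tt
    E <- E - t %*% t(pvec)
    f <- f - q * t
    W <- cbind(W, w); P <- cbind(P, pvec); Q <- c(Q, q)
    Tm <- cbind(Tm, t)
  }
  if (ncol(W) == 0) {
    beta <- numeric(p)
  } else {
    beta <- as.numeric(W %*% solve(crossprod(P, W), Q))
  }
  list(coefficients = beta, intercept = ybar - sum(xbar * beta),
       xbar = xbar, ybar = ybar, nFactorsUsed = ncol(W))
}

#' Fit an atom-based grid QSAR model
#'
#' Partial least squares (3 factors) of pIC50 on binary occupancy bits.
#'
#' @param bitList list of bit-id character vectors (one per training
#'   compound, from \code{computeOccupancy}).
#' @param activities numeric pIC50 vector.
#' @param grid the \code{GridSpec} the bits refer to.
#' @param nFactors PLS factor count (default 3).
#' @param hypothesisRef id of the aligning hypothesis (bookkeeping).
#' @param statsSeed seed for the stability resampling.
#' @return a \code{QsarModel} (stats filled in, including LOO Q2).
#' @export
fitQsar <- function(bitList, activities, grid, nFactors = 3L,
                    hypothesisRef = "", statsSeed = 1L) {
  n <- length(bitList)
  stopifnot(n == length(activities), n >= nFactors + 2)
  if (stats::sd(activities) < 1e-12)
    stop("degenerate response: all training activities are equal")
  universe <- sort(unique(unlist(bitList)))
  if (length(universe) == 0)
    stop("no occupancy bits in the training set")
  X <- matrix(0, n, length(universe),
              dimnames = list(NULL, universe))
  for (i in seq_len(n)) X[i, bitList[[i]]] <- 1
  if (all(apply(X, 2, function(col) length(unique(col))) == 1))
    stop("no occupancy bit varies across the training set")
  fit <- plsFit(X, activities, nFactors)
  pred <- as.numeric(X %*% fit$coefficients) + fit$intercept
  q2 <- looQ2(X, activities, nFactors)
  stab <- stabilityScore(X, activities, nFactors, pred, seed = statsSeed)
  st <- computeStats(activities, pred, nPredictorsEffective = nFactors)
  stats <- c(r2 = st$r2, sd = st$sd, f = st$f, p = st$p,
             stability = stab, q2_loo = q2)
  new("QsarModel", grid = grid, bits = universe,
      coefficients = fit$coefficients, intercept = fit$intercept,
      nFactors = as.integer(nFactors), stats = stats,
      hypothesisRef = hypothesisRef)
}

#' Leave-one-out cross-validated Q2
#'
#' Each compound is predicted by a model refitted on all others;
#' Q2 = 1 - PRESS / SS_tot.
#'
#' @param X binary predictor matrix.
#' @param y activities.
#' @param nFactors PLS factors.
#' @return Q2 (can be negative).
#' @export
looQ2 <- function(X, y, nFactors = 3L) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    fit <- plsFit(X[-i, , drop = FALSE], y[-i], nFactors)
    pred <- sum(X[i, ] * fit$coefficients) + fit$intercept
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Stability: 10 rounds of leave-25%-out refits; mean Pearson correlation
# between full-model and refit-model predictions on the held-out quarter.
stabilityScore <- function(X, y, nFactors, fullPred, rounds = 10L,
                           seed = 1L) {
  n <- nrow(X)
  hold <- max(2L, round(n / 4))
  withSeed(seed, {
    vals <- numeric(0)
    for (r in seq_len(rounds)) {
      out <- sample(n, hold)
      fit <- plsFit(X[-out, , drop = FALSE], y[-out], nFactors)
      predOut <- as.numeric(X[out, , drop = FALSE] %*% fit$coefficients) +
        fit$intercept
      if (stats::sd(predOut) < 1e-12 || stats::sd(fullPred[out]) < 1e-12)
        next
      vals <- c(vals, stats::cor(fullPred[out], predOut))
    }
    if (length(vals) == 0) NA_real_ else mean(vals)
  })
}

#' Predict activity from occupancy bits
#'
#' Intercept plus the sum of coefficients over set bits; bits unseen in
#' training contribute nothing.
#'
#' @param model a \code{QsarModel}.
#' @param bits character vector of set bit ids.
#' @return predicted pIC50.
#' @export
predictQsar <- function(model, bits) {
  idx <- match(bits, model@bits)
  model@intercept + sum(model@coefficients[idx[!is.na(idx)]])
}

#' Predict activity for a molecule conformer aligned to the model's frame
#'
#' @param model a \code{QsarModel}.
#' @param mol the Molecule.
#' @param conf aligned conformer coordinates.
#' @return predicted pIC50.
#' @export
predictQsarConformer <- function(model, mol, conf) {
  predictQsar(model, computeOccupancy(mol, conf, model@grid))
}

#' Classical regression statistics for a QSAR fit
#'
#' r2 is the squared Pearson correlation between observed and predicted;
#' SD = sqrt(SSE / (n - k - 1)) with k the effective model dimension (the
#' PLS factor count); F = (SSR / k) / (SSE / (n - k - 1)); p is the
#' upper-tail probability of F(k, n - k - 1). Optionally, stability is
#' the mean correlation between full-model and resampled-model
#' predictions.
#'
#' @param observed,predicted equal-length activity vectors (n >= 4).
#' @param nPredictorsEffective effective model dimension k (default 3).
#' @param resamplePredictions optional list of prediction vectors from
#'   resampled models (each full length); stability is their mean Pearson
#'   correlation with \code{predicted}.
#' @return list: r2, sd, f, p, and stability (NA when no resamples).
#' @export
computeStats <- function(observed, predicted, nPredictorsEffective = 3L,
                         resamplePredictions = NULL) {
  n <- length(observed)
  stopifnot(n == length(predicted), n >= 4)
  if (stats::sd(observed) < 1e-12)
    stop("zero variance in observed activities")
  k <- nPredictorsEffective
  sse <- sum((observed - predicted)^2)
  ssr <- sum((predicted - mean(observed))^2)
  df2 <- n - k - 1
  r2 <- if (stats::sd(predicted) < 1e-12) 0 else
    stats::cor(observed, predicted)^2
  sdv <- sqrt(sse / df2)
  fv <- (ssr / k) / (sse / df2)
  pv <- stats::pf(fv, k, df2, lower.tail = FALSE)
  stab <- NA_real_
  if (!is.null(resamplePredictions) && length(resamplePredictions) > 0) {
    stab <- mean(vapply(resamplePredictions, function(rp)
      stats::cor(predicted, rp), numeric(1)))
  }
  list(r2 = r2, sd = sdv, f = fv, p = pv, stability = stab)
}

#' Export the per-bit coefficient map
#'
#' One row per nonzero coefficient: channel, cube centre coordinates and
#' the regression coefficient (positive = favorable to activity).
#'
#' @param model a \code{QsarModel}.
#' @param zeroTol coefficients with |value| <= zeroTol are suppressed.
#' @return data.frame (channel, x, y, z, coefficient).
#' @export
coefficientMap <- function(model, zeroTol = 0) {
  keep <- which(abs(model@coefficients) > zeroTol)
  if (length(keep) == 0)
    return(data.frame(channel = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0),
                      coefficient = numeric(0)))
  parts <- strsplit(model@bits[keep], ":", fixed = TRUE)
  ixyz <- t(vapply(parts, function(p) as.numeric(p[1:3]), numeric(3)))
  sp <- model@grid@spacing
  ctr <- sweep(ixyz * sp + sp / 2, 2, model@grid@origin, `+`)
  data.frame(channel = vapply(parts, `[[`, character(1), 4),
             x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
             coefficient = model@coefficients[keep])
}
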