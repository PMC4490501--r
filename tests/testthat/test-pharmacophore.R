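# Site perception, pharmacophore enumeration, CPH search, scoring,
# filtering/clustering and alignment.

test_that("site perception matches the shipped pattern definitions", {
  benz <- smilesMol("c1ccccc1", "benzene")
  sb <- perceiveSites(benz)
  expect_equal(siteTypeString(sb), "R")
  # centroid and normal of the single aromatic ring
  r <- sb[[1]]
  expect_equal(r@position, colMeans(conformer(benz)), tolerance = 0.05)
  expect_equal(sqrt(sum(r@direction^2)), 1, tolerance = 1e-6)
  ph <- perceiveSites(smilesMol("Oc1ccccc1", "phenol"))
  expect_equal(siteTypeString(ph), "ADR")
  ac <- perceiveSites(smilesMol("CC([O-])=O", "acetate"))
  types <- vapply(ac, function(s) s@type, character(1))
  expect_equal(sum(types == "N"), 1)
  # the N site sits at the carboxylate group centroid, not on one atom
  nsite <- ac[[which(types == "N")]]
  expect_length(nsite@atoms, 3)
})

test_that("pharmacophore enumeration counts and canonical distances", {
  ds <- refDataset()
  sites <- perceiveSites(ds$molecules[[1]])
  n <- length(sites)
  e4 <- enumeratePharmacophores(sites[1:4], 4)
  expect_length(e4, 1)
  expect_length(e4[[1]]$dvec, 6)
  e6 <- enumeratePharmacophores(sites[seq_len(min(6, n))], 4)
  expect_length(e6, choose(min(6, n), 4))
  expect_length(enumeratePharmacophores(sites[1:3], 4), 0)
})

test_that("CPH search recovers the planted arrangement", {
  ds <- refDataset()
  grp <- ds$molecules[1:20]
  actives <- grp[classifyActivity(vapply(grp, activity,
                                         numeric(1))) == "active"]
  hyps <- findCommonPharmacophores(actives, k = 4)
  labs <- vapply(hyps, function(h) h@label, character(1))
  expect_true("ARRR" %in% labs)
  found <- hyps[[which(labs == "ARRR")[1]]]
  planted <- ds$truth$groups[[1]]$plantedDistances
  expect_equal(sort(found@distances[upper.tri(found@distances)]),
               sort(planted[upper.tri(planted)]), tolerance = 0.15)
  # order invariance over the actives
  hyps2 <- findCommonPharmacophores(rev(actives), k = 4)
  expect_identical(sort(vapply(hyps2, function(h) h@label, character(1))),
                   sort(labs))
})

test_that("two identical molecules share every k-point pharmacophore", {
  ds <- refDataset()
  m <- ds$molecules[[1]]
  m2 <- m; m2@id <- "copy"
  hyps <- findCommonPharmacophores(list(m, m2), k = 4, mustMatch = 2)
  nSites <- length(perceiveSites(m))
  expect_gte(length(hyps), 1)
  expect_equal(attr(hyps, "mustMatch"), 2)
})

test_that("feature-poor actives give a typed no-CPH error", {
  benz <- smilesMol("c1ccccc1", "b1"); tol <- smilesMol("Cc1ccccc1", "t1")
  activity(benz) <- 8; activity(tol) <- 8
  expect_error(findCommonPharmacophores(list(benz, tol), k = 4),
               "no common pharmacophore")
})

test_that("self-alignment is exact and rigid-motion invariant", {
  ds <- refDataset()
  grp <- ds$molecules[1:20]
  actives <- grp[classifyActivity(vapply(grp, activity,
                                         numeric(1))) == "active"]
  hyps <- findCommonPharmacophores(actives, k = 4)
  h <- hyps[[1]]
  ref <- actives[[match(h@referenceId,
                        vapply(actives, molId, character(1)))]]
  al <- alignToHypothesis(ref, h)
  expect_true(al$matched)
  expect_lt(al$siteRmsd, 1e-6)
  expect_gt(al$volumeScore, 0.97)
  # rotate 90 degrees and translate 10 A: superposition recovers it
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- ref
  moved@conformers <- list(m = sweep(conformer(ref) %*% R90, 2,
                                     c(10, 0, 0), `+`))
  al2 <- alignToHypothesis(moved, h)
  expect_true(al2$matched)
  expect_lt(al2$siteRmsd, 1e-6)
})

test_that("type-incompatible ligands report no feature match", {
  ds <- refDataset()
  grp <- ds$molecules[1:20]
  actives <- grp[classifyActivity(vapply(grp, activity,
                                         numeric(1))) == "active"]
  h <- findCommonPharmacophores(actives, k = 4)[[1]]
  hex <- smilesMol("CCCCCC", "hexane")  # no aromatic ring, no acceptor
  al <- alignToHypothesis(hex, h)
  expect_false(al$matched)
  expect_equal(al$reason, "no feature match")
})

test_that("survival scoring averages matched actives and ranks tight
           hypotheses above distorted ones", {
  ds <- refDataset()
  grp <- ds$molecules[1:20]
  actives <- grp[classifyActivity(vapply(grp, activity,
                                         numeric(1))) == "active"]
  hyps <- findCommonPharmacophores(actives, k = 4)
  labs <- vapply(hyps, function(h) h@label, character(1))
  h <- hyps[[which(labs == "ARRR")[1]]]
  scored <- scoreHypothesis(h, actives)
  expect_gt(scored@survival, 0)
  expect_gte(scored@nActivesMatched, length(actives) - 1)
  # duplicated reference: survival equals the self-score
  ref <- actives[[match(h@referenceId,
                        vapply(actives, molId, character(1)))]]
  dup <- lapply(1:5, function(i) { r <- ref; r@id <- paste0("d", i); r })
  sDup <- scoreHypothesis(h, dup)
  sSelf <- scoreHypothesis(h, list(ref))
  expect_equal(sDup@survival, sSelf@survival, tolerance = 1e-9)
  # distorting a site loosens every match and lowers the survival score
  hBad <- h
  hBad@sites[[1]]@position <- h@sites[[1]]@position + c(0.9, 0, 0)
  d <- combiphore:::sitePositions(hBad@sites)
  hBad@distances <- as.matrix(stats::dist(d)); dimnames(hBad@distances) <- NULL
  sBad <- scoreHypothesis(hBad, actives)
  expect_lt(sBad@survival, scored@survival)
})

test_that("zero matched actives yields survival 0 with a flag", {
  ds <- refDataset()
  grp <- ds$molecules[1:20]
  actives <- grp[classifyActivity(vapply(grp, activity,
                                         numeric(1))) == "active"]
  h <- findCommonPharmacophores(actives, k = 4)[[1]]
  hex <- smilesMol("CCCCCC", "hx"); activity(hex) <- 8
  s <- scoreHypothesis(h, list(hex))
  expect_equal(s@survival, 0)
  expect_true(isTRUE(attr(s, "zeroMatched")))
})

test_that("filtering keeps the top fraction and clustering collapses
           identical distance vectors", {
  ds <- refDataset()
  grp <- ds$molecules[1:20]
  actives <- grp[classifyActivity(vapply(grp, activity,
                                         numeric(1))) == "active"]
  hyps <- findCommonPharmacophores(actives, k = 4)
  scored <- lapply(hyps, scoreHypothesis, actives = actives)
  # pad with survival-only stubs to reach 20 hypotheses
  pad <- lapply(seq_len(max(0, 20 - length(scored))), function(i) {
    h <- scored[[1]]
    h@survival <- 0.01 * i
    attr(h, "matches") <- NULL
    h
  })
  all20 <- c(scored, pad)[1:20]
  reps <- filterAndCluster(all20)
  expect_lte(length(reps), ceiling(0.10 * 20))
  expect_gte(length(reps), 1)
  # two hypotheses with identical distance vectors -> one representative
  twin <- scored[[1]]
  reps2 <- filterAndCluster(list(scored[[1]], twin),
                            keepFraction = 1.0)
  expect_length(reps2, 1)
})

test_that("superposition RMSD agrees with an independent quaternion
           oracle on random point sets", {
  # Horn's closed-form absolute orientation via the quaternion
  # eigenproblem: an independent route to the optimal rotation
  hornRmsd <- function(X, Y) {
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    S <- crossprod(Xc, Yc)
    K <- matrix(0, 4, 4)
    K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
    K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
    K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
    K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
    K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
    K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
    K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
    K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
    K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
    K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
    lmax <- max(eigen(K, symmetric = TRUE)$values)
    msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lmax) / nrow(X)
    sqrt(max(0, msd))
  }
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(4:6, 1)
    X <- matrix(rnorm(3 * k, sd = 3), k, 3)
    Y <- matrix(rnorm(3 * k, sd = 3), k, 3)
    expect_equal(kabsch(X, Y)$rmsd, hornRmsd(X, Y), tolerance = 1e-3)
  }
})
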