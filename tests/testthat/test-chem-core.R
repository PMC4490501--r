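# Molecule model, activity bookkeeping, fingerprints, similarity and
# conformer ensembles.

test_that("IC50 to pIC50 conversion and round trip", {
  expect_equal(pIC50FromIC50(1000), 6.0)
  expect_equal(pIC50FromIC50(1), 9.0)
  expect_equal(pIC50FromIC50(1, units = "uM"), 6.0)
  for (p in seq(3, 12, by = 0.5))
    expect_equal(9 - log10(10^(9 - p)), p, tolerance = 1e-12)
})

test_that("activity classification uses strict thresholds", {
  expect_equal(classifyActivity(7.5), "active")
  expect_equal(classifyActivity(4.2), "inactive")
  expect_equal(classifyActivity(7.0), "moderate")  # not "greater than"
  expect_equal(classifyActivity(5.0), "moderate")
  expect_error(classifyActivity(NaN))
})

test_that("activity table reading skips malformed records and converts units", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles,ic50_nM",
               "X,c1ccccc1O,1000",
               "BAD,not_a_smiles(((,50",
               "Y,CCO,1"), tf)
  mols <- suppressWarnings(readMolecules(tf, format = "activity-csv"))
  expect_length(mols, 2)
  expect_equal(attr(mols, "skipped"), 1L)
  expect_equal(activity(mols[[1]]), 6.0)
  expect_equal(activity(mols[[2]]), 9.0)
})

test_that("unreadable or empty inputs are fatal", {
  expect_error(readMolecules("/nonexistent/file.sdf", "sdf"),
               "cannot read")
  tf <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles,ic50_nM", "A,xxxxx((((,1"), tf)
  expect_error(suppressWarnings(readMolecules(tf, "activity-csv")),
               "no valid records")
})

test_that("SDF round trip preserves structure and coordinates", {
  m <- smilesMol("Oc1ccccc1C", "cresol")
  tf <- tempfile(fileext = ".sdf")
  writeSdf(list(m), tf)
  back <- readMolecules(tf, format = "sdf")
  expect_length(back, 1)
  b <- back[[1]]
  expect_equal(molId(b), "cresol")
  expect_equal(nAtoms(b), nAtoms(m))
  expect_equal(sort(atomTable(b)$element), sort(atomTable(m)$element))
  expect_equal(conformer(b), conformer(m), tolerance = 1e-3)
})

test_that("Molecule validity rejects malformed objects", {
  at <- data.frame(element = "C", charge = 0L, aromatic = FALSE, nH = 4L)
  expect_error(Molecule("bad", at,
    bonds = data.frame(a1 = 1L, a2 = 5L, order = 1L)),
    "invalid atom index")
  expect_error(Molecule("bad", at, data.frame(),
    conformers = list(matrix(0, 3, 3))), "nAtoms x 3")
  expect_error(Molecule("bad", at, data.frame(), activity = Inf),
               "finite")
})

test_that("tanimoto arithmetic, symmetry and the empty-set convention", {
  expect_equal(tanimoto(1:5, 1:5), 1.0)
  expect_equal(tanimoto(1:3, 4:6), 0.0)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 9)), 0.5)
  expect_warning(z <- tanimoto(integer(0), integer(0)), "empty")
  expect_equal(z, 0)
  set.seed(11)
  for (i in 1:200) {
    a <- sample(0:50, sample(0:12, 1))
    b <- sample(0:50, sample(1:12, 1))
    t1 <- tanimoto(a, b)
    expect_identical(t1, tanimoto(b, a))
    expect_gte(t1, 0); expect_lte(t1, 1)
  }
})

test_that("fingerprint is canonical-order invariant and discriminative", {
  m <- smilesMol("CCO", "ethanol")
  # same structure, permuted atom input order
  perm <- c(3, 1, 2)
  at <- atomTable(m)[perm, ]; rownames(at) <- NULL
  inv <- order(perm)
  b <- bondTable(m)
  m2 <- Molecule("ethanol-permuted", at,
                 data.frame(a1 = inv[b$a1], a2 = inv[b$a2],
                            order = b$order),
                 conformers = list(conformer(m)[perm, ]))
  expect_identical(computeFingerprint(m), computeFingerprint(m2))
  expect_false(identical(
    computeFingerprint(smilesMol("c1ccccc1", "benzene")),
    computeFingerprint(smilesMol("c1ccncc1", "pyridine"))))
  # methane: a single-atom environment still yields bits
  expect_gt(length(computeFingerprint(smilesMol("C", "methane"))), 0)
})

test_that("rigid molecules keep a single conformer", {
  benz <- smilesMol("c1ccccc1", "benzene")
  out <- generateConformers(benz, maxCount = 10)
  expect_length(conformers(out), 1)
})

test_that("conformer ensembles respect the RMSD cutoff and match a
           brute-force pruning oracle", {
  hex <- smilesMol("CCCCCC", "hexane")
  out <- generateConformers(hex, maxCount = 32, rmsdCutoff = 1.0,
                            seed = 3)
  cfs <- conformers(out)
  expect_gte(length(cfs), 2)
  expect_lte(length(cfs), 32)
  for (i in seq_along(cfs)) for (j in seq_len(i - 1))
    expect_gt(bestFitRmsd(cfs[[i]], cfs[[j]]), 1.0)
  # independent all-pairs greedy pruning oracle on the raw candidates
  rb <- rotatableBonds(hex)$bonds
  raw <- combiphore:::genTorsionCandidates(hex, conformer(hex), rb,
                                           seed = 3, maxCandidates = 200)
  keys <- vapply(raw, function(cf) paste(sprintf("%.4f", cf),
                                         collapse = ","), character(1))
  raw <- raw[order(keys)]
  oracle <- list()
  for (cf in raw) {
    if (all(vapply(oracle, function(k) kabsch(cf, k)$rmsd > 1.0,
                   logical(1))))
      oracle[[length(oracle) + 1]] <- cf
  }
  expect_equal(length(cfs), min(32, length(oracle)))
})

test_that("conformer dedup count is invariant to candidate order", {
  hex <- smilesMol("CCCCCC", "hexane2")
  rb <- rotatableBonds(hex)$bonds
  raw <- combiphore:::genTorsionCandidates(hex, conformer(hex), rb,
                                           seed = 5, maxCandidates = 100)
  n1 <- length(combiphore:::pruneByRmsd(raw, 1.0))
  set.seed(9)
  n2 <- length(combiphore:::pruneByRmsd(raw[sample(length(raw))], 1.0))
  expect_identical(n1, n2)
})

test_that("conformer generation without a starting geometry is a typed error", {
  at <- data.frame(element = "C", charge = 0L, aromatic = FALSE, nH = 4L)
  m <- Molecule("naked", at, data.frame())
  expect_error(generateConformers(m), "naked")
})
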