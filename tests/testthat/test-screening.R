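# Enrichment factors, Lipinski filtering, decoy assembly and the
# screening pipeline contracts.

test_that("enrichment factor arithmetic", {
  expect_equal(enrichmentFactor(2, 2, 2, 10), 5.0)
  expect_equal(enrichmentFactor(7, 100, 7, 100), 1.0)
  expect_equal(enrichmentFactor(0, 10, 5, 100), 0.0)
  expect_error(enrichmentFactor(0, 0, 5, 100), "nS = 0")
})

test_that("EF curve: perfect ranking, whole-database identity and the
           direct-count oracle", {
  ranked <- data.frame(id = paste0("c", 1:100),
                       score = seq(10, 0.1, length.out = 100),
                       is_active = c(rep(TRUE, 10), rep(FALSE, 90)))
  ef <- efCurve(ranked, c(0.10, 1.0))
  expect_equal(ef$ef_values[1], 10.0)
  expect_equal(ef$ef_values[2], 1.0)
  expect_error(efCurve(transform(ranked, is_active = FALSE)),
               "no actives")
  # oracle equality and bounds on random lists
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(50:200, 1)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE,
                  prob = c(0.1, 0.9))
    if (!any(lab)) lab[1] <- TRUE
    rl <- data.frame(id = seq_len(n), score = sort(runif(n),
                                                   decreasing = TRUE),
                     is_active = lab)
    for (phi in c(0.01, 0.05, 0.25, 1.0)) {
      nS <- ceiling(phi * n)
      oracle <- (sum(lab[1:nS]) * n) / (nS * sum(lab))  # exact rational
      got <- efCurve(rl, phi)$ef_values
      expect_identical(got, oracle)
      expect_lte(got, 1 / phi + 1e-12)
      expect_lte(got, n / sum(lab) + 1e-12)
    }
  }
})

test_that("Lipinski filter: small molecules pass, gross violators fail,
           one violation is tolerated", {
  eth <- smilesMol("CCO", "ethanol")
  lf <- lipinskiFilter(list(eth))
  expect_length(lf$passing, 1)
  expect_equal(unname(lf$violations["ethanol"]), 0L)
  # hand-built violator: C32 lipophilic backbone (logP >> 5, MW > 500)
  # decorated with 6 hydroxyls (donors > 5) and 8 ethers (acceptors > 10)
  big <- smilesMol(paste0(
    "OCC(O)C(O)C(O)C(O)C(O)COCCOCCOCCOCCOCCOCCOC",
    "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"), "violator")
  lfB <- lipinskiFilter(list(big))
  expect_length(lfB$passing, 0)
  expect_gte(unname(lfB$violations["violator"]), 2L)
  # exactly one violation (MW just over 500, rest compliant) passes:
  # a tetra-amide with N-methylated (donor-free) amides
  mono <- smilesMol(paste0("CN(C)C(=O)CCCCCCN(C)C(=O)CCCCCC",
                           "N(C)C(=O)CCCCCCN(C)C(=O)C"), "amide-chain")
  p <- molProperties(mono)
  expect_gt(p$MW, 500)
  expect_lte(p$logP, 5); expect_lte(p$HBD, 5); expect_lte(p$HBA, 10)
  lfM <- lipinskiFilter(list(mono))
  expect_equal(unname(lfM$violations["amide-chain"]), 1L)
  expect_length(lfM$passing, 1)
  expect_length(lipinskiFilter(list(big), strict = TRUE)$passing, 0)
})

test_that("screening pipeline: self-retrieval, provenance and stable
           ordering", {
  ds <- refDataset()
  model <- refModel()
  grp1 <- ds$molecules[1:10]
  hits <- screenLibrary(model, grp1, activityMin = 5.0, topN = 100)
  expect_gt(nrow(hits), 0)
  expect_true(all(diff(hits$score) <= 0))
  # training actives populate the list near their activities
  expect_gt(max(hits$score), 7)
  prov <- attr(hits, "provenance")
  expect_setequal(names(prov), vapply(grp1, molId, character(1)))
  # molecules failing the filter stage are logged there
  big <- smilesMol(paste0(
    "OCC(O)C(O)C(O)C(O)C(O)COCCOCCOCCOCCOCCOCCOC",
    "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"), "fatso")
  h2 <- suppressWarnings(
    screenLibrary(model, list(big), activityMin = 5.0))
  expect_equal(unname(attr(h2, "provenance")["fatso"]), "lipinski")
  expect_equal(nrow(h2), 0)
})

test_that("decoy selection enforces windows, the Tc bound and
           deduplication", {
  ds <- refDataset()
  actives <- ds$molecules[1:2]
  pool <- generateDecoyPool(list(molecules = actives,
                                 truth = ds$truth), ratio = 8)
  sel <- suppressWarnings(
    makeDecoySet(actives, pool, ratio = 3, tcMax = 0.75,
                 windows = c(MW = 60, logP = 2.5, HBD = 3, HBA = 3,
                             RotB = 4)))
  expect_lte(length(sel), 6)
  expect_false(anyDuplicated(vapply(sel, molId, character(1))) > 0)
  # post-hoc verification of every selected decoy
  aProps <- lapply(actives, molProperties)
  aRotB <- vapply(actives, function(m) rotatableBonds(m)$count,
                  integer(1))
  aFps <- lapply(actives, fingerprint)
  for (d in sel) {
    dp <- molProperties(d)
    okWin <- any(vapply(seq_along(actives), function(i) {
      abs(dp$MW - aProps[[i]]$MW) <= 60 &&
        abs(dp$logP - aProps[[i]]$logP) <= 2.5 &&
        abs(dp$HBD - aProps[[i]]$HBD) <= 3 &&
        abs(dp$HBA - aProps[[i]]$HBA) <= 3 &&
        abs(rotatableBonds(d)$count - aRotB[i]) <= 4
    }, logical(1)))
    expect_true(okWin)
    expect_true(all(vapply(aFps, function(f)
      tanimoto(fingerprint(d), f) < 0.75, logical(1))))
  }
  # candidates identical to an active are excluded by the Tc bound
  clone <- actives[[1]]; clone@id <- "clone"
  selC <- suppressWarnings(makeDecoySet(actives, list(clone),
                                        ratio = 36))
  expect_length(selC, 0)
})
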