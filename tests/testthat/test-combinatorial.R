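# Best-model selection, combinatorial assembly, Tc dispatch and the
# prediction contracts.

test_that("best-model selection ranks r2, stability, F, then p", {
  h <- refModel()@entries[[1]]$hypothesis
  cand <- function(...) list(hypothesis = h, qsar = stubQsar(...))
  pick <- selectBestModel(list(cand(0.8), cand(0.9)))
  expect_equal(unname(pick$qsar@stats["r2"]), 0.9)
  pick <- selectBestModel(list(cand(0.9, stability = 0.7),
                               cand(0.9, stability = 0.5)))
  expect_equal(unname(pick$qsar@stats["stability"]), 0.7)
  pick <- selectBestModel(list(cand(0.9, 0.7, f = 5),
                               cand(0.9, 0.7, f = 9)))
  expect_equal(unname(pick$qsar@stats["f"]), 9)
  pick <- selectBestModel(list(cand(0.9, 0.7, 9, p = 0.02),
                               cand(0.9, 0.7, 9, p = 0.01)))
  expect_equal(unname(pick$qsar@stats["p"]), 0.01)
  single <- cand(0.5)
  expect_identical(selectBestModel(list(single)), single)
  expect_error(selectBestModel(list()), "no model candidates")
})

test_that("the combinatorial model covers every viable group with strong
           training fits", {
  model <- refModel()
  expect_length(model@entries, 3)
  rep_ <- attr(model, "report")
  expect_true(all(rep_$r2 >= 0.8))
  expect_true(all(is.finite(rep_$q2_loo)))
  expect_true(all(rep_$n_matched >= 5))
})

test_that("groups whose actives share no pharmacophore are dropped,
           others retained", {
  ds <- refDataset()
  mols <- ds$molecules[1:20]
  # a 6-member group of feature-poor actives (single aromatic ring each)
  bad <- lapply(1:6, function(i) {
    m <- smilesMol("c1ccccc1", paste0("bad", i)); activity(m) <- 8; m
  })
  grouped <- new("GroupedDataset",
    groups = list(
      list(group_id = 1L, skeleton = "good",
           member_ids = vapply(mols, molId, character(1))),
      list(group_id = 2L, skeleton = "bad",
           member_ids = vapply(bad, molId, character(1)))),
    unassigned = character(0), split = character(0))
  model <- suppressWarnings(
    buildCombinatorial(c(mols, bad), grouped, kValues = 4L))
  expect_length(model@entries, 1)
  expect_named(model@entries, "1")
  expect_match(attr(model, "dropped")[["2"]], "pharmacophore")
})

test_that("dispatch sends a training member to its own group and
           reproduces the single-model prediction", {
  ds <- refDataset()
  model <- refModel()
  m <- ds$molecules[[1]]
  own <- truthGroupToPartitionId(refGrouped(), 1)
  pr <- predictCombinatorial(model, m)
  expect_equal(pr$group_id, own)
  expect_true(pr$matched)
  # equals the dispatched group's model applied directly
  e <- model@entries[[as.character(own)]]
  al <- alignToHypothesis(m, e$hypothesis)
  expect_identical(pr$predicted,
                   predictQsarConformer(e$qsar, m, al$alignedConformer))
})

test_that("dispatch and prediction are deterministic and unaffected by
           unrelated groups", {
  ds <- refDataset()
  model <- refModel()
  q <- heldOutDataset()$molecules[[5]]
  p1 <- predictCombinatorial(model, q)
  p2 <- predictCombinatorial(model, q)
  expect_identical(p1, p2)
  # dropping a group the query is not dispatched to changes nothing
  keep <- setdiff(names(model@entries), as.character(p1$group_id))[1]
  reduced <- model
  reduced@entries <- model@entries[setdiff(names(model@entries), keep)]
  p3 <- predictCombinatorial(reduced, q)
  expect_identical(p1$predicted, p3$predicted)
  expect_identical(p1$group_id, p3$group_id)
})

test_that("queries unrelated to every group come back unmatched", {
  model <- refModel()
  hex <- smilesMol("CCCCCC", "hexq")
  pr <- predictCombinatorial(model, hex)
  expect_false(pr$matched)
  expect_true(is.na(pr$predicted))
  expect_true(is.finite(pr$mean_tc))
})

test_that("model serialization round-trips bit-for-bit predictions", {
  model <- refModel()
  tf <- tempfile(fileext = ".json")
  writeCombinatorialModel(model, tf)
  back <- readCombinatorialModel(tf)
  expect_named(back@entries, names(model@entries))
  q <- heldOutDataset()$molecules[[1]]
  p1 <- predictCombinatorial(model, q)
  # two runs on the same serialized model agree bit for bit
  p2 <- predictCombinatorial(back, q)
  p3 <- predictCombinatorial(back, q)
  expect_identical(p2$predicted, p3$predicted)
  expect_identical(p1$group_id, p2$group_id)
  # and the round trip reproduces the in-memory model to within the
  # decimal serialization of coordinates
  expect_equal(p1$predicted, p2$predicted, tolerance = 1e-9)
})
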