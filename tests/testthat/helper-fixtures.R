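# Shared fixtures. Expensive objects (the reference synthetic dataset and
# the combinatorial model built on it) are constructed once per test run
# and memoised here.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

smilesMol <- function(smiles, id) combiphore:::molFromSmiles(smiles, id)

# Reference study conditions: 3 scaffold families x 20 members, noise
# 0.2, seed 42.
refDataset <- function() fixture("refDataset", function()
  generateDataset(syntheticSpec()))

refGrouped <- function() fixture("refGrouped", function()
  partitionByScaffold(refDataset()$molecules, minSize = 15L))

refModel <- function() fixture("refModel", function()
  suppressWarnings(buildCombinatorial(refDataset()$molecules,
                                      refGrouped())))

# Held-out compounds: identical structures, independent jitter/noise.
heldOutDataset <- function() fixture("heldOut", function()
  generateDataset(syntheticSpec(seed = 101L)))

# Map a truth group number to the partition's group id.
truthGroupToPartitionId <- function(grouped, g) {
  for (gg in grouped@groups)
    if (any(grepl(sprintf("^g%d_", g), gg$member_ids)))
      return(gg$group_id)
  NA_integer_
}

siteTypeString <- function(sites)
  paste(sort(vapply(sites, function(s) s@type, character(1))),
        collapse = "")

# A small QsarModel stub with given stats (for selection-order tests).
stubQsar <- function(r2, stability = 0.5, f = 10, p = 0.01) {
  grid <- new("GridSpec", origin = c(0, 0, 0), spacing = 1,
              extents = c(2L, 2L, 2L))
  new("QsarModel", grid = grid, bits = "0:0:0:H", coefficients = 1,
      intercept = 0, nFactors = 3L,
      stats = c(r2 = r2, sd = 0.1, f = f, p = p, stability = stability,
                q2_loo = 0.5),
      hypothesisRef = "stub")
}
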