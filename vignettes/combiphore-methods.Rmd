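---
title: "Combinatorial pharmacophore QSAR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial pharmacophore QSAR: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, what the
synthetic ground-truth generator does and does not emulate, and the
places where the design was genuinely open and a choice had to be made.

## The model

The method addresses inhibitor collections too structurally diverse for
one QSAR model. It has five stages, each exposed as package functions.

**Scaffold grouping.** The "core skeleton" of a compound is
operationalized as the canonical Bemis–Murcko framework: terminal atoms
are pruned until only rings and inter-ring linkers remain, atoms
multiply bonded to the framework (exocyclic carbonyls) are retained,
and the result is canonicalized to SMILES through OpenBabel. Groups are
equivalence classes under identical framework string; classes below
`minSize = 15` members are set aside as statistically insufficient, and
group ids are assigned by descending size with a lexicographic
tie-break so numbering is reproducible. Framework extraction is the
standard operationalization of a rule the source workflow left
unspecified; an exact-string match (rather than a similarity merge)
keeps the partition deterministic and auditable.

**Pharmacophore perception.** Six feature types: acceptor (A), donor
(D), hydrophobe (H), negative (N) and positive (P) ionizable groups,
aromatic ring (R). A/D/N/P are driven by an editable SMARTS pattern
file (`inst/extdata/feature_patterns.json`) matched through OpenBabel;
R comes from in-package aromatic ring perception (Kekulé-pattern based)
with the centroid as position and the plane normal as direction; H
sites are centroids of connected nonpolar fragments (aliphatic carbons
without polar neighbours, plus halogens). Acceptors and donors carry a
direction approximated as the unit vector away from the mean of the
bonded neighbours — a lone-pair/X–H proxy that avoids any force-field
dependency. Ring normals are sign-ambiguous, so directional scoring
uses |cos| for R and signed cosine for A/D.

**Common pharmacophore hypotheses.** For k = 4, 5, 6, all k-subsets of
each active's sites are encoded as a feature label plus a canonically
ordered inter-site distance vector (sites ordered by feature letter,
ties by each site's sorted distance profile). Vectors sharing a label
are binned by a recursive partition of distance space: cells start at
4 Å width and halve to a final width of 1 Å — implemented directly as
the final 1 Å lattice, which the halving schedule determines uniquely —
and each vector also registers to neighbour cells within 0.5 Å so that
arrangements straddling a cell boundary are not missed. The neighbour
expansion is capped at 256 cells per vector, nearest-boundary
dimensions first; for k = 4 (6 distance dimensions) the expansion is
exhaustive, for k = 6 (15 dimensions) the cap trades a small
boundary-miss risk for tractability. A cell containing all actives
yields a hypothesis; if no cell does, the threshold relaxes once to
`floor(2n/3) + 1` — the smallest count exceeding two-thirds. The
hypothesis takes its sites from the contributing active with the
highest pIC50 (the reference ligand); that selection rule was open, and
the most potent ligand is the natural representative of the
binding-competent geometry.

**Scoring and filtering.** Every active is rigidly aligned to each
hypothesis (type-respecting injective site mappings, optimal rotation
by singular-value decomposition of the cross-covariance matrix,
distance-consistency pruning, a 1e5 mapping guard). The survival score
sums three equally weighted components averaged over matched actives:
alignment `max(0, 1 - RMSD/1.2)`, the directional score on a [0,1]
cosine scale, and the shared/union van der Waals volume against the
reference ligand (1 Å voxel approximation). The component weights were
not recoverable from any published description ("specific weights"),
so they default to 1 and are exposed as arguments. Matches with
directional score ≤ 0.5 or inter-site distance RMSD ≥ 1.2 Å are
discarded before ranking — the published threshold "vector scores above
0.5 Å" mixes a score with a length unit, and is read here as a unitless
0.5 on the cosine scale. The top 10% of hypotheses by survival are
kept, clustered by complete linkage on distance-vector dissimilarity
(cut at 1 Å, the partition cell width), one top-survival representative
per cluster.

**Atom-based grid QSAR.** Aligned members are rasterized onto 1 Å
cubes. Each heavy atom is a van der Waals sphere (element radii from
`inst/extdata/vdw_radii.csv`) under one of six channels with precedence
N > P > D > W > H > X, where W (electron-withdrawing) covers acceptor
atoms and halogens and X is the catch-all. A bit (cube, channel) is set
when the sphere *intersects* the cube — geometric intersection rather
than centre-in-sphere, because "occupied" should be stable under
sub-cube shifts. Channels are kept separate per cube (one bit per
(cube, type) pair), the richer of the two readings the source left
ambiguous. Donor hydrogens are rasterized at 1.2 Å under channel D;
other hydrogens are implicit. Activities are regressed on the binary
matrix by PLS1 (NIPALS on centered, unscaled data) with 3 factors —
the documented over-fitting guard — and the per-bit regression
coefficients are exportable as a coefficient map (positive =
favourable). Statistics: R² (squared Pearson), SD = sqrt(SSE/(n−k−1))
and the F/p pair with k = 3 — the PLS factor count is used as the
effective model dimension, an interpretation the package documents
rather than hides; LOO Q² by explicit refits; and stability, for which
no formula was published, defined here as the mean correlation between
full-model and refit-model predictions over 10 seeded leave-25%-out
rounds. The PLS core is implemented in the package (the CRAN `pls`
solver is not among the supported dependencies) and is cross-checked
against `mixOmics::pls` in the test suite.

**Combination and dispatch.** Per group the best (hypothesis, model)
pair is chosen by lexicographic ranking R² → stability → F → p; the
published list of criteria is unordered, and this order puts fit before
robustness before significance. A query is fingerprinted (circular
functional-class fingerprint, diameter 4, 2048-bit hash space — the
same fingerprint backs the similarity dispatch and any novelty
analysis, one knob), assigned to the group with the highest mean
Tanimoto to the training members (ties to the lowest group id), and
predicted by exactly one model. Queries whose alignment fails are
reported unmatched rather than silently predicted; an optional fallback
flag tries the remaining groups in mean-Tc order.

**Validation and screening.** EF(φ) = (Hits_s/N_s)/(Hits_t/N_t) with
N_s = ceiling(φ·N_t) (the rounding rule was unspecified); unmatched
compounds rank last by default, with a flag to restrict to matched
compounds only. Screening: Lipinski rule-of-five filter (pass = at most
one violation of MW ≤ 500, logP ≤ 5, donors ≤ 5, acceptors ≤ 10; a
strict flag requires zero), conformer generation, dispatch +
prediction, drop unmatched and predictions ≤ 5.0, rank, truncate to the
top 100. Decoy assembly mirrors the DecoyFinder-style windows: MW ± 40,
logP ± 1, donors/acceptors ± 1, rotatable bonds ± 1, Tanimoto < 0.75 to
every active — all configurable; note that ligand-property-matched
decoys can bias ligand-based screens optimistically, which is why the
enrichment validation is read qualitatively.

## Conformers

Ensembles are generated by deterministic torsion driving (staggered
offsets of all rotatable bonds, seeded search order, steric-clash
rejection) from an embedded starting geometry, then pruned so retained
pairs differ by heavy-atom best-fit RMSD > 1.00 Å; candidates are
pruned in a canonical order so the retained set is independent of
enumeration order. Stereoisomer enumeration is capped at 32 as optional
preprocessing. This replaces a commercial conformer/force-field stack
with a generic "diverse low-strain ensemble" contract: no energies are
computed, and the ensemble makes no claim about Boltzmann weights.

## The synthetic ground truth

`generateDataset` defines the package's reference study conditions: 3
scaffold families × 20 members, a planted 4-point ARRR pharmacophore
(carbonyl acceptor + three ring centroids in a scalene arrangement, so
the site mapping is unambiguous), activity noise sd 0.2 pIC50, jitter
within 0.3 Å, decoy ratio 36:1, seed 42. Three families keep the whole
pipeline under a few minutes while preserving the multi-group
structure; noise 0.2 puts training R² in the high range typical of
well-fit atom-based models without making the fit trivial.

Families share the planted geometry but differ in framework (a
CH2/O/NH bridge), in ring composition (benzene/pyridine/pyrazine third
ring) and in a constant tag substituent, so scaffold partition and
similarity dispatch have real signal to work with. Members vary over a
3-slot substituent lattice; the activity is *exactly* linear in the
member's own occupancy bits: each slot's weight lives on cubes that
every jitter-displaced substituent sphere provably covers (an eroded
sphere support) and that no other atom can reach (an inflated-sphere
exclusion), so a member's slot contribution equals the nominal weight
and activities regenerate from stored truth to machine precision. Slot
weights (+0.7, −1.6, −1.4 around a 7.6 intercept) span the active
(> 7) and inactive (< 5) regimes. Every member is randomly rigidly
transformed, so the pipeline's alignment genuinely has to recover the
frame.

What the generator does **not** emulate: conformational flexibility of
real inhibitors (members are single-conformer), activity cliffs,
assay noise structure, tautomerism/ionization, and decoys that share
the pharmacophore but not the activity. Green tests therefore show the
pipeline is internally correct and recovers planted signal — not that
any particular real target will yield models of this quality.

## Numerical choices and degenerate inputs

- Tanimoto of two empty bit sets is defined as 0 (with a warning): the
  undefined case must not create spurious dispatch ties.
- IC50 → pIC50 assumes nM inputs (pIC50 = 9 − log10 IC50); a units
  argument overrides.
- Activity bands use strict inequalities: pIC50 exactly 7.0 is
  moderate, not active.
- Grid extents are frozen at training time; query atoms outside the
  grid contribute no bits (documented truncation).
- All-zero descriptors predict the model intercept.
- Zero matched actives gives survival 0 with a flag rather than NaN.
- Degenerate responses (all activities equal, zero observed variance)
  raise typed errors instead of producing vacuous models.
- Every stochastic step (splits, stability resampling, torsion search,
  generator jitter/noise/transforms) takes an explicit seed and
  restores the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run the reference
conditions: 3 × 20 training compounds, 60 held-out compounds per
evaluation seed, a 120-compound mixed set for the
combinatorial-vs-single comparison, 720 decoys for the enrichment
screen, and 10–20 seeded generator runs for recovery rates. These sizes
are the package's chosen reference scale: large enough that every
statistic is meaningful, small enough that a full rebuild is a
coffee-break computation.

## Known limitations

- Feature perception and atom typing are pattern-based approximations;
  the SMARTS file is deliberately editable because no fixed pattern set
  covers all chemistry.
- Site directions are geometric proxies, not orbital models.
- The rigid alignment does not explore torsions at scoring time;
  flexibility must come from the conformer ensemble.
- Survival-score weights, the tree-partition schedule and the
  stability formula are documented reconstructions of quantities whose
  published descriptions were incomplete; all are exposed as
  parameters.
- Fingerprint-similarity dispatch assumes the query resembles at least
  one training family; out-of-domain queries are flagged unmatched
  rather than extrapolated.
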