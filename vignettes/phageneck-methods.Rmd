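---
title: "Detecting and classifying the phage head-neck-tail module"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying the phage head-neck-tail module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageneck)
```

## The problem

More than 96% of isolated bacteriophages are tailed, double-stranded DNA
phages (*Caudovirales*). Their virions share a common assembly logic: an
icosahedral head built from a major capsid protein (MCP), packaged
through a portal channel by the large terminase (TermL), then sealed by
*head-completion* proteins — an adaptor (Ad) that binds the portal,
optionally supplemented by a head-closure protein (Hc) — to which a tail
is joined via a tail-completion protein (Tc). The Ad/Hc/Tc proteins form
the *head-to-tail connection* (the neck, together with the portal).
Long-tailed phages carry a major tail protein (MTP); contractile-tailed
ones in addition a sheath.

These neck proteins are short, fast-evolving and frequently
unannotated: pairwise identities between genuine homologs routinely fall
in the 10–20% range, far below what sequence–sequence or even
profile–sequence searches resolve. `phageneck` implements a detection
and classification strategy that copes with this divergence by combining
**profile–profile remote homology evidence** with **gene-context
constraints**, and then organizes the detected modules into neck
**Types** and, within a Type, **Clusters** of similar head-neck-tail
modules.

The package does not run the homology searches themselves. It consumes
their results through a `HomologyProvider` — either an all-vs-all TSV
hit table or parsed plain-text search reports — with probabilities and
identities on the percent scale. Profile construction (PSI-BLAST against
a reference database, secondary-structure enrichment) is upstream
preprocessing outside the package's scope.

## Detection: iterative expansion, then context-gated relaxation

Detection proceeds in the four steps of the pipeline's design:

1. **Seeds.** Each of the protein classes starts from functionally
   characterized reference proteins (`defaultSeedSet()`): SPP1
   gp15/gp16/gp17 for the Type 1 adaptor, head-closure and
   tail-completion classes (Ad1/Hc1/Tc1), T4 gp13/gp14/gp15 for Type 2,
   P22 gp4/gp10 for Type 3, phi29 gp11 for Type 4, lambda gpW for the
   adaptor-replacement class, SPP1 gp16.1 for Ne1, and
   structure-characterized seeds for MCP, TermL, Portal, MTP and Sheath.
2. **Strict expansion** (`iterativeExpand`, threshold 90%). Every
   protein hit at probability ≥ 90% is accepted and becomes a probe in
   turn, until a fixed point: the transitive closure of the thresholded
   hit graph. Membership depends only on the graph, so the result is
   independent of traversal order; the reported probability is the best
   over all probes that reached a protein. Head and tail classes use
   only this strict round.
3. **Distance learning** (`learnDistanceModel`). For each ordered pair
   of a Type's canonical neck classes, the signed inter-gene distance
   (rank difference; an adjacent downstream gene is at +1) is averaged
   over all genomes carrying both. The canonical Type 1 arrangement
   Ad1-Hc1-x-Tc1 gives means (1, 2, 3); consecutive Type 2 Ad2-Hc2-Tc2
   gives (1, 1, 2). The *tolerated* distance is mean + 2·sd.
4. **Relaxed, context-constrained search**
   (`constrainedRelaxedSearch`, threshold 70%). Expansion is repeated at
   70%, but a new candidate is only accepted if, for *every* already
   detected neck partner in the same phage, the observed distance has
   the canonical sign and magnitude ≤ tolerated. Candidates in phages
   without a strict anchor cannot be validated and are rejected.

Two special rules complete the neck picture. The **gpW rule**
(`detectGpW`): phages with Hc1 and Tc1 but no Ad1 may carry a gpW-family
adaptor replacement, accepted only at ≥ 95% probability and at the
canonical position 6–7 genes upstream of Hc1 and 9 (± 1) upstream of
Tc1. The **Ne1 rule** (`detectNe1`): the gp16.1 superfamily neck gene of
Type 1 phages is accepted at the strict threshold anywhere, or at the
relaxed threshold when it lies strictly between Hc1 and Tc1 — its
canonical Ad1-Hc1-Ne1-Tc1 slot.

Finally, `flagLowSupportCandidates` surfaces — but never auto-accepts —
proteins that could fill a phage's single missing neck class when their
homology profile was built from fewer than 5 sequences (too few for
reliable profile–profile comparison) and their position fits the
tolerated matrix. These flagged rows carry `round = "flagged"` and count
as no evidence anywhere downstream; accepting them is a human decision.

Throughout, a **single-copy control** is enforced: at most one accepted
protein per neck class per phage; violations keep the best candidate
and log a diagnostic, mirroring the observation that genuine necks
never contain duplicated Ad/Hc/Tc components.

## Typing and morphology

`assignNeckType` counts which Type-specific classes are present (gpW
occupies the Ad1 evidence slot). Types 1 and 2 require at least two
detected connection proteins; Types 3 and 4 require one. A lone Type 1
component yields `"type1_like"` — recognizable, but too sparse to place
in a cluster. Ne1 counts toward the completeness display of Type 1
(expected Ad1-Hc1-Ne1-Tc1, so a neck without Ne1 reports completeness
0.75) but not toward the two-protein minimum, because the minimum
predates Ne1's inclusion in the Type 1 description. When classes of
several Types co-occur the majority wins and ties are left unassigned
with a diagnostic; this precedence is a package choice — the situation
does not arise in canonical data — and is labeled as such.

`inferMorphology` deduces the family: Type 1 with a sheath →
*Myoviridae*, without → *Siphoviridae*; Type 2 → *Myoviridae*; Types 3
and 4 → *Podoviridae*. A sheath alongside a Type 3/4 neck contradicts
the short-tailed architecture; the call stays *Podoviridae* and the
contradiction is reported. Because no Type containing a tail-completion
class maps to *Podoviridae*, Tc evidence can never produce a
*Podoviridae* call — a property the test suite asserts.

## Similarity, WPGMA clustering and query placement

For two phages of the same Type, each module class detected in *both*
genomes contributes a component score

\[ S = P_{\mathrm{prob}} + 0.1 \cdot P_{\mathrm{ident}} \in [0, 110], \]

where \(P_{\mathrm{prob}}\) is the profile–profile probability and
\(P_{\mathrm{ident}}\) the sequence identity between the two phages'
proteins of that class (an absent hit contributes 0 + 0). The 0.1
weight makes identity a tie-breaker that only matters once the
probability saturates at 100%, where remote-homology probabilities stop
discriminating. The phage-pair similarity is the mean over shared
classes; classes detected in only one phage are ignored, and a pair
sharing no class is explicitly *missing* (NA), not zero.

`buildSimilarityMatrix` assembles the symmetric N×N matrix (diagonal
110) over the phages of a Type; `wpgmaTree` computes Euclidean
distances between matrix *rows* — each phage described by its vector of
similarities to all phages — and clusters them with WPGMA linkage
(weighted pair-group averaging; `stats::hclust`'s `"mcquitty"` method),
with merge heights reported as half the cluster distance so the
ultrametric, inversion-free property is explicit. Phages with missing
cells are pruned (sparsest first) before clustering, with a message.
`cutClusters` either cuts at a requested cluster count (how a reference
classification's labeled count is reproduced) or places the cut in the
largest gap between consecutive merge heights (the de novo heuristic,
stated in output). `assignCluster` places a query at the cluster with
the highest mean similarity to its members, breaking ties toward the
lowest cluster index with a warning.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `strictThreshold` | 90 | % probability | acceptance in iterative expansion |
| `relaxedThreshold` | 70 | % probability | context-gated second pass |
| `gpwThreshold` | 95 | % probability | gpW adaptor-replacement rule |
| tolerated distance | mean + 2·sd | gene ranks | positional gate of the relaxed pass |
| identity weight | 0.1 | — | contribution of identity to the component score |
| `components` | `"all"` | — | class subset scored (also `"portal"`, `"mcp-terml-portal"`) |

The thresholds are the method's published operating points and are not
meant to be tuned per run; `runConfig` validates `0 < relaxed < strict
≤ 100`, and reference bundles are stamped with a configuration hash so
a bundle built at one operating point cannot silently be queried at
another.

## Numerical choices and degenerate inputs

* Distances are **rank differences** (adjacent = +1), not counts of
  intervening genes — the convention under which the canonical Type 1
  arrangement yields means (1, 2, 3). Genomes are linear gene lists; no
  circular wrap-around.
* Standard deviations are sample (n−1) deviations; a single observation
  gives sd = 0 and tolerated = mean. Tolerated values stay real-valued
  — printed integer matrices arise from data, not from rounding.
* The context check is a conjunction over *all* detected partners, and
  enforces the canonical sign by default; `signed = FALSE` gives the
  magnitude-only reading for sensitivity analysis, since printed
  distances such as "6 to 7 from Hc1" are directionless.
* Symmetrization takes the max probability over the two directions and
  carries the identity of the winning direction; it is idempotent and
  optional (pass a raw provider for directed expansion).
* Duplicate (query, target) hits keep the maximum probability: expansion
  only cares about threshold crossings.
* Row-vector Euclidean distances include the diagonal by default
  (`includeDiagonal = FALSE` drops each phage's self column).
* Ties everywhere break deterministically: lexicographic class label in
  cross-class conflicts, lexicographic leaf order in clustering, lowest
  cluster index in placement.
* Degenerate inputs: empty FASTA and duplicate protein ids are errors;
  nucleotide-looking input warns; a probability outside [0, 100] is an
  error naming the row; an all-seeds-absent class is an error in
  `iterativeExpand` but corpus-level wrappers skip such classes with a
  warning, so a single-Type corpus still runs.

## What the synthetic universe emulates — and what it does not

`generateUniverse` builds ground-truthed corpora: Type-structured
genomes with canonical neck arrangements embedded among decoys, a
seed-rooted chain plus complete within-cluster hit graph per family
(probabilities U(92, 100)), cross-cluster probabilities U(20, 50) that
block-structure the similarity matrix, identity bands decaying with
cluster distance (U(25, 60) within a cluster, U(10, 25) across
clusters, U(2, 10) across Types — the 10–20% remote-homology regime),
and three adversarial features: *divergent* neck proteins whose hits
straddle the relaxed band (recoverable only via gene context),
threshold-straddling hits onto decoys at non-canonical positions (which
the context filter must reject), and *missing* neck proteins with
low-support profiles (which must be flagged, not accepted). Gap noise
between neck genes defaults to probability 0.1 per slot, giving
distance spreads comparable to the published tolerated matrices; the
canonical-statistics checks use gap noise 0.

The generator emulates the *hit-level* statistics of real corpora, not
sequence evolution: sequences are random amino-acid strings of
class-typical lengths (Ne1 drawn from 56–231 residues), and homology
flows entirely through the hit table. Passing tests therefore
demonstrate the correctness of the detection, context, typing and
clustering logic under the stated evidence regimes — they do not
demonstrate the sensitivity of any upstream homology search on real
proteins, which is outside the package.

Validation problem sizes (the package's own choices): universes of 28
phages across the four Types for end-to-end checks; 50 genomes per Type
for the canonical distance-convention checks; 200 Type 1 genomes for
parameter recovery (learned means within 2 SE of the generator truth);
planted-block recovery at K = 2..10 with 20 seeds each.

## Known limitations

* Exactly one protein per class per phage enters similarity scoring;
  genuinely duplicated head/tail genes are collapsed to the
  best-supported copy.
* The largest-gap cluster heuristic is undefined at N = 2 and weak when
  the corpus is a single homogeneous cluster; supplying a cluster count
  is preferred when one is known.
* The precedence between co-occurring Types is a package convention
  (majority, ties unassigned), labeled in diagnostics.
* Flagged low-support candidates are surfaced for review only; the
  package never auto-accepts them, so corpora whose necks are largely
  invisible to profile–profile comparison will legitimately report
  incomplete necks.
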