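# phageneck

Detection and classification of the **head-neck-tail module** in tailed
bacteriophages (*Caudovirales*), from ordered proteomes and
profile–profile remote-homology evidence.

## The problem

Tailed phages assemble their virions from a small set of structural
superfamilies: the major capsid protein (MCP), large terminase (TermL)
and portal on the head side; the major tail protein (MTP) and, in
contractile tails, a sheath; and — hardest to detect — the
**head-to-tail connection** proteins: the adaptor (Ad), head-closure
(Hc) and tail-completion (Tc) proteins that seal the packaged head and
join it to the tail. These neck proteins diverge so fast that genuine
homologs often share only 10–20% identity, which defeats ordinary
annotation and leaves the genes hypothetical. Yet their composition and
gene order are strongly conserved within a handful of architectures,
so detecting them both annotates the structural module and classifies
the phage.

## The method

For an ordered proteome (gene order = record order) and a homology
source giving per-pair probability *P* and identity *I* (percent):

1. **Iterative expansion.** From reference seeds (SPP1 gp15/gp16/gp17,
   T4 gp13/gp14/gp15, P22 gp4/gp10, phi29 gp11, lambda gpW, SPP1
   gp16.1, plus structure-based head/tail seeds), accept every protein
   with *P* ≥ 90% and re-use it as a probe until a fixed point — the
   transitive closure of the thresholded hit graph.
2. **Gene-context learning.** For each neck Type, the signed inter-gene
   distances between detected classes are averaged; the *tolerated*
   distance is mean + 2·sd (e.g. canonical Type 1 order Ad1-Hc1-x-Tc1
   gives means 1, 2, 3).
3. **Constrained relaxation.** Expansion is repeated at *P* ≥ 70%, but
   candidates are accepted only at positions consistent with the
   tolerated matrix against every detected partner. Special rules
   detect the lambda-like gpW adaptor replacement (*P* ≥ 95% at its
   canonical −6/−9 position) and the Ne1 neck gene (between Hc1 and
   Tc1). Low-support candidates are flagged for review, never
   auto-accepted.
4. **Typing and clustering.** The detected classes determine one of 4
   neck Types (Types 1/2 need ≥ 2 connection proteins, Types 3/4 ≥ 1)
   and, with sheath presence, the morphology (*Siphoviridae* /
   *Myoviridae* / *Podoviridae*). Within a Type, phages are compared by
   the mean over shared module components of the score
   *S = P + 0.1·I* ∈ [0, 110], and the resulting N×N matrix is
   clustered by WPGMA on Euclidean row distances into Clusters; query
   phages are placed at their most similar Cluster.

## Worked example

The package ships generators for ground-truthed fixtures. The six
classic reference phages, run end to end:

```r
library(phageneck)
wx  <- generateWorkedExamples()
ref <- runBuildReference(wx$genomes, wx$provider, runConfig())
ref$assignments[, c("phage_id", "neck_type", "morphology", "completeness")]
#>  phage_id neck_type   morphology completeness
#>      HK97         1 Siphoviridae         0.75
#>    lambda         1 Siphoviridae         0.75
#>       P22         3  Podoviridae         1.00
#>     phi29         4  Podoviridae         1.00
#>      SPP1         1 Siphoviridae         0.75
#>        T4         2   Myoviridae         1.00
```

Each phage gets its published neck Type (1, 1, 1, 2, 3, 4) and
morphology; the Type 1 phages report completeness 0.75 because the
display counts the Ne1 slot these minimal fixtures omit. Classifying
lambda as a query shows the gpW adaptor replacement accepted at its
canonical position:

```r
rep <- runClassify(wx$genomes$lambda, wx$provider, ref)
subset(rep$gene_map, !is.na(class))
#>  rank protein_id  class
#>     2 lambda_g02  TermL
#>     3 lambda_g03 Portal
#>     4 lambda_g04    MCP
#>     5 lambda_g05    gpW
#>    11 lambda_g11    Hc1
#>    14 lambda_g14    Tc1
#>    15 lambda_g15    MTP
```

`generateUniverse()` builds larger universes with planted clusters,
divergent and missing neck genes and positional decoys; see the
methods vignette (`vignettes/phageneck-methods.Rmd`) for what these
emulate. A thin command-line wrapper lives at
`inst/scripts/phageneck-cli.R` (`simulate`, `build-reference`,
`classify`; exit code 3 means no head-to-tail connection was found).

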