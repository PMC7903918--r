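# corenet

Causal regulatory-network prediction from signed interaction data.

When a microRNA (or any regulator) is knocked out, transcriptome
profiling yields a list of misregulated genes — but most of them are
not direct targets. `corenet` connects the perturbed regulator to the
observed misregulation through a compendium of curated, signed
regulatory interactions: it keeps only the links lying on directed
paths from the root regulator to the misregulated genes, propagates
misregulation signs upstream, prunes links inconsistent with the
inferred directions, and reports the union of all shortest
root-to-target paths as an explanatory network (SIF output, loadable
in Cytoscape).

The sign model is deliberately simple and fully testable. Every link
`u -> v` has a sign `s` (+1 activates, −1 represses) and every gene a
direction `d` (+1 up, −1 down). An unobserved gene `u` is scored

```
score(u) = Σ over signed links u -> v with known d(v) of  s · d(v)
```

and predicted `d(u) = sign(score(u))`; a zero score means *no
prediction*. A link is kept only when `d(u) · s = d(v)`. A knockout
root is fixed at −1 (the regulator is absent), so a repressive edge
out of the root predicts derepression of its target.

Around this core the package provides:

* **Interaction I/O** — TSV link tables with sign vocabulary mapping,
  deduplication with evidence merging, case-insensitive evidence-class
  filtering, one-to-one orthologue conversion, and derivation of
  miRNA→target repression edges from 3'UTR seed matches.
* **Seed scanning** — seed-complement heptamers from mature miRNA
  sequences (bases 2–8, reverse-complemented), overlap-counting match
  scans of UTR FASTA, and per-gene between-strain comparison.
* **Word-enrichment landscapes** — exact hypergeometric
  enrichment/depletion of every 7-mer over cumulative leading bins of
  a ranked gene list.
* **Network metrics** — degree and normalised directed betweenness.
* **Design statistics** — two-group normal-approximation power and
  Mendelian genotype-ratio summaries.
* **Seeded synthetic generators** — planted signed cascades, UTR sets
  with planted words, and ranked lists with bin-concentrated
  enrichment, so every stage is testable offline.

## Worked example

A miRNA knockout with two observed misregulated genes, explained
through a small curated link set:

```r
library(corenet)

links <- data.frame(
  source   = c("Mir96", "Mir96", "Hnf4a", "A",       "Trp53",    "A"),
  sign     = c(-1L,     -1L,     1L,      -1L,       -1L,        1L),
  target   = c("A",     "Hnf4a", "Grp",   "Slc26a5", "A",        "Grp"),
  evidence = c("seed-match", "seed-match", "literature",
               "reporter assay", "literature", "literature"))

observed <- c(Grp = 1L, Slc26a5 = -1L)   # up, down in the mutant

net <- buildCausalNetwork(links, observed, roots = "Mir96",
                          rootMode = "knockout")
show(net)
#> CausalNetwork: 5 genes, 5 links
#>   node status: observed=2, predicted=2, root=1

networkNodes(net)
#>      gene direction score    status
#> 1   Mir96        -1     0      root
#> 2       A         1     2 predicted
#> 3     Grp         1     0  observed
#> 4   Hnf4a        1     1 predicted
#> 5 Slc26a5       -1     0  observed
```

Reading the output: the knockout root `Mir96` is down; gene `A`
represses the observed-down `Slc26a5` and activates the observed-up
`Grp`, so both its signed out-edges vote +1 (score 2) and `A` is
predicted up — derepression, consistent with `Mir96 ⊣ A`. `Trp53`
regulates `A` but lies on no path from the root, so path restriction
removes it. `writeSif(net, "net")` writes the Cytoscape files, and

```r
centralityReport(net)
#>      gene degree betweenness
#> 1       A      3  0.12500000
#> 2     Grp      2  0.00000000
#> 3   Hnf4a      2  0.04166667
#> 4   Mir96      2  0.00000000
#> 5 Slc26a5      1  0.00000000
```

ranks `A` as the hub mediating most root-to-target paths. The
closed-form design statistics print their textbook values:

```r
100 * powerTwoGroupZ(delta = 7, sd1 = 2.5, n1 = 4)  # 97.7 (% power)
ratioSummary(43, 242)$percent                       # 17.8 (% homozygotes)
seedComplement("UUUGGCACUAGCACAUUUUUGCU")           # "GTGCCAA"
```

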