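---
title: "Predicting causal regulatory networks by sign propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting causal regulatory networks by sign propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corenet)
```

## The problem

A microRNA knockout changes the transcriptome of its tissue, but only a
handful of the misregulated genes are direct targets: the rest are
reached through cascades of transcription factors and signalling
intermediates. Given (i) a compendium of curated, signed regulatory
interactions (gene A activates/represses gene B), (ii) the list of genes
observed up- or downregulated in the mutant, and (iii) the identity of
the perturbed regulator(s), `corenet` asks which regulatory paths can
*explain* the observed misregulation, and what that implies for the
direction of every intermediate gene along the way.

The package builds the interaction compendium from flattened TSV tables
(with orthologue conversion and evidence filtering), adds
miRNA-to-target repression edges supported by seed matches in 3'UTRs,
propagates misregulation signs upstream, discards links inconsistent
with the inferred directions, and reports the union of shortest
root-to-target paths as the final causal network, in Cytoscape-loadable
SIF form.

## The sign-propagation model

All reasoning is in the sign algebra \{+1, −1\}. Each interaction
`u -> v` carries a sign `s` (+1 activation, −1 repression, 0 unknown),
and each gene has a direction `d` (+1 up, −1 down in mutant vs wild
type). A link is **consistent** when `d(u) · s = d(v)`: an activating
link wants equal directions, a repressive link opposite ones.

The pipeline has four stages, each only ever shrinking the graph:

1. **Path restriction** (`restrictToPaths`). Only nodes and edges lying
   on at least one directed path from a root regulator to an observed
   misregulated gene are retained — the intersection of the roots'
   descendants with the targets' ancestors. Targets with no upstream
   connection are reported as excluded rather than silently lost.
2. **Score propagation** (`propagateScores`). Observed genes keep their
   measured directions, immutably. The root's direction is fixed by the
   perturbation: a knockout root is *down* (−1), so a repressive edge
   out of the root predicts derepression of its target; an
   overexpressed root is up (+1). Every other gene `u` receives an
   integer score
   `score(u) = Σ s(u→v) · d(v)` over its signed out-edges whose
   downstream gene currently has a direction, and its predicted
   direction is `sign(score(u))`. A zero score — balanced evidence, or
   no signed informative out-edge — yields *no prediction*, which is an
   honest outcome, not an error. Updates are synchronous sweeps to a
   fixed point.
3. **Consistency pruning** (`pruneInconsistent`). Edges that are
   unsigned, touch a no-prediction gene, or contradict the direction
   algebra are removed.
4. **Shortest-path assembly** (`shortestPathNetwork`). For each target
   still reachable, *all* minimum-length root-to-target paths are kept
   (ties are never broken arbitrarily) and their union is the final
   network. With several roots, each root's own shortest paths are
   unioned. Targets disconnected by pruning are recorded as excluded
   with reason `"inconsistent"`.

The concrete scoring rule — integer sum of edge-sign times downstream
direction, with the sign of the sum as the prediction and zero meaning
no prediction — is this package's own formalisation of upstream sign
scoring; it is the simplest rule that produces iterative upstream
propagation, admits no-prediction outcomes, and supports a consistency
filter, and it is what all tests and guarantees here refer to.

Two properties make the model testable. It is **odd**: negating every
observed direction together with the root mode negates every prediction
and leaves the retained edge set unchanged. And on noise-free planted
cascades (below) it is **exact**: every internal gene with at least one
observed descendant recovers its planted direction and no edge is
pruned.

### Cycles and convergence

Real interaction compendia contain feedback loops. The synchronous
sweep either reaches a fixed point or is stopped at `maxIter` (default
100) sweeps; genes still changing at the cap are marked
`no_prediction` with a warning. A DAG converges in at most
`depth` sweeps, so the cap is only ever reached through genuinely
contradictory cycles.

### Hold-out validation

`validateAgainstStudy` grades the model against an independent
perturbation experiment: the known intermediate genes are removed from
the observed input, the network is rebuilt, and each held-out gene's
prediction is scored `correct`, `incorrect` or `no_prediction`. The
package exercises this harness on synthetic cascades where the truth is
planted; validating against a published study compendium only requires
its interaction and misregulation tables in the documented TSV formats.

## Seed matching

The seed region of a mature miRNA is bases 2–8; its reverse complement
in DNA alphabet (`seedComplement`) is the word whose occurrences in a
3'UTR mark candidate target sites. Matching is exact and
case-insensitive, `N` never matches, and **overlapping occurrences are
counted** — the standard motif-counting convention, and the one our
brute-force oracle implements. Multiple UTR records per gene are summed
(with the per-record breakdown retained): absent a principled isoform
choice, summation is the conservative superset. Between-strain
comparison (`compareStrains`) classifies each gene with a shared
identifier into exactly one of eight categories (same count, different
counts, matches in one strain only, absent in both, or missing UTR
sequence per strain); genes without a shared identifier must be dropped
first, since no cross-strain correspondence exists for them.

## The heptamer landscape

`wordLandscape` measures, for every word of length 7 (configurable),
its enrichment or depletion among the 3'UTRs of the most upregulated
genes. The universe is the multiset of **word positions** (tokens): a
UTR of length L contributes L − 6 overlapping windows. For cumulative
leading bins of the ranking (default step 500 genes) the bin's token
count `n`, the word's bin count `x` and its universe count `K` give
hypergeometric tails `P[X ≥ x]` (enrichment) and `P[X ≤ x]`
(depletion); the displayed score is `−log10` of the smaller tail,
signed positive for enrichment and negative for depletion. The final
bin is the whole universe, so every score there is exactly 0 — a useful
self-check. Tails are computed on the log scale, so scores stay finite
at any enrichment strength.

Raw p-values are reported; a Bonferroni guide level over all 4^7 words
at α = 0.05 is attached as an annotation attribute, not applied as a
filter. Composition-bias correction and word purging, as found in
dedicated word-enrichment tools, are deliberately not implemented:
within this package the landscape serves hypothesis display and
fixture recovery, and the exact hypergeometric identities
(`Σx = n` per bin; `P[X≥x] + P[X≤x] = 1 + P[X=x]`) are tested instead.
Ties in the input ranking are kept in input order.

## Network metrics

Degree counts incident edges (in + out); parallel opposite-direction
edges count separately and a self-loop counts once. Betweenness is
directed by default (regulation has a direction), normalised by
(n−1)(n−2) so values lie in [0, 1]; self-loops are excluded and graphs
with fewer than three nodes have no pairs to mediate, hence betweenness
0. Both agree with an exhaustive all-pairs shortest-path enumeration on
every small graph we throw at them.

## Design statistics

`powerTwoGroupZ` is the normal-approximation power of a two-sided
two-sample comparison with unequal group variances:

power = Φ( Δ / √(sd₁²/n₁ + sd₂²/n₂) − z₁₋α/₂ ).

It is monotone in effect and sample sizes, tends to α/2 as Δ → 0 and to
1 as Δ → ∞. It is an approximation: for very small groups an exact
noncentral-t calculation would be slightly more conservative, which is
out of scope here. `ratioSummary` summarises an observed genotype count
against a Mendelian expectation with the observed percentage and a
1-df goodness-of-fit chi-squared (no continuity correction), via
`stats::chisq.test`.

## Synthetic data: what it emulates and what it does not

The generators make every stage testable without any external download,
and their defaults are the conditions under which the package's
guarantees are stated.

* `simulateCascade` (default 200 genes, depth 6, activation and
  repression equally likely, 30% extra cross-level edges, all leaves
  observed, no noise) plants a rooted signed DAG whose true directions
  are generated top-down from a knockout root through a spanning tree;
  cross edges are added only where consistent with the planted
  directions. This makes noise-free recovery provably exact, so the
  recovery checks are sharp. `fractionObserved` samples the *leaf*
  genes exported as observed — internal genes are what propagation must
  reconstruct — and `noise` flips each exported direction
  independently. Unsigned edges are only generated if their probability
  is raised explicitly, because they are always removed by consistency
  pruning.
* `simulateUtrSet` draws uniform-random DNA of uniform-random length
  (default 50–300 nt) and can plant a word at a logged position per
  chosen gene, guaranteeing a minimum match count.
* `simulateRankedList` plants a word preferentially in the top fraction
  of a ranked list (planting probability 0.9 per top gene), giving a
  landscape whose peak must sit in the leading bins; with
  `topFraction = 1` the planting carries no positional signal and is
  the null case for calibration.

A single integer seed drives a separate named pseudo-random stream per
generator, so fixtures are byte-reproducible and adding a generator
never perturbs existing ones.

What the synthetic conditions do *not* emulate: scale-free topology and
hub structure of curated interaction compendia, correlated evidence
errors, nucleotide composition bias of real 3'UTRs, or dependence
between expression rank and UTR length. Passing the recovery and
calibration suites therefore demonstrates algorithmic correctness under
the stated model — not that predictions on a particular real compendium
will be accurate, which depends on that compendium's coverage and sign
quality.

## Problem sizes and numerical choices

The test and acceptance suites run at sizes chosen to make the checked
properties sharp while keeping the whole suite fast: 20 noise-free
cascades of 200 genes for recovery; 500 random digraphs of up to 8
nodes for oracle equivalence of betweenness and shortest-path
extraction (exhaustive enumeration above 8 nodes adds cost but no
discriminating power); 1,000 random UTRs for the match-counting oracle;
null calibrations of the landscape at 30-gene universes across tens of
seeded replicates. Hypergeometric tails use `stats::phyper` on the log
scale; graph reachability, shortest paths and centralities are
delegated to `igraph`; sequence handling to `Biostrings`.

Degenerate inputs are defined, not accidental: a UTR shorter than the
word counts 0 matches; a bin step larger than the gene list yields the
single full-universe bin with a warning; a single-node cascade is a
root with nothing observed; an interaction file with malformed rows
skips them with a warning and accounts for every input row in its
bookkeeping counters.

## Known limitations

* Sign propagation is purely qualitative: no magnitude weighting, no
  probabilistic scores, no distinction between strong and weak edges.
  A gene regulated in both directions by equally many informative edges
  gets no prediction, by design.
* The final network depends on the interaction compendium supplied;
  the package ships no curated compendium of its own.
* Word enrichment is exact-match only — no thermodynamics, no
  3'-supplementary pairing, no background correction.
* The power formula is a normal approximation; the chi-squared ratio
  test has 1 df and no continuity correction.
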