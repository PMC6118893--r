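---
title: "Classifying homeobox genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying homeobox genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

homeoclass implements the computational core of a homeobox gene survey:
finding homeodomains in assembled nucleotide scaffolds, typing them,
building a neighbor-joining phylogeny with bootstrap support, combining
support values from several phylogenetic analyses on one tree, turning
well-supported nodes into named clades reconciled against a persistent
nomenclature, and reconstructing minimum gene-family gain and loss on a
species cladogram. This vignette explains the models and the choices
behind them. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## The problem

Homeobox genes encode a ~60-amino-acid helix-turn-helix DNA-binding
domain (the homeodomain). TALE-class homeodomains carry a three-residue
loop extension between helices 1 and 2, for 63 residues in all.
Lineage-restricted homeobox radiations — most dramatically the spiralian
TALE expansion — are hard to annotate: members diverge quickly, duplicate
and disappear freely, and are routinely missed by searches seeded only
with canonical queries. The remedy exercised here is a *recursive* search:
every newly discovered homeodomain joins the query pool and the search
repeats until an iteration discovers nothing new (search saturation).

## The simulator defines the study conditions

Because the survey's real inputs are large external assemblies, the
package ships a generator that emulates their statistical structure with
full ground truth, so every downstream stage is testable end-to-end.

* **Gene families** arise as a birth–death process along a species tree
  (duplication bifurcates a gene lineage within an edge, loss prunes it).
  The default species tree has five taxa with tip-to-root depths of
  0.25–0.30 substitutions-per-site units, duplication rate 0.3 and loss
  rate 0.2 per gene per unit branch length — enough turnover to produce
  single-species expansions and patchy presence/absence without losing
  most families.
* **Sequences** evolve by independent-site substitution: along a branch of
  length $t$ each site is hit with probability $1 - e^{-rt}$ and redrawn
  uniformly from the 19 other residues, so the realised per-branch
  difference probability is exactly $1 - e^{-rt}$ (no rate heterogeneity;
  downstream tests only need controllable divergence). Family ancestors
  sit `family_divergence` = 0.2 expected substitutions per site from the
  shared ancestral profile and members evolve at rate 0.5; these two
  values were chosen together so that planted domains score far above the
  scan's acceptance threshold while families remain clearly distinct
  clades.
* **Architecture.** Half the families are TALE (the 3-aa insert is placed
  between positions 24 and 25 of the 60-aa frame, fixing one unambiguous
  column mapping for true alignments); half of those carry a second
  homeodomain descended from an internal tandem duplication of the family
  ancestor; half of the doubled families have the second domain
  *degraded*. A degraded remnant decays independently per gene at five
  times the substitution rate plus a uniform scramble of 10% of its
  positions, and is rejection-sampled into a fixed score band (75–140
  BLOSUM62 units against the ancestral profiles). The band implements the
  remnants' defining phenotype — recognizably homeodomain-derived but too
  decayed to pass for an intact domain — and keeps them above anything
  random sequence reaches (empirically ≤ 55 at desk-scale corpus sizes)
  and below the acceptance score. Without the band, unconstrained decay
  occasionally produces remnants that are either undetectable in
  principle or still intact-looking, which contradicts the generator's
  own intent.
* **Scaffolds.** Proteins (leader + domain(s) + linker/tail + optional
  conserved C-terminal motif) are reverse-translated with uniform codon
  choice and embedded between random flanks (300 nt each side); alternate
  scaffolds go on the reverse strand. The truth table records exact
  0-based half-open forward-strand coordinates, strand and frame.

What the generator does **not** emulate: codon structure and composition
bias, indels (other than the fixed TALE insert), introns (so split
homeoboxes never occur), sequencing error, and assembly artefacts.
Passing recovery tests therefore demonstrate correctness of the machinery
under the stated statistical conditions, not performance on real
assemblies.

## Homeodomain search

BLAST is replaced by exact Smith–Waterman local alignment (Rcpp): at desk
scale the heuristic buys nothing, and an exact scorer makes oracle testing
possible. Gaps are affine (`gap_open` 10 + `gap_extend` 1 per residue,
BLOSUM62), and tie-breaking is fully deterministic: within a cell diagonal
beats a gap-in-target beats a gap-in-query; among equal-score maxima the
smallest (target start, query start) wins.

The recursive scan aligns every pool query against every frame of every
target (six-frame translation for nucleotide targets), accepts
non-overlapping hits scoring at least `accept_score` (greedy by descending
score; a candidate whose *full domain window* overlaps an accepted hit by
more than 30 aa on the same frame is discarded — windows, not raw
alignment intervals, so a ragged partial alignment of an already-claimed
domain cannot survive as a phantom second domain), excises each accepted
domain (extending the local alignment by the query overhang), types it
against the 60-aa and 63-aa profiles (margin 5 matrix units, otherwise
`unresolved`), and adds it to the pool. Saturation = an iteration that
adds no new accepted hit. Two further safeguards matter in practice:

* a query never scores the locus it was excised from (self-matches would
  otherwise inflate any accepted locus to a near-maximal score);
* scores in `[degraded_floor, accept_score)` are reported as degraded
  remnants but never join the pool.

`accept_score` = 150 stands in for the expert's manual inspection of
candidate hits: comfortably above the empirical random-sequence ceiling
(~55) and below the scores of genuinely homologous domains at the study
conditions. `degraded_floor` defaults to 0.4 × `accept_score` = 60, low
enough to catch the remnant band with margin, still above random.
Both are configurable.

Read quantification counts a read when its best local alignment to a
transcript covers at least 90% of the read at an identity of at least
0.95; the identity boundary is inclusive, and the coverage rule is an
explicit addition (identity alone says nothing about how much of the read
aligned). Counts normalise per million library reads.

## Trees, supports, clades

Distances use pairwise deletion (manually edited homeodomain alignments
retain gappy rows; complete-column deletion would discard most sites),
with a `p` or Poisson-corrected model; the model tag travels with every
matrix because published NJ pipelines often leave it unstated. No gamma
rate correction is applied — in the original three-analysis design that
setting belongs to the (externally supplied) likelihood analyses.
Neighbor joining is canonical Saitou–Nei with two decisions: negative
branch lengths are clamped to zero with the deficit moved to the sister
edge (preserving the joined pair's path length), and Q-matrix ties break
toward the lexicographically smallest leaf ids so results are identical
across platforms. Bootstrapping resamples columns with replacement under
a seed; saturated Poisson distances within a replicate are capped at the
largest resolvable distance so every replicate completes. Outgroup
rooting bisects the outgroup's pendant edge.

Support values from different analyses (NJ bootstrap counts, ML bootstrap
percentages, Bayesian posteriors) are combined on one target tree by
*unrooted bipartition* equivalence — robust to the analyses' different
root conventions; where the two root-adjacent edges of a rooted tree
describe the same split, the labelled copy wins. A slot whose split is
missing from a source tree is explicitly absent and rendered `-` in the
`nj|ml|pp` node-label dialect; leaf-set mismatches are an error unless
pruning to the common set is requested, because silent pruning hides data
errors. Source polytomies match no resolved target edge.

Clade calling follows three disjunctive criteria — any normalised support
strictly above 70% (strictness configurable), reconstruction in all three
analyses, or explicit structural evidence such as a shared
two-homeodomain architecture — with justification recorded in that order
of precedence. Registry reconciliation matches calls to prior clades by
Jaccard overlap above 0.5 over previously classified members (majority
correspondence, deterministic; two disjoint prior clades cannot both
exceed 0.5), records additions (origin `N`) and reclassifications (prior
name kept), and names genuinely new clades with the next unused Roman
numeral — retired numerals are never reused. Paralogue letters are
assigned within (clade, species) by lexicographic sequence name; the
lettering carries no orthology claim, so any stable rule suffices, and
pre-existing letters are preserved with new members continuing the
series.

## Gain/loss reconstruction

Gene-family history on the species cladogram uses Dollo parsimony: one
gain per family, any number of subsequent losses. This matches the
figure-convention of marking exactly one origin per family — unordered
Fitch parsimony would permit multiple gains and contradict that
semantics. The minimum reconstruction places the gain at the MRCA of the
carriers (ties in total events resolve toward the root, i.e. the earliest
origin) and one loss per maximal carrier-free subtree below it; an
exhaustive single-gain enumeration over internal states serves as the
test oracle. Multi-species taxon groups collapse by the any-gain/all-loss
rule: a group is a carrier if any member carries the family, and a loss
is only marked when no member does. Taxa absent from the cladogram simply
carry no states.

## Conservation analyses

Identity masks dot out positions equal to a reference row; gaps are never
masked as identity. Sole-variant positions are columns where every
non-focal row carries one identical residue (no gaps among them) and the
focal row differs; columns with a focal gap or any background gap are
excluded — the homeodomain blocks this is used on are effectively
ungapped, so the rule is conservative. Motif scanning uses a log-odds
PSSM with +0.5 pseudocounts against a uniform background; the default
threshold of 60% of the profile's maximum achievable score holds the
empirical false-positive rate on background-composition random sequence
below 1% (checked at n = 10,000 in the test suite). The consensus scores
exactly the sum of column maxima.

The package also ships `synthetic_medial_hox_alignment()`, a constructed
stand-in for the published medial-Hox alignment in which a divergent Antp
orthologue is the sole variant at exactly six otherwise-invariant
homeodomain positions; it exists so that the sole-variant analysis can be
exercised end-to-end without the original supplementary alignment, and
its six planted positions are true by construction.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → scan → buildtree → reconcile →
callclades → gainloss, writing every stage's outputs before the next
starts and hashing them into a run manifest; two runs with the same
configuration are byte-identical. One global seed derives per-stage seeds
through a stable hash so stages are uncorrelated but individually
reproducible. Multiple-sequence alignment between excision and tree
building is deliberately an *external* hand-off (in real use: an aligner
plus manual editing); the simulator's true alignment fills that slot in
tests. There is no shell entry point: the exported functions are the
interface, and this vignette plus the README document the composition.

Problem sizes in the shipped tests — 3–10 families (roughly 15–70 genes)
per simulated data set, bootstrap replicates between 60 and 400 in tests
(the interactive default remains 1000), 200 alignment-oracle pairs, 100
additive trees, 500 Dollo matrices, 1000 dialect round trips — were
chosen so the whole suite exercises every stage at depths where the
oracles are exhaustive.

## Known limitations

* The intact/degraded boundary is a score threshold; remnants just below
  the detection floor are genuinely invisible, and remnant families decaying
  in concert could in principle pull one another over the acceptance
  score (the generator's remnant band makes both events rare at the study
  conditions, but real data offers no such guarantee).
* NJ is the only tree builder included; likelihood and Bayesian trees are
  accepted as Newick inputs, never computed.
* Bipartition-based support transfer cannot express support for clades
  that exist only under a particular rooting.
* Dollo parsimony is a minimum-event reconstruction, not a probabilistic
  model; it cannot express convergent gain.
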