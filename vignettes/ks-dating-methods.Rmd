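---
title: "Dating and classifying gene duplicates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and classifying gene duplicates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksdater)
```

This vignette explains the models behind `ksdater`, the parameters that
matter, and the design choices made where the underlying methods leave room
for interpretation. The running example is the kind of analysis done for
small plant transcription-factor families such as the celery BZR1
brassinosteroid-signaling regulators: a handful of paralogous pairs whose
ages, relative to the genome's polyploidization history, explain how the
family expanded.

## 1. The NG86 Ka/Ks estimator

For two in-frame, pre-aligned coding sequences the Nei–Gojobori (1986)
counting method proceeds codon by codon.

**Site counting.** Each sense codon has nine single-nucleotide neighbours.
A neighbour encoding the same amino acid contributes 1/3 to the codon's
synonymous site count $s$; every other neighbour — including those creating
a stop codon — contributes 1/3 to the nonsynonymous count $n$, so $s + n =
3$ exactly. Totals $S$ and $N$ are averaged over the two sequences, which
preserves $S + N = 3L$ for $L$ retained codons (asserted to $10^{-9}$ in
the tests).

**Difference counting.** Codons differing at $k$ positions are connected by
$k!$ single-step mutational pathways. Each step is synonymous or
nonsynonymous by amino-acid comparison; pathway step counts are averaged.
Pathways whose intermediates are stop codons are excluded from the average;
in the rare case that *every* pathway passes through a stop, all pathways
are used with stop-entering steps counted as nonsynonymous, so $S_d + N_d =
k$ always holds. Both conventions are recorded in the pipeline's run
metadata so downstream users can audit which variant produced a number.

**Correction.** The proportions $p_S = S_d/S$ and $p_N = N_d/N$ are
corrected for multiple hits with Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1 -
\tfrac{4}{3}p)$. The formula diverges at $p = 0.75$; at or beyond that
boundary the estimate is reported as `NaN` with a saturation flag rather
than clamped, and `NaN` propagates through dating and binning. This
matters because genuinely old pairs (Ks near 1.8 still convert to
meaningful ages under the rates below) must survive, while saturated pairs
must not masquerade as old ones.

**Preprocessing.** Codon columns containing a gap or ambiguity symbol in
either sequence are dropped whole (complete deletion at codon granularity),
which keeps the $S + N = 3L$ identity exact; a terminal stop codon column
is stripped; an internal stop in a retained column is an error, since it
indicates a frame problem the estimator cannot repair. Pairs shorter than
30 retained codons are flagged `too_short` with a warning — the estimator
still runs, but variance at that length makes single-pair conclusions
fragile. The implementation precomputes per-codon site counts and the
61 × 61 pathway-averaged difference table once per session, so per-pair
work is table lookup; the test suite checks it against an independent
brute-force enumerator written with a different translation route, on 200
random pairs, to $10^{-9}$.

Only the standard genetic code is supported. The families this package
targets are nuclear plant genes; alternative codes would silently change
$S$/$N$ and are rejected rather than half-supported.

## 2. Divergence dating

Ages follow the neutral molecular clock $T = K_s / (2r)$, reported in
millions of years. Two rates are built in: $r = 5.2 \times 10^{-9}$
substitutions·site⁻¹·year⁻¹ for comparisons within Apiaceae (celery,
coriander, carrot) and $r = 1.5 \times 10^{-8}$, the dicotyledon average,
for comparisons against distant outgroups such as Arabidopsis.
`select_rate()` applies the within-clade rate when both species share a
clade in the lineage map and the cross-clade rate otherwise; the map is
configuration, so users comparing, say, celery and grape must decide which
clock they believe and the choice is logged. Times are kept at full
precision internally and rounded to two decimals on output, the precision
at which such estimates are conventionally reported.

## 3. Assigning paralog pairs to polyploidization events

A polyploidization event leaves a mode in the genome-wide Ks distribution
of surviving duplicate pairs; that modal Ks is the event's *anchor*. The
built-in anchor sets are the published constants for five genomes —
γ = 1.2560 and α = 0.3659 shared across Apiaceae, the genome-specific ω
events (celery 0.7154, coriander 0.7194, carrot 0.7470), lettuce L1 =
0.6415, and ginseng G1 = 0.2884 / G2 = 0.0297. Anchors are *consumed as
configuration*: fitting mixture models to Ks distributions to discover
anchors is a different problem, deliberately out of scope.

Binning uses half-open intervals $(\text{lower}, \text{upper}]$. The
boundary convention is a genuine design choice — published descriptions
use strict inequalities and never state the boundary case — and equality is
resolved *to the anchor's own event*, because a pair born exactly at the
event has exactly the anchor Ks. Attribution is to the upper bounding
anchor: a pair inside (α, ω] arose after α but is read as created with ω.
A Ks above the oldest anchor predates all modelled events and gets no
attribution; a Ks at or below the youngest anchor is attributed to that
youngest event. When an anchor set has exactly three events the four
intervals also carry the conventional plot colours (red, green, orange,
blue from youngest to oldest); with other anchor counts no colour scheme is
implied. `NaN` Ks values (saturated pairs) are reported in a separate
`unassigned` table with a warning, never silently dropped.

## 4. Duplication-type classification

Each family gene receives exactly one of five labels with fixed precedence:
`wgd_segmental` (appears in any collinear pair) beats `tandem` (a homolog
at adjacent gene rank on the same chromosome) beats `proximal` (a homolog
within the rank window) beats `dispersed` (any other homolog) beats
`singleton`. The precedence itself is not stated by the published
classifiers' descriptions; this order mirrors the MCScanX
`duplicate_gene_classifier`, whose outputs the field treats as the
reference. Two further choices:

* **Rank is genome-wide.** Gene order is computed over *all* genes on a
  chromosome, not just family members; family-only ranks would make distant
  family genes look adjacent and inflate tandem calls.
* **`proximal_window` defaults to 10 gene ranks.** Published analyses give
  no window; order-10 is the MCScanX-style default. The value is
  configurable, carried in the result's attributes, and written to run
  metadata.

Collinear pairs are an input (from MCScanX or equivalent), not computed:
synteny-block detection is a separate dynamic-programming problem and the
classification is agnostic to where the blocks came from.

## 5. Duplication–loss reconciliation

`count_duplications_losses()` performs parsimony LCA reconciliation with
unit costs. Every gene-tree node is mapped to the last common ancestor of
its descendants' species; a node is a duplication iff it maps to the same
species node as at least one child. Losses follow the path-length rule:
for a gene-tree edge whose endpoints map $d$ species-tree edges apart, the
surviving copy dropped a sibling at each species node it entered —
$d - 1$ losses below a speciation node, $d$ below a duplication node — and
each loss is attributed to the species branch where the copy disappeared.

Non-binary trees are rejected rather than resolved: multifurcation
resolution changes the counts and no resolution policy is obviously right,
so the choice is left to the user's tree-preparation step. Bootstrap-aware
rearrangement of weakly supported edges (as performed by Notung) is
likewise out of scope; counts from this module are pure parsimony on the
input topology.

## 6. What the simulators model — and what they do not

**Codon pairs** (`simulate_codon_pair()`). The ancestor is uniform over
the 61 sense codons and two lineages evolve independently by
accept/reject: proposals uniform over sites and alternative bases, stop
proposals rejected, synonymous proposals always accepted, nonsynonymous
accepted with probability ω. Divergence is controlled by *counting
realized accepted synonymous events* until they reach $K_s/2$ per
NG86-counted ancestral synonymous site, rather than by a rate × time
parameterization — this gives exact ground-truth event counts without
solving for expected substitution numbers under rejection sampling. The
NG86 estimate on such a pair differs from the target only through
multiple-hit effects, which is why the recovery criterion is a 15% band on
the mean over 200 pairs of 300 codons rather than exactness: at the study
condition (true Ks 0.3, ω 0.2) the estimator lands within a few percent.
Not modelled: codon-usage bias, indels, rate heterogeneity across sites —
so passing recovery tests demonstrates correctness of the counting
machinery, not robustness to those real-data features.

**Genomes** (`simulate_genome()`). Chromosomes carry evenly spaced genes;
tandem arrays, proximal pairs, collinear blocks and dispersed pairs are
planted in *disjoint* rank slots, and homology exists only where planted.
That disjointness is what makes exact label recovery the correct
expectation; real genomes, where one gene can carry several kinds of
evidence, are precisely why the classifier has a precedence order. The
generator's contribution is ground truth, not realism: gene density, array
sizes and block lengths are arbitrary but recorded in the spec.

**Gene trees** (`simulate_gene_tree()`). The gene tree grows top-down
along the species tree; a duplication splits one lineage on a branch, a
loss removes one. Not every event history is recoverable by parsimony —
a duplication erased by a same-branch loss, an entire clade deleted by
several leaf losses, or losses above the surviving root all collapse to
cheaper explanations. Truth is therefore reported as the events that
remain identifiable in the realized tree (surviving duplication nodes,
applied losses), and recovery tests sample *identifiable* scenarios:
duplications on internal branches, losses at leaves that are neither
mutual siblings nor, when emptied, children of the root. The congruent
no-event case — zero duplications, zero losses, the pattern expected for a
family conserved between two recently diverged species — is asserted
separately.

## 7. Problem sizes and numerical choices

The validation suite uses 200 random 30-codon pairs for the
oracle-equivalence check, 200 simulated 300-codon pairs for parameter
recovery, and 50 seeded replicates each for classifier and reconciliation
recovery; these sizes put Monte-Carlo error well inside the asserted bands
while keeping a full run in tens of seconds. All tolerances are stated in
the tests themselves: $10^{-9}$ for algebraic identities and oracle
equivalence, 15% relative on mean Ks recovery, exactness for discrete
labels and counts. Output floats are written with four decimals (the
precision at which Ks values like 0.6081 are conventionally printed), with
`NA` for undefined values; divergence times print at two decimals.

## 8. Known limitations

* NG86 ignores transition/transversion bias and codon frequencies;
  maximum-likelihood codon models typically give slightly higher Ks for
  diverged pairs. For event *binning* this rarely matters (anchors and
  pair Ks shift together when estimated by the same method), but absolute
  ages inherit both the estimator's and the clock's biases.
* The molecular clock's rates are assumptions; the two built-in rates can
  differ threefold, and the package intentionally refuses to guess a rate
  for unmapped species pairs.
* Anchors are treated as exact constants; uncertainty in the anchor fits is
  not propagated into interval assignment.
* Reconciliation is parsimony with unit costs on the given topology;
  gene-tree estimation error shows up directly as spurious duplications
  and losses.
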