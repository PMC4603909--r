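---
title: "Methods: comparative analysis of two-component system gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of two-component system gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcsevo)
```

## The problem

Two-component systems (TCSs) — histidine kinases (HKs), response
regulators (RRs), hybrid kinases and phosphotransfer proteins (PPs) —
are the main signalling gene families of prokaryotes. Comparing the TCS
inventories of related genomes lets one infer which evolutionary events
(gene gain/loss, duplication, horizontal transfer, domain gain/loss,
rearrangement) shaped them, but every inference is conditional on how
related the compared genomes are: the same method applied to a
within-genus pair and a cross-order pair yields very different apparent
event frequencies. `tcsevo` implements the whole inference chain —
classification, gene-organisation analysis, orthology clustering, 16S
distance phylogenetics, event inference — together with a simulator
that plants known events, so the chain can be validated end to end
against ground truth rather than anecdote.

Domain prediction is deliberately out of scope: the package consumes
per-protein domain hits (`receiver`, `transmitter`, `phosphoacceptor`,
`input`, `output`, `TM`) produced by any annotation pipeline, plus a
gene-order table and protein sequences (an "annotation bundle").

## Classification and focus model

A protein's class is a total function of its domain counts: hybrid HK
(≥1 T and ≥1 R), HK (≥1 T), RR (≥1 R), PP (phosphoacceptor only), NONE
otherwise. Architectures are written N→C over `{R, T, H}`; a transmitter
is the kinase core (phosphoacceptor + ATPase region). Because input data
may carry the core pre-merged or as split hits,
`transmitter_from_parts()` merges a phosphoacceptor followed within 200
residues by an ATPase-flavoured `input` hit into one `T`; an isolated
phosphoacceptor stays `H`. The 200-residue gap is generous on purpose —
kinase cores are contiguous in practice — and is configurable.

Foci group co-oriented TCS genes: a focus is a maximal same-strand run
in which consecutive TCS genes are separated by at most one non-TCS
gene. Categories:

* **orphan** — single gene with exactly one TCS domain (auxiliary
  input/output domains do not disqualify it);
* **paired** — the focus's TCS-domain multiset is exactly {one T, one
  R}: a lone hybrid (`RT`/`TR`) or an HK/RR pair (`T,R`/`R,T`), i.e.
  one complete system;
* **complex** — anything else;
* **intricate** (orthogonal flag) — ≥2 R and ≥2 T in one protein or
  focus.

Decisions taken where the method description was open:

* *Unidirectionality* is read strictly as same-strand; adjacent TCS
  genes on opposite strands start separate foci. Divergently or
  convergently transcribed pairs are genuinely ambiguous; the strict
  reading is deterministic and configurable.
* Intervening genes are counted irrespective of their own strand.
* A contig end satisfies the "two non-TCS genes on each side" flank
  condition, so draft genomes are not biased toward complex calls at
  contig boundaries.
* The orphan rule is implemented through the focus machinery (a
  single-gene, single-domain focus); under the construction above it
  coincides with the distance phrasing ("more than two genes from
  another TCS gene").
* Minus-strand focus notation follows transcription: member order is
  reversed, while within-protein domain order is already N→C.

Per-genome statistics use gene-weighted organisation percentages (the
fraction of TCS genes in foci of each category), one-decimal rounding
half away from zero, and all HK-type proteins (non-hybrid + hybrid) as
the denominator for both the hybrid and TM percentages. Incomplete
genomes report organisation percentages and intricate counts as NA, and
cohort means skip NA entries. The shipped published summary table
(`myxo_table2()`) reproduces under these conventions except for three
cells that are internally inconsistent in the printed source (two
hybrid percentages and one row total), which are documented and
excluded from assertions.

## Similarity and orthology clustering

Similarity between proteins is the identity fraction of a global
alignment, divided by the *shorter* sequence's length — the semantics
of greedy incremental clustering tools, and robust to domain gains,
truncations and fusions because the shared core still scores ~1.
Scoring is match +2 / mismatch −1 with affine gaps (a gap of length L
costs 10 + L); since only identities are counted, the substitution
matrix beyond match/mismatch is irrelevant. To make the statistic
implementation-independent, the aligner maximises the pair
(score, identities) lexicographically: among all optimal-score
alignments the identity count reported is the maximal one, so no
traceback tie-break can change the result. The test suite checks the
C++ implementation against an independently written pure-R dynamic
program. Under this scoring, unrelated random proteins score ≈ 0.12
(max ≈ 0.16 over repeated draws), comfortably below the permissive
cut-off.

Clustering is greedy and incremental: proteins sorted by length
descending (ties: id ascending) either join the first representative
they match at ≥ cut-off or found a new cluster. Two tiers are used — a
permissive 30 % pass to capture divergent orthologues, then an
automated curation step: any low-tier cluster in which some genome
contributes ≥2 members (a paralogue agglomeration) is replaced by the
high-confidence sub-clusters obtained by re-running the greedy pass
*within* that cluster at 90 %. Running the strict pass inside the
permissive clusters (rather than globally) makes the emitted partition
a refinement of the low-tier partition by construction — global greedy
passes at two cut-offs are not guaranteed to nest. Clusters are flagged
(`SIZE_DIFF` >100 aa span, `ARCH_DIFF`, `FAMILY_DIFF`, `ORG_DIFF`,
`MULTIPLICITY`) but only multiplicity triggers splitting, mirroring the
manual curation it automates. Reciprocal best hits (unique mutual
maxima; ties excluded) provide an independent check of 1:1 pairs.

## Distances, trees, bands

16S distances are uncorrected p-distances (substitutions per site) on
gap-free columns; `N` is excluded pairwise from numerator and
denominator. A Jukes-Cantor-style correction was considered and
rejected: the distances of interest here are small (≤ ~0.2) and the
banding is rank-based, so the correction would not change any
assignment. Trees are neighbour-joining (via \pkg{ape}, the standard
implementation) with negative branch-length estimates clamped to zero.
Bootstrap support resamples alignment columns with replacement,
rebuilds the NJ tree, and reports the percentage of replicates
containing each internal split of the point tree; zero-length internal
edges of the point tree are collapsed first, so an alignment of
identical sequences reports no splits rather than arbitrary ones.

Pairwise distances are discretised into k bands by placing the k−1
boundaries at the k−1 largest gaps of the sorted distance sequence —
a reconstruction of the visual band structure seen in rank-ordered
distance plots, since no numeric boundaries are published. For k = 4
the bands are labelled genus < family < sub-order < order; the labels
are descriptive only. The decay of orthologue recovery with distance is
fitted as y = a·exp(−b·d) by least squares on log y, with the RMS
log-space residual reported.

## Event inference

All events are defined on clusters restricted to a genome pair:
singletons (cluster lacking the other genome), duplications (exactly
one genome with ≥2 members, detail `local` if the copies' minimum rank
gap ≤ 5), organisation / architecture / family / size (>100 aa) changes
and pseudogene mixes per multi-member cluster, and HGT candidates —
singletons whose best non-self hit in a labelled reference set carries
a clade label outside the focal clade (ties spanning inside and outside
are conservatively not flagged). Gain versus loss is deliberately not
polarised from two genomes.

Synteny dot-plots place one point per 1:1 orthologue pair at its
gene-order ranks. Collinear runs are extracted greedily over points
sorted by the first genome's rank: a run continues while both rank
steps are ≤ 25 and the second genome's step keeps the run's +1/−1
direction. Points in no run of ≥ 3 pairs are relocations. A pure
diagonal, or a diagonal broken by one contiguous inversion, yields no
relocation calls; the inversion appears as a single anti-diagonal
segment.

Frequency tables report, per event type, the percentage of clusters
affected. Change-type events use multi-member clusters as denominator;
singleton-type events (SINGLETON, HGT) use all clusters, since a
singleton is by construction its own cluster — keeping every numerator
within its denominator.

## The simulator: a stated world

`sim_config()` describes an ancestral genome (140 background genes, 16
TCS foci mixed 35/35/22/8 % orphan/paired/complex/intricate, echoing
published organisation percentages at desk scale) evolved along a
Newick tree whose branch lengths are 16S substitutions per site.
Proteins are random sequences of realistic composition assembled from
domain blocks (receiver 115 aa, transmitter 210 aa, phosphoacceptor 95
aa, output 105 aa, input 85 aa, TM 20 aa) so that every domain edit can
be bookkept exactly; ground truth must be exact, which rules out
sampling real proteomes.

Event rates are per target (gene, focus, or genome for HGT) per unit
branch length; expected counts are rate × branch length × targets, and
every applied event is appended to the truth log. The defaults state a
within-genus world (pairwise 16S distance 0.016) calibrated a priori to
the reported within-genus event frequencies: gene/focus losses such
that ~10 % of genes are gained or lost per pair, duplications ≪1 %,
horizontal insertions a minority of singletons, small indels and
frameshifts at the ~1 % level. Protein sequences diverge at 3× the 16S
rate — consistent with the observation that ~90 % of within-genus
orthologues remain recoverable — with optional gamma rate heterogeneity
across genes (shape 1.5 in the distance-regime experiments) so that
orthologue detectability decays smoothly rather than as a step
function. The four distance regimes (0.016 / 0.05 / 0.10 / 0.19) are
read off the centres of the four observed 16S distance bands.

Simulator invariants the suite enforces: determinism given (config,
seed); truth-log conservation (tip TCS count = ancestor − losses +
duplications + insertions along the root-to-tip path); planted focus
mixes classify back to their categories. To keep the conservation
arithmetic exact, a domain loss never removes a gene's last core
domain (total functional loss is modelled as gene loss), and a
frameshift truncates downstream of the first core domain — which also
reproduces the observed coupling between frameshifts, family changes
and pseudogene formation. HGT insertions draw from a separately seeded
foreign pool that also populates the labelled reference set
(`other-order`), alongside mildly diverged copies of the ancestral
proteins labelled with the focal clade — the information a database
search would supply.

The truth-side oracle (`truth_expected_events()`) derives the events a
*perfect* detector should report from the true orthology map and the
realised tip annotations, using the same definitions as the detectors
but keyed on true groups rather than inferred clusters. Precision and
recall against it therefore measure exactly the fidelity of the
clustering-based inference chain.

**What the simulator does not emulate** — and hence what a green test
does not establish: codon-level evolution and realistic indel length
spectra; back-substitution saturation models; gene gain balancing loss
over long timescales (at order-level distances simulated gene sets
shrink, unlike real ones); paralogous families with correlated
sequences (ancestral proteins are mutually random, making clustering
easier than for, say, an expanded NtrC family); multi-contig drafts.
Green acceptance tests establish that the inference chain is correct
under its stated assumptions, not that those assumptions capture every
difficulty of real genomes.

## Acceptance criteria and scale

The acceptance tests (one `test_that()` per criterion) cover: exact
reproduction of the published cohort summary row and the internally
consistent derived percentages; brute-force rule-table equality for
protein and focus classification; DP-oracle equality for similarity
(200 random pairs) and the refinement property of two-tier clustering
(100 random inputs); NJ additivity to 1e−9 on 4–8 taxa, ≥95 %
bootstrap support of the true split in a two-clade simulation (500
columns, 200 replicates), and planted band recovery; pooled precision
and recall ≥0.95 for singleton/duplication/HGT/organisation events over
20 within-genus replicates, with exact recovery in noiseless
deletion-only runs; monotone decay of orthology across the four
regimes with exact exponential-fit recovery on noiseless points; and
the inversion/relocation dot-plot patterns. Replicate counts (20
simulated pairs, 200 bootstrap replicates, 120 Poisson-moment
replicates) keep the full suite within a few minutes on one CPU while
leaving the stochastic assertions ~3 standard errors of slack.
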