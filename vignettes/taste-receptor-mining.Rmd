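---
title: "Mining and evolutionary analysis of taste receptor repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and evolutionary analysis of taste receptor repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tastemine)
```

# The problem

Vertebrate taste perception rests on two families of G-protein-coupled
receptors: the three Tas1r genes, whose Tas1r1–Tas1r3 heterodimer senses
umami and Tas1r2–Tas1r3 heterodimer senses sweet, and the Tas2r bitter
receptors, an intronless family of roughly 900 bp genes whose repertoire
size varies enormously across species. Comparative questions — which
species lost which modality, where duplications and losses happened, how
strongly purifying selection acts — all hinge on one upstream task:
reliably enumerating every intact gene, pseudogene and fragment of the
family in a set of genome assemblies.

`tastemine` implements that workflow as composable stages, and couples it
to a synthetic-data module that plants genes with known coordinates,
categories and disruptions, so that every stage is validated against
ground truth rather than by eyeball.

# Repertoire mining

## Translated search

Protein queries are compared against all six reading frames of every
contig. Matching is seeded on exact amino-acid words (default length 4)
and extended without gaps under an X-drop rule (default 40) with BLOSUM62
scoring. A hit is kept when its raw score reaches `min_score` (60) *and*
its score per aligned residue reaches `min_score_per_res` (1.5). These two
thresholds are the deterministic stand-in for an e-value cutoff: an
e-value cannot be reproduced exactly without replicating an external
aligner's statistics, so the nominal threshold (1e-10) is carried only as
configuration metadata, and the score thresholds are set so that
same-family matches pass while seed hits in random sequence, whose
ungapped extensions rarely exceed a score of ~35, fail.

Three post-processing rules shape hits into candidate loci:

* hits spanning **< 100 nt** of genome are discarded (the boundary is read
  strictly, so a 100 nt hit survives);
* overlapping hits on one contig and strand are transitively unioned into
  maximal disjoint loci — half-open semantics, so abutting hits stay
  separate; hits in *different frames* separated by at most
  `frameshift_gap` (50 nt) are additionally fused, because a frameshifted
  pseudogene necessarily presents as split-frame hits;
* each locus is extended by `flank` (500 nt) on both sides, clipped at the
  contig bounds, so that start/stop codons just outside the aligned region
  are recovered.

Interval union is delegated to `IRanges::reduce()` and is checked in the
test suite against a brute-force coverage-vector oracle on 500 random
intervals.

## Gene models and classification

Within each (strand-oriented) locus, ORF-like candidates are enumerated in
all three frames: complete ORFs (ATG to stop), an open-ended head (locus
start to first stop) and an open-ended tail (last ATG to locus end). The
candidate maximising local alignment score against the locus's best query
is retained; since the maximal ORF can begin at a chance upstream in-frame
ATG in the flank, the start is trimmed to the methionine the guide
alignment extrapolates to. Loci scoring below `floor_score` (60) are
dropped as spurious.

Disruption detection re-aligns the guide against the three frame
translations iteratively (masking found segments so several segments per
frame can surface), chains the segments along the guide, and interprets
the chain: an in-frame stop before codon `guide_length − 5` is a premature
stop; a frame transition between chained segments is a frameshift whose
indel length mod 3 follows from the frame difference. Two numerical
tolerances matter here. First, chained segments may overlap by up to
min(60 nt, 30%) at their boundaries — local alignments slop over
breakpoints by a few residues. Second, a strong (score ≥ 60)
different-frame segment *nested inside* a chained segment is interpreted
as a bridged double frameshift (net in-frame indels, e.g. a 1 nt plus a
2 nt deletion): the aligner spans the out-of-frame stretch as mismatches,
and the nested segment in the true local frame is the only evidence that
the region is frameshifted.

Classification then follows fixed rules with a deliberate precedence:

| category | rule |
|---|---|
| `INTACT` | > 270 aa, start + stop, no disruptions, ≥ 7 TM segments |
| `PSEUDO` | any disruption; or complete ORF failing the 7-TM screen |
| `PARTIAL` | start or stop missing *and* the truncation is at a contig edge |
| `SHORT` | clean complete ORF ≤ 270 aa (reported, never counted intact) |

Disruption evidence outranks truncation: a fragment carrying a frameshift
is a pseudogene, because a disruption is positive evidence of
non-functionality while a truncation is only missing evidence. The 270 aa
boundary is read strictly (a 270 aa ORF is `SHORT`); the transmembrane
screen — Kyte–Doolittle hydropathy in 19-residue windows, threshold 1.6,
above-threshold runs separated by ≥ 3 windows counted as segments — is
applied to complete ORFs only, since fragments cannot be screened fairly.
A truncation *not* at a contig edge falls through to `PSEUDO`: the rules
make the categories mutually exclusive and exhaustive over retained loci.
Partial fragments of one species are grouped by their aligned guide
intervals: overlapping fragments must be distinct loci, disjoint
complementary fragments are fused into one inferred locus. Finally, models
can be checked by reciprocal best hit against a labelled reference panel
(with vomeronasal-receptor-like decoys, the nearest GPCR relatives) and
named `Xxxx_FamN` — first two letters of genus plus first two of epithet,
numbered in genomic order.

# Synteny-based absence calls

Failure to find a gene never proves loss: the locus may simply be missing
from the assembly. A family is called `ABSENT` only when both conserved
flanking markers lie on the same contig within `max_span` (default 1 Mb —
the literature never quantifies "adjacent", so the default is deliberately
conservative and configurable) with no target hit between them. Since the
evidence that a same-contig marker pair proves loss rather than merely
suggesting it is genuinely ambiguous, both a `strict` mode (the pair must
fall within `max_span`) and a `permissive` mode (same contig suffices) are
exposed. Anything less — markers missing or split across contigs —
is `UNDETERMINED`. Marker positions are consumed from annotations
(GFF3/TSV) rather than re-searched: finding the markers is outside the
pipeline's remit.

# Reconciliation and trajectories

Duplication/loss histories come from the LCA (last-common-ancestor)
mapping of a rooted gene tree into a rooted binary species tree: a gene
node is a duplication exactly when its mapping coincides with a child's
mapping; losses are counted along the species-tree path below each gene
edge (one fewer for speciation nodes) and charged to the branch where the
lineage disappeared; duplications are charged to the branch above their
mapped node. The LCA mapping minimises duplications and losses
simultaneously; the test suite verifies the counts against an exhaustive
dynamic program over *every* embedding for 200 random gene/species tree
pairs. Unrooted gene trees (the usual output of ML inference) are rooted
by evaluating every branch and keeping the rooting minimising D + L (ties:
fewer duplications, then fewer losses, then branch order). Non-binary
trees are rejected with a clear error rather than silently resolved, and
no rearrangement of weakly supported edges is attempted — the input
topology is reconciled as given, because any rearrangement threshold would
be arbitrary here. Branch lengths are ignored; only topology informs the
counts.

Per-branch events summed over families propagate into ancestral
repertoire counts from the root; the bookkeeping identity
`child = parent + gains − losses` is asserted on every branch, and
propagated leaf counts are checked against observed per-species counts
when supplied (a mismatch errors, naming the branch). A family whose gene
root maps below the species root contributes an origination gain on the
branch above its mapping, which keeps the identity global.

# Selection

Pairwise dN/dS follows the classic counting method: per-codon
synonymous/nonsynonymous site fractions with changes-to-stop excluded from
the denominator (so S + N = 3 per codon), site counts averaged over the
two sequences, difference counts averaged uniformly over all shortest
mutational pathways with stop-traversing pathways excluded, Jukes–Cantor
correction d = −(3/4)·log(1 − 4p/3) (undefined at p ≥ 3/4, flagged), and
ω = dN/dS flagged undefined when dS = 0. Gapped or ambiguous codons are
dropped pairwise. The per-codon site counts are verified in the tests by
exhaustive enumeration over all 61 sense codons, and the pathway
arithmetic against hand-enumerated cases (for TTT vs TTA the single
pathway gives Nd = 1, and averaging sites over both codons gives
pN = 1/2.5 = 0.4 — the Leu codon TTA has synonymous exits at two
positions, which site averaging must respect).

The site-wise scan is a deliberate simplification of codon-model
machinery: per codon column, observed nonsynonymous vs synonymous change
counts (Fitch parsimony along a guide tree when one is supplied, pooled
pairwise pathway counts otherwise) are compared to the column's neutral
expectation by a mid-P binomial tail score in [0, 1]; sites scoring ≥ 0.9
toward nonsynonymous excess are `POSITIVE`, toward deficit `NEGATIVE`,
else `NEUTRAL`. Random-effects likelihood or beta-mixture machinery is
intentionally out of scope: the counting scan delivers the same
qualitative outputs (mean ω, positive/negative site lists), is
dependency-free, and is validated by simulation with known site-wise ω.

# The synthetic-data module

The generators are first-class, tested code — they define the conditions
under which every downstream guarantee is demonstrated.

**Genomes.** Contigs are i.i.d. background sequence at a given GC content
(default 0.42). Intact plants are built from receptor-shaped templates:
seven 21-residue hydrophobic blocks (drawn from I/L/V/F/A/M) alternating
with hydrophilic loops, an N-terminal Met and a length drawn so the ORF
spans 816–1272 nt — the length range real intact bitter receptor genes
occupy. Divergence is applied at the protein level (a fraction of residues
substituted, never the initial Met) and back-translated with uniform codon
choice, which preserves ORF integrity; substitutions inside
transmembrane blocks draw from the hydrophobic alphabet, because real 7-TM
receptors conserve TM hydrophobicity and intact plants must remain intact
by construction — this deliberately decouples the simulator from the
specifics of any TM predictor. Pseudogene plants pass through
`mutate_to_pseudogene()`, which engineers an exact, recorded number of
premature stops and/or 1–2 nt deletions away from both ORF ends. Partial
plants are in-frame fragments flush against a contig edge. Coordinates are
recorded 0-based half-open on the forward strand with a strand flag;
GFF3 output converts to 1-based inclusive.

What the simulator does *not* emulate: repeats and low-complexity
intergenic structure, introns, assembly gaps (N-runs), sequencing error,
and base-composition heterogeneity. Passing recovery tests therefore
demonstrate the pipeline's logic — frame handling, merging, disruption
detection, classification — not robustness to repeat-rich real assemblies.

**Family histories.** Gene copies evolve down the species tree under a
continuous-time birth–death process with per-branch expected rates;
the full event log is retained, with duplications flagged unobservable
when fewer than two daughter lineages survive — no reconciliation method
can recover those, so truth-log comparisons use the observable subset
(with `death_rate = 0` every event is observable, which is why loss-free
histories are the exact-recovery benchmark). Total extinction is a flagged
empty history, not an error.

**Codon alignments.** Sites evolve independently under a continuous-time
codon process: single-nucleotide exchanges, transition/transversion ratio
`kappa`, nonsynonymous rates scaled by the site's ω, stop codons
unreachable, branch lengths in expected substitutions per codon under
neutrality. The default `kappa = 1` is chosen deliberately: the package's
estimator is a counting method that does not model transition bias, so
parameter-recovery validation is run under the model the estimator
assumes; `kappa` is exposed for users who want to study that bias.

# Problem sizes and numerical choices

The validation suite uses: a 30-contig × 6 kb genome with 20/5/5
intact/partial/pseudogene plants at 10% divergence (the reference
recovery condition, with recall/precision ≥ 0.95 and category accuracy
≥ 0.9 required), 200 random reconciliation cases (gene trees ≤ 6 leaves,
species trees ≤ 4) against the exhaustive oracle, 50 loss-free simulated
families for trajectory checks, a 9-taxon/500-codon alignment for ω
recovery (±0.05 at ω = 0.2), and a 32-taxon tree with 0.15-substitution
branches for the site-scan power/specificity runs — deep, short-branched
trees keep per-branch multiple hits rare, which parsimony counting needs.
All generators take explicit seeds and are byte-reproducible; ties in
search output are broken by (contig, start, query) order so the whole
pipeline is deterministic.

# Known limitations

* Multi-exon Tas1r gene structure is not modelled: extraction assumes a
  single ORF (or pre-spliced input), where a full study would use a
  splice-aware aligner for the three Tas1r genes.
* The search scores are not e-values; sensitivity at large evolutionary
  distance depends on the seed word length and score floors, and the
  defaults are calibrated on the simulator's divergence range (≤ ~0.3).
* Whether `SHORT` clean ORFs should count as pseudogenes is genuinely
  undecidable from the classification rules alone; they are reported as
  their own category and excluded from intact counts.
* NG86 with Jukes–Cantor correction underestimates ω when transition bias
  or unequal codon frequencies are strong; the site scan's parsimony
  counts saturate on long branches. Both are counting methods by design,
  not substitutes for likelihood machinery on real data.
* The LCA reconciliation is event-minimal; real histories with hidden
  duplication-then-loss are undercounted, as the unobservable flags in the
  simulator's truth logs make explicit.
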