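---
title: "Models and methods behind mitorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mitorder` is a pipeline for comparative analysis of animal mitochondrial
genome architecture. Animal mitogenomes carry an almost fixed complement
of 37 genes (13 protein-coding genes, 2 rRNAs, 22 tRNAs) on a circular
molecule, but the *order* and *strand* of those genes — the mitochondrial
gene order, MGO — varies between lineages, in some groups (decapod
crustaceans among them) dramatically. The package turns a set of
annotated mitogenomes plus a phylogeny into: MGO patterns and their
distribution, explicit rearrangement scenarios, reconstructed ancestral
arrangements, composition and strand-asymmetry profiles, a single-factor
index of relative mitochondrial evolutionary speed, and
correlation/ordination summaries. A seeded simulator of mitogenome
evolution makes every step testable without any download.

This vignette records the models, conventions and numerical choices.

## Canonical gene orders

A gene order is a circular sequence of signed tokens, e.g. `cox1`,
`-trnC`. Internally every order is held in a canonical form: rotated so
an anchor gene comes first and, if the anchor sits on the minus strand,
reflected (list reversed, all signs flipped — a circular molecule has no
intrinsic strand, so two deposited records differing only in strand or
sequence start are the same MGO). The anchor is `cox1`, falling back to
`cob`, then `rrnL`, then the lexicographically smallest token; `cox1` is
present in all complete decapod-like mitogenomes and is conventionally
drawn first. When the anchor gene itself is duplicated (possible after
simulated duplication events), all candidate rotations in both
orientations are generated and the lexicographically smallest
representation wins, which keeps canonicalisation rotation- and
reflection-invariant in every case.

Coordinates from GenBank (1-based, inclusive) are converted once, at the
reader boundary, to 0-based half-open intervals on the forward strand;
origin-spanning `join()` features are kept as single features with a
flag. Gene names are normalised through a shipped synonym table;
leucine/serine tRNAs are resolved by an anticodon or codon-family tag or
an explicit `L1/L2/S1/S2` suffix, and are otherwise reported as
unresolvable rather than guessed from position. Public-database
annotation errors (missing genes, duplicated labels, unknown names) are
surfaced as diagnostics, never repaired silently.

Pattern clustering uses exact equality of canonical orders; the pattern
matching the shipped reference arrangement is labelled `Gr`, other
patterns get a group prefix plus an index in order of first appearance.
Patterns default to the full gene complement while the
arrangement-sharing fraction AMIGA is computed on protein-coding genes
only; both modes are exposed. The reference arrangement (the
pancrustacean ancestral order) ships as an editable text file under
`extdata/`.

## Rearrangement events and scenarios

Six forward operators act on circular signed orders: transposition `T`
(move a contiguous segment), reversal `r` (reverse a segment and flip
its signs), reverse transposition `rT` (move and flip), tandem
duplication–random loss `tdrl` (duplicate a window in tandem, then lose
one copy of each gene — equivalently a stable two-class partition of the
window), duplication `d` and deletion `x`. `d` and `x` exist for the
simulator; scenario inference operates on duplicate-collapsed,
shared-gene-restricted orders and never infers them.

`infer_scenario()` produces one deterministic scenario per ordered pair:

1. equal orders give the empty scenario;
2. an exhaustive search for a single `r`, `T` or `rT` event, enumerated
   in preference order `r` before `T` before `rT`, shorter segments
   first, then leftmost, with the first hit returned. The search is
   gated by the signed circular breakpoint distance: one reversal can
   change at most 2 adjacencies and one (reverse) transposition at most
   3, so pairs further apart skip this stage entirely. Segment
   enumeration covers wrap-around segments, since an event acting across
   the anchor is not always expressible on the complement segment;
3. if the relative permutation carries uniform plus signs, a pure tdrl
   scenario of provably minimum length. With `s` maximal ascending
   contiguous runs (strips) of the anchor-linearised relative
   permutation, the minimum is `ceil(log2 s)`: a tdrl applied to any
   sequence at most doubles the number of realisable ascending runs, and
   a radix construction attains the bound. The constructive steps keep,
   in round `b`, the genes whose strip index has bit `b` clear — a
   least-significant-bit-first stable radix partition, which is the same
   event sequence as iteratively keeping odd-numbered strips first;
4. otherwise, one reversal per maximal run of minus-strand genes
   (restoring uniform signs), followed by the tdrl steps. Scenarios that
   accumulate more than 8 events are returned `complete = FALSE`: such
   pairs are reported with their breakpoint distance rather than trusted,
   mirroring the practice of treating heavily rearranged pairs as cases
   for expert inspection.

For permutation inputs, `tdrl_min_count()` uses the linear convention
(the permutation as given); for gene-order inputs the relative
permutation is linearised at the anchor. The two conventions agree on
what the package itself ever compares, and the breadth-first-search
oracle in the test suite verifies the count for every permutation up to
`n = 6`.

The scalar "MGO divergence" of a taxon is the length of the inferred
scenario from the reference arrangement, falling back to the breakpoint
distance (flagged) when the scenario is incomplete.

## Ancestral reconstruction

`reconstruct_ancestral()` assigns a gene order to every internal node of
a rooted binary tree by candidate parsimony. Bottom-up, each node
considers its children's orders and the reference; top-down, the
parent's assigned order joins the candidate set. The candidate
minimising the summed scenario lengths over the incident edges wins.
Two refinements matter in practice:

* **Intermediate enrichment.** When all incident edges of a node carry
  events, the true ancestral order is not any neighbour's order. The
  candidate set is therefore enriched with the intermediate orders of
  two-event scenarios between existing candidates; the
  reversal-then-tdrl composition passes exactly through the missing
  intermediate in these cases. Without this, roughly one node per ten
  16-leaf replicates is unrecoverable at moderate event rates.
* **Tie-breaking toward the reference.** Cost ties are resolved first
  toward the candidate closest (breakpoint distance) to the reference,
  then toward the reference itself. This derived-state-averse convention
  is appropriate when the reference is the presumed ancestral
  arrangement; it also resolves the frequent root tie between the true
  root order and a one-event derived order.

Each internal node receives a confidence label: `consistent` when the
final choice is the unique cost minimiser or a tie resolved by the
documented reference preference; `intermediate` when the top-down pass
overturned a uniquely-resolved bottom-up choice; `fallback` when a
residual tie was broken deterministically among non-reference
candidates. The three levels correspond to the no-mark / mid / high
uncertainty convention used when such reconstructions are drawn on
trees.

Candidate parsimony deliberately replaces a full strong-interval-tree
consistency machinery: it is simple, fully testable, and recovers
planted histories exactly on clean instances (at most one event per
branch, operand-disjoint events — the suite requires 95 of 100 seeded
16-leaf replicates to recover *every* ancestral node with all nodes
labelled consistent). On real data with dense, overlapping events it
will understate certainty; the labels say so.

## Composition metrics

All whole-molecule quantities are computed on the forward strand, with
`N` runs (assembly gaps) excluded from every denominator so a gapped
control region cannot bias AT%. Definitions:
`at_percent = 100 (A+T)/(A+C+G+T)`; `at_skew = (A-T)/(A+T)`;
`gc_skew = (G-C)/(G+C)`; strand-usage skew
`su_skew = (L+ - L-)/(L+ + L-)` over annotated gene lengths per strand;
unassigned-region percentage `ur_percent` = 100 × (genome length −
interval union of gene features)/length. The control region is counted
as unassigned by default — it carries no gene annotation — with a switch
(`count_control_region_as_gene`) for the opposite convention.

Codon usage reads every protein-coding gene 5'→3' on its coding strand
under the invertebrate mitochondrial genetic code (translation table 5,
taken from `Biostrings`): initiation codons count as given, trailing
incomplete codons (polyadenylation-completed stops) and terminal stop
codons are excluded, internal stops warn with their position but still
count. RSCU is the observed count over the equal-usage expectation
within each synonymous family, over sense codons only; family means are
exactly 1 whenever the family is observed.

## The evolutionary-speed index

Five per-taxon variables — root-to-tip distance, path distance from the
outgroup, UR%, AMIGA and SUskew — are standardised and summarised by a
single-factor maximum-likelihood factor model on their Pearson
correlation matrix. Uniquenesses are optimised numerically over the
concentrated likelihood (box-constrained quasi-Newton, lower bound 0.005
— a uniqueness pinned there flags a Heywood case); loadings come from
the leading eigen-structure of the uniqueness-rescaled correlation
matrix. The implementation is validated in the test suite against an
independent ML factoriser (`stats::factanal`) to 4 decimals.

Fit statistics use the Bartlett-corrected likelihood-ratio chi-square
`chi2_model = (n - 1 - (2p+5)/6 - 2k/3) F_ML` on
`df = ((p-k)^2 - (p+k))/2 = 5` degrees of freedom; the null model is the
Bartlett sphericity statistic on `p(p-1)/2 = 10` degrees of freedom; TLI,
RMSEA and SRMR (root mean square residual correlation over the lower
triangle including the diagonal) follow their standard formulas.
Per-taxon index scores are regression (Thomson) scores, with the factor
oriented so the root-to-tip loading is non-negative — larger scores mean
faster mitochondrial evolution.

When the independence test is non-significant the one-factor likelihood
is flat along a ridge and any optimiser (including `factanal`) drifts to
a boundary solution that loads a single arbitrary variable. The package
detects this case first and reports the minimal-departure solution (unit
uniquenesses, loadings from the correlation matrix's leading eigenpair)
together with a `degenerate` flag, rather than an artefactual boundary
fit.

AMIGA enters as the raw sharing fraction; any monotone transform would be
absorbed by standardisation and the loading orientation. Note that when
both tree distances are read off the *same* tree they are exactly
collinear (the outgroup path is the root-to-tip distance plus a
constant) and the correlation matrix is singular; in real use the
outgroup distance is an independently estimated ML distance. The
simulator therefore provides `simulate_hermes_regimes()`, which draws
the five variables from a one-factor model with independent noise on
the two distances, a negative AMIGA loading (sharing an arrangement
marks slow structural evolution) and a latent-factor shift between a
ground-pattern-like and a rearranged regime.

## Ordination and correlation tests

PCA is an eigendecomposition of the Pearson correlation matrix; variance
fractions are eigenvalues over the number of variables, constant columns
are dropped with a message, and the sign convention makes the
largest-magnitude loading of each component positive. Spearman tests use
average ranks, the t approximation on `n - 2` degrees of freedom, and a
seeded two-sided permutation p-value with add-one correction. Habitat
enters as one binary indicator per category — the least-assumptive
encoding. Tests are two-sided and exploratory; Benjamini–Hochberg
adjustment is available behind a flag but off by default.

## The simulator and what passing tests mean

`simulate_dataset()` draws a Yule tree (constant birth rate, the
standard prior for species-level trees) with an outgroup grafted at the
root, plants Poisson(`lambda` × branch length) rearrangement events per
branch (multinomial types, geometric segment lengths; deletion only ever
removes one copy of a currently-duplicated gene), and writes annotated
GenBank records whose sequences hit per-taxon composition targets in
expectation. Defaults are chosen once to emulate a decapod-like study:
AT 70% (between the caridean ~65% and brachyuran ~71% clade means),
AT skew 0.05, GC skew −0.2 (most decapods show negative GC skew), ~5%
unassigned region, genomes in the 15–18 kb range via field-typical gene
lengths, and an event rate low enough that most branches are quiet.
Between-taxon jitter on the composition targets and the UR fraction
reflects the variation real datasets show (multiple control regions,
long intergenic spacers); without it several index variables would be
degenerate constants, which no real dataset is. Minus-strand coding
genes are sampled from the complement-swapped base measure so the
deposited strand still matches the composition targets; a configurable
within-family codon bias makes RSCU depart detectably from 1. One
global seed feeds fixed per-stage offsets (tree, events, sequences,
rates), so stages can be regenerated in isolation and every output is a
pure function of configuration and seed.

The simulator does **not** evolve nucleotide substitutions along the
tree (no alignments, no phylogeny estimation), does not correlate gene
lengths or composition with the phylogeny, and does not imitate
annotation error. Passing tests therefore demonstrate algorithmic
correctness — canonicalisation, scenario soundness against exhaustive
and BFS oracles, ancestral recovery on clean planted histories, factor
recovery under a true one-factor model, exact composition identities —
not that real decapod data satisfy those models.

Problem sizes used by the test suite, chosen to exercise each guarantee
at full strength while keeping a default run in the tens of seconds per
file: 2×10⁴ random single-event pairs at up to 10 genes for the
inference/oracle comparison; every permutation up to `n = 6` for the
tdrl distance; 10³ multi-event scenarios for soundness fuzzing; 100
seeded 16-leaf replicates for ancestral recovery; 20 seeds at `n = 1000`
for loading recovery (the per-seed maximum elementwise error is averaged
over seeds — the maximum over all 100 estimates concentrates near 1.9
standard errors, so a fixed 0.05 bound on the overall maximum would be a
coin flip for any correct estimator); 60 taxa for the full
simulate–write–read–extract round trip.

## Known limitations

* One deterministic scenario per pair; alternative co-optimal scenarios
  (which a strong-interval enumeration would list) are not reported.
* Minimum mixed-event distances are NP-hard in general; the fallback
  composition is sound but not guaranteed minimal, and scenarios longer
  than 8 events are flagged incomplete rather than trusted.
* Candidate parsimony (even with intermediate enrichment) can miss
  ancestral states when several long-branch histories interact; labels
  report, but cannot eliminate, that uncertainty.
* The tdrl distance convention is linear after anchor rotation;
  rotations of the strip structure across the origin are not exploited.
* The index assumes one common factor; with fewer than ~10 taxa or
  near-constant variables it refuses to fit rather than extrapolate.
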