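---
title: "Rule-based characterization of bZIP families: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based characterization of bZIP families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzipr)
```

## The biological model

A bZIP transcription factor binds DNA as a dimer. Its defining domain has
three parts in fixed register: an ~18-residue basic region carrying the
invariant N-x7-R/K motif that contacts the DNA major groove, a 9-residue
hinge, and a C-terminal leucine zipper — a coiled-coil helix of heptad
repeats whose composition decides whether the protein homodimerizes,
heterodimerizes, or can do both. Everything bzipr computes follows from a
signed coordinate system laid over that architecture: the anchor Asn is
position −18, the basic Arg/Lys is −10, the hinge spans −9…−1, and the
first zipper leucine is +1. Position 0 does not exist, and the numbering
is a bijection over the covered span (`seq_to_paper()` / `paper_to_seq()`
invert each other exactly).

Two residue substitutions are tolerated at the anchor because they define
real binding groups: a Lys in place of the −18 Asn (group IX) and a
hydrophobic Ile in place of the −10 Arg/Lys (group XI, probably unable to
bind DNA conventionally). The wild-type literature is not fully consistent
about whether the −18 consensus residue should be read as Asn or Arg; the
package anchors on Asn and treats Lys/other letters there as reportable
anomalies rather than guessing intent.

## Anchoring and ambiguity

`scan_basic_anchor()` reports *every* position triple compatible with the
N-x7-R/K-x9-initiator spacing, left to right. Real proteins occasionally
contain coincidental copies of so permissive a motif, so selection is a
separate, deterministic step: `select_domain()` keeps the candidate with
the longest downstream zipper (the zipper is the defining C-terminal
feature of the domain) and breaks ties toward the leftmost anchor. The
zipper is bounded by the first α-helix breaker at or after +1; the breaker
set defaults to `{P}` with `{P, G}` selectable, because the surveys that
use the concept never define it precisely. The zipper initiator defaults
to Leu alone and can be widened to the bulky hydrophobics
`{L, I, V, F, M}` for degenerate zippers.

## Heptad registers and the g↔e′ pair classes

The package places zipper position +1 on register *d*. The literature that
defines the signed numbering never states this phase explicitly, but
canonical zipper leucines occupy *d*, and the choice yields the standard
*i*, *i*+5 spacing in which the *g* residue of heptad *n* faces the *e*
residue of heptad *n*+1 across the dimer interface. A configurable integer
register offset is honoured by every downstream statistic for users who
prefer a different convention; the tests pin the default by asserting
d-residues at +1, +8, +15.

Pair classification is purely categorical: with acidic = `{D, E}` and
basic = `{K, R}`, a g↔e′ pair is *complete* when both residues are
charged, *incomplete* when exactly one is, *uncharged* otherwise, and
complete pairs split into acidic repulsive, basic repulsive, +/−
attractive and −/+ attractive by the charge signs at *g* and *e′*.
Histidine is uncharged by default (its protonation is
condition-dependent); a switch moves it to the basic set, and the
exhaustive truth-table test runs under both conventions. The unknown
residue X matches no class. A trailing *g* with no following *e* (and the
leading *e* of heptad 1) participates in no pair; partial final heptads
contribute to register composition only for the registers they actually
contain.

## Dimerization calls and subfamilies

The propensity rules are deliberately coarse, matching how family surveys
state them: *homodimer* requires an attractive pair in the first heptad
and the absence of any repulsive pair; *heterodimer* requires at least one
complete pair with every complete pair repulsive; everything else is
*both*. Incomplete pairs are neutral — they contribute little to homodimer
stability but can complete attractively in a heteropartner.

Published subfamily schemes (BZ1…BZ24 style) rest on supplementary tables
that are not machine-readable, so the package uses a documented stand-in
that reproduces the stated exemplar behaviours: each protein's signature
is its heptad count plus the ordered per-heptad pair-class string, equal
signatures share a subfamily, and labels are assigned in lexicographic
signature order so they are deterministic across runs and input
orderings. Signature-identical planting of 24 templates recovers exactly
24 subfamilies; all-repulsive plants are never called homodimer.

## Intron phases, the window, and patterns a–f

Phases are computed from CDS segments only (introns within UTRs are
ignored; surveys drop 5′ UTR exons for exactly this reason). With `c`
coding nucleotides 5′ of a junction, phase is `c mod 3` (P0 between
codons, P1 after the first nucleotide, P2 between the second and third)
and the affected protein position is `floor(c/3) + 1` — the codon being
interrupted for P1/P2, the codon following the junction for P0. An
independent base-by-base codon-walk oracle checks this arithmetic on 1,000
random gene models.

Pattern classification restricts introns to those whose protein position
maps into −18…−1 (a P2 codon straddling the boundary counts as inside
when the interrupted residue's signed position is inside; the +1 codon is
excluded). The published positional split between the two single-P0
patterns is shown only in a non-machine-readable figure, so the default —
pattern *a* for the basic sub-window −18…−11, *b* for the hinge −10…−1 —
is shipped as configurable data (`default_pattern_table()`). Patterns *d*
and *e* are single P2 introns interrupting Gln and Arg respectively;
pattern *c* is two P0 introns; *f* is an empty window. No published
pattern carries a P1 window intron, so such genes come back
`unclassified` with a reason instead of being forced into a bin. The
census reports intronless genes separately from pattern *f* because *f*
also contains genes whose introns all lie outside the window.

Genes with alternative transcripts collapse to the longest CDS per gene
by default (flagged on the model); the source surveys never state their
collapsing rule, and the longest CDS is the least lossy deterministic
choice.

## Tandem clusters and blocks

No survey defines "gene cluster" operationally. The default here chains
family genes on one chromosome when at most one annotated non-family gene
intervenes (when a full gene census is supplied) or when the genomic gap
is ≤ 100 kb otherwise; both thresholds are exposed and documented as
stand-ins. Segmental-duplication blocks are consumed as a 4-column
interval table from external synteny tools — membership is computed,
synteny never is.

## Family composition denominators

Per-heptad Asn-at-*a* frequencies depend on the denominator: all family
members, or only members whose zipper reaches that heptad. Published
percentages for deep heptads are not integer fractions of the family
size under either reading, so both modes are provided
(`denominator_mode`), defaulting to all members; the restricted mode can
only raise a frequency, which the tests assert as an inequality.

## Expression

`ddct()` averages replicates on the Ct scale (the aggregation level is
unstated in the sources; averaging Ct before ΔCt is the conventional
reading), normalizes within sample against the reference gene, references
the calibrator sample, and returns `2^−ΔΔCt`; the calibrator fold is
exactly 1 by construction, which the tests assert with `expect_identical`.
Clustering uses 1 − Pearson distance with average linkage on log2 folds
(the heatmap convention), sorts genes lexicographically before clustering
so ties break deterministically, and sets the distance of zero-variance
profiles — where Pearson is undefined — to the maximum of 2 rather than
dropping the genes. A naive O(n³) agglomeration oracle verifies the merge
heights and cophenetic structure on random matrices.

## What the synthetic generator does and does not emulate

`generate_family()` plants, per protein: one anchor (with the group IX/XI
substitutions), a zipper of 3–9 full heptads (the range reported for a
real family) with Leu at every *d*, Asn at *a* in ~30 % of heptads,
per-junction pair classes drawn with a mix weighted toward incomplete and
uncharged pairs (roughly matching the reported predominance of
single-charged interactions), a gene model whose CDS length is exactly 3×
the protein length with introns realized at the planted positions and
phases, a chromosome layout in which ~30 % of genes sit in tandem clusters
of 2–3 (gaps of 2–20 kb inside clusters, ≥300 kb between neighbours), and
a Ct table with N(0, 2²) log2 fold effects, three replicates and 0.2-cycle
Gaussian noise. Background residues are drawn from uncharged letters that
carry no structural meaning, which — together with a post-generation
rescan — guarantees exactly one anchor per protein. All randomness flows
from one seed; equal seeds give byte-identical files, and the caller's RNG
stream is restored afterwards.

What it deliberately does not emulate: phylogenetic relatedness between
family members, codon-usage variation (back-translation uses a fixed
codon per residue — reproducibility over realism), UTRs and alternative
transcripts, partial final heptads, and decoy anchor motifs unless
requested. Passing the recovery tests therefore shows the pipeline is
exact on sequences that obey the domain grammar; it does not show
robustness to annotation errors or to proteins that violate the grammar,
which real families contain.

## Problem sizes and numerical choices

The test suite and the acceptance script run the recovery analysis at 200
proteins, the subfamily planting at 69 proteins over 24 templates, the
phase oracle at 1,000 random gene models, and the clustering oracle on
10×6 matrices — sizes at which every property is exercised many times over
while the whole suite stays fast. All category assignments are exact
string/set operations with no tolerances; the only floating-point
comparisons (oracle merge heights, cophenetic distances) use a 1e−10
tolerance. Conservation identities (pair categories partition the pair
total; the pattern census sums to the gene count; calibrator fold = 1) are
asserted exactly.

## Known limitations

* Binding groups II–VIII and X ship with placeholder single-position
  rules, because the full per-group residue table exists only in
  non-machine-readable supplementary material; the table is data
  (`inst/extdata/binding_group_rules.yaml`) and should be replaced for
  serious use on a real family.
* Subfamily labels are canonical-order artifacts; they will not match a
  published BZ numbering, only its partition structure.
* Domain anchoring is motif-based, not profile-HMM-based; confirmation
  against Pfam/SMART profiles is out of scope, as is any genome-wide
  mining, alignment, tree building or motif discovery upstream of the
  family list.
* The pattern a/b positional split and the tandem-cluster thresholds are
  documented conventions, not published definitions; headline counts that
  depend on them should be read accordingly.
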