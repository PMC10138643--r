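---
title: "Classifying cuticular protein families: models, rules and design choices"
author: "cuticleR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cuticular protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuticleR)
```

Structural cuticular proteins (CPs) make up most of the insect exoskeleton.
Unlike enzyme families, CP families are not defined by overall sequence
homology — many are short, repetitive and fast-evolving — but by small
diagnostic features: a conserved chitin-binding consensus, a cysteine
spacing, a handful of ordered sequence blocks, or a compositional bias.
cuticleR turns those published diagnostics into an explicit, configurable
decision cascade, and surrounds it with the standard downstream analyses of
a gene-family study: ortholog naming, tandem-array mapping, subfamily
phylogenies, and tissue expression profiling from FPKM tables.

This vignette records the models and the choices behind them: what each rule
computes, which thresholds are interpretation rather than specification, and
what the synthetic benchmark does and does not demonstrate.

## The classification cascade

Each protein receives exactly one verdict. Rules are evaluated in a fixed
order and the first hit wins:

1. **CPAP (ChtBD2 spacing).** A protein with at least three non-overlapping
   hits of the CPAP3 cysteine-spacing pattern is CPAP3; otherwise one CPAP1
   spacing hit makes it CPAP1. CPAP precedes the consensus rule because a
   ChtBD2-bearing protein is a peritrophin-analogous CP by definition, even
   if it happens to score against an R&R consensus.
2. **CPR (R&R consensus).** `consensusScore()` slides the extended RR-1 and
   RR-2 consensus over the protein (gaps at minimal width) and reports the
   best fraction of fixed positions matched. A profile HMM would weight
   positions unequally; the positional fraction is a deliberately simple,
   dependency-free surrogate whose behaviour is easy to audit. The CPR
   threshold (`cprScore = 0.5`) and the RR-1/RR-2 tie margin
   (`cprTieMargin = 0.05`, below which the call is RR-NC) are exposed in
   `cpConfig()` because the literature specifies the rule but not the
   numbers. RR-3, which has no consensus of its own, is claimed by identity
   to known RR-3 exemplars (`rr3Identity = 0.5`) when that identity beats
   both consensus scores.
3. **CPT (Tweedle).** At least `tweedleMinBlocks = 3` of the four blocks,
   in order along the sequence. Requiring order (first-hit positions
   strictly increasing) rejects sequences that contain the blocks by
   composition alone.
4. **Low-complexity and homology families**, in fixed order: CPCFC
   (≥ 2 non-overlapping `C-X5-C` repeats), then CPF/CPFL/18aa/CPLCA by
   reference identity (`familyIdentity = 0.40`), then CPLCP (PV + PY
   occurrences ≥ 10 and proline fraction ≥ 0.10), then CPG (glycine
   fraction ≥ 0.20 — the operational meaning of "glycine-rich" — and ≥ 2
   `GGxGG` repeats), then CPH (identity ≥ 0.36 to a CPG/CPH reference
   member, or ≥ 3 `AAP[AVL]` repeats). The 0.36 floor is calibrated from
   the lowest identity reported for verified CPH–CPG homology, not a
   specified constant, and is flagged as such.
5. Anything left is **not-CP**.

Manual curation is real in this field (synteny arguments, database
disagreements). It enters as an explicit override table applied after the
cascade and flagged in the output, never as hidden code.

### Motif semantics

Patterns are written in the field's notation (`x` wildcard, `x(14-16)`
bounded gap, `[AVL]` / `Y/F` alternatives) and parsed into element lists.
Scanning allows a configurable number of substitutions at fixed/alternative
positions — gaps and wildcards never count — and an `X` in the protein never
satisfies an informative position (an unknown residue is evidence of
nothing). Although spacing patterns are nominally exact, the classifier
tolerates one substitution across the six cysteines of a ChtBD2 hit
(`cpapMaxMismatches = 1`), mirroring the tolerance a profile HMM would have;
with six anchor cysteines per domain, demanding all six survive makes the
call fragile to single sequencing or prediction errors.

Two counting conventions are fixed deliberately: repeat counting is greedy
left-to-right with the next repeat allowed to begin on the previous one's
final residue (tandem `C-X5-C` units share their boundary cysteine), and
dipeptide counting allows overlaps (`PPP` contains two `PP`), the natural
reading of "occurrences".

## Alignment and orthology

Candidate-to-reference identity and reciprocal best hits use exact global
alignment (Needleman–Wunsch with Gotoh's affine-gap recursion, implemented
in C++), BLOSUM62, gap open 10, extend 1 — the defaults of a protein BLAST —
with a fixed traceback tie-break (aligned pair > gap in query > gap in
subject) so results are bit-reproducible. At gene-family scale (hundreds of
sequences) exact alignment is affordable and removes both an external
binary and E-value heuristics. Identity is matches / aligned columns with
columns inside terminal gap runs excluded; this is the least
length-punitive convention for comparing full-length proteins of unequal
length, and it is the one under which a short perfect fragment of a longer
protein scores 1.

A query–reference pair is a 1:1 ortholog when each is the other's unique
best hit at identity ≥ `minOrthologIdentity` (0.3). Best-hit edges failing
reciprocity are grouped into connected components and reported as
co-ortholog groups — the many-to-many signature of recently expanded tandem
families. 1:1 partners inherit the reference name stem
(`BmorCPAP3-A1 → ApCPAP3-A1`); the rest are numbered within family in
genomic annotation order.

## Phylogeny and logos

Subfamily trees use the region where the R&R consensus aligns best, widened
by `consensusFlank = 10` residues. Because every extracted window has the
consensus's minimal-gap width, the windows are columnwise comparable
without re-alignment; an externally aligned MSA (e.g. from MAFFT) is
accepted wherever an alignment is an input. Distances are Poisson-corrected
proportions, d = −ln(1 − p), computed with pairwise deletion (only columns
where both rows are ungapped and not `X`); saturated pairs (p = 1) are
flagged infinite and must be excluded rather than silently truncated. Trees
are standard neighbor-joining; negative branch-length estimates are clamped
to zero with a message. Bootstrap support resamples alignment columns with
replacement and reports the percentage of replicates containing each
internal bipartition; it is seed-deterministic. Logo matrices report
per-column residue frequencies over non-gap residues and information
R = log2 20 − H bits, uncorrected by default (the small-sample correction
is available but off, because the package's fixtures have few sequences and
the correction would obscure the closed-form checks).

## Genomic organization

"Tandem array" has no standard quantitative definition. Here, same-family
genes (same subfamily for CPR — RR-1 and RR-2 never share an array) chain
into an array when consecutive members are ≤ `maxGapKb = 100` apart
start-to-start and separated by ≤ `maxIntervening = 1` non-family genes;
singletons are dropped. Both knobs are configuration and are echoed in
output headers, because published array-size ranges depend on exactly these
choices. Distances are start-to-start and strand-agnostic — the simplest
deterministic convention, stated rather than implied.

## Expression

FPKM tables are inputs; read mapping and FPKM estimation happen upstream.
The six bins partition [0, ∞) at 1, 10, 100, 1000 and 10000 with
left-closed intervals, so a value of exactly 10 is "low" and exactly 1000
is "high" — endpoint placement in prose bin labels is ambiguous and one
convention had to be fixed. A gene is "expressed" at FPKM ≥ 1
(`expressedThreshold`), the only reading consistent with the lowest bin
being "no or extremely low expression"; since published expressed counts
rarely state their cutoff, the threshold is printed in every report.
Heat-map cells are log10(FPKM + 1); the pseudocount handles zeros and keeps
the transform strictly monotone. Row ordering is average-linkage
hierarchical clustering of transformed profiles (Euclidean), or genomic
order. A gene is tissue-specific when its top tissue holds ≥ 80% of its
total FPKM; all-zero genes are "silent", not zero-ratio.

Percentages in the family-by-tissue table are rendered at one decimal,
rounded half away from zero — the convention that reproduces published
figures like 60.8% (132/217) and 48.7% (115/236) exactly.

## The synthetic benchmark

`simulateProteome()` plants each family's diagnostic into random flanks:
instantiated R&R consensus (wildcards randomized), one or three ChtBD2
spacing instances, the four Tweedle blocks in order, three `C-X5-C` repeats
(the literature reports two or three; three keeps the planted signal
detectable after mutation), PV/PY-dense cores, `GGxGG`-rich glycine cores,
`AAP[AVL]` repeats, and — for the purely homology-defined families — mutated
copies of reference members. The default fixture is 60 genes, five per
category across the twelve categories relevant to an *A. pernyi*-like
proteome (the three CPR subfamilies count separately; CPLCA and 18aa are
absent from that species). Decoys are random sequences rejection-sampled
until the classifier itself rejects them, so the truth table is sound on
both sides by construction. Reference members of homology-defined families
are generated cysteine-free so that a chance `C-X5-C` pair can never
pre-empt the homology rule in a planted copy.

Clade fixtures for the phylogeny tests derive each clade ancestor from a
root at rate (between − within) and leaves from ancestors at rate within;
setting within = between then genuinely erases the clade signal, giving a
working negative control.

What passing these benchmarks shows: the rules fire on their defining
features, tolerate a 2% per-site substitution load, and reject
uniform-composition decoys. What it does not show: performance on real
proteomes, where gene models are fragmented, isoforms duplicate loci
(the package assumes one protein per gene), compositional bias is pervasive
(glycine-rich non-CPs exist), and the borderline cases that required manual
curation in published catalogs reappear. The published 217/236-gene rosters
depend on genome downloads and curation decisions and are not a target of
the synthetic suite; what the package does reproduce exactly is the
published census arithmetic — totals, per-tissue expressed counts and every
derived percentage — when fed the printed per-family counts bundled under
`inst/extdata/`.

## Problem sizes and numerical notes

The test-suite and demo fixtures are deliberately desk-scale: 60–70 protein
proteomes, reference catalogs of ~20 sequences, 120-column alignments with
100 bootstrap replicates, and 5-taxon exhaustive topology checks (15
trees). These sizes exercise every code path while keeping the whole suite
fast; all thresholds above were chosen from the family definitions before
any benchmark was run, and none is tuned to a fixture.

Degenerate inputs are handled explicitly rather than by fallthrough: empty
proteomes classify to an empty table; an alignment of identical sequences
yields an unresolved tree with a warning; an all-`X` protein has no
composition; a protein shorter than a consensus scores 0 with no location;
all-gap logo columns are missing, not zero. NJ tie-breaking inside the
agglomeration is delegated to the ape implementation, which is
deterministic; what the package adds is the clamping of negative branch
estimates and the refusal to build trees over infinite distances.
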