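---
title: "Detecting recently mobile TE subfamilies: model and methods"
author: "rmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recently mobile TE subfamilies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

A polymorphic mobile-element insertion (pMEI) is a TE copy present in
the reference genome but absent in part of the population. Seen from
the reference, carriers of the ancestral (empty) allele show a
*deletion* whose boundaries coincide with the TE; and because the
insertion is evolutionarily recent, the TE has no orthologue in
closely related primate genomes. `rmscan` turns these two signatures
into a per-subfamily test of recent mobility. The confounder it must
remove is the opposite event, a polymorphic mobile-element *deletion*
(pMED): an ancestral TE deleted in some humans. pMEDs retain primate
orthologues and their deletions typically spill into flanking
sequence, so the two filters — cross-genome mapping and exact boundary
matching — act in concert.

## The pseudo-indel null and the per-subfamily test

The null hypothesis for a subfamily is that polymorphic deletions
arise independently of its human-specific instances, so a deletion is
as likely to coincide with such an instance as a randomly placed
segment of the same size in the same neighbourhood. Rather than
shuffling deletions genome-wide (which would confound local TE density
with mobility), the null is *local*: each true deletion of length
$L$ is complemented by `nPseudo = 500` pseudo-indels of the same
length, 250 tiled into each flank starting flush with the deletion
boundaries, consecutive same-side tiles sharing $\lfloor L/2 \rfloor$
bp. Matching uses mutual overlap — overlap length divided by the
*longer* of the two segments — at threshold 0.9.

Summing over the genome gives the 2×2 table
$[[T_{TE},\,N_{true}-T_{TE}],\,[P_{TE},\,N_{pseudo}-P_{TE}]]$, tested
one-sided (enrichment of true matches) with Fisher's exact test and
corrected by Benjamini–Hochberg across the tested universe (all
subfamilies with at least one human-specific instance). Subfamilies
with $Q \le 0.001$ (inclusive) are called recently mobile. The
expected match count is reported as $P_{TE} \cdot N_{true} /
N_{pseudo}$ and fold enrichment as $T_{TE}$ over that expectation.

Design choices that the procedure leaves open, fixed here:

* **Mutual overlap** is overlap/longer-interval, the strictest of the
  common reciprocal-overlap readings: a mutual overlap $\ge f$
  guarantees the shared segment covers $\ge f$ of *both* intervals.
  This makes near-exact boundary matches pass while flank-spilling
  pMED deletions fail.
* **Pseudo-indel split** is symmetric, 250 per side, tiled outward;
  for odd $L$ the step is $L - \lfloor L/2 \rfloor$ so neighbours
  share exactly $\lfloor L/2 \rfloor$ bp. Tiles crossing a chromosome
  end are dropped, not reflected, and the realised tile count (not the
  nominal $500 \cdot N_{true}$) enters the contingency table so
  clipping cannot bias the null. Pseudo-indels are not tested for
  collision with true indels or each other; no such exclusion is part
  of the model.
* **Sidedness**: one-sided "greater", since the question is an excess
  of true matches; the worked enrichment examples below reproduce
  under this convention.
* The Fisher tail is summed in log space (`lchoose` + log-sum-exp), so
  Q-values of $10^{-300}$ are representable; the result table carries
  a `log10_q` column alongside.

## Catalogue curation

Deletion call sets are pooled as published (no per-sample
genotyping), restricted to deletions relative to the reference (the
human-specificity of *insertions* against outgroup genomes cannot be
assessed from reference coordinates), and to length $\ge 50$ bp,
below which mobile-element events are implausible. Near-duplicate
records across call sets are then resolved on an overlap graph:
nodes are deletions, edges join pairs with $\ge 50\%$ mutual overlap,
and the node of highest degree is removed repeatedly (degrees updated
after every removal) until the graph is edge-free. Ties in degree are
broken towards the lexicographically smallest (chrom, start, end, id)
node, making the retained set invariant to input row order; the
survivors provably contain no pair at $\ge 50\%$ mutual overlap and
re-pruning them removes nothing. Discarded records are kept with
`retained = FALSE`: after subfamilies are called, the *expanded pMEI
scan* re-admits TE instances whose only matching deletion was
discarded as redundant, deduplicated by instance id.

Human specificity is assigned from per-genome mapped fractions
(a LiftOver summary supplied as a table, keeping the package
independent of genome builds and chain parameters): human-specific
$\iff$ mapped fraction $\le 0.20$ in *every* non-human genome
surveyed, the boundary read inclusively from "no more than 20%".
Candidates completely contained within a tandem-repeat interval are
discarded as potential tandem duplications; partial overlap is kept.

## Downstream annotation and enrichment

* **Catalogue enrichment** (`subfamilySetEnrichment()`): one-sided
  Fisher on a finite subfamily universe. From printed counts alone —
  universe 464, called set 20, disease-associated set 10 with overlap
  8; tumour-mobilized set 17 with overlap 13 — the test returns
  $P = 1.1\times10^{-10}$ and $P = 2.8\times10^{-17}$ respectively
  (2 s.f.), which the acceptance suite recomputes. Catalogue names
  missing from an annotation set are first translated with
  `remapSubfamilies()` (consensus-alignment table, e.g. AluYb11 →
  AluYb9).
* **Context classification** (`classifyContext()`): precedence
  exonic (≥ 5 bp exon overlap) > promoter (≥ 50 bp overlap with the
  strand-aware TSS −2 kb/+1 kb window) > intronic (gene-body overlap)
  > intergenic. The precedence order is fixed so the four classes
  partition any pMEI set. A pMEI near two genes is assigned the
  nearer TSS, ties broken lexicographically by gene id.
* **cCRE proximity** (`assignCcre()`): cCREs are extended by 50 bp on
  both sides (young TE sequence maps poorly, so signal just outside
  the element is informative) and any ≥ 1 bp overlap assigns the
  label; labels are not exclusive.
* **ASE proximity** (`geneProximityEnrichment()`): a gene is
  pMEI-flanking when its edge-to-edge distance to the nearest pMEI is
  strictly below 50,000 bp (0 when overlapping); Fisher contrasts ASE
  status of flanking vs all expressed genes.

## Hypersensitivity post-processing

Per-tile scores from a sequence model of DNase hypersensitivity are
consumed as input (training is out of scope). The genome is tiled
into 151 bp windows stepping by 75 bp (76 bp shared); tiles scoring
$\ge 1$ are merged greedily left-to-right with the span capped at
601 bp — exactly a run of 7 tiles — each region taking its best
member's score and being trimmed symmetrically back to 151 bp (odd
excess trims the extra base from the right; the choice is arbitrary
but fixed). Regions are then ranked by score and cut so that the
predicted count equals the measured hypersensitive-site count in the
same cell type, with ties at the cut broken by (score, chrom, start).
A subfamily's hypersensitive fraction in a cell line is the fraction
of *all* its genomic instances (polymorphic or not) overlapping a
hypersensitive site by $\ge 50$ bp; fold enrichment divides a cell
line's fraction by the subfamily's mean across cell lines, so
complete rows average to 1. The ancient reference set is
parameterised as average divergence $\ge 20\%$ with $\ge 1000$
instances.

## What the simulator emulates — and what it does not

`simulateGenome()` plants the full generative structure the screen is
meant to detect: non-overlapping TE instances of many subfamilies
placed uniformly; mobile subfamilies whose planted instances have
mapped fraction 0 everywhere and carry a boundary-matched deletion;
ancestral instances with mapped fractions near 1, a fraction of them
deleted with flank spill (pMEDs); and uniform background deletions
$\ge 50$ bp with log-normal sizes. Two arithmetic guarantees are built
in rather than hoped for: planted pMEI boundary jitter is capped at
$\lfloor L/38 \rfloor$ per side so mutual overlap stays $\ge 0.9$,
and pMED flank spill is at least $6\%$ of $L$ per side so it stays
$< 0.9$.

Default conditions: one 10 Mb chromosome, 40 subfamilies × 60
instances, 3 mobile subfamilies with 15 planted pMEIs each, 30% of
non-planted instances human-specific (so every subfamily enters the
tested universe), 5,000 background deletions, 500 pseudo-indels per
deletion. At this scale a screen runs in a few seconds, and the
acceptance suite repeats it over 20 seeds (plus 20 null seeds with
nothing planted, where no subfamily may reach $Q \le 0.001$ and the
raw p-value distribution is checked one-sided against uniform).

Deliberately *not* modelled: nucleotide sequence and target-site
duplications; insertion-site preference (TE placement is uniform —
consistent with reports that L1 integration is largely insensitive to
local chromatin state); SV-caller error beyond boundary jitter; the
empirical deletion size spectrum; linkage between deletions. Passing
the recovery tests therefore demonstrates correctness of the
statistical machinery under its own assumptions, not robustness to
every artefact of real call sets — the screen's behaviour under
pervasive boundary noise or caller-specific redundancy structure must
be judged on real data.

## Numerical and convention notes

* Intervals live in `GRanges` (1-based, closed). Readers convert:
  RepeatMasker `.out` rows are already 1-based inclusive; BED is
  0-based half-open; a sequence-resolved VCF deletion at POS with a
  301 bp REF and 1 bp ALT deletes the 300 bp starting one base after
  POS. Writers emit BED/TSV back in 0-based half-open coordinates, and
  coordinates round-trip exactly.
* All thresholds sit on inclusive boundaries where the defining
  phrase is inclusive ("no more than 20%", "≥ 50 bp", "≥ 90%",
  "Q ≤ 0.001") and tests pin each boundary from both sides.
* Degenerate inputs: an empty mapping table means nothing maps (all
  instances human-specific); an empty subfamily has an undefined
  hypersensitive fraction (`NA`); a subfamily with zero matches gets
  $p = 1$; fold enrichment with zero expectation and positive
  matches is `Inf`.
* All simulation randomness flows from the config seed; screens
  contain no randomness, so fixed-seed runs are bit-identical.

## Limitations

The screen detects subfamily-level recent mobility, not individual
insertion genotypes; a subfamily with very few polymorphic copies can
escape detection (a single matching deletion is statistically
indistinguishable from chance at genome scale, by design of the FDR
control). Mapped fractions are taken at face value: reference
assembly errors or missing outgroup coverage masquerade as human
specificity upstream of this package. The hypersensitivity module
inherits whatever biases the upstream sequence model carries.
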