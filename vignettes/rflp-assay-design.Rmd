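---
title: "In-silico PCR-RFLP assay design and species typing"
author: "rflpTyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico PCR-RFLP assay design and species typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpTyper)
```

## The method

A PCR-RFLP assay identifies a lineage from the band pattern a
restriction digest of a PCR amplicon leaves on a gel. The design
problem has three parts, and `rflpTyper` models each explicitly.

**Digestion model.** A restriction enzyme is a recognition sequence in
IUPAC code plus two cut offsets, written the way enzyme datasheets do:
SacI `GAGCT'C / C'TCGAG` cuts the top strand after 5 recognition bases
(`cutTop = 5`) and the printed bottom string puts the bottom-strand cut
1 aligned base from the left edge (`cutBottom = 1`). A forward match
starting at position $s$ cleaves the reported (top) strand after
$s - 1 + t$. For a non-palindromic enzyme (AciI `CCGC` here) the
reverse complement of the site is also scanned; for such a match the
only cleavage of the top strand is the enzyme's bottom-strand cut, at
$s - 1 + b$. Complete digestion is assumed: fragments are the intervals
between the distinct cut positions, so fragment lengths always sum to
the input length. Degenerate codes in the *recognition sequence* expand
via the IUPAC table; ambiguity codes in the *subject sequence* never
match, so an uncertain base can never predict a phantom band.

**Diagnostic sites.** Given an alignment whose records carry group
labels (species or haplotype lineages), `findFixedSNPs()` returns the
columns where every record of one group carries one concrete base and
every other record carries a different base; `findSharedSNPs()`
generalises this to a subset of groups. Columns containing a gap in any
record are excluded by default, because an indel shifts every
downstream restriction coordinate; records with an ambiguity code at a
column are treated as missing data there rather than as mismatches.
`screenEnzymes()` then digests each record and partitions the groups by
whether their patterns can be told apart on a gel.

**Keys and classification.** `buildKey()` grows a decision tree
greedily: at each node it picks the assay (amplicon × enzyme) that
splits the remaining candidate groups into the most distinguishable
pattern classes, breaking ties by the smallest sum of squared block
sizes (a one-step proxy for the fewest expected follow-up assays) and
then by enzyme name, so the construction is deterministic. Greedy
rather than exhaustive search is a deliberate choice: pattern tables in
this setting are tiny, and a reproducible tree matters more than
optimality. `publishedKey()` hard-codes the field cascade (SacI first;
then XhoI on the histone amplicon, AlwNI, AciI; NlaIV then Tsp45I) for
faithful replication of the laboratory workflow. `classifySequence()`
digests supplied amplicons in silico and walks the key;
`classifyObserved()` scores measured band lengths against every group's
predicted pattern and returns all compatible groups, so "no match" and
"ambiguous" are ordinary outcomes rather than errors — the panel is
regional, and unknown haplotypes from other oceans are expected.

## Gel-realism parameters

Two parameters separate in-silico patterns from what a gel can show:

* `minDetect` (bp): the smallest scorable band. Default 0 for exact
  in-silico comparison; 50 bp is realistic for a 2% agarose gel — the
  panel's NlaIV digest produces a 30 bp fragment that is never scored.
* `tolBp`, `tolFrac`: two bands co-migrate when their lengths differ by
  at most `max(tolBp, tolFrac × length)`. The gel profile used by
  `classifyObserved()` defaults to `max(10 bp, 5%)`.

Shrinking the tolerance can only remove candidate species, never add
them; this monotonicity is property-tested.

## What the synthetic fixtures are (and are not)

`generateFixtureSet()` builds six species × two amplicons (mtORF 978 bp,
PocHistone 669 bp) of synthetic sequences satisfying every published
coordinate of the panel: primer footprints verbatim at both termini,
each recognition site implanted at its published position for the
groups that carry it and broken by a single base — the diagnostic SNP —
in the groups that do not, and a rejection-resampling loop that redraws
any background window which would create an unintended site of any
panel enzyme or a stray primer hit. The constraint layout is fixed; the
seed only changes the background, so fragment patterns are identical
across seeds. A post-generation self-check (`checkFixtures()`)
re-derives every constraint with the package's own machinery and
reports per-constraint pass/fail.

These fixtures are constraint-satisfying strings, not biological
mimics: they carry no real codon usage, no phylogenetic signal, and no
within-group polymorphism. Tests passing on them demonstrate that the
machinery is coordinate- and fragment-exact, not that the assay is
robust to the sequence variation of real populations — the screening
step flags within-group pattern disagreement as "unreliable" precisely
because real data can contain it.

Three published numbers cannot be satisfied simultaneously with the
rest of the table, and the generator resolves them in favour of the
cross-checkable fragment sums (single coordinates cannot be validated
against the amplicon total; fragment sums can):

* the shared AciI cross-cut is placed at 547 bp, giving fragments
  (431, 547) — the alternative (430, 548) is inconsistent with
  547 + 431 = 978;
* the SacI footprint starts at column 676 (cut after 680, fragments
  298 + 680), which forces `G` at 676 in mtORF type 1; the column
  remains the type-1 diagnostic site with inverted alleles;
* the Tsp45I footprint sits at 531–535 (cut after 530, fragments
  530 + 448), forcing `A` at column 534 in *P. damicornis*, again with
  inverted alleles.

All three are recorded in the constraints report that
`writeFixtures()` emits.

## Numerical and degenerate-input choices

* Coordinates are 1-based and fully closed on the top strand in every
  report.
* Cuts falling exactly at position 0 or at the sequence end are no-ops
  (they would create empty fragments); duplicate cut positions collapse.
* Fragment lengths are computed from top-strand cut positions only;
  staggered bottom-strand cuts do not alter lengths.
* Amplicons include both primer footprints, which is what makes the
  978 bp total internally consistent with the fragment sums.
* Primer matching requires the 3′-terminal base to pair regardless of
  the allowed mismatch count (polymerase extension needs a paired 3′
  end); degenerate primer positions accept any base in their expansion,
  and template ambiguity codes count as mismatches.
* `classifySequence()` matches branch patterns exactly (tolerance 0):
  in-silico digests are deterministic, so blur is reserved for observed
  bands. A traversal that needs an amplicon the caller did not supply
  emits a classed warning naming it and returns the ambiguous set of
  species still in play.

## Known limitations

* **Strand orientation of terminal fragments.** With the published cut
  coordinates, digesting the reverse complement of a linear sequence
  shifts the two terminal fragments by the overhang width $2t - L$ for
  any palindromic enzyme whose cut is off-centre (SacI, XhoI, AlwNI,
  Tsp45I); interior fragments are invariant, and AciI and NlaIV digests
  are fully strand-symmetric. This is a property of any single-cut
  model that reproduces the published fragment lengths exactly, not an
  implementation artefact; the exact mirror law is pinned by a test.
  On a gel the shift (≤ 5 bp) is far below sizing resolution.
* Complete digestion only: partial-digest laddering, methylation
  sensitivity, star activity and buffer effects are out of scope.
* Circular templates are not digested (the panel's amplicons are
  linear).
* No melting-temperature or primer-dimer model: primer placement is
  purely sequence-combinatorial.

## Problem sizes used in the test suite

The property suites run on randomly drawn sequences of 50–2000 bp:
1,000 draws for length conservation, 25 × 6 enzyme draws for the
strand-mirror law, and 15–20 draws for oracle equivalence against a
position-by-position brute-force matcher, which keeps each suite within
seconds on one CPU while covering every enzyme and both orientations.
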