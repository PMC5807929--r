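# rflpTyper

In-silico design and execution of PCR-RFLP species-identification assays,
built around the six-enzyme panel that distinguishes the six *Pocillopora*
coral species of Hawai‘i.

## The problem

*Pocillopora* corals are notoriously plastic: colony morphology routinely
misleads field identification. The mitochondrial open reading frame
(mtORF) marker separates most lineages, but *P. eydouxi* and
*P. meandrina* share one mtORF haplotype ("type 1") and need a second,
nuclear marker (a 669-bp histone 3 region, "PocHistone"). Instead of
sequencing, each species can be called from the band pattern that a
restriction digest of a PCR amplicon leaves on an agarose gel — a
restriction fragment length polymorphism (RFLP) assay. Designing such an
assay means finding alignment columns where one lineage is fixed for a
private allele, picking a restriction enzyme whose degenerate recognition
site is created or destroyed by that allele, and ordering the assays into
a stepwise identification key.

`rflpTyper` implements that whole workflow:

* **enzyme model + digestion** — IUPAC-degenerate recognition sites with
  strand-specific cut offsets (`GAGCT'C / C'TCGAG` notation), both-strand
  scanning for non-palindromic sites, complete linear digestion, and a
  gel-realism comparison (detection limit `minDetect`, sizing tolerance
  `max(tolBp, tolFrac × length)`),
* **in-silico PCR** — degenerate primer matching with an exact-3′ rule
  and amplicon extraction,
* **diagnostics** — fixed/shared SNP discovery in grouped alignments,
  enzyme screening by the partition of groups each digest induces, codon
  annotation of coding SNPs,
* **keying** — greedy key construction, the published sequential cascade
  (`publishedKey()`), classification of sequences or observed gel bands,
* **fixtures** — a constraint-satisfying synthetic sequence generator
  that reproduces every published coordinate and fragment length of the
  panel, so the pipeline is fully testable offline.

## The assay panel

| Species | Amplicon × enzyme | Diagnostic fragments (bp) |
|---|---|---|
| mtORF type 1 (*P. eydouxi*, *P. meandrina*) | mtORF × SacI | 680, 298 |
| *P. eydouxi* (vs *P. meandrina*) | PocHistone × XhoI | 382, 287 (vs 669 uncut) |
| *P. verrucosa* | mtORF × AciI | 431, 338, 209 |
| *P. ligulata* | mtORF × AlwNI | 511, 467 |
| *P. acuta* / *P. damicornis* | mtORF × NlaIV | 462, 315, 171, 30 |
| *P. damicornis* (vs *P. acuta*) | mtORF × Tsp45I | 530, 448 (vs 978 uncut) |

## Worked example

```r
library(rflpTyper)

fx  <- generateFixtureSet(seed = 1)          # synthetic six-species panel
enz <- defaultEnzymes()

digestDNA(fixtureSeq(fx, "P. verrucosa", "mtORF"), enz[["AciI"]])
#> FragmentPattern: 431, 338, 209 (total 978 bp)

amplify(fixtureSeq(fx, "P. eydouxi", "mtORF"), "FatP6.1", "RORF")
#> Amplicon 978 bp on template:1-978 (FatP6.1 / RORF)

key <- buildKey(fixturePatternTable(fx))
classifySequence(list(mtORF      = fixtureSeq(fx, "P. damicornis", "mtORF"),
                      PocHistone = fixtureSeq(fx, "P. damicornis", "PocHistone")),
                 key)
#> SpeciesCall: P. damicornis
#>   mtORF:NlaIV -> 462, 315, 171, 30
#>   mtORF:Tsp45I -> 530, 448

# scoring a real gel lane: the 30 bp NlaIV band is invisible on 2% agarose
classifyObserved(list("mtORF:NlaIV" = c(460, 320, 170)), fixturePatternTable(fx))
#> SpeciesCall: ambiguous {P. acuta, P. damicornis}
#>   mtORF:NlaIV -> 460, 320, 170
```

The digest says the verrucosa amplicon carries AciI sites cutting after
209 and 547 bp; the key resolves *P. damicornis* in two steps (NlaIV
places the sample in the fine-branched pair, Tsp45I splits it from
*P. acuta*); the gel-scored lane stays ambiguous because NlaIV cannot
separate that pair — exactly why the panel adds the Tsp45I digest.

A command-line interface wraps the same functions:

```sh
rflp-typer fixtures --out fixtures/ --seed 1
rflp-typer digest   --fasta fixtures/mtORF.fasta --enzymes SacI
rflp-typer key-build --fixtures --published --out key.json
rflp-typer identify --key key.json --bands "mtORF:SacI=978"
```

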