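# Shared fixture set for the whole suite (constraints are
# seed-independent; the seed only sets the background composition).
FX <- generateFixtureSet(seed = 101)
FX_TAB <- fixturePatternTable(FX)
ENZ <- defaultEnzymes()

fixtureSample <- function(sp, fx = FX) {
  list(mtORF = fixtureSeq(fx, sp, "mtORF"),
       PocHistone = fixtureSeq(fx, sp, "PocHistone"))
}

# The published per-species fragment multisets of the assay panel.
EXPECTED_PATTERNS <- list(
  "mtORF:SacI" = list(
    "P. eydouxi" = c(680, 298), "P. meandrina" = c(680, 298),
    "P. verrucosa" = 978, "P. ligulata" = 978,
    "P. acuta" = 978, "P. damicornis" = 978),
  "mtORF:AciI" = list(
    "P. eydouxi" = c(547, 431), "P. meandrina" = c(547, 431),
    "P. verrucosa" = c(431, 338, 209), "P. ligulata" = c(547, 431),
    "P. acuta" = c(547, 431), "P. damicornis" = c(547, 431)),
  "mtORF:AlwNI" = list(
    "P. eydouxi" = 978, "P. meandrina" = 978,
    "P. verrucosa" = 978, "P. ligulata" = c(511, 467),
    "P. acuta" = 978, "P. damicornis" = 978),
  "mtORF:NlaIV" = list(
    "P. eydouxi" = c(462, 315, 201), "P. meandrina" = c(462, 315, 201),
    "P. verrucosa" = c(516, 462), "P. ligulata" = c(462, 315, 201),
    "P. acuta" = c(462, 315, 171, 30), "P. damicornis" = c(462, 315, 171, 30)),
  "mtORF:Tsp45I" = list(
    "P. eydouxi" = 978, "P. meandrina" = 978,
    "P. verrucosa" = 978, "P. ligulata" = 978,
    "P. acuta" = 978, "P. damicornis" = c(530, 448)),
  "PocHistone:XhoI" = list(
    "P. eydouxi" = c(382, 287), "P. meandrina" = 669,
    "P. verrucosa" = 669, "P. ligulata" = 669,
    "P. acuta" = 669, "P. damicornis" = 669)
)
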