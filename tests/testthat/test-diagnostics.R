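test_that("fixed diagnostic SNPs are recovered at the designed columns", {
  mtAln <- fixtureAlignment(FX, "mtORF")
  t1 <- findFixedSNPs(mtAln, "mtORF type 1")
  expect_true(676L %in% t1$column)
  expect_equal(t1$type, rep("group-fixed-unique", nrow(t1)))

  ver <- findFixedSNPs(mtAln, "P. verrucosa")
  expect_true(all(c(210L, 211L) %in% ver$column))
  expect_equal(ver$target_allele[ver$column == 210L], "C")
  expect_equal(ver$target_allele[ver$column == 211L], "G")

  lig <- findFixedSNPs(mtAln, "P. ligulata")
  expect_true(462L %in% lig$column)
  expect_equal(lig$target_allele[lig$column == 462L], "C")

  dam <- findFixedSNPs(mtAln, "P. damicornis")
  expect_true(534L %in% dam$column)

  hiAln <- fixtureAlignment(FX, "PocHistone")
  eyd <- findFixedSNPs(hiAln, "P. eydouxi")
  expect_equal(eyd$column, c(279L, 287L))  # the SNP plus the XhoI site break
  expect_equal(eyd$target_allele[eyd$column == 279L], "T")
  expect_equal(eyd$other_alleles[eyd$column == 279L], "G")

  expect_error(findFixedSNPs(mtAln, "P. imaginaria"),
               class = "rflp_invalid_input")
})

test_that("every reported site withstands direct column recounting", {
  mtAln <- fixtureAlignment(FX, "mtORF")
  m <- as.matrix(alnSeqs(mtAln))
  for (g in unique(alnGroups(mtAln))) {
    res <- findFixedSNPs(mtAln, g)
    for (i in seq_len(nrow(res))) {
      col <- m[, res$column[i]]
      inG <- alnGroups(mtAln) == g
      expect_equal(unique(col[inG]), res$target_allele[i])
      expect_false(res$target_allele[i] %in% col[!inG])
    }
  }
})

test_that("no column is diagnostic when the target group is polymorphic everywhere", {
  aln <- groupedAlignment(c(a1 = "ACGT", a2 = "TGCA", b1 = "AAAA", b2 = "AAAA"),
                          c("A", "A", "B", "B"))
  expect_equal(nrow(findFixedSNPs(aln, "A")), 0L)
})

test_that("subset-shared SNPs generalize the single-group scan", {
  fx2 <- generateFixtureSet(seed = 101, includeExtra = TRUE)
  aln <- fixtureAlignment(fx2, "mtORF")
  shared <- findSharedSNPs(aln, c("P. ligulata", "mtORF type 11"))
  expect_true(462L %in% shared$column)
  expect_equal(shared$target_allele[shared$column == 462L], "C")
  expect_equal(unique(shared$type), "shared-by-subset")

  # single-group call is the fixed-SNP scan
  mtAln <- fixtureAlignment(FX, "mtORF")
  expect_equal(findSharedSNPs(mtAln, "P. verrucosa"),
               findFixedSNPs(mtAln, "P. verrucosa"))

  expect_error(findSharedSNPs(mtAln, unique(alnGroups(mtAln))),
               class = "rflp_invalid_input")
  expect_error(findSharedSNPs(mtAln, character()),
               class = "rflp_invalid_input")
})

test_that("gap columns are excluded unless allowed and ambiguity codes are missing data", {
  aln <- groupedAlignment(
    c(a1 = "AC-TA", a2 = "ACNTA", b1 = "AAGTC", b2 = "AAGTC"),
    c("A", "A", "B", "B"))
  res <- findFixedSNPs(aln, "A")
  # column 2: A-group fixed C vs B-group A; column 3 has a gap (skipped);
  # column 5: a1 A, a2 A vs C -> diagnostic
  expect_setequal(res$column, c(2L, 5L))
  resGaps <- findFixedSNPs(aln, "A", allowGaps = TRUE)
  # with gaps allowed, column 3 tallies only a2's N (missing) -> still skipped
  expect_setequal(resGaps$column, c(2L, 5L))
})

test_that("enzyme screening finds the published discriminating assays", {
  mtAln <- fixtureAlignment(FX, "mtORF")
  cands <- screenEnzymes(mtAln, ENZ, ampliconLabel = "mtORF")
  byEnzyme <- setNames(cands, vapply(cands, function(x) x@enzyme, character(1)))

  sac <- byEnzyme[["SacI"]]
  blocks <- sac@partition[order(vapply(sac@partition, length, integer(1)))]
  expect_equal(blocks[[1L]], "mtORF type 1")

  tsp <- byEnzyme[["Tsp45I"]]
  expect_true(any(vapply(tsp@partition, identical, logical(1), "P. damicornis")))

  nla <- byEnzyme[["NlaIV"]]
  expect_equal(length(nla@partition), 3L)

  # candidates are ranked by how many groups they separate
  nblocks <- vapply(cands, function(x) length(x@partition), integer(1))
  expect_true(all(diff(nblocks) <= 0L))
})

test_that("screening a single-group alignment induces only trivial partitions", {
  aln <- groupedAlignment(c(a1 = "AAGAGCTCAA", a2 = "AAGAGCTCAA"), c("A", "A"))
  cands <- screenEnzymes(aln, ENZ)
  expect_true(all(vapply(cands, function(x) length(x@partition), integer(1)) == 1L))
})

test_that("screening patterns agree with digestion of the ungapped records", {
  mtAln <- fixtureAlignment(FX, "mtORF")
  cands <- screenEnzymes(mtAln, ENZ)
  for (cand in cands) {
    for (g in names(cand@patterns)) {
      rec <- which(alnGroups(mtAln) == g)[1L]
      s <- gsub("-", "", as.character(alnSeqs(mtAln)[[rec]]), fixed = TRUE)
      expect_equal(cand@patterns[[g]],
                   fragmentLengths(digestDNA(s, ENZ[[cand@enzyme]])))
    }
  }
})

test_that("a polymorphic extra site marks the group unreliable instead of dropping it", {
  withSite <- paste0(strrep("AT", 10), "GAGCTC", strrep("GA", 10))
  noSite <- paste0(strrep("AT", 10), "GATCTC", strrep("GA", 10))
  aln <- groupedAlignment(
    c(a1 = withSite, a2 = withSite, a3 = noSite, b1 = noSite, b2 = noSite),
    c("A", "A", "A", "B", "B"))
  cands <- screenEnzymes(aln, ENZ["SacI"])
  expect_equal(cands[[1L]]@unreliable, "A")
  # majority pattern (two of three records carry the site) is used
  expect_equal(length(cands[[1L]]@patterns[["A"]]), 2L)
})

test_that("record order never changes diagnostics output", {
  mtAln <- fixtureAlignment(FX, "mtORF")
  set.seed(3)
  perm <- sample(length(alnSeqs(mtAln)))
  shuffled <- groupedAlignment(alnSeqs(mtAln)[perm], alnGroups(mtAln)[perm])
  expect_equal(findFixedSNPs(shuffled, "P. verrucosa"),
               findFixedSNPs(mtAln, "P. verrucosa"))
  c1 <- screenEnzymes(mtAln, ENZ)
  c2 <- screenEnzymes(shuffled, ENZ)
  for (i in seq_along(c1)) {
    expect_equal(c1[[i]]@patterns, c2[[i]]@patterns)
    expect_equal(c1[[i]]@partition, c2[[i]]@partition)
  }
})

test_that("ORF annotation translates the diagnostic codon", {
  orfStart <- 2L
  hist <- fixtureSeq(FX, "P. eydouxi", "PocHistone")
  ann <- annotateCodon(hist, orfStart, 279L, "G")
  expect_equal(ann$position_in_codon, 2L)
  expect_equal(ann$ref_aa, "L")  # leucine in P. eydouxi
  expect_equal(ann$alt_aa, "R")  # arginine in all other species

  # synonymous third-position change
  syn <- annotateCodon("ATGCTT", 1L, 6L, "G")
  expect_equal(syn$position_in_codon, 3L)
  expect_equal(syn$ref_aa, syn$alt_aa)

  expect_error(annotateCodon(hist, 10L, 5L, "A"), class = "rflp_invalid_input")
})
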