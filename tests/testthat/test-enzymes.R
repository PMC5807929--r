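test_that("IUPAC code matching follows the expansion table and rejects bad symbols", {
  expect_true(iupacMatch("S", "G"))
  expect_true(iupacMatch("S", "C"))
  expect_false(iupacMatch("S", "A"))
  expect_true(iupacMatch("N", "T"))
  expect_true(all(iupacMatch("N", c("A", "C", "G", "T"))))
  expect_false(iupacMatch("A", "N"))  # subject ambiguity never matches
  expect_false(iupacMatch("N", "N"))
  expect_error(iupacMatch("X", "A"), class = "rflp_invalid_input")
})

test_that("palindromy is derived from the IUPAC reverse complement", {
  expect_true(isPalindromic("GAGCTC"))
  expect_true(isPalindromic("GTSAC"))   # S is self-complementary
  expect_false(isPalindromic("CCGC"))
  expect_true(isPalindromic(ENZ[["NlaIV"]]))
  expect_false(isPalindromic(ENZ[["AciI"]]))
})

test_that("enzyme construction validates recognition sequences and offsets", {
  e <- restrictionEnzyme("SacI", "GAGCTC", 5, 1)
  expect_s4_class(e, "RestrictionEnzyme")
  expect_error(restrictionEnzyme("bad", "GAXCTC", 1, 1), "IUPAC")
  expect_error(restrictionEnzyme("bad", "GAGCTC", 7, 1), "0\\.\\.6")
  expect_error(restrictionEnzyme("bad", "ACG", 1, 1), "length")
})

test_that("the bundled enzyme table carries the six panel enzymes with their offsets", {
  expect_setequal(names(ENZ),
                  c("SacI", "XhoI", "AciI", "AlwNI", "NlaIV", "Tsp45I"))
  offsets <- t(vapply(ENZ, function(e) c(e@cutTop, e@cutBottom), integer(2)))
  expect_equal(offsets["SacI", ], c(5L, 1L))
  expect_equal(offsets["XhoI", ], c(1L, 5L))
  expect_equal(offsets["AciI", ], c(1L, 3L))
  expect_equal(offsets["AlwNI", ], c(6L, 3L))
  expect_equal(offsets["NlaIV", ], c(3L, 3L))
  expect_equal(offsets["Tsp45I", ], c(0L, 5L))
  expect_equal(recognitionSite(ENZ[["Tsp45I"]]), "GTSAC")
})

test_that("readEnzymeTable rejects malformed tables", {
  bad <- tempfile(fileext = ".tsv")
  writeLines("name\trecognition\n\"Foo\"\t\"GAGCTC\"", bad)
  expect_error(readEnzymeTable(bad), class = "rflp_data_error")
})

test_that("cut sites carry 1-based site starts and transformed cut positions", {
  sites <- findCutSites(fixtureSeq(FX, "P. eydouxi", "mtORF"), ENZ[["SacI"]])
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$site_start, 676L)
  expect_equal(sites$cut_after, 680L)  # cut after the 5th site base
  expect_equal(sites$orientation, "forward")

  expect_equal(nrow(findCutSites("ATATATATAT", ENZ[["SacI"]])), 0L)

  # non-palindromic AciI: a GCGG window is a reverse-orientation site
  rev <- findCutSites("AAAGCGGAAA", ENZ[["AciI"]])
  expect_equal(rev$orientation, "reverse")
  expect_equal(rev$site_start, 4L)
  expect_equal(rev$cut_after, 6L)  # GCG'G: the bottom-strand cut, s - 1 + cutBottom
})

test_that("subject ambiguity codes never create cut sites", {
  expect_equal(nrow(findCutSites("AAGAGCTCAA", ENZ[["SacI"]])), 1L)
  expect_equal(nrow(findCutSites("AAGAGCNCAA", ENZ[["SacI"]])), 0L)
  # degenerate pattern position over subject N is still conservative
  expect_equal(nrow(findCutSites("AAGGNNCCAA", ENZ[["NlaIV"]])), 0L)
})

test_that("overlapping recognition sites are all reported", {
  # CCGCGG: forward CCGC at 1 overlaps reverse GCGG at 3
  sites <- findCutSites("CCGCGG", ENZ[["AciI"]])
  expect_equal(sites$site_start[order(sites$site_start)], c(1L, 3L))
  expect_setequal(sites$orientation, c("forward", "reverse"))
})

test_that("digestion reproduces the panel fragment multisets on fixtures", {
  expect_equal(
    fragmentLengths(digestDNA(fixtureSeq(FX, "P. eydouxi", "mtORF"),
                              ENZ[["SacI"]])),
    c(680L, 298L))
  expect_equal(
    fragmentLengths(digestDNA(fixtureSeq(FX, "P. acuta", "mtORF"),
                              ENZ[["Tsp45I"]])),
    978L)
  expect_equal(
    fragmentLengths(digestDNA(fixtureSeq(FX, "P. verrucosa", "mtORF"),
                              ENZ[["AciI"]])),
    c(431L, 338L, 209L))
  expect_equal(patternTotal(digestDNA(fixtureSeq(FX, "P. verrucosa", "mtORF"),
                                      ENZ[["AciI"]])), 978L)
})

test_that("a digest with no sites returns the whole sequence as one fragment", {
  expect_equal(fragmentLengths(digestDNA("ATATATAT", ENZ[["SacI"]])), 8L)
})

test_that("length is conserved and fragment counts grow with extra enzymes", {
  set.seed(7)
  for (i in 1:60) {
    s <- randomDNA(sample(100:1500, 1))
    picks <- sample(ENZ, sample(1:4, 1))
    pat <- digestDNA(s, picks)
    expect_equal(patternTotal(pat), nchar(s))
    # monotonicity: adding an enzyme never decreases the fragment count
    more <- digestDNA(s, c(picks, ENZ[sample(names(ENZ), 1)]))
    expect_gte(length(fragmentLengths(more)), length(fragmentLengths(pat)))
  }
})

test_that("digestion of the reverse complement follows the mirror law", {
  # Cut coordinates mirror as c' = n - c + (2t - L): a site found at cut c
  # on one strand is found at n - c shifted by the overhang width 2t - L
  # on the other. Enzymes whose top-strand cut is duplex-central
  # (NlaIV), or non-palindromic with the bottom-cut transform (AciI),
  # have 2t = L eff. zero shift, so their digests are fully
  # strand-symmetric; for off-centre palindromic cutters only the two
  # terminal fragments shift, interior fragments are invariant.
  set.seed(11)
  for (i in 1:25) {
    s <- randomDNA(sample(200:1200, 1))
    n <- nchar(s)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (e in ENZ) {
      cuts <- unique(findCutSites(s, e)$cut_after)
      delta <- if (isPalindromic(e)) 2L * e@cutTop - nchar(e@recognition) else 0L
      mirrored <- n - cuts + delta
      mirrored <- sort(unique(mirrored[mirrored > 0L & mirrored < n]))
      expected <- sort(diff(c(0L, mirrored, n)), decreasing = TRUE)
      expect_equal(fragmentLengths(digestDNA(rc, e)), expected,
                   info = enzymeName(e))
    }
  }
})

test_that("digestion is fully strand-symmetric for centre-cutting and non-palindromic enzymes", {
  set.seed(19)
  for (i in 1:25) {
    s <- randomDNA(sample(200:1200, 1))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (e in ENZ[c("NlaIV", "AciI")]) {
      expect_equal(fragmentLengths(digestDNA(rc, e)),
                   fragmentLengths(digestDNA(s, e)),
                   info = enzymeName(e))
    }
  }
})

test_that("site finding agrees with the brute-force oracle on random sequences", {
  set.seed(13)
  for (i in 1:20) {
    s <- randomDNA(sample(50:2000, 1))
    for (e in ENZ) {
      impl <- sort(unique(findCutSites(s, e)$cut_after))
      expect_equal(impl, oracleCuts(s, e@recognition, e@cutTop, e@cutBottom),
                   info = enzymeName(e))
    }
  }
})

test_that("forward-only scanning of palindromic sites equals a dedup'd both-strand scan", {
  set.seed(17)
  palindromes <- Filter(isPalindromic, ENZ)
  expect_gte(length(palindromes), 5L)
  for (i in 1:10) {
    s <- randomDNA(600)
    for (e in palindromes) {
      # oracleCuts always scans both orientations and dedups
      expect_equal(sort(unique(findCutSites(s, e)$cut_after)),
                   oracleCuts(s, e@recognition, e@cutTop, e@cutBottom))
    }
  }
})

test_that("gel distinguishability drops invisible bands and merges within tolerance", {
  expect_true(patternsDistinguishable(c(680, 298), 978, 50, 0, 0.05))
  expect_false(patternsDistinguishable(c(680, 298), c(680, 298), 50, 10, 0.05))
  # 171 vs 201 differ by more than 5% once the 30 bp band is dropped
  expect_true(patternsDistinguishable(c(462, 315, 171, 30), c(462, 315, 201),
                                      50, 0, 0.05))
  # but a 2% sizing blur on near-identical bands hides the difference
  expect_false(patternsDistinguishable(c(462, 315, 201), c(460, 318, 199),
                                       50, 10, 0.05))
  expect_error(patternsDistinguishable(978, 978, 50, -1, 0),
               class = "rflp_invalid_input")
})
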