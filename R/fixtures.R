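#' The six Hawaiian Pocillopora species of the assay panel
#'
#' @return character vector of species labels.
#' @export
pocSpecies <- function() {
  c("P. eydouxi", "P. meandrina", "P. verrucosa",
    "P. ligulata", "P. acuta", "P. damicornis")
}

# Replace IUPAC ambiguity codes by the first base of their expansion
# (used to concretize primer footprints implanted in fixtures).
.concretize <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(c) .IUPAC_EXPAND[[c]][1L], character(1)),
        collapse = "")
}

# ---- declarative fixture constraints -------------------------------------
#
# Every coordinate below is a 1-based top-strand position on the
# amplicon. Each "feature" implants a restriction site (the `present`
# string) for the groups in `presentIn` and a one-base-broken variant
# (`absent`) for everyone else; `absent = NA` means the site is shared
# by all groups. Degenerate site positions are fixed to concrete bases
# chosen not to create sites of the other panel enzymes. The SNP columns
# the assays were designed around fall inside these windows (or are
# implanted separately), so diagnostic-site discovery and digestion stay
# coordinate-consistent.
.fixtureSpec <- function(includeExtra = FALSE) {
  sp <- pocSpecies()
  t1 <- c("P. eydouxi", "P. meandrina")
  extra <- if (includeExtra) "mtORF type 11" else character()
  mtGroups <- c(sp, extra)

  feat <- function(enzyme, start, present, absent, presentIn) {
    list(enzyme = enzyme, start = start, present = present,
         absent = absent, presentIn = presentIn)
  }

  mtORF <- list(
    label = "mtORF", length = 978L,
    fwdPrimer = "FatP6.1", revPrimer = "RORF",
    groups = mtGroups,
    features = list(
      feat("AciI",   209L, "CCGC",      "CTAC",      "P. verrucosa"),
      feat("NlaIV",  313L, "GGTACC",    "AGTACC",    setdiff(mtGroups, "P. verrucosa")),
      feat("NlaIV",  343L, "GGTACC",    "AGTACC",    c("P. acuta", "P. damicornis")),
      feat("AlwNI",  462L, "CAGTATCTG", "TAGTATCTG", c("P. ligulata", extra)),
      feat("NlaIV",  514L, "GGTACC",    NA,          mtGroups),
      feat("Tsp45I", 531L, "GTGAC",     "GTGCC",     "P. damicornis"),
      feat("AciI",   547L, "CCGC",      NA,          mtGroups),
      feat("SacI",   676L, "GAGCTC",    "AAGCTC",    t1)
    ),
    snps = list(),
    orfStart = NA_integer_
  )

  pocHistone <- list(
    label = "PocHistone", length = 669L,
    fwdPrimer = "PocHistoneF", revPrimer = "PocHistoneR",
    groups = sp,
    features = list(
      feat("XhoI", 287L, "CTCGAG", "ATCGAG", "P. eydouxi")
    ),
    # codon context: the diagnostic SNP at 279 is the 2nd position of a
    # leucine codon (CTG) in P. eydouxi; all others carry G, giving
    # arginine (CGG). Frame starts at position 2.
    snps = list(
      list(column = 278L, base = "C", groups = sp),
      list(column = 279L, base = "T", groups = "P. eydouxi"),
      list(column = 279L, base = "G", groups = setdiff(sp, "P. eydouxi")),
      list(column = 280L, base = "G", groups = sp)
    ),
    orfStart = 2L
  )

  list(mtORF = mtORF, PocHistone = pocHistone)
}

# Designed cut positions (top-strand cut_after) per group and enzyme.
.designedCuts <- function(ampSpec, enzymes) {
  cuts <- list()
  for (g in ampSpec$groups) {
    cuts[[g]] <- lapply(enzymes, function(e) integer())
    names(cuts[[g]]) <- names(enzymes)
  }
  for (f in ampSpec$features) {
    e <- enzymes[[f$enzyme]]
    cutAfter <- f$start - 1L + e@cutTop
    for (g in f$presentIn) {
      cuts[[g]][[f$enzyme]] <- sort(c(cuts[[g]][[f$enzyme]], cutAfter))
    }
  }
  cuts
}

# Per-group sequence overrides implied by the amplicon layout (features,
# SNP columns, primer footprints). Returns list(shared = named base vector,
# perGroup = list(group -> named base vector)).
.fixtureOverrides <- function(ampSpec) {
  shared <- character()
  perGroup <- setNames(
    replicate(length(ampSpec$groups), character(), simplify = FALSE),
    ampSpec$groups)

  place <- function(ov, start, bases) {
    chars <- strsplit(bases, "", fixed = TRUE)[[1]]
    ov[as.character(seq.int(start, start + length(chars) - 1L))] <- chars
    ov
  }

  primers <- pocPrimers()
  fwdFoot <- .concretize(primers[[ampSpec$fwdPrimer]])
  revFoot <- .revcomp(.concretize(primers[[ampSpec$revPrimer]]))
  shared <- place(shared, 1L, fwdFoot)
  shared <- place(shared, ampSpec$length - nchar(revFoot) + 1L, revFoot)

  for (f in ampSpec$features) {
    absentIn <- setdiff(ampSpec$groups, f$presentIn)
    if (length(absentIn) == 0L || is.na(f$absent)) {
      shared <- place(shared, f$start, f$present)
      next
    }
    for (g in f$presentIn) perGroup[[g]] <- place(perGroup[[g]], f$start, f$present)
    for (g in absentIn) perGroup[[g]] <- place(perGroup[[g]], f$start, f$absent)
  }
  for (s in ampSpec$snps) {
    if (setequal(s$groups, ampSpec$groups)) {
      shared <- place(shared, s$column, s$base)
    } else {
      for (g in s$groups) perGroup[[g]] <- place(perGroup[[g]], s$column, s$base)
    }
  }
  list(shared = shared, perGroup = perGroup)
}

# Generate one amplicon's per-group sequences: random background under
# the current RNG state, constraint overrides implanted, then
# rejection-resampling of any background window that creates an
# unintended recognition site or a stray primer hit.
.generateAmplicon <- function(ampSpec, enzymes, maxIter = 300L) {
  len <- ampSpec$length
  ov <- .fixtureOverrides(ampSpec)
  bg <- sample(.DNA_BASES, len, replace = TRUE)

  seqs <- lapply(ampSpec$groups, function(g) {
    chars <- bg
    chars[as.integer(names(ov$shared))] <- ov$shared
    pg <- ov$perGroup[[g]]
    if (length(pg)) chars[as.integer(names(pg))] <- pg
    chars
  })
  names(seqs) <- ampSpec$groups

  fixedPos <- sort(unique(c(
    as.integer(names(ov$shared)),
    unlist(lapply(ov$perGroup, function(p) as.integer(names(p))))
  )))
  designed <- .designedCuts(ampSpec, enzymes)
  primers <- pocPrimers()
  fwdSeq <- primers[[ampSpec$fwdPrimer]]
  revSeq <- primers[[ampSpec$revPrimer]]

  for (iter in seq_len(maxIter)) {
    redraw <- integer()
    for (g in ampSpec$groups) {
      s <- paste(seqs[[g]], collapse = "")
      for (en in names(enzymes)) {
        sites <- findCutSites(s, enzymes[[en]])
        want <- designed[[g]][[en]]
        if (!all(want %in% sites$cut_after)) {
          stop(rflpError(
            sprintf("fixture constraint lost: %s site missing in %s %s",
                    en, ampSpec$label, g),
            "rflp_generation_error"))
        }
        bad <- sites[!sites$cut_after %in% want, , drop = FALSE]
        L <- nchar(enzymes[[en]]@recognition)
        for (i in seq_len(nrow(bad))) {
          foot <- seq.int(bad$site_start[i], bad$site_start[i] + L - 1L)
          free <- setdiff(foot, fixedPos)
          if (length(free) == 0L) {
            stop(rflpError(
              sprintf(
                "fixture constraint collision: unintended %s site at %d in %s %s overlaps only fixed positions",
                en, bad$site_start[i], ampSpec$label, g),
              "rflp_generation_error"))
          }
          redraw <- c(redraw, free)
        }
      }
      for (pr in list(list(seq = fwdSeq, strand = "+", pos = 1L),
                      list(seq = revSeq, strand = "-",
                           pos = len - nchar(revSeq) + 1L))) {
        hits <- findPrimerSites(s, pr$seq, 0L)
        hits <- hits[hits$strand == pr$strand, , drop = FALSE]
        stray <- hits[hits$start != pr$pos, , drop = FALSE]
        for (i in seq_len(nrow(stray))) {
          foot <- seq.int(stray$start[i], stray$end[i])
          free <- setdiff(foot, fixedPos)
          if (length(free) == 0L) {
            stop(rflpError(
              sprintf("fixture constraint collision: stray primer hit at %d in %s %s",
                      stray$start[i], ampSpec$label, g),
              "rflp_generation_error"))
          }
          redraw <- c(redraw, free)
        }
      }
    }
    if (length(redraw) == 0L) {
      return(vapply(seqs, paste, character(1), collapse = ""))
    }
    redraw <- unique(redraw)
    bg[redraw] <- sample(.DNA_BASES, length(redraw), replace = TRUE)
    for (g in ampSpec$groups) seqs[[g]][redraw] <- bg[redraw]
  }
  stop(rflpError(
    sprintf("fixture generation for %s did not converge", ampSpec$label),
    "rflp_generation_error"))
}

#' FixtureSet class
#'
#' Synthetic per-species mtORF (978 bp) and PocHistone (669 bp)
#' amplicons satisfying every coordinate and fragment-length constraint
#' of the assay panel, generated by [generateFixtureSet()].
#'
#' @slot sequences list: amplicon label -> named character vector of
#'   sequences (one per group).
#' @slot seed integer seed the set was generated under.
#' @slot info list of generation metadata (`orfStart`, `snpColumns`,
#'   `notes`).
#' @export
setClass("FixtureSet",
  representation(sequences = "list", seed = "integer", info = "list"))

setMethod("show", "FixtureSet", function(object) {
  cat(sprintf("FixtureSet (seed %d):\n", object@seed))
  for (a in names(object@sequences)) {
    s <- object@sequences[[a]]
    cat(sprintf("  %s: %d bp x %d group(s)\n", a, nchar(s[[1L]]), length(s)))
  }
})

#' @describeIn FixtureSet-class one group's amplicon sequence
#'   (character).
#' @param x,object a `FixtureSet`.
#' @param group group/species label.
#' @param amplicon `"mtORF"` or `"PocHistone"`.
#' @export
fixtureSeq <- function(x, group, amplicon) {
  s <- x@sequences[[amplicon]]
  if (is.null(s) || !group %in% names(s)) {
    stop(rflpError(sprintf("no fixture for (%s, %s)", group, amplicon),
                   "rflp_invalid_input"))
  }
  s[[group]]
}

#' Generate the synthetic fixture set
#'
#' Builds six species x two amplicons (plus, optionally, the extra
#' mtORF type 11 haplotype) of constraint-satisfying synthetic
#' sequences: random background composition under `seed`, with primer
#' footprints at both termini, the panel's recognition sites implanted
#' at their published coordinates (or broken by a single diagnostic
#' base in the groups that lack them), and no unintended recognition
#' site of any panel enzyme anywhere. The constraint coordinates are
#' seed-independent; only the background varies.
#'
#' These are constraint-satisfying strings, not biological mimics: they
#' carry none of the codon usage or phylogenetic signal of real mtORF
#' sequences.
#'
#' @param seed integer random seed.
#' @param includeExtra also generate the mtORF type 11 haplotype (shares
#'   the AlwNI site and the 462 C allele with P. ligulata)?
#' @return a [FixtureSet-class].
#' @examples
#' fx <- generateFixtureSet(seed = 1)
#' fragmentLengths(digestDNA(fixtureSeq(fx, "P. verrucosa", "mtORF"),
#'                           defaultEnzymes()[["AciI"]]))
#' @export
generateFixtureSet <- function(seed = 1L, includeExtra = FALSE) {
  seed <- as.integer(seed)
  if (is.na(seed)) {
    stop(rflpError("seed must be an integer", "rflp_invalid_input"))
  }
  set.seed(seed)
  spec <- .fixtureSpec(includeExtra = includeExtra)
  enzymes <- defaultEnzymes()
  sequences <- lapply(spec, .generateAmplicon, enzymes = enzymes)
  if (includeExtra) {
    # give the extra haplotype one private background difference so it
    # is a distinct haplotype (cycled base at a neutral column)
    s <- sequences$mtORF[["mtORF type 11"]]
    i <- 100L
    old <- substr(s, i, i)
    substr(s, i, i) <- .DNA_BASES[match(old, .DNA_BASES) %% 4L + 1L]
    sequences$mtORF[["mtORF type 11"]] <- s
  }
  new("FixtureSet", sequences = sequences, seed = seed,
      info = list(
        orfStart = c(PocHistone = spec$PocHistone$orfStart),
        snpColumns = list(
          mtORF = c(676L, 210L, 211L, 462L, 534L),
          PocHistone = 279L),
        notes = .fixtureNotes()))
}

.fixtureNotes <- function() {
  c(
    "AciI cross-cut fragments fixed at (431, 547) from the shared site at 547 bp (547 + 431 = 978); the alternative reading (430, 548) is inconsistent with the amplicon total.",
    "The GAGCTC footprint starts at 676 (cut after 680, fragments 298 + 680), so mtORF type 1 carries G at column 676 and the other groups carry A; the column remains the type-1 diagnostic site with alleles inverted relative to the assay's original description.",
    "The GTSAC footprint sits at 531..535 (cut after 530, fragments 530 + 448), forcing A at column 534 in P. damicornis; the other groups carry C, keeping 534 the P. damicornis diagnostic column with alleles inverted.",
    "The PocHistone XhoI site (cut 287, fragments 287 + 382) cannot be co-located with the SNP at column 279 under the site's offsets; the SNP and the site are implanted independently."
  )
}

#' Grouped alignment view of a fixture set
#'
#' Returns the fixture amplicons as a gap-free [GroupedAlignment-class].
#' mtORF records are grouped by haplotype lineage (P. eydouxi and
#' P. meandrina share mtORF type 1); PocHistone records are grouped by
#' species. Each group contributes `nPerGroup` records.
#'
#' @param x a [FixtureSet-class].
#' @param amplicon `"mtORF"` or `"PocHistone"`.
#' @param nPerGroup records per sequence (>= 1).
#' @return a [GroupedAlignment-class].
#' @export
fixtureAlignment <- function(x, amplicon = c("mtORF", "PocHistone"),
                             nPerGroup = 2L) {
  amplicon <- match.arg(amplicon)
  s <- x@sequences[[amplicon]]
  groupOf <- function(sp) {
    if (amplicon == "mtORF" && sp %in% c("P. eydouxi", "P. meandrina"))
      "mtORF type 1" else sp
  }
  ids <- character(); seqs <- character(); groups <- character()
  for (sp in names(s)) {
    for (i in seq_len(nPerGroup)) {
      ids <- c(ids, sprintf("%s_%d", gsub("[ .]+", "_", sp), i))
      seqs <- c(seqs, s[[sp]])
      groups <- c(groups, groupOf(sp))
    }
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  groupedAlignment(ss, groups)
}

#' Pattern table of the fixture panel
#'
#' Digests every species' fixture amplicons with the panel assays
#' (mtORF x SacI/AciI/AlwNI/NlaIV/Tsp45I, PocHistone x XhoI) and
#' assembles the resulting [PatternTable-class].
#'
#' @param x a [FixtureSet-class].
#' @param enzymes named list of [RestrictionEnzyme-class].
#' @return a [PatternTable-class] over the six species.
#' @export
fixturePatternTable <- function(x, enzymes = defaultEnzymes()) {
  assays <- list(mtORF = c("SacI", "AciI", "AlwNI", "NlaIV", "Tsp45I"),
                 PocHistone = "XhoI")
  patterns <- list()
  for (amp in names(assays)) {
    for (en in assays[[amp]]) {
      lab <- paste0(amp, ":", en)
      patterns[[lab]] <- lapply(
        setNames(pocSpecies(), pocSpecies()),
        function(sp) fragmentLengths(digestDNA(fixtureSeq(x, sp, amp),
                                               enzymes[[en]])))
    }
  }
  patternTable(patterns, enzymes)
}

#' Verify a fixture set against its design constraints
#'
#' Recomputes, with the package's own digestion and PCR machinery, every
#' constraint the fixtures are supposed to satisfy: amplicon lengths,
#' the full fragment-length matrix of every group under every panel
#' enzyme (including that enzymes with no designed site leave the
#' amplicon uncut), amplifiability with the published primers, recovery
#' of the designed diagnostic SNP columns, and the codon annotation of
#' the PocHistone SNP. Failures are report rows, not errors.
#'
#' @param x a [FixtureSet-class].
#' @param enzymes named list of [RestrictionEnzyme-class].
#' @return `data.frame` with columns `check`, `amplicon`, `group`,
#'   `expected`, `observed`, `pass`; design caveats are attached as
#'   `attr(, "notes")`.
#' @export
checkFixtures <- function(x, enzymes = defaultEnzymes()) {
  spec <- .fixtureSpec(includeExtra = "mtORF type 11" %in%
                         names(x@sequences$mtORF))
  rows <- list()
  add <- function(check, amplicon, group, expected, observed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, amplicon = amplicon, group = group,
      expected = expected, observed = observed,
      pass = identical(expected, observed), stringsAsFactors = FALSE)
  }

  for (amp in names(spec)) {
    ampSpec <- spec[[amp]]
    designed <- .designedCuts(ampSpec, enzymes)
    for (g in names(x@sequences[[amp]])) {
      s <- x@sequences[[amp]][[g]]
      add("length", amp, g, as.character(ampSpec$length),
          as.character(nchar(s)))
      for (en in names(enzymes)) {
        cuts <- sort(designed[[g]][[en]])
        frag <- sort(diff(c(0L, cuts, ampSpec$length)), decreasing = TRUE)
        obs <- fragmentLengths(digestDNA(s, enzymes[[en]]))
        add(paste0("digest:", en), amp, g,
            paste(frag, collapse = ","), paste(obs, collapse = ","))
      }
      amplicon <- tryCatch(
        amplify(s, ampSpec$fwdPrimer, ampSpec$revPrimer),
        error = function(e) NULL)
      add("amplify", amp, g, s,
          if (is.null(amplicon)) "<no product>" else ampliconSeq(amplicon))
    }
  }

  snpFound <- function(aln, groups, column, allele) {
    res <- findSharedSNPs(aln, groups)
    hit <- res[res$column == column, , drop = FALSE]
    nrow(hit) == 1L && hit$target_allele == allele
  }
  mtAln <- fixtureAlignment(x, "mtORF")
  hiAln <- fixtureAlignment(x, "PocHistone")
  snpChecks <- list(
    list(amp = "mtORF", groups = "mtORF type 1", column = 676L, allele = "G"),
    list(amp = "mtORF", groups = "P. verrucosa", column = 210L, allele = "C"),
    list(amp = "mtORF", groups = "P. verrucosa", column = 211L, allele = "G"),
    list(amp = "mtORF", groups = "P. ligulata", column = 462L, allele = "C"),
    list(amp = "mtORF", groups = "P. damicornis", column = 534L, allele = "A"),
    list(amp = "PocHistone", groups = "P. eydouxi", column = 279L, allele = "T")
  )
  if ("mtORF type 11" %in% alnGroups(mtAln)) {
    snpChecks[[4L]]$groups <- c("P. ligulata", "mtORF type 11")
  }
  for (sc in snpChecks) {
    aln <- if (sc$amp == "mtORF") mtAln else hiAln
    add(sprintf("snp:%d", sc$column), sc$amp,
        paste(sc$groups, collapse = "+"), "recovered",
        if (snpFound(aln, sc$groups, sc$column, sc$allele))
          "recovered" else "missing")
  }

  cod <- annotateCodon(fixtureSeq(x, "P. eydouxi", "PocHistone"),
                       x@info$orfStart[["PocHistone"]], 279L, "G")
  add("codon:279", "PocHistone", "P. eydouxi", "2/L/R",
      paste(cod$position_in_codon, cod$ref_aa, cod$alt_aa, sep = "/"))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "notes") <- x@info$notes
  out
}

#' Write a fixture set to disk
#'
#' Writes one multi-FASTA per amplicon (header: `id group`), a
#' two-column groups TSV and the constraints report as JSON.
#'
#' @param x a [FixtureSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFixtures <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  groupRows <- list()
  for (amp in names(x@sequences)) {
    aln <- fixtureAlignment(x, amp, nPerGroup = 1L)
    ss <- alnSeqs(aln)
    names(ss) <- paste(names(ss), alnGroups(aln))
    p <- file.path(dir, paste0(amp, ".fasta"))
    Biostrings::writeXStringSet(ss, p)
    paths <- c(paths, p)
    groupRows[[amp]] <- data.frame(
      id = vapply(strsplit(names(ss), " "), `[`, character(1), 1L),
      group = alnGroups(aln), stringsAsFactors = FALSE)
  }
  gp <- file.path(dir, "groups.tsv")
  write.table(do.call(rbind, groupRows), gp, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths <- c(paths, gp)

  rep <- checkFixtures(x)
  cp <- file.path(dir, "constraints.json")
  jsonlite::write_json(
    list(seed = x@seed, notes = attr(rep, "notes"),
         all_pass = all(rep$pass), checks = rep),
    cp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, cp)
  invisible(paths)
}
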