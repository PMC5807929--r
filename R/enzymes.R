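#' RestrictionEnzyme class
#'
#' Models a (possibly degenerate) type II restriction enzyme as a
#' recognition sequence in IUPAC code plus strand-specific cut offsets.
#' `cutTop` is the number of recognition bases 5' of the top-strand cut
#' for a forward-orientation match; `cutBottom` is the same quantity read
#' on the bottom strand 5'->3'. The apostrophe notation used on enzyme
#' datasheets maps directly: SacI GAGCT'C has `cutTop = 5`, and its
#' bottom strand C'TCGAG gives `cutBottom = 1`.
#'
#' @slot name enzyme name, e.g. `"SacI"`.
#' @slot recognition IUPAC recognition sequence (length >= 4).
#' @slot cutTop integer in `0..nchar(recognition)`.
#' @slot cutBottom integer in `0..nchar(recognition)`.
#' @export
setClass("RestrictionEnzyme",
  representation(
    name = "character",
    recognition = "character",
    cutTop = "integer",
    cutBottom = "integer"
  )
)

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  rec <- object@recognition
  if (length(rec) != 1L || nchar(rec) < 4L)
    msg <- c(msg, "recognition sequence must have length >= 4")
  else if (!.isIupac(rec))
    msg <- c(msg, "recognition sequence contains non-IUPAC characters")
  L <- nchar(rec)
  for (s in c("cutTop", "cutBottom")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0L || v > L)
      msg <- c(msg, sprintf("%s must be an integer in 0..%d", s, L))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RestrictionEnzyme
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition sequence.
#' @param cutTop,cutBottom cut offsets (see [RestrictionEnzyme-class]).
#' @return a [RestrictionEnzyme-class] object.
#' @examples
#' restrictionEnzyme("SacI", "GAGCTC", 5, 1)
#' @export
restrictionEnzyme <- function(name, recognition, cutTop, cutBottom) {
  new("RestrictionEnzyme",
      name = as.character(name),
      recognition = toupper(as.character(recognition)),
      cutTop = as.integer(cutTop),
      cutBottom = as.integer(cutBottom))
}

#' @describeIn RestrictionEnzyme-class enzyme name accessor.
#' @param x,object a `RestrictionEnzyme`.
#' @export
enzymeName <- function(x) x@name

#' @describeIn RestrictionEnzyme-class recognition sequence accessor.
#' @export
recognitionSite <- function(x) x@recognition

#' Is a recognition site palindromic?
#'
#' A site is palindromic when it equals its own IUPAC reverse complement
#' (GAGCTC is; GTSAC is, since S is self-complementary; CCGC is not).
#' Non-palindromic enzymes require scanning both strands.
#'
#' @param x a [RestrictionEnzyme-class] or an IUPAC string.
#' @return logical scalar.
#' @export
isPalindromic <- function(x) {
  rec <- if (is(x, "RestrictionEnzyme")) x@recognition else toupper(x)
  identical(.revcomp(rec), rec)
}

setMethod("show", "RestrictionEnzyme", function(object) {
  L <- nchar(object@recognition)
  top <- paste0(substr(object@recognition, 1, object@cutTop), "'",
                substr(object@recognition, object@cutTop + 1L, L))
  bottom <- .revcomp(object@recognition)
  bottom <- paste0(substr(bottom, 1, object@cutBottom), "'",
                   substr(bottom, object@cutBottom + 1L, L))
  cat(sprintf("RestrictionEnzyme %s: %s / %s%s\n",
              object@name, top, bottom,
              if (isPalindromic(object)) " (palindromic)" else ""))
})

#' Read a restriction-enzyme table
#'
#' Reads a REBASE-style tab-separated table with columns `name`,
#' `recognition`, `cut_top`, `cut_bottom`. Lines starting with `#` are
#' comments.
#'
#' @param path path to the TSV file.
#' @return named list of [RestrictionEnzyme-class] objects.
#' @export
readEnzymeTable <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_top", "cut_bottom")
  if (!all(need %in% names(tab))) {
    stop(rflpError(
      sprintf("enzyme table must have columns: %s", paste(need, collapse = ", ")),
      "rflp_data_error"))
  }
  enz <- lapply(seq_len(nrow(tab)), function(i) {
    restrictionEnzyme(tab$name[i], tab$recognition[i],
                      tab$cut_top[i], tab$cut_bottom[i])
  })
  setNames(enz, tab$name)
}

#' The bundled six-enzyme assay panel
#'
#' Returns the enzymes of the Pocillopora mtORF/PocHistone RFLP panel:
#' SacI GAGCT'C, XhoI C'TCGAG, AciI C'CGC, AlwNI CAGNNN'CTG,
#' NlaIV GGN'NCC and Tsp45I 'GTSAC.
#'
#' @return named list of [RestrictionEnzyme-class] objects.
#' @examples
#' defaultEnzymes()[["SacI"]]
#' @export
defaultEnzymes <- function() {
  path <- system.file("extdata", "enzymes.tsv", package = "rflpTyper",
                      mustWork = TRUE)
  readEnzymeTable(path)
}

#' Locate recognition sites of an enzyme on a linear sequence
#'
#' Scans the top strand for forward-orientation matches of the enzyme's
#' recognition sequence and, for non-palindromic enzymes, also for
#' matches of its reverse complement. Degenerate positions in the
#' recognition sequence expand by the IUPAC table; ambiguity codes in the
#' subject sequence never match (no cut is predicted from an uncertain
#' base). Overlapping matches are all reported.
#'
#' Coordinates are 1-based on the top strand. `cut_after` is the position
#' after which the top strand is cleaved: for a forward match starting at
#' `s`, `cut_after = s - 1 + cutTop`. For a reverse-complement match the
#' only cleavage of the top strand is the enzyme's bottom-strand cut,
#' which sits `cutBottom` aligned bases from the left edge of the
#' footprint, so `cut_after = s - 1 + cutBottom`; this is also the unique
#' transform under which digestion is invariant to reverse-complementing
#' the input. A footprint matching both orientations (possible only for
#' degenerate non-palindromic sites) is reported once, as forward.
#'
#' @param sequence nucleotide string or `DNAString` (linear).
#' @param enzyme a [RestrictionEnzyme-class].
#' @return `data.frame` with columns `site_start`, `orientation`
#'   (`"forward"`/`"reverse"`) and `cut_after`, sorted by `cut_after`.
#' @examples
#' sacI <- defaultEnzymes()[["SacI"]]
#' findCutSites("AAGAGCTCAA", sacI)
#' @export
findCutSites <- function(sequence, enzyme) {
  seq <- .asSeqChar(sequence)
  if (!nzchar(seq)) {
    stop(rflpError("sequence must be non-empty", "rflp_invalid_input"))
  }
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  subj <- Biostrings::DNAString(seq)
  L <- nchar(enzyme@recognition)

  scan <- function(pattern, cutOffset, orientation) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subj,
                                  fixed = "subject")
    starts <- Biostrings::start(m)
    if (length(starts) == 0L) return(NULL)
    # conservative rule: drop windows containing subject ambiguity codes
    ok <- vapply(starts, function(s) {
      win <- substr(seq, s, s + L - 1L)
      all(strsplit(win, "", fixed = TRUE)[[1]] %in% .DNA_BASES)
    }, logical(1))
    starts <- starts[ok]
    if (length(starts) == 0L) return(NULL)
    data.frame(site_start = starts,
               orientation = orientation,
               cut_after = starts - 1L + cutOffset,
               stringsAsFactors = FALSE)
  }

  hits <- scan(enzyme@recognition, enzyme@cutTop, "forward")
  if (!isPalindromic(enzyme)) {
    rev <- scan(.revcomp(enzyme@recognition), enzyme@cutBottom, "reverse")
    if (!is.null(rev) && !is.null(hits)) {
      rev <- rev[!rev$site_start %in% hits$site_start, , drop = FALSE]
    }
    hits <- rbind(hits, rev)
  }
  if (is.null(hits)) {
    hits <- data.frame(site_start = integer(), orientation = character(),
                       cut_after = integer(), stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$cut_after, hits$site_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' FragmentPattern class
#'
#' The multiset of fragment lengths produced by a complete linear digest,
#' stored sorted in decreasing order (the order bands appear down a gel
#' lane).
#'
#' @slot lengths integer vector of positive fragment lengths, decreasing.
#' @export
setClass("FragmentPattern", representation(lengths = "integer"))

setValidity("FragmentPattern", function(object) {
  if (length(object@lengths) == 0L) return("at least one fragment required")
  if (any(object@lengths <= 0L)) return("fragment lengths must be positive")
  if (is.unsorted(rev(object@lengths))) return("lengths must be decreasing")
  TRUE
})

#' @describeIn FragmentPattern-class constructor; sorts the lengths.
#' @param lengths numeric vector of fragment lengths.
#' @export
fragmentPattern <- function(lengths) {
  new("FragmentPattern", lengths = sort(as.integer(lengths), decreasing = TRUE))
}

#' @describeIn FragmentPattern-class fragment lengths (decreasing integer
#'   vector).
#' @param x,object a `FragmentPattern`.
#' @export
fragmentLengths <- function(x) {
  if (is(x, "FragmentPattern")) x@lengths else sort(as.integer(x), decreasing = TRUE)
}

#' @describeIn FragmentPattern-class total digested length (sum of
#'   fragments).
#' @export
patternTotal <- function(x) sum(fragmentLengths(x))

setMethod("show", "FragmentPattern", function(object) {
  cat(sprintf("FragmentPattern: %s (total %d bp)\n",
              paste(object@lengths, collapse = ", "), sum(object@lengths)))
})

#' Complete in-silico digestion of a linear sequence
#'
#' Cuts the sequence at every distinct top-strand cut position of the
#' given enzyme(s) (complete digestion, no partials) and returns the
#' fragment-length multiset. Fragment lengths are computed from
#' top-strand cut positions only; staggered bottom-strand cuts do not
#' change fragment lengths. Cuts falling at position 0 or at the sequence
#' end are no-ops (they would produce empty fragments).
#'
#' @param sequence nucleotide string or `DNAString`.
#' @param enzymes a single [RestrictionEnzyme-class] or a list of them.
#' @return a [FragmentPattern-class].
#' @examples
#' digestDNA("AAGAGCTCAA", defaultEnzymes()[["SacI"]])
#' @export
digestDNA <- function(sequence, enzymes) {
  seq <- .asSeqChar(sequence)
  if (is(enzymes, "RestrictionEnzyme")) enzymes <- list(enzymes)
  cuts <- unlist(lapply(enzymes, function(e) findCutSites(seq, e)$cut_after))
  n <- nchar(seq)
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0L & cuts < n]
  fragmentPattern(diff(c(0L, cuts, n)))
}

# Bands visible on a gel: drop fragments below the detection limit,
# return sorted decreasing.
.visibleBands <- function(lengths, minDetect) {
  lengths <- fragmentLengths(lengths)
  sort(lengths[lengths >= minDetect], decreasing = TRUE)
}

# Can two band lists be superposed within the sizing tolerance?
# Both must already be sorted decreasing. The tolerance for a band pair
# is max(tolBp, tolFrac * larger band).
.bandsMatch <- function(a, b, tolBp, tolFrac) {
  if (length(a) != length(b)) return(FALSE)
  if (length(a) == 0L) return(TRUE)
  tol <- pmax(tolBp, tolFrac * pmax(a, b))
  all(abs(a - b) <= tol)
}

#' Are two fragment patterns distinguishable on a gel?
#'
#' Compares two fragment patterns under a gel-realism model: fragments
#' shorter than `minDetect` are invisible, and two bands co-migrate when
#' their lengths differ by at most `max(tolBp, tolFrac * length)`.
#' Patterns are indistinguishable when the visible bands can be matched
#' one-to-one within tolerance.
#'
#' The defaults (0/0/0) give the exact comparison appropriate for purely
#' in-silico patterns; for scoring real 2% agarose gels, `minDetect = 50`,
#' `tolBp = 10`, `tolFrac = 0.05` are realistic.
#'
#' @param a,b [FragmentPattern-class] objects or numeric length vectors.
#' @param minDetect smallest scorable band, bp.
#' @param tolBp absolute sizing tolerance, bp.
#' @param tolFrac relative sizing tolerance (fraction of band length).
#' @return `TRUE` if the patterns are distinguishable.
#' @examples
#' patternsDistinguishable(c(680, 298), 978)
#' @export
patternsDistinguishable <- function(a, b, minDetect = 0, tolBp = 0, tolFrac = 0) {
  if (tolBp < 0 || tolFrac < 0 || minDetect < 0) {
    stop(rflpError("tolerances and minDetect must be non-negative",
                   "rflp_invalid_input"))
  }
  va <- .visibleBands(a, minDetect)
  vb <- .visibleBands(b, minDetect)
  !.bandsMatch(va, vb, tolBp, tolFrac)
}
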