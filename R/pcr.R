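#' The built-in primer set
#'
#' Named IUPAC primer sequences (5'->3') for the two amplicons of the
#' Pocillopora RFLP panel: FatP6.1/RORF amplify the mitochondrial open
#' reading frame (mtORF) and PocHistoneF/PocHistoneR the histone 3
#' region.
#'
#' @return named character vector of primer sequences.
#' @examples
#' pocPrimers()[["FatP6.1"]]
#' @export
pocPrimers <- function() {
  c(
    "FatP6.1"     = "TTTGGGSATTCGTTTAGCAG",
    "RORF"        = "SCCAATATGTTAAACASCATGTCA",
    "PocHistoneF" = "ATTCAGTCTCACTCACTCACTCAC",
    "PocHistoneR" = "TATCTTCGAACAGACCCACCAAAT"
  )
}

# Resolve a primer given as a built-in name or a raw IUPAC sequence.
# Returns c(name, sequence).
.resolvePrimer <- function(primer) {
  builtin <- pocPrimers()
  if (length(primer) != 1L || !is.character(primer)) {
    stop(rflpError("primer must be a single string", "rflp_invalid_input"))
  }
  nm <- names(primer)
  if (primer %in% names(builtin)) {
    return(c(name = primer, sequence = unname(builtin[[primer]])))
  }
  seq <- toupper(primer)
  if (!.isIupac(seq)) {
    stop(rflpError(sprintf("primer '%s' is not a valid IUPAC sequence", primer),
                   "rflp_invalid_input"))
  }
  c(name = if (!is.null(nm) && nzchar(nm)) nm else seq, sequence = seq)
}

#' Find degenerate primer binding sites on a template
#'
#' Slides the primer along both strands of the template counting
#' IUPAC-incompatible positions. A primer position is compatible with a
#' template base when the base lies in the IUPAC expansion of the primer
#' code (degenerate primer positions match any base they expand to);
#' ambiguity codes in the template always count as mismatches. The
#' 3'-terminal primer base must match regardless of `maxMismatch`, since
#' polymerase extension requires a paired 3' end.
#'
#' @param template nucleotide string or `DNAString`.
#' @param primer primer sequence (IUPAC) or the name of a built-in primer
#'   (see [pocPrimers()]).
#' @param maxMismatch maximum number of mismatched positions (>= 0).
#' @return `data.frame` with columns `start`, `end` (1-based footprint on
#'   the top strand), `strand` (`"+"` forward, `"-"` reverse) and
#'   `mismatches`.
#' @export
findPrimerSites <- function(template, primer, maxMismatch = 0) {
  tmpl <- .asSeqChar(template, "template")
  pr <- .resolvePrimer(primer)
  pseq <- pr[["sequence"]]
  if (maxMismatch < 0) {
    stop(rflpError("maxMismatch must be >= 0", "rflp_invalid_input"))
  }
  n <- nchar(tmpl)
  m <- nchar(pseq)
  if (m > n) {
    stop(rflpError("primer is longer than the template", "rflp_invalid_input"))
  }
  tchars <- strsplit(tmpl, "", fixed = TRUE)[[1]]

  scanStrand <- function(codes, threePrimeAt) {
    nw <- n - m + 1L
    mism <- integer(nw)
    compat3 <- rep(TRUE, nw)
    for (j in seq_len(m)) {
      ok <- iupacMatch(codes[j], tchars[seq.int(j, j + nw - 1L)])
      mism <- mism + !ok
      if (j == threePrimeAt) compat3 <- ok
    }
    which(mism <= maxMismatch & compat3)
  }

  pcodes <- strsplit(pseq, "", fixed = TRUE)[[1]]
  fwd <- scanStrand(pcodes, m)
  # reverse-strand binding: footprint on the top strand is the reverse
  # complement of the primer; the primer's 3' end sits at the footprint's
  # 5' (left) edge
  rcodes <- strsplit(.revcomp(pseq), "", fixed = TRUE)[[1]]
  rev <- scanStrand(rcodes, 1L)

  countMism <- function(codes, starts) {
    vapply(starts, function(s) {
      sum(!iupacMatch(codes, tchars[seq.int(s, s + m - 1L)]))
    }, integer(1))
  }
  out <- rbind(
    if (length(fwd)) data.frame(start = fwd, end = fwd + m - 1L, strand = "+",
                                mismatches = countMism(pcodes, fwd),
                                stringsAsFactors = FALSE),
    if (length(rev)) data.frame(start = rev, end = rev + m - 1L, strand = "-",
                                mismatches = countMism(rcodes, rev),
                                stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Amplicon class
#'
#' A predicted PCR product: the template interval spanning both primer
#' footprints, inclusive.
#'
#' @slot sequence amplicon sequence (top strand of the template).
#' @slot templateId template identifier.
#' @slot start,end 1-based inclusive template coordinates.
#' @slot fwdPrimer,revPrimer primer names.
#' @export
setClass("Amplicon",
  representation(sequence = "character", templateId = "character",
                 start = "integer", end = "integer",
                 fwdPrimer = "character", revPrimer = "character"))

setValidity("Amplicon", function(object) {
  if (object@end - object@start + 1L != nchar(object@sequence))
    return("end - start + 1 must equal the sequence length")
  TRUE
})

#' @describeIn Amplicon-class amplicon sequence as a character string.
#' @param x,object an `Amplicon`.
#' @export
ampliconSeq <- function(x) x@sequence

#' @describeIn Amplicon-class amplicon length in bp.
#' @export
ampliconLength <- function(x) nchar(x@sequence)

setMethod("show", "Amplicon", function(object) {
  cat(sprintf("Amplicon %d bp on %s:%d-%d (%s / %s)\n",
              nchar(object@sequence), object@templateId,
              object@start, object@end, object@fwdPrimer, object@revPrimer))
})

#' In-silico PCR: extract the predicted amplicon
#'
#' Requires exactly one forward-strand hit of the forward primer and one
#' reverse-strand hit of the reverse primer, with the forward footprint
#' 5' of the reverse footprint. The product includes both primer
#' footprints (so amplifying a sequence that is itself the amplicon
#' returns the full input).
#'
#' @param template nucleotide string or `DNAString`.
#' @param fwd,rev primer sequences or built-in primer names.
#' @param maxMismatch maximum mismatches per primer (3' base always
#'   exact).
#' @param templateId identifier recorded on the product.
#' @return an [Amplicon-class].
#' @examples
#' fx <- generateFixtureSet(seed = 1)
#' amplify(fixtureSeq(fx, "P. eydouxi", "mtORF"), "FatP6.1", "RORF")
#' @export
amplify <- function(template, fwd, rev, maxMismatch = 0,
                    templateId = "template") {
  tmpl <- .asSeqChar(template, "template")
  f <- .resolvePrimer(fwd)
  r <- .resolvePrimer(rev)
  fh <- findPrimerSites(tmpl, f[["sequence"]], maxMismatch)
  fh <- fh[fh$strand == "+", , drop = FALSE]
  rh <- findPrimerSites(tmpl, r[["sequence"]], maxMismatch)
  rh <- rh[rh$strand == "-", , drop = FALSE]
  if (nrow(fh) == 0L || nrow(rh) == 0L) {
    stop(rflpError(
      sprintf("no amplification: %d forward hit(s) of %s, %d reverse hit(s) of %s",
              nrow(fh), f[["name"]], nrow(rh), r[["name"]]),
      "rflp_no_amplification"))
  }
  if (nrow(fh) > 1L || nrow(rh) > 1L) {
    pairs <- expand.grid(f = seq_len(nrow(fh)), r = seq_len(nrow(rh)))
    desc <- apply(pairs, 1L, function(p) {
      sprintf("%s@%d..%s@%d", f[["name"]], fh$start[p[1]],
              r[["name"]], rh$end[p[2]])
    })
    stop(rflpError(
      sprintf("multiple products possible: %s", paste(desc, collapse = "; ")),
      "rflp_multiple_products"))
  }
  if (rh$start <= fh$end) {
    stop(rflpError(
      "no amplification: reverse-primer footprint is not 3' of the forward footprint",
      "rflp_no_amplification"))
  }
  new("Amplicon",
      sequence = substr(tmpl, fh$start, rh$end),
      templateId = as.character(templateId),
      start = as.integer(fh$start), end = as.integer(rh$end),
      fwdPrimer = f[["name"]], revPrimer = r[["name"]])
}
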