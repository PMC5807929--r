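#' Find alignment columns fixed for a subset of groups
#'
#' Scans every alignment column for sites where all records of the given
#' group subset carry one and the same concrete base while every record
#' outside the subset carries a different base. These are the fixed
#' diagnostic SNPs on which a discriminating restriction assay can be
#' built.
#'
#' Columns containing a gap in any record are excluded unless
#' `allowGaps = TRUE` (indels shift restriction coordinates
#' unpredictably). Records with an ambiguity code at a column are treated
#' as missing data for that column's tally rather than as mismatches; a
#' column is only called when at least one record remains on each side.
#'
#' @param aln a [GroupedAlignment-class].
#' @param groups character vector of group labels: a non-empty proper
#'   subset of the alignment's groups.
#' @param allowGaps keep columns containing gaps?
#' @return `data.frame` with columns `column` (1-based alignment
#'   coordinate), `target_allele`, `other_alleles` (comma-separated) and
#'   `type` (`"group-fixed-unique"` for a single target group,
#'   `"shared-by-subset"` otherwise).
#' @seealso [findFixedSNPs()] for the single-group case.
#' @export
findSharedSNPs <- function(aln, groups, allowGaps = FALSE) {
  stopifnot(is(aln, "GroupedAlignment"))
  all_groups <- unique(aln@groups)
  groups <- unique(as.character(groups))
  if (length(groups) == 0L) {
    stop(rflpError("group subset must be non-empty", "rflp_invalid_input"))
  }
  unknown <- setdiff(groups, all_groups)
  if (length(unknown)) {
    stop(rflpError(sprintf("unknown group(s): %s",
                           paste(unknown, collapse = ", ")),
                   "rflp_invalid_input"))
  }
  if (length(setdiff(all_groups, groups)) == 0L) {
    stop(rflpError("group subset must be a proper subset of the alignment groups",
                   "rflp_invalid_input"))
  }
  m <- .alnMatrix(aln)
  inSet <- aln@groups %in% groups
  type <- if (length(groups) == 1L) "group-fixed-unique" else "shared-by-subset"

  res <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (!allowGaps && any(col == "-")) return(NULL)
    concrete <- col %in% .DNA_BASES
    tin <- col[inSet & concrete]
    tout <- col[!inSet & concrete]
    if (length(tin) == 0L || length(tout) == 0L) return(NULL)
    allele <- unique(tin)
    if (length(allele) != 1L) return(NULL)
    others <- sort(unique(tout))
    if (allele %in% others) return(NULL)
    data.frame(column = j, target_allele = allele,
               other_alleles = paste(others, collapse = ","),
               type = type, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(column = integer(), target_allele = character(),
                      other_alleles = character(), type = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Find fixed diagnostic SNPs for one group
#'
#' Convenience wrapper around [findSharedSNPs()] for a single target
#' group: every column where all target-group records carry one base and
#' all other records carry different bases.
#'
#' @inheritParams findSharedSNPs
#' @param group a single group label present in the alignment.
#' @return as [findSharedSNPs()], with `type = "group-fixed-unique"`.
#' @examples
#' fx <- generateFixtureSet(seed = 1)
#' aln <- fixtureAlignment(fx, "mtORF")
#' findFixedSNPs(aln, "mtORF type 1")
#' @export
findFixedSNPs <- function(aln, group, allowGaps = FALSE) {
  if (length(group) != 1L) {
    stop(rflpError("exactly one target group expected", "rflp_invalid_input"))
  }
  findSharedSNPs(aln, group, allowGaps = allowGaps)
}

#' AssayCandidate class
#'
#' The outcome of screening one enzyme against one amplicon's grouped
#' alignment: the per-group digest patterns and the partition of groups
#' they induce (groups falling in the same block are indistinguishable
#' on a gel).
#'
#' @slot amplicon amplicon label.
#' @slot enzyme enzyme name.
#' @slot patterns named list, group -> decreasing integer vector of
#'   fragment lengths (the group's consensus pattern).
#' @slot partition list of character vectors: blocks of groups with
#'   indistinguishable patterns.
#' @slot unreliable group labels whose records disagree internally on
#'   the digest pattern.
#' @export
setClass("AssayCandidate",
  representation(amplicon = "character", enzyme = "character",
                 patterns = "list", partition = "list",
                 unreliable = "character"))

setMethod("show", "AssayCandidate", function(object) {
  cat(sprintf("AssayCandidate %s x %s: %d block(s)\n",
              object@amplicon, object@enzyme, length(object@partition)))
  for (b in object@partition) {
    pat <- object@patterns[[b[1L]]]
    cat(sprintf("  {%s}: %s\n", paste(b, collapse = ", "),
                paste(pat, collapse = ", ")))
  }
  if (length(object@unreliable)) {
    cat("  unreliable:", paste(object@unreliable, collapse = ", "), "\n")
  }
})

# Partition labelled patterns into blocks of pairwise-indistinguishable
# patterns. Greedy over groups in the given order: a group joins the
# first block whose representative it cannot be told apart from.
.partitionPatterns <- function(patterns, minDetect, tolBp, tolFrac) {
  blocks <- list()
  for (g in names(patterns)) {
    placed <- FALSE
    for (i in seq_along(blocks)) {
      rep <- patterns[[blocks[[i]][1L]]]
      if (!patternsDistinguishable(patterns[[g]], rep, minDetect, tolBp, tolFrac)) {
        blocks[[i]] <- c(blocks[[i]], g)
        placed <- TRUE
        break
      }
    }
    if (!placed) blocks[[length(blocks) + 1L]] <- g
  }
  blocks
}

#' Screen an enzyme panel for discriminating digest patterns
#'
#' Digests each record's ungapped sequence with every enzyme and asks,
#' per enzyme, which groups the resulting band patterns can tell apart.
#' A group whose records disagree on the pattern (for example a
#' polymorphic extra site segregating within the group) is flagged
#' `unreliable` rather than dropped; its majority pattern is used.
#'
#' @param aln a [GroupedAlignment-class] of amplicon sequences.
#' @param enzymes named list of [RestrictionEnzyme-class] objects.
#' @param minDetect,tolBp,tolFrac gel-realism parameters, see
#'   [patternsDistinguishable()].
#' @param ampliconLabel label recorded on the candidates.
#' @return list of [AssayCandidate-class], sorted by decreasing number of
#'   partition blocks, then enzyme name.
#' @export
screenEnzymes <- function(aln, enzymes = defaultEnzymes(), minDetect = 0,
                          tolBp = 0, tolFrac = 0, ampliconLabel = "amplicon") {
  stopifnot(is(aln, "GroupedAlignment"))
  groups <- sort(unique(aln@groups))
  ungapped <- gsub("-", "", as.character(aln@seqs), fixed = TRUE)

  cands <- lapply(names(enzymes), function(en) {
    enz <- enzymes[[en]]
    recPatterns <- lapply(ungapped, function(s) fragmentLengths(digestDNA(s, enz)))
    patterns <- list()
    unreliable <- character()
    for (g in groups) {
      pats <- recPatterns[aln@groups == g]
      keys <- vapply(pats, paste, character(1), collapse = ",")
      tab <- sort(table(keys), decreasing = TRUE)
      patterns[[g]] <- pats[[match(names(tab)[1L], keys)]]
      if (length(tab) > 1L) unreliable <- c(unreliable, g)
    }
    new("AssayCandidate", amplicon = ampliconLabel, enzyme = en,
        patterns = patterns,
        partition = .partitionPatterns(patterns, minDetect, tolBp, tolFrac),
        unreliable = unreliable)
  })
  nb <- vapply(cands, function(x) length(x@partition), integer(1))
  cands[order(-nb, vapply(cands, function(x) x@enzyme, character(1)))]
}

#' Annotate a SNP within an open reading frame
#'
#' Places an alignment/sequence position into the codon structure of an
#' ORF and translates the reference and alternate codons with the
#' standard genetic code.
#'
#' @param sequence ungapped nucleotide string or `DNAString` carrying the
#'   reference allele.
#' @param orfStart 1-based position where the reading frame begins.
#' @param position 1-based position of the SNP (must be >= `orfStart`).
#' @param altBase alternate allele (concrete base).
#' @return `data.frame` with `codon_index`, `position_in_codon`,
#'   `ref_codon`, `ref_aa`, `alt_codon`, `alt_aa`.
#' @examples
#' annotateCodon("ATGCTGTAA", 1, 5, "G")  # CTG (L) -> CGG (R)
#' @export
annotateCodon <- function(sequence, orfStart, position, altBase) {
  seq <- .asSeqChar(sequence)
  orfStart <- as.integer(orfStart)
  position <- as.integer(position)
  altBase <- toupper(as.character(altBase))
  if (position < orfStart) {
    stop(rflpError("position lies upstream of the reading frame start",
                   "rflp_invalid_input"))
  }
  if (!altBase %in% .DNA_BASES) {
    stop(rflpError("altBase must be a concrete base (A/C/G/T)",
                   "rflp_invalid_input"))
  }
  offset <- position - orfStart
  codonIndex <- offset %/% 3L + 1L
  posInCodon <- offset %% 3L + 1L
  c0 <- orfStart + (codonIndex - 1L) * 3L
  if (c0 + 2L > nchar(seq)) {
    stop(rflpError("codon extends past the end of the sequence",
                   "rflp_invalid_input"))
  }
  refCodon <- substr(seq, c0, c0 + 2L)
  if (!all(strsplit(refCodon, "", fixed = TRUE)[[1]] %in% .DNA_BASES)) {
    stop(rflpError("reading frame is not intact at this codon",
                   "rflp_invalid_input"))
  }
  altCodon <- refCodon
  substr(altCodon, posInCodon, posInCodon) <- altBase
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon_index = codonIndex, position_in_codon = posInCodon,
             ref_codon = refCodon, ref_aa = unname(gc[refCodon]),
             alt_codon = altCodon, alt_aa = unname(gc[altCodon]),
             stringsAsFactors = FALSE)
}
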