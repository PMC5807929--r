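#' GroupedAlignment class
#'
#' A gapped multiple sequence alignment whose records are partitioned
#' into groups (species or haplotype lineages). Columns are addressed by
#' 1-based alignment coordinates.
#'
#' @slot seqs `DNAStringSet` of equal-width aligned sequences (gaps as
#'   `-`), named by record id.
#' @slot groups character vector of group labels, parallel to `seqs`.
#' @export
setClass("GroupedAlignment",
  representation(seqs = "DNAStringSet", groups = "character"))

setValidity("GroupedAlignment", function(object) {
  msg <- character()
  if (length(object@seqs) == 0L) msg <- c(msg, "alignment has no records")
  w <- Biostrings::width(object@seqs)
  if (length(w) && length(unique(w)) != 1L)
    msg <- c(msg, "aligned sequences must all have equal length")
  if (length(object@groups) != length(object@seqs))
    msg <- c(msg, "one group label required per record")
  if (any(!nzchar(object@groups) | is.na(object@groups)))
    msg <- c(msg, "group labels must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a GroupedAlignment
#'
#' @param seqs aligned sequences: a `DNAStringSet` or named character
#'   vector, all the same width (gaps as `-`).
#' @param groups group label per record. If missing, the second
#'   whitespace-separated token of each sequence name is used.
#' @return a [GroupedAlignment-class].
#' @export
groupedAlignment <- function(seqs, groups) {
  if (!is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  if (missing(groups) || is.null(groups)) {
    if (is.null(names(seqs))) {
      stop(rflpError("groups missing and sequences are unnamed",
                     "rflp_invalid_input"))
    }
    tokens <- strsplit(names(seqs), "[ \t]+")
    groups <- vapply(tokens, function(t) {
      if (length(t) < 2L) NA_character_ else paste(t[-1L], collapse = " ")
    }, character(1))
    if (anyNA(groups)) {
      stop(rflpError("some FASTA headers lack a group token (second field)",
                     "rflp_invalid_input"))
    }
    names(seqs) <- vapply(tokens, `[`, character(1), 1L)
  }
  new("GroupedAlignment", seqs = seqs, groups = as.character(groups))
}

#' Read a grouped alignment from FASTA
#'
#' Group labels come either from a two-column TSV (`id`, `group`) or from
#' the second whitespace-separated token of each FASTA header. Lowercase
#' sequence is normalized to uppercase.
#'
#' @param fasta path to an aligned multi-FASTA.
#' @param groupsFile optional path to a two-column TSV mapping record ids
#'   to groups.
#' @return a [GroupedAlignment-class].
#' @export
readGroupedAlignment <- function(fasta, groupsFile = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) {
    stop(rflpError(sprintf("no records in %s", fasta), "rflp_data_error"))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  if (!is.null(groupsFile)) {
    tab <- read.delim(groupsFile, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, character(1), 1L)
    idx <- match(ids, tab[[1L]])
    if (anyNA(idx)) {
      stop(rflpError(
        sprintf("no group for record(s): %s",
                paste(ids[is.na(idx)], collapse = ", ")),
        "rflp_data_error"))
    }
    names(seqs) <- ids
    return(groupedAlignment(seqs, tab[[2L]][idx]))
  }
  groupedAlignment(seqs)
}

#' @describeIn GroupedAlignment-class group label per record.
#' @param x,object a `GroupedAlignment`.
#' @export
alnGroups <- function(x) x@groups

#' @describeIn GroupedAlignment-class aligned sequences (`DNAStringSet`).
#' @export
alnSeqs <- function(x) x@seqs

#' @describeIn GroupedAlignment-class alignment width (number of
#'   columns).
#' @export
alnWidth <- function(x) {
  if (length(x@seqs) == 0L) 0L else Biostrings::width(x@seqs)[1L]
}

setMethod("show", "GroupedAlignment", function(object) {
  g <- table(object@groups)
  cat(sprintf("GroupedAlignment: %d records x %d columns, %d group(s)\n",
              length(object@seqs), alnWidth(object), length(g)))
  cat(paste(sprintf("  %s (n=%d)", names(g), as.integer(g)), collapse = "\n"),
      "\n")
})

# Character matrix view (records x columns).
.alnMatrix <- function(aln) {
  m <- as.matrix(aln@seqs)
  rownames(m) <- names(aln@seqs)
  m
}

#' Map alignment columns to ungapped sequence positions
#'
#' For one alignment record, returns the ungapped (sequence) position of
#' each alignment column, or `NA` at gap columns.
#'
#' @param aln a [GroupedAlignment-class].
#' @param record record index or name.
#' @return integer vector of length `alnWidth(aln)`.
#' @export
alnToSeqPositions <- function(aln, record) {
  chars <- strsplit(as.character(aln@seqs[[record]]), "", fixed = TRUE)[[1]]
  pos <- cumsum(chars != "-")
  pos[chars == "-"] <- NA_integer_
  pos
}
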