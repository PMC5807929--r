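#' @importFrom methods new validObject show setValidity is slot
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head
NULL

# Single-letter IUPAC nucleotide codes and their concrete expansions.
.IUPAC_EXPAND <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "", fixed = TRUE)[[1]])
})

.DNA_BASES <- c("A", "C", "G", "T")

.isIupac <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  all(chars %in% names(.IUPAC_EXPAND))
}

#' Does an IUPAC code match a concrete base?
#'
#' Tests whether `base` belongs to the expansion of the IUPAC ambiguity
#' code `code` (e.g. `S` expands to G/C, `N` to all four). Ambiguity codes
#' on the subject side never match: `base` must be a concrete A/C/G/T, so
#' an uncertain template base can never create a phantom cut site or
#' primer hit.
#'
#' @param code single IUPAC nucleotide symbol (pattern side).
#' @param base single concrete base, one of A/C/G/T (subject side).
#' @return `TRUE` or `FALSE`. Vectorised over pairs.
#' @examples
#' iupacMatch("S", "G")  # TRUE
#' iupacMatch("S", "A")  # FALSE
#' @export
iupacMatch <- function(code, base) {
  code <- toupper(as.character(code))
  base <- toupper(as.character(base))
  n <- max(length(code), length(base))
  code <- rep_len(code, n)
  base <- rep_len(base, n)
  bad <- !(code %in% names(.IUPAC_EXPAND)) | nchar(code) != 1L
  if (any(bad)) {
    stop(rflpError(
      sprintf("invalid IUPAC symbol: %s",
              paste(unique(code[bad]), collapse = ", ")),
      "rflp_invalid_input"))
  }
  if (any(nchar(base) != 1L)) {
    stop(rflpError("base must be a single character", "rflp_invalid_input"))
  }
  vapply(seq_len(n), function(i) {
    base[i] %in% .DNA_BASES && base[i] %in% .IUPAC_EXPAND[[code[i]]]
  }, logical(1))
}

# Reverse complement of an IUPAC string (keeps ambiguity codes).
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Normalize a sequence argument (character or XString) to an uppercase
# character scalar.
.asSeqChar <- function(x, what = "sequence") {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L) {
    stop(rflpError(sprintf("%s must be a single string or DNAString", what),
                   "rflp_invalid_input"))
  }
  toupper(x)
}

# Classed condition constructor so callers can distinguish error kinds.
rflpError <- function(message, class, call = sys.call(-1)) {
  structure(
    class = c(class, "rflp_error", "error", "condition"),
    list(message = message, call = call)
  )
}

.rflpWarn <- function(message, class) {
  warning(structure(
    class = c(class, "rflp_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}
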