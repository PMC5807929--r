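# Independent brute-force oracles for site finding and digestion.
# Deliberately self-contained: they share no code with the package.

.ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                  B = "V", D = "H", H = "D", V = "B", N = "N")

oracleRevcomp <- function(x) {
  paste(rev(.ORACLE_COMP[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

# All top-strand cut positions (unique, sorted) of one enzyme, by
# position-by-position scanning of both orientations.
oracleCuts <- function(seq, recognition, cutTop, cutBottom) {
  schars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- nchar(recognition)
  n <- length(schars)
  matchesAt <- function(rec, s) {
    rchars <- strsplit(rec, "", fixed = TRUE)[[1]]
    all(vapply(seq_len(L), function(j) {
      schars[s + j - 1L] %in% .ORACLE_IUPAC[[rchars[j]]]
    }, logical(1)))
  }
  cuts <- integer()
  for (s in seq_len(max(0L, n - L + 1L))) {
    # a footprint is one site: forward reading takes precedence, and a
    # reverse-orientation site cleaves the top strand at the enzyme's
    # bottom-strand cut (cutBottom aligned bases from the left edge)
    if (matchesAt(recognition, s)) {
      cuts <- c(cuts, s - 1L + cutTop)
    } else if (matchesAt(oracleRevcomp(recognition), s)) {
      cuts <- c(cuts, s - 1L + cutBottom)
    }
  }
  sort(unique(cuts))
}

oracleDigest <- function(seq, enzymes) {
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) {
    oracleCuts(seq, e@recognition, e@cutTop, e@cutBottom)
  }))))
  n <- nchar(seq)
  cuts <- cuts[cuts > 0 & cuts < n]
  sort(diff(c(0L, cuts, n)), decreasing = TRUE)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
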