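# Internal helpers shared across modules.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")

#' Reverse complement of a DNA string
#'
#' Handles all IUPAC ambiguity codes and alignment gaps (`-`).
#'
#' @param seq Character vector of DNA strings (uppercase IUPAC).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(seq) {
  vapply(seq, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- IUPAC_COMPLEMENT[ch]
    if (anyNA(comp)) stop("non-IUPAC character in sequence")
    paste0(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Validate an unaligned DNA sequence; returns position of first bad char or 0L.
first_bad_char <- function(seq, allow_gap = FALSE) {
  ok <- IUPAC_CODES
  if (allow_gap) ok <- c(ok, "-")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% ok)
  if (length(bad)) bad[1] else 0L
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
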