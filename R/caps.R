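# CAPS marker design: restriction enzymes whose recognition site is
# created or destroyed by a SNP between two alleles of a locus, plus
# digestion fragment-pattern prediction for gel resolution.

iupac_revcomp_pattern <- function(site) revcomp(site)

#' Load a restriction-enzyme catalog
#'
#' Tab-separated columns `name`, `site` (IUPAC recognition pattern),
#' `cut_offset` (top-strand cut position within/adjacent to the site).
#' Without a path the built-in catalog of common enzymes is loaded.
#'
#' @param path Optional catalog file.
#' @return Data frame with `name`, `site`, `cut_offset`, `palindromic`.
#' @export
load_enzyme_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "homeolocus")
  e <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "site", "cut_offset") %in% names(e)))
  e$site <- toupper(e$site)
  stopifnot(all(nchar(e$site) >= 4),
            all(e$cut_offset >= 0 & e$cut_offset <= nchar(e$site)))
  e$palindromic <- e$site == iupac_revcomp_pattern(e$site)
  e
}

#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param site IUPAC recognition pattern (length >= 4).
#' @param cut_offset Top-strand cut position within the site (0 = before
#'   the first base).
#' @return A one-row enzyme data frame.
#' @export
enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  stopifnot(nchar(site) >= 4, cut_offset >= 0, cut_offset <= nchar(site))
  data.frame(name = name, site = site, cut_offset = as.integer(cut_offset),
             palindromic = site == iupac_revcomp_pattern(site),
             stringsAsFactors = FALSE)
}

# Match intervals (0-based half-open) of a recognition site on the top
# strand, plus bottom-strand (reverse-complement pattern) matches for
# non-palindromic enzymes. Returns data frame start, end, cut.
site_matches <- function(seq, enz) {
  subj <- Biostrings::DNAString(seq)
  L <- nchar(enz$site)
  tops <- Biostrings::matchPattern(enz$site, subj,
                                   fixed = c(pattern = FALSE, subject = TRUE))
  res <- data.frame(start = Biostrings::start(tops) - 1L,
                    end = Biostrings::end(tops),
                    cut = Biostrings::start(tops) - 1L + enz$cut_offset)
  if (!enz$palindromic) {
    rc <- iupac_revcomp_pattern(enz$site)
    bots <- Biostrings::matchPattern(rc, subj,
                                     fixed = c(pattern = FALSE, subject = TRUE))
    if (length(bots)) {
      res <- rbind(res, data.frame(
        start = Biostrings::start(bots) - 1L,
        end = Biostrings::end(bots),
        cut = Biostrings::start(bots) - 1L + (L - enz$cut_offset)))
    }
  }
  res <- unique(res)
  res[order(res$start, res$cut), , drop = FALSE]
}

#' Find restriction cut positions
#'
#' All top-strand matches of the recognition pattern (IUPAC codes in the
#' pattern match their base sets) and, for non-palindromic enzymes, matches
#' of its reverse complement, with the cut offset mirrored on bottom-strand
#' sites. Positions are 0-based (a cut at position p falls between bases p
#' and p+1 counting from the sequence start).
#'
#' @param seq A DNA string or single-row [dna_set()].
#' @param enz A one-row enzyme data frame (see [enzyme()]).
#' @return Sorted unique integer cut positions.
#' @export
find_sites <- function(seq, enz) {
  if (is.data.frame(seq)) seq <- seq$seq[1]
  sort(unique(site_matches(seq, enz)$cut))
}

#' Digest a sequence with a restriction enzyme
#'
#' @param seq A DNA string or single-row [dna_set()].
#' @param enz A one-row enzyme data frame.
#' @return Sorted fragment lengths; they always sum to the sequence length.
#'   A sequence without a site yields a single full-length fragment.
#' @export
digest <- function(seq, enz) {
  if (is.data.frame(seq)) seq <- seq$seq[1]
  n <- nchar(seq)
  cuts <- find_sites(seq, enz)
  cuts <- cuts[cuts > 0 & cuts < n]
  sort(diff(c(0L, cuts, n)))
}

#' Find CAPS candidates between two alleles
#'
#' Globally aligns the two allele sequences, enumerates their SNPs, and
#' reports every enzyme whose recognition site overlapping a SNP exists in
#' exactly one allele -- the SNP creates or destroys the site, so the
#' digestion patterns of the two alleles differ and the polymorphism can be
#' scored on a gel. Candidates whose differential fragments fall below
#' `min_frag` (gel resolution) or whose patterns do not differ are dropped.
#' Ranked by fragment-size separability: the distance from the
#' hardest-to-resolve differential fragment to the nearest fragment of the
#' other allele, largest first.
#'
#' @param allele_a,allele_b Single-row [dna_set()] objects (or plain
#'   strings) of the two allele sequences.
#' @param catalog Enzyme catalog (default: built-in).
#' @param min_frag Minimum resolvable differential fragment length (bp).
#' @param scheme A [scoring_scheme()] for the allele alignment.
#' @return Data frame: `enzyme`, `site`, `snp_col` (alignment column),
#'   `pos_a`, `pos_b` (0-based SNP positions in each allele), `cut_allele`
#'   ("a" or "b": which allele has the differential site), `fragments_a`,
#'   `fragments_b` (comma-separated sorted lengths), `separability`.
#' @export
find_caps <- function(allele_a, allele_b, catalog = load_enzyme_catalog(),
                      min_frag = 50L, scheme = scoring_scheme()) {
  sa <- if (is.data.frame(allele_a)) allele_a$seq[1] else toupper(allele_a)
  sb <- if (is.data.frame(allele_b)) allele_b$seq[1] else toupper(allele_b)
  if (sa == sb) stop("no polymorphism between alleles")
  al <- pairwise_align_global(sa, sb, scheme)
  ca <- strsplit(al$a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$b, "", fixed = TRUE)[[1]]
  snp <- which(ca != cb & ca != "-" & cb != "-")
  if (!length(snp)) stop("no polymorphism between alleles")
  pos_a <- cumsum(ca != "-")  # 1-based position in allele a per column
  pos_b <- cumsum(cb != "-")
  out <- list()
  for (k in seq_len(nrow(catalog))) {
    enz <- catalog[k, ]
    ma <- site_matches(sa, enz)
    mb <- site_matches(sb, enz)
    fa <- digest(sa, enz)
    fb <- digest(sb, enz)
    if (identical(fa, fb)) next
    for (col in snp) {
      pa <- pos_a[col] - 1L
      pb <- pos_b[col] - 1L
      in_a <- nrow(ma) > 0 && any(ma$start <= pa & ma$end > pa)
      in_b <- nrow(mb) > 0 && any(mb$start <= pb & mb$end > pb)
      if (in_a == in_b) next  # site must exist in exactly one allele
      diff_a <- setdiff_multiset(fa, fb)
      diff_b <- setdiff_multiset(fb, fa)
      dfrag <- c(diff_a, diff_b)
      if (!length(dfrag) || any(dfrag < min_frag)) next
      sep <- min(c(
        if (length(diff_a)) vapply(diff_a, function(f) min(abs(f - fb)),
                                   numeric(1)) else numeric(0),
        if (length(diff_b)) vapply(diff_b, function(f) min(abs(f - fa)),
                                   numeric(1)) else numeric(0)))
      out[[length(out) + 1L]] <- data.frame(
        enzyme = enz$name, site = enz$site, snp_col = col - 1L,
        pos_a = pa, pos_b = pb,
        cut_allele = if (in_a) "a" else "b",
        fragments_a = paste(fa, collapse = ","),
        fragments_b = paste(fb, collapse = ","),
        separability = sep, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(enzyme = character(0), site = character(0),
                      snp_col = integer(0), pos_a = integer(0),
                      pos_b = integer(0), cut_allele = character(0),
                      fragments_a = character(0), fragments_b = character(0),
                      separability = numeric(0), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res <- res[order(-res$separability, res$enzyme, res$snp_col), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# multiset difference: elements of x not matched 1:1 by elements of y
setdiff_multiset <- function(x, y) {
  for (v in y) {
    i <- match(v, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}
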