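# Homology search: internal seed-and-extend local aligner producing HSPs
# between query CDS and genome contigs, Karlin-Altschul statistics, and the
# hit-count / E-value filters applied by the pipeline (max 10 subjects,
# E <= 1e-5).

#' Alignment scoring scheme
#'
#' blastn-like defaults: match +2, mismatch -3, affine gaps (a gap of length
#' L costs `gap_open + L * gap_extend`), with Karlin-Altschul parameters for
#' converting raw scores to bit scores and E-values.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening score (< 0), charged once per gap.
#' @param gap_extend Gap extension score (< 0), charged per gapped position.
#' @param karlin_lambda,karlin_k Karlin-Altschul lambda and K (> 0).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L,
                           gap_open = -5L, gap_extend = -2L,
                           karlin_lambda = 0.625, karlin_k = 0.41) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            karlin_lambda > 0, karlin_k > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k),
            class = "scoring_scheme")
}

hsp_table <- function(query_id, subject_id, qstart, qend, sstart, send,
                      strand, identity, aln_length, raw_score, bitscore,
                      evalue) {
  structure(data.frame(query_id = query_id, subject_id = subject_id,
                       qstart = qstart, qend = qend,
                       sstart = sstart, send = send, strand = strand,
                       identity = identity, aln_length = aln_length,
                       raw_score = raw_score, bitscore = bitscore,
                       evalue = evalue, stringsAsFactors = FALSE),
            class = c("hsp_table", "data.frame"))
}

empty_hsp_table <- function() {
  hsp_table(character(0), character(0), integer(0), integer(0), integer(0),
            integer(0), character(0), numeric(0), integer(0), integer(0),
            numeric(0), numeric(0))
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `raw_score`:
#' `E = K * m * n * exp(-lambda * S)`. Strictly decreasing in the score,
#' linear in each of the search-space dimensions.
#'
#' @param raw_score Raw alignment score(s).
#' @param m Query length.
#' @param n Total subject length (sum over the searched database).
#' @param scheme A [scoring_scheme()].
#' @return Numeric E-value(s).
#' @export
evalue_karlin <- function(raw_score, m, n, scheme = scoring_scheme()) {
  stopifnot(m >= 1, n >= 1)
  scheme$karlin_k * as.numeric(m) * as.numeric(n) *
    exp(-scheme$karlin_lambda * raw_score)
}

bitscore_karlin <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$karlin_lambda * raw_score - log(scheme$karlin_k)) / log(2)
}

#' Find local alignments (HSPs) between a query and subject sequences
#'
#' Seed-and-extend local alignment on both strands: exact `seed_k`-mers
#' shared between query and subject seed an ungapped X-drop extension, whose
#' footprint is then re-aligned by full affine-gap local dynamic
#' programming. Overlapping extensions are deduplicated, keeping the
#' highest-scoring HSP per overlapping region. Ambiguity codes (including
#' N) never match. E-values use the total subject length of the search.
#'
#' @param query A single-row [dna_set()] (or a row of one).
#' @param subjects A [dna_set()] of contigs to search.
#' @param scheme A [scoring_scheme()].
#' @param seed_k Seed word size.
#' @param xdrop X-drop threshold for the ungapped extension.
#' @return An `hsp_table` with internal 0-based half-open coordinates;
#'   subject intervals are on the plus strand with a `strand` flag.
#' @export
find_hsps <- function(query, subjects, scheme = scoring_scheme(),
                      seed_k = 11L, xdrop = 20L) {
  stopifnot(nrow(query) == 1, nrow(subjects) >= 1)
  if (nchar(query$seq) < seed_k) stop("query too short")
  n_total <- sum(nchar(subjects$seq))
  res <- vector("list", 2L * nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    sseq <- subjects$seq[i]
    slen <- nchar(sseq)
    for (strand in c("+", "-")) {
      s_use <- if (strand == "+") sseq else revcomp(sseq)
      d <- cpp_seed_extend(query$seq, s_use,
                           scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend,
                           as.integer(seed_k), as.integer(xdrop), 30L)
      if (nrow(d) == 0) next
      sstart <- if (strand == "+") d$sstart else slen - d$send
      send <- if (strand == "+") d$send else slen - d$sstart
      h <- hsp_table(
        query_id = rep(query$id, nrow(d)), subject_id = rep(subjects$id[i], nrow(d)),
        qstart = d$qstart, qend = d$qend,
        sstart = sstart, send = send, strand = rep(strand, nrow(d)),
        identity = d$matches / d$aln_length, aln_length = d$aln_length,
        raw_score = d$raw_score,
        bitscore = bitscore_karlin(d$raw_score, scheme),
        evalue = evalue_karlin(d$raw_score, nchar(query$seq), n_total, scheme)
      )
      res[[2L * (i - 1L) + (strand == "-") + 1L]] <- h
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_hsp_table())
  out <- do.call(rbind, res)
  class(out) <- c("hsp_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Filter hits by E-value and subject count
#'
#' Removes HSPs with E-value above `evalue_max`, then ranks subject
#' sequences by their best bit score and keeps only the top `max_hits`
#' subjects (all surviving HSPs of a retained subject are kept) --
#' the `num_alignments`-style semantics of capping the number of subject
#' sequences, not of individual HSPs. Order within a subject is preserved.
#'
#' @param hsps An `hsp_table` for a single query.
#' @param max_hits Maximum number of subject sequences retained.
#' @param evalue_max E-value threshold.
#' @return The filtered `hsp_table` (a subset of the input; idempotent).
#' @export
filter_hits <- function(hsps, max_hits = 10L, evalue_max = 1e-5) {
  if (nrow(hsps) == 0) return(hsps)
  if (length(unique(hsps$query_id)) > 1)
    stop("filter requires a single query")
  keep <- hsps[hsps$evalue <= evalue_max, , drop = FALSE]
  if (nrow(keep) == 0) {
    keep <- hsps[0, , drop = FALSE]
    class(keep) <- c("hsp_table", "data.frame")
    return(keep)
  }
  best <- tapply(keep$bitscore, keep$subject_id, max)
  ord <- order(-best, names(best))  # bitscore desc, id for determinism
  retained <- names(best)[ord][seq_len(min(max_hits, length(best)))]
  out <- keep[keep$subject_id %in% retained, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hsp_table", "data.frame")
  out
}
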