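# Locus building: chain HSPs into putative homoeologous gene loci under
# intron/exon length constraints and extract the genomic sequences with
# flanking regions.

#' Pipeline configuration
#'
#' Defaults are the zero-configuration behaviour of the pipeline: introns at
#' most 5,000 bp, exons (HSP subject footprints) at least 200 bp, 300 bp of
#' 5' and 3' flanking sequence, E-value threshold 1e-5 and at most 10
#' subject hits per query.
#'
#' @param max_intron Maximum subject gap (bp) between chained HSPs.
#' @param min_exon Minimum HSP subject length (bp) to enter chaining.
#' @param flank Flanking sequence (bp) extracted on each side of a locus.
#' @param evalue_max E-value threshold for [filter_hits()].
#' @param max_hits Maximum subject sequences retained per query.
#' @param query_overlap_slop Small query-coordinate overlap (bp) tolerated
#'   between consecutive chained HSPs; local extension of adjacent exon hits
#'   can consume a few shared query bases at exon boundaries.
#' @param colinear Require query and subject orders to agree (strand-aware)
#'   along a chain. When `FALSE`, only subject-side constraints apply.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(max_intron = 5000L, min_exon = 200L,
                            flank = 300L, evalue_max = 1e-5,
                            max_hits = 10L, query_overlap_slop = 40L,
                            colinear = TRUE) {
  stopifnot(max_intron > 0, min_exon > 0, flank > 0, evalue_max > 0,
            max_hits > 0, query_overlap_slop >= 0)
  structure(list(max_intron = as.integer(max_intron),
                 min_exon = as.integer(min_exon), flank = as.integer(flank),
                 evalue_max = evalue_max, max_hits = as.integer(max_hits),
                 query_overlap_slop = as.integer(query_overlap_slop),
                 colinear = isTRUE(colinear)),
            class = "pipeline_config")
}

# Can HSP i precede HSP j in a chain? Both rows of an hsp_table sorted
# on the subject. Subject: ordered, non-overlapping, gap <= max_intron.
# Query (if colinear): order agrees with subject order on "+", is reversed
# on "-", with a small overlap slop.
chain_compatible <- function(h, i, j, cfg) {
  gap <- h$sstart[j] - h$send[i]
  if (gap < 0 || gap > cfg$max_intron) return(FALSE)
  if (!cfg$colinear) return(TRUE)
  slop <- cfg$query_overlap_slop
  if (h$strand[i] == "+") {
    h$qstart[j] >= h$qend[i] - slop && h$qstart[j] > h$qstart[i] &&
      h$qend[j] > h$qend[i]
  } else {
    h$qend[j] <= h$qstart[i] + slop && h$qend[j] < h$qend[i] &&
      h$qstart[j] < h$qstart[i]
  }
}

#' Chain HSPs into gene loci
#'
#' Dynamic-programming chaining of HSPs from one (query, subject, strand)
#' group into putative gene loci. HSPs whose subject footprint is shorter
#' than `min_exon` are discarded first. Chains maximize the sum of member
#' raw scores subject to: subject blocks ordered and non-overlapping,
#' subject gaps (introns) at most `max_intron`, and query/subject
#' colinearity (strand-aware). Maximal-score chains are extracted greedily
#' (best chain reported, members removed, repeat), so one contig may yield
#' several loci (paralogs). Ties break toward fewer blocks, then leftmost
#' subject start.
#'
#' @param hsps An `hsp_table` whose rows share query, subject and strand.
#' @param cfg A [pipeline_config()].
#' @return A list of `locus_model` objects with fields `query_id`,
#'   `subject_id`, `strand`, `blocks` (subject intervals, 0-based
#'   half-open), `q_blocks`, `chain_score` and `span`.
#' @export
chain_hsps <- function(hsps, cfg = pipeline_config()) {
  if (nrow(hsps) == 0) return(list())
  if (length(unique(hsps$query_id)) > 1 ||
      length(unique(hsps$subject_id)) > 1 ||
      length(unique(hsps$strand)) > 1)
    stop("chain requires one subject/strand group")
  h <- hsps[(hsps$send - hsps$sstart) >= cfg$min_exon, , drop = FALSE]
  if (nrow(h) == 0) return(list())
  h <- h[order(h$sstart, h$send), , drop = FALSE]
  rownames(h) <- NULL
  loci <- list()
  active <- rep(TRUE, nrow(h))
  while (any(active)) {
    idx <- which(active)
    hh <- h[idx, , drop = FALSE]
    n <- nrow(hh)
    score <- hh$raw_score        # best chain score ending at i
    nblk <- rep(1L, n)
    prev <- rep(0L, n)
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1L)) {
        if (!chain_compatible(hh, i, j, cfg)) next
        cand <- score[i] + hh$raw_score[j]
        better <- cand > score[j] ||
          (cand == score[j] && nblk[i] + 1L < nblk[j])
        if (better) {
          score[j] <- cand
          nblk[j] <- nblk[i] + 1L
          prev[j] <- i
        }
      }
    }
    # best chain end: max score, then fewer blocks, then leftmost start
    best <- order(-score, nblk, hh$sstart)[1]
    members <- integer(0)
    at <- best
    while (at != 0L) { members <- c(at, members); at <- prev[at] }
    blocks <- cbind(start = hh$sstart[members], end = hh$send[members])
    qb <- cbind(start = hh$qstart[members], end = hh$qend[members])
    loci[[length(loci) + 1L]] <- structure(
      list(query_id = hh$query_id[1], subject_id = hh$subject_id[1],
           strand = hh$strand[1], blocks = blocks, q_blocks = qb,
           chain_score = sum(hh$raw_score[members]),
           span = c(min(blocks[, "start"]), max(blocks[, "end"]))),
      class = "locus_model")
    active[idx[members]] <- FALSE
  }
  loci
}

#' Extract the genomic sequence of a locus with flanking regions
#'
#' Returns the contig sequence from `span_start - flank` to
#' `span_end + flank`, clipped at contig boundaries. Extraction is
#' span-based: introns between chained blocks are retained. Minus-strand
#' loci are reverse-complemented (and flank labels swapped) so the record
#' reads 5' to 3' of the gene.
#'
#' @param locus A `locus_model` from [chain_hsps()].
#' @param contig The subject contig as a single-row [dna_set()].
#' @param cfg A [pipeline_config()]; `cfg$flank` bp requested per side.
#' @return An `extracted_locus` list: `record` (id, seq), `source_subject`,
#'   `source_span` (plus-strand interval including flanks), `strand`,
#'   `locus_span`, `left_flank_len`, `right_flank_len`, `query_id`.
#' @export
extract_locus <- function(locus, contig, cfg = pipeline_config()) {
  stopifnot(nrow(contig) == 1, contig$id == locus$subject_id)
  clen <- nchar(contig$seq)
  if (locus$span[1] < 0 || locus$span[2] > clen)
    stop("locus/contig mismatch")
  a <- max(0L, locus$span[1] - cfg$flank)
  b <- min(clen, locus$span[2] + cfg$flank)
  seq <- substr(contig$seq, a + 1L, b)
  lf <- locus$span[1] - a
  rf <- b - locus$span[2]
  if (locus$strand == "-") {
    seq <- revcomp(seq)
    tmp <- lf; lf <- rf; rf <- tmp
  }
  id <- sprintf("%s|%s:%d-%d%s", locus$query_id, locus$subject_id,
                a + 1L, b, locus$strand)
  structure(list(record = list(id = id, seq = seq),
                 source_subject = locus$subject_id,
                 source_span = c(a, b), strand = locus$strand,
                 locus_span = locus$span,
                 left_flank_len = lf, right_flank_len = rf,
                 query_id = locus$query_id),
            class = "extracted_locus")
}

#' Collect the homoeolog set of one query into a multi-FASTA
#'
#' Deduplicates loci extracted from the same (subject, span), optionally
#' prepends the query CDS as a reference row, and writes all records to a
#' single per-query FASTA file when `path` is given.
#'
#' @param query The query CDS as a single-row [dna_set()].
#' @param loci List of `extracted_locus` objects for this query.
#' @param include_query Prepend the query CDS as the first record.
#' @param path Optional output FASTA path.
#' @return A [dna_set()] of the collected records.
#' @export
collect_homeolog_set <- function(query, loci, include_query = FALSE,
                                 path = NULL) {
  if (!length(loci)) stop("no homoeologs retrieved for query ", query$id)
  key <- vapply(loci, function(l)
    paste(l$source_subject, l$source_span[1], l$source_span[2], l$strand),
    character(1))
  if (anyDuplicated(key)) {
    warning("duplicate loci for query ", query$id, "; deduplicated")
    loci <- loci[!duplicated(key)]
  }
  ids <- vapply(loci, function(l) l$record$id, character(1))
  seqs <- vapply(loci, function(l) l$record$seq, character(1))
  if (include_query) {
    ids <- c(query$id, ids)
    seqs <- c(query$seq, seqs)
  }
  out <- dna_set(ids, seqs)
  if (!is.null(path)) write_fasta(out, path)
  out
}
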