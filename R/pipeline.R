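# End-to-end pipeline: search -> filter -> chain -> extract -> align ->
# diagnostic sites -> primers / conserved regions -> in-silico PCR, with
# per-query failure isolation and a machine-readable run manifest.

#' Run the locus-isolation pipeline
#'
#' Executes all stages for every query: homology search against the genome
#' contigs (internal seed-and-extend, or hits supplied via `hits`),
#' E-value/hit-count filtering, HSP chaining into loci, flanked extraction,
#' progressive multiple alignment of the homoeolog set, diagnostic-site
#' detection per row, genome-specific primer design per row, fully
#' conserved (qPCR) region discovery, and in-silico PCR validation of the
#' top primer pair per row against the hit contigs. Queries failing a stage
#' are recorded with a status and skipped, never aborting the run.
#'
#' @param queries A [dna_set()] of query gene/CDS sequences.
#' @param genome A [dna_set()] of target contigs.
#' @param cfg A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @param hits Optional precomputed `hsp_table` (e.g. from
#'   [read_tabular_hits()]); skips the internal search.
#' @param out_dir Optional output directory: per-query homoeolog FASTA,
#'   aligned FASTA, `.htm` reports, primer table, and the manifest
#'   (TSV + JSON) are written there.
#' @param report Write browser-readable `.htm` alignment reports.
#' @param constraints A [primer_constraints()].
#' @param validate Run in-silico PCR on the top pair per target row.
#' @return A `pipeline_run`: list with `manifest` (per-query status data
#'   frame), `counts` (funnel tallies: queries >= with hits >= with
#'   alignments >= with primers), and `genes` (per-query results: hits,
#'   loci, msa, sites, pairs, conserved regions, in-silico products).
#' @export
run_pipeline <- function(queries, genome, cfg = pipeline_config(),
                         scheme = scoring_scheme(), hits = NULL,
                         out_dir = NULL, report = FALSE,
                         constraints = primer_constraints(),
                         validate = TRUE) {
  if (is.null(queries) || nrow(queries) == 0) stop("empty input: queries")
  if (is.null(genome) || nrow(genome) == 0) stop("empty input: genome")
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- vector("list", nrow(queries))
  names(genes) <- queries$id
  status <- character(nrow(queries))
  n_hits <- integer(nrow(queries)); n_loci <- integer(nrow(queries))
  n_rows <- integer(nrow(queries)); n_pairs <- integer(nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    q <- queries[qi, , drop = FALSE]
    res <- list(query_id = q$id)
    h <- if (is.null(hits)) find_hsps(q, genome, scheme)
         else hits[hits$query_id == q$id, , drop = FALSE]
    h <- filter_hits(h, max_hits = cfg$max_hits, evalue_max = cfg$evalue_max)
    n_hits[qi] <- nrow(h)
    if (nrow(h) == 0) { status[qi] <- "no_hits"; genes[[qi]] <- res; next }
    res$hits <- h
    # chain per (subject, strand) group
    loci <- list()
    for (grp in split(seq_len(nrow(h)),
                      paste(h$subject_id, h$strand, sep = "\r"))) {
      hh <- h[grp, , drop = FALSE]
      class(hh) <- c("hsp_table", "data.frame")
      loci <- c(loci, chain_hsps(hh, cfg))
    }
    n_loci[qi] <- length(loci)
    if (!length(loci)) { status[qi] <- "no_alignment"; genes[[qi]] <- res; next }
    extracted <- lapply(loci, function(l)
      extract_locus(l, genome[genome$id == l$subject_id, , drop = FALSE], cfg))
    set <- tryCatch(collect_homeolog_set(q, extracted), error = function(e) NULL)
    if (is.null(set) || nrow(set) < 2) {
      status[qi] <- "no_alignment"; res$loci <- extracted
      genes[[qi]] <- res; next
    }
    if (!is.null(out_dir))
      write_fasta(set, file.path(out_dir, paste0(q$id, ".fa")))
    prov <- do.call(rbind, lapply(extracted, function(l) data.frame(
      id = l$record$id, subject_id = l$source_subject,
      span_start = l$source_span[1], span_end = l$source_span[2],
      strand = l$strand, stringsAsFactors = FALSE)))
    prov <- prov[!duplicated(prov$id), , drop = FALSE]
    prov <- prov[match(set$id, prov$id), , drop = FALSE]
    prov <- prov[!is.na(prov$id), , drop = FALSE]
    msa <- progressive_align(set, scheme = scheme, query_id = q$id,
                             provenance = prov)
    res$loci <- extracted
    res$msa <- msa
    n_rows[qi] <- length(msa$ids)
    res$conserved <- conserved_regions(msa)
    res$blocks <- select_conserved_blocks(msa)
    res$sites <- lapply(setNames(msa$ids, msa$ids), function(r)
      diagnostic_sites(msa, r))
    if (report || !is.null(out_dir)) {
      aligned <- dna_set_gapped(msa)
      if (!is.null(out_dir))
        write_aligned_fasta(msa, file.path(out_dir, paste0(q$id, ".aln.fa")))
    }
    if (report && !is.null(out_dir)) {
      all_cols <- unique(unlist(lapply(res$sites, function(s)
        if (nrow(s)) s$col_start else integer(0))))
      write_alignment_report(msa, sort(all_cols),
                             file.path(out_dir, paste0(q$id, ".htm")))
    }
    res$pairs <- lapply(setNames(msa$ids, msa$ids), function(r)
      tryCatch(design_primer_pairs(msa, r, constraints,
                                   sites = res$sites[[r]]),
               error = function(e) NULL))
    got_pairs <- !vapply(res$pairs, is.null, logical(1))
    n_pairs[qi] <- sum(vapply(res$pairs[got_pairs], nrow, integer(1)))
    if (validate && any(got_pairs)) {
      templ <- genome[genome$id %in% unique(h$subject_id), , drop = FALSE]
      res$ispcr <- lapply(setNames(msa$ids, msa$ids), function(r) {
        pr <- res$pairs[[r]]
        if (is.null(pr) || nrow(pr) == 0) return(NULL)
        insilico_pcr(pr[1, , drop = FALSE], templ,
                     product_range = constraints$product_range)
      })
    }
    status[qi] <- if (any(got_pairs)) "ok" else "no_primers"
    genes[[qi]] <- res
  }
  manifest <- data.frame(query_id = queries$id, status = status,
                         n_hits = n_hits, n_loci = n_loci,
                         n_msa_rows = n_rows, n_primer_pairs = n_pairs,
                         stringsAsFactors = FALSE)
  counts <- c(queries = nrow(queries),
              with_hits = sum(n_hits > 0),
              with_alignments = sum(n_rows >= 2),
              with_primers = sum(status == "ok"))
  run <- structure(list(manifest = manifest, counts = counts, genes = genes,
                        cfg = cfg),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(counts = as.list(counts),
                              config = unclass(cfg),
                              queries = manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run:", x$counts["queries"], "queries;",
      x$counts["with_hits"], "with hits;",
      x$counts["with_alignments"], "with alignments;",
      x$counts["with_primers"], "with genome-specific primers\n")
  invisible(x)
}

dna_set_gapped <- function(msa) {
  structure(data.frame(id = msa$ids, desc = "", seq = msa$rows,
                       stringsAsFactors = FALSE),
            class = c("dna_set", "data.frame"))
}

# aligned-FASTA persistence for MSAs (gaps allowed, unlike write_fasta)
write_aligned_fasta <- function(msa, path, wrap = 60L) {
  x <- Biostrings::BStringSet(msa$rows)
  names(x) <- msa$ids
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(wrap))
  invisible(path)
}

#' Read an aligned FASTA file as an MSA
#'
#' @param path Aligned FASTA (equal-length gapped rows).
#' @param query_id Optional query id to attach.
#' @return A `homeolog_msa`.
#' @export
read_aligned_fasta <- function(path, query_id = NULL) {
  x <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(x))
  if (length(unique(nchar(rows))) != 1)
    stop("alignment rows differ in length")
  structure(list(ids = sub("[[:space:]].*$", "", names(x)),
                 rows = unname(rows), query_id = query_id,
                 provenance = NULL),
            class = "homeolog_msa")
}
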