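# Sequence and hit-table I/O: FASTA, 12-column tabular hits (BLAST outfmt 6
# convention), and the browser-readable per-gene alignment report.
#
# Internal coordinate convention: 0-based half-open on the plus strand
# everywhere; 1-based inclusive only at the tabular-hit file boundary.

#' Construct a set of DNA sequence records
#'
#' The basic container used throughout the pipeline: a data frame with one
#' row per record and columns `id`, `desc`, `seq`. Sequences are
#' case-normalized to uppercase and must be non-empty IUPAC DNA without
#' alignment gaps; ids must be unique, non-empty and whitespace-free.
#'
#' @param id Character vector of record identifiers.
#' @param seq Character vector of DNA sequences.
#' @param desc Optional character vector of free-text descriptions.
#' @return A `dna_set` data frame.
#' @export
#' @examples
#' dna_set(c("a", "b"), c("acgt", "TTTT"))
dna_set <- function(id, seq, desc = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  desc <- if (is.null(desc)) rep("", length(id)) else as.character(desc)
  stopifnot(length(id) == length(seq), length(desc) == length(id))
  if (any(!nzchar(id)) || any(grepl("[[:space:]]", id)))
    stop("record ids must be non-empty and whitespace-free")
  if (anyDuplicated(id))
    stop("duplicate sequence id: ", id[duplicated(id)][1])
  if (any(!nzchar(seq))) stop("empty sequence for record ", id[!nzchar(seq)][1])
  for (i in seq_along(seq)) {
    p <- first_bad_char(seq[i])
    if (p > 0L)
      stop(sprintf("non-IUPAC character at record %s position %d", id[i], p))
  }
  structure(data.frame(id = id, desc = desc, seq = seq,
                       stringsAsFactors = FALSE),
            class = c("dna_set", "data.frame"))
}

#' Read a FASTA file
#'
#' Multi-line records are concatenated and sequences upper-cased. The record
#' id is the first whitespace-delimited token of the header; the remainder
#' becomes the description. Gap characters are rejected (unaligned input).
#'
#' @param path Path to a FASTA file.
#' @return A [dna_set()] with one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !startsWith(first, ">"))
    stop("not FASTA (file must begin with '>'): ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("empty input: ", path)
  headers <- names(x)
  id <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  dna_set(id, as.character(x), desc)
}

#' Write records to a FASTA file
#'
#' @param records A [dna_set()].
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (>= 1).
#' @return `path`, invisibly. `read_fasta(write_fasta(x, p), )` is identity.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (is.null(records) || nrow(records) == 0) stop("nothing to write")
  stopifnot(wrap >= 1)
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- ifelse(nzchar(records$desc),
                     paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(wrap))
  invisible(path)
}

#' Read a 12-column tabular hit file
#'
#' Columns follow the BLAST `outfmt 6` convention: qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore,
#' with 1-based inclusive coordinates. On the subject, `sstart > send` marks
#' a minus-strand hit. Coordinates are converted to the internal 0-based
#' half-open convention with `sstart < send`; the strand is kept as a flag.
#'
#' @param path Path to a tab-separated hit file.
#' @return An `hsp_table` data frame (see [find_hsps()] for columns).
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(empty_hsp_table())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L))
    stop("malformed hit line ", which(nc != 12L)[1])
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (anyNA(num))
    stop("parse error line ", which(rowSums(is.na(num)) > 0)[1])
  sstart <- num[, 7]; send <- num[, 8]
  minus <- sstart > send
  s_lo <- ifelse(minus, send, sstart)
  s_hi <- ifelse(minus, sstart, send)
  pident <- num[, 1]
  alnlen <- as.integer(num[, 2])
  hsp_table(
    query_id = m[, 1], subject_id = m[, 2],
    qstart = as.integer(num[, 5] - 1), qend = as.integer(num[, 6]),
    sstart = as.integer(s_lo - 1), send = as.integer(s_hi),
    strand = ifelse(minus, "-", "+"),
    identity = pident / 100, aln_length = alnlen,
    raw_score = rep(NA_integer_, nrow(m)),
    bitscore = num[, 10], evalue = num[, 9]
  )
}

#' Write hits as a 12-column tabular file
#'
#' Inverse of [read_tabular_hits()]: internal 0-based half-open coordinates
#' are converted back to 1-based inclusive, with subject start/end swapped
#' for minus-strand hits.
#'
#' @param hsps An `hsp_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hsps, path) {
  minus <- hsps$strand == "-"
  sstart <- ifelse(minus, hsps$send, hsps$sstart + 1L)
  send <- ifelse(minus, hsps$sstart + 1L, hsps$send)
  mism <- round(hsps$aln_length * (1 - hsps$identity))
  out <- data.frame(
    hsps$query_id, hsps$subject_id,
    sprintf("%.2f", hsps$identity * 100), hsps$aln_length,
    mism, 0L,
    hsps$qstart + 1L, hsps$qend, sstart, send,
    format(hsps$evalue, digits = 3, scientific = TRUE),
    format(hsps$bitscore, digits = 4),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a browser-readable alignment report
#'
#' Writes a self-contained `.htm` file showing the alignment as a
#' fixed-width grid in blocks, with row ids in a left margin and
#' subgenome-diagnostic columns highlighted and marked by an asterisk line,
#' so candidate genome-specific polymorphisms can be inspected in any web
#' browser.
#'
#' @param aln A `homeolog_msa` (see [progressive_align()]) or a list with
#'   elements `ids` and `rows` (equal-length gapped sequences).
#' @param annotations Integer vector of diagnostic alignment columns
#'   (0-based) or a data frame with a `column` element; may be empty.
#' @param path Output path; the `.htm` suffix is appended if absent.
#' @param block Columns per grid block.
#' @return The path written, invisibly.
#' @export
write_alignment_report <- function(aln, annotations = integer(), path,
                                   block = 60L) {
  ids <- aln$ids
  rows <- aln$rows
  stopifnot(length(ids) == length(rows),
            length(unique(nchar(rows))) == 1)
  width <- nchar(rows[1])
  cols <- if (is.data.frame(annotations)) annotations$column else
    as.integer(annotations)
  cols <- unique(cols[!is.na(cols)])
  stopifnot(all(cols >= 0 & cols < width))
  if (!grepl("\\.html?$", path)) path <- paste0(path, ".htm")
  idw <- max(nchar(ids)) + 2L
  mark <- rep(" ", width)
  mark[cols + 1L] <- "*"
  out <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>%s</title>", html_escape(aln$query_id %||% "alignment")),
    "<style>",
    "body { font-family: monospace; white-space: pre; }",
    ".diag { background: #ffd54f; font-weight: bold; }",
    "</style></head><body>",
    sprintf("<h3>%s</h3>",
            html_escape(aln$query_id %||% "multiple sequence alignment"))
  )
  starts <- seq(1L, width, by = block)
  chunks <- character(0)
  for (s in starts) {
    e <- min(s + block - 1L, width)
    local_cols <- cols[cols + 1L >= s & cols + 1L <= e]
    for (i in seq_along(ids)) {
      piece <- substr(rows[i], s, e)
      ch <- strsplit(piece, "", fixed = TRUE)[[1]]
      ch <- html_escape(ch)
      if (length(local_cols))
        ch[local_cols - s + 2L] <-
          sprintf("<span class=\"diag\">%s</span>", ch[local_cols - s + 2L])
      chunks <- c(chunks, sprintf("%-*s%s", idw, html_escape(ids[i]),
                                  paste0(ch, collapse = "")))
    }
    chunks <- c(chunks,
                sprintf("%-*s%s", idw, "",
                        paste0(mark[s:e], collapse = "")),
                "")
  }
  out <- c(out, "<div>", chunks, "</div>", "</body></html>")
  writeLines(out, path)
  invisible(path)
}
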