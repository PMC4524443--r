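# Subgenome-diagnostic polymorphism detection and genome-specific assay
# design: diagnostic SNP/indel columns, fully conserved (qPCR) regions,
# primer windows anchored on diagnostic bases, primer-pair design, and
# in-silico PCR validation.

#' Detect subgenome-diagnostic alignment columns
#'
#' A column is diagnostic for `target_row` when the target's state differs
#' from every other row AND all other rows agree with each other (the
#' strict-background rule: one primer then discriminates the target from
#' every homoeolog simultaneously). Contiguous diagnostic gap columns are
#' collapsed into a single indel site (one mutational event, one
#' discriminating feature). Columns where any row carries an ambiguity code
#' are skipped, as are columns inside leading/trailing gaps of any row
#' (terminal gaps are missing data, not states).
#'
#' In relaxed mode (`strict_background = FALSE`) the target only needs to
#' differ from each other row; backgrounds may vary among themselves.
#'
#' @param msa A `homeolog_msa` with at least 2 rows.
#' @param target_row Row id to call diagnostic sites for.
#' @param strict_background Require all background rows to agree.
#' @return Data frame with `col_start`, `col_end` (0-based half-open
#'   alignment columns; length 1 for SNPs), `kind` ("SNP"/"indel"),
#'   `target_state`, `background_state`, `target_pos` (0-based position in
#'   the target row's ungapped sequence of the site's first column; for a
#'   deletion in the target, the position of the next target base).
#' @export
diagnostic_sites <- function(msa, target_row, strict_background = TRUE) {
  ti <- match(target_row, msa$ids)
  if (is.na(ti)) stop("row not in alignment")
  m <- msa_char_matrix(msa)
  nr <- nrow(m); L <- ncol(m)
  stopifnot(nr >= 2)
  # per-row terminal-gap mask: a row's leading/trailing gap columns are
  # missing data for that row only (partial rows, e.g. split loci, do not
  # veto detection across the rest of the alignment)
  interior <- matrix(FALSE, nr, L)
  for (i in seq_len(nr)) {
    bases <- which(m[i, ] != "-")
    if (length(bases)) interior[i, bases[1]:bases[length(bases)]] <- TRUE
  }
  bg_rows <- setdiff(seq_len(nr), ti)
  bgT <- interior[bg_rows, , drop = FALSE]
  bgm <- m[bg_rows, , drop = FALSE]
  n_bg <- colSums(bgT)  # background rows with data per column
  syms <- c("A", "C", "G", "T", "-")
  cnt <- vapply(syms, function(s) colSums((bgm == s) & bgT), numeric(L))
  if (L == 1) cnt <- matrix(cnt, nrow = 1)
  top <- max.col(cnt, ties.method = "first")
  top_n <- cnt[cbind(seq_len(L), top)]
  bg_state <- syms[top]
  # ambiguity in any row with data at the column masks it
  amb <- colSums(matrix(!(as.vector(m) %in% syms), nr, L) & interior) > 0
  tgt <- m[ti, ]
  agree <- if (strict_background) top_n == n_bg else rep(TRUE, L)
  if (!strict_background) {
    # relaxed: target must differ from every background row with data
    diffall <- colSums((bgm != matrix(tgt, nrow(bgm), L, byrow = TRUE)) |
                         !bgT) == nrow(bgm)
  }
  differs <- if (strict_background) tgt != bg_state else diffall
  diag_col <- interior[ti, ] & n_bg >= 1 & !amb & differs & agree
  if (!any(diag_col)) {
    return(data.frame(col_start = integer(0), col_end = integer(0),
                      kind = character(0), target_state = character(0),
                      background_state = character(0),
                      target_pos = integer(0), stringsAsFactors = FALSE))
  }
  tpos_before <- cumsum(tgt != "-")  # bases up to and including column
  is_gapsite <- diag_col & (tgt == "-" | bg_state == "-")
  cols <- which(diag_col)
  # collapse runs of adjacent diagnostic gap columns of the same character
  sites <- list()
  i <- 1L
  while (i <= length(cols)) {
    c0 <- cols[i]
    if (is_gapsite[c0]) {
      j <- i
      while (j < length(cols) && cols[j + 1] == cols[j] + 1 &&
             is_gapsite[cols[j + 1]] &&
             (tgt[cols[j + 1]] == "-") == (tgt[c0] == "-")) j <- j + 1L
      c1 <- cols[j]
      sites[[length(sites) + 1L]] <- data.frame(
        col_start = c0 - 1L, col_end = c1,
        kind = "indel",
        target_state = if (tgt[c0] == "-") "-" else
          paste0(tgt[c0:c1], collapse = ""),
        background_state = if (bg_state[c0] == "-") "-" else
          paste0(bg_state[c0:c1], collapse = ""),
        target_pos = if (tgt[c0] == "-") tpos_before[c0] else
          tpos_before[c0] - 1L,
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else {
      sites[[length(sites) + 1L]] <- data.frame(
        col_start = c0 - 1L, col_end = c0,
        kind = "SNP", target_state = tgt[c0],
        background_state = bg_state[c0],
        target_pos = tpos_before[c0] - 1L,
        stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  do.call(rbind, sites)
}

#' Fully conserved regions of an alignment
#'
#' Maximal runs of columns in which all rows carry the same base and no row
#' has a gap, of at least `min_len` columns -- candidate regions for
#' primers that amplify all homoeologs alike (RT-qPCR across subgenomes).
#'
#' @param msa A `homeolog_msa`.
#' @param min_len Minimum region length in columns.
#' @return Data frame with 0-based half-open `start`, `end` columns.
#' @export
conserved_regions <- function(msa, min_len = 18L) {
  m <- msa_char_matrix(msa)
  L <- ncol(m)
  same <- colSums(m != matrix(m[1, ], nrow(m), L, byrow = TRUE)) == 0 &
    m[1, ] %in% c("A", "C", "G", "T")
  r <- rle(same)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

#' Primer melting temperature
#'
#' Wallace rule for short oligos (`< 14` nt): `2*(A+T) + 4*(G+C)`.
#' GC-fraction formula otherwise: `64.9 + 41*(GC - 16.4)/N`.
#'
#' @param seq Character vector of gap-free A/C/G/T primer sequences
#'   (length >= 8).
#' @return Melting temperature(s) in degrees Celsius.
#' @export
#' @examples
#' melting_temp("AAAATTTT")  # 16
melting_temp <- function(seq) {
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    stopifnot(n >= 8)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!all(ch %in% c("A", "C", "G", "T")))
      stop("cannot compute Tm for ambiguous primer")
    gc <- sum(ch %in% c("G", "C"))
    at <- n - gc
    if (n < 14) 2 * at + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
  }, numeric(1), USE.NAMES = FALSE)
}

gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(ch %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Enumerate candidate genome-specific primer windows
#'
#' Windows on the target row (ungapped base coordinates) of primer-feasible
#' length that cover at least one diagnostic site in their 3'-terminal
#' `anchor` bases -- the allele-specific mechanism: a 3' mismatch on every
#' non-target homoeolog blocks extension. Forward windows anchor sites at
#' their right end, reverse windows (minus-strand primers) at their left
#' end. Ranked by number of covered diagnostic sites, then 3' proximity of
#' the nearest site.
#'
#' @param sites Output of [diagnostic_sites()] for this target.
#' @param msa The `homeolog_msa` the sites came from.
#' @param target_row Target row id.
#' @param win_len Length range (nt) of candidate windows.
#' @param anchor Number of 3'-terminal bases that must contain a site.
#' @return Data frame: `strand` ("F"/"R"), `start`, `end` (0-based
#'   half-open target-row base coordinates), `n_diag`, `dist3p` (distance of
#'   the nearest covered site from the 3' end, 0 = terminal base).
#' @export
primer_windows <- function(sites, msa, target_row, win_len = c(18L, 27L),
                           anchor = 3L) {
  ti <- match(target_row, msa$ids)
  if (is.na(ti)) stop("row not in alignment")
  n <- sum(strsplit(msa$rows[ti], "", fixed = TRUE)[[1]] != "-")
  if (is.null(sites) || nrow(sites) == 0)
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), n_diag = integer(0),
                      dist3p = integer(0), stringsAsFactors = FALSE))
  tp <- sort(unique(sites$target_pos))
  lens <- win_len[1]:win_len[2]
  # forward: 3' end (exclusive) in t+1 .. t+anchor; reverse: start in
  # t-anchor+1 .. t (plus-strand coordinates of the minus-strand primer)
  grid <- expand.grid(t = tp, off = seq_len(anchor) - 1L, L = lens,
                      KEEP.OUT.ATTRS = FALSE)
  f <- data.frame(strand = "F", start = grid$t + 1L + grid$off - grid$L,
                  end = grid$t + 1L + grid$off, stringsAsFactors = FALSE)
  r <- data.frame(strand = "R", start = grid$t - grid$off,
                  end = grid$t - grid$off + grid$L, stringsAsFactors = FALSE)
  w <- rbind(f, r)
  w <- unique(w[w$start >= 0 & w$end <= n, , drop = FALSE])
  if (nrow(w) == 0)
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), n_diag = integer(0),
                      dist3p = integer(0), stringsAsFactors = FALSE))
  # sites covered: tp in [start, end)
  lo <- findInterval(w$start - 1L, tp)   # tp <= start-1
  hi <- findInterval(w$end - 1L, tp)     # tp <= end-1
  w$n_diag <- hi - lo
  # nearest covered site to the 3' end (F: right end, R: left end)
  w$dist3p <- ifelse(w$n_diag == 0, NA_integer_, ifelse(
    w$strand == "F", w$end - 1L - tp[pmax(hi, 1L)],
    tp[pmin(lo + 1L, length(tp))] - w$start))
  # 3'-anchor requirement
  w <- w[!is.na(w$dist3p) & w$dist3p < anchor, , drop = FALSE]
  w <- w[order(-w$n_diag, w$dist3p, w$start, w$end, w$strand), , drop = FALSE]
  rownames(w) <- NULL
  w[, c("strand", "start", "end", "n_diag", "dist3p")]
}

#' Primer-pair design constraints
#'
#' @param tm_range Melting-temperature bounds (degrees C).
#' @param gc_range GC-fraction bounds.
#' @param len_range Primer length bounds (nt).
#' @param product_range Product length bounds (bp) on the target row.
#' @param max_tm_gap Maximum |Tm(F) - Tm(R)|.
#' @param min_total_diag Minimum distinct diagnostic sites covered by the
#'   two primers in total.
#' @param anchor 3'-terminal window (nt) that must contain a diagnostic
#'   base on every genome-specific primer.
#' @return A `primer_constraints` list.
#' @export
primer_constraints <- function(tm_range = c(50, 70), gc_range = c(0.3, 0.7),
                               len_range = c(18L, 27L),
                               product_range = c(80L, 1500L),
                               max_tm_gap = 5, min_total_diag = 2L,
                               anchor = 3L) {
  structure(list(tm_range = tm_range, gc_range = gc_range,
                 len_range = as.integer(len_range),
                 product_range = as.integer(product_range),
                 max_tm_gap = max_tm_gap,
                 min_total_diag = as.integer(min_total_diag),
                 anchor = as.integer(anchor)),
            class = "primer_constraints")
}

#' Design genome-specific primer pairs
#'
#' Builds forward and reverse primer candidates from diagnostic windows
#' (each genome-specific primer carries at least one diagnostic base in its
#' 3'-terminal bases), applies Tm/GC/length constraints, and pairs them so
#' that the pair covers at least `min_total_diag` distinct diagnostic sites
#' in total (single-SNP primers do not always amplify a specific fragment,
#' so pairs are required to rest on two or more SNPs or indels). Pairs are
#' ranked by total covered sites (descending), Tm gap (ascending), product
#' length (ascending), with positional tie-breaks for determinism.
#'
#' @param msa A `homeolog_msa`.
#' @param target_row Row id the primers must be specific for.
#' @param constraints A [primer_constraints()].
#' @param max_candidates Candidate windows kept per orientation before
#'   pairing.
#' @param max_pairs Maximum pairs returned.
#' @param sites Optional precomputed [diagnostic_sites()] result.
#' @return A data frame of primer pairs (`f_seq`, `f_start`, `f_end`,
#'   `f_tm`, `f_gc`, `r_seq`, `r_start`, `r_end`, `r_tm`, `r_gc`,
#'   `product_len`, `total_diag`, `target_row`), best first. Reverse-primer
#'   sequences are reverse-complemented (5'->3' of the minus strand).
#' @export
design_primer_pairs <- function(msa, target_row,
                                constraints = primer_constraints(),
                                max_candidates = 60L, max_pairs = 20L,
                                sites = NULL) {
  cs <- constraints
  if (is.null(sites)) sites <- diagnostic_sites(msa, target_row)
  if (is.null(sites) || nrow(sites) == 0)
    stop("no genome-specific pair under constraints")
  ti <- match(target_row, msa$ids)
  trow <- gsub("-", "", msa$rows[ti], fixed = TRUE)
  w <- primer_windows(sites, msa, target_row, win_len = cs$len_range,
                      anchor = cs$anchor)
  if (nrow(w) == 0) stop("no genome-specific pair under constraints")
  w$win_seq <- substring(trow, w$start + 1L, w$end)
  ok_chars <- !grepl("[^ACGT]", w$win_seq)
  w <- w[ok_chars, , drop = FALSE]
  if (nrow(w) == 0) stop("no genome-specific pair under constraints")
  w$gc <- gc_fraction(w$win_seq)
  w$tm <- melting_temp(w$win_seq)
  w <- w[w$gc >= cs$gc_range[1] & w$gc <= cs$gc_range[2] &
           w$tm >= cs$tm_range[1] & w$tm <= cs$tm_range[2], , drop = FALSE]
  if (nrow(w) == 0) stop("no genome-specific pair under constraints")
  tp <- sort(unique(sites$target_pos))
  fw <- head(w[w$strand == "F", , drop = FALSE], max_candidates)
  rv <- head(w[w$strand == "R", , drop = FALSE], max_candidates)
  if (nrow(fw) == 0 || nrow(rv) == 0)
    stop("no genome-specific pair under constraints")
  g <- expand.grid(i = seq_len(nrow(fw)), j = seq_len(nrow(rv)),
                   KEEP.OUT.ATTRS = FALSE)
  prod <- rv$end[g$j] - fw$start[g$i]
  dtm <- abs(fw$tm[g$i] - rv$tm[g$j])
  # primers must not overlap, so covered sites are disjoint and add up
  tot <- fw$n_diag[g$i] + rv$n_diag[g$j]
  ok <- rv$start[g$j] >= fw$end[g$i] &
    prod >= cs$product_range[1] & prod <= cs$product_range[2] &
    dtm <= cs$max_tm_gap & tot >= cs$min_total_diag
  if (!any(ok)) stop("no genome-specific pair under constraints")
  g <- g[ok, , drop = FALSE]
  out <- data.frame(
    target_row = target_row,
    f_seq = fw$win_seq[g$i], f_start = fw$start[g$i], f_end = fw$end[g$i],
    f_tm = fw$tm[g$i], f_gc = fw$gc[g$i],
    r_seq = revcomp(rv$win_seq[g$j]), r_start = rv$start[g$j],
    r_end = rv$end[g$j], r_tm = rv$tm[g$j], r_gc = rv$gc[g$j],
    product_len = prod[ok], total_diag = tot[ok], tm_gap = dtm[ok],
    stringsAsFactors = FALSE)
  out <- out[order(-out$total_diag, out$tm_gap, out$product_len,
                   out$f_start, out$r_end), , drop = FALSE]
  rownames(out) <- NULL
  head(out, max_pairs)
}

# Binding sites of a primer on one template strand. Returns 0-based starts
# of plus-strand footprints. sense = "plus": primer as given must match the
# template; 3'-exact window is the last bases of the footprint.
# sense = "minus": the primer binds the bottom strand, i.e. its reverse
# complement must match the top strand; 3'-exact window is the first bases.
primer_bind_sites <- function(primer, template, max_mismatch = 2L,
                              three_prime_exact = 3L, sense = "plus") {
  pat <- if (sense == "plus") primer else revcomp(primer)
  subj <- Biostrings::DNAString(template)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                   max.mismatch = max_mismatch,
                                   with.indels = FALSE)
  if (length(hits) == 0) return(integer(0))
  st <- Biostrings::start(hits); en <- Biostrings::end(hits)
  L <- nchar(pat)
  keep <- logical(length(st))
  pch <- strsplit(pat, "", fixed = TRUE)[[1]]
  for (h in seq_along(st)) {
    tch <- strsplit(substr(template, st[h], en[h]), "", fixed = TRUE)[[1]]
    mm <- pch != tch
    exact_idx <- if (sense == "plus")
      (L - three_prime_exact + 1L):L else 1L:three_prime_exact
    keep[h] <- sum(mm) <= max_mismatch && !any(mm[exact_idx])
  }
  st[keep] - 1L
}

#' In-silico PCR
#'
#' Predicts amplification products of a primer pair on template sequences.
#' A primer binds where it matches with at most `max_mismatch` mismatches
#' overall and zero mismatches in its `three_prime_exact` 3'-terminal bases
#' (no indels in the duplex). Products are reported wherever any two
#' binding events on opposite strands converge within the product-length
#' bounds; both strands and all primer combinations (F/R, F/F, R/R) are
#' enumerated. The computational analog of locating a marker with
#' aneuploid (nulli-tetrasomic) lines: absence of a product from the other
#' homoeologs demonstrates subgenome specificity.
#'
#' @param pair A single-row data frame from [design_primer_pairs()], or any
#'   list with `f_seq`, `r_seq`.
#' @param templates A [dna_set()] of template sequences.
#' @param max_mismatch Maximum mismatches tolerated per primer binding.
#' @param three_prime_exact 3'-terminal bases that must match exactly.
#' @param product_range Product length bounds (bp).
#' @return Data frame: `template_id`, `start`, `end` (0-based half-open),
#'   `product_len`, `plus_primer`, `minus_primer`.
#' @export
insilico_pcr <- function(pair, templates, max_mismatch = 2L,
                         three_prime_exact = 3L,
                         product_range = c(80L, 1500L)) {
  stopifnot(nrow(templates) >= 1)
  primers <- c(F = as.character(pair$f_seq)[1], R = as.character(pair$r_seq)[1])
  out <- list()
  for (t in seq_len(nrow(templates))) {
    tmpl <- templates$seq[t]
    plus <- lapply(primers, primer_bind_sites, template = tmpl,
                   max_mismatch = max_mismatch,
                   three_prime_exact = three_prime_exact, sense = "plus")
    minus <- lapply(primers, primer_bind_sites, template = tmpl,
                    max_mismatch = max_mismatch,
                    three_prime_exact = three_prime_exact, sense = "minus")
    for (p1 in names(primers)) for (p2 in names(primers)) {
      a <- plus[[p1]]; b <- minus[[p2]]
      if (!length(a) || !length(b)) next
      l1 <- nchar(primers[[p1]]); l2 <- nchar(primers[[p2]])
      for (x in a) for (y in b) {
        if (y < x + l1) next  # convergent, non-overlapping
        len <- y + l2 - x
        if (len < product_range[1] || len > product_range[2]) next
        out[[length(out) + 1L]] <- data.frame(
          template_id = templates$id[t], start = x, end = y + l2,
          product_len = len, plus_primer = p1, minus_primer = p2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), product_len = integer(0),
                      plus_primer = character(0), minus_primer = character(0),
                      stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$template_id, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}
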