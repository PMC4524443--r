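# Progressive multiple alignment of homoeolog sets: k-mer distances, a
# UPGMA guide tree, affine-gap profile alignment ("once a gap, always a
# gap"), and conserved-block selection over the resulting alignment.

#' K-mer distance matrix
#'
#' `d(i, j) = 1 - |shared k-mer set| / |smaller k-mer set|`, a fast
#' approximate distance adequate for guide trees over highly similar
#' homoeologous sequences.
#'
#' @param records A [dna_set()] (or any data frame with `id`, `seq`).
#' @param k Word size.
#' @return A symmetric matrix with zero diagonal, entries in \[0, 1\],
#'   dimnames from record ids.
#' @export
kmer_distance_matrix <- function(records, k = 6L) {
  n <- nrow(records)
  stopifnot(n >= 2)
  if (any(nchar(records$seq) < k))
    stop("sequence too short for k-mer distance")
  sets <- lapply(records$seq, function(s) {
    L <- nchar(s)
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    smaller <- min(length(sets[[i]]), length(sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / smaller
  }
  d
}

#' Build a UPGMA guide tree
#'
#' Average-linkage agglomeration of a distance matrix (UPGMA), as used by
#' Clustal-style progressive aligners. Deterministic for a given matrix.
#'
#' @param dist A symmetric distance matrix with zero diagonal.
#' @return An [stats::hclust] object (rooted, ultrametric heights).
#' @export
build_guide_tree <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist) ||
      !isTRUE(all.equal(dist, t(dist), tolerance = 1e-9)) ||
      any(diag(dist) != 0))
    stop("invalid distance matrix")
  stopifnot(nrow(dist) >= 2)
  stats::hclust(stats::as.dist(dist), method = "average")
}

# 6 x L frequency profile over A,C,G,T,N(other),gap for gapped rows.
profile_from_rows <- function(rows) {
  L <- nchar(rows[1])
  m <- matrix(unlist(strsplit(rows, "", fixed = TRUE)),
              nrow = length(rows), ncol = L, byrow = TRUE)
  syms <- c("A", "C", "G", "T")
  p <- matrix(0, 6, L)
  for (i in 1:4) p[i, ] <- colMeans(m == syms[i])
  p[6, ] <- colMeans(m == "-")
  p[5, ] <- 1 - colSums(p[c(1:4, 6), , drop = FALSE])
  p
}

apply_ops <- function(rows, ops, gap_code) {
  # ops: 0 = consume both, gap_code = insert gap into these rows
  n_out <- length(ops)
  keep <- ops != gap_code
  idx <- integer(n_out)
  idx[keep] <- seq_len(sum(keep))
  vapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    out <- rep("-", n_out)
    out[keep] <- ch[idx[keep]]
    paste0(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

align_band <- function(La, Lb) {
  if (max(La, Lb) <= 2000L) max(La, Lb) else 400L
}

#' Optimal global pairwise alignment (affine gaps)
#'
#' Needleman-Wunsch/Gotoh global alignment. Inputs may be plain sequences
#' or gapped rows (profiles of previously aligned groups are supported via
#' [progressive_align()]); a gap of length L costs
#' `gap_open + L * gap_extend`. For inputs up to 2 kb the full dynamic
#' program is run and the score is exact; longer inputs use a banded DP
#' sized for near-identical homoeologs.
#'
#' @param a,b DNA strings (gaps allowed).
#' @param scheme A [scoring_scheme()].
#' @return List with `a`, `b` (aligned, equal length) and `score`.
#' @export
pairwise_align_global <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(nzchar(a), nzchar(b))
  pa <- profile_from_rows(a)
  pb <- profile_from_rows(b)
  band <- align_band(ncol(pa), ncol(pb))
  r <- cpp_profile_align(pa, pb, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend, band)
  list(a = apply_ops(a, r$ops, 1L), b = apply_ops(b, r$ops, 2L),
       score = r$score)
}

#' Progressive multiple alignment along a guide tree
#'
#' Merges sequence groups in the post-order of the guide tree using
#' profile-profile affine-gap alignment. Gaps introduced at earlier merges
#' are never removed ("once a gap, always a gap"), so stripping gaps from
#' any output row reproduces its input sequence exactly.
#'
#' @param records A [dna_set()] of the sequences to align (>= 2).
#' @param tree An [stats::hclust] guide tree whose leaves are
#'   `records$id` (defaults to UPGMA on k-mer distances).
#' @param scheme A [scoring_scheme()].
#' @param query_id Optional query identifier carried in the result.
#' @param provenance Optional data frame (one row per record, in record
#'   order) describing row origins (subject, span, strand).
#' @return A `homeolog_msa`: list with `ids`, `rows` (equal-length gapped
#'   sequences, input order), `query_id`, `provenance`.
#' @export
progressive_align <- function(records, tree = NULL,
                              scheme = scoring_scheme(),
                              query_id = NULL, provenance = NULL) {
  n <- nrow(records)
  stopifnot(n >= 2)
  if (is.null(tree))
    tree <- build_guide_tree(kmer_distance_matrix(records))
  if (!inherits(tree, "hclust") || length(tree$order) != n ||
      !setequal(tree$labels %||% records$id, records$id))
    stop("tree does not cover records")
  lab <- tree$labels %||% records$id
  leaf_of <- match(lab, records$id)  # tree leaf index -> record row
  groups <- list()  # per merge node: list(idx = record rows, rows = gapped)
  for (m in seq_len(nrow(tree$merge))) {
    pick <- function(v) {
      if (v < 0) list(idx = leaf_of[-v], rows = records$seq[leaf_of[-v]])
      else groups[[v]]
    }
    ga <- pick(tree$merge[m, 1])
    gb <- pick(tree$merge[m, 2])
    pa <- profile_from_rows(ga$rows)
    pb <- profile_from_rows(gb$rows)
    band <- align_band(ncol(pa), ncol(pb))
    r <- cpp_profile_align(pa, pb, scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend, band)
    groups[[m]] <- list(
      idx = c(ga$idx, gb$idx),
      rows = c(apply_ops(ga$rows, r$ops, 1L), apply_ops(gb$rows, r$ops, 2L)),
      score = r$score)
  }
  final <- groups[[nrow(tree$merge)]]
  ord <- order(final$idx)
  structure(list(ids = records$id[final$idx[ord]],
                 rows = final$rows[ord],
                 score = final$score,
                 query_id = query_id,
                 provenance = provenance),
            class = "homeolog_msa")
}

#' @export
print.homeolog_msa <- function(x, ...) {
  cat(sprintf("homeolog MSA: %d rows x %d columns%s\n",
              length(x$ids), nchar(x$rows[1]),
              if (!is.null(x$query_id)) paste0(" (query ", x$query_id, ")")
              else ""))
  invisible(x)
}

#' Conserved-block filter parameters
#'
#' Parameter semantics follow the conserved-block model of alignment
#' trimmers: a column is conserved when its most frequent residue exceeds
#' `conserved_frac` of rows (strict majority at 0.5) and, with
#' `allow_gap_cols = "none"`, contains no gap. Defaults approximate relaxed
#' trimming.
#'
#' @param min_block_len Minimum block length (columns).
#' @param max_nonconserved_run Longest run of non-conserved columns allowed
#'   inside a block.
#' @param conserved_frac Fraction of rows the majority residue must exceed.
#' @param allow_gap_cols `"none"` (gap columns break blocks) or
#'   `"with_half"` (columns with less than half gaps may be conserved).
#' @return A `block_filter_params` list.
#' @export
block_filter_params <- function(min_block_len = 10L,
                                max_nonconserved_run = 8L,
                                conserved_frac = 0.5,
                                allow_gap_cols = c("none", "with_half")) {
  allow_gap_cols <- match.arg(allow_gap_cols)
  stopifnot(min_block_len > 0, max_nonconserved_run > 0,
            conserved_frac > 0, conserved_frac <= 1)
  structure(list(min_block_len = as.integer(min_block_len),
                 max_nonconserved_run = as.integer(max_nonconserved_run),
                 conserved_frac = conserved_frac,
                 allow_gap_cols = allow_gap_cols),
            class = "block_filter_params")
}

msa_char_matrix <- function(msa) {
  matrix(unlist(strsplit(msa$rows, "", fixed = TRUE)),
         nrow = length(msa$rows), ncol = nchar(msa$rows[1]), byrow = TRUE)
}

#' Select conserved blocks of an alignment
#'
#' Classifies every column as conserved or not, breaks the alignment at gap
#' columns (under `allow_gap_cols = "none"`) and at non-conserved runs
#' longer than `max_nonconserved_run`, trims non-conserved flanks from each
#' segment and keeps segments of at least `min_block_len` columns. Used for
#' conserved-region (qPCR) discovery; diagnostic-site scanning runs on the
#' untrimmed alignment.
#'
#' @param msa A `homeolog_msa`.
#' @param p A [block_filter_params()].
#' @return Data frame of blocks with 0-based half-open `start`, `end`.
#' @export
select_conserved_blocks <- function(msa, p = block_filter_params()) {
  m <- msa_char_matrix(msa)
  nr <- nrow(m); L <- ncol(m)
  gapfrac <- colMeans(m == "-")
  basecount <- vapply(c("A", "C", "G", "T"),
                      function(s) colSums(m == s), numeric(L))
  if (L == 1) basecount <- matrix(basecount, nrow = 1)
  topfrac <- apply(basecount, 1, max) / nr
  hasgap <- gapfrac > 0
  conserved <- topfrac > p$conserved_frac &
    (if (p$allow_gap_cols == "none") !hasgap else gapfrac < 0.5)
  hard_break <- if (p$allow_gap_cols == "none") hasgap else gapfrac >= 0.5
  blocks <- list()
  seg_start <- 1L
  flush_segment <- function(s, e) {
    # trim nonconserved flanks; split at long nonconserved runs
    cols <- s:e
    cons <- conserved[cols]
    if (!any(cons)) return(NULL)
    lo <- cols[which(cons)[1]]
    hi <- cols[tail(which(cons), 1)]
    res <- list()
    run_start <- lo; run_bad <- 0L; piece_start <- lo
    i <- lo
    while (i <= hi) {
      if (conserved[i]) run_bad <- 0L
      else {
        run_bad <- run_bad + 1L
        if (run_bad > p$max_nonconserved_run) {
          piece_end <- i - run_bad
          if (piece_end >= piece_start)
            res[[length(res) + 1L]] <- c(piece_start, piece_end)
          # next piece starts at next conserved column
          nxt <- i + 1L
          while (nxt <= hi && !conserved[nxt]) nxt <- nxt + 1L
          piece_start <- nxt
          i <- nxt
          run_bad <- 0L
          next
        }
      }
      i <- i + 1L
    }
    if (piece_start <= hi)
      res[[length(res) + 1L]] <- c(piece_start, hi)
    res
  }
  pieces <- list()
  i <- 1L
  while (i <= L) {
    if (hard_break[i]) {
      if (i > seg_start)
        pieces <- c(pieces, flush_segment(seg_start, i - 1L))
      seg_start <- i + 1L
    }
    i <- i + 1L
  }
  if (seg_start <= L)
    pieces <- c(pieces, flush_segment(seg_start, L))
  pieces <- Filter(function(x) x[2] - x[1] + 1L >= p$min_block_len, pieces)
  if (!length(pieces))
    return(data.frame(start = integer(0), end = integer(0)))
  out <- do.call(rbind, pieces)
  data.frame(start = out[, 1] - 1L, end = out[, 2])  # 0-based half-open
}
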