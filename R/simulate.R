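# Synthetic allopolyploid genomes with full ground truth: ancestral genes
# with exon/intron structure and homologous flanking sequence, k
# independently diverged subgenome copies embedded in contigs on random
# strands, and a complete per-base event log from which the set of truly
# subgenome-diagnostic positions is derived.

#' Simulation configuration
#'
#' Defaults emulate a hexaploid (k = 3) target at 2% subgenome divergence
#' with a 0.1% per-base indel rate; exon lengths start at the pipeline's
#' minimum-exon cutoff and introns stay below its maximum-intron cutoff so
#' the true gene structures are recoverable. `contig_pad` bp of homologous
#' (ancestrally shared, then diverged) flanking sequence surround each gene
#' copy -- homoeologous chromosomes are homologous beyond the gene -- with
#' a short random tail at the contig ends.
#'
#' @param n_genes Number of genes.
#' @param n_subgenomes Subgenome count k.
#' @param exons_per_gene Range of exon counts.
#' @param exon_len Range of exon lengths (bp); minimum >= 200.
#' @param intron_len Range of intron lengths (bp); maximum < 5000.
#' @param divergence Per-base substitution probability per subgenome.
#' @param indel_rate Per-base indel event probability per subgenome.
#' @param indel_len Range of indel lengths (bp).
#' @param contig_pad Homologous flanking sequence (bp) per side (>= 400,
#'   so 300 bp flank extraction never leaves homologous sequence).
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50L, n_subgenomes = 3L,
                       exons_per_gene = c(1L, 5L),
                       exon_len = c(200L, 600L),
                       intron_len = c(60L, 4800L),
                       divergence = 0.02, indel_rate = 0.001,
                       indel_len = c(1L, 10L), contig_pad = 450L,
                       seed = 1L) {
  ok <- n_genes >= 1 && n_subgenomes >= 2 &&
    exons_per_gene[1] >= 1 && exons_per_gene[2] >= exons_per_gene[1] &&
    exon_len[1] >= 200 && exon_len[2] >= exon_len[1] &&
    intron_len[1] >= 1 && intron_len[2] >= intron_len[1] &&
    intron_len[2] < 5000 &&
    divergence >= 0 && divergence <= 1 &&
    indel_rate >= 0 && indel_rate <= 1 &&
    indel_len[1] >= 1 && indel_len[2] >= indel_len[1] &&
    contig_pad >= 400
  if (!ok) stop("invalid simulation config")
  structure(list(n_genes = as.integer(n_genes),
                 n_subgenomes = as.integer(n_subgenomes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 divergence = divergence, indel_rate = indel_rate,
                 indel_len = as.integer(indel_len),
                 contig_pad = as.integer(contig_pad),
                 seed = as.integer(seed)),
            class = "sim_config")
}

sample_range <- function(r, n = 1L) {
  if (r[1] == r[2]) rep(r[1], n) else sample(r[1]:r[2], n, replace = TRUE)
}

#' Mutate a sequence, logging every event
#'
#' Applies substitutions (never silent: the alternative base always differs
#' from the reference) and insertion/deletion events at the given per-base
#' rates, using the current RNG stream. Every event is logged with its
#' coordinates in both the source and the mutated sequence, and full
#' coordinate maps between the two are returned (strictly monotone over
#' surviving bases).
#'
#' @param seq Source DNA string.
#' @param sub_rate Per-base substitution probability.
#' @param indel_rate Per-base indel event probability.
#' @param indel_len Indel length range.
#' @return List: `seq` (mutated), `events` (data frame `kind`
#'   ("sub"/"ins"/"del"), `src_start`, `src_end`, `mut_start`, `mut_end`
#'   (0-based half-open; insertions have an empty source interval,
#'   deletions an empty mutated interval), `ref`, `alt`), `src2mut`
#'   (0-based mutated position per source base, NA where deleted),
#'   `src2mut_filled` (NAs replaced by the next surviving base's position),
#'   `mut2src` (source position per mutated base, NA for inserted bases),
#'   `mut2src_filled`, `deleted` (logical per source base).
#' @export
mutate_seq <- function(seq, sub_rate, indel_rate, indel_len = c(1L, 10L)) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  events <- list()
  # substitutions (applied before indels; a later deletion removes them)
  sub_pos <- if (sub_rate > 0) which(runif(n) < sub_rate) else integer(0)
  sub_alt <- character(length(sub_pos))
  for (i in seq_along(sub_pos)) {
    p <- sub_pos[i]
    sub_alt[i] <- sample(bases[bases != ch[p]], 1L)
  }
  ch2 <- ch
  if (length(sub_pos)) ch2[sub_pos] <- sub_alt
  # indel events
  ind_pos <- if (indel_rate > 0) which(runif(n) < indel_rate) else integer(0)
  ind <- list()
  last_end <- 0L  # 1-based source position already consumed by a deletion
  for (p in ind_pos) {
    if (p <= last_end) next
    type <- sample(c("ins", "del"), 1L)
    len <- sample_range(indel_len)
    if (type == "del") {
      len <- min(len, n - p + 1L)
      ind[[length(ind) + 1L]] <- list(type = "del", p = p, len = len)
      last_end <- p + len - 1L
    } else {
      ins_seq <- paste0(sample(bases, len, replace = TRUE), collapse = "")
      ind[[length(ind) + 1L]] <- list(type = "ins", p = p, len = len,
                                      ins = ins_seq)
      last_end <- p
    }
  }
  # build mutated sequence and coordinate maps by walking the source
  seq2 <- paste0(ch2, collapse = "")
  parts <- character(0)
  cur <- 1L       # next source base (1-based) to copy
  out_len <- 0L
  deleted <- logical(n)
  delta <- integer(n + 1L)  # shift of mut-src offset starting at src index
  for (e in ind) {
    p <- e$p
    if (p > cur) {
      parts <- c(parts, substr(seq2, cur, p - 1L))
      out_len <- out_len + (p - cur)
    }
    if (e$type == "ins") {
      # insertion before source base p
      events[[length(events) + 1L]] <- data.frame(
        kind = "ins", src_start = p - 1L, src_end = p - 1L,
        mut_start = out_len, mut_end = out_len + e$len,
        ref = "", alt = e$ins, stringsAsFactors = FALSE)
      parts <- c(parts, e$ins)
      out_len <- out_len + e$len
      delta[p] <- delta[p] + e$len
      cur <- p
    } else {
      events[[length(events) + 1L]] <- data.frame(
        kind = "del", src_start = p - 1L, src_end = p - 1L + e$len,
        mut_start = out_len, mut_end = out_len,
        ref = substr(seq, p, p + e$len - 1L), alt = "",
        stringsAsFactors = FALSE)
      deleted[p:(p + e$len - 1L)] <- TRUE
      if (p + e$len <= n) delta[p + e$len] <- delta[p + e$len] - e$len
      cur <- p + e$len
    }
  }
  if (cur <= n) {
    parts <- c(parts, substr(seq2, cur, n))
    out_len <- out_len + (n - cur + 1L)
  }
  mut <- paste0(parts, collapse = "")
  shift <- cumsum(delta)[seq_len(n)]
  src2mut <- (seq_len(n) - 1L) + shift
  src2mut[deleted] <- NA_integer_
  # substitution events (skip those erased by a deletion)
  for (i in seq_along(sub_pos)) {
    p <- sub_pos[i]
    if (deleted[p]) next
    events[[length(events) + 1L]] <- data.frame(
      kind = "sub", src_start = p - 1L, src_end = p,
      mut_start = src2mut[p], mut_end = src2mut[p] + 1L,
      ref = ch[p], alt = sub_alt[i], stringsAsFactors = FALSE)
  }
  nm <- nchar(mut)
  mut2src <- rep(NA_integer_, nm)
  alive <- which(!deleted)
  mut2src[src2mut[alive] + 1L] <- alive - 1L
  fill_forward <- function(map, limit) {
    # replace NA with the next non-NA value (or limit at the tail)
    idx <- rev(seq_along(map))
    nxt <- limit
    for (i in idx) {
      if (is.na(map[i])) map[i] <- nxt else nxt <- map[i]
    }
    map
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), src_start = integer(0),
               src_end = integer(0), mut_start = integer(0),
               mut_end = integer(0), ref = character(0),
               alt = character(0), stringsAsFactors = FALSE)
  ev <- ev[order(ev$src_start, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL
  list(seq = mut, events = ev,
       src2mut = src2mut,
       src2mut_filled = fill_forward(src2mut, nm),
       mut2src = mut2src,
       mut2src_filled = fill_forward(mut2src, n),
       deleted = deleted)
}

derive_diagnostic_truth <- function(cfg, unit, gene_span, copies) {
  k <- length(copies)
  subg <- names(copies)
  # substitution states per position with any sub event
  sub_ev <- lapply(copies, function(cp)
    cp$mut$events[cp$mut$events$kind == "sub", , drop = FALSE])
  pos <- sort(unique(unlist(lapply(sub_ev, function(e) e$src_start))))
  anc <- strsplit(unit, "", fixed = TRUE)[[1]]
  diag <- list()
  for (p in pos) {
    # skip positions deleted in any copy (covered by indel events instead)
    if (any(vapply(copies, function(cp) cp$mut$deleted[p + 1L], logical(1))))
      next
    states <- vapply(seq_len(k), function(s) {
      e <- sub_ev[[s]]
      hit <- e$src_start == p
      if (any(hit)) e$alt[hit][1] else anc[p + 1L]
    }, character(1))
    for (s in seq_len(k)) {
      others <- states[-s]
      if (all(others == others[1]) && states[s] != others[1]) {
        diag[[length(diag) + 1L]] <- data.frame(
          subgenome = subg[s], kind = "SNP", src_start = p, src_end = p + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  # indels private to one subgenome (no other copy with an indel within 2 bp)
  ind_ev <- lapply(copies, function(cp)
    cp$mut$events[cp$mut$events$kind %in% c("ins", "del"), , drop = FALSE])
  for (s in seq_len(k)) {
    e <- ind_ev[[s]]
    for (i in seq_len(nrow(e))) {
      a <- e$src_start[i] - 2L; b <- e$src_end[i] + 2L
      clash <- FALSE
      for (h in seq_len(k)[-s]) {
        eh <- ind_ev[[h]]
        if (nrow(eh) && any(eh$src_end >= a & eh$src_start <= b)) {
          clash <- TRUE; break
        }
      }
      if (!clash) {
        diag[[length(diag) + 1L]] <- data.frame(
          subgenome = subg[s], kind = "indel",
          src_start = e$src_start[i], src_end = e$src_end[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(diag))
    return(data.frame(subgenome = character(0), kind = character(0),
                      src_start = integer(0), src_end = integer(0),
                      in_gene = logical(0), stringsAsFactors = FALSE))
  d <- do.call(rbind, diag)
  d$in_gene <- d$src_end > gene_span[1] & d$src_start < gene_span[2]
  d <- d[order(d$subgenome, d$src_start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Simulate an allopolyploid query/genome pair with ground truth
#'
#' Each gene is an ancestral sequence of 1-5 exons separated by introns,
#' surrounded by `contig_pad` bp of homologous flanking sequence. Each of
#' the k subgenome copies diverges independently from the ancestor (star
#' phylogeny) by substitutions and indels, is placed on its own contig on a
#' random strand, and padded with a short random tail. The query set holds
#' the ancestral CDS (concatenated exons). The truth object records, per
#' gene and subgenome, the contig, copy interval, orientation, full event
#' log and coordinate maps, plus the derived set of diagnostic positions
#' (positions where exactly one subgenome deviates and all others share a
#' state). With `divergence = 0` and `indel_rate = 0` the copies are
#' identical and the diagnostic truth is empty.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; writes `queries.fa`, `genome.fa` and
#'   `truth.tsv` (diagnostic-site table) when given.
#' @return List with `queries` ([dna_set()] of CDS), `genome` ([dna_set()]
#'   of contigs), `truth` (per-gene list), `cfg`.
#' @export
simulate_polyploid <- function(cfg = sim_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  k <- cfg$n_subgenomes
  subg <- paste0("sub", LETTERS[seq_len(k)])
  q_ids <- character(cfg$n_genes); q_seqs <- character(cfg$n_genes)
  g_ids <- character(0); g_seqs <- character(0)
  truth <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("gene%03d", g)
    n_ex <- sample_range(cfg$exons_per_gene)
    ex_len <- sample_range(cfg$exon_len, n_ex)
    in_len <- if (n_ex > 1) sample_range(cfg$intron_len, n_ex - 1L) else integer(0)
    pad <- cfg$contig_pad
    # unit layout: [flank | e1 i1 e2 ... en | flank]
    exon_starts <- pad + cumsum(c(0L, head(ex_len, -1) + in_len))
    gene_len <- sum(ex_len) + sum(in_len)
    unit_len <- gene_len + 2L * pad
    unit <- random_dna(unit_len)
    gene_span <- c(pad, pad + gene_len)
    exon_spans <- cbind(start = exon_starts, end = exon_starts + ex_len)
    cds <- paste0(substring(unit, exon_spans[, 1] + 1L, exon_spans[, 2]),
                  collapse = "")
    q_ids[g] <- gid; q_seqs[g] <- cds
    copies <- list()
    for (s in seq_len(k)) {
      mut <- mutate_seq(unit, cfg$divergence, cfg$indel_rate, cfg$indel_len)
      orient <- sample(c("+", "-"), 1L)
      tl <- random_dna(sample(30:80, 1L))
      tr <- random_dna(sample(30:80, 1L))
      contig_plus <- paste0(tl, mut$seq, tr)
      a <- nchar(tl); b <- a + nchar(mut$seq)
      contig <- contig_plus
      if (orient == "-") {
        L <- nchar(contig_plus)
        contig <- revcomp(contig_plus)
        tmp <- a; a <- L - b; b <- L - tmp
      }
      cid <- paste0(gid, "_", subg[s])
      g_ids <- c(g_ids, cid); g_seqs <- c(g_seqs, contig)
      copies[[subg[s]]] <- list(subgenome = subg[s], contig_id = cid,
                                copy_interval = c(a, b), orient = orient,
                                mut = mut)
    }
    diag <- derive_diagnostic_truth(cfg, unit, gene_span, copies)
    truth[[g]] <- list(query_id = gid, unit_len = unit_len,
                       gene_span = gene_span, exon_spans = exon_spans,
                       copies = copies, diag = diag)
    names(truth)[g] <- gid
  }
  out <- list(queries = dna_set(q_ids, q_seqs),
              genome = dna_set(g_ids, g_seqs),
              truth = truth, cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$queries, file.path(out_dir, "queries.fa"))
    write_fasta(out$genome, file.path(out_dir, "genome.fa"))
    dtab <- do.call(rbind, lapply(names(truth), function(id) {
      d <- truth[[id]]$diag
      if (nrow(d)) cbind(query_id = id, d) else NULL
    }))
    if (is.null(dtab))
      dtab <- data.frame(query_id = character(0), subgenome = character(0),
                         kind = character(0), src_start = integer(0),
                         src_end = integer(0), in_gene = logical(0))
    write.table(dtab, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Map a position on an extracted-locus row back to ancestral coordinates
#'
#' Translates a 0-based base position on an extracted homoeolog row (gene
#' orientation) to the position on the ancestral unit of the simulated gene
#' it derives from, via the contig and the mutation coordinate map.
#'
#' @param t 0-based base position(s) on the row's ungapped sequence.
#' @param prov One provenance entry: list/row with `source_span` (c(start,
#'   end) on the contig plus strand) and `strand`.
#' @param copy The matching truth copy (with `copy_interval`, `orient`,
#'   `mut`).
#' @return Integer vector of 0-based ancestral-unit positions (NA when the
#'   position falls outside the simulated copy).
#' @export
row_pos_to_unit <- function(t, prov, copy) {
  p <- if (prov$strand == "+") prov$source_span[1] + t
       else prov$source_span[2] - 1L - t
  m <- if (copy$orient == "+") p - copy$copy_interval[1]
       else copy$copy_interval[2] - 1L - p
  nm <- length(copy$mut$mut2src_filled)
  u <- rep(NA_integer_, length(t))
  ok <- !is.na(m) & m >= 0 & m < nm
  u[ok] <- copy$mut$mut2src_filled[m[ok] + 1L]
  u
}
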