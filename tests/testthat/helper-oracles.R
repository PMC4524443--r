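# Independent oracles used to verify the package's dynamic-programming
# implementations on small instances. Deliberately naive: exhaustive
# recursion/enumeration, no shared code with the implementations.

# Exhaustive global affine-gap alignment score by recursion over edit
# operations (memoized on position + previous operation). Gap of length L
# costs gap_open + L * gap_extend.
oracle_global_score <- function(a, b, sch = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  memo <- array(NA_real_, dim = c(na + 1, nb + 1, 3))
  states <- c(M = 1, GA = 2, GB = 3)  # GA: gap in a, GB: gap in b
  rec <- function(i, j, st) {
    if (i > na && j > nb) return(0)
    if (!is.na(memo[i, j, st])) return(memo[i, j, st])
    best <- -Inf
    if (i <= na && j <= nb) {
      s <- if (A[i] == B[j]) sch$match else sch$mismatch
      best <- max(best, s + rec(i + 1, j + 1, states["M"]))
    }
    if (j <= nb) {  # consume b, gap in a
      open <- if (st == states["GA"]) 0 else sch$gap_open
      best <- max(best, open + sch$gap_extend + rec(i, j + 1, states["GA"]))
    }
    if (i <= na) {  # consume a, gap in b
      open <- if (st == states["GB"]) 0 else sch$gap_open
      best <- max(best, open + sch$gap_extend + rec(i + 1, j, states["GB"]))
    }
    memo[i, j, st] <<- best
    best
  }
  rec(1, 1, states["M"])
}

# Exhaustive best-chain score: enumerate all subsets of HSPs, keep those
# whose subject-sorted order satisfies the chaining constraints, return the
# maximum raw-score sum (0 when no HSP survives the min-exon filter).
oracle_chain_score <- function(h, cfg) {
  h <- h[(h$send - h$sstart) >= cfg$min_exon, , drop = FALSE]
  n <- nrow(h)
  if (n == 0) return(0)
  best <- 0
  for (mask in 1:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    hh <- h[sel, , drop = FALSE]
    hh <- hh[order(hh$sstart, hh$send), , drop = FALSE]
    ok <- TRUE
    if (nrow(hh) > 1) {
      for (t in 2:nrow(hh)) {
        gap <- hh$sstart[t] - hh$send[t - 1]
        if (gap < 0 || gap > cfg$max_intron) { ok <- FALSE; break }
        if (cfg$colinear) {
          sl <- cfg$query_overlap_slop
          if (hh$strand[1] == "+") {
            if (!(hh$qstart[t] >= hh$qend[t - 1] - sl &&
                  hh$qstart[t] > hh$qstart[t - 1] &&
                  hh$qend[t] > hh$qend[t - 1])) { ok <- FALSE; break }
          } else {
            if (!(hh$qend[t] <= hh$qstart[t - 1] + sl &&
                  hh$qend[t] < hh$qend[t - 1] &&
                  hh$qstart[t] < hh$qstart[t - 1])) { ok <- FALSE; break }
          }
        }
      }
    }
    if (ok) best <- max(best, sum(hh$raw_score))
  }
  best
}

# Naive UPGMA agglomeration returning the cophenetic distance matrix.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- matrix(0, n, n)
  active <- rep(TRUE, n)
  dd <- d
  sizes <- rep(1L, n)
  repeat {
    idx <- which(active)
    if (length(idx) == 1) break
    best <- c(NA, NA); bv <- Inf
    for (i in idx) for (j in idx) if (i < j && dd[i, j] < bv) {
      bv <- dd[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      heights[a, b] <- heights[b, a] <- bv
    # average linkage update into slot i
    for (k in idx) if (k != i && k != j) {
      dd[i, k] <- dd[k, i] <-
        (dd[i, k] * sizes[i] + dd[j, k] * sizes[j]) / (sizes[i] + sizes[j])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  heights
}

# Smith-Waterman optimum via Biostrings (independent of the package's
# seed-and-extend path).
oracle_sw_score <- function(q, s, sch = scoring_scheme()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = sch$match, mismatch = sch$mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = mat, gapOpening = -sch$gap_open,
    gapExtension = -sch$gap_extend, scoreOnly = TRUE)
}

# Naive hit filter: drop by E-value, rank subjects by best bitscore, keep
# top max_hits subjects.
oracle_filter <- function(h, max_hits = 10L, evalue_max = 1e-5) {
  h <- h[h$evalue <= evalue_max, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  bests <- sapply(split(h$bitscore, h$subject_id), max)
  keep <- names(sort(bests, decreasing = TRUE))
  # deterministic among equal bitscores: id order
  keep <- keep[order(-bests[keep], keep)]
  keep <- keep[seq_len(min(max_hits, length(keep)))]
  h[h$subject_id %in% keep, , drop = FALSE]
}

# Naive double-strand IUPAC restriction-site scan.
iupac_regex <- function(pat) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste0(map[strsplit(pat, "")[[1]]], collapse = "")
}

oracle_cut_positions <- function(seq, enz) {
  find_all <- function(pattern, x) {
    res <- integer(0); start <- 1L
    rx <- iupac_regex(pattern)
    repeat {
      m <- regexpr(rx, substr(x, start, nchar(x)), perl = TRUE)
      if (m == -1) break
      pos <- start + as.integer(m) - 1L
      res <- c(res, pos)
      start <- pos + 1L
    }
    res
  }
  L <- nchar(enz$site)
  cuts <- find_all(enz$site, seq) - 1L + enz$cut_offset
  if (!enz$palindromic) {
    rc <- revcomp(enz$site)
    cuts <- c(cuts, find_all(rc, seq) - 1L + (L - enz$cut_offset))
  }
  sort(unique(cuts))
}

# Random test-data builders -------------------------------------------------

random_records <- function(n, len_range = c(20L, 120L)) {
  dna_set(paste0("r", seq_len(n)),
          vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
                 random_dna_str, character(1)),
          desc = ifelse(seq_len(n) %% 2 == 0, paste("desc", seq_len(n)), ""))
}

random_dna_str <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random HSP table on one (query, subject, strand) group.
random_hsp_group <- function(n, strand = "+", min_len = 100L,
                             max_len = 400L) {
  slen <- sample(min_len:max_len, n, replace = TRUE)
  sstart <- sort(sample(0:20000, n))
  qlen <- pmax(50L, slen - sample(0:50, n, replace = TRUE))
  qstart <- sample(0:3000, n, replace = TRUE)
  hsps <- data.frame(
    query_id = "q", subject_id = "s",
    qstart = qstart, qend = qstart + qlen,
    sstart = sstart, send = sstart + slen,
    strand = strand, identity = 0.98, aln_length = slen,
    raw_score = sample(100:900, n, replace = TRUE),
    bitscore = 0, evalue = 0, stringsAsFactors = FALSE)
  class(hsps) <- c("hsp_table", "data.frame")
  hsps
}
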