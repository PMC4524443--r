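test_that("k-mer distances separate identical, disjoint and graded pairs", {
  r <- dna_set(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"))
  d <- kmer_distance_matrix(r)
  expect_equal(d["a", "b"], 0)

  r2 <- dna_set(c("a", "b"), c("AAAAAAAAAA", "CCCCCCCCCC"))
  expect_equal(kmer_distance_matrix(r2)["a", "b"], 1)

  expect_error(kmer_distance_matrix(dna_set(c("a", "b"), c("ACG", "ACGTAA"))),
               "too short")

  # graded divergence: the closer pair has the smaller distance
  set.seed(301)
  anc <- random_dna_str(400)
  near1 <- mutate_seq(anc, 0.01, 0)$seq
  near2 <- mutate_seq(anc, 0.01, 0)$seq
  far <- mutate_seq(anc, 0.10, 0)$seq
  d <- kmer_distance_matrix(dna_set(c("n1", "n2", "f"), c(near1, near2, far)))
  expect_lt(d["n1", "n2"], d["n1", "f"])
  expect_lt(d["n1", "n2"], d["n2", "f"])
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("UPGMA guide tree matches naive agglomeration", {
  # forced topology
  d <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_guide_tree(d)
  expect_s3_class(tr, "hclust")
  expect_equal(sort(tr$merge[1, ]), c(-2, -1))  # (A,B) first

  expect_error(build_guide_tree(matrix(c(0, 1, 2, 0), 2, 2)),
               "invalid distance matrix")

  set.seed(302)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- build_guide_tree(m)
    coph <- as.matrix(stats::cophenetic(tr))[rownames(m), colnames(m)]
    expect_equal(unname(coph), unname(oracle_upgma_cophenetic(m)),
                 tolerance = 1e-10)
  }
})

test_that("pairwise global aligner is optimal on small instances", {
  sch <- scoring_scheme()
  r <- pairwise_align_global("ACGTACGT", "ACGTACGT", sch)
  expect_equal(r$a, "ACGTACGT")
  expect_equal(r$score, 8 * sch$match)

  r2 <- pairwise_align_global("ACGT", "AGT", sch)
  expect_equal(nchar(r2$a), 4)
  expect_equal(sum(strsplit(r2$b, "")[[1]] == "-"), 1)
  expect_equal(r2$score, oracle_global_score("ACGT", "AGT", sch))

  set.seed(303)
  for (rep in 1:100) {
    a <- random_dna_str(sample(1:8, 1))
    b <- random_dna_str(sample(1:8, 1))
    r <- pairwise_align_global(a, b, sch)
    expect_equal(r$score, oracle_global_score(a, b, sch),
                 info = paste(a, b))
    expect_equal(gsub("-", "", r$a), a)
    expect_equal(gsub("-", "", r$b), b)
  }
})

test_that("affine gaps keep an inserted block contiguous", {
  set.seed(304)
  a <- random_dna_str(60)
  b <- paste0(substr(a, 1, 30), "TTT", substr(a, 31, 60))
  # avoid accidental homopolymer ambiguity: just require one 3-long gap run
  r <- pairwise_align_global(a, b)
  gaps <- gregexpr("-+", r$a)[[1]]
  expect_equal(sum(attr(gaps, "match.length")), 3)
  expect_equal(length(gaps[gaps > 0]), 1)  # a single run, not split gaps
})

test_that("progressive alignment dealigns exactly and handles planted indels", {
  set.seed(305)
  # identical sequences: gap-free alignment
  s <- random_dna_str(200)
  msa <- progressive_align(dna_set(c("a", "b", "c"), c(s, s, s)))
  expect_false(any(grepl("-", msa$rows)))
  expect_equal(length(unique(nchar(msa$rows))), 1)

  # diverged homoeologs, one with a planted 5 bp deletion
  anc <- random_dna_str(500)
  h1 <- mutate_seq(anc, 0.02, 0)$seq
  h2 <- mutate_seq(anc, 0.02, 0)$seq
  h3 <- paste0(substr(anc, 1, 249), substr(anc, 255, 500))
  recs <- dna_set(c("h1", "h2", "h3"), c(h1, h2, h3))
  msa <- progressive_align(recs)
  # round trip: stripping gaps recovers every input
  for (i in 1:3)
    expect_equal(gsub("-", "", msa$rows[match(recs$id[i], msa$ids)]),
                 recs$seq[i])
  # the deletion shows as a 5-column gap run in exactly that row
  r3 <- msa$rows[match("h3", msa$ids)]
  gaps <- gregexpr("-+", r3)[[1]]
  expect_true(any(attr(gaps, "match.length") == 5))

  # n = 2 degenerates to the exact pairwise optimum
  two <- dna_set(c("x", "y"), c("ACGTACGTAA", "ACGACGTAA"))
  msa2 <- progressive_align(two)
  pw <- pairwise_align_global(two$seq[1], two$seq[2])
  expect_equal(msa2$score, pw$score)

  expect_error(progressive_align(recs, tree = build_guide_tree(
    matrix(c(0, .1, .1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))),
    "tree does not cover records")
})

test_that("dealignment round-trip holds for random homoeolog sets", {
  set.seed(306)
  for (rep in 1:5) {
    anc <- random_dna_str(sample(300:800, 1))
    n <- sample(3:5, 1)
    recs <- dna_set(paste0("h", 1:n),
                    vapply(1:n, function(i) mutate_seq(anc, 0.03, 0.002)$seq,
                           character(1)))
    msa <- progressive_align(recs)
    expect_equal(length(unique(nchar(msa$rows))), 1)
    for (i in seq_len(n))
      expect_equal(gsub("-", "", msa$rows[match(recs$id[i], msa$ids)]),
                   recs$seq[i])
  }
})

test_that("conserved-block selection follows the block model", {
  p <- block_filter_params()
  mk_msa <- function(rows) structure(
    list(ids = paste0("r", seq_along(rows)), rows = rows),
    class = "homeolog_msa")

  # fully conserved alignment: one block covering everything
  s <- random_dna_str(60)
  b <- select_conserved_blocks(mk_msa(c(s, s, s)), p)
  expect_equal(b, data.frame(start = 0L, end = 60L))

  # a single central gap column splits the alignment in two blocks
  left <- random_dna_str(30); right <- random_dna_str(29)
  rows <- c(paste0(left, "A", right), paste0(left, "A", right),
            paste0(left, "-", right))
  b2 <- select_conserved_blocks(mk_msa(rows), p)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$start, c(0L, 31L))
  expect_equal(b2$end, c(30L, 60L))

  # planted conserved/divergent mosaic: blocks coincide with the plant
  # (divergent stretch has three distinct states per column, so it cannot
  # satisfy a strict-majority conservation rule)
  set.seed(307)
  conserved1 <- random_dna_str(40)
  conserved2 <- random_dna_str(40)
  divergent <- c(strrep("A", 20), strrep("C", 20), strrep("G", 20))
  rows3 <- vapply(1:3, function(i)
    paste0(conserved1, divergent[i], conserved2), character(1))
  b3 <- select_conserved_blocks(mk_msa(rows3), p)
  expect_equal(nrow(b3), 2)
  expect_lte(abs(b3$start[1] - 0), 1)
  expect_lte(abs(b3$end[1] - 40), 1)
  expect_lte(abs(b3$start[2] - 60), 1)
  expect_lte(abs(b3$end[2] - 100), 1)
  # every in-block column satisfies the conservation predicate
  m <- do.call(rbind, strsplit(rows3, ""))
  for (k in seq_len(nrow(b3))) {
    cols <- (b3$start[k] + 1):b3$end[k]
    for (cc in cols) {
      tab <- table(m[, cc])
      expect_gt(max(tab[names(tab) != "-"]) / nrow(m), p$conserved_frac)
      expect_false("-" %in% names(tab))
    }
  }
})
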