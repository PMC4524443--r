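mk_hsp <- function(qstart, qend, sstart, send, score, strand = "+") {
  h <- data.frame(query_id = "q", subject_id = "s", qstart = qstart,
                  qend = qend, sstart = sstart, send = send,
                  strand = strand, identity = 1,
                  aln_length = send - sstart, raw_score = score,
                  bitscore = 0, evalue = 0, stringsAsFactors = FALSE)
  class(h) <- c("hsp_table", "data.frame")
  h
}

test_that("intron and exon length rules force chain structure", {
  cfg <- pipeline_config()
  # single HSP above the exon minimum: one locus, one block
  loci <- chain_hsps(mk_hsp(0, 250, 1000, 1250, 500), cfg)
  expect_length(loci, 1)
  expect_equal(nrow(loci[[1]]$blocks), 1)

  # a 150 bp footprint is discarded, a 250 bp one survives
  expect_length(chain_hsps(mk_hsp(0, 150, 1000, 1150, 300), cfg), 0)
  expect_length(chain_hsps(mk_hsp(0, 250, 1000, 1250, 300), cfg), 1)

  # subject gap of 4,800 bp chains; 5,001 bp splits
  two <- function(gap) rbind(mk_hsp(0, 250, 1000, 1250, 500),
                             mk_hsp(250, 500, 1250 + gap, 1500 + gap, 500))
  near <- two(4800); class(near) <- c("hsp_table", "data.frame")
  far <- two(5001); class(far) <- c("hsp_table", "data.frame")
  expect_length(chain_hsps(near, cfg), 1)
  expect_equal(nrow(chain_hsps(near, cfg)[[1]]$blocks), 2)
  expect_length(chain_hsps(far, cfg), 2)

  mixed <- rbind(mk_hsp(0, 250, 0, 250, 1), mk_hsp(0, 250, 0, 250, 1, "-"))
  class(mixed) <- c("hsp_table", "data.frame")
  expect_error(chain_hsps(mixed, cfg), "one subject/strand group")
})

test_that("chaining DP equals exhaustive subset enumeration", {
  set.seed(201)
  cfg <- pipeline_config()
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    strand <- sample(c("+", "-"), 1)
    h <- random_hsp_group(n, strand = strand)
    if (strand == "-") {
      # roughly anti-colinear query coordinates for some realism
      h$qstart <- rev(h$qstart)
      h$qend <- h$qstart + (h$send - h$sstart)
    }
    loci <- chain_hsps(h, cfg)
    got <- if (length(loci)) max(vapply(loci, function(l) l$chain_score,
                                        numeric(1))) else 0
    expect_equal(got, oracle_chain_score(h, cfg),
                 info = paste("instance", rep))
  }
})

test_that("dropping a sub-minimum HSP never increases any chain score", {
  set.seed(202)
  cfg <- pipeline_config()
  for (rep in 1:20) {
    h <- random_hsp_group(6, min_len = 150L, max_len = 400L)
    loci_all <- chain_hsps(h, cfg)
    h_strict <- h[(h$send - h$sstart) >= cfg$min_exon, , drop = FALSE]
    class(h_strict) <- c("hsp_table", "data.frame")
    loci_strict <- chain_hsps(h_strict, cfg)
    best <- function(l) if (length(l))
      max(vapply(l, function(x) x$chain_score, numeric(1))) else 0
    expect_equal(best(loci_all), best(loci_strict))
  }
})

test_that("extract_locus takes 300 bp flanks, clips at contig ends", {
  set.seed(203)
  cfg <- pipeline_config()
  contig <- dna_set("s", random_dna_str(10000))
  l <- chain_hsps(mk_hsp(0, 1000, 1000, 2000, 900), cfg)[[1]]
  ex <- extract_locus(l, contig, cfg)
  expect_equal(ex$record$seq, substr(contig$seq, 701, 2300))
  expect_equal(ex$left_flank_len, 300)
  expect_equal(ex$right_flank_len, 300)
  expect_equal(nchar(ex$record$seq),
               min(2000 + 300, 10000) - max(1000 - 300, 0))

  l2 <- chain_hsps(mk_hsp(0, 400, 100, 500, 400), cfg)[[1]]
  ex2 <- extract_locus(l2, contig, cfg)
  expect_equal(ex2$left_flank_len, 100)  # clipped at the contig start
  expect_equal(ex2$right_flank_len, 300)

  bad <- l
  bad$span <- c(9900, 10100)
  expect_error(extract_locus(bad, contig, cfg), "locus/contig mismatch")
})

test_that("minus-strand extraction is the reverse complement of plus", {
  set.seed(204)
  cfg <- pipeline_config()
  contig <- dna_set("s", random_dna_str(5000))
  lp <- chain_hsps(mk_hsp(0, 800, 2000, 2800, 700))[[1]]
  lm <- chain_hsps(mk_hsp(0, 800, 2000, 2800, 700, "-"))[[1]]
  xp <- extract_locus(lp, contig, cfg)
  xm <- extract_locus(lm, contig, cfg)
  expect_equal(xm$record$seq, revcomp(xp$record$seq))
  expect_equal(xm$left_flank_len, xp$right_flank_len)
  # length exactness
  expect_equal(nchar(xm$record$seq),
               min(2800 + 300, 5000) - max(2000 - 300, 0))
})

test_that("collect_homeolog_set writes one deduplicated file per query", {
  set.seed(205)
  cfg <- pipeline_config()
  q <- dna_set("q", random_dna_str(300))
  contigs <- dna_set(paste0("c", 1:3),
                     replicate(3, random_dna_str(3000)))
  loci <- lapply(1:3, function(i) {
    l <- chain_hsps({
      h <- mk_hsp(0, 300, 1000, 1300, 500); h$subject_id <- paste0("c", i)
      class(h) <- c("hsp_table", "data.frame"); h
    }, cfg)[[1]]
    extract_locus(l, contigs[i, , drop = FALSE], cfg)
  })
  p <- withr::local_tempfile(fileext = ".fa")
  out <- collect_homeolog_set(q, loci, path = p)
  expect_equal(nrow(out), 3)
  expect_equal(nrow(read_fasta(p)), 3)
  out_q <- collect_homeolog_set(q, loci, include_query = TRUE)
  expect_equal(nrow(out_q), 4)
  expect_equal(out_q$id[1], "q")
  expect_warning(collect_homeolog_set(q, c(loci, loci[1])), "deduplicated")
  expect_error(collect_homeolog_set(q, list()), "no homoeologs")
})
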