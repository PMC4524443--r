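test_that("restriction sites are found on both strands with IUPAC codes", {
  cat <- load_enzyme_catalog()
  haeIII <- cat[cat$name == "HaeIII", ]
  aciI <- cat[cat$name == "AciI", ]
  expect_true(haeIII$palindromic)
  expect_false(aciI$palindromic)

  expect_equal(find_sites("TTGGCCAA", haeIII), 4)
  # AciI C^CGC: top strand at 2 -> cut 3; bottom-strand site GCGG
  expect_equal(find_sites("AACCGCAA", aciI), 3)
  expect_length(find_sites("AAGCGGAA", aciI), 1)

  # IUPAC in the pattern: BstNI CC[AT]GG
  bstni <- cat[cat$name == "BstNI", ]
  expect_length(find_sites("AACCAGGAACCTGGAA", bstni), 2)
  expect_length(find_sites("AACCGGGAA", bstni), 0)
})

test_that("cut positions equal a naive double-strand regex scan", {
  set.seed(501)
  cat <- load_enzyme_catalog()
  for (rep in 1:20) {
    s <- random_dna_str(300)
    enz <- cat[sample(nrow(cat), 1), ]
    expect_equal(find_sites(s, enz), oracle_cut_positions(s, enz),
                 info = enz$name)
  }
})

test_that("digestion fragments always sum to the sequence length", {
  cat <- load_enzyme_catalog()
  haeIII <- cat[cat$name == "HaeIII", ]
  expect_equal(digest("TTGGCCAA", haeIII), c(4, 4))
  expect_equal(digest("TTTTTTTT", haeIII), 8)

  set.seed(502)
  for (rep in 1:50) {
    s <- random_dna_str(sample(50:500, 1))
    enz <- cat[sample(nrow(cat), 1), ]
    f <- digest(s, enz)
    expect_equal(sum(f), nchar(s))
    expect_equal(f, sort(f))
  }
})

test_that("palindromic digests mirror under reverse complement", {
  set.seed(503)
  cat <- load_enzyme_catalog()
  # centred cutters: the top-strand cut is strand-symmetric, so the cut set
  # must be exactly mirrored on the reverse complement
  pal <- cat[cat$palindromic & cat$cut_offset * 2 == nchar(cat$site), ]
  for (rep in 1:10) {
    s <- random_dna_str(400)
    enz <- pal[sample(nrow(pal), 1), ]
    cuts <- find_sites(s, enz)
    cuts_rc <- find_sites(revcomp(s), enz)
    # mirrored coordinates: a cut at p maps to len - p
    expect_equal(sort(400 - cuts_rc), cuts)
  }
})

test_that("find_caps detects site-destroying SNPs like the AciI example", {
  set.seed(504)
  pad1 <- random_dna_str(150); pad2 <- random_dna_str(150)
  # C/T SNP inside an AciI site (CCGC vs CTGC), away from other sites
  a <- paste0(pad1, "AACCGCAA", pad2)
  b <- paste0(pad1, "AACTGCAA", pad2)
  caps <- find_caps(dna_set("a", a), dna_set("b", b), min_frag = 20)
  expect_true("AciI" %in% caps$enzyme)
  hit <- caps[caps$enzyme == "AciI", ][1, ]
  fa <- as.integer(strsplit(hit$fragments_a, ",")[[1]])
  fb <- as.integer(strsplit(hit$fragments_b, ",")[[1]])
  expect_equal(sum(fa), nchar(a))
  expect_equal(sum(fb), nchar(b))
  expect_false(identical(fa, fb))

  expect_error(find_caps(dna_set("a", a), dna_set("b", a)),
               "no polymorphism")
})

test_that("find_caps equals an exhaustive enzyme-by-SNP scan", {
  set.seed(505)
  cat <- load_enzyme_catalog()
  anc <- random_dna_str(300)
  b <- strsplit(anc, "")[[1]]
  snps <- sample(20:280, 4)
  for (p in snps) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  bs <- paste(b, collapse = "")
  caps <- find_caps(dna_set("a", anc), dna_set("b", bs), cat, min_frag = 1)
  # oracle: for every enzyme and SNP, check one-sided site overlap
  ora <- character(0)
  for (k in seq_len(nrow(cat))) {
    enz <- cat[k, ]
    ma <- homeolocus:::site_matches(anc, enz)
    mb <- homeolocus:::site_matches(bs, enz)
    fa <- digest(anc, enz); fb <- digest(bs, enz)
    if (identical(fa, fb)) next
    for (p in snps - 1L) {
      ina <- nrow(ma) > 0 && any(ma$start <= p & ma$end > p)
      inb <- nrow(mb) > 0 && any(mb$start <= p & mb$end > p)
      if (xor(ina, inb)) ora <- c(ora, paste(enz$name, p))
    }
  }
  expect_setequal(paste(caps$enzyme, caps$pos_a), unique(ora))
})

test_that("caps candidates respect the gel-resolution cutoff", {
  set.seed(506)
  anc <- random_dna_str(400)
  b <- strsplit(anc, "")[[1]]
  for (p in sample(30:370, 3)) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  caps <- find_caps(dna_set("a", anc),
                    dna_set("b", paste(b, collapse = "")), min_frag = 50)
  if (nrow(caps)) {
    for (i in seq_len(nrow(caps))) {
      fa <- as.integer(strsplit(caps$fragments_a[i], ",")[[1]])
      fb <- as.integer(strsplit(caps$fragments_b[i], ",")[[1]])
      dif <- c(homeolocus:::setdiff_multiset(fa, fb),
               homeolocus:::setdiff_multiset(fb, fa))
      expect_true(all(dif >= 50))
      expect_false(identical(fa, fb))
    }
  } else succeed()
})
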