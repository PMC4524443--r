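mk_msa <- function(rows, ids = paste0("r", seq_along(rows)),
                   provenance = NULL) {
  structure(list(ids = ids, rows = rows, query_id = "q",
                 provenance = provenance),
            class = "homeolog_msa")
}

test_that("diagnostic sites obey the strict-background rule", {
  msa <- mk_msa(c("ACGT", "ACGT", "ACAT"), c("A", "B", "C"))
  s <- diagnostic_sites(msa, "C")
  expect_equal(nrow(s), 1)
  expect_equal(s$col_start, 2)
  expect_equal(s$kind, "SNP")
  expect_equal(s$target_state, "A")
  expect_equal(s$background_state, "G")
  # the same column is not diagnostic for a background row
  expect_equal(nrow(diagnostic_sites(msa, "A")), 0)

  # all rows identical: nothing
  expect_equal(nrow(diagnostic_sites(mk_msa(rep("ACGT", 3)), "r1")), 0)

  # three distinct states: background disagrees, not diagnostic for anyone
  msa3 <- mk_msa(c("AAGT", "ACGT", "AGGT"), c("A", "B", "C"))
  for (r in c("A", "B", "C"))
    expect_equal(nrow(diagnostic_sites(msa3, r)), 0)

  expect_error(diagnostic_sites(msa, "nope"), "row not in alignment")
})

test_that("diagnostic indel runs collapse and terminal gaps are ignored", {
  # a 3-column gap private to the target is one indel site
  msa <- mk_msa(c("ACGTTTACGT", "ACG---ACGT", "ACGTTTACGT"),
                c("A", "B", "C"))
  s <- diagnostic_sites(msa, "B")
  expect_equal(nrow(s), 1)
  expect_equal(s$kind, "indel")
  expect_equal(s$col_start, 3)
  expect_equal(s$col_end, 6)

  # ambiguity in a background row masks the column
  msaN <- mk_msa(c("ACGT", "ACNT", "ACAT"), c("A", "B", "C"))
  expect_equal(nrow(diagnostic_sites(msaN, "C")), 0)

  # leading/trailing gap columns (ragged ends) are not called
  msaT <- mk_msa(c("--GTACGT", "ACGTACGT", "ACGTACGT"), c("A", "B", "C"))
  expect_equal(nrow(diagnostic_sites(msaT, "A")), 0)
})

test_that("conserved regions are maximal identical gap-free runs", {
  s <- random_dna_str(100)
  msa <- mk_msa(c(s, s, s))
  r <- conserved_regions(msa, min_len = 18)
  expect_equal(r, data.frame(start = 0L, end = 100L))

  # one central SNP splits in two regions
  s2 <- strsplit(s, "")[[1]]
  s2[50] <- setdiff(c("A", "C", "G", "T"), s2[50])[1]
  msa2 <- mk_msa(c(s, paste(s2, collapse = ""), s))
  r2 <- conserved_regions(msa2, min_len = 18)
  expect_equal(r2, data.frame(start = c(0L, 50L), end = c(49L, 100L)))

  # conserved regions and diagnostic columns are disjoint by construction
  sites <- diagnostic_sites(msa2, "r2")
  expect_equal(sites$col_start, 49)
  in_region <- any(sites$col_start >= r2$start & sites$col_start < r2$end)
  expect_false(in_region)
})

test_that("melting temperature follows Wallace and GC-fraction formulas", {
  expect_equal(melting_temp("AAAATTTT"), 16)
  expect_equal(melting_temp("GGGGCCCC"), 32)
  # 20-mer, 10 G+C: 64.9 + 41 * (10 - 16.4) / 20
  p <- "GCGCGCGCGCATATATATAT"
  expect_equal(melting_temp(p), 64.9 + 41 * (10 - 16.4) / 20)
  expect_equal(melting_temp(p), 51.78)
  expect_error(melting_temp("ACGTNACGTA"), "ambiguous primer")
  # monotone in GC at fixed length, slope 41/N for long oligos
  t1 <- melting_temp("AAAAAAAAAAAAAAAAAAAA")
  t2 <- melting_temp("GAAAAAAAAAAAAAAAAAAA")
  expect_equal(t2 - t1, 41 / 20)
})

test_that("primer windows match an exhaustive scan and rank by coverage", {
  set.seed(401)
  anc <- random_dna_str(200)
  tr <- anc
  bg <- strsplit(anc, "")[[1]]
  for (p in c(61, 101)) bg[p] <- setdiff(c("A", "C", "G", "T"), bg[p])[1]
  msa <- mk_msa(c(tr, paste(bg, collapse = ""), paste(bg, collapse = "")),
                c("T", "B1", "B2"))
  sites <- diagnostic_sites(msa, "T")
  expect_equal(sort(sites$target_pos), c(60, 100))
  w <- primer_windows(sites, msa, "T")
  # exhaustive oracle over every window of feasible length
  tp <- sites$target_pos
  ora <- list()
  for (st in 0:199) for (L in 18:27) {
    en <- st + L
    if (en > 200) next
    cov <- tp[tp >= st & tp < en]
    if (!length(cov)) next
    if (any(en - 1 - cov < 3))
      ora[[length(ora) + 1]] <- c("F", st, en)
    if (any(cov - st < 3))
      ora[[length(ora) + 1]] <- c("R", st, en)
  }
  ora <- unique(do.call(rbind, ora))
  expect_setequal(paste(w$strand, w$start, w$end),
                  paste(ora[, 1], ora[, 2], ora[, 3]))
  # zero sites: empty
  empty <- primer_windows(sites[0, ], msa, "T")
  expect_equal(nrow(empty), 0)
})

test_that("two-site windows outrank single-site windows", {
  set.seed(402)
  anc <- random_dna_str(120)
  bg <- strsplit(anc, "")[[1]]
  for (p in c(11, 26)) bg[p] <- setdiff(c("A", "C", "G", "T"), bg[p])[1]
  msa <- mk_msa(c(anc, paste(bg, collapse = ""), paste(bg, collapse = "")),
                c("T", "B1", "B2"))
  sites <- diagnostic_sites(msa, "T")
  w <- primer_windows(sites, msa, "T", win_len = c(18L, 22L))
  expect_equal(w$n_diag[1], 2)  # a window covering positions 10 and 25
  expect_true(all(diff(w$n_diag) <= 0))
})

test_that("primer pair design enforces the two-or-more-sites rule", {
  set.seed(403)
  # identical rows: no diagnostic sites at all
  s <- random_dna_str(400)
  expect_error(design_primer_pairs(mk_msa(c(s, s, s)), "r1"),
               "no genome-specific pair")

  # a single diagnostic column cannot give a two-site pair
  bg <- strsplit(s, "")[[1]]
  bg[200] <- setdiff(c("A", "C", "G", "T"), bg[200])[1]
  one <- mk_msa(c(s, paste(bg, collapse = ""), paste(bg, collapse = "")),
                c("T", "B1", "B2"))
  expect_error(design_primer_pairs(one, "T"), "no genome-specific pair")
})

test_that("designed pairs cover planted sites and amplify only the target", {
  set.seed(404)
  anc <- random_dna_str(600)
  bg <- strsplit(anc, "")[[1]]
  for (p in c(151, 401)) bg[p] <- setdiff(c("A", "C", "G", "T"), bg[p])[1]
  bgs <- paste(bg, collapse = "")
  msa <- mk_msa(c(anc, bgs, bgs), c("T", "B1", "B2"))
  pairs <- design_primer_pairs(msa, "T")
  expect_gte(nrow(pairs), 1)
  expect_true(all(pairs$total_diag >= 2))
  top <- pairs[1, ]
  # top-ranked pair covers both planted sites
  expect_equal(top$total_diag, 2)
  expect_true(top$f_start <= 150 && top$f_end > 150)
  expect_true(top$r_start <= 400 && top$r_end > 400)
  # primer sequences come from the target row
  expect_equal(top$f_seq, substr(anc, top$f_start + 1, top$f_end))
  expect_equal(top$r_seq, revcomp(substr(anc, top$r_start + 1, top$r_end)))
  # in-silico PCR: product from the target template only
  templ <- dna_set(c("T", "B1", "B2"), c(anc, bgs, bgs))
  prod <- insilico_pcr(top, templ)
  expect_true("T" %in% prod$template_id)
  expect_false(any(c("B1", "B2") %in% prod$template_id))
  expect_equal(prod$product_len[prod$template_id == "T"][1],
               top$product_len)
})

test_that("in-silico PCR enforces the 3'-exactness rule", {
  set.seed(405)
  tmpl <- random_dna_str(500)
  f <- substr(tmpl, 101, 122)
  r <- revcomp(substr(tmpl, 279, 300))
  pair <- list(f_seq = f, r_seq = r)
  hit <- insilico_pcr(pair, dna_set("t", tmpl))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$product_len, 200)
  expect_equal(hit$start, 100)
  expect_equal(hit$end, 300)

  # one mismatch at the forward primer's 3'-terminal base: no product
  f_bad <- f
  substr(f_bad, 22, 22) <- setdiff(c("A", "C", "G", "T"),
                                   substr(f, 22, 22))[1]
  expect_equal(nrow(insilico_pcr(list(f_seq = f_bad, r_seq = r),
                                 dna_set("t", tmpl))), 0)
  # internal mismatches within tolerance still amplify
  f_mid <- f
  substr(f_mid, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                 substr(f, 5, 5))[1]
  expect_equal(nrow(insilico_pcr(list(f_seq = f_mid, r_seq = r),
                                 dna_set("t", tmpl))), 1)
  # a template without any primer site yields nothing
  expect_equal(nrow(insilico_pcr(pair, dna_set("x", random_dna_str(400)))), 0)
})
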