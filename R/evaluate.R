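# Ground-truth evaluation of a pipeline run on simulated data: locus
# recovery, diagnostic-site recall/precision, and end-to-end primer
# specificity under in-silico PCR.

sim_copy_for_contig <- function(truth_gene, contig_id) {
  for (cp in truth_gene$copies)
    if (cp$contig_id == contig_id) return(cp)
  NULL
}

# Gene region of a simulated copy in final-contig plus-strand coordinates.
gene_region_on_contig <- function(truth_gene, cp) {
  gs <- truth_gene$gene_span
  s2m <- cp$mut$src2mut_filled
  m0 <- s2m[gs[1] + 1L]
  m1 <- if (gs[2] <= length(s2m)) {
    last <- cp$mut$src2mut[gs[2]]
    if (is.na(last)) s2m[gs[2]] else last + 1L
  } else length(cp$mut$mut2src_filled)
  ci <- cp$copy_interval
  if (cp$orient == "+") c(ci[1] + m0, ci[1] + m1)
  else c(ci[2] - m1, ci[2] - m0)
}

#' Evaluate locus recovery against simulation truth
#'
#' A gene counts as fully recovered when, for every subgenome copy, the
#' pipeline extracted at least one locus on the correct contig whose span
#' covers at least `min_cov` of the true gene region.
#'
#' @param run A `pipeline_run` on simulator output.
#' @param sim The matching [simulate_polyploid()] result.
#' @param min_cov Minimum fraction of the true gene region covered.
#' @return List: `full_recovery_rate` (fraction of genes with all copies
#'   recovered), `per_gene` data frame.
#' @export
evaluate_locus_recovery <- function(run, sim, min_cov = 0.8) {
  per <- lapply(names(sim$truth), function(gid) {
    tg <- sim$truth[[gid]]
    res <- run$genes[[gid]]
    found <- vapply(tg$copies, function(cp) {
      region <- gene_region_on_contig(tg, cp)
      if (is.null(res$loci)) return(FALSE)
      for (l in res$loci) {
        if (l$source_subject != cp$contig_id) next
        ov <- min(l$locus_span[2], region[2]) - max(l$locus_span[1], region[1])
        if (ov >= min_cov * (region[2] - region[1])) return(TRUE)
      }
      FALSE
    }, logical(1))
    data.frame(query_id = gid, n_copies = length(found),
               n_recovered = sum(found), full = all(found),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(full_recovery_rate = mean(per$full), per_gene = per)
}

# Map detected sites of one MSA row to ancestral-unit intervals.
detected_site_units <- function(sites, prov_row, cp) {
  if (is.null(sites) || nrow(sites) == 0)
    return(data.frame(u_start = integer(0), u_end = integer(0)))
  u1 <- row_pos_to_unit(sites$target_pos, prov_row, cp)
  # width on the target row (>= 1 position for mapping purposes)
  w <- ifelse(sites$kind == "SNP", 1L,
              pmax(1L, sites$col_end - sites$col_start))
  u2 <- row_pos_to_unit(sites$target_pos + w - 1L, prov_row, cp)
  lo <- pmin(u1, u2); hi <- pmax(u1, u2) + 1L
  data.frame(u_start = lo, u_end = hi)
}

#' Diagnostic-site recall and precision against simulation truth
#'
#' Pools detected diagnostic sites over all genes and target rows of a run
#' on simulated data. Recall is measured over true diagnostic events inside
#' the gene region (the region every extracted locus is guaranteed to
#' cover); a truth event is recalled when any detected site for the right
#' subgenome overlaps it within `tol` bp in ancestral coordinates.
#' Precision is measured over all detected sites, anywhere in the aligned
#' region: a site is a true positive when it overlaps any true diagnostic
#' event of its subgenome (flanking sequence included).
#'
#' @param run A `pipeline_run`.
#' @param sim The matching [simulate_polyploid()] result.
#' @param tol Matching tolerance (bp) in ancestral coordinates.
#' @return List with `recall`, `precision`, `n_truth`, `n_detected`,
#'   `n_matched_truth`, `n_tp_detected`.
#' @export
evaluate_diagnostics <- function(run, sim, tol = 2L) {
  n_truth <- 0L; n_matched <- 0L; n_det <- 0L; n_tp <- 0L
  for (gid in names(sim$truth)) {
    tg <- sim$truth[[gid]]
    res <- run$genes[[gid]]
    if (is.null(res$msa)) {
      n_truth <- n_truth + sum(tg$diag$in_gene)
      next
    }
    prov <- res$msa$provenance
    for (ri in seq_along(res$msa$ids)) {
      rid <- res$msa$ids[ri]
      pr <- prov[prov$id == rid, , drop = FALSE]
      if (nrow(pr) == 0) next
      cp <- sim_copy_for_contig(tg, pr$subject_id[1])
      if (is.null(cp)) next
      truth_s <- tg$diag[tg$diag$subgenome == cp$subgenome, , drop = FALSE]
      sites <- res$sites[[rid]]
      units <- detected_site_units(sites, list(
        source_span = c(pr$span_start[1], pr$span_end[1]),
        strand = pr$strand[1]), cp)
      units <- units[!is.na(units$u_start), , drop = FALSE]
      n_det <- n_det + nrow(units)
      # truth -> detected (recall over in-gene events)
      tg_in <- truth_s[truth_s$in_gene, , drop = FALSE]
      n_truth <- n_truth + nrow(tg_in)
      if (nrow(tg_in) && nrow(units)) {
        hit <- vapply(seq_len(nrow(tg_in)), function(i)
          any(units$u_end + tol > tg_in$src_start[i] &
                units$u_start - tol < tg_in$src_end[i]), logical(1))
        n_matched <- n_matched + sum(hit)
      }
      # detected -> truth (precision over all events incl. flanks)
      if (nrow(units)) {
        tp <- vapply(seq_len(nrow(units)), function(i)
          nrow(truth_s) > 0 &&
            any(truth_s$src_end + tol > units$u_start[i] &
                  truth_s$src_start - tol < units$u_end[i]), logical(1))
        n_tp <- n_tp + sum(tp)
      }
    }
  }
  list(recall = if (n_truth) n_matched / n_truth else NA_real_,
       precision = if (n_det) n_tp / n_det else NA_real_,
       n_truth = n_truth, n_detected = n_det,
       n_matched_truth = n_matched, n_tp_detected = n_tp)
}

#' End-to-end primer specificity under in-silico PCR
#'
#' For every (gene, target subgenome) with at least one designed pair, the
#' top-ranked pair is amplified in silico against all of that gene's
#' homoeologous contigs. A design is specific when it yields a product on
#' its own subgenome's contig and none on any other homoeolog -- the
#' computational analog of chromosome assignment with nulli-tetrasomic
#' aneuploid lines, where absence of the product in the line missing the
#' chromosome proves locus specificity.
#'
#' @param run A `pipeline_run` with `validate = TRUE`, or any run (PCR is
#'   recomputed here from the genome).
#' @param sim The matching [simulate_polyploid()] result.
#' @param max_mismatch,three_prime_exact In-silico PCR binding stringency.
#' @return List: `specificity` (fraction specific), `n_designs`,
#'   `per_design` data frame.
#' @export
evaluate_specificity <- function(run, sim, max_mismatch = 2L,
                                 three_prime_exact = 3L) {
  rows <- list()
  for (gid in names(sim$truth)) {
    tg <- sim$truth[[gid]]
    res <- run$genes[[gid]]
    if (is.null(res$msa) || is.null(res$pairs)) next
    contig_ids <- vapply(tg$copies, function(cp) cp$contig_id, character(1))
    templ <- sim$genome[sim$genome$id %in% contig_ids, , drop = FALSE]
    prov <- res$msa$provenance
    for (rid in res$msa$ids) {
      pr <- res$pairs[[rid]]
      if (is.null(pr) || nrow(pr) == 0) next
      own <- prov$subject_id[prov$id == rid][1]
      if (is.na(own) || !(own %in% contig_ids)) next
      prod <- insilico_pcr(pr[1, , drop = FALSE], templ,
                           max_mismatch = max_mismatch,
                           three_prime_exact = three_prime_exact)
      on_target <- sum(prod$template_id == own) > 0
      off_target <- sum(prod$template_id != own) > 0
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = gid, target_row = rid, target_contig = own,
        on_target = on_target, off_target = off_target,
        specific = on_target && !off_target, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(list(specificity = NA_real_, n_designs = 0L,
                per_design = data.frame()))
  per <- do.call(rbind, rows)
  list(specificity = mean(per$specific), n_designs = nrow(per),
       per_design = per)
}
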