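# End-to-end driver: synthetic study -> preprocessing -> co-registration ->
# spatial correlation -> enrichment -> candidate lists, per compartment.

#' Run the full signature-discovery pipeline on a study
#'
#' Convenience driver tying the modules together for one term map:
#' background filtering and probe selection, per-donor compartment-wise
#' z-scoring, positive-z masking with spherical smoothing, per-donor
#' spatial correlation combined into a ranked list, pre-ranked enrichment,
#' and leading-edge candidate ranking — separately for the cortical and
#' subcortical compartments.
#'
#' @param study a `synthetic_study` from [simulate_study()] (or any list
#'   with `expression`, `samples`, `map`, `gene_sets`).
#' @param radius_mm smoothing radius in mm.
#' @param n_perm permutations per set size.
#' @param seed RNG seed for the permutation null.
#' @param fdr FDR threshold for significance and candidate ranking.
#' @param p weight exponent of the enrichment statistic.
#' @param compartments which compartments to analyze.
#' @return list of class `signature_result` with, per compartment:
#'   `ranked`, `enrichment`, `candidates` (positive/negative),
#'   `significant` (set ids by sign), `genes` (member-gene union of the
#'   significant sets by sign); plus the shared `prep` QC.
#' @export
run_signature_pipeline <- function(study, radius_mm = 6, n_perm = 1000,
                                   seed = 1, fdr = 0.05, p = 1,
                                   compartments = c("cortical", "subcortical")) {
  prep <- preprocess_study(study$expression, study$samples)
  paired <- pair_samples(prep, study$samples, study$map, radius_mm = radius_mm)
  out <- list(qc = prep$qc, selection = prep$selection)
  for (cm in compartments) {
    ranked <- spatial_correlation(paired, cm)
    enr <- gsea_preranked(ranked, study$gene_sets, p = p, n_perm = n_perm,
                          seed = child_seed(seed, match(cm, compartments)))
    cand <- candidate_ranking(enr, ranked, fdr = fdr)
    sig_pos <- significant_sets(enr, 1, fdr)
    sig_neg <- significant_sets(enr, -1, fdr)
    member_union <- function(sig) unique(unlist(
      lapply(study$gene_sets[sig$set_id],
             function(g) intersect(g, ranked$gene_id))))
    out[[cm]] <- list(
      ranked = ranked,
      enrichment = enr,
      candidates = cand,
      significant = list(positive = sig_pos$set_id, negative = sig_neg$set_id),
      genes = list(positive = member_union(sig_pos),
                   negative = member_union(sig_neg))
    )
  }
  class(out) <- "signature_result"
  out
}

#' @export
print.signature_result <- function(x, ...) {
  for (cm in setdiff(names(x), c("qc", "selection"))) {
    r <- x[[cm]]
    cat(sprintf("%s: %d genes ranked (%d +, %d -); %d / %d sets enriched (+/-)\n",
                cm, nrow(r$ranked), attr(r$ranked, "n_positive"),
                attr(r$ranked, "n_negative"),
                length(r$significant$positive), length(r$significant$negative)))
    for (s in c("positive", "negative")) {
      cl <- r$candidates[[s]]
      if (!is.null(cl))
        cat(sprintf("  %s candidates: %s\n", s,
                    paste(utils::head(cl$gene_id, 10), collapse = ", ")))
    }
  }
  invisible(x)
}
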