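#' Run the full plasticity analysis on a study
#'
#' End-to-end pipeline: detection filter + median-of-ratios normalization +
#' log2 transform; normality QC; variance decomposition (on a transcript
#' subset, the fits being by far the most expensive step); both
#' differential-expression model families (date/provenance and
#' environmental); responder sets; resampled GO overrepresentation; and
#' kappa clustering of the significant categories.  Deterministic given the
#' study and `seed`.
#'
#' @param study a `plast_study` from [simulate_study()], or any list with
#'   the same elements (counts, library_totals, samples, regressors, go).
#' @param fdr FDR threshold for responder calls (default 0.01).
#' @param dr2 marginal R-squared gate for environmental responders
#'   (default 0.2).
#' @param repeats best-hit resampling repeats for enrichment (default 100).
#' @param seed seed for the resampling.
#' @param min_observed strict lower bound on mean responder count per
#'   significant category (default 10).
#' @param min_parents parental-term filter before clustering (default 2;
#'   the toy ontology is three levels deep, real GO analyses use 5).
#' @param varcomp_transcripts number of transcripts (from the top of the
#'   filtered matrix) used for variance decomposition; `0` skips it.
#' @return A list with `expr`, `size_factors`, `qc`, `varcomp`, `de_date`,
#'   `de_env`, `responders`, `enrichment`, `significant`, `kappa`,
#'   `clustering`.
#' @export
run_pipeline <- function(study, fdr = 0.01, dr2 = 0.2, repeats = 100,
                         seed = 1L, min_observed = 10, min_parents = 2,
                         varcomp_transcripts = 100) {
  norm <- normalize_counts(study$counts, study$library_totals)
  qc <- normality_qc(norm$expr)
  varcomp <- NULL
  if (varcomp_transcripts > 0) {
    idx <- seq_len(min(varcomp_transcripts, nrow(norm$expr)))
    varcomp <- decompose_variance(norm$expr[idx, , drop = FALSE],
                                  study$samples)
  }
  de_date <- run_date_provenance(norm$expr, study$samples, fdr = fdr)
  de_env <- run_environment(norm$expr, study$samples, study$regressors,
                            fdr = fdr, dr2 = dr2)
  responders <- responder_sets(de_env)
  ann <- propagate_annotations(study$go$annotation, study$go$ontology)
  ann <- ann[names(ann) %in% rownames(norm$expr)]
  enr <- resampled_overrep(responders, ann, study$go$besthit,
                           repeats = repeats, seed = seed,
                           min_observed = min_observed)
  sig <- select_significant(enr, min_observed = min_observed)
  kappa <- clustering <- NULL
  sig_terms <- depth_filter(unique(sig$term_id), study$go$ontology,
                            min_parents = min_parents)
  if (length(sig_terms) >= 2) {
    resp_all <- unique(unlist(responders, use.names = FALSE))
    cols <- intersect(names(ann)[vapply(ann, function(tt)
      any(tt %in% sig_terms), logical(1))], resp_all)
    if (length(cols) >= 2) {
      M <- membership_matrix(sig_terms, ann, cols)
      kappa <- kappa_matrix(M)
      clustering <- cluster_categories(kappa)
    }
  }
  list(expr = norm$expr, size_factors = norm$size_factors, qc = qc,
       varcomp = varcomp, de_date = de_date, de_env = de_env,
       responders = responders, enrichment = enr, significant = sig,
       kappa = kappa, clustering = clustering)
}
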