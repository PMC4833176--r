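#' End-to-end CNV phenotype enrichment
#'
#' Drives the full pipeline for one cohort: restrict case CNVs to those
#' longer than `min_length_bp` (strictly), assign genes under the
#' dosage-specific rules (span containment for gains, coding-exon
#' disruption in all transcripts for losses), deduplicate to per-dosage
#' gene sets, discard genes copy-changed in the same direction by any
#' control CNV (controls are never length-filtered), and test the chosen
#' dosage class for per-term enrichment under the ontology root.
#'
#' @param case_cnvs,control_cnvs `cnv_table`s (see [read_cnvs()]).
#' @param genes a [gene_models()] object.
#' @param universe an [annotate_closure()] result.
#' @param root_term ontology term whose descendants are tested (e.g. the
#'   behavioural category).
#' @param dosage which gene set to test, `"gain"` (default) or `"loss"`.
#' @param min_length_bp strict case-CNV length cutoff (default 500 kb).
#' @param min_term_genes minimum closure-set size for a term to be tested
#'   (default 20): terms with very small closure sets give unstable
#'   enrichment estimates, and tiny descendants of a genuinely enriched
#'   term tend to recapture its signal redundantly. Set to 1 to test every
#'   annotated descendant.
#' @param fdr,method FDR control, passed to [run_enrichment()].
#' @return an `enrichment_result` with extra attributes `gene_sets` (the
#'   control-filtered per-dosage sets) and `assignments` (the per-CNV
#'   assignment table).
#' @export
cnv_phenotype_enrichment <- function(case_cnvs, control_cnvs, genes,
                                     universe, root_term,
                                     dosage = c("gain", "loss"),
                                     min_length_bp = 5e5,
                                     min_term_genes = 20,
                                     fdr = 0.05,
                                     method = c("storey", "bh")) {
  dosage <- match.arg(dosage)
  method <- match.arg(method)
  large <- filter_large_cnvs(case_cnvs, min_length_bp)
  assignments <- assign_cnv_genes(large, genes)
  sets <- filter_control_genes(cnv_gene_sets(assignments), control_cnvs,
                               genes)
  terms <- select_test_terms(universe, root_term,
                             min_genes = min_term_genes)
  res <- run_enrichment(sets[[dosage]], universe, terms = terms,
                        fdr = fdr, method = method)
  attr(res, "gene_sets") <- sets
  attr(res, "assignments") <- assignments
  res
}
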