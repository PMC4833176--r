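#' Assign genes to copy-number gains
#'
#' A gene is assigned to a gain only when its whole span (the union of its
#' transcripts, from minimum exon start to maximum exon end) is completely
#' contained in the gain interval on the same chromosome. Partial overlap is
#' never sufficient: amplifying part of a gene does not duplicate its
#' product. A gene may be assigned to several gains, and overlap is
#' strand-agnostic.
#'
#' @param cnvs a `cnv_table`; only rows with `dosage == "gain"` are used.
#' @param genes a [gene_models()] object.
#' @return data.frame of assignments with columns `gene_id`, `subject`,
#'   `cohort`, `chrom`, `start`, `end`, `dosage`, `rule`
#'   (`"gain_full_overlap"`) and `cnv_row` (row index into the gain subset
#'   order of `cnvs`).
#' @export
assign_gain_genes <- function(cnvs, genes) {
  stopifnot(inherits(genes, "gene_models"))
  gains <- cnvs[cnvs$dosage == "gain", , drop = FALSE]
  spans <- gene_spans(genes)
  if (!nrow(gains) || !nrow(spans)) return(.empty_assignment())
  lev <- unique(c(spans$chrom, gains$chrom))
  hits <- GenomicRanges::findOverlaps(
    .as_granges(spans$chrom, spans$start, spans$end, lev),
    .as_granges(gains$chrom, gains$start, gains$end, lev),
    type = "within")
  gi <- S4Vectors::queryHits(hits)
  ci <- S4Vectors::subjectHits(hits)
  .assignment_frame(spans$gene_id[gi], gains[ci, , drop = FALSE], ci,
                    rule = "gain_full_overlap")
}

#' Assign genes to copy-number losses
#'
#' A gene is assigned to a loss only when the loss overlaps (by at least one
#' base) a coding (CDS) segment of *every* coding transcript of the gene, so
#' that the protein product is disrupted whichever transcript is expressed.
#' Non-coding isoforms are ignored by the all-transcripts quantifier (they
#' have no coding exon to disrupt); genes with no coding transcript are
#' never loss-genes. Overlap of untranslated exon regions does not count.
#'
#' @inheritParams assign_gain_genes
#' @return data.frame of assignments as in [assign_gain_genes()], with
#'   `rule = "loss_coding_all_transcripts"`.
#' @export
assign_loss_genes <- function(cnvs, genes) {
  stopifnot(inherits(genes, "gene_models"))
  losses <- cnvs[cnvs$dosage == "loss", , drop = FALSE]
  cds <- genes$cds
  if (!nrow(losses) || !nrow(cds)) return(.empty_assignment())
  lev <- unique(c(cds$chrom, losses$chrom))
  hits <- GenomicRanges::findOverlaps(
    .as_granges(cds$chrom, cds$start, cds$end, lev),
    .as_granges(losses$chrom, losses$start, losses$end, lev))
  if (!length(hits)) return(.empty_assignment())
  di <- S4Vectors::queryHits(hits)
  ci <- S4Vectors::subjectHits(hits)
  # distinct coding transcripts of each gene hit by each loss
  pair <- unique(data.frame(gene_id = cds$gene_id[di],
                            transcript_id = cds$transcript_id[di],
                            cnv = ci, stringsAsFactors = FALSE))
  n_hit <- stats::aggregate(transcript_id ~ gene_id + cnv, data = pair,
                            FUN = function(x) length(unique(x)))
  need <- setNames(genes$genes$n_coding_tx, genes$genes$gene_id)
  full <- n_hit[n_hit$transcript_id == need[n_hit$gene_id] &
                  need[n_hit$gene_id] > 0, , drop = FALSE]
  if (!nrow(full)) return(.empty_assignment())
  .assignment_frame(full$gene_id, losses[full$cnv, , drop = FALSE],
                    full$cnv, rule = "loss_coding_all_transcripts")
}

#' Assign genes to CNVs of both dosage classes
#'
#' Convenience wrapper applying [assign_gain_genes()] and
#' [assign_loss_genes()] to one CNV table.
#'
#' @inheritParams assign_gain_genes
#' @return data.frame combining both assignment sets.
#' @export
assign_cnv_genes <- function(cnvs, genes) {
  rbind(assign_gain_genes(cnvs, genes), assign_loss_genes(cnvs, genes))
}

.empty_assignment <- function() {
  data.frame(gene_id = character(0), subject = character(0),
             cohort = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), dosage = character(0),
             rule = character(0), cnv_row = integer(0),
             stringsAsFactors = FALSE)
}

.assignment_frame <- function(gene_id, cnv_rows, cnv_idx, rule) {
  out <- data.frame(gene_id = gene_id,
                    subject = cnv_rows$subject, cohort = cnv_rows$cohort,
                    chrom = cnv_rows$chrom, start = cnv_rows$start,
                    end = cnv_rows$end, dosage = cnv_rows$dosage,
                    rule = rep_len(rule, length(gene_id)),
                    cnv_row = as.integer(cnv_idx),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$cnv_row), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unique CNV-gene sets per dosage
#'
#' Deduplicates assignment rows to the per-dosage gene sets used by the
#' enrichment stage (a gene hit by several CNVs or in several subjects
#' counts once).
#'
#' @param assignments output of [assign_cnv_genes()] (or either single-rule
#'   variant).
#' @return list with sorted character vectors `gain` and `loss`.
#' @export
cnv_gene_sets <- function(assignments) {
  list(gain = sort(unique(assignments$gene_id[assignments$dosage == "gain"])),
       loss = sort(unique(assignments$gene_id[assignments$dosage == "loss"])))
}

#' Remove genes copy-changed in the same direction in a control cohort
#'
#' Discards case CNV-genes that are also copy changed *in the same
#' direction* by any control CNV: case gain-genes present among control
#' gain-genes, and case loss-genes among control loss-genes. Control genes
#' are derived with exactly the same assignment rules as cases, and control
#' CNVs are not length-filtered (all lengths count).
#'
#' @param case_genes list with elements `gain` and `loss` (character
#'   vectors), e.g. from [cnv_gene_sets()].
#' @param control_cnvs a `cnv_table` of control-cohort CNVs.
#' @param genes a [gene_models()] object.
#' @return list with elements `gain` and `loss` (retained case genes,
#'   sorted) and attribute `removed` (the per-dosage removed sets).
#' @export
filter_control_genes <- function(case_genes, control_cnvs, genes) {
  stopifnot(is.list(case_genes), all(c("gain", "loss") %in% names(case_genes)))
  ctrl <- cnv_gene_sets(assign_cnv_genes(control_cnvs, genes))
  removed <- list(
    gain = sort(intersect(unique(case_genes$gain), ctrl$gain)),
    loss = sort(intersect(unique(case_genes$loss), ctrl$loss)))
  out <- list(gain = sort(setdiff(unique(case_genes$gain), ctrl$gain)),
              loss = sort(setdiff(unique(case_genes$loss), ctrl$loss)))
  attr(out, "removed") <- removed
  out
}

#' Write a CNV-gene assignment table
#'
#' @param assignments assignment data.frame.
#' @param path output TSV path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
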