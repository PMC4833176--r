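#' Simulation configuration
#'
#' Parameters for the synthetic-data generators. Defaults mirror the scale
#' of the motivating study design: an annotated universe of 6,350 genes of
#' which 439 carry the focal phenotype (within a behavioural category of
#' 2,089), a case cohort whose large (>500 kb) gains number about 70 after
#' the strict length filter, CNV lengths log-uniform across the 500 kb
#' cutoff so the filter is exercised on both sides, and a planted 3-fold
#' enrichment of focal genes among gain-genes. Control-cohort sizes are set
#' so that direction-matched filtering removes roughly the observed share
#' of case genes (~8% of gain-genes, ~4% of loss-genes). Expression is a
#' latent-factor model whose within-module correlation is the target `r`
#' by construction (`noise_sd` solved from `r`).
#'
#' @param seed integer seed; all generators derive their streams from it.
#' @param n_genes genes in the toy genome (all annotated; the universe).
#' @param n_chroms chromosomes the genes are spread over.
#' @param gene_spacing_bp distance between gene anchors; larger than the
#'   maximum CNV length, so one case CNV anchors exactly one gene and the
#'   planted enrichment is analytically exact.
#' @param transcripts_per_gene,exons_per_transcript inclusive integer
#'   ranges.
#' @param exon_meanlog,exon_sdlog,intron_meanlog,intron_sdlog log-normal
#'   parameters of exon/intron lengths (bp).
#' @param noncoding_tx_rate probability a transcript beyond the first is
#'   non-coding (the first transcript of each gene is always coding).
#' @param n_case_gains,n_case_losses case CNV counts before length
#'   filtering.
#' @param n_control_gains,n_control_losses control CNV counts (never length
#'   filtered).
#' @param cnv_length_range log-uniform CNV length bounds (bp), straddling
#'   `min_cnv_length_bp`.
#' @param min_cnv_length_bp the strict large-CNV cutoff (bp).
#' @param universe_size,focal_term_size,behaviour_term_size universe N,
#'   focal-term closure size K and behavioural-category closure size.
#' @param n_focal_children,n_other_behaviour_terms,n_organ_terms leaf-term
#'   counts under the focal, behavioural and non-behavioural branches.
#' @param planted_fold target fold enrichment of focal genes among case
#'   gain-genes (1 = null).
#' @param second_annotation_rate probability of a second direct annotation
#'   (drawn within the same branch so closure sizes stay exact).
#' @param non_one_to_one_rate rate of decoy non-1:1 orthology rows.
#' @param n_samples expression samples.
#' @param n_modules,module_size planted co-expression modules.
#' @param within_module_r target Pearson correlation within a module.
#' @param silent_gene_rate fraction of background genes expressed below the
#'   RPKM filter everywhere.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 6350L, n_chroms = 20L,
                       gene_spacing_bp = 3e6,
                       transcripts_per_gene = c(1L, 5L),
                       exons_per_transcript = c(1L, 8L),
                       exon_meanlog = log(200), exon_sdlog = 0.45,
                       intron_meanlog = log(2000), intron_sdlog = 0.6,
                       noncoding_tx_rate = 0.1,
                       n_case_gains = 94L, n_case_losses = 29L,
                       n_control_gains = 1800L, n_control_losses = 900L,
                       cnv_length_range = c(2.5e5, 2e6),
                       min_cnv_length_bp = 5e5,
                       universe_size = 6350L, focal_term_size = 439L,
                       behaviour_term_size = 2089L,
                       n_focal_children = 38L,
                       n_other_behaviour_terms = 119L,
                       n_organ_terms = 40L,
                       planted_fold = 3,
                       second_annotation_rate = 0.3,
                       non_one_to_one_rate = 0.005,
                       n_samples = 120L, n_modules = 1L,
                       module_size = 22L, within_module_r = 0.8,
                       silent_gene_rate = 0.1) {
  cfg <- as.list(environment())
  stopifnot(cfg$planted_fold >= 0,
            cfg$focal_term_size <= cfg$behaviour_term_size,
            cfg$behaviour_term_size <= cfg$universe_size,
            cfg$universe_size <= cfg$n_genes,
            cfg$within_module_r > 0, cfg$within_module_r < 1,
            cfg$cnv_length_range[1] < cfg$cnv_length_range[2],
            cfg$gene_spacing_bp > cfg$cnv_length_range[2])
  class(cfg) <- "sim_config"
  cfg
}

.gene_ids <- function(cfg) sprintf("G%05d", seq_len(cfg$n_genes))

#' Generate a toy genome of gene models
#'
#' Genes are laid out on `n_chroms` chromosomes with spacing larger than
#' any simulated CNV, each with 1-5 transcripts of 1-8 exons; coding
#' transcripts have CDS trimmed by untranslated stretches at both ends, and
#' a configurable fraction of extra transcripts are non-coding isoforms.
#' Every gene keeps at least one coding transcript. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [gene_models()] object with `cfg$n_genes` genes.
#' @export
make_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101L)
  n <- cfg$n_genes
  gene_id <- .gene_ids(cfg)
  per_chrom <- ceiling(n / cfg$n_chroms)
  chrom <- as.character(rep(seq_len(cfg$n_chroms), each = per_chrom)[1:n])
  idx_within <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  anchor <- (idx_within - 1) * cfg$gene_spacing_bp +
    cfg$gene_spacing_bp / 2 +
    floor(runif(n, 0, cfg$gene_spacing_bp / 10))

  n_tx <- sample(cfg$transcripts_per_gene[1]:cfg$transcripts_per_gene[2],
                 n, replace = TRUE)
  txg <- rep(seq_len(n), n_tx)
  tx_within <- sequence(n_tx)
  transcript_id <- sprintf("%s.t%d", gene_id[txg], tx_within)
  tx_start <- anchor[txg] + sample(0:300, length(txg), replace = TRUE)

  n_ex <- sample(cfg$exons_per_transcript[1]:cfg$exons_per_transcript[2],
                 length(txg), replace = TRUE)
  ext <- rep(seq_along(txg), n_ex)               # exon -> transcript index
  exon_len <- pmax(30, round(rlnorm(length(ext), cfg$exon_meanlog,
                                    cfg$exon_sdlog)))
  intron_len <- pmax(50, round(rlnorm(length(ext), cfg$intron_meanlog,
                                      cfg$intron_sdlog)))
  step <- exon_len + intron_len
  cum <- stats::ave(step, ext, FUN = cumsum)
  ex_start <- tx_start[ext] + cum - step
  ex_end <- ex_start + exon_len
  ex_within <- sequence(n_ex)
  is_first <- ex_within == 1L
  is_last <- ex_within == n_ex[ext]

  coding <- runif(length(txg)) >= cfg$noncoding_tx_rate
  coding[!duplicated(txg)] <- TRUE               # first transcript coding

  exons <- data.frame(gene_id = gene_id[txg][ext],
                      transcript_id = transcript_id[ext],
                      chrom = chrom[txg][ext],
                      start = ex_start, end = ex_end,
                      stringsAsFactors = FALSE)

  in_coding <- coding[ext]
  trim <- pmin(60, floor((exon_len - 1) / 3))
  cds_start <- ex_start + ifelse(is_first, trim, 0)
  cds_end <- ex_end - ifelse(is_last, trim, 0)
  cds <- exons[in_coding, , drop = FALSE]
  cds$start <- cds_start[in_coding]
  cds$end <- cds_end[in_coding]

  gene_models(exons, cds)
}

#' Generate the synthetic ontology, annotations and orthology
#'
#' Builds a small DAG (root, a behavioural branch containing the focal term
#' with leaf children, sibling behavioural leaves, and a non-behavioural
#' branch), partitions the gene universe over the leaves so closure sizes
#' are exact by construction (`K` focal genes, the behavioural category
#' total, the remainder non-behavioural), annotates only at leaves (so
#' ancestor closure is exercised everywhere), and emits a 1:1 orthology
#' table with a configurable rate of non-1:1 decoy rows that loaders must
#' drop. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids human gene ids to annotate; defaults to the ids
#'   [make_gene_models()] produces for the same config.
#' @return list with `ontology` (a [phenotype_ontology()]), `annotations`
#'   (data.frame `mouse_id`, `term_id`), `orthology` (raw data.frame
#'   including decoys), `root_term`, `behaviour_term`, `focal_term`,
#'   `focal_genes`, `behaviour_genes`.
#' @export
make_annotation_universe <- function(cfg, gene_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 202L)
  N <- cfg$universe_size
  if (is.null(gene_ids)) gene_ids <- .gene_ids(cfg)[seq_len(N)]
  stopifnot(length(gene_ids) == N)

  root <- "SP:0000001"; beh <- "SP:0000002"
  focal <- "SP:0000003"; organ <- "SP:0000004"
  focal_children <- sprintf("SP:%07d", 100L + seq_len(cfg$n_focal_children))
  other_beh <- sprintf("SP:%07d", 200L + seq_len(cfg$n_other_behaviour_terms))
  organ_leaves <- sprintf("SP:%07d", 400L + seq_len(cfg$n_organ_terms))
  terms <- c(root, beh, focal, organ, focal_children, other_beh,
             organ_leaves)
  parents <- c(list(), setNames(list(character(0), root, beh, root),
                                c(root, beh, focal, organ)),
               setNames(rep(list(focal), length(focal_children)),
                        focal_children),
               setNames(rep(list(beh), length(other_beh)), other_beh),
               setNames(rep(list(organ), length(organ_leaves)),
                        organ_leaves))
  nms <- setNames(c("mammalian phenotype",
                    "behaviour/neurological phenotype",
                    "abnormal learning/memory/conditioning",
                    "organ system phenotype",
                    paste("learning/memory subtype", seq_along(focal_children)),
                    paste("behavioural phenotype", seq_along(other_beh)),
                    paste("organ phenotype", seq_along(organ_leaves))),
                  terms)
  onto <- phenotype_ontology(terms, parents, nms)

  perm <- sample(gene_ids)
  beh_genes <- perm[seq_len(cfg$behaviour_term_size)]
  focal_genes <- beh_genes[seq_len(cfg$focal_term_size)]
  other_beh_genes <- setdiff(beh_genes, focal_genes)
  organ_genes <- setdiff(perm, beh_genes)

  assign_leaves <- function(genes, leaves) {
    if (!length(genes)) return(character(0))
    sample(rep(leaves, length.out = length(genes)))
  }
  direct <- data.frame(
    gene_id = c(focal_genes, other_beh_genes, organ_genes),
    term_id = c(assign_leaves(focal_genes, focal_children),
                assign_leaves(other_beh_genes, other_beh),
                assign_leaves(organ_genes, organ_leaves)),
    stringsAsFactors = FALSE)
  # optional second annotation within the same branch: closure sizes of the
  # focal and behavioural terms are unchanged by construction
  pool <- c(setNames(rep(list(focal_children), length(focal_genes)),
                     focal_genes),
            setNames(rep(list(other_beh), length(other_beh_genes)),
                     other_beh_genes),
            setNames(rep(list(organ_leaves), length(organ_genes)),
                     organ_genes))
  extra <- runif(nrow(direct)) < cfg$second_annotation_rate
  if (any(extra)) {
    second <- data.frame(
      gene_id = direct$gene_id[extra],
      term_id = vapply(direct$gene_id[extra],
                       function(g) sample(pool[[g]], 1), character(1)),
      stringsAsFactors = FALSE)
    direct <- unique(rbind(direct, second))
  }
  mouse_of <- function(h) sub("^G", "Mg", h)
  annotations <- data.frame(mouse_id = mouse_of(direct$gene_id),
                            term_id = direct$term_id,
                            stringsAsFactors = FALSE)

  orthology <- data.frame(human_id = gene_ids,
                          mouse_id = mouse_of(gene_ids),
                          stringsAsFactors = FALSE)
  n_decoy <- round(cfg$non_one_to_one_rate * N)
  if (n_decoy > 0) {
    decoy_h <- sprintf("GX%04d", seq_len(n_decoy))
    decoys <- data.frame(
      human_id = rep(decoy_h, each = 2),
      mouse_id = paste0(sub("^G", "Mg", rep(decoy_h, each = 2)),
                        c("a", "b")),
      stringsAsFactors = FALSE)
    # annotate the decoy mice too: loaders must exclude them via the 1:1 rule
    annotations <- rbind(annotations, data.frame(
      mouse_id = decoys$mouse_id,
      term_id = sample(organ_leaves, nrow(decoys), replace = TRUE),
      stringsAsFactors = FALSE))
    orthology <- rbind(orthology, decoys)
  }

  list(ontology = onto, annotations = annotations, orthology = orthology,
       root_term = root, behaviour_term = beh, focal_term = focal,
       focal_genes = sort(focal_genes), behaviour_genes = sort(beh_genes))
}

#' Generate case and control CNV cohorts with a planted enrichment
#'
#' Case gains are anchored on single genes (the anchor's span is fully
#' contained in the CNV); because gene spacing exceeds the maximum CNV
#' length, each gain contributes exactly its anchor as a gain-gene. The
#' planted enrichment targets the *analyzed* cohort: gain-genes only arise
#' from CNVs surviving the strict length cutoff, so among the gains longer
#' than `min_cnv_length_bp` exactly `round(q * n_large)` carry focal
#' anchors, with `q = min(1, planted_fold * K / N)` — the focal fraction
#' among gain-genes then equals `planted_fold * K / N` by construction.
#' Focal and non-focal large-gain anchors are drawn without replacement so
#' the planted gene count is exact; sub-threshold gains (which never reach
#' the analysis) get Bernoulli(`q`) focal anchors. Case losses are anchored
#' uniformly (no planting). Control CNVs are placed uniformly over the
#' genome with the same log-uniform length distribution; lengths straddle
#' the 500 kb cutoff in all cohorts. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param genes a [make_gene_models()] result.
#' @param focal_set character vector of focal gene ids (must be gene ids of
#'   `genes`).
#' @return list with `case` and `control` (both `cnv_table`) and
#'   `planted_q` (the focal anchor probability used).
#' @export
make_cnv_cohort <- function(cfg, genes, focal_set) {
  stopifnot(inherits(cfg, "sim_config"), inherits(genes, "gene_models"))
  set.seed(cfg$seed + 303L)
  spans <- gene_spans(genes)
  stopifnot(all(focal_set %in% spans$gene_id))
  nonfocal <- setdiff(spans$gene_id, focal_set)
  q <- min(1, cfg$planted_fold * length(focal_set) / nrow(spans))

  draw_len <- function(n)
    round(exp(runif(n, log(cfg$cnv_length_range[1]),
                    log(cfg$cnv_length_range[2]))))
  anchored <- function(anchors, dosage, len = NULL) {
    sp <- spans[match(anchors, spans$gene_id), , drop = FALSE]
    if (is.null(len)) len <- draw_len(length(anchors))
    len <- pmax(len, (sp$end - sp$start) + 1000)
    offset <- floor(runif(length(anchors)) * (len - (sp$end - sp$start)))
    start <- pmax(0, sp$start - offset)
    data.frame(chrom = sp$chrom, start = start, end = start + len,
               dosage = rep_len(dosage, nrow(sp)), stringsAsFactors = FALSE)
  }

  ng <- cfg$n_case_gains; nl <- cfg$n_case_losses
  gain_len <- pmax(draw_len(ng), 1)
  large <- gain_len > cfg$min_cnv_length_bp
  m_focal <- min(round(q * sum(large)), length(focal_set))
  gain_anchors <- character(ng)
  li <- which(large)
  focal_pos <- sample(li, m_focal)
  gain_anchors[focal_pos] <- sample(focal_set, m_focal)
  rest_large <- setdiff(li, focal_pos)
  gain_anchors[rest_large] <- sample(nonfocal, length(rest_large))
  small <- which(!large)
  if (length(small)) {
    small_focal <- runif(length(small)) < q
    gain_anchors[small] <- ifelse(
      small_focal, sample(focal_set, length(small), replace = TRUE),
      sample(nonfocal, length(small), replace = TRUE))
  }
  loss_anchors <- sample(spans$gene_id, nl, replace = TRUE)
  gains <- anchored(gain_anchors, "gain", len = gain_len)
  case <- rbind(gains, anchored(loss_anchors, "loss"))
  n_subj <- max(1L, round(0.94 * nrow(case)))
  case_tab <- cnv_table(
    subject = sprintf("case%04d", sample.int(n_subj, nrow(case),
                                             replace = TRUE)),
    chrom = case$chrom, start = case$start, end = case$end,
    dosage = case$dosage, cohort = "case",
    origin = sample(c("inherited", "de_novo", "unknown"), nrow(case),
                    replace = TRUE, prob = c(0.8, 0.1, 0.1)))

  chrom_tab <- stats::aggregate(end ~ chrom, data = spans, FUN = max)
  chrom_tab$len <- chrom_tab$end + cfg$gene_spacing_bp
  nc <- cfg$n_control_gains + cfg$n_control_losses
  ci <- sample.int(nrow(chrom_tab), nc, replace = TRUE,
                   prob = chrom_tab$len)
  clen <- draw_len(nc)
  cstart <- floor(runif(nc) * pmax(1, chrom_tab$len[ci] - clen))
  control_tab <- cnv_table(
    subject = sprintf("ctrl%05d", sample.int(max(1L, round(0.8 * nc)), nc,
                                             replace = TRUE)),
    chrom = chrom_tab$chrom[ci], start = cstart, end = cstart + clen,
    dosage = rep(c("gain", "loss"),
                 c(cfg$n_control_gains, cfg$n_control_losses)),
    cohort = "control", origin = "unknown")

  list(case = case_tab, control = control_tab, planted_q = q)
}

#' Generate an expression matrix with planted correlated modules
#'
#' Latent-factor model on the log2 scale: genes of module `m` have profile
#' `mu + sqrt(r) * f_m + sqrt(1 - r) * eps` with standard-normal factor and
#' noise, so the within-module Pearson correlation of the log profiles is
#' `r` in expectation (equivalently `noise_sd = sqrt(1/r - 1)` relative to
#' the factor). Background genes are independent noise; a configurable
#' fraction are silent (below the RPKM filter everywhere). RPKM values are
#' `max(2^z - 1, 0)`, so `log2(RPKM + 1)` recovers the latent profile for
#' expressed genes. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param modules list of disjoint character vectors of gene ids (one per
#'   planted module).
#' @param background_genes gene ids outside any module.
#' @return RPKM matrix (genes x samples) with `attr(, "modules")`.
#' @export
make_expression <- function(cfg, modules, background_genes = character(0)) {
  stopifnot(inherits(cfg, "sim_config"))
  mod_genes <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(c(mod_genes, background_genes)))
    stop("modules and background must be disjoint gene sets")
  set.seed(cfg$seed + 404L)
  S <- cfg$n_samples
  r <- cfg$within_module_r
  a <- sqrt(r); s_noise <- sqrt(1 - r)
  mu <- 5

  rows <- list()
  for (m in seq_along(modules)) {
    g <- modules[[m]]
    f <- rnorm(S)
    z <- matrix(rep(a * f, each = length(g)), nrow = length(g)) +
      matrix(rnorm(length(g) * S, sd = s_noise), nrow = length(g))
    rows[[m]] <- mu + z
  }
  nb <- length(background_genes)
  if (nb) {
    silent <- runif(nb) < cfg$silent_gene_rate
    zb <- matrix(rnorm(nb * S), nrow = nb)
    zb <- zb * ifelse(silent, 0.5, 1) + ifelse(silent, -3, mu)
    rows <- c(rows, list(zb))
  }
  z <- do.call(rbind, rows)
  rownames(z) <- c(mod_genes, background_genes)
  colnames(z) <- sprintf("s%03d", seq_len(S))
  expr <- pmax(2^z - 1, 0)
  attr(expr, "modules") <- modules
  expr
}

#' Generate a complete synthetic study
#'
#' Runs all generators under one configuration: gene models, ontology +
#' annotations + orthology, case/control CNV cohorts planted on the focal
#' term's genes, and an expression matrix over the focal genes with
#' `cfg$n_modules` planted modules. Optionally writes every input in its
#' on-disk format (TSV/GFF3/OBO) plus `truth.json` recording the planted
#' parameters, so the format readers can be exercised on the same data.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @return list with `config`, `genes`, `ontology_set` (the
#'   [make_annotation_universe()] output), `universe` (built via
#'   [annotate_closure()]), `cohort`, `expression`, `modules` and `truth`.
#' @export
simulate_study <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- make_gene_models(cfg)
  onto_set <- make_annotation_universe(cfg)
  orth <- suppressMessages(orthology_map(onto_set$orthology$human_id,
                                         onto_set$orthology$mouse_id))
  universe <- annotate_closure(onto_set$ontology, onto_set$annotations, orth)
  cohort <- make_cnv_cohort(cfg, genes, onto_set$focal_genes)

  set.seed(cfg$seed + 505L)
  picked <- sample(onto_set$focal_genes,
                   cfg$n_modules * cfg$module_size)
  modules <- split(picked, rep(seq_len(cfg$n_modules),
                               each = cfg$module_size))
  names(modules) <- sprintf("module%d", seq_along(modules))
  background <- setdiff(onto_set$focal_genes, picked)
  expr <- make_expression(cfg, modules, background)

  truth <- list(seed = cfg$seed, planted_fold = cfg$planted_fold,
                planted_q = cohort$planted_q,
                focal_term = onto_set$focal_term,
                behaviour_term = onto_set$behaviour_term,
                root_term = onto_set$root_term,
                universe_size = cfg$universe_size,
                focal_term_size = cfg$focal_term_size,
                modules = modules,
                within_module_r = cfg$within_module_r)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    write_cnvs(cohort$case, p("cnvs_case.tsv"))
    write_cnvs(cohort$control, p("cnvs_control.tsv"))
    write_gene_models(genes, p("genes.tsv"), format = "tsv")
    write_gene_models(genes, p("genes.gff3"), format = "gff3")
    write_obo(onto_set$ontology, p("ontology.obo"))
    utils::write.table(onto_set$annotations, p("annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(onto_set$orthology, p("orthology.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_expression(expr, p("expression.tsv"))
    jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  list(config = cfg, genes = genes, ontology_set = onto_set,
       universe = universe, cohort = cohort, expression = expr,
       modules = modules, truth = truth)
}
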