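test_that("generated gene models satisfy the structural invariants", {
  cfg <- small_sim_config(seed = 2)
  gm <- make_gene_models(cfg)   # constructor validates exon/CDS structure
  expect_equal(nrow(gm$genes), cfg$n_genes)
  expect_true(all(gm$genes$n_coding_tx >= 1))
  expect_true(all(gm$genes$n_tx >= cfg$transcripts_per_gene[1] &
                    gm$genes$n_tx <= cfg$transcripts_per_gene[2]))

  # sweep-line check: no two gene spans overlap on any chromosome
  sp <- gene_spans(gm)
  for (chr in unique(sp$chrom)) {
    s <- sp[sp$chrom == chr, ]
    s <- s[order(s$start), ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }

  # non-coding isoforms appear at a non-zero rate, and vanish at rate 0
  expect_gt(sum(!gm$transcripts$coding), 0)
  all_coding <- make_gene_models(small_sim_config(seed = 2,
                                                  noncoding_tx_rate = 0))
  expect_true(all(all_coding$transcripts$coding))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 9)
  g1 <- make_gene_models(cfg); g2 <- make_gene_models(cfg)
  expect_identical(g1$exons, g2$exons)
  a1 <- make_annotation_universe(cfg); a2 <- make_annotation_universe(cfg)
  expect_identical(a1$annotations, a2$annotations)
  expect_identical(a1$orthology, a2$orthology)
  c1 <- make_cnv_cohort(cfg, g1, a1$focal_genes)
  c2 <- make_cnv_cohort(cfg, g1, a1$focal_genes)
  expect_identical(as.data.frame(c1$case), as.data.frame(c2$case))
  e1 <- make_expression(cfg, list(a1$focal_genes[1:5]))
  e2 <- make_expression(cfg, list(a1$focal_genes[1:5]))
  expect_identical(e1, e2)
})

test_that("synthetic universe has exact closure sizes by construction", {
  cfg <- small_sim_config(seed = 4)
  u <- make_annotation_universe(cfg)
  orth <- suppressMessages(orthology_map(u$orthology$human_id,
                                         u$orthology$mouse_id))
  uni <- annotate_closure(u$ontology, u$annotations, orth)
  expect_equal(length(uni$genes), cfg$universe_size)
  expect_equal(length(uni$term_gene_sets[[u$focal_term]]),
               cfg$focal_term_size)
  expect_equal(length(uni$term_gene_sets[[u$behaviour_term]]),
               cfg$behaviour_term_size)
  expect_equal(length(uni$term_gene_sets[[u$root_term]]),
               cfg$universe_size)
  expect_equal(sort(uni$term_gene_sets[[u$focal_term]]), u$focal_genes)

  # direct annotations sit only on leaves; internal terms are filled purely
  # by closure
  internal <- c(u$root_term, u$behaviour_term, u$focal_term, "SP:0000004")
  expect_false(any(u$annotations$term_id %in% internal))

  # decoy non-1:1 rows exist and are annotated, so loaders must drop them
  dup <- u$orthology$human_id[duplicated(u$orthology$human_id)]
  expect_gt(length(dup), 0)
  expect_false(any(grepl("^GX", uni$genes)))
})

test_that("planted cohorts straddle the length cutoff and plant focal genes", {
  cfg <- small_sim_config(seed = 6)
  gm <- make_gene_models(cfg)
  u <- make_annotation_universe(cfg)
  cohort <- make_cnv_cohort(cfg, gm, u$focal_genes)
  len <- cohort$case$length
  expect_gt(sum(len > cfg$min_cnv_length_bp), 0)
  expect_gt(sum(len <= cfg$min_cnv_length_bp), 0)
  expect_equal(cohort$planted_q,
               min(1, cfg$planted_fold * cfg$focal_term_size / cfg$n_genes))

  # among length-retained gains the focal anchor count is exact
  large <- filter_large_cnvs(cohort$case, cfg$min_cnv_length_bp)
  gain_genes <- cnv_gene_sets(assign_cnv_genes(large, gm))$gain
  n_large_gains <- sum(large$dosage == "gain")
  expect_equal(sum(gain_genes %in% u$focal_genes),
               round(cohort$planted_q * n_large_gains))

  # control CNVs are generated for both dosages across the genome
  expect_equal(sum(cohort$control$dosage == "gain"), cfg$n_control_gains)
  expect_equal(sum(cohort$control$dosage == "loss"), cfg$n_control_losses)
})

test_that("an empty case cohort propagates to a no-analyzable-genes outcome", {
  cfg <- small_sim_config(seed = 8, n_case_gains = 0L, n_case_losses = 0L)
  gm <- make_gene_models(cfg)
  u <- make_annotation_universe(cfg)
  cohort <- make_cnv_cohort(cfg, gm, u$focal_genes)
  expect_equal(nrow(cohort$case), 0)
  orth <- suppressMessages(orthology_map(u$orthology$human_id,
                                         u$orthology$mouse_id))
  uni <- annotate_closure(u$ontology, u$annotations, orth)
  expect_warning(
    res <- cnv_phenotype_enrichment(cohort$case, cohort$control, gm, uni,
                                    u$behaviour_term, min_term_genes = 1),
    "no analyzable genes")
  expect_equal(nrow(res), 0)
})

test_that("planted expression modules hit the target correlation", {
  cfg <- small_sim_config(seed = 10, n_samples = 200,
                          within_module_r = 0.8)
  ids <- sprintf("E%03d", 1:80)
  expr <- make_expression(cfg, modules = list(ids[1:20]),
                          background_genes = ids[21:80])
  x <- log2(expr + 1)
  rmat <- suppressWarnings(cor(t(x)))
  within <- rmat[1:20, 1:20][upper.tri(diag(20))]
  expect_gt(mean(within), 0.75)
  expect_lt(mean(within), 0.85)

  bg <- rmat[41:80, 41:80][upper.tri(diag(40))]
  bg <- bg[!is.na(bg)]
  expect_lt(abs(mean(bg)), 0.05)
  expect_lt(mean(abs(bg) >= 0.7), 0.001)   # strong null edges are rare

  # module genes always survive the expression filter
  kept <- rownames(filter_expressed(expr))
  expect_true(all(ids[1:20] %in% kept))
  # some silent background genes are filtered out
  expect_lt(length(kept), nrow(expr))
})

test_that("a full synthetic study writes consistent on-disk inputs", {
  cfg <- small_sim_config(seed = 12)
  dir <- withr::local_tempdir()
  st <- suppressMessages(simulate_study(cfg, dir = dir))
  expect_true(all(file.exists(file.path(dir,
    c("cnvs_case.tsv", "cnvs_control.tsv", "genes.tsv", "genes.gff3",
      "ontology.obo", "annotations.tsv", "orthology.tsv",
      "expression.tsv", "truth.json")))))

  cnvs <- read_cnvs(file.path(dir, "cnvs_case.tsv"), coords = "one_based")
  expect_equal(cnvs$start, st$cohort$case$start)
  expect_equal(cnvs$dosage, st$cohort$case$dosage)

  gm_tsv <- read_gene_models(file.path(dir, "genes.tsv"), format = "tsv")
  expect_equal(gene_spans(gm_tsv), gene_spans(st$genes))
  gm_gff <- read_gene_models(file.path(dir, "genes.gff3"), format = "gff3")
  expect_equal(gene_spans(gm_gff), gene_spans(st$genes))
  expect_equal(gm_gff$genes$n_coding_tx, st$genes$genes$n_coding_tx)

  onto <- read_obo(file.path(dir, "ontology.obo"))
  expect_setequal(onto$terms, st$ontology_set$ontology$terms)

  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(dim(expr), dim(st$expression))

  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$planted_fold, cfg$planted_fold)
  expect_equal(truth$focal_term, st$ontology_set$focal_term)

  # the written inputs reproduce the in-memory universe
  orth <- suppressMessages(read_orthology(file.path(dir, "orthology.tsv")))
  ann <- read_annotations(file.path(dir, "annotations.tsv"), onto)
  uni <- annotate_closure(onto, ann, orth)
  expect_equal(uni$term_gene_sets[[st$ontology_set$focal_term]],
               st$universe$term_gene_sets[[st$ontology_set$focal_term]])
})
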