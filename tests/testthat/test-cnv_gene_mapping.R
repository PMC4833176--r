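test_that("CNV reader converts coordinate dialects and dosage labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tchrom\tstart\tend\tdosage",
               "s1\tchr1\t100\t200\tdup",
               "s2\t2\t500\t400\tdel",        # inverted interval -> dropped
               "s3\tX\t10\t20\tloss"), f)
  expect_warning(cnvs <- read_cnvs(f, coords = "one_based"),
                 "line\\(s\\): 3")
  expect_equal(nrow(cnvs), 2)
  # 1-based inclusive (100, 200) becomes internal [99, 200)
  expect_equal(cnvs$start[1], 99)
  expect_equal(cnvs$end[1], 200)
  expect_equal(cnvs$dosage[1], "gain")
  expect_equal(cnvs$chrom, c("1", "X"))      # chr prefix stripped

  writeLines(c("subject\tchrom\tstart\tend\tdosage",
               "s1\t1\t99\t200\tgain"), f)
  bed <- read_cnvs(f, coords = "bed")
  expect_equal(bed$start, 99)
  expect_equal(bed$end, 200)

  writeLines(c("subject\tchrom\tend\tdosage", "s1\t1\t200\tgain"), f)
  expect_error(read_cnvs(f), "start")
})

test_that("large-CNV filter applies a strict length inequality", {
  cnvs <- cnv_table(subject = c("a", "b", "c"), chrom = "1",
                    start = c(0, 0, 0), end = c(5e5, 5e5 + 1, 4e5),
                    dosage = "gain")
  kept <- filter_large_cnvs(cnvs, 5e5)
  expect_equal(kept$subject, "b")   # exactly 500 kb is excluded

  set.seed(11)
  len <- round(exp(runif(100, log(1e5), log(2e6))))
  big <- cnv_table(subject = sprintf("s%d", 1:100), chrom = "1",
                   start = 0, end = len, dosage = "gain")
  expect_equal(nrow(filter_large_cnvs(big, 5e5)), sum(len > 5e5))
})

test_that("gain assignment requires full span containment", {
  g <- toy_gene_models(
    toy_gene("gA", "1", list(t1 = list(exons = list(c(1000, 1400),
                                                    c(1800, 2000)),
                                       cds = list(c(1100, 1400))))))
  inside <- cnv_table("s1", "1", 500, 5000, "gain")
  partial <- cnv_table("s1", "1", 1500, 5000, "gain")
  expect_equal(assign_gain_genes(inside, g)$gene_id, "gA")
  expect_equal(nrow(assign_gain_genes(partial, g)), 0)
  # exact boundary containment counts
  exact <- cnv_table("s1", "1", 1000, 2000, "gain")
  expect_equal(assign_gain_genes(exact, g)$gene_id, "gA")
  # wrong chromosome never matches
  off <- cnv_table("s1", "2", 500, 5000, "gain")
  expect_equal(nrow(assign_gain_genes(off, g)), 0)
})

test_that("gain assignment equals the brute-force all-pairs oracle", {
  set.seed(21)
  for (rep in 1:3) {
    genes <- random_gene_models(40)
    sp <- gene_spans(genes)
    cnvs <- cnv_table(subject = sprintf("s%d", 1:15),
                      chrom = sample(c("1", "2"), 15, replace = TRUE),
                      start = st <- sample.int(2e5, 15),
                      end = st + sample(c(3000, 20000, 60000), 15,
                                        replace = TRUE),
                      dosage = "gain")
    got <- assign_gain_genes(cnvs, genes)
    expect_equal(sort(paste(got$gene_id, got$cnv_row)),
                 oracle_gain_genes(cnvs, genes))
  }
})

test_that("loss assignment needs a coding exon hit in every transcript", {
  g <- toy_gene_models(
    toy_gene("gA", "1", list(
      t1 = list(exons = list(c(1000, 1100), c(1500, 1600)),
                cds = list(c(1000, 1100))),
      t2 = list(exons = list(c(1000, 1100), c(3000, 3100)),
                cds = list(c(3000, 3100))))))
  # hits t1's CDS only (t2's CDS is at 3000) -> not assigned
  one_tx <- cnv_table("s1", "1", 1050, 1200, "loss")
  expect_equal(nrow(assign_loss_genes(one_tx, g)), 0)
  # spans both CDS regions -> assigned
  both <- cnv_table("s1", "1", 1050, 3050, "loss")
  expect_equal(assign_loss_genes(both, g)$gene_id, "gA")

  # UTR-only overlap does not count
  utr <- toy_gene_models(
    toy_gene("gU", "1", list(t1 = list(exons = list(c(1000, 2000)),
                                       cds = list(c(1400, 1600))))))
  expect_equal(nrow(assign_loss_genes(
    cnv_table("s1", "1", 1000, 1200, "loss"), utr)), 0)
  expect_equal(assign_loss_genes(
    cnv_table("s1", "1", 1000, 1401, "loss"), utr)$gene_id, "gU")

  # non-coding isoforms are outside the quantifier; all-non-coding genes
  # are never loss-genes
  mixed <- toy_gene_models(
    toy_gene("gM", "1", list(
      t1 = list(exons = list(c(1000, 1100)), cds = list(c(1000, 1100))),
      nc = list(exons = list(c(5000, 5100))))),
    toy_gene("gN", "1", list(nc = list(exons = list(c(1000, 1100))))))
  hit <- cnv_table("s1", "1", 900, 1200, "loss")
  expect_equal(assign_loss_genes(hit, mixed)$gene_id, "gM")
})

test_that("loss assignment equals its brute-force oracle", {
  set.seed(31)
  genes <- random_gene_models(30)
  cnvs <- cnv_table(subject = sprintf("s%d", 1:12),
                    chrom = sample(c("1", "2"), 12, replace = TRUE),
                    start = st <- sample.int(2e5, 12),
                    end = st + sample(c(500, 5000, 40000), 12,
                                      replace = TRUE),
                    dosage = "loss")
  got <- assign_loss_genes(cnvs, genes)
  expect_equal(sort(paste(got$gene_id, got$cnv_row)),
               oracle_loss_genes(cnvs, genes))
})

test_that("gain/loss asymmetry: partial overlap can lose but never gain", {
  g <- toy_gene_models(
    toy_gene("gA", "1", list(t1 = list(exons = list(c(1000, 2000)),
                                       cds = list(c(1100, 1900))))))
  iv <- list(chrom = "1", start = 1500, end = 5000)
  gain <- cnv_table("s1", iv$chrom, iv$start, iv$end, "gain")
  loss <- cnv_table("s1", iv$chrom, iv$start, iv$end, "loss")
  expect_equal(nrow(assign_gain_genes(gain, g)), 0)
  expect_equal(assign_loss_genes(loss, g)$gene_id, "gA")
})

test_that("assignments are invariant to row order and cohort splitting", {
  set.seed(41)
  genes <- random_gene_models(30)
  st <- sample.int(2e5, 20)
  cnvs <- cnv_table(subject = sprintf("s%d", 1:20),
                    chrom = sample(c("1", "2"), 20, replace = TRUE),
                    start = st, end = st + sample(c(4000, 50000), 20,
                                                  replace = TRUE),
                    dosage = sample(c("gain", "loss"), 20, replace = TRUE))
  whole <- cnv_gene_sets(assign_cnv_genes(cnvs, genes))
  shuffled <- cnvs[sample(nrow(cnvs)), ]
  expect_equal(cnv_gene_sets(assign_cnv_genes(shuffled, genes)), whole)
  half <- list(cnvs[1:10, ], cnvs[11:20, ])
  merged <- lapply(c("gain", "loss"), function(d)
    sort(unique(unlist(lapply(half, function(h)
      cnv_gene_sets(assign_cnv_genes(h, genes))[[d]])))))
  expect_equal(setNames(merged, c("gain", "loss")), whole)
})

test_that("enlarging a gain never removes assignments (monotonicity)", {
  set.seed(51)
  genes <- random_gene_models(30)
  st <- sample.int(2e5, 10)
  base <- cnv_table(subject = sprintf("s%d", 1:10), chrom = "1",
                    start = st, end = st + 8000, dosage = "gain")
  grown <- base
  grown$start <- pmax(0, grown$start - 5000)
  grown$end <- grown$end + 5000
  a_base <- assign_gain_genes(base, genes)
  a_grown <- assign_gain_genes(grown, genes)
  expect_true(all(paste(a_base$gene_id, a_base$cnv_row) %in%
                    paste(a_grown$gene_id, a_grown$cnv_row)))
})

test_that("control filtering removes direction-matched genes only", {
  genes <- toy_gene_models(
    toy_gene("gA", "1", list(t1 = list(exons = list(c(1000, 2000)),
                                       cds = list(c(1100, 1900))))),
    toy_gene("gB", "1", list(t1 = list(exons = list(c(10000, 12000)),
                                       cds = list(c(10100, 11900))))))
  case <- list(gain = c("gA", "gB"), loss = character(0))
  # control: gA gained (same direction), gB lost (opposite)
  control <- cnv_table(c("c1", "c2"), "1", c(500, 9000), c(3000, 13000),
                       c("gain", "loss"))
  out <- filter_control_genes(case, control, genes)
  expect_equal(out$gain, "gB")
  expect_equal(attr(out, "removed")$gain, "gA")
  # idempotent and unaffected by duplicated case entries
  again <- filter_control_genes(out, control, genes)
  expect_equal(again$gain, out$gain)
  dup <- filter_control_genes(list(gain = c("gA", "gA", "gB"),
                                   loss = character(0)), control, genes)
  expect_equal(dup$gain, out$gain)
})

test_that("control filtering matches a set-difference oracle at scale", {
  set.seed(61)
  genes <- random_gene_models(60)
  sp <- gene_spans(genes)
  case <- list(gain = sp$gene_id[1:40], loss = character(0))
  # build control gains that fully cover a known subset of the case genes
  covered <- sp[sp$gene_id %in% sp$gene_id[seq(1, 40, by = 6)], ]
  control <- cnv_table(sprintf("c%d", seq_len(nrow(covered))),
                       covered$chrom, covered$start - 10,
                       covered$end + 10, "gain")
  out <- filter_control_genes(case, control, genes)
  expect_equal(out$gain, sort(setdiff(case$gain, covered$gene_id)))
  expect_equal(length(out$gain), 40 - nrow(covered))
})
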