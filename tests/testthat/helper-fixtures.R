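# Shared fixture builders. Everything is generated in code; coordinates are
# 0-based half-open throughout.

# A gene with arbitrary transcript/exon/CDS structure from compact lists:
# tx = list(t1 = list(exons = list(c(s, e), ...), cds = list(c(s, e), ...)))
toy_gene <- function(gene_id, chrom, tx) {
  exons <- do.call(rbind, lapply(names(tx), function(t)
    do.call(rbind, lapply(tx[[t]]$exons, function(iv)
      data.frame(gene_id = gene_id, transcript_id = paste0(gene_id, ".", t),
                 chrom = chrom, start = iv[1], end = iv[2])))))
  cds_list <- lapply(names(tx), function(t) {
    if (is.null(tx[[t]]$cds)) return(NULL)
    do.call(rbind, lapply(tx[[t]]$cds, function(iv)
      data.frame(gene_id = gene_id, transcript_id = paste0(gene_id, ".", t),
                 chrom = chrom, start = iv[1], end = iv[2])))
  })
  list(exons = exons, cds = do.call(rbind, cds_list))
}

toy_gene_models <- function(...) {
  parts <- list(...)
  exons <- do.call(rbind, lapply(parts, `[[`, "exons"))
  cds <- do.call(rbind, lapply(parts, `[[`, "cds"))
  if (is.null(cds))
    cds <- data.frame(gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0))
  gene_models(exons, cds)
}

# Random single-exon gene models: n genes of given length, spaced out so a
# brute-force all-pairs oracle stays trivial to reason about.
random_gene_models <- function(n, chroms = c("1", "2"), span_len = 2000,
                               spacing = 10000) {
  per <- ceiling(n / length(chroms))
  chrom <- rep(chroms, each = per)[1:n]
  within <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- (within - 1) * spacing + sample.int(spacing - span_len - 1, n,
                                               replace = TRUE)
  g <- sprintf("g%03d", 1:n)
  exons <- data.frame(gene_id = g, transcript_id = paste0(g, ".t1"),
                      chrom = chrom, start = start, end = start + span_len)
  cds <- exons
  cds$start <- cds$start + 100
  cds$end <- cds$end - 100
  gene_models(exons, cds)
}

# Brute-force all-pairs containment oracle for gain assignment.
oracle_gain_genes <- function(cnvs, genes) {
  sp <- gene_spans(genes)
  out <- character(0)
  gains <- cnvs[cnvs$dosage == "gain", ]
  for (i in seq_len(nrow(gains))) {
    for (j in seq_len(nrow(sp))) {
      if (gains$chrom[i] == sp$chrom[j] &&
          gains$start[i] <= sp$start[j] && sp$end[j] <= gains$end[i])
        out <- c(out, paste(sp$gene_id[j], i))
    }
  }
  sort(out)
}

# Brute-force oracle for loss assignment (>=1 bp CDS overlap in every
# coding transcript).
oracle_loss_genes <- function(cnvs, genes) {
  losses <- cnvs[cnvs$dosage == "loss", ]
  out <- character(0)
  for (i in seq_len(nrow(losses))) {
    for (g in genes$genes$gene_id) {
      ctx <- genes$transcripts$transcript_id[
        genes$transcripts$gene_id == g & genes$transcripts$coding]
      if (!length(ctx)) next
      all_hit <- all(vapply(ctx, function(t) {
        cd <- genes$cds[genes$cds$transcript_id == t, ]
        any(cd$chrom == losses$chrom[i] & cd$start < losses$end[i] &
              losses$start[i] < cd$end)
      }, logical(1)))
      if (all_hit) out <- c(out, paste(g, i))
    }
  }
  sort(out)
}

# Random DAG ontology: term i may have parents among terms 1..(i-1), so the
# graph is acyclic by construction.
random_ontology <- function(n_terms, p_edge = 0.3) {
  ids <- sprintf("T%03d", seq_len(n_terms))
  parents <- setNames(vector("list", n_terms), ids)
  for (i in seq_len(n_terms)[-1]) {
    k <- rbinom(1, min(i - 1, 3), p_edge)
    if (k > 0) parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], k)
  }
  phenotype_ontology(ids, parents)
}

# Independent fixed-point closure oracle: repeatedly push gene sets from
# child terms into parents until nothing changes.
oracle_closure <- function(onto, direct_sets) {
  sets <- setNames(vector("list", length(onto$terms)), onto$terms)
  sets[names(direct_sets)] <- direct_sets
  repeat {
    changed <- FALSE
    for (t in onto$terms) {
      for (p in onto$parents[[t]]) {
        merged <- union(sets[[p]], sets[[t]])
        if (length(merged) > length(sets[[p]])) {
          sets[[p]] <- merged
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lapply(sets, function(x) sort(unlist(x)))
}

# Build a coexpression_network directly from an edge data.frame.
toy_network <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  r <- diag(1, length(nodes))
  dimnames(r) <- list(nodes, nodes)
  for (i in seq_len(nrow(edges))) {
    r[edges$gene_a[i], edges$gene_b[i]] <- edges$r[i]
    r[edges$gene_b[i], edges$gene_a[i]] <- edges$r[i]
  }
  threshold_network(r, mode = "absolute_r", value = min(edges$r))
}

# Random weighted graph over n nodes with edge probability p and weights in
# [0.7, 1): returned as a coexpression_network.
random_network <- function(n, p = 0.1) {
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                      r = runif(sum(keep), 0.7, 1))
  toy_network(edges, nodes = nodes)
}

# Small-but-complete simulation config for fast synthetic-module tests.
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_genes = 300L, n_chroms = 4L,
                   gene_spacing_bp = 3e6,
                   universe_size = 300L, focal_term_size = 40L,
                   behaviour_term_size = 120L, n_focal_children = 5L,
                   n_other_behaviour_terms = 10L, n_organ_terms = 6L,
                   n_case_gains = 30L, n_case_losses = 10L,
                   n_control_gains = 150L, n_control_losses = 80L,
                   n_samples = 60L, module_size = 10L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
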