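#' Read / write a genes-by-samples expression matrix
#'
#' TSV with a `gene_id` first column and one column per sample; values are
#' RPKM (non-negative). Duplicate gene ids are an error.
#'
#' @param path TSV path.
#' @return numeric matrix, rownames = gene ids, colnames = sample ids.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  stopifnot("gene_id" %in% names(df))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in expression file")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_expression
#' @param expr numeric matrix (genes x samples) with rownames.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter genes by minimum expression
#'
#' Retains genes expressed at `>= min_rpkm` in at least
#' `ceiling(min_fraction * n_samples)` samples; both comparisons are
#' inclusive. The canonical filter is RPKM >= 1 in >= 5% of samples.
#'
#' @param expr genes-by-samples matrix.
#' @param min_rpkm expression threshold (default 1).
#' @param min_fraction minimum fraction of samples, in `(0, 1]`
#'   (default 0.05).
#' @return the retained submatrix (warns if empty).
#' @export
filter_expressed <- function(expr, min_rpkm = 1, min_fraction = 0.05) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * ncol(expr))
  keep <- rowSums(expr >= min_rpkm) >= need
  if (!any(keep)) warning("no genes pass the expression filter")
  expr[keep, , drop = FALSE]
}

#' Pairwise expression correlations
#'
#' Pearson correlation between all gene pairs across samples, optionally on
#' `log2(x + 1)`-transformed values (the default; correlation of expression
#' magnitudes is dominated by a few high-RPKM genes otherwise). Genes with
#' zero variance across samples get `NA` correlations and form no edges.
#'
#' @param expr genes-by-samples matrix (>= 3 samples).
#' @param transform `"log2p1"` or `"none"`.
#' @return symmetric correlation matrix with `attr(, "transform")`.
#' @export
correlation_matrix <- function(expr, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (ncol(expr) < 3)
    stop("at least 3 samples are required to estimate correlations")
  x <- if (transform == "log2p1") log2(expr + 1) else expr
  sds <- apply(x, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(x)))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  attr(r, "transform") <- transform
  r
}

#' Threshold a correlation matrix into a co-expression network
#'
#' Builds an undirected weighted network whose edges are the retained gene
#' pairs. Two retention modes mirror each other: `"absolute_r"` keeps pairs
#' with signed correlation `r >= value` (negative correlations are never
#' edges); `"top_fraction"` keeps the `floor(value * n_pairs)` strongest
#' pairs by `r`, extending through ties at the boundary value (a message
#' reports tie counts). Both modes record the achieved edge fraction and
#' the implied r cutoff so they can be cross-checked against each other.
#'
#' @param r correlation matrix from [correlation_matrix()].
#' @param mode `"absolute_r"` or `"top_fraction"`.
#' @param value threshold in `(0, 1)`: the r cutoff, or the fraction of
#'   pairs to keep.
#' @return object of class `coexpression_network`: list with `nodes`
#'   (genes with defined correlations), `edges` (data.frame `gene_a`,
#'   `gene_b`, `r`, pairs stored canonically with `gene_a < gene_b`),
#'   `mode`, `value`, `r_cutoff` (smallest retained r, NA if no edges) and
#'   `achieved_fraction`.
#' @export
threshold_network <- function(r, mode = c("absolute_r", "top_fraction"),
                              value = 0.7) {
  mode <- match.arg(mode)
  stopifnot(value > 0, value < 1)
  stopifnot(nrow(r) == ncol(r))
  genes <- rownames(r)
  defined <- !is.na(diag(r))
  nodes <- sort(genes[defined])

  ut <- upper.tri(r)
  ij <- which(ut & !is.na(r), arr.ind = TRUE)
  w <- r[cbind(ij[, 1], ij[, 2])]
  n_pairs <- length(w)

  if (mode == "absolute_r") {
    keep <- w >= value
  } else {
    m <- floor(value * n_pairs)
    if (m == 0) {
      keep <- rep(FALSE, n_pairs)
    } else {
      cutoff <- sort(w, decreasing = TRUE)[m]
      keep <- w >= cutoff
      ties_extra <- sum(keep) - m
      if (ties_extra > 0)
        message("kept ", ties_extra, " extra edge(s) tied at r = ", cutoff)
    }
  }

  a <- genes[ij[keep, 1]]
  b <- genes[ij[keep, 2]]
  swap <- a > b
  edges <- data.frame(gene_a = ifelse(swap, b, a),
                      gene_b = ifelse(swap, a, b),
                      r = w[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mode = mode, value = value,
                 r_cutoff = if (nrow(edges)) min(edges$r) else NA_real_,
                 achieved_fraction = if (n_pairs) nrow(edges) / n_pairs
                                     else NA_real_),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", x$mode, " = ", x$value, ")\n", sep = "")
  cat("  achieved fraction ", signif(x$achieved_fraction, 3),
      ", r cutoff ", signif(x$r_cutoff, 3), "\n", sep = "")
  invisible(x)
}

#' Convert a co-expression network to an igraph object
#'
#' @param net a `coexpression_network`.
#' @return an undirected weighted [igraph::graph] including isolated nodes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$gene_a, to = net$edges$gene_b,
               weight = net$edges$r),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Write / read a network as an edge list plus node file
#'
#' Edge list: TSV `gene_a`, `gene_b`, `r`; node file: one gene id per line
#' (needed to preserve isolated nodes).
#'
#' @param net a `coexpression_network`.
#' @param edge_path,nodes_path output paths.
#' @export
write_network <- function(net, edge_path, nodes_path) {
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(net$nodes, nodes_path)
  invisible(edge_path)
}

#' @rdname write_network
#' @return `read_network` returns a `coexpression_network` (mode and
#'   thresholds are not stored on disk and come back as `absolute_r` with
#'   the minimum retained weight).
#' @export
read_network <- function(edge_path, nodes_path) {
  edges <- utils::read.delim(edge_path, header = TRUE,
                             stringsAsFactors = FALSE)
  nodes <- sort(readLines(nodes_path))
  stopifnot(all(c("gene_a", "gene_b", "r") %in% names(edges)))
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mode = "absolute_r",
                 value = if (nrow(edges)) min(edges$r) else NA_real_,
                 r_cutoff = if (nrow(edges)) min(edges$r) else NA_real_,
                 achieved_fraction = NA_real_),
            class = "coexpression_network")
}
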