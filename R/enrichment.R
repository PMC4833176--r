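#' Fold enrichment of a gene set in a term set
#'
#' Ratio of the observed proportion to the background proportion:
#' `(k/n) / (K/N)`, where `k` of the `n` analyzable test genes fall in a
#' term set of size `K` within a universe of `N` annotated genes. Full
#' precision is returned; reporting layers round to 2 significant figures.
#'
#' @param k hits among test genes (in the term set).
#' @param n analyzable test genes (in the universe).
#' @param K term set size within the universe.
#' @param N universe size.
#' @return numeric fold enrichment (vectorised over the arguments).
#' @export
fold_enrichment <- function(k, n, K, N) {
  .check_enrichment_input(k, n, K, N)
  if (any(n == 0) || any(K == 0))
    stop("fold enrichment undefined for n = 0 or K = 0")
  (k / n) / (K / N)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at
#' least `k` term-set genes in a uniform draw of `n` genes from a universe
#' of `N` containing `K` term-set members. Computed with [stats::phyper()]
#' (exact tail summation, stable in log space for large `N`).
#'
#' @inheritParams fold_enrichment
#' @return upper-tail probability, 1 when `k = 0` (vectorised).
#' @export
hypergeom_upper_p <- function(k, n, K, N) {
  .check_enrichment_input(k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.check_enrichment_input <- function(k, n, K, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(n, K)))
    stop("invalid enrichment input: need 0 <= k <= min(n, K), n <= N, K <= N")
  invisible(TRUE)
}

#' FDR adjustment
#'
#' Adjusts p-values for multiple testing, either as Storey q-values (pi0
#' estimated by the smoother method: natural cubic spline of `pi0(lambda)`
#' over `lambda = 0.05 ... 0.95`, evaluated at the largest lambda) or as
#' Benjamini-Hochberg step-up values. Storey's pi0 estimate is unstable for
#' small families; a warning is emitted below 100 tests, where `"bh"` is
#' the safer choice. Output order matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"storey"` or `"bh"`.
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (method == "bh") return(stats::p.adjust(p, method = "BH"))
  if (length(p) < 100)
    warning("Storey pi0 estimate is unstable for < 100 tests; ",
            "consider method = 'bh'")
  pi0 <- .storey_pi0(p)
  q <- pi0 * stats::p.adjust(p, method = "BH")
  pmin(q, 1)
}

# Smoother estimate of the null proportion pi0 (Storey & Tibshirani 2003).
.storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  lambda <- lambda[lambda < max(p)]
  if (length(lambda) < 4) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1 / length(p)), 1)   # clamp to (0, 1]
}

#' Per-term enrichment of a CNV gene set
#'
#' Tests a gene set (typically deduplicated, control-filtered CNV-genes)
#' for over-representation in each term's closure gene set by the one-sided
#' upper-tail hypergeometric test, with fold enrichment and FDR control
#' across the tested terms. Depletion is visible through fold < 1 but is
#' not tested (the test is directional).
#'
#' @param genes character vector of gene ids to test; only the distinct
#'   genes that belong to the universe enter the statistics
#'   (`n = |genes intersect universe|`).
#' @param universe an [annotate_closure()] result (or any list with `genes`
#'   and `term_gene_sets`).
#' @param terms term ids to test; default all terms with closure sets. See
#'   [select_test_terms()].
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @param method FDR method, `"storey"` (default) or `"bh"`.
#' @return data.frame of class `enrichment_result`, one row per term,
#'   sorted by p then term id, with columns `term_id`, `name`, `k`, `n`,
#'   `K`, `N`, `fold`, `p`, `q`, `significant`. Attributes: `n_input`,
#'   `n_analyzable`, `N`, `method`, `fdr`. With no analyzable genes a
#'   zero-row result is returned with a warning (`n_analyzable = 0`).
#' @export
run_enrichment <- function(genes, universe, terms = NULL, fdr = 0.05,
                           method = c("storey", "bh")) {
  method <- match.arg(method)
  genes <- unique(as.character(genes))
  in_univ <- intersect(genes, universe$genes)
  n <- length(in_univ)
  N <- length(universe$genes)
  if (is.null(terms)) terms <- sort(names(universe$term_gene_sets))
  unknown <- setdiff(terms, names(universe$term_gene_sets))

  onto_names <- universe$ontology$names
  term_name <- function(t)
    if (!is.null(onto_names) && t %in% names(onto_names)) onto_names[[t]]
    else t

  if (n == 0) {
    warning("no analyzable genes: none of the input genes are in the ",
            "annotated universe")
    res <- data.frame(term_id = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0))
    return(.as_enrichment_result(res, length(genes), 0L, N, method, fdr))
  }

  K <- vapply(terms, function(t) {
    s <- universe$term_gene_sets[[t]]
    if (is.null(s)) 0L else length(s)
  }, integer(1))
  k <- vapply(terms, function(t)
    length(intersect(in_univ, universe$term_gene_sets[[t]])), integer(1))
  if (any(K == 0))
    stop("term(s) with empty closure set in this universe: ",
         paste(terms[K == 0 | terms %in% unknown], collapse = ", "))

  fold <- (k / n) / (K / N)
  p <- hypergeom_upper_p(k, n, K, N)
  q <- fdr_adjust(p, method = method)
  res <- data.frame(term_id = terms,
                    name = vapply(terms, term_name, character(1)),
                    k = k, n = n, K = K, N = N, fold = fold, p = p, q = q,
                    significant = q < fdr, stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  .as_enrichment_result(res, length(genes), n, N, method, fdr)
}

.as_enrichment_result <- function(res, n_input, n_analyzable, N, method,
                                  fdr) {
  attr(res, "n_input") <- n_input
  attr(res, "n_analyzable") <- n_analyzable
  attr(res, "N") <- N
  attr(res, "method") <- method
  attr(res, "fdr") <- fdr
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, n_show = 10, ...) {
  cat("Phenotype-term enrichment: ", attr(x, "n_analyzable"),
      " analyzable genes (of ", attr(x, "n_input"), " input) in a universe of ",
      attr(x, "N"), "\n", sep = "")
  cat(nrow(x), " terms tested, ", sum(x$significant), " significant at FDR < ",
      attr(x, "fdr"), " (", attr(x, "method"), ")\n\n", sep = "")
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x), n_show)
    show$fold <- signif(show$fold, 2)   # report folds to 2 significant figures
    show$p <- signif(show$p, 2)
    show$q <- signif(show$q, 2)
    print(show, row.names = FALSE)
    if (nrow(x) > n_show) cat("... and", nrow(x) - n_show, "more terms\n")
  }
  invisible(x)
}

#' @export
summary.enrichment_result <- function(object, ...) {
  out <- list(n_terms = nrow(object),
              n_significant = sum(object$significant),
              n_analyzable = attr(object, "n_analyzable"),
              N = attr(object, "N"),
              method = attr(object, "method"), fdr = attr(object, "fdr"),
              top = if (nrow(object)) object$term_id[1] else NA_character_)
  class(out) <- "summary.enrichment_result"
  out
}

#' @export
print.summary.enrichment_result <- function(x, ...) {
  cat("enrichment of", x$n_analyzable, "genes over", x$n_terms,
      "terms (universe", paste0(x$N, "):"), x$n_significant,
      "significant at FDR <", x$fdr, paste0("(", x$method, ")"), "\n")
  if (!is.na(x$top)) cat("top term:", x$top, "\n")
  invisible(x)
}

#' Write an enrichment result table
#'
#' TSV with the reported fold rounded to 2 significant figures alongside
#' the full-precision value.
#'
#' @param result an `enrichment_result`.
#' @param path output path.
#' @export
write_enrichment <- function(result, path) {
  out <- as.data.frame(result)
  out$fold_reported <- signif(out$fold, 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
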