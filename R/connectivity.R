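# Adjacency of the thresholded network as a sparse symmetric matrix over
# net$nodes; genes outside the network simply have no row and contribute
# zero weight wherever they appear in a test set.
.net_adjacency <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  n <- length(net$nodes)
  i <- match(net$edges$gene_a, net$nodes)
  j <- match(net$edges$gene_b, net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(net$edges$r, 2), dims = c(n, n),
                       dimnames = list(net$nodes, net$nodes))
}

#' Summed edge weight within a gene set
#'
#' Sum of the weights of the network edges whose two endpoints both belong
#' to the set. Genes absent from the network contribute nothing.
#'
#' @param net a `coexpression_network`.
#' @param genes character vector of gene ids.
#' @return non-negative numeric scalar.
#' @export
within_set_weight <- function(net, genes) {
  A <- .net_adjacency(net)
  idx <- stats::na.omit(match(unique(genes), net$nodes))
  if (length(idx) < 2) return(0)
  sum(A[idx, idx]) / 2
}

#' Summed edge weight between two disjoint gene sets
#'
#' Sum of the weights of the edges with one endpoint in each set. The sets
#' must be disjoint: shared genes must have been removed explicitly (see
#' [exclude_shared()]) before testing, mirroring the exclusion step of the
#' cross-set analyses.
#'
#' @param net a `coexpression_network`.
#' @param a,b character vectors of gene ids, `a` and `b` disjoint.
#' @return non-negative numeric scalar.
#' @export
between_set_weight <- function(net, a, b) {
  shared <- intersect(a, b)
  if (length(shared))
    stop("gene sets must be disjoint; remove shared gene(s) first ",
         "(exclude_shared): ", paste(shared, collapse = ", "))
  A <- .net_adjacency(net)
  ia <- stats::na.omit(match(unique(a), net$nodes))
  ib <- stats::na.omit(match(unique(b), net$nodes))
  if (!length(ia) || !length(ib)) return(0)
  sum(A[ia, ib, drop = FALSE])
}

#' Remove genes shared between two gene sets
#'
#' The exclusion step required before any cross-set connectivity test:
#' genes present in both the candidate and the target set are removed from
#' both sets and from the permutation background.
#'
#' @param candidates,target,background character vectors of gene ids.
#' @return list with pruned `candidates`, `target`, `background` and the
#'   removed `shared` genes.
#' @export
exclude_shared <- function(candidates, target, background = character(0)) {
  shared <- intersect(candidates, target)
  list(candidates = setdiff(candidates, shared),
       target = setdiff(target, shared),
       background = setdiff(background, shared),
       shared = shared)
}

#' Empirical p-value from a permutation null
#'
#' `p = (k + 1) / (n_perm + 1)` where `k` counts null statistics greater
#' than *or equal to* the observed one (ties count against the observed).
#' The `+1` makes p strictly positive: with 100,000 permutations the
#' smallest attainable p is 1/100,001.
#'
#' @param observed observed statistic.
#' @param null_stats non-empty numeric vector of permutation statistics.
#' @param ... further fields stored on the result (e.g. seed, set sizes).
#' @return object of class `connectivity_result`: list with `observed`,
#'   `n_perm`, `k_ge`, `p_emp` plus any extra fields.
#' @export
empirical_p <- function(observed, null_stats, ...) {
  if (!length(null_stats)) stop("null_stats must be non-empty")
  k <- sum(null_stats >= observed)
  structure(c(list(observed = observed, n_perm = length(null_stats),
                   k_ge = k, p_emp = (k + 1) / (length(null_stats) + 1)),
              list(...)),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat("connectivity permutation test\n")
  cat("  observed summed weight: ", signif(x$observed, 6), "\n", sep = "")
  cat("  permutations: ", x$n_perm, "; null >= observed: ", x$k_ge, "\n",
      sep = "")
  cat("  empirical p = (k + 1)/(n_perm + 1) = ", signif(x$p_emp, 4), "\n",
      sep = "")
  extra <- setdiff(names(x), c("observed", "n_perm", "k_ge", "p_emp"))
  for (nm in extra)
    cat("  ", nm, ": ", paste(format(x[[nm]]), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# Draw n_perm without-replacement samples of size m from the background and
# evaluate stat_fun (a function of an index vector into `background`).
.perm_null <- function(background, m, n_perm, stat_fun) {
  vapply(seq_len(n_perm),
         function(i) stat_fun(sample.int(length(background), m)),
         numeric(1))
}

#' Within-set cohesion permutation test
#'
#' Tests whether a candidate gene set is more tightly co-expressed (larger
#' within-set summed edge weight) than random same-size subsets of a
#' background gene set, e.g. 22 candidate genes against the 439 genes whose
#' mouse orthologues yield the same phenotype. Sampling is uniform without
#' replacement; candidates absent from the network stay in the draw and
#' contribute zero weight.
#'
#' @param net a `coexpression_network`.
#' @param candidates character vector, a subset of `background`.
#' @param background character vector of gene ids to draw from.
#' @param n_perm number of permutations (default 100,000).
#' @param seed integer seed for the single RNG stream of this invocation
#'   (recorded on the result); `NULL` uses the current RNG state.
#' @return a [empirical_p()] result with fields `seed`, `n_candidates`,
#'   `n_background`.
#' @export
cohesion_test <- function(net, candidates, background, n_perm = 1e5,
                          seed = NULL) {
  candidates <- unique(candidates)
  background <- unique(background)
  if (!all(candidates %in% background))
    stop("candidates must be a subset of the background")
  if (length(background) <= length(candidates))
    stop("background must be larger than the candidate set")
  if (!is.null(seed)) set.seed(seed)
  A <- .net_adjacency(net)
  # dense submatrix indexing is far faster inside the permutation loop
  if (length(net$nodes) <= 4000) A <- as.matrix(A)
  pos <- match(background, net$nodes)          # NA for absent genes
  m <- length(candidates)
  stat <- function(idx) {
    ii <- pos[idx]
    ii <- ii[!is.na(ii)]
    if (length(ii) < 2) 0 else sum(A[ii, ii]) / 2
  }
  observed <- within_set_weight(net, candidates)
  null_stats <- .perm_null(background, m, n_perm, stat)
  empirical_p(observed, null_stats, seed = seed, n_candidates = m,
              n_background = length(background))
}

#' Cross-set connectivity permutation test
#'
#' Tests whether the candidate set is more connected (summed edge weight)
#' to a fixed target set than random same-size subsets of a background are.
#' Genes shared between candidates and target must already have been
#' removed from both sets and from the background ([exclude_shared()]);
#' overlapping inputs are an error so the exclusion bookkeeping stays
#' explicit.
#'
#' @inheritParams cohesion_test
#' @param target character vector of target gene ids (fixed across
#'   permutations).
#' @return a [empirical_p()] result with fields `seed`, `n_candidates`,
#'   `n_target`, `n_background`.
#' @export
cross_set_test <- function(net, candidates, target, background,
                           n_perm = 1e5, seed = NULL) {
  candidates <- unique(candidates)
  target <- unique(target)
  background <- unique(background)
  if (length(intersect(candidates, target)))
    stop("candidates and target overlap; apply exclude_shared() first")
  if (length(intersect(background, intersect(candidates, target))))
    stop("background still contains shared genes")
  if (length(background) <= length(candidates))
    stop("background must be larger than the candidate set")
  if (!is.null(seed)) set.seed(seed)
  A <- .net_adjacency(net)
  # weight from every node to the fixed target set, so each permutation is
  # a sum of |candidates| precomputed values
  it <- stats::na.omit(match(target, net$nodes))
  w_target <- if (length(it))
    as.numeric(Matrix::rowSums(A[, it, drop = FALSE])) else
    numeric(length(net$nodes))
  pos <- match(background, net$nodes)
  w_bg <- ifelse(is.na(pos), 0, w_target[pos])
  m <- length(candidates)
  observed <- between_set_weight(net, candidates, target)
  null_stats <- .perm_null(background, m, n_perm,
                           function(idx) sum(w_bg[idx]))
  empirical_p(observed, null_stats, seed = seed, n_candidates = m,
              n_target = length(target), n_background = length(background))
}

#' Comparative composite-background connectivity test
#'
#' Asks whether the target set is more connected to the candidates than to
#' a competitor set, by drawing null sets of size `|candidates|` from the
#' composite background `candidates + competitor` (after removing from both
#' any gene belonging to the target set, and deduplicating the overlap
#' between them). The statistic is the summed edge weight to the target.
#'
#' @inheritParams cross_set_test
#' @param competitor character vector of competitor gene ids.
#' @return a [empirical_p()] result with fields `seed`, `n_candidates`,
#'   `n_competitor`, `n_composite`, `n_target`.
#' @export
comparative_background_test <- function(net, candidates, competitor, target,
                                        n_perm = 1e5, seed = NULL) {
  candidates <- setdiff(unique(candidates), target)
  competitor <- setdiff(unique(competitor), target)
  composite <- union(candidates, competitor)
  if (length(composite) <= length(candidates))
    stop("composite background must be larger than the candidate set")
  res <- cross_set_test(net, candidates, unique(target), composite,
                        n_perm = n_perm, seed = seed)
  res$n_competitor <- length(competitor)
  res$n_composite <- length(composite)
  res$n_background <- NULL
  res
}
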