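#' Construct a phenotype ontology
#'
#' A directed acyclic graph of phenotype terms with `is_a` parents, as used
#' by the Mammalian Phenotype Ontology. Every referenced parent must itself
#' be a term and the parent graph must be acyclic.
#'
#' @param terms character vector of term identifiers.
#' @param parents named list mapping each term to a character vector of its
#'   parent terms (may be empty for roots); names must be a subset of
#'   `terms`.
#' @param names named character vector of human-readable labels (optional).
#' @return An object of class `phenotype_ontology`.
#' @export
phenotype_ontology <- function(terms, parents = list(), names = character(0)) {
  terms <- unique(as.character(terms))
  parents <- parents[intersect(base::names(parents), terms)]
  full <- setNames(vector("list", length(terms)), terms)
  full[base::names(parents)] <- lapply(parents, as.character)
  unknown <- setdiff(unlist(full, use.names = FALSE), terms)
  if (length(unknown))
    stop("parent term(s) not in ontology: ", paste(unknown, collapse = ", "))
  onto <- structure(list(terms = terms, parents = full,
                         names = names[intersect(base::names(names), terms)]),
                    class = "phenotype_ontology")
  .check_dag(onto)
  onto
}

.ontology_graph <- function(onto) {
  edges <- do.call(rbind, lapply(onto$terms, function(t) {
    p <- onto$parents[[t]]
    if (length(p)) cbind(t, p) else NULL
  }))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(onto$terms), name = onto$terms)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(matrix(match(edges, onto$terms),
                                       ncol = 2)))
  g
}

.check_dag <- function(onto) {
  g <- .ontology_graph(onto)
  if (!igraph::is_dag(g)) {
    cyc <- tryCatch({
      comp <- igraph::components(g, mode = "strong")
      bad <- which(comp$membership == which(comp$csize > 1)[1])
      paste(onto$terms[bad], collapse = " -> ")
    }, error = function(e) "unknown")
    stop("ontology parent graph contains a cycle: ", cyc)
  }
  invisible(TRUE)
}

#' @export
print.phenotype_ontology <- function(x, ...) {
  cat("phenotype_ontology: ", length(x$terms), " terms, ",
      sum(lengths(x$parents)), " is_a edges, ",
      sum(lengths(x$parents) == 0), " root(s)\n", sep = "")
  invisible(x)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name`, `is_a` and `is_obsolete`
#' fields. Obsolete terms are dropped, together with any `is_a` edge
#' pointing at a dropped or undeclared term (with a warning). The resulting
#' parent graph is validated as a DAG; a cycle is an error naming the
#' offending terms.
#'
#' @param path path to an OBO file.
#' @return A [phenotype_ontology()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s*!.*$", "", lines)          # strip OBO comments
  stanza_at <- grep("^\\[", lines)
  is_term <- lines[stanza_at] == "[Term]"
  bounds <- c(stanza_at, length(lines) + 1L)

  ids <- character(0); nms <- character(0)
  parents <- list(); obsolete <- character(0)
  for (s in seq_along(stanza_at)) {
    if (!is_term[s]) next
    block <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    val <- function(key) {
      m <- grep(paste0("^", key, ":"), block, value = TRUE)
      trimws(sub(paste0("^", key, ":"), "", m))
    }
    id <- val("id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (any(val("is_obsolete") == "true")) { obsolete <- c(obsolete, id); next }
    ids <- c(ids, id)
    nm <- val("name")[1]
    nms[id] <- if (is.na(nm)) id else nm
    parents[[id]] <- val("is_a")
  }
  known <- ids
  dropped <- 0L
  for (id in names(parents)) {
    p <- parents[[id]]
    keep <- p %in% known
    dropped <- dropped + sum(!keep)
    parents[[id]] <- p[keep]
  }
  if (dropped > 0)
    warning("dropped ", dropped,
            " is_a edge(s) to obsolete or undeclared terms")
  phenotype_ontology(ids, parents, nms)
}

#' Write an ontology as OBO 1.2
#'
#' @param onto a `phenotype_ontology`.
#' @param path output path.
#' @export
write_obo <- function(onto, path) {
  stopifnot(inherits(onto, "phenotype_ontology"))
  out <- c("format-version: 1.2", "")
  for (t in onto$terms) {
    nm <- if (t %in% names(onto$names)) onto$names[[t]] else t
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: ", nm),
             if (length(onto$parents[[t]]))
               paste0("is_a: ", onto$parents[[t]]),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Ancestors of a term
#'
#' All terms reachable from `term` by following `is_a` edges upward
#' (excluding the term itself).
#'
#' @param onto a `phenotype_ontology`.
#' @param term a term identifier.
#' @return character vector of ancestor term ids (sorted).
#' @export
term_ancestors <- function(onto, term) {
  .reach(onto$parents, term, include_self = FALSE)
}

#' Descendants of a term
#'
#' All terms from which `term` is reachable by `is_a` edges.
#'
#' @inheritParams term_ancestors
#' @param include_self include `term` itself (default TRUE).
#' @return character vector of descendant term ids (sorted).
#' @export
term_descendants <- function(onto, term, include_self = TRUE) {
  children <- setNames(vector("list", length(onto$terms)), onto$terms)
  for (t in onto$terms)
    for (p in onto$parents[[t]])
      children[[p]] <- c(children[[p]], t)
  .reach(children, term, include_self = include_self)
}

.reach <- function(adj, term, include_self) {
  if (!term %in% names(adj)) stop("unknown term: ", term)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, term))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(if (include_self) c(term, seen) else seen)
}

#' Read a strictly 1:1 orthology table
#'
#' Reads a TSV with columns `human_id` and `mouse_id` and keeps only pairs
#' that are 1:1 in both directions; genes appearing in one-to-many or
#' many-to-many relations are dropped with a message reporting the count.
#'
#' @param path TSV path.
#' @return data.frame with columns `human_id`, `mouse_id`, class
#'   `orthology_map`.
#' @export
read_orthology <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("human_id", "mouse_id") %in% names(df)))
  orthology_map(df$human_id, df$mouse_id)
}

#' Construct a 1:1 orthology map
#'
#' @param human_id,mouse_id parallel id vectors; non-1:1 rows are dropped.
#' @return data.frame of class `orthology_map`.
#' @export
orthology_map <- function(human_id, mouse_id) {
  df <- unique(data.frame(human_id = as.character(human_id),
                          mouse_id = as.character(mouse_id),
                          stringsAsFactors = FALSE))
  dup_h <- df$human_id %in% df$human_id[duplicated(df$human_id)]
  dup_m <- df$mouse_id %in% df$mouse_id[duplicated(df$mouse_id)]
  bad <- dup_h | dup_m
  if (any(bad))
    message("dropped ", sum(bad), " non-1:1 orthology row(s)")
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("orthology_map", "data.frame")
  df
}

#' Read a gene-phenotype annotation table
#'
#' TSV with columns `mouse_id` and `term_id` (direct annotations). Rows
#' whose term is not in the ontology (e.g. annotations to obsolete terms)
#' are dropped with a warning.
#'
#' @param path TSV path.
#' @param onto a `phenotype_ontology`.
#' @return data.frame with columns `mouse_id`, `term_id`.
#' @export
read_annotations <- function(path, onto) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("mouse_id", "term_id") %in% names(df)))
  bad <- !df$term_id %in% onto$terms
  if (any(bad))
    warning("dropped ", sum(bad), " annotation(s) to unknown term ids")
  unique(df[!bad, c("mouse_id", "term_id"), drop = FALSE])
}

#' Build the annotated universe under ancestor closure
#'
#' Maps direct mouse-gene annotations through a strict 1:1 orthology onto
#' human genes and propagates them up the ontology: a human gene belongs to
#' a term's gene set iff its mouse orthologue is directly annotated with the
#' term or with any of its descendants. Genes without a 1:1 orthologue, or
#' whose orthologue carries no annotation, are outside the universe.
#'
#' @param onto a `phenotype_ontology`.
#' @param annotations data.frame with `mouse_id`, `term_id` (direct
#'   annotations), e.g. from [read_annotations()].
#' @param orthology an [orthology_map()].
#' @return An object of class `annotated_universe`: list with `genes`
#'   (sorted human ids with any annotation), `term_gene_sets` (named list of
#'   sorted human-id vectors, one per term with a non-empty closure set) and
#'   `ontology` (the input DAG, kept for term selection).
#' @export
annotate_closure <- function(onto, annotations, orthology) {
  stopifnot(inherits(onto, "phenotype_ontology"),
            inherits(orthology, "orthology_map"))
  bad <- setdiff(unique(annotations$term_id), onto$terms)
  if (length(bad))
    stop("annotation term(s) not in ontology: ", paste(bad, collapse = ", "))
  h_of_m <- setNames(orthology$human_id, orthology$mouse_id)
  ann <- annotations[annotations$mouse_id %in% names(h_of_m), , drop = FALSE]
  ann$human_id <- unname(h_of_m[ann$mouse_id])

  # direct sets, then accumulate child -> parent in reverse topological order
  direct <- lapply(split(ann$human_id, ann$term_id), unique)
  sets <- setNames(vector("list", length(onto$terms)), onto$terms)
  sets[names(direct)] <- direct
  g <- .ontology_graph(onto)   # edges child -> parent
  ord <- onto$terms[as.integer(igraph::topo_sort(g, mode = "out"))]
  for (t in ord) {
    for (p in onto$parents[[t]])
      sets[[p]] <- c(sets[[p]], sets[[t]])
  }
  sets <- lapply(sets, function(x) sort(unique(x)))
  sets <- sets[lengths(sets) > 0]
  structure(list(genes = sort(unique(ann$human_id)),
                 term_gene_sets = sets, ontology = onto),
            class = "annotated_universe")
}

#' @export
print.annotated_universe <- function(x, ...) {
  cat("annotated_universe: ", length(x$genes), " genes, ",
      length(x$term_gene_sets), " terms with non-empty closure sets\n",
      sep = "")
  invisible(x)
}

#' Select ontology terms to test
#'
#' Returns the descendants of a root term whose closure gene set in the
#' universe has at least `min_genes` members, in deterministic lexicographic
#' order (stable input order for FDR adjustment).
#'
#' @param universe an [annotate_closure()] result.
#' @param root_term term id whose sub-DAG is tested.
#' @param min_genes minimum closure-set size (default 1).
#' @param include_root also consider the root term itself (default FALSE:
#'   only more specific terms are tested).
#' @return character vector of term ids, sorted.
#' @export
select_test_terms <- function(universe, root_term, min_genes = 1,
                              include_root = FALSE) {
  stopifnot(inherits(universe, "annotated_universe"))
  onto <- universe$ontology
  if (!root_term %in% onto$terms) stop("unknown root term: ", root_term)
  cand <- term_descendants(onto, root_term, include_self = include_root)
  sizes <- vapply(cand, function(t) {
    s <- universe$term_gene_sets[[t]]
    if (is.null(s)) 0L else length(s)
  }, integer(1))
  sort(cand[sizes >= min_genes])
}

#' Write / read the annotated universe as TSV
#'
#' Two-column TSV (`term_id`, `gene_id`), one row per closure membership,
#' plus rows with the pseudo-term `_UNIVERSE_` listing every universe gene,
#' so that genes outside all listed terms round-trip too.
#'
#' @param universe an `annotated_universe`.
#' @param path TSV path.
#' @return `write_universe` returns the path invisibly; `read_universe`
#'   returns a list with `genes` and `term_gene_sets` (no ontology).
#' @export
write_universe <- function(universe, path) {
  stopifnot(inherits(universe, "annotated_universe"))
  rows <- data.frame(
    term_id = c(rep("_UNIVERSE_", length(universe$genes)),
                rep(names(universe$term_gene_sets),
                    lengths(universe$term_gene_sets))),
    gene_id = c(universe$genes,
                unlist(universe$term_gene_sets, use.names = FALSE)),
    stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_universe
#' @export
read_universe <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  genes <- sort(unique(df$gene_id[df$term_id == "_UNIVERSE_"]))
  rest <- df[df$term_id != "_UNIVERSE_", , drop = FALSE]
  sets <- lapply(split(rest$gene_id, rest$term_id),
                 function(x) sort(unique(x)))
  list(genes = genes, term_gene_sets = sets)
}
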