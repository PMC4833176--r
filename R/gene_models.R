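#' Construct a set of gene models
#'
#' A gene model is a gene with one or more transcripts, each an ordered set
#' of exons of which some portions are coding (CDS). Coordinates are 0-based
#' half-open. Exons of a transcript must not overlap; CDS intervals must lie
#' within the transcript's exons. Transcripts without CDS rows are
#' non-coding isoforms.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` — one row per exon.
#' @param cds data.frame with the same columns — one row per coding segment
#'   (the coding portion of a coding exon). May have zero rows.
#' @return An object of class `gene_models`: a list with elements
#'   `exons`, `cds`, `transcripts` (per-transcript table with a `coding`
#'   flag) and `genes` (per-gene span table with `n_tx`, `n_coding_tx`).
#' @export
gene_models <- function(exons, cds) {
  req <- c("gene_id", "transcript_id", "chrom", "start", "end")
  stopifnot(all(req %in% names(exons)), all(req %in% names(cds)))
  exons <- as.data.frame(exons)[req]
  cds <- as.data.frame(cds)[req]
  exons$chrom <- .norm_chrom(exons$chrom)
  cds$chrom <- .norm_chrom(cds$chrom)
  for (nm in c("start", "end")) {
    exons[[nm]] <- as.numeric(exons[[nm]])
    cds[[nm]] <- as.numeric(cds[[nm]])
  }
  if (any(exons$start >= exons$end)) stop("empty exon interval")
  if (nrow(cds) && any(cds$start >= cds$end)) stop("empty CDS interval")

  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ]
  rownames(exons) <- NULL
  # exon non-overlap within each transcript
  tx <- exons$transcript_id
  same_tx <- c(FALSE, tx[-1] == tx[-length(tx)])
  if (any(same_tx & exons$start < c(-Inf, exons$end[-nrow(exons)])))
    stop("overlapping exons within a transcript")

  # every CDS interval must lie inside an exon of its transcript
  if (nrow(cds) && anyNA(.cds_exon_match(cds, exons)))
    stop("CDS interval outside its transcript's exons")

  tx_tab <- unique(exons[, c("gene_id", "transcript_id", "chrom")])
  tx_tab$coding <- tx_tab$transcript_id %in% cds$transcript_id
  rownames(tx_tab) <- NULL

  gsplit <- split(seq_len(nrow(exons)), exons$gene_id)
  genes <- data.frame(
    gene_id = names(gsplit),
    chrom = vapply(gsplit, function(i) exons$chrom[i[1]], character(1)),
    start = vapply(gsplit, function(i) min(exons$start[i]), numeric(1)),
    end = vapply(gsplit, function(i) max(exons$end[i]), numeric(1)),
    stringsAsFactors = FALSE)
  nt <- table(tx_tab$gene_id)
  genes$n_tx <- as.integer(nt[genes$gene_id])
  nc <- table(tx_tab$gene_id[tx_tab$coding])
  genes$n_coding_tx <- as.integer(nc[genes$gene_id])
  genes$n_coding_tx[is.na(genes$n_coding_tx)] <- 0L
  rownames(genes) <- NULL

  structure(list(exons = exons, cds = cds, transcripts = tx_tab,
                 genes = genes),
            class = "gene_models")
}

# Index of the containing exon for each CDS row (NA if none). Transcript
# identity is enforced by using the transcript id as the sequence name.
.cds_exon_match <- function(cds, exons) {
  key_e <- paste(exons$transcript_id, exons$chrom)
  key_c <- paste(cds$transcript_id, cds$chrom)
  lev <- unique(c(key_e, key_c))
  q <- GenomicRanges::GRanges(factor(key_c, lev),
                              IRanges::IRanges(cds$start + 1, cds$end))
  s <- GenomicRanges::GRanges(factor(key_e, lev),
                              IRanges::IRanges(exons$start + 1, exons$end))
  hit <- GenomicRanges::findOverlaps(q, s, type = "within", select = "first")
  as.integer(hit)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", nrow(x$genes), " genes, ", nrow(x$transcripts),
      " transcripts (", sum(x$transcripts$coding), " coding), ",
      nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' Gene spans
#'
#' Per-gene span (minimum exon start to maximum exon end across all
#' transcripts), 0-based half-open.
#'
#' @param gm a `gene_models` object.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_spans <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  gm$genes[, c("gene_id", "chrom", "start", "end")]
}

#' Read gene models from disk
#'
#' Two formats are supported: a flattened TSV (one row per exon, columns
#' `gene_id`, `transcript_id`, `chrom`, `exon_start`, `exon_end`,
#' `cds_start`, `cds_end`, the CDS columns empty/NA for non-coding exons)
#' and GFF3 with `gene`/`mRNA` (or `transcript`)/`exon`/`CDS` features
#' linked by `ID`/`Parent` attributes (parsed with rtracklayer).
#'
#' @param path input file.
#' @param format `"tsv"` or `"gff3"`.
#' @param coords coordinate dialect for `format = "tsv"`: `"bed"` (0-based
#'   half-open, the default) or `"one_based"` (1-based inclusive). GFF3 is
#'   1-based inclusive by definition.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("tsv", "gff3"),
                             coords = c("bed", "one_based")) {
  format <- match.arg(format)
  coords <- match.arg(coords)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    req <- c("gene_id", "transcript_id", "chrom", "exon_start", "exon_end")
    if (!all(req %in% names(df)))
      stop("gene model TSV lacks required column(s): ",
           paste(setdiff(req, names(df)), collapse = ", "))
    off <- if (coords == "one_based") 1 else 0
    exons <- data.frame(gene_id = df$gene_id,
                        transcript_id = df$transcript_id,
                        chrom = df$chrom,
                        start = as.numeric(df$exon_start) - off,
                        end = as.numeric(df$exon_end),
                        stringsAsFactors = FALSE)
    has_cds <- !is.na(df$cds_start) & !is.na(df$cds_end)
    cds <- data.frame(gene_id = df$gene_id[has_cds],
                      transcript_id = df$transcript_id[has_cds],
                      chrom = df$chrom[has_cds],
                      start = as.numeric(df$cds_start[has_cds]) - off,
                      end = as.numeric(df$cds_end[has_cds]),
                      stringsAsFactors = FALSE)
    return(gene_models(exons, cds))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  id <- as.character(meta$ID)
  parent <- vapply(as.list(meta$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  tx_rows <- type %in% c("mRNA", "transcript")
  tx2gene <- setNames(parent[tx_rows], id[tx_rows])
  take <- function(which_type) {
    i <- which(type == which_type)
    data.frame(gene_id = unname(tx2gene[parent[i]]),
               transcript_id = parent[i],
               chrom = as.character(GenomicRanges::seqnames(gr)[i]),
               start = GenomicRanges::start(gr)[i] - 1,  # to 0-based
               end = GenomicRanges::end(gr)[i],
               stringsAsFactors = FALSE)
  }
  gene_models(take("exon"), take("CDS"))
}

#' Write gene models to disk
#'
#' @param gm a `gene_models` object.
#' @param path output file.
#' @param format `"tsv"` (flattened exon table, 0-based half-open, CDS
#'   columns NA where the exon has no coding overlap) or `"gff3"`.
#' @export
write_gene_models <- function(gm, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  stopifnot(inherits(gm, "gene_models"))
  if (format == "tsv") {
    ex <- gm$exons
    out <- data.frame(gene_id = ex$gene_id, transcript_id = ex$transcript_id,
                      chrom = ex$chrom, exon_start = ex$start,
                      exon_end = ex$end, cds_start = NA_real_,
                      cds_end = NA_real_, stringsAsFactors = FALSE)
    if (nrow(gm$cds)) {
      j <- .cds_exon_match(gm$cds, ex)
      out$cds_start[j] <- gm$cds$start
      out$cds_end[j] <- gm$cds$end
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  # GFF3: 1-based inclusive on disk
  fmt <- function(chrom, type, start, end, attrs)
    paste(chrom, "cnvphen", type, start + 1, end, ".", ".", ".", attrs,
          sep = "\t")
  lines <- "##gff-version 3"
  g <- gm$genes
  lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end,
                        paste0("ID=", g$gene_id)))
  tx <- gm$transcripts
  tx_span <- do.call(rbind, lapply(split(gm$exons, gm$exons$transcript_id),
    function(e) data.frame(transcript_id = e$transcript_id[1],
                           chrom = e$chrom[1], start = min(e$start),
                           end = max(e$end))))
  tx_span <- tx_span[match(tx$transcript_id, tx_span$transcript_id), ]
  gene_of <- setNames(tx$gene_id, tx$transcript_id)
  lines <- c(lines, fmt(tx_span$chrom, "mRNA", tx_span$start, tx_span$end,
                        paste0("ID=", tx$transcript_id, ";Parent=",
                               tx$gene_id)))
  ex <- gm$exons
  lines <- c(lines, fmt(ex$chrom, "exon", ex$start, ex$end,
                        paste0("ID=exon-", seq_len(nrow(ex)), ";Parent=",
                               ex$transcript_id)))
  cd <- gm$cds
  if (nrow(cd))
    lines <- c(lines, fmt(cd$chrom, "CDS", cd$start, cd$end,
                          paste0("ID=cds-", seq_len(nrow(cd)), ";Parent=",
                                 cd$transcript_id)))
  writeLines(lines, path)
  invisible(path)
}
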