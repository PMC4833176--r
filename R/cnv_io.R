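#' Construct a CNV call table
#'
#' Builds the canonical CNV table used throughout the package. Coordinates
#' are 0-based half-open (`[start, end)`); use [read_cnvs()] to convert from
#' on-disk dialects. Chromosome labels are normalised by stripping a leading
#' `"chr"`.
#'
#' @param subject subject identifiers (character).
#' @param chrom chromosome labels.
#' @param start,end 0-based half-open interval bounds; `start < end`.
#' @param dosage `"gain"` or `"loss"` per call.
#' @param cohort cohort label(s), recycled.
#' @param origin `"de_novo"`, `"inherited"` or `"unknown"`, recycled.
#' @return A `data.frame` of class `cnv_table` with columns `subject`,
#'   `cohort`, `chrom`, `start`, `end`, `dosage`, `origin` and a derived
#'   `length` column (`end - start`).
#' @export
cnv_table <- function(subject, chrom, start, end, dosage,
                      cohort = "cohort", origin = "unknown") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  dosage <- as.character(dosage)
  if (!all(dosage %in% c("gain", "loss")))
    stop("dosage must be 'gain' or 'loss'")
  origin <- rep_len(as.character(origin), length(start))
  if (!all(origin %in% c("de_novo", "inherited", "unknown")))
    stop("origin must be 'de_novo', 'inherited' or 'unknown'")
  if (any(start >= end))
    stop("all CNV intervals require start < end (0-based half-open)")
  chrom <- .norm_chrom(chrom)
  if (any(!nzchar(chrom))) stop("empty chromosome label")
  out <- data.frame(subject = as.character(subject),
                    cohort = rep_len(as.character(cohort), length(start)),
                    chrom = chrom, start = start, end = end,
                    dosage = dosage, origin = origin,
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  class(out) <- c("cnv_table", "data.frame")
  out
}

#' Read a CNV call table from disk
#'
#' Reads a TSV with header columns `subject`, `chrom`, `start`, `end`,
#' `dosage` (optionally `cohort`, `origin`) and converts coordinates to the
#' internal 0-based half-open convention.
#'
#' @param path path to a tab-separated file with a header row.
#' @param coords coordinate dialect of the file: `"one_based"` (1-based
#'   inclusive; `start` is decremented on load) or `"bed"` (already 0-based
#'   half-open).
#' @param dosage_map named character vector mapping the file's dosage labels
#'   onto `"gain"`/`"loss"`, e.g. `c(dup = "gain", del = "loss")`. Labels
#'   already equal to `"gain"`/`"loss"` pass through.
#' @return A `cnv_table` (see [cnv_table()]). Rows whose interval is empty
#'   after conversion, or whose dosage label is unmapped, are dropped with a
#'   warning naming the offending line numbers.
#' @export
read_cnvs <- function(path, coords = c("one_based", "bed"),
                      dosage_map = c(gain = "gain", loss = "loss",
                                     dup = "gain", del = "loss")) {
  coords <- match.arg(coords)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("subject", "chrom", "start", "end", "dosage")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("CNV file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"cohort" %in% names(df)) df$cohort <- "cohort"
  if (!"origin" %in% names(df)) df$origin <- "unknown"

  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  if (coords == "one_based") start <- start - 1
  dosage <- unname(dosage_map[df$dosage])

  # line numbers reported relative to the file (header = line 1)
  bad <- is.na(start) | is.na(end) | start >= end | is.na(dosage)
  if (any(bad)) {
    warning("dropped ", sum(bad), " malformed CNV row(s) at file line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
  }
  keep <- !bad
  cnv_table(subject = df$subject[keep], chrom = df$chrom[keep],
            start = start[keep], end = end[keep], dosage = dosage[keep],
            cohort = df$cohort[keep], origin = df$origin[keep])
}

#' Write a CNV table to disk
#'
#' Inverse of [read_cnvs()]; the same `coords` dialect choices apply.
#'
#' @param cnvs a `cnv_table`.
#' @param path output path.
#' @param coords coordinate dialect to emit.
#' @export
write_cnvs <- function(cnvs, path, coords = c("one_based", "bed")) {
  coords <- match.arg(coords)
  out <- as.data.frame(cnvs)[, c("subject", "cohort", "chrom", "start",
                                 "end", "dosage", "origin")]
  if (coords == "one_based") out$start <- out$start + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Keep only CNVs longer than a minimum length
#'
#' Applies the large-CNV restriction with a strict inequality: a CNV of
#' exactly `min_length_bp` is excluded. The canonical analysis threshold is
#' 500 kb.
#'
#' @param cnvs a `cnv_table`.
#' @param min_length_bp minimum length in bp (exclusive bound); default 5e5.
#' @return The subset of `cnvs` with `end - start > min_length_bp`.
#' @export
filter_large_cnvs <- function(cnvs, min_length_bp = 5e5) {
  stopifnot(min_length_bp > 0)
  cnvs[(cnvs$end - cnvs$start) > min_length_bp, , drop = FALSE]
}
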