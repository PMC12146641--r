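#' Construct a table of genomic intervals
#'
#' Intervals are the unit of peaks, CREs, genome bins and TF peaks throughout
#' the package. Coordinates are uniformly 0-based half-open (BED convention):
#' an interval covers bases \code{start, ..., end - 1}.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start; must be >= 0.
#' @param end integer vector, exclusive end; must satisfy \code{end > start}.
#' @param strand optional character vector in \code{c("+", "-", ".")}.
#'   Peaks and CREs may be unstranded (\code{"."}); genes may not.
#' @param ... further equal-length vectors kept as annotation columns.
#' @return a \code{data.frame} with class \code{c("gintervals", "data.frame")}.
#' @export
gintervals <- function(chrom, start, end, strand = NULL, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_gintervals(df)
  class(df) <- c("gintervals", "data.frame")
  df
}

#' Validate interval invariants
#'
#' Checks \code{end > start}, \code{start >= 0}, non-empty chromosome names,
#' and (if present) strand values.
#'
#' @param df a data.frame with columns chrom, start, end.
#' @param where label used in error messages.
#' @return the input, invisibly.
#' @export
validate_gintervals <- function(df, where = "intervals") {
  stopifnot(is.data.frame(df))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(where, ": missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
      stop(where, ": empty chromosome name")
    if (any(df$start < 0)) stop(where, ": negative start coordinate")
    bad <- which(df$end <= df$start)
    if (length(bad))
      stop(where, ": end <= start at row ", bad[1],
           " (", df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]], ")")
    if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
      stop(where, ": strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' Convert an interval table to a GRanges object
#'
#' Internal 0-based half-open coordinates are translated to the 1-based
#' closed convention GRanges uses. Strand is dropped ("*") because every
#' overlap operation in this package is strand-blind.
#'
#' @param df interval table (chrom, start, end).
#' @return a \code{GenomicRanges::GRanges}.
#' @export
gi_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Half-open overlap test matrix between two interval sets
#'
#' @param a,b interval tables.
#' @return integer matrix of overlap pair indices (columns: a index, b index),
#'   as from \code{GenomicRanges::findOverlaps}.
#' @export
gi_overlap_pairs <- function(a, b) {
  # disjoint chromosome sets are a legitimate "no overlap" case, not a
  # user error worth a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gi_to_granges(a), gi_to_granges(b)))
  cbind(a = S4Vectors::queryHits(hits), b = S4Vectors::subjectHits(hits))
}

#' Standard "chrom:start-end" names for intervals
#' @param df interval table.
#' @return character vector of names.
#' @export
gi_names <- function(df) {
  if (nrow(df) == 0) return(character(0))
  paste0(df$chrom, ":", df$start, "-", df$end)
}
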