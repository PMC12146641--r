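# Readers and writers for the plain-text formats the toolkit exchanges:
# BED, fragments TSV, MatrixMarket triplets + id lists, gene annotation
# (GTF or minimal TSV), linkage tables, chrom.sizes, bedGraph.

#' Read a BED file of genomic intervals
#'
#' BED is 0-based half-open, matching the package-internal convention, so
#' coordinates are taken verbatim. Columns beyond the third are preserved as
#' annotation columns (column 4 as \code{name}, 5 as \code{score}, 6 as
#' \code{strand}, further columns as \code{V7}, ...).
#'
#' @param path path to a BED file (plain text; lines starting with '#',
#'   'track' or 'browser' are skipped).
#' @return a \code{gintervals} table in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("read_bed: no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(gintervals(character(), integer(), integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3))
    stop("read_bed: line ", lineno[which(ncol < 3)[1]], ": fewer than 3 columns")
  nmax <- max(ncol)
  fields <- lapply(seq_len(nmax), function(i)
    vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, ""))
  start <- suppressWarnings(as.integer(fields[[2]]))
  end <- suppressWarnings(as.integer(fields[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("read_bed: line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop("read_bed: line ", lineno[bad[1]], ": invalid interval (end <= start or start < 0)")
  df <- data.frame(chrom = fields[[1]], start = start, end = end,
                   stringsAsFactors = FALSE)
  extras <- c("name", "score", "strand")
  if (nmax >= 4) for (i in 4:nmax) {
    nm <- if (i - 3 <= length(extras)) extras[i - 3] else paste0("V", i)
    df[[nm]] <- fields[[i]]
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."), na.rm = TRUE)) {
    # non-BED sixth column; keep it but rename so strand invariants stay valid
    names(df)[names(df) == "strand"] <- "V6"
  }
  validate_gintervals(df, "read_bed")
  class(df) <- c("gintervals", "data.frame")
  df
}

#' Write intervals as BED
#'
#' @param df interval table; annotation columns \code{name}, \code{score},
#'   \code{strand} are written as BED columns 4-6 when present.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, df$start, df$end)
  for (nm in c("name", "score", "strand"))
    if (nm %in% names(df)) cols <- c(cols, list(df[[nm]])) else break
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read an ATAC fragments file
#'
#' Expects the 10x-style 5-column TSV: chrom, start, end, cell barcode,
#' duplicate count. Plain or gzip/bgzip-compressed input is accepted; '#'
#' comment lines are skipped. Fragments need not be sorted.
#'
#' @param path path to the fragments file.
#' @return data.frame with columns chrom, start, end, barcode, count,
#'   in file order.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("read_fragments: no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      barcode = character(), count = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5))
    stop("read_fragments: line ", lineno[which(lengths(parts) < 5)[1]],
         ": fewer than 5 columns")
  m <- matrix(unlist(lapply(parts, `[`, 1:5)), ncol = 5, byrow = TRUE)
  df <- data.frame(chrom = m[, 1],
                   start = suppressWarnings(as.integer(m[, 2])),
                   end = suppressWarnings(as.integer(m[, 3])),
                   barcode = m[, 4],
                   count = suppressWarnings(as.integer(m[, 5])),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$count))
  if (length(bad))
    stop("read_fragments: line ", lineno[bad[1]], ": non-integer field")
  bad <- which(df$count < 1L)
  if (length(bad))
    stop("read_fragments: line ", lineno[bad[1]], ": count < 1")
  bad <- which(df$end <= df$start | df$start < 0L)
  if (length(bad))
    stop("read_fragments: line ", lineno[bad[1]], ": invalid interval")
  if (any(!nzchar(df$barcode)))
    stop("read_fragments: empty barcode")
  df
}

#' Write a fragments file
#' @param frags data.frame chrom/start/end/barcode/count.
#' @param path output path ('.gz' suffix writes gzip).
#' @export
write_fragments <- function(frags, path) {
  out <- paste(frags$chrom, frags$start, frags$end, frags$barcode, frags$count,
               sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(out, con)
  close(con)
  invisible(path)
}

#' Read a MatrixMarket triplet matrix with feature and barcode id files
#'
#' @param mtx path to the MatrixMarket coordinate file.
#' @param features path to a one-id-per-line feature list (rows).
#' @param barcodes path to a one-id-per-line barcode list (columns).
#' @return a \code{count_matrix} with layer \code{"raw"}.
#' @export
read_counts_mtx <- function(mtx, features, barcodes) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feat <- readLines(features)
  bc <- readLines(barcodes)
  # id files may be multi-column TSVs (10x style); the first field is the id
  feat <- vapply(strsplit(feat, "\t", fixed = TRUE), `[`, "", 1L)
  bc <- vapply(strsplit(bc, "\t", fixed = TRUE), `[`, "", 1L)
  if (nrow(m) != length(feat) || ncol(m) != length(bc))
    stop("read_counts_mtx: matrix is ", nrow(m), "x", ncol(m),
         " but id files have ", length(feat), " features and ",
         length(bc), " barcodes")
  if (anyDuplicated(feat)) stop("read_counts_mtx: duplicate feature ids")
  if (anyDuplicated(bc)) stop("read_counts_mtx: duplicate barcodes")
  dimnames(m) <- list(feat, bc)
  count_matrix(m, layer = "raw")
}

#' Write a count matrix as MatrixMarket triplets plus id files
#' @param cm a \code{count_matrix}.
#' @param mtx,features,barcodes output paths.
#' @export
write_counts_mtx <- function(cm, mtx, features, barcodes) {
  Matrix::writeMM(methods::as(methods::as(cm$values, "dMatrix"),
                              "CsparseMatrix"), mtx)
  writeLines(rownames(cm$values), features)
  writeLines(colnames(cm$values), barcodes)
  invisible(mtx)
}

#' Read gene models from GTF or a minimal TSV
#'
#' The TSV dialect has header \code{gene,chrom,start,end,strand} with 0-based
#' half-open coordinates. The GTF dialect is 1-based inclusive and converted
#' at this boundary (start - 1); only lines with feature type \code{gene} are
#' used, and the gene id is taken from the \code{gene_id} attribute. The TSS
#' is \code{start} for + genes and \code{end - 1} for - genes (0-based).
#'
#' @param path input path.
#' @param dialect \code{"gtf"} or \code{"tsv"}.
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss.
#' @export
read_gene_models <- function(path, dialect = c("tsv", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    req <- c("gene", "chrom", "start", "end", "strand")
    if (!all(req %in% names(df)))
      stop("read_gene_models: TSV must have columns ", paste(req, collapse = ","))
    out <- data.frame(gene_id = as.character(df$gene), chrom = df$chrom,
                      start = as.integer(df$start), end = as.integer(df$end),
                      strand = df$strand, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    parts <- parts[vapply(parts, function(p) length(p) >= 9 && p[3] == "gene",
                          logical(1))]
    if (!length(parts)) stop("read_gene_models: no 'gene' features in GTF")
    gid <- vapply(parts, function(p) {
      m <- regmatches(p[9], regexec('gene_id[ =]+"?([^";]+)"?', p[9]))[[1]]
      if (length(m) < 2) stop("read_gene_models: missing gene_id attribute")
      m[2]
    }, "")
    out <- data.frame(
      gene_id = gid,
      chrom = vapply(parts, `[`, "", 1L),
      start = as.integer(vapply(parts, `[`, "", 4L)) - 1L,  # GTF is 1-based
      end = as.integer(vapply(parts, `[`, "", 5L)),
      strand = vapply(parts, `[`, "", 7L),
      stringsAsFactors = FALSE)
  }
  if (!all(out$strand %in% c("+", "-")))
    stop("read_gene_models: gene strand must be '+' or '-' (TSS undefined otherwise)")
  validate_gintervals(out, "read_gene_models")
  out$tss <- ifelse(out$strand == "+", out$start, out$end - 1L)
  out
}

#' Write gene models in the minimal TSV dialect (0-based half-open)
#' @param genes gene model table.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(gene = genes$gene_id, chrom = genes$chrom,
                   start = genes$start, end = genes$end, strand = genes$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

linkage_cols <- c("gene_id", "chrom", "start", "end", "score", "zscore",
                  "pvalue", "sample_id")

#' Validate a table of CRE-gene linkage records
#' @param df linkage table.
#' @return input, invisibly.
#' @export
validate_linkages <- function(df) {
  miss <- setdiff(linkage_cols, names(df))
  if (length(miss))
    stop("linkage table: missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(abs(df$score) > 1 + 1e-9)) stop("linkage table: |score| > 1")
    if (any(df$pvalue < 0 | df$pvalue > 1)) stop("linkage table: pvalue outside [0,1]")
    validate_gintervals(df, "linkage table")
  }
  invisible(df)
}

#' Write a per-sample linkage table as TSV
#'
#' Schema: gene_id, chrom, start, end, score, zscore, pvalue, sample_id.
#' Numeric columns are written at 6 significant digits.
#'
#' @param records linkage table.
#' @param path output path.
#' @export
write_linkage_table <- function(records, path) {
  validate_linkages(records)
  df <- records[, linkage_cols]
  for (col in c("score", "zscore", "pvalue"))
    df[[col]] <- signif(df[[col]], 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a linkage table written by \code{write_linkage_table}
#' @param path input path.
#' @return validated linkage data.frame.
#' @export
read_linkage_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in intersect(c("gene_id", "chrom", "sample_id"), names(df)))
    df[[col]] <- as.character(df[[col]])
  validate_linkages(df)
  df
}

#' Read a UCSC chrom.sizes file (two columns: chrom, length)
#' @param path input path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}

#' Write a per-group coverage track as bedGraph
#' @param df data.frame chrom, start, end, value.
#' @param path output path.
#' @export
write_bedgraph <- function(df, path) {
  out <- paste(df$chrom, df$start, df$end, signif(df$value, 6), sep = "\t")
  writeLines(out, path)
  invisible(path)
}
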