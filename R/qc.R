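# Per-cell QC metrics (nucleosome signal, TSS enrichment, modality read
# counts) and the six-criteria cell filter.

#' Default QC thresholds for the six-criteria cell filter
#'
#' All comparisons are strict: a cell is retained iff
#' rna_reads > rna_min, rna_reads < rna_max, atac_reads > atac_min,
#' atac_reads < atac_max, nucleosome_signal < nuc_max (and defined),
#' tss_enrichment > tss_min.
#'
#' @param rna_min,rna_max RNA read-count bounds (default 1000 / 25000).
#' @param atac_min,atac_max ATAC read-count bounds (default 1000 / 100000).
#' @param nuc_max maximum nucleosome signal (default 2).
#' @param tss_min minimum TSS enrichment score (default 1).
#' @return a named list of thresholds.
#' @export
qc_thresholds <- function(rna_min = 1000, rna_max = 25000,
                          atac_min = 1000, atac_max = 100000,
                          nuc_max = 2, tss_min = 1) {
  if (rna_min >= rna_max) stop("qc_thresholds: rna_min must be < rna_max")
  if (atac_min >= atac_max) stop("qc_thresholds: atac_min must be < atac_max")
  list(rna_min = rna_min, rna_max = rna_max, atac_min = atac_min,
       atac_max = atac_max, nuc_max = nuc_max, tss_min = tss_min)
}

#' Nucleosome signal of one cell
#'
#' Ratio of count-weighted mononucleosome-length fragments (147-294 bp,
#' inclusive) to nucleosome-free fragments (< 147 bp). Undefined (NA) when
#' the cell has no sub-147 bp fragments; cells with undefined signal fail
#' the QC filter.
#'
#' @param fragments_of_cell data.frame of the cell's fragments
#'   (start, end, count).
#' @return a single numeric, or NA_real_ when undefined.
#' @export
nucleosome_signal <- function(fragments_of_cell) {
  len <- fragments_of_cell$end - fragments_of_cell$start
  w <- fragments_of_cell$count
  free <- sum(w[len < 147])
  mono <- sum(w[len >= 147 & len <= 294])
  if (free == 0) return(NA_real_)
  mono / free
}

#' TSS enrichment score of one cell
#'
#' Per-base fragment coverage is aggregated over windows of +/- `window` bp
#' centered on every TSS. The score is the mean coverage in the central
#' 100 bp bin divided by the mean coverage in the two outermost `flank` bp
#' flanks. When the flanks have zero coverage the score is 1.0 if the
#' center is also zero, otherwise the configurable ceiling `cap`.
#'
#' @param fragments_of_cell data.frame of the cell's fragments.
#' @param gene_models gene model table with a \code{tss} column.
#' @param window half-window around each TSS in bp (default 1000).
#' @param flank width of each outer flank in bp (default 100).
#' @param center_width width of the central bin in bp (default 100).
#' @param cap ceiling applied when flanks are zero but center is not
#'   (default 20).
#' @return a single numeric score.
#' @export
tss_enrichment <- function(fragments_of_cell, gene_models, window = 1000,
                           flank = 100, center_width = 100, cap = 20) {
  if (nrow(gene_models) == 0) stop("tss_enrichment: no gene models")
  L <- 2L * window + 1L
  cov <- numeric(L)
  frag <- fragments_of_cell
  if (nrow(frag)) {
    tssw <- gintervals(gene_models$chrom,
                       pmax(0L, gene_models$tss - window),
                       gene_models$tss + window + 1L)
    hits <- gi_overlap_pairs(frag, tssw)
    if (nrow(hits)) {
      # relative coordinates within the [-window, window] profile
      t0 <- gene_models$tss[hits[, "b"]] - window
      s <- pmax(frag$start[hits[, "a"]] - t0, 0L) + 1L
      e <- pmin(frag$end[hits[, "a"]] - t0, L)
      w <- frag$count[hits[, "a"]]
      # difference-array accumulation, vectorized over hits
      d <- numeric(L + 1L)
      inc <- rowsum(as.numeric(w), s)
      d[as.integer(rownames(inc))] <- d[as.integer(rownames(inc))] + inc[, 1]
      dec <- rowsum(as.numeric(w), e + 1L)
      d[as.integer(rownames(dec))] <- d[as.integer(rownames(dec))] - dec[, 1]
      cov <- cumsum(d[seq_len(L)])
    }
  }
  half <- center_width %/% 2L
  center <- mean(cov[(window + 1L - half):(window + center_width - half)])
  flanks <- mean(c(cov[seq_len(flank)], cov[(L - flank + 1L):L]))
  if (flanks == 0) {
    if (center == 0) return(1.0)
    return(cap)
  }
  min(center / flanks, cap)
}

#' Per-cell QC metrics for a sample
#'
#' One record per barcode in the RNA matrix. \code{rna_reads} is the RNA
#' matrix column sum; \code{atac_reads} the summed duplicate count of the
#' barcode's fragments (0 when absent from the fragments file).
#'
#' @param rna raw-layer RNA \code{count_matrix}.
#' @param fragments fragments data.frame for the sample.
#' @param gene_models gene model table (for TSS enrichment).
#' @param window TSS enrichment half-window in bp (default 1000).
#' @param ... passed to \code{tss_enrichment}.
#' @return data.frame: barcode, rna_reads, atac_reads, nucleosome_signal,
#'   tss_enrichment.
#' @export
compute_cell_qc <- function(rna, fragments, gene_models, window = 1000, ...) {
  stopifnot(inherits(rna, "count_matrix"))
  barcodes <- colnames(rna$values)
  if (!length(intersect(barcodes, unique(fragments$barcode))))
    stop("compute_cell_qc: RNA matrix and fragments share no barcode")
  rna_reads <- Matrix::colSums(rna$values)

  frag <- fragments[fragments$barcode %in% barcodes, , drop = FALSE]
  atac_reads <- stats::setNames(numeric(length(barcodes)), barcodes)
  if (nrow(frag)) {
    s <- rowsum(as.numeric(frag$count), frag$barcode)
    atac_reads[rownames(s)] <- s[, 1]
  }

  len <- frag$end - frag$start
  ns <- stats::setNames(rep(NA_real_, length(barcodes)), barcodes)
  if (nrow(frag)) {
    free <- rowsum(as.numeric(frag$count) * (len < 147), frag$barcode)
    mono <- rowsum(as.numeric(frag$count) * (len >= 147 & len <= 294), frag$barcode)
    ok <- free[, 1] > 0
    ns[rownames(free)[ok]] <- mono[ok, 1] / free[ok, 1]
    ns[rownames(free)[!ok]] <- NA_real_
  }

  # restrict to fragments near any TSS before the per-cell profile loop
  tssw <- gintervals(gene_models$chrom,
                     pmax(0L, gene_models$tss - as.integer(window)),
                     gene_models$tss + as.integer(window) + 1L)
  near <- unique(gi_overlap_pairs(frag, tssw)[, "a"])
  fnear <- frag[near, , drop = FALSE]
  by_bc <- split(seq_len(nrow(fnear)), fnear$barcode)
  tss <- stats::setNames(numeric(length(barcodes)), barcodes)
  for (bc in barcodes) {
    idx <- by_bc[[bc]]
    cell_frags <- if (is.null(idx))
      fnear[integer(0), , drop = FALSE] else fnear[idx, , drop = FALSE]
    tss[bc] <- tss_enrichment(cell_frags, gene_models, window = window, ...)
  }

  data.frame(barcode = barcodes,
             rna_reads = as.numeric(rna_reads),
             atac_reads = as.numeric(atac_reads),
             nucleosome_signal = as.numeric(ns),
             tss_enrichment = as.numeric(tss),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the six-criteria cell filter
#'
#' All six inequalities are strict; a cell with undefined (NA) nucleosome
#' signal is removed.
#'
#' @param metrics data.frame from \code{compute_cell_qc}.
#' @param thresholds list from \code{qc_thresholds}.
#' @return character vector of retained barcodes, in input order.
#' @export
apply_cell_filters <- function(metrics, thresholds = qc_thresholds()) {
  t <- thresholds
  keep <- metrics$rna_reads > t$rna_min &
    metrics$rna_reads < t$rna_max &
    metrics$atac_reads > t$atac_min &
    metrics$atac_reads < t$atac_max &
    !is.na(metrics$nucleosome_signal) &
    metrics$nucleosome_signal < t$nuc_max &
    metrics$tss_enrichment > t$tss_min
  metrics$barcode[keep]
}
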