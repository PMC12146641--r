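# CRE-gene linkage: candidate windowing around the TSS, observed
# expression-accessibility Pearson correlation, a matched-background null
# (peaks matched on GC content, total accessibility and width), and a
# z-score / upper-tail p-value per candidate pair.

#' Linkage configuration
#'
#' @param window_bp candidate window half-width around the TSS (default
#'   50000 bp).
#' @param n_background number of matched background peaks (default 200).
#' @param min_cells minimum number of cells in which a gene or peak must be
#'   detected (count > 0) to be tested (default 10).
#' @param pvalue_cutoff retain links with p below this (default 0.05).
#' @param score_cutoff retain links with |r| above this (default 0.05).
#' @param two_sided use a two-sided p-value instead of the default
#'   upper-tail test (default FALSE; with the one-sided test negative links
#'   are never significant).
#' @param seed integer seed for reproducibility.
#' @return named list of settings.
#' @export
linkage_config <- function(window_bp = 50000, n_background = 200,
                           min_cells = 10, pvalue_cutoff = 0.05,
                           score_cutoff = 0.05, two_sided = FALSE,
                           seed = 1L) {
  stopifnot(window_bp > 0, n_background > 0, min_cells > 0,
            pvalue_cutoff > 0, pvalue_cutoff < 1, score_cutoff > 0)
  list(window_bp = window_bp, n_background = n_background,
       min_cells = min_cells, pvalue_cutoff = pvalue_cutoff,
       score_cutoff = score_cutoff, two_sided = two_sided, seed = seed)
}

#' Candidate peaks within the TSS window of a gene
#'
#' A peak is a candidate iff its full interval intersects
#' [tss - window, tss + window + 1) on the gene's chromosome (half-open
#' intersection; the window covers bases tss - window .. tss + window).
#'
#' @param gene one row of a gene model table (gene_id, chrom, tss).
#' @param peaks interval table of peaks.
#' @param window_bp half-window (default 50000).
#' @return integer vector of peak row indices (possibly empty).
#' @export
candidate_peaks <- function(gene, peaks, window_bp = 50000) {
  lo <- gene$tss - window_bp
  hi <- gene$tss + window_bp + 1L  # exclusive
  which(peaks$chrom == gene$chrom & peaks$start < hi & peaks$end > lo)
}

#' Pearson correlation between expression and accessibility
#'
#' @param expr numeric vector of log-normalized expression over cells.
#' @param acc numeric vector of log-normalized accessibility over the same
#'   cells.
#' @return Pearson r, or NA_real_ when either vector is constant (the pair
#'   is then skipped by \code{link_peaks}).
#' @export
pearson_link_score <- function(expr, acc) {
  if (length(expr) != length(acc)) stop("pearson_link_score: length mismatch")
  if (length(expr) < 3) stop("pearson_link_score: need at least 3 cells")
  if (stats::sd(expr) == 0 || stats::sd(acc) == 0) return(NA_real_)
  stats::cor(expr, acc)
}

#' Per-peak features used for background matching
#'
#' @param peaks interval table.
#' @param acc raw-layer accessibility \code{count_matrix} whose rows align
#'   with \code{peaks}.
#' @param gc optional numeric vector of per-peak GC fractions in [0,1].
#' @return data.frame: gc (may be all NA), log1p_total, log_width.
#' @export
peak_features <- function(peaks, acc, gc = NULL) {
  tot <- Matrix::rowSums(acc$values)
  if (!is.null(gc) && (any(gc < 0) || any(gc > 1)))
    stop("peak_features: gc fractions must be in [0,1]")
  data.frame(gc = if (is.null(gc)) NA_real_ else gc,
             log1p_total = log1p(tot),
             log_width = log(peaks$end - peaks$start))
}

#' Select background peaks matched on peak features
#'
#' Features (GC fraction when available, log1p total accessibility, log
#' width) are standardized over the pool; the n pool peaks nearest the
#' target in Euclidean feature distance are returned (distance ties broken
#' by pool order). If the pool is smaller than n the whole pool is returned
#' with a warning.
#'
#' @param target single-row data.frame of the target peak's features.
#' @param pool data.frame of candidate background peak features (must
#'   exclude the target and the current gene's candidate peaks).
#' @param n number of background peaks (default 200).
#' @return integer vector of pool row indices.
#' @export
matched_background <- function(target, pool, n = 200) {
  if (nrow(pool) == 0) stop("matched_background: empty background pool")
  use_gc <- !all(is.na(pool$gc)) && !is.na(target$gc[1])
  cols <- c(if (use_gc) "gc", "log1p_total", "log_width")
  pm <- as.matrix(pool[, cols, drop = FALSE])
  mu <- colMeans(pm)
  sdv <- apply(pm, 2, stats::sd)
  sdv[sdv == 0] <- 1
  pm <- sweep(sweep(pm, 2, mu), 2, sdv, "/")
  tv <- (as.numeric(target[1, cols]) - mu) / sdv
  d2 <- colSums((t(pm) - tv)^2)
  if (nrow(pool) < n) {
    warning("matched_background: pool (", nrow(pool),
            ") smaller than requested n (", n, "); using all")
    return(order(d2))
  }
  order(d2)[seq_len(n)]
}

#' z-test of an observed correlation against matched-background correlations
#'
#' z = (r_obs - mean(bg)) / sd(bg) with the unbiased sd; p is the standard
#' normal upper tail 1 - Phi(z) (or the two-sided 2 * (1 - Phi(|z|))).
#'
#' @param r_obs observed Pearson r.
#' @param r_background numeric vector of background correlations (length
#'   >= 2, sd > 0).
#' @param two_sided two-sided alternative (default FALSE).
#' @return list(zscore, pvalue); both NA when the background sd is 0 (the
#'   pair is then skipped).
#' @export
linkage_ztest <- function(r_obs, r_background, two_sided = FALSE) {
  r_background <- r_background[!is.na(r_background)]
  if (length(r_background) < 2)
    stop("linkage_ztest: need at least 2 background correlations")
  s <- stats::sd(r_background)
  if (s == 0) return(list(zscore = NA_real_, pvalue = NA_real_))
  z <- (r_obs - mean(r_background)) / s
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
  list(zscore = z, pvalue = p)
}

#' Compute CRE-gene linkages for a sample
#'
#' For every gene: find candidate peaks within the TSS window; drop genes
#' and peaks detected in fewer than \code{min_cells} cells; for each
#' candidate compute the observed Pearson correlation between log-normalized
#' expression and log-normalized peak accessibility, a matched background of
#' \code{n_background} peaks (excluding the target and the gene's
#' candidates), and the background z-test. Records with
#' p < \code{pvalue_cutoff} and |r| > \code{score_cutoff} are retained.
#'
#' @param rna_lognorm lognorm-layer RNA \code{count_matrix} over QC-passed
#'   cells.
#' @param atac_raw raw-layer peak accessibility \code{count_matrix} over the
#'   same cells (row i = peaks row i).
#' @param genes gene model table.
#' @param peaks interval table aligned with \code{atac_raw} rows.
#' @param config list from \code{linkage_config}.
#' @param sample_id sample identifier stamped on each record.
#' @param gc optional per-peak GC fractions for background matching.
#' @return linkage data.frame (gene_id, chrom, start, end, score, zscore,
#'   pvalue, sample_id), ordered by gene then genomic position.
#' @export
link_peaks <- function(rna_lognorm, atac_raw, genes, peaks, config = linkage_config(),
                       sample_id = "sample", gc = NULL) {
  stopifnot(inherits(rna_lognorm, "count_matrix"), rna_lognorm$layer == "lognorm",
            inherits(atac_raw, "count_matrix"), atac_raw$layer == "raw",
            nrow(peaks) == nrow(atac_raw$values))
  cells <- colnames(rna_lognorm$values)
  if (!identical(cells, colnames(atac_raw$values)))
    stop("link_peaks: RNA and ATAC matrices must share cell order")
  set.seed(config$seed)

  acc_ln <- lognormalize(atac_raw)$values
  feats <- peak_features(peaks, atac_raw, gc = gc)
  peak_ncells <- Matrix::rowSums(atac_raw$values > 0)
  gene_ncells <- Matrix::rowSums(rna_lognorm$values > 0)

  acc_dense <- as.matrix(acc_ln)  # peaks x cells; small at package scale
  acc_sd <- apply(acc_dense, 1, stats::sd)

  genes_use <- genes[genes$gene_id %in% rownames(rna_lognorm$values), , drop = FALSE]
  genes_use <- genes_use[gene_ncells[genes_use$gene_id] >= config$min_cells, , drop = FALSE]
  if (nrow(genes_use) == 0) {
    warning("link_peaks: no genes left after detection filtering")
    return(empty_linkage_table())
  }

  rows <- vector("list", nrow(genes_use))
  for (gi in seq_len(nrow(genes_use))) {
    gene <- genes_use[gi, , drop = FALSE]
    cand <- candidate_peaks(gene, peaks, config$window_bp)
    cand <- cand[peak_ncells[cand] >= config$min_cells & acc_sd[cand] > 0]
    if (!length(cand)) next
    expr <- as.numeric(rna_lognorm$values[gene$gene_id, ])
    if (stats::sd(expr) == 0) next
    r_all <- as.numeric(stats::cor(expr, t(acc_dense[cand, , drop = FALSE])))
    pool_idx <- setdiff(which(peak_ncells >= config$min_cells & acc_sd > 0), cand)
    if (!length(pool_idx)) next
    out <- vector("list", length(cand))
    for (ci in seq_along(cand)) {
      pk <- cand[ci]
      bg <- matched_background(feats[pk, , drop = FALSE],
                               feats[pool_idx, , drop = FALSE],
                               n = config$n_background)
      bg_idx <- pool_idx[bg]
      r_bg <- as.numeric(stats::cor(expr, t(acc_dense[bg_idx, , drop = FALSE])))
      zt <- linkage_ztest(r_all[ci], r_bg, two_sided = config$two_sided)
      if (is.na(zt$zscore)) next
      if (zt$pvalue < config$pvalue_cutoff && abs(r_all[ci]) > config$score_cutoff)
        out[[ci]] <- data.frame(gene_id = gene$gene_id, chrom = peaks$chrom[pk],
                                start = peaks$start[pk], end = peaks$end[pk],
                                score = r_all[ci], zscore = zt$zscore,
                                pvalue = zt$pvalue, sample_id = sample_id,
                                stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out)) rows[[gi]] <- do.call(rbind, out)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("link_peaks: no significant linkages")
    return(empty_linkage_table())
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$gene_id, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  validate_linkages(res)
  res
}

empty_linkage_table <- function() {
  data.frame(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), score = numeric(), zscore = numeric(),
             pvalue = numeric(), sample_id = character(),
             stringsAsFactors = FALSE)
}
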