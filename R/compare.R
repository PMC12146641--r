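# Cross-sample layer: union CRE set, linkage remapping onto it, the
# tissue-presence distribution, tissue-specific gene-linked CRE calling
# (with the optional cell-type peak restriction), and the single-sample
# region view.

#' Merge per-sample peak sets into a union CRE set
#'
#' All peaks are pooled and transitively merged into maximal intervals
#' under half-open overlap; bookended intervals (sharing no base) are NOT
#' merged. Each original peak maps to the unique union CRE containing it.
#' Samples of different species must never share a union set; if a
#' \code{species} map is given, mixing raises an error.
#'
#' @param peak_sets named list: sample_id -> interval table of peaks
#'   (pairwise disjoint within each sample).
#' @param species optional named character vector sample_id -> species.
#' @return a \code{union_cre_map}: list with \code{union_cres} (sorted
#'   disjoint interval table) and \code{mapping} (data.frame sample_id,
#'   peak_chrom, peak_start, peak_end, cre_index).
#' @export
build_union_cres <- function(peak_sets, species = NULL) {
  stopifnot(is.list(peak_sets), length(peak_sets) > 0,
            !is.null(names(peak_sets)))
  if (!is.null(species)) {
    sp <- unique(species[names(peak_sets)])
    if (length(sp) > 1)
      stop("build_union_cres: refusing to merge peaks across species: ",
           paste(sp, collapse = ", "))
  }
  pooled <- do.call(rbind, lapply(names(peak_sets), function(sid) {
    p <- peak_sets[[sid]]
    data.frame(sample_id = sid, chrom = p$chrom, start = p$start, end = p$end,
               stringsAsFactors = FALSE)
  }))
  gr <- gi_to_granges(pooled)
  # min.gapwidth = 0 keeps bookended (adjacent) intervals separate
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  # deterministic output order by (chrom, start) regardless of the order
  # chromosomes were first seen in
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               GenomicRanges::start(red))
  red <- red[ord]
  union_cres <- gintervals(as.character(GenomicRanges::seqnames(red)),
                           GenomicRanges::start(red) - 1L,
                           GenomicRanges::end(red))
  hits <- GenomicRanges::findOverlaps(gr, red)
  if (length(hits) != nrow(pooled) || anyDuplicated(S4Vectors::queryHits(hits)))
    stop("build_union_cres: internal error: peak not mapped to exactly one union CRE")
  idx <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  contained <- pooled$start >= union_cres$start[idx] &
    pooled$end <= union_cres$end[idx]
  if (!all(contained))
    stop("build_union_cres: internal error: mapped peak not contained in union CRE")
  mapping <- data.frame(sample_id = pooled$sample_id,
                        peak_chrom = pooled$chrom,
                        peak_start = pooled$start, peak_end = pooled$end,
                        cre_index = idx, stringsAsFactors = FALSE)
  structure(list(union_cres = union_cres, mapping = mapping),
            class = "union_cre_map")
}

#' Remap per-sample linkages onto the union CRE coordinate system
#'
#' Each linkage's peak is replaced by the index of its union CRE. When
#' several peaks of one sample merge into one union CRE and are linked to
#' the same gene, the duplicate rows collapse keeping the smallest p-value.
#'
#' @param linkages linkage data.frame (possibly several samples row-bound).
#' @param cre_map \code{union_cre_map} from \code{build_union_cres}.
#' @return data.frame: gene_id, cre_index, sample_id, score, zscore, pvalue.
#' @export
remap_linkages <- function(linkages, cre_map) {
  if (nrow(linkages) == 0)
    return(data.frame(gene_id = character(), cre_index = integer(),
                      sample_id = character(), score = numeric(),
                      zscore = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE))
  map <- cre_map$mapping
  key <- function(s, c, a, b) paste(s, c, a, b, sep = "\r")
  lut <- stats::setNames(map$cre_index,
                         key(map$sample_id, map$peak_chrom, map$peak_start, map$peak_end))
  k <- key(linkages$sample_id, linkages$chrom, linkages$start, linkages$end)
  idx <- lut[k]
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("remap_linkages: unmapped peak ", linkages$chrom[bad], ":",
         linkages$start[bad], "-", linkages$end[bad], " in sample ",
         linkages$sample_id[bad])
  }
  out <- data.frame(gene_id = linkages$gene_id, cre_index = as.integer(idx),
                    sample_id = linkages$sample_id, score = linkages$score,
                    zscore = linkages$zscore, pvalue = linkages$pvalue,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue), , drop = FALSE]
  dup <- duplicated(out[, c("gene_id", "cre_index", "sample_id")])
  out <- out[!dup, , drop = FALSE]
  out <- out[order(out$gene_id, out$cre_index, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tissue-presence distribution of CRE-gene linkages
#'
#' A linkage (gene, union CRE) is present in a tissue iff it is present in
#' at least one sample of that tissue. Returns the histogram over the
#' number of tissues each distinct linkage is present in, plus fractions
#' and cumulative fractions.
#'
#' @param remapped data.frame from \code{remap_linkages}.
#' @param tissue_of named character vector sample_id -> tissue.
#' @return data.frame: n_tissues, count, fraction, cumulative_fraction
#'   (ascending in n_tissues).
#' @export
tissue_presence_distribution <- function(remapped, tissue_of) {
  if (anyNA(tissue_of[unique(remapped$sample_id)]))
    stop("tissue_presence_distribution: sample without a tissue label")
  if (nrow(remapped) == 0)
    return(data.frame(n_tissues = integer(), count = integer(),
                      fraction = numeric(), cumulative_fraction = numeric()))
  tis <- tissue_of[remapped$sample_id]
  lk <- paste(remapped$gene_id, remapped$cre_index, sep = "\r")
  ntis <- vapply(split(tis, lk), function(x) length(unique(x)), 0L)
  tab <- table(ntis)
  out <- data.frame(n_tissues = as.integer(names(tab)),
                    count = as.integer(tab))
  out <- out[order(out$n_tissues), , drop = FALSE]
  out$fraction <- out$count / sum(out$count)
  out$cumulative_fraction <- cumsum(out$fraction)
  rownames(out) <- NULL
  out
}

#' Gene-linked CRE presence/score matrix for one gene
#'
#' Rows are the union CREs linked to the gene in any selected sample,
#' ordered by genomic position; each cell carries the (remapped) linkage
#' score or NA. The per-sample mean log-normalized expression of the gene
#' is attached when supplied.
#'
#' @param gene gene id.
#' @param samples character vector of selected sample ids (matrix columns).
#' @param cre_map \code{union_cre_map}.
#' @param remapped remapped linkage data.frame.
#' @param mean_expr optional named numeric vector sample_id -> mean
#'   log-normalized expression of the gene.
#' @param tissue_of optional named character vector sample_id -> tissue,
#'   stored for the tissue-specificity rule.
#' @return a \code{presence_matrix}: list(scores = CRE x sample numeric
#'   matrix, present = logical matrix, cre_index, cres = interval table,
#'   gene, mean_expr, tissue_of).
#' @export
gene_linked_cre_matrix <- function(gene, samples, cre_map, remapped,
                                   mean_expr = NULL, tissue_of = NULL) {
  sub <- remapped[remapped$gene_id == gene & remapped$sample_id %in% samples, ,
                  drop = FALSE]
  cre_idx <- sort(unique(sub$cre_index))
  cres <- cre_map$union_cres[cre_idx, , drop = FALSE]
  ord <- order(cres$chrom, cres$start)
  cre_idx <- cre_idx[ord]
  cres <- cres[ord, , drop = FALSE]
  scores <- matrix(NA_real_, nrow = length(cre_idx), ncol = length(samples),
                   dimnames = list(gi_names(cres), samples))
  if (nrow(sub)) {
    ri <- match(sub$cre_index, cre_idx)
    ci <- match(sub$sample_id, samples)
    scores[cbind(ri, ci)] <- sub$score
  }
  structure(list(scores = scores, present = !is.na(scores),
                 cre_index = cre_idx, cres = cres, gene = gene,
                 mean_expr = mean_expr, tissue_of = tissue_of),
            class = "presence_matrix")
}

#' Restrict a sample's linkages to CREs open in a cell type
#'
#' Keeps linkage records whose peak half-open-overlaps at least one
#' cell-type-level ATAC peak (the cell-type restriction applied before
#' building presence matrices).
#'
#' @param linkages linkage data.frame of one sample.
#' @param celltype_peaks interval table of cell-type-level peaks.
#' @return filtered linkage data.frame.
#' @export
restrict_to_celltype <- function(linkages, celltype_peaks) {
  if (nrow(linkages) == 0 || nrow(celltype_peaks) == 0)
    return(linkages[integer(0), , drop = FALSE])
  hits <- gi_overlap_pairs(linkages, celltype_peaks)
  out <- linkages[sort(unique(hits[, "a"])), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tissue-specificity rule
#' @param target_tissue tissue of interest.
#' @param in_threshold presence fraction that must be exceeded in the
#'   target tissue (strict >, default 1/2).
#' @param out_threshold presence fraction that must not be reached in any
#'   other tissue (strict <, default 1/2).
#' @return named list.
#' @export
tissue_spec_rule <- function(target_tissue, in_threshold = 0.5,
                             out_threshold = 0.5) {
  stopifnot(in_threshold > 0, in_threshold < 1,
            out_threshold > 0, out_threshold < 1)
  list(target_tissue = target_tissue, in_threshold = in_threshold,
       out_threshold = out_threshold)
}

#' Call tissue-specific gene-linked CREs
#'
#' A union CRE is tissue-specific iff it is present in more than half of
#' the samples from the target tissue AND in less than half of the samples
#' from every other tissue (both inequalities strict; thresholds
#' configurable).
#'
#' @param pm \code{presence_matrix} with a tissue map (or pass
#'   \code{tissue_of}).
#' @param rule list from \code{tissue_spec_rule}.
#' @param tissue_of named character vector sample_id -> tissue (overrides
#'   the one stored in \code{pm}).
#' @return integer vector of union CRE indices (pm$cre_index subset).
#' @export
tissue_specific_cres <- function(pm, rule, tissue_of = NULL) {
  tissue_of <- if (!is.null(tissue_of)) tissue_of else pm$tissue_of
  if (is.null(tissue_of)) stop("tissue_specific_cres: no sample -> tissue map")
  samples <- colnames(pm$present)
  tis <- tissue_of[samples]
  if (anyNA(tis)) stop("tissue_specific_cres: sample without tissue label")
  if (!rule$target_tissue %in% tis)
    stop("tissue_specific_cres: unknown tissue: ", rule$target_tissue)
  in_cols <- which(tis == rule$target_tissue)
  keep <- logical(nrow(pm$present))
  for (i in seq_len(nrow(pm$present))) {
    frac_in <- mean(pm$present[i, in_cols])
    if (frac_in <= rule$in_threshold) next
    ok <- TRUE
    for (t in setdiff(unique(tis), rule$target_tissue)) {
      if (mean(pm$present[i, tis == t]) >= rule$out_threshold) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  pm$cre_index[keep]
}

#' Single-sample region view around a gene
#'
#' Builds the data behind a coverage-plot style figure: per-group
#' depth-normalized binned fragment coverage over the gene body plus
#' flanks, per-group expression value lists, the gene/CRE interval tracks,
#' and the arcs of the gene's linkages.
#'
#' Normalization: per-base coverage in the window divided by the group's
#' total fragment count (all fragments of the group, genome-wide) times
#' 1e4, so tracks are comparable between groups of different depth.
#'
#' @param gene gene id.
#' @param genes gene model table.
#' @param fragments sample fragments data.frame.
#' @param groups named character vector barcode -> group (cell type);
#'   barcodes without a group are ignored.
#' @param peaks interval table of the sample's peaks.
#' @param linkages linkage data.frame of the sample.
#' @param expr optional lognorm \code{count_matrix} to extract per-group
#'   expression values of the gene.
#' @param flank flanking distance in bp (default 10000).
#' @param bin_size coverage bin width in bp (default 100).
#' @return a \code{region_view} list: window, coverage (data.frame chrom,
#'   start, end, one column per group), expression (named list of numeric
#'   vectors), gene_track, cre_track, arcs.
#' @export
region_view <- function(gene, genes, fragments, groups, peaks, linkages,
                        expr = NULL, flank = 10000, bin_size = 100) {
  gi <- which(genes$gene_id == gene)
  if (!length(gi)) stop("region_view: gene not in annotation: ", gene)
  g <- genes[gi[1], ]
  w0 <- max(0L, g$start - as.integer(flank))
  w1 <- g$end + as.integer(flank)
  starts <- seq.int(w0, w1 - 1L, by = bin_size)
  ends <- pmin(starts + as.integer(bin_size), w1)
  nb <- length(starts)

  glev <- sort(unique(unname(groups)))
  cov <- matrix(0, nrow = nb, ncol = length(glev),
                dimnames = list(NULL, glev))
  f <- fragments[fragments$barcode %in% names(groups), , drop = FALSE]
  fg <- unname(groups[f$barcode])
  totals <- stats::setNames(numeric(length(glev)), glev)
  tt <- rowsum(as.numeric(f$count), fg)
  totals[rownames(tt)] <- tt[, 1]
  inwin <- f$chrom == g$chrom & f$start < w1 & f$end > w0
  fw <- f[inwin, , drop = FALSE]
  fgw <- fg[inwin]
  if (nrow(fw)) {
    for (grp in glev) {
      sel <- fgw == grp
      if (!any(sel)) next
      fs <- fw[sel, , drop = FALSE]
      # per-base overlap of each fragment with each bin, accumulated
      b0 <- pmax(fs$start, w0)
      b1 <- pmin(fs$end, w1)
      i0 <- (b0 - w0) %/% bin_size + 1L
      i1 <- (b1 - 1L - w0) %/% bin_size + 1L
      for (k in seq_len(nrow(fs))) {
        bins <- i0[k]:i1[k]
        ov <- pmin(ends[bins], b1[k]) - pmax(starts[bins], b0[k])
        cov[bins, grp] <- cov[bins, grp] + ov * fs$count[k]
      }
    }
    for (grp in glev)
      if (totals[grp] > 0) cov[, grp] <- cov[, grp] / (ends - starts) / totals[grp] * 1e4
  }
  coverage <- data.frame(chrom = g$chrom, start = starts, end = ends,
                         stringsAsFactors = FALSE)
  for (grp in glev) coverage[[grp]] <- cov[, grp]

  expression <- NULL
  if (!is.null(expr) && gene %in% rownames(expr$values)) {
    v <- expr$values[gene, ]
    bcs <- intersect(colnames(expr$values), names(groups))
    expression <- split(as.numeric(v[bcs]), unname(groups[bcs]))
  }
  cre_track <- peaks[peaks$chrom == g$chrom & peaks$start < w1 & peaks$end > w0, ,
                     drop = FALSE]
  arcs <- linkages[linkages$gene_id == gene, , drop = FALSE]
  structure(list(window = gintervals(g$chrom, w0, w1), gene = g,
                 coverage = coverage, expression = expression,
                 cre_track = cre_track, arcs = arcs,
                 group_totals = totals),
            class = "region_view")
}

#' Export a region view to disk (bedGraph per group + TSV tables)
#' @param rv \code{region_view} object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_region_view <- function(rv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  glev <- setdiff(names(rv$coverage), c("chrom", "start", "end"))
  for (grp in glev) {
    df <- rv$coverage[, c("chrom", "start", "end")]
    df$value <- rv$coverage[[grp]]
    write_bedgraph(df, file.path(dir, paste0("coverage_", gsub("\\W", "_", grp),
                                             ".bedGraph")))
  }
  write_bed(rv$cre_track, file.path(dir, "cres.bed"))
  utils::write.table(rv$arcs, file.path(dir, "arcs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(rv$expression)) {
    df <- data.frame(group = rep(names(rv$expression),
                                 lengths(rv$expression)),
                     value = unlist(rv$expression, use.names = FALSE))
    utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
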