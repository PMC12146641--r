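# Per-sample orchestration: QC -> normalization -> reductions -> joint
# clustering -> annotation -> linkage. Thin glue over the module functions,
# shared by the CLI and the end-to-end tests.

#' Load a sample bundle from a directory in the exchange formats
#'
#' Expects matrix.mtx / features.tsv / barcodes.tsv, fragments.tsv (or
#' .tsv.gz), peaks.bed, genes.tsv and optionally meta.tsv
#' (key/value: sample_id, tissue, species).
#'
#' @param dir sample directory.
#' @return a sample bundle list (same shape as \code{simulate_sample}).
#' @export
load_sample_bundle <- function(dir) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "peaks.bed",
            "genes.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("load_sample_bundle: ", dir, " is missing ",
         paste(miss, collapse = ", "),
         " (produce it with the 'simulate' subcommand or your own export)")
  fragpath <- file.path(dir, "fragments.tsv")
  if (!file.exists(fragpath)) fragpath <- paste0(fragpath, ".gz")
  if (!file.exists(fragpath)) stop("load_sample_bundle: no fragments file in ", dir)
  meta <- list(sample_id = basename(dir), tissue = "unknown",
               species = "unknown")
  mpath <- file.path(dir, "meta.tsv")
  if (file.exists(mpath)) {
    mt <- utils::read.table(mpath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    for (i in seq_len(nrow(mt))) meta[[mt$key[i]]] <- mt$value[i]
  }
  list(sample_id = meta$sample_id, tissue = meta$tissue,
       species = meta$species,
       rna = read_counts_mtx(file.path(dir, "matrix.mtx"),
                             file.path(dir, "features.tsv"),
                             file.path(dir, "barcodes.tsv")),
       fragments = read_fragments(fragpath),
       peaks = read_bed(file.path(dir, "peaks.bed")),
       genes = read_gene_models(file.path(dir, "genes.tsv"), "tsv"))
}

#' Run QC, normalization, reductions, clustering and annotation for a sample
#'
#' @param bundle sample bundle (from \code{load_sample_bundle} or
#'   \code{simulate_sample}).
#' @param thresholds QC thresholds (default \code{qc_thresholds()}).
#' @param n_var number of variable RNA features for PCA (default 2000).
#' @param k_pca,k_lsi reduction dimensionalities (defaults 50 / 40).
#' @param k_nn SNN neighbors (default 20, capped below the cell count).
#' @param resolution Louvain resolution (default 1).
#' @param min_cutoff ATAC top-feature cutoff (default 5).
#' @param reference optional reference \code{pseudobulk_set} for
#'   annotation; without it the sample's tissue name is the fallback label.
#' @param seed integer seed.
#' @return a processed-sample list: qc, retained, rna_lognorm, atac_raw,
#'   peaks (rows aligned to atac_raw), reductions, clusters, annotation,
#'   cell_meta.
#' @export
process_sample <- function(bundle, thresholds = qc_thresholds(),
                           n_var = 2000, k_pca = 50, k_lsi = 40, k_nn = 20,
                           resolution = 1, min_cutoff = 5, reference = NULL,
                           seed = 1L) {
  qc <- compute_cell_qc(bundle$rna, bundle$fragments, bundle$genes)
  retained <- apply_cell_filters(qc, thresholds)
  if (length(retained) < 3)
    stop("process_sample: fewer than 3 cells pass QC in ", bundle$sample_id)

  rna_raw <- count_matrix(bundle$rna$values[, retained, drop = FALSE], "raw")
  rna_ln <- lognormalize(rna_raw)
  vf <- select_variable_features(rna_ln, min(n_var, nrow(rna_ln$values)))
  scaled <- scale_features(count_matrix(
    rna_ln$values[vf, , drop = FALSE], "lognorm"))
  pca <- pca_reduce(scaled, k = k_pca)

  atac_all <- feature_matrix(bundle$fragments, bundle$peaks, retained)
  atac_f <- filter_top_features(atac_all, min_cutoff = min_cutoff)
  peaks_kept <- bundle$peaks[match(rownames(atac_f$values),
                                   gi_names(bundle$peaks)), , drop = FALSE]
  lsi <- lsi_reduce(tfidf(atac_f), k = k_lsi)

  k_nn <- min(k_nn, length(retained) - 1L)
  g <- joint_neighbor_graph(pca, lsi, k = k_nn)
  clusters <- louvain_cluster(g, resolution = resolution, seed = seed)

  if (!is.null(reference)) {
    pb <- pseudobulk_mean(rna_ln, stats::setNames(as.character(clusters),
                                                  names(clusters)))
    ann <- annotate_clusters(pb, reference)
  } else {
    ann <- fallback_annotation(as.character(clusters), bundle$tissue)
  }
  labels <- stats::setNames(ann$label, ann$cluster)
  cell_meta <- data.frame(barcode = names(clusters),
                          cluster = as.integer(clusters),
                          cell_type = unname(labels[as.character(clusters)]),
                          stringsAsFactors = FALSE)
  list(sample_id = bundle$sample_id, qc = qc, retained = retained,
       rna_lognorm = rna_ln, atac_raw = atac_f, peaks = peaks_kept,
       pca = pca, lsi = lsi, clusters = clusters, annotation = ann,
       cell_meta = cell_meta)
}

#' Compute linkages for a processed sample
#'
#' @param processed list from \code{process_sample}.
#' @param genes gene model table.
#' @param config \code{linkage_config}.
#' @param gc optional per-peak GC fractions (aligned with
#'   \code{processed$peaks}).
#' @return linkage data.frame.
#' @export
link_sample <- function(processed, genes, config = linkage_config(),
                        gc = NULL) {
  link_peaks(processed$rna_lognorm, processed$atac_raw, genes,
             processed$peaks, config = config,
             sample_id = processed$sample_id, gc = gc)
}
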