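# Synthetic multiome generator: samples and multi-tissue corpora with
# planted, known structure (gene-peak links of a target correlation,
# tissue-specific links, TF peak placements), so every downstream module is
# testable offline. Counts follow a Poisson-lognormal model: each gene has
# a per-cell lognormal latent activity; gene counts are Poisson around
# lambda_g * a, and a linked peak's counts are Poisson around
# lambda_p * a^gamma with gamma calibrated so the realized correlation of
# the log-transformed values matches the target.

#' Simulation specification
#'
#' Defaults describe the standard test corpus: 3 tissues x 2 samples,
#' 300 cells, 200 genes, 3 peaks per gene (600 peaks), every gene with one
#' planted linked (distal) peak at target correlation 0.6, 30% of links
#' tissue-specific.
#'
#' @param n_tissues number of tissues (default 3).
#' @param samples_per_tissue samples per tissue (default 2).
#' @param n_cells_per_sample cells per sample (default 300).
#' @param n_genes genes on the toy genome (default 200).
#' @param peaks_per_gene peaks per gene, 1..5 (default 3; peak 1 covers the
#'   TSS, further peaks sit 20-40 kb away, all within the 50 kb window).
#' @param fraction_linked_peaks fraction of peaks carrying a planted link
#'   (default 1/3, i.e. one linked peak per gene); linked peaks are distal.
#' @param planted_link_r target Pearson correlation of log values for
#'   planted links (default 0.6).
#' @param fraction_tissue_specific fraction of linked genes whose link is
#'   planted in one tissue only (default 0.3); the rest are planted in
#'   every sample.
#' @param gene_mean_meanlog,gene_mean_sdlog lognormal law of per-gene mean
#'   counts (defaults log(8), 0.4).
#' @param peak_mean_meanlog,peak_mean_sdlog lognormal law of per-peak mean
#'   counts (defaults log(4), 0.3).
#' @param latent_sdlog sd of the per-cell lognormal latent activity
#'   (default 0.6).
#' @param nucfree_prob probability a synthetic fragment is
#'   nucleosome-free-length (60-140 bp) rather than mononucleosome-length
#'   (160-280 bp) (default 0.65, giving nucleosome signal ~ 0.5).
#' @param species species label stamped on samples (default "synthetic").
#' @param seed master seed.
#' @return a \code{simulation_spec} list.
#' @export
simulation_spec <- function(n_tissues = 3, samples_per_tissue = 2,
                            n_cells_per_sample = 300, n_genes = 200,
                            peaks_per_gene = 3, fraction_linked_peaks = 1 / 3,
                            planted_link_r = 0.6,
                            fraction_tissue_specific = 0.3,
                            gene_mean_meanlog = log(8), gene_mean_sdlog = 0.4,
                            peak_mean_meanlog = log(4), peak_mean_sdlog = 0.3,
                            latent_sdlog = 0.6, nucfree_prob = 0.65,
                            species = "synthetic", seed = 1L) {
  stopifnot(n_tissues >= 1, samples_per_tissue >= 1, n_cells_per_sample >= 1,
            n_genes >= 1, peaks_per_gene >= 1, peaks_per_gene <= 5,
            fraction_linked_peaks >= 0, fraction_linked_peaks <= 1,
            fraction_tissue_specific >= 0, fraction_tissue_specific <= 1,
            planted_link_r > 0, planted_link_r < 1)
  structure(list(n_tissues = n_tissues, samples_per_tissue = samples_per_tissue,
                 n_cells_per_sample = n_cells_per_sample, n_genes = n_genes,
                 peaks_per_gene = peaks_per_gene,
                 fraction_linked_peaks = fraction_linked_peaks,
                 planted_link_r = planted_link_r,
                 fraction_tissue_specific = fraction_tissue_specific,
                 gene_mean_meanlog = gene_mean_meanlog,
                 gene_mean_sdlog = gene_mean_sdlog,
                 peak_mean_meanlog = peak_mean_meanlog,
                 peak_mean_sdlog = peak_mean_sdlog,
                 latent_sdlog = latent_sdlog, nucfree_prob = nucfree_prob,
                 species = species, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' The tiny preset used by CLI smoke tests
#' @param seed master seed.
#' @return a \code{simulation_spec}.
#' @export
tiny_spec <- function(seed = 1L) {
  # with only 30 genes / 90 peaks, per-feature means must be higher so
  # cells still clear the absolute read-count QC thresholds
  simulation_spec(n_tissues = 2, samples_per_tissue = 2,
                  n_cells_per_sample = 80, n_genes = 30, peaks_per_gene = 3,
                  gene_mean_meanlog = log(60), peak_mean_meanlog = log(15),
                  seed = seed)
}

# Gene/peak layout on a toy two-chromosome genome. Genes are spaced 120 kb
# apart so TSS windows never reach a neighbor's peaks; the promoter peak
# covers the TSS (so cells show TSS enrichment) and distal peaks sit >= 2 kb
# outside the enrichment flanks but inside the 50 kb linkage window.
genome_layout <- function(spec) {
  spacing <- 120000L
  per_chrom <- ceiling(spec$n_genes / 2)
  chrom <- rep(c("chr1", "chr2"), times = c(per_chrom, spec$n_genes - per_chrom))
  slot <- c(seq_len(per_chrom), seq_len(spec$n_genes - per_chrom))
  tss <- 60000L + (slot - 1L) * spacing
  strand <- rep_len(c("+", "-"), spec$n_genes)
  start <- ifelse(strand == "+", tss, tss - 9999L)
  end <- ifelse(strand == "+", tss + 10000L, tss + 1L)
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(spec$n_genes)),
                      chrom = chrom, start = as.integer(start),
                      end = as.integer(end), strand = strand,
                      tss = as.integer(tss), stringsAsFactors = FALSE)
  sizes <- c(chr1 = max(tss[chrom == "chr1"]) + 70000L,
             chr2 = if (any(chrom == "chr2")) max(tss[chrom == "chr2"]) + 70000L else 200000L)

  offsets <- list(c(-250L, 250L), c(20000L, 20500L), c(-20500L, -20000L),
                  c(35000L, 35500L), c(-35500L, -35000L))[seq_len(spec$peaks_per_gene)]
  roles <- c("promoter", "distal", "distal", "distal", "distal")[seq_len(spec$peaks_per_gene)]
  pk <- do.call(rbind, lapply(seq_len(spec$n_genes), function(g) {
    data.frame(gene_id = genes$gene_id[g], chrom = genes$chrom[g],
               start = genes$tss[g] + vapply(offsets, `[`, 0L, 1L),
               end = genes$tss[g] + vapply(offsets, `[`, 0L, 2L),
               role = roles, stringsAsFactors = FALSE)
  }))
  pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
  rownames(pk) <- NULL
  pk$peak_id <- gi_names(pk)
  n_linked <- min(spec$n_genes,
                  round(spec$fraction_linked_peaks * nrow(pk)))
  linked_genes <- genes$gene_id[seq_len(n_linked)]
  # the linked peak of a gene is its first distal peak (or the promoter
  # when the gene has only one peak)
  pk$linked <- FALSE
  for (g in linked_genes) {
    cand <- which(pk$gene_id == g & pk$role == "distal")
    if (!length(cand)) cand <- which(pk$gene_id == g)
    pk$linked[cand[1]] <- TRUE
  }
  list(genes = genes, peaks = pk, chrom_sizes = sizes)
}

# Calibrate gamma so that Pearson(lognormalized gene counts, lognormalized
# peak counts) over cells hits the target for the planted model. scale_g /
# scale_p approximate the factor the library-size log-normalization applies
# (scale factor / expected cell total), which compresses correlations and
# must be part of the calibration. Grid search with common random numbers,
# monotone interpolation.
calibrate_gamma <- function(target_r, lambda_g, lambda_p, sdlog,
                            scale_g = 1, scale_p = 1, n = 2000, seed = 99L) {
  grid <- seq(0.2, 4, by = 0.2)
  rs <- vapply(grid, function(gam) {
    set.seed(seed)
    a <- stats::rlnorm(n, 0, sdlog)
    g <- stats::rpois(n, lambda_g * a)
    p <- stats::rpois(n, lambda_p * a^gam)
    suppressWarnings(stats::cor(log1p(g * scale_g), log1p(p * scale_p)))
  }, 0)
  rs[is.na(rs)] <- 0
  if (max(rs) <= target_r) return(grid[which.max(rs)])
  i <- which(rs >= target_r)[1]
  if (i == 1) return(grid[1])
  # linear interpolation between the bracketing grid points
  g0 <- grid[i - 1]; g1 <- grid[i]
  r0 <- rs[i - 1]; r1 <- rs[i]
  g0 + (target_r - r0) / (r1 - r0) * (g1 - g0)
}

# Draw per-sample peak coordinates: canonical peaks expanded outward by
# 0-30 bp on each side, so union-CRE merging across samples is exercised
# while every canonical peak stays contained in its sample peak.
jitter_peaks <- function(canonical) {
  n <- nrow(canonical)
  data.frame(chrom = canonical$chrom,
             start = pmax(0L, canonical$start - sample.int(31L, n, replace = TRUE) + 1L),
             end = canonical$end + sample.int(31L, n, replace = TRUE) - 1L,
             name = canonical$peak_id, stringsAsFactors = FALSE)
}

sim_fragment_block <- function(peak_row, cell_idx, counts, barcodes, spec) {
  # expand (peak, cell, count) into one fragment per unit count
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  cells <- rep.int(cell_idx, counts)
  free <- stats::runif(tot) < spec$nucfree_prob
  len <- ifelse(free, 60L + sample.int(81L, tot, replace = TRUE) - 1L,
                160L + sample.int(121L, tot, replace = TRUE) - 1L)
  maxs <- peak_row$end - len
  start <- peak_row$start +
    floor(stats::runif(tot) * (maxs - peak_row$start + 1L))
  data.frame(chrom = peak_row$chrom, start = as.integer(start),
             end = as.integer(start + len), barcode = barcodes[cells],
             count = 1L, stringsAsFactors = FALSE)
}

# Core per-sample generator; layout, per-gene/peak lambdas, gamma and the
# set of links active in this sample are decided by the caller.
sim_sample_core <- function(spec, layout, lambdas, gamma, active_links,
                            tissue, sample_id, seed, closed_peaks = character(0)) {
  set.seed(seed)
  n <- spec$n_cells_per_sample
  genes <- layout$genes
  peaks <- layout$peaks
  barcodes <- sprintf("%s-BC%04d", sample_id, seq_len(n))

  latent <- matrix(stats::rlnorm(nrow(genes) * n, 0, spec$latent_sdlog),
                   nrow = nrow(genes))
  rna <- matrix(stats::rpois(nrow(genes) * n, lambdas$gene * latent),
                nrow = nrow(genes),
                dimnames = list(genes$gene_id, barcodes))

  gene_row <- match(peaks$gene_id, genes$gene_id)
  atac <- matrix(0L, nrow = nrow(peaks), ncol = n,
                 dimnames = list(peaks$peak_id, barcodes))
  for (p in seq_len(nrow(peaks))) {
    if (peaks$peak_id[p] %in% closed_peaks) next  # closed chromatin: no signal
    if (peaks$peak_id[p] %in% active_links) {
      mu <- lambdas$peak[p] * latent[gene_row[p], ]^gamma
    } else {
      mu <- lambdas$peak[p] * stats::rlnorm(n, 0, spec$latent_sdlog)
    }
    atac[p, ] <- stats::rpois(n, mu)
  }

  sample_peaks <- jitter_peaks(peaks)
  frag_blocks <- lapply(seq_len(nrow(peaks)), function(p) {
    nz <- which(atac[p, ] > 0)
    if (!length(nz)) return(NULL)
    sim_fragment_block(sample_peaks[p, ], nz, atac[p, nz], barcodes, spec)
  })
  fragments <- do.call(rbind, frag_blocks[!vapply(frag_blocks, is.null, TRUE)])
  fragments <- fragments[order(fragments$chrom, fragments$start), , drop = FALSE]
  rownames(fragments) <- NULL

  truth_links <- which(peaks$peak_id %in% active_links)
  sample_links <- data.frame(gene_id = peaks$gene_id[truth_links],
                             chrom = sample_peaks$chrom[truth_links],
                             start = sample_peaks$start[truth_links],
                             end = sample_peaks$end[truth_links],
                             score = rep(spec$planted_link_r, length(truth_links)),
                             zscore = rep(NA_real_, length(truth_links)),
                             pvalue = rep(0, length(truth_links)),
                             sample_id = rep(sample_id, length(truth_links)),
                             canonical_peak = peaks$peak_id[truth_links],
                             stringsAsFactors = FALSE)

  pk_tab <- gintervals(sample_peaks$chrom, sample_peaks$start,
                       sample_peaks$end, name = sample_peaks$name)
  list(sample_id = sample_id, tissue = tissue, species = spec$species,
       rna = count_matrix(rna, layer = "raw"),
       atac_counts = count_matrix(atac, layer = "raw"),
       fragments = fragments, peaks = pk_tab, genes = genes,
       chrom_sizes = layout$chrom_sizes, truth_links = sample_links)
}

#' Simulate one multiome sample
#'
#' Standalone single-sample generator: builds the toy genome layout, plants
#' every linked peak, and emits an in-memory bundle (optionally written to
#' disk in the package's exchange formats).
#'
#' @param spec \code{simulation_spec}.
#' @param tissue tissue label (default "tissueA").
#' @param sample_id sample identifier (default "s1").
#' @param dir optional output directory; when given, the bundle is written
#'   with \code{write_sample_bundle}.
#' @return a sample bundle list: sample_id, tissue, species, rna (raw
#'   \code{count_matrix}), atac_counts (intended peak x cell counts),
#'   fragments, peaks, genes, chrom_sizes, truth_links.
#' @export
simulate_sample <- function(spec, tissue = "tissueA", sample_id = "s1",
                            dir = NULL) {
  layout <- genome_layout(spec)
  set.seed(spec$seed)
  lambdas <- list(
    gene = stats::rlnorm(nrow(layout$genes), spec$gene_mean_meanlog,
                         spec$gene_mean_sdlog),
    peak = stats::rlnorm(nrow(layout$peaks), spec$peak_mean_meanlog,
                         spec$peak_mean_sdlog))
  latent_mean <- exp(spec$latent_sdlog^2 / 2)
  gamma <- calibrate_gamma(spec$planted_link_r,
                           stats::median(lambdas$gene),
                           stats::median(lambdas$peak),
                           spec$latent_sdlog,
                           scale_g = 1e4 / (sum(lambdas$gene) * latent_mean),
                           scale_p = 1e4 / (sum(lambdas$peak) * latent_mean))
  active <- layout$peaks$peak_id[layout$peaks$linked]
  bundle <- sim_sample_core(spec, layout, lambdas, gamma, active, tissue,
                            sample_id, seed = spec$seed + 1L)
  if (!is.null(dir)) write_sample_bundle(bundle, dir)
  bundle
}

#' Simulate a multi-tissue corpus with planted tissue-specific links
#'
#' Linked genes are split into tissue-specific links (planted in every
#' sample of exactly one tissue, assigned round-robin) and shared links
#' (planted in every sample). A tissue-specific CRE is closed chromatin in
#' every other tissue: it emits no fragments there, as a per-sample peak
#' caller would find no peak at a closed locus. The intended
#' tissue-presence count of every planted linkage is recorded exactly in
#' the returned ground truth.
#'
#' @param spec \code{simulation_spec}.
#' @param dir optional output directory; when given, every sample plus the
#'   corpus tables are written.
#' @return list(samples = list of sample bundles, truth = ground-truth
#'   list: genes, peaks, links, gamma, lambdas, tissue_of).
#' @export
simulate_corpus <- function(spec, dir = NULL) {
  layout <- genome_layout(spec)
  set.seed(spec$seed)
  lambdas <- list(
    gene = stats::rlnorm(nrow(layout$genes), spec$gene_mean_meanlog,
                         spec$gene_mean_sdlog),
    peak = stats::rlnorm(nrow(layout$peaks), spec$peak_mean_meanlog,
                         spec$peak_mean_sdlog))
  latent_mean <- exp(spec$latent_sdlog^2 / 2)
  gamma <- calibrate_gamma(spec$planted_link_r,
                           stats::median(lambdas$gene),
                           stats::median(lambdas$peak),
                           spec$latent_sdlog,
                           scale_g = 1e4 / (sum(lambdas$gene) * latent_mean),
                           scale_p = 1e4 / (sum(lambdas$peak) * latent_mean))

  tissues <- sprintf("tissue%02d", seq_len(spec$n_tissues))
  linked <- layout$peaks[layout$peaks$linked, , drop = FALSE]
  n_ts <- round(spec$fraction_tissue_specific * nrow(linked))
  link_type <- rep("shared", nrow(linked))
  link_tissue <- rep(NA_character_, nrow(linked))
  if (n_ts > 0) {
    link_type[seq_len(n_ts)] <- "tissue_specific"
    link_tissue[seq_len(n_ts)] <- rep_len(tissues, n_ts)
  }
  links <- data.frame(gene_id = linked$gene_id, peak_id = linked$peak_id,
                      chrom = linked$chrom, start = linked$start,
                      end = linked$end, type = link_type,
                      tissue = link_tissue,
                      n_tissues = ifelse(link_type == "shared",
                                         spec$n_tissues, 1L),
                      stringsAsFactors = FALSE)

  samples <- list()
  tissue_of <- character(0)
  si <- 0L
  for (ti in seq_len(spec$n_tissues)) {
    for (ri in seq_len(spec$samples_per_tissue)) {
      si <- si + 1L
      sid <- sprintf("%s_s%d", tissues[ti], ri)
      active <- links$peak_id[links$type == "shared" |
                                (!is.na(links$tissue) & links$tissue == tissues[ti])]
      # tissue-specific CREs of other tissues are closed chromatin here:
      # they produce no fragments, mirroring per-sample peak calling that
      # would not report them as peaks in this sample
      closed <- links$peak_id[links$type == "tissue_specific" &
                                links$tissue != tissues[ti]]
      samples[[sid]] <- sim_sample_core(spec, layout, lambdas, gamma, active,
                                        tissues[ti], sid,
                                        seed = spec$seed + 1000L + si,
                                        closed_peaks = closed)
      tissue_of[sid] <- tissues[ti]
    }
  }
  truth <- list(genes = layout$genes, peaks = layout$peaks, links = links,
                gamma = gamma, lambdas = lambdas, tissue_of = tissue_of,
                chrom_sizes = layout$chrom_sizes)
  out <- list(samples = samples, truth = truth)
  if (!is.null(dir)) write_corpus(out, dir)
  out
}

#' Simulate per-TF ChIP-seq peak sets with planted enrichment
#'
#' Enriched TFs receive one peak inside \code{enrichment_fraction_in} of
#' the target CREs and \code{enrichment_fraction_out} of the remaining
#' background CREs; decoy TFs are placed uniformly over the genome.
#'
#' @param target_cres interval table of target CREs.
#' @param background_cres interval table of the background universe
#'   (including the targets).
#' @param chrom_sizes named chromosome lengths (for decoy placement).
#' @param n_enriched,n_decoy numbers of enriched and decoy TFs.
#' @param enrichment_fraction_in,enrichment_fraction_out planted hit
#'   fractions (defaults 0.8 / 0.05).
#' @param peak_width TF peak width in bp (default 200).
#' @param seed integer seed.
#' @return list(tf_peak_sets = named list of interval tables,
#'   truth = data.frame(tf, enriched)).
#' @export
simulate_tf_peaks <- function(target_cres, background_cres, chrom_sizes,
                              n_enriched = 3, n_decoy = 7,
                              enrichment_fraction_in = 0.8,
                              enrichment_fraction_out = 0.05,
                              peak_width = 200, seed = 1L) {
  set.seed(seed)
  tkey <- gi_names(target_cres)
  bkey <- gi_names(background_cres)
  rest <- background_cres[!bkey %in% tkey, , drop = FALSE]
  peak_in_cre <- function(cres, rows) {
    mid <- (cres$start[rows] + cres$end[rows]) %/% 2L
    half <- peak_width %/% 2L
    data.frame(chrom = cres$chrom[rows], start = pmax(0L, mid - half),
               end = mid + half, stringsAsFactors = FALSE)
  }
  sets <- list()
  truth <- data.frame(tf = character(), enriched = logical(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_enriched)) {
    n_in <- round(enrichment_fraction_in * nrow(target_cres))
    n_out <- round(enrichment_fraction_out * nrow(rest))
    rows_in <- sample.int(nrow(target_cres), n_in)
    pk <- peak_in_cre(target_cres, rows_in)
    if (n_out > 0 && nrow(rest) > 0)
      pk <- rbind(pk, peak_in_cre(rest, sample.int(nrow(rest), n_out)))
    nm <- sprintf("TF_enriched%02d", i)
    sets[[nm]] <- gintervals(pk$chrom, pk$start, pk$end)
    truth <- rbind(truth, data.frame(tf = nm, enriched = TRUE))
  }
  for (i in seq_len(n_decoy)) {
    n_pk <- max(5L, round(0.02 * nrow(background_cres)))
    chroms <- sample(names(chrom_sizes), n_pk, replace = TRUE)
    start <- vapply(chroms, function(ch)
      floor(stats::runif(1) * (chrom_sizes[[ch]] - peak_width)), 0)
    nm <- sprintf("TF_decoy%02d", i)
    sets[[nm]] <- gintervals(chroms, as.integer(start),
                             as.integer(start + peak_width))
    truth <- rbind(truth, data.frame(tf = nm, enriched = FALSE))
  }
  list(tf_peak_sets = sets, truth = truth)
}

#' Write one sample bundle in the package's exchange formats
#'
#' Creates \code{dir/sample_id/} with matrix.mtx + features.tsv +
#' barcodes.tsv (RNA), fragments.tsv, peaks.bed, genes.tsv and
#' truth_links.tsv.
#'
#' @param bundle from \code{simulate_sample} / \code{simulate_corpus}.
#' @param dir parent output directory.
#' @return sample directory path, invisibly.
#' @export
write_sample_bundle <- function(bundle, dir) {
  sdir <- file.path(dir, bundle$sample_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  write_counts_mtx(bundle$rna, file.path(sdir, "matrix.mtx"),
                   file.path(sdir, "features.tsv"),
                   file.path(sdir, "barcodes.tsv"))
  write_fragments(bundle$fragments, file.path(sdir, "fragments.tsv"))
  write_bed(bundle$peaks, file.path(sdir, "peaks.bed"))
  write_gene_models(bundle$genes, file.path(sdir, "genes.tsv"))
  write_linkage_table(bundle$truth_links[, linkage_cols],
                      file.path(sdir, "truth_links.tsv"))
  meta <- data.frame(key = c("sample_id", "tissue", "species"),
                     value = c(bundle$sample_id, bundle$tissue, bundle$species))
  utils::write.table(meta, file.path(sdir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sdir)
}

#' Write a corpus (all samples plus ground-truth tables)
#' @param corpus from \code{simulate_corpus}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in corpus$samples) write_sample_bundle(b, dir)
  st <- data.frame(sample_id = names(corpus$truth$tissue_of),
                   tissue = unname(corpus$truth$tissue_of),
                   species = corpus$samples[[1]]$species)
  utils::write.table(st, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$truth$links, file.path(dir, "truth_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cs <- corpus$truth$chrom_sizes
  utils::write.table(data.frame(names(cs), unname(cs)),
                     file.path(dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
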