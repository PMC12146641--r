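# Normalization, variable features, reductions, pseudobulks, the ATAC
# feature matrix and the 100 kb-bin QC pseudobulk layer.

#' Construct a count matrix container
#'
#' A thin wrapper around a features x cells matrix (sparse dgCMatrix for raw
#' counts, possibly dense after scaling) carrying the normalization layer.
#'
#' @param values features x cells matrix with dimnames set.
#' @param layer one of "raw", "lognorm", "tfidf", "scaled".
#' @return object of class \code{count_matrix}.
#' @export
count_matrix <- function(values, layer = c("raw", "lognorm", "tfidf", "scaled")) {
  layer <- match.arg(layer)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("count_matrix: values must have feature and barcode dimnames")
  if (anyDuplicated(rownames(values))) stop("count_matrix: duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("count_matrix: duplicate barcodes")
  if (layer == "raw") {
    x <- if (methods::is(values, "sparseMatrix")) values@x else as.vector(values)
    if (any(x < 0) || any(x != round(x)))
      stop("count_matrix: raw layer must be non-negative integers")
  }
  structure(list(values = values, layer = layer), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix [", x$layer, "]: ", nrow(x$values), " features x ",
      ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

#' Library-size log-normalization
#'
#' Each value v in a cell with total T becomes \code{log(1 + v * scale / T)}
#' (natural log), the standard scRNA-seq log-normalization with scale factor
#' 10,000.
#'
#' @param cm raw-layer \code{count_matrix}.
#' @param scale scale factor (default 10000).
#' @return \code{count_matrix} with layer "lognorm".
#' @export
lognormalize <- function(cm, scale = 10000) {
  stopifnot(inherits(cm, "count_matrix"), cm$layer == "raw")
  totals <- Matrix::colSums(cm$values)
  zero <- which(totals == 0)
  if (length(zero))
    stop("lognormalize: zero-total cell(s): ",
         paste(utils::head(colnames(cm$values)[zero], 3), collapse = ", "))
  m <- methods::as(cm$values, "CsparseMatrix")
  # per-column scaling on the sparse slots; zeros map to zero
  percol <- diff(m@p)
  m@x <- log1p(m@x * scale / rep.int(totals, percol))
  count_matrix(m, layer = "lognorm")
}

row_means_sparse <- function(m) Matrix::rowSums(m) / ncol(m)

row_vars <- function(m) {
  # unbiased per-feature variance; works for sparse and dense
  n <- ncol(m)
  if (n < 2) return(rep(0, nrow(m)))
  mu <- Matrix::rowSums(m) / n
  (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Select the most variable features
#'
#' Features are ranked by plain variance of the (log-normalized) values,
#' descending; ties keep feature-list order.
#'
#' @param cm \code{count_matrix} (lognorm layer expected).
#' @param n number of features to return.
#' @return character vector of feature ids, highest variance first.
#' @export
select_variable_features <- function(cm, n) {
  stopifnot(inherits(cm, "count_matrix"))
  if (n <= 0) stop("select_variable_features: n must be positive")
  if (n > nrow(cm$values))
    stop("select_variable_features: n exceeds feature count")
  v <- row_vars(cm$values)
  rownames(cm$values)[order(-v)[seq_len(n)]]
}

#' Center and scale each feature
#'
#' Each feature (row) is centered to mean 0 and scaled to unit standard
#' deviation; zero-variance features become all-zero rows. The result is
#' dense.
#'
#' @param cm \code{count_matrix}.
#' @return \code{count_matrix} with layer "scaled".
#' @export
scale_features <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- as.matrix(cm$values)
  mu <- rowMeans(m)
  sdv <- sqrt(row_vars(m))
  m <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  m[sdv == 0, ] <- 0
  count_matrix(m, layer = "scaled")
}

#' Construct a reduced-dimension container
#' @param embedding cells x components matrix.
#' @param method "pca" or "lsi".
#' @param sdev component standard deviations / singular values.
#' @param component_range integer range used downstream.
#' @return object of class \code{reduced_matrix}.
#' @export
reduced_matrix <- function(embedding, method, sdev = NULL,
                           component_range = seq_len(ncol(embedding))) {
  structure(list(embedding = embedding, method = method, sdev = sdev,
                 component_range = component_range),
            class = "reduced_matrix")
}

fix_signs <- function(loadings, embedding) {
  # sign convention: the largest-magnitude loading of each component positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      embedding[, j] <- -embedding[, j]
    }
  }
  list(loadings = loadings, embedding = embedding)
}

#' Principal component analysis of a scaled matrix
#'
#' Computes the top-k principal components of the cells over the (scaled)
#' features. Deterministic: exact SVD with a fixed sign convention
#' (largest-magnitude feature loading positive per component).
#'
#' @param cm scaled-layer \code{count_matrix} (features x cells).
#' @param k number of components (capped at min(dim) - 1).
#' @return \code{reduced_matrix} with method "pca"; embedding rows are cells.
#' @export
pca_reduce <- function(cm, k = 50) {
  stopifnot(inherits(cm, "count_matrix"), cm$layer == "scaled")
  m <- as.matrix(cm$values)
  k <- min(k, nrow(m), ncol(m) - 1L)
  s <- svd(m, nu = k, nv = k)
  fx <- fix_signs(s$u, s$v %*% diag(s$d[seq_len(k)], k))
  emb <- fx$embedding
  rownames(emb) <- colnames(m)
  colnames(emb) <- paste0("PC", seq_len(k))
  reduced_matrix(emb, "pca", sdev = s$d[seq_len(k)] / sqrt(max(1, ncol(m) - 1)))
}

#' Build the peak x cell accessibility count matrix from fragments
#'
#' Entry (peak, cell) is the summed duplicate count of the cell's fragments
#' whose interval half-open-overlaps the peak (fragment.start < peak.end and
#' fragment.end > peak.start). A fragment spanning two peaks is counted in
#' each.
#'
#' @param fragments fragments data.frame (chrom, start, end, barcode, count).
#' @param peaks interval table of peaks (non-overlapping within a sample).
#' @param cells barcodes defining the columns; fragments with other barcodes
#'   are ignored.
#' @return raw-layer \code{count_matrix}, peaks x cells; peak rows named
#'   "chrom:start-end".
#' @export
feature_matrix <- function(fragments, peaks, cells) {
  pk_names <- gi_names(peaks)
  frag <- fragments[fragments$barcode %in% cells, , drop = FALSE]
  if (nrow(frag) == 0 || nrow(peaks) == 0) {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nrow(peaks), length(cells)),
                              dimnames = list(pk_names, cells))
    return(count_matrix(m, layer = "raw"))
  }
  hits <- gi_overlap_pairs(frag, peaks)
  ci <- match(frag$barcode[hits[, "a"]], cells)
  m <- Matrix::sparseMatrix(i = hits[, "b"], j = ci,
                            x = as.numeric(frag$count[hits[, "a"]]),
                            dims = c(nrow(peaks), length(cells)),
                            dimnames = list(pk_names, cells))
  count_matrix(m, layer = "raw")
}

#' Drop low-count features
#'
#' Retains features whose total count across cells is at least
#' \code{min_cutoff} (>= semantics, matching the conventional min.cutoff
#' behavior of scATAC top-feature selection).
#'
#' @param cm raw-layer \code{count_matrix}.
#' @param min_cutoff minimum total count (default 5).
#' @return filtered \code{count_matrix}.
#' @export
filter_top_features <- function(cm, min_cutoff = 5) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- Matrix::rowSums(cm$values) >= min_cutoff
  count_matrix(cm$values[keep, , drop = FALSE], layer = cm$layer)
}

#' TF-IDF normalization of an accessibility matrix
#'
#' TF(f,c) = count(f,c) / total(c); IDF(f) = n_cells / total_count(f);
#' value = log(1 + TF * IDF * scale). Features with zero total count should
#' be removed beforehand (\code{filter_top_features}).
#'
#' @param cm raw-layer \code{count_matrix}.
#' @param scale scale factor inside the log (default 10000).
#' @return \code{count_matrix} with layer "tfidf".
#' @export
tfidf <- function(cm, scale = 10000) {
  stopifnot(inherits(cm, "count_matrix"), cm$layer == "raw")
  coltot <- Matrix::colSums(cm$values)
  if (any(coltot == 0))
    stop("tfidf: zero-total cell(s): ",
         paste(utils::head(colnames(cm$values)[coltot == 0], 3), collapse = ", "))
  rowtot <- Matrix::rowSums(cm$values)
  if (any(rowtot == 0))
    stop("tfidf: zero-count feature(s); apply filter_top_features first")
  m <- methods::as(cm$values, "CsparseMatrix")
  idf <- ncol(m) / rowtot
  percol <- diff(m@p)
  tf <- m@x / rep.int(coltot, percol)
  m@x <- log1p(tf * idf[m@i + 1L] * scale)
  count_matrix(m, layer = "tfidf")
}

#' Latent semantic indexing (truncated SVD) of a TF-IDF matrix
#'
#' Cell embedding = V D from the SVD of the features x cells TF-IDF matrix.
#' By convention the first LSI component tracks sequencing depth, so
#' downstream consumers use components 2..k.
#'
#' @param cm tfidf-layer \code{count_matrix}.
#' @param k number of components (capped at min(dim)).
#' @return \code{reduced_matrix} with method "lsi" and
#'   \code{component_range} 2..k.
#' @export
lsi_reduce <- function(cm, k = 40) {
  stopifnot(inherits(cm, "count_matrix"), cm$layer == "tfidf")
  m <- as.matrix(cm$values)
  k <- min(k, nrow(m), ncol(m))
  s <- svd(m, nu = k, nv = k)
  fx <- fix_signs(s$u, s$v %*% diag(s$d[seq_len(k)], k))
  emb <- fx$embedding
  rownames(emb) <- colnames(m)
  colnames(emb) <- paste0("LSI", seq_len(k))
  reduced_matrix(emb, "lsi", sdev = s$d[seq_len(k)],
                 component_range = seq(min(2L, k), k))
}

#' Per-group mean expression profiles (pseudobulks)
#'
#' @param cm lognorm-layer \code{count_matrix}.
#' @param groups named character vector: barcode -> group id. Barcodes absent
#'   from the matrix are ignored.
#' @return a \code{pseudobulk_set}: list with \code{values} (features x
#'   groups matrix of means) and \code{n_cells} (named integer vector).
#' @export
pseudobulk_mean <- function(cm, groups) {
  stopifnot(inherits(cm, "count_matrix"))
  bc <- colnames(cm$values)
  groups <- groups[names(groups) %in% bc]
  if (!length(groups)) stop("pseudobulk_mean: no matrix barcode has a group")
  gl <- sort(unique(unname(groups)))
  ind <- Matrix::sparseMatrix(i = match(names(groups), bc),
                              j = match(groups, gl), x = 1,
                              dims = c(length(bc), length(gl)))
  n_cells <- Matrix::colSums(ind)
  vals <- as.matrix(cm$values %*% ind) %*% diag(1 / n_cells, length(gl))
  dimnames(vals) <- list(rownames(cm$values), gl)
  structure(list(values = vals, n_cells = stats::setNames(as.integer(n_cells), gl)),
            class = "pseudobulk_set")
}

#' Count fragments in non-overlapping genome bins
#'
#' The genome is segmented into fixed-size bins [i*B, (i+1)*B) per
#' chromosome; a fragment contributes its count to every bin it half-open
#' overlaps. Used as the ATAC pseudobulk layer for cross-sample QC
#' (default 100,000 bp bins).
#'
#' @param fragments fragments data.frame.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin_size bin width in bp (default 100000).
#' @return named numeric vector over all bins ("chrom:start-end"), in
#'   genome order.
#' @export
bin_genome_counts <- function(fragments, chrom_sizes, bin_size = 100000) {
  stopifnot(bin_size >= 1)
  nbins <- stats::setNames(pmax(1L, as.integer(ceiling(chrom_sizes / bin_size))),
                           names(chrom_sizes))
  offsets <- stats::setNames(cumsum(c(0L, nbins[-length(nbins)])), names(nbins))
  total <- sum(nbins)
  counts <- numeric(total)
  f <- fragments[fragments$chrom %in% names(chrom_sizes), , drop = FALSE]
  if (nrow(f)) {
    b0 <- f$start %/% bin_size
    b1 <- (f$end - 1L) %/% bin_size  # last overlapped bin (end exclusive)
    span <- b1 - b0 + 1L
    idx <- offsets[f$chrom] + b0  # 0-based global index of first bin
    reps <- rep.int(seq_len(nrow(f)), span)
    bump <- sequence(span) - 1L
    gidx <- idx[reps] + bump + 1L
    add <- rowsum(as.numeric(f$count[reps]), gidx)
    counts[as.integer(rownames(add))] <- counts[as.integer(rownames(add))] + add[, 1]
  }
  starts <- unlist(lapply(nbins, function(n) (seq_len(n) - 1L) * bin_size),
                   use.names = FALSE)
  chroms <- rep(names(nbins), nbins)
  ends <- pmin(starts + bin_size, chrom_sizes[chroms])
  names(counts) <- paste0(chroms, ":", starts, "-", as.integer(ends))
  counts
}
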