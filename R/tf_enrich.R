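# TF ChIP-seq peak-overlap enrichment: for each TF peak set, a 2x2 overlap
# table of query CREs vs the rest of a background CRE universe, a one-sided
# Fisher exact test (hypergeometric upper tail), and BH-adjusted ranking.

#' 2x2 overlap table of a TF peak set against a query within a background
#'
#' A CRE "hits" the TF iff it half-open-overlaps at least one TF peak
#' (multiple overlapping peaks still count once). The table is
#' [[hits in query, misses in query], [hits in rest, misses in rest]] with
#' rest = background \\ query.
#'
#' @param query_cres interval table of query CREs (a subset of the
#'   background universe).
#' @param background_cres interval table of the background CRE universe,
#'   including the query rows (matched by chrom/start/end).
#' @param tf_peaks interval table of the TF's ChIP-seq peaks.
#' @return 2x2 integer matrix.
#' @export
overlap_counts <- function(query_cres, background_cres, tf_peaks) {
  if (nrow(query_cres) == 0) stop("overlap_counts: empty query")
  qkey <- gi_names(query_cres)
  bkey <- gi_names(background_cres)
  if (!all(qkey %in% bkey))
    stop("overlap_counts: query CREs must belong to the background universe")
  is_query <- bkey %in% qkey
  if (all(is_query)) stop("overlap_counts: background \\ query is empty")
  hit <- logical(nrow(background_cres))
  if (nrow(tf_peaks)) {
    hits <- gi_overlap_pairs(background_cres, tf_peaks)
    hit[unique(hits[, "a"])] <- TRUE
  }
  a <- sum(hit & is_query)
  b <- sum(!hit & is_query)
  c_ <- sum(hit & !is_query)
  d <- sum(!hit & !is_query)
  matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
         dimnames = list(c("query", "rest"), c("hit", "miss")))
}

#' One-sided Fisher exact enrichment of a 2x2 table
#'
#' Odds ratio is the plain cross-product ad/bc (Inf when bc = 0 and ad > 0;
#' 0 when ad = 0). The p-value is the hypergeometric upper tail
#' P(X >= a) in the enrichment direction.
#'
#' @param tab 2x2 matrix [[a, b], [c, d]] as from \code{overlap_counts}.
#' @return list(odds_ratio, pvalue).
#' @export
fisher_enrichment <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  odds <- if (a * d == 0) 0 else if (b * c_ == 0) Inf else (a * d) / (b * c_)
  # X ~ Hypergeometric(total hits a+c, total misses b+d, draws a+b)
  p <- stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
  list(odds_ratio = odds, pvalue = p)
}

#' Enrichment of every TF peak set in a query CRE set
#'
#' @param query_cres,background_cres interval tables (see
#'   \code{overlap_counts}).
#' @param tf_peak_sets named list: TF name -> interval table of peaks.
#' @return data.frame: tf, overlap_in_query, overlap_in_background,
#'   odds_ratio, pvalue, score (-log10 p), one row per TF (unranked).
#' @export
tf_enrichment <- function(query_cres, background_cres, tf_peak_sets) {
  stopifnot(length(tf_peak_sets) > 0, !is.null(names(tf_peak_sets)))
  rows <- lapply(names(tf_peak_sets), function(tf) {
    tab <- overlap_counts(query_cres, background_cres, tf_peak_sets[[tf]])
    fe <- fisher_enrichment(tab)
    data.frame(tf = tf, overlap_in_query = tab[1, 1],
               overlap_in_background = tab[1, 1] + tab[2, 1],
               odds_ratio = fe$odds_ratio, pvalue = fe$pvalue,
               score = -log10(fe$pvalue), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank TF enrichment results with BH adjustment
#'
#' Benjamini-Hochberg adjustment across TFs, sorted by adjusted p
#' ascending; ties broken by odds ratio descending, then TF name.
#'
#' @param results data.frame from \code{tf_enrichment}.
#' @return the input with an \code{adjusted_pvalue} column, re-ordered.
#' @export
rank_tfs <- function(results) {
  results$adjusted_pvalue <- stats::p.adjust(results$pvalue, method = "BH")
  ord <- order(results$adjusted_pvalue, -results$odds_ratio, results$tf)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a directory of per-TF BED files
#'
#' Each file's basename (minus the .bed extension) is the TF name.
#'
#' @param dir directory containing .bed files.
#' @return named list of interval tables.
#' @export
read_tf_peak_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  if (!length(files)) stop("read_tf_peak_dir: no .bed files in ", dir)
  sets <- lapply(files, read_bed)
  names(sets) <- sub("\\.bed$", "", basename(files))
  sets
}
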