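# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check (no GRanges, no phyper shortcuts in the
# enumeration, loop-based statistics).

# O(n^2) interval union: pairwise overlap adjacency + connected components.
brute_union <- function(df) {
  n <- nrow(df)
  if (n == 0) return(df[, c("chrom", "start", "end")])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- df$chrom[i] == df$chrom[j] &&
      df$start[i] < df$end[j] && df$end[i] > df$start[j]
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- do.call(rbind, lapply(seq_len(cid), function(k) {
    rows <- which(comp == k)
    data.frame(chrom = df$chrom[rows[1]], start = min(df$start[rows]),
               end = max(df$end[rows]), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# loop-based half-open overlap counting: peak x cell fragment count sums
brute_feature_matrix <- function(fragments, peaks, cells) {
  m <- matrix(0, nrow(peaks), length(cells))
  for (fi in seq_len(nrow(fragments))) {
    ci <- match(fragments$barcode[fi], cells)
    if (is.na(ci)) next
    for (pi in seq_len(nrow(peaks))) {
      if (fragments$chrom[fi] == peaks$chrom[pi] &&
          fragments$start[fi] < peaks$end[pi] &&
          fragments$end[fi] > peaks$start[pi])
        m[pi, ci] <- m[pi, ci] + fragments$count[fi]
    }
  }
  m
}

# exhaustive hypergeometric upper-tail for a 2x2 table [[a,b],[c,d]]
brute_fisher_p <- function(a, b, c_, d) {
  m <- a + c_   # total hits
  k <- a + b    # query size
  n <- b + d    # total misses
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 0)
  sum(probs[xs >= a])
}

# the six-criteria filter as six separately evaluated predicates
brute_cell_filter <- function(metrics, t) {
  p1 <- metrics$rna_reads > t$rna_min
  p2 <- metrics$rna_reads < t$rna_max
  p3 <- metrics$atac_reads > t$atac_min
  p4 <- metrics$atac_reads < t$atac_max
  p5 <- !is.na(metrics$nucleosome_signal) & metrics$nucleosome_signal < t$nuc_max
  p6 <- metrics$tss_enrichment > t$tss_min
  metrics$barcode[p1 & p2 & p3 & p4 & p5 & p6]
}

# direct enumeration of the tissue-specificity rule on a logical matrix
brute_tissue_specific <- function(present, tissues, target) {
  out <- integer(0)
  for (i in seq_len(nrow(present))) {
    fin <- mean(present[i, tissues == target])
    ok <- fin > 0.5
    if (ok) for (t in setdiff(unique(tissues), target))
      if (mean(present[i, tissues == t]) >= 0.5) { ok <- FALSE; break }
    if (ok) out <- c(out, i)
  }
  out
}

# adjusted Rand index between two labelings
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# partition pooled intervals into pseudo-samples whose members are pairwise
# disjoint (greedy coloring), to satisfy build_union_cres' precondition
split_into_disjoint <- function(iv) {
  n <- nrow(iv)
  bin <- integer(n)
  for (i in seq_len(n)) {
    b <- 1L
    repeat {
      members <- which(bin == b)
      clash <- any(iv$chrom[members] == iv$chrom[i] &
                     iv$start[members] < iv$end[i] &
                     iv$end[members] > iv$start[i])
      if (!clash) break
      b <- b + 1L
    }
    bin[i] <- b
  }
  sets <- lapply(seq_len(max(bin)), function(b) iv[bin == b, , drop = FALSE])
  names(sets) <- paste0("s", seq_along(sets))
  sets
}

# small random fixtures
random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 5000,
                             max_width = 200) {
  start <- sample.int(max_pos, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), start,
             start + sample.int(max_width, n, replace = TRUE))
}

random_count_matrix <- function(nf, nc, lambda = 2, prefix = "f") {
  m <- matrix(rpois(nf * nc, lambda), nf, nc,
              dimnames = list(paste0(prefix, seq_len(nf)),
                              paste0("cell", seq_len(nc))))
  count_matrix(m, layer = "raw")
}
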