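test_that("candidate_peaks: window arithmetic around the TSS", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", tss = 100000L)
  peaks <- gintervals(c("chr1", "chr1", "chr2", "chr1"),
                      c(149000L, 151000L, 149000L, 60000L),
                      c(151000L, 152000L, 151000L, 61000L))
  idx <- candidate_peaks(gene, peaks, 50000)
  # [149000,151000) intersects the window up to base 150000; [151000,...) not
  expect_true(1 %in% idx)
  expect_false(2 %in% idx)
  expect_false(3 %in% idx)  # other chromosome
  expect_true(4 %in% idx)   # within upstream window
  # bases tss-50000 .. tss+50000 inclusive: a peak ending at 50000 is out,
  # one ending at 50001 touches base 50000
  expect_false(length(candidate_peaks(gene, gintervals("chr1", 49000, 50000))) > 0)
  expect_true(length(candidate_peaks(gene, gintervals("chr1", 49000, 50001))) > 0)
})

test_that("pearson_link_score: hand values and degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_link_score(x, x), 1)
  expect_equal(pearson_link_score(x, -x + 10), -1)
  expect_equal(pearson_link_score(x, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_link_score(x, rep(2, 4))))
  expect_error(pearson_link_score(x, 1:3), "length")
  expect_error(pearson_link_score(1:2, 1:2), "3 cells")
})

test_that("matched_background selects nearest peaks in feature space", {
  pf <- function(tot, w = 500) data.frame(gc = NA_real_,
                                          log1p_total = log1p(tot),
                                          log_width = log(w))
  target <- pf(10)
  pool <- rbind(pf(9), pf(11), pf(50))
  expect_setequal(matched_background(target, pool, n = 2), c(1, 2))
  # exact duplicates come first
  pool2 <- rbind(pf(50), pf(10), pf(10))
  expect_setequal(matched_background(target, pool2, n = 2), c(2, 3))
  expect_warning(idx <- matched_background(target, pool, n = 10), "smaller")
  expect_equal(sort(idx), 1:3)
  expect_error(matched_background(target, pool[0, ], n = 2), "empty")
  # gc used when available on both sides
  t2 <- data.frame(gc = 0.5, log1p_total = log1p(10), log_width = log(500))
  p3 <- data.frame(gc = c(0.5, 0.9), log1p_total = log1p(c(10, 10)),
                   log_width = log(c(500, 500)))
  expect_equal(matched_background(t2, p3, n = 1), 1L)
})

test_that("linkage_ztest: z and upper-tail p", {
  bg <- c(-0.1, 0, 0.1)
  zt <- linkage_ztest(mean(bg), bg)
  expect_equal(zt$zscore, 0)
  expect_equal(zt$pvalue, 0.5)
  # sd of {-0.1, 0.1} = sqrt(0.02); z = 0.5/sqrt(0.02)
  zt2 <- linkage_ztest(0.5, c(-0.1, 0.1))
  expect_equal(zt2$zscore, 0.5 / sqrt(0.02), tolerance = 1e-12)
  # bg mean exactly 0, sd exactly 0.1 -> z = 5, p = upper normal tail
  bg5 <- scale(rnorm(100))[, 1] * 0.1
  zt3 <- linkage_ztest(0.5, bg5)
  expect_equal(zt3$zscore, 5, tolerance = 1e-9)
  expect_equal(zt3$pvalue, 2.866516e-07, tolerance = 1e-4)
  # sd = 0 -> skipped
  expect_true(is.na(linkage_ztest(0.5, rep(0.2, 10))$zscore))
  expect_error(linkage_ztest(0.5, 0.1), "at least 2")
  # monotonicity: higher r_obs gives higher z
  bg2 <- rnorm(50, 0, 0.05)
  z_lo <- linkage_ztest(0.2, bg2)$zscore
  z_hi <- linkage_ztest(0.6, bg2)$zscore
  expect_gt(z_hi, z_lo)
})

make_link_fixture <- function(n_cells = 200, n_null_peaks = 60, seed = 77,
                              r_target = 0.6) {
  set.seed(seed)
  genes <- data.frame(gene_id = "gene1", chrom = "chr1", start = 100000L,
                      end = 110000L, strand = "+", tss = 100000L,
                      stringsAsFactors = FALSE)
  # peak 1 near the TSS (the candidate); null peaks far away
  peaks <- gintervals("chr1",
                      c(120000L, 300000L + (seq_len(n_null_peaks) - 1L) * 2000L),
                      c(120500L, 300400L + (seq_len(n_null_peaks) - 1L) * 2000L))
  a <- rlnorm(n_cells, 0, 0.6)
  expr_counts <- rpois(n_cells, 8 * a)
  linked_counts <- rpois(n_cells, 5 * a^1.6)
  null_counts <- t(sapply(seq_len(n_null_peaks), function(i)
    rpois(n_cells, 5 * rlnorm(n_cells, 0, 0.6))))
  # a constitutive housekeeping gene keeps every cell total positive
  rna <- rbind(gene1 = expr_counts, hk = rpois(n_cells, 50))
  colnames(rna) <- paste0("c", 1:n_cells)
  atac <- rbind(linked_counts, null_counts)
  dimnames(atac) <- list(gi_names(peaks), paste0("c", 1:n_cells))
  list(rna = lognormalize(count_matrix(rna, "raw")),
       atac = count_matrix(atac, "raw"), genes = genes, peaks = peaks)
}

test_that("link_peaks retains a planted link and respects filters", {
  fx <- make_link_fixture()
  cfg <- linkage_config(n_background = 50, seed = 3)
  links <- link_peaks(fx$rna, fx$atac, fx$genes, fx$peaks, cfg, "s1")
  expect_equal(nrow(links), 1)
  expect_equal(links$start, 120000L)
  expect_gt(links$zscore, 3)
  expect_gt(links$score, 0.4)
  expect_equal(links$sample_id, "s1")

  # gene with no peaks within 50 kb -> no records
  far_genes <- fx$genes; far_genes$tss <- 900000L; far_genes$start <- 900000L
  far_genes$end <- 910000L
  expect_warning(none <- link_peaks(fx$rna, fx$atac, far_genes, fx$peaks,
                                    cfg, "s1"), "no significant|no genes")
  expect_equal(nrow(none), 0)
})

test_that("link_peaks is byte-deterministic under a fixed seed", {
  fx <- make_link_fixture(seed = 123)
  cfg <- linkage_config(n_background = 40, seed = 11)
  l1 <- link_peaks(fx$rna, fx$atac, fx$genes, fx$peaks, cfg, "s1")
  l2 <- link_peaks(fx$rna, fx$atac, fx$genes, fx$peaks, cfg, "s1")
  expect_identical(serialize(l1, NULL), serialize(l2, NULL))
})

test_that("planted links are recovered across replicates (power, scaled down)", {
  # scaled-down version of the full acceptance run (20 replicates here)
  set.seed(42)
  hits <- 0L
  for (rep in 1:20) {
    fx <- make_link_fixture(n_cells = 300, n_null_peaks = 50,
                            seed = 1000 + rep)
    links <- link_peaks(fx$rna, fx$atac, fx$genes, fx$peaks,
                        linkage_config(n_background = 50, seed = rep), "s")
    if (nrow(links) >= 1 && any(links$start == 120000L &
                                  links$pvalue < 0.05 &
                                  abs(links$score) > 0.05))
      hits <- hits + 1L
  }
  expect_gte(hits, 19)
})
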