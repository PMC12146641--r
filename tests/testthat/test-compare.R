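test_that("build_union_cres merges transitively but not bookended", {
  ps <- list(s1 = gintervals("chr1", c(100L, 250L, 400L),
                             c(200L, 350L, 500L)),
             s2 = gintervals("chr1", 150L, 250L))
  um <- build_union_cres(ps)
  # [100,200)+[150,250) merge; [250,350) is bookended at 250 -> separate
  expect_equal(um$union_cres$start, c(100L, 250L, 400L))
  expect_equal(um$union_cres$end, c(250L, 350L, 500L))
  # every peak maps to exactly one containing union CRE
  expect_equal(nrow(um$mapping), 4)
  expect_equal(um$mapping$cre_index[um$mapping$peak_start == 250], 2L)

  # disjoint inputs: union equals input set
  dj <- list(a = gintervals("chr2", c(0L, 1000L), c(100L, 1100L)))
  um2 <- build_union_cres(dj)
  expect_equal(um2$union_cres$start, c(0L, 1000L))

  expect_error(build_union_cres(ps, species = c(s1 = "human", s2 = "mouse")),
               "species")
})

test_that("union construction equals the O(n^2) oracle and is idempotent", {
  set.seed(55)
  for (rep in 1:8) {
    n <- sample(50:200, 1)
    iv <- random_intervals(n, max_pos = 3000, max_width = 150)
    iv <- iv[!duplicated(gi_names(iv)), ]
    # oracle works on the pooled set; split it into fake per-sample disjoint
    # sets so the within-sample disjointness precondition holds
    um <- build_union_cres(split_into_disjoint(iv))
    oracle <- brute_union(iv)
    expect_equal(um$union_cres$chrom, oracle$chrom)
    expect_equal(um$union_cres$start, oracle$start)
    expect_equal(um$union_cres$end, oracle$end)
    # idempotence: merging the union returns it unchanged
    again <- build_union_cres(list(u = um$union_cres))
    expect_equal(again$union_cres$start, um$union_cres$start)
    expect_equal(again$union_cres$end, um$union_cres$end)
    # totality + uniqueness
    expect_equal(nrow(um$mapping), nrow(iv))
    expect_false(anyNA(um$mapping$cre_index))
  }
})

test_that("remap_linkages replaces peaks and collapses duplicates by min p", {
  ps <- list(s1 = gintervals("chr1", c(100L, 210L), c(200L, 300L)))
  # note: [100,200) and [210,300) are disjoint within s1 but both fall into
  # union CREs; add an s2 peak bridging them so they merge
  ps$s2 <- gintervals("chr1", 150L, 260L)
  um <- build_union_cres(ps)
  expect_equal(nrow(um$union_cres), 1)
  links <- data.frame(gene_id = "gA", chrom = "chr1",
                      start = c(100L, 210L), end = c(200L, 300L),
                      score = c(0.5, 0.7), zscore = c(3, 4),
                      pvalue = c(0.01, 0.001), sample_id = "s1",
                      stringsAsFactors = FALSE)
  rm_ <- remap_linkages(links, um)
  expect_equal(nrow(rm_), 1)
  expect_equal(rm_$pvalue, 0.001)  # min-p row kept
  expect_equal(rm_$cre_index, 1L)

  expect_equal(nrow(remap_linkages(links[0, ], um)), 0)
  bad <- links; bad$start[1] <- 999999L; bad$end[1] <- 1000100L
  expect_error(remap_linkages(bad, um), "unmapped")
})

test_that("tissue_presence_distribution counts distinct linkages per tissue", {
  tissue_of <- c(h1 = "heart", h2 = "heart", b1 = "brain", l1 = "liver")
  rm_ <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g3"),
    cre_index = c(1L, 1L, 2L, 3L, 3L, 3L),
    sample_id = c("h1", "h2", "b1", "h1", "b1", "l1"),
    score = 0.5, zscore = 3, pvalue = 0.01, stringsAsFactors = FALSE)
  hist <- tissue_presence_distribution(rm_, tissue_of)
  # g1:1 tissue (heart, 2 samples), g2:1, g3:3 -> {1:2, 3:1}
  expect_equal(hist$n_tissues, c(1L, 3L))
  expect_equal(hist$count, c(2L, 1L))
  expect_equal(hist$fraction, c(2 / 3, 1 / 3))
  expect_equal(hist$cumulative_fraction[2], 1)
  expect_equal(sum(hist$count), 3)  # sums to distinct (gene, CRE) keys

  # single-tissue corpus: all mass at k = 1
  h2 <- tissue_presence_distribution(rm_, c(h1 = "x", h2 = "x", b1 = "x",
                                            l1 = "x"))
  expect_equal(h2$n_tissues, 1L)
  expect_error(tissue_presence_distribution(rm_, c(h1 = "heart")), "tissue")
})

test_that("gene_linked_cre_matrix rows are position-ordered; empty gene ok", {
  ps <- list(s1 = gintervals("chr1", c(500L, 100L), c(600L, 200L)))
  um <- build_union_cres(ps)
  rm_ <- data.frame(gene_id = "gA", cre_index = c(2L, 1L),
                    sample_id = c("s1", "s2"), score = c(0.4, 0.6),
                    zscore = 3, pvalue = 0.01, stringsAsFactors = FALSE)
  pm <- gene_linked_cre_matrix("gA", c("s1", "s2"), um, rm_)
  expect_equal(rownames(pm$scores), c("chr1:100-200", "chr1:500-600"))
  expect_true(all(diff(pm$cres$start) > 0))
  expect_equal(pm$scores["chr1:500-600", "s1"],
               rm_$score[rm_$cre_index == 2])
  expect_equal(sum(pm$present), 2)

  pm0 <- gene_linked_cre_matrix("nope", c("s1"), um, rm_)
  expect_equal(nrow(pm0$scores), 0)
})

test_that("restrict_to_celltype keeps only overlapping linkage peaks", {
  links <- data.frame(gene_id = "g", chrom = "chr1",
                      start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
                      score = 0.5, zscore = 3, pvalue = 0.01,
                      sample_id = "s1", stringsAsFactors = FALSE)
  ct <- gintervals("chr1", c(150L, 400L), c(250L, 450L))
  kept <- restrict_to_celltype(links, ct)
  # [100,200) overlaps [150,250); [300,400) is bookended to [400,450) -> drop
  expect_equal(kept$start, 100L)
  expect_equal(nrow(restrict_to_celltype(links, ct[0, ])), 0)
  # identical peak kept
  expect_equal(nrow(restrict_to_celltype(links,
                                         gintervals("chr1", 500L, 600L))), 1)
})

test_that("tissue_specific_cres: strict inequality edge cases", {
  um <- build_union_cres(list(s = gintervals("chr1", c(0L, 100L, 200L),
                                             c(50L, 150L, 250L))))
  tissue_of <- c(H1 = "heart", H2 = "heart", B1 = "brain", B2 = "brain")
  mk <- function(present) {
    rows <- which(present, arr.ind = TRUE)
    data.frame(gene_id = "g", cre_index = rows[, 1],
               sample_id = colnames(present)[rows[, 2]], score = 0.5,
               zscore = 3, pvalue = 0.01, stringsAsFactors = FALSE)
  }
  pres <- matrix(FALSE, 3, 4, dimnames = list(NULL, names(tissue_of)))
  pres[1, c("H1", "H2")] <- TRUE                 # heart-specific
  pres[2, c("H1", "H2", "B1")] <- TRUE           # brain fraction 1/2: fails
  pres[3, ] <- TRUE                              # ubiquitous
  pm <- gene_linked_cre_matrix("g", names(tissue_of), um, mk(pres),
                               tissue_of = tissue_of)
  got <- tissue_specific_cres(pm, tissue_spec_rule("heart"))
  expect_equal(got, 1L)
  expect_error(tissue_specific_cres(pm, tissue_spec_rule("kidney")),
               "unknown tissue")
})

test_that("tissue rule matches exhaustive enumeration on random matrices", {
  # scaled-down version of the acceptance fuzz (200 matrices here)
  set.seed(66)
  tissues <- c("a", "a", "b", "b", "b", "c")
  samples <- paste0("s", seq_along(tissues))
  for (rep in 1:200) {
    present <- matrix(runif(5 * 6) < 0.5, 5, 6,
                      dimnames = list(NULL, samples))
    pm <- structure(list(present = present, cre_index = 1:5),
                    class = "presence_matrix")
    target <- sample(unique(tissues), 1)
    got <- tissue_specific_cres(pm, tissue_spec_rule(target),
                                tissue_of = setNames(tissues, samples))
    expect_identical(got, brute_tissue_specific(present, tissues, target))
  }
})

test_that("region_view: depth normalization, flanks, empty groups", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 20000L,
                      end = 30000L, strand = "+", tss = 20000L,
                      stringsAsFactors = FALSE)
  frA <- data.frame(chrom = "chr1", start = c(21000L, 25000L),
                    end = c(21500L, 25200L), barcode = "A", count = 1L,
                    stringsAsFactors = FALSE)
  frB <- frA; frB$barcode <- "B"; frB$count <- 2L
  groups <- c(A = "grpA", B = "grpB", C = "grpC")
  peaks <- gintervals("chr1", 21000L, 21500L)
  rv <- region_view("g1", genes, rbind(frA, frB), groups, peaks,
                    empty_linkage_table(), flank = 10000, bin_size = 100)
  expect_equal(rv$window$start, 10000L)
  expect_equal(rv$window$end, 40000L)
  # identical fragments with doubled counts -> identical normalized tracks
  expect_equal(rv$coverage$grpA, rv$coverage$grpB, tolerance = 1e-12)
  # group with no fragments -> all-zero track
  expect_true(all(rv$coverage$grpC == 0))
  # flank = 0 -> window equals gene body
  rv0 <- region_view("g1", genes, frA, groups, peaks,
                     empty_linkage_table(), flank = 0)
  expect_equal(rv0$window$start, 20000L)
  expect_equal(rv0$window$end, 30000L)
  expect_error(region_view("zz", genes, frA, groups, peaks,
                           empty_linkage_table()), "not in annotation")

  d <- withr::local_tempdir()
  write_region_view(rv, d)
  expect_true(file.exists(file.path(d, "coverage_grpA.bedGraph")))
  expect_true(file.exists(file.path(d, "cres.bed")))
})
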