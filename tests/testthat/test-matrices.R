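test_that("lognormalize: closed form, zeros, symmetry, monotonicity", {
  m <- matrix(c(9, 0, 3, 3), nrow = 2,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  ln <- lognormalize(count_matrix(m, "raw"))
  expect_equal(ln$values["g1", "A"], log(10001), tolerance = 1e-12)
  expect_equal(ln$values["g2", "A"], 0)  # zeros preserved
  # all-equal column stays all-equal
  expect_equal(ln$values["g1", "B"], ln$values["g2", "B"])
  expect_equal(ln$layer, "lognorm")
  # strictly monotone in v at fixed total
  v <- as.matrix(lognormalize(count_matrix(
    matrix(c(1, 2, 7), 3, dimnames = list(paste0("g", 1:3), "A")),
    "raw"))$values)
  expect_true(all(diff(v[, 1]) > 0))

  zero <- matrix(c(1, 0), 2, 1, dimnames = list(c("a", "b"), "dead"))
  zero[1, 1] <- 0
  expect_error(lognormalize(count_matrix(zero, "raw")), "dead")
})

test_that("select_variable_features ranks by variance with stable ties", {
  m <- matrix(0, 4, 4, dimnames = list(c("flat", "hi", "mid", "mid2"),
                                       paste0("c", 1:4)))
  m["hi", ] <- c(0, 9, 0, 9)
  m["mid", ] <- c(0, 3, 0, 3)
  m["mid2", ] <- c(3, 0, 3, 0)  # same variance as mid -> list order wins
  cm <- count_matrix(m, "raw")
  expect_equal(select_variable_features(cm, 2), c("hi", "mid"))
  expect_equal(select_variable_features(cm, 4),
               c("hi", "mid", "mid2", "flat"))
  expect_error(select_variable_features(cm, 0), "positive")
  expect_error(select_variable_features(cm, 9), "exceeds")
})

test_that("scale_features standardizes rows and is idempotent", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "flat"), paste0("c", 1:3)))
  sc <- scale_features(count_matrix(m, "raw"))
  expect_equal(mean(sc$values["a", ]), 0, tolerance = 1e-12)
  expect_equal(sd(sc$values["a", ]), 1, tolerance = 1e-12)
  expect_equal(unname(sc$values["flat", ]), c(0, 0, 0))
  twice <- scale_features(sc)
  expect_equal(twice$values, sc$values, tolerance = 1e-12)
})

test_that("pca_reduce matches dense eigendecomposition and is deterministic", {
  set.seed(5)
  m <- matrix(rnorm(100), 10, 10,
              dimnames = list(paste0("f", 1:10), paste0("c", 1:10)))
  sc <- scale_features(count_matrix(m, layer = "lognorm"))
  red <- pca_reduce(sc, k = 4)
  # oracle: eigendecomposition of the cell-cell covariance of scaled data
  X <- t(as.matrix(sc$values))
  ev <- eigen(crossprod(scale(X, center = TRUE, scale = FALSE)) /
                (nrow(X) - 1))
  # compare explained variance spectra (sign/rotation free)
  expect_equal(red$sdev^2, ev$values[1:4], tolerance = 1e-6)
  # embedding reproduces pairwise cell distances in top-k space
  expect_equal(abs(cor(red$embedding[, 1], X %*% ev$vectors[, 1])[1, 1]), 1,
               tolerance = 1e-6)
  expect_identical(pca_reduce(sc, k = 4)$embedding, red$embedding)

  # rank-1 data: first component carries ~all variance
  r1 <- outer(rnorm(6), rnorm(8))
  dimnames(r1) <- list(paste0("f", 1:6), paste0("c", 1:8))
  red1 <- pca_reduce(count_matrix(r1 - rowMeans(r1), layer = "scaled"), k = 3)
  expect_gt(red1$sdev[1]^2 / sum(red1$sdev^2), 0.999)
})

test_that("feature_matrix: half-open overlap semantics and brute-force equality", {
  peaks <- gintervals("chr1", c(100, 300), c(200, 400))
  fr <- data.frame(chrom = "chr1",
                   start = c(10L, 10L, 150L, 190L),
                   end = c(110L, 100L, 350L, 200L),
                   barcode = c("A", "A", "A", "B"),
                   count = c(1L, 5L, 2L, 3L), stringsAsFactors = FALSE)
  fm <- feature_matrix(fr, peaks, c("A", "B"))
  # [10,110) overlaps [100,200); [10,100) is bookended and does not;
  # [150,350) spans both peaks
  expect_equal(unname(as.matrix(fm$values)), matrix(c(3, 2, 3, 0), 2))
  # fragment [150,350) spans both peaks, counted once in each
  expect_equal(fm$values["chr1:300-400", "A"], 2)

  set.seed(33)
  for (rep in 1:5) {
    peaks2 <- random_intervals(8, chroms = "chrQ", max_pos = 900)
    peaks2 <- peaks2[!duplicated(gi_names(peaks2)), ]
    cells <- c("A", "B", "C")
    fr2 <- data.frame(chrom = "chrQ", start = sample.int(1000, 40),
                      end = 0L, barcode = sample(c(cells, "ZZ"), 40, TRUE),
                      count = sample.int(3, 40, TRUE))
    fr2$end <- fr2$start + sample.int(150, 40)
    got <- as.matrix(feature_matrix(fr2, peaks2, cells)$values)
    expect_equal(unname(got), brute_feature_matrix(fr2, peaks2, cells))
  }
})

test_that("filter_top_features uses >= min_cutoff semantics", {
  m <- matrix(c(4, 0, 5, 0, 6, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("p4", "p5", "p6"), c("A", "B")))
  kept <- filter_top_features(count_matrix(m, "raw"), min_cutoff = 5)
  expect_equal(rownames(kept$values), c("p5", "p6"))
  empty <- filter_top_features(count_matrix(m[0, , drop = FALSE], "raw"))
  expect_equal(nrow(empty$values), 0)
})

test_that("tfidf: closed form, zero preservation, column symmetry", {
  m1 <- matrix(4, 1, 1, dimnames = list("p", "A"))
  tf1 <- tfidf(count_matrix(m1, "raw"))
  expect_equal(tf1$values["p", "A"], log1p(2500), tolerance = 1e-12)

  m2 <- matrix(c(2, 0, 2, 1), 2, dimnames = list(c("p1", "p2"), c("A", "B")))
  tf2 <- tfidf(count_matrix(m2, "raw"))
  expect_equal(tf2$values["p2", "A"], 0)
  # two identical cells get identical columns
  m3 <- matrix(c(3, 1, 3, 1), 2, dimnames = list(c("p1", "p2"), c("A", "B")))
  tf3 <- as.matrix(tfidf(count_matrix(m3, "raw"))$values)
  expect_equal(tf3[, "A"], tf3[, "B"])

  m4 <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("p1", "p2"), c("A", "B")))
  expect_error(tfidf(count_matrix(m4, "raw")), "zero-total|zero-count")
})

test_that("lsi_reduce matches dense SVD on a small fixture", {
  set.seed(9)
  m <- matrix(rpois(48, 3), 8, 6,
              dimnames = list(paste0("p", 1:8), paste0("c", 1:6)))
  m[1, ] <- m[1, ] + 1  # no zero rows/cols
  tf <- tfidf(count_matrix(m, "raw"))
  red <- lsi_reduce(tf, k = 4)
  s <- svd(as.matrix(tf$values))
  expect_equal(red$sdev, s$d[1:4], tolerance = 1e-9)
  expect_true(all(diff(red$sdev) <= 1e-12))  # non-increasing
  expect_equal(ncol(red$embedding), 4)
  expect_equal(red$component_range, 2:4)
  for (j in 1:4)
    expect_equal(abs(cor(red$embedding[, j], s$v[, j])), 1, tolerance = 1e-9)
})

test_that("pseudobulk_mean equals the loop oracle and is permutation invariant", {
  set.seed(12)
  cm <- lognormalize(random_count_matrix(20, 30))
  groups <- setNames(sample(c("x", "y", "z"), 30, TRUE),
                     colnames(cm$values))
  pb <- pseudobulk_mean(cm, groups)
  for (g in c("x", "y", "z")) {
    cols <- names(groups)[groups == g]
    oracle <- rowMeans(as.matrix(cm$values[, cols, drop = FALSE]))
    expect_equal(pb$values[, g], oracle, tolerance = 1e-12)
    expect_equal(unname(pb$n_cells[g]), length(cols))
  }
  perm <- sample(30)
  cm2 <- count_matrix(cm$values[, perm], "lognorm")
  pb2 <- pseudobulk_mean(cm2, groups)
  expect_equal(pb2$values, pb$values, tolerance = 1e-12)

  # single-cell group returns that cell's vector
  solo <- pseudobulk_mean(cm, setNames("solo", colnames(cm$values)[1]))
  expect_equal(solo$values[, "solo"], as.numeric(cm$values[, 1]),
               ignore_attr = TRUE)
})

test_that("bin_genome_counts assigns fragments to every overlapped bin", {
  cs <- c(chr1 = 250000L)
  fr <- data.frame(chrom = "chr1", start = c(99950L, 0L, 100L),
                   end = c(100050L, 100L, 200L), barcode = "A",
                   count = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  bins <- bin_genome_counts(fr, cs, bin_size = 100000)
  expect_equal(length(bins), 3)
  # boundary-spanning fragment counted in bins 0 and 1
  expect_equal(unname(bins), c(1 + 2 + 1, 1, 0))
  expect_equal(names(bins)[1], "chr1:0-100000")

  # total contribution = count x number of overlapped bins (brute force)
  set.seed(21)
  fr2 <- data.frame(chrom = "chr1", start = sample.int(240000, 50),
                    end = 0L, barcode = "A", count = sample.int(4, 50, TRUE))
  fr2$end <- pmin(fr2$start + sample.int(20000, 50), 250000L)
  bins2 <- bin_genome_counts(fr2, cs, bin_size = 100000)
  nbins_per_frag <- (pmin(fr2$end - 1, 249999) %/% 1e5) - (fr2$start %/% 1e5) + 1
  expect_equal(sum(bins2), sum(fr2$count * nbins_per_frag))
})
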