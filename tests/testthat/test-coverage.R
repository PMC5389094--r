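# Coverage tracks, metagene and peak-centred matrices, peak-length
# summaries and the rank-sum machinery.

test_that("RPKM arithmetic on a single bin matches the closed form", {
  reads <- tibble::tibble(chrom = "chr1", start = rep(2, 1000),
                          end = rep(9, 1000))
  tr <- binned_coverage(reads, c(chr1 = 10), bin_size = 10,
                        library_size = 1e6, mode = "RPKM")
  expect_equal(tr$values$chr1[1], 1000 / (0.01 * 1))
})

test_that("zero reads give an all-zero track and doubling the library halves RPKM", {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  tr0 <- binned_coverage(empty, c(chr1 = 100), library_size = 1e6)
  expect_true(all(tr0$values$chr1 == 0))
  reads <- tibble::tibble(chrom = "chr1", start = c(0, 15, 33),
                          end = c(60, 80, 90))
  t1 <- binned_coverage(reads, c(chr1 = 100), library_size = 1e6)
  t2 <- binned_coverage(reads, c(chr1 = 100), library_size = 2e6)
  expect_equal(t1$values$chr1, 2 * t2$values$chr1)
})

test_that("reads beyond the chromosome end are clipped with a warning", {
  reads <- tibble::tibble(chrom = "chr1", start = 90, end = 150)
  expect_warning(tr <- binned_coverage(reads, c(chr1 = 100),
                                       library_size = 1e6, mode = "RPM"),
                 "clipped")
  expect_equal(sum(tr$values$chr1 > 0), 1)
})

test_that("raw binned counts conserve total read-bin overlap count", {
  set.seed(31)
  reads <- tibble::tibble(chrom = "chr1",
                          start = sample(0:900, 200, replace = TRUE))
  reads$end <- reads$start + 35
  tr <- binned_coverage(reads, c(chr1 = 1000), bin_size = 10, mode = "raw")
  bins <- tibble::tibble(chrom = "chr1", start = seq(0, 990, 10),
                         end = seq(10, 1000, 10))
  manual <- 0
  for (i in seq_len(nrow(bins))) {
    manual <- manual + sum(reads$start < bins$end[i] & reads$end > bins$start[i])
  }
  expect_equal(sum(tr$values$chr1), manual)
})

test_that("constant coverage yields a constant metagene matrix (exact)", {
  genes <- toy_genes()
  tr <- flat_track(3.5, c(chr1 = 1e5, chr2 = 1e5))
  mm <- metagene_matrix(tr, genes, body_bins = 40, flank_bp = 500,
                        flank_bins = 20)
  expect_true(all(mm$matrix == 3.5))
  expect_equal(ncol(mm$matrix), 80)
})

test_that("a coverage step at the TSS appears at the left edge for minus-strand genes", {
  # minus-strand gene: TSS at its end coordinate; put high coverage inside
  # the gene, zero outside
  genes <- gene_regions(tibble::tibble(
    gene_id = "gm", chrom = "chr1", start = 5000, end = 7000, strand = "-"),
    chrom_length = 2e4)
  vals <- rep(0, 2000)
  vals[(5000 / 10 + 1):(7000 / 10)] <- 10
  tr <- structure(list(values = list(chr1 = vals), bin_size = 10,
                       mode = "RPM", chrom_sizes = c(chr1 = 2e4),
                       library_size = 1e6), class = "coverage_track")
  mm <- metagene_matrix(tr, genes, body_bins = 20, flank_bp = 1000,
                        flank_bins = 10)
  row <- mm$matrix[1, ]
  expect_true(all(row[1:10] == 0))         # upstream flank (beyond TSS) empty
  expect_true(all(row[11:30] == 10))       # body full
  expect_true(all(row[31:40] == 0))        # downstream flank empty
})

test_that("mirroring coordinates and flipping strands preserves the mean profile", {
  set.seed(77)
  L <- 50000
  genes <- gene_regions(tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(10000, 30000), end = c(14000, 33000),
    strand = c("+", "-")), chrom_length = L)
  vals <- runif(L / 10)
  tr <- structure(list(values = list(chr1 = vals), bin_size = 10,
                       mode = "RPM", chrom_sizes = c(chr1 = L),
                       library_size = 1e6), class = "coverage_track")
  mm <- metagene_matrix(tr, genes, body_bins = 30, flank_bp = 800,
                        flank_bins = 16)
  # mirrored genome: x -> L - x, strands flipped, same coverage mirrored
  genes_m <- gene_regions(tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = L - c(14000, 33000), end = L - c(10000, 30000),
    strand = c("-", "+")), chrom_length = L)
  tr_m <- structure(list(values = list(chr1 = rev(vals)), bin_size = 10,
                         mode = "RPM", chrom_sizes = c(chr1 = L),
                         library_size = 1e6), class = "coverage_track")
  mm_m <- metagene_matrix(tr_m, genes_m, body_bins = 30, flank_bp = 800,
                          flank_bins = 16)
  expect_equal(colMeans(mm$matrix), colMeans(mm_m$matrix), tolerance = 1e-10)
})

test_that("peak-centred matrices: uniform coverage gives a constant matrix, flank 0 one column", {
  tr <- flat_track(2, c(chr1 = 1e4))
  pks <- tibble::tibble(peak_id = c("p1", "p2"), chrom = "chr1",
                        start = c(2000, 6000), end = c(2400, 6800))
  m <- peak_center_matrix(tr, pks, flank_bp = 500, bins = 20)
  expect_true(all(m$matrix == 2))
  m0 <- peak_center_matrix(tr, pks, flank_bp = 0)
  expect_equal(dim(m0$matrix), c(2, 1))
  expect_true(all(m0$matrix == 2))
})

test_that("symmetric synthetic peaks give near-symmetric center profiles", {
  set.seed(55)
  # reads drawn symmetrically around a center
  center <- 5000
  n <- 4000
  starts <- round(center + rnorm(n, 0, 300)) - 50
  reads <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 100)
  tr <- binned_coverage(reads, c(chr1 = 1e4), bin_size = 10,
                        library_size = 1e6, mode = "RPM")
  pks <- tibble::tibble(peak_id = "p", chrom = "chr1",
                        start = center - 400, end = center + 400)
  m <- peak_center_matrix(tr, pks, flank_bp = 800, bins = 40)
  prof <- m$matrix[1, ]
  asym <- sum(abs(prof - rev(prof))) / sum(prof)
  expect_lt(asym, 0.15)
})

test_that("rank-sum exact p matches brute-force enumeration for n1, n2 <= 8", {
  set.seed(101)
  for (n1 in c(1, 2, 3, 5, 8)) {
    for (n2 in c(1, 3, 6, 8)) {
      x <- sample(1:6, n1, replace = TRUE)   # ties likely
      y <- sample(1:6, n2, replace = TRUE)
      got <- rank_sum_test(x, y)
      expect_equal(got$p_value, oracle_ranksum_p(x, y), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("rank-sum exact mode agrees with stats::wilcox.test without ties", {
  set.seed(33)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(7)
    got <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(got$p_value, ref, tolerance = 1e-10)
  }
})

test_that("documented exact examples hold", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("normal approximation is within 0.02 of exact at n = 8 vs 8", {
  set.seed(202)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    exact <- rank_sum_test(x, y, exact_max = 8)$p_value
    approx <- rank_sum_test(x, y, exact_max = 0)$p_value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("peak length summary reports means, medians and the comparison", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = c(500, 700, 600))
  b <- tibble::tibble(chrom = "chr1", start = 0, end = c(1500, 1900, 1700))
  res <- peak_length_summary(a, b)
  expect_equal(res$summary$mean, c(600, 1700))
  expect_lt(res$p_value, 0.11)
  expect_error(peak_length_summary(a[0, ], b), "non-empty")
})

test_that("coverage comparison identities: identical matrices and global doubling", {
  genes <- toy_genes()
  tr <- flat_track(4, c(chr1 = 1e5, chr2 = 1e5))
  m1 <- metagene_matrix(tr, genes, body_bins = 10, flank_bp = 200,
                        flank_bins = 5)
  cmp <- compare_coverage(m1, m1)
  expect_equal(cmp$median_ratio, 1)
  expect_equal(cmp$p_value, 1)
  tr2 <- flat_track(8, c(chr1 = 1e5, chr2 = 1e5))
  m2 <- metagene_matrix(tr2, genes, body_bins = 10, flank_bp = 200,
                        flank_bins = 5)
  expect_equal(compare_coverage(m1, m2)$median_ratio, 2)
  bad <- m2; bad$row_ids <- c("x", "y", "z")
  expect_error(compare_coverage(m1, bad), "aligned")
})
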