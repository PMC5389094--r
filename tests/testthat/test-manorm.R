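# Constrained-MAnorm quantitative comparison: matching, M-A transform,
# reference selection, robust rescaling, the binomial test, retention
# classes, replicate intersection and gene-level assignment.

test_that("identical peak sets match into common regions equal to the peaks", {
  pks <- tibble::tibble(chrom = "chr1", start = c(100, 500), end = c(200, 800))
  reads <- tibble::tibble(chrom = "chr1", start = c(120, 600, 700),
                          end = c(220, 700, 800))
  rec <- match_common_peaks(pks, pks, reads, reads, 1e6, 1e6)
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$is_common))
  expect_equal(rec$start, c(100, 500))
  expect_equal(rec$wt_count, rec$mut_count)
})

test_that("WT-only peaks are kept non-common with mutant counts still computed", {
  pks_wt <- tibble::tibble(chrom = "chr1", start = c(100, 5000),
                           end = c(600, 5400))
  pks_mut <- tibble::tibble(chrom = "chr1", start = 100, end = 600)
  reads_mut <- tibble::tibble(chrom = "chr1", start = c(150, 5100),
                              end = c(250, 5200))
  reads_wt <- reads_mut
  rec <- match_common_peaks(pks_wt, pks_mut, reads_wt, reads_mut, 1e6, 1e6)
  expect_equal(rec$is_common, c(TRUE, FALSE))
  expect_equal(rec$mut_count[2], 1)
})

test_that("overlapping mutant peaks merge into a single union region", {
  pks_wt <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000)
  pks_mut <- tibble::tibble(chrom = "chr1", start = c(800, 1800),
                            end = c(1200, 2500))
  rd <- tibble::tibble(chrom = "chr1", start = 1000, end = 1100)
  rec <- match_common_peaks(pks_wt, pks_mut, rd, rd, 1e6, 1e6)
  # interval-union oracle: [800,1200) u [1000,2000) u [1800,2500) = [800,2500)
  expect_equal(nrow(rec), 1)
  expect_equal(c(rec$start, rec$end), c(800, 2500))
})

test_that("mutant-only regions are excluded from the universe", {
  pks_wt <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  pks_mut <- tibble::tibble(chrom = "chr1", start = c(100, 9000),
                            end = c(200, 9500))
  rd <- tibble::tibble(chrom = "chr1", start = 110, end = 190)
  rec <- match_common_peaks(pks_wt, pks_mut, rd, rd, 1e6, 1e6)
  expect_equal(nrow(rec), 1)
})

test_that("M-A transform: equal intensities give M = 0; quarter intensity M = -2; swap antisymmetry", {
  rec <- records_from_counts(c(100, 400), c(100, 100))
  ma <- ma_transform(rec, 1e6, 1e6)
  expect_equal(ma$M[1], 0)
  expect_equal(ma$M[2], -2)
  swapped <- records_from_counts(c(100, 100), c(100, 400))
  ma_sw <- ma_transform(swapped, 1e6, 1e6)
  expect_equal(ma_sw$M, -ma$M)
  expect_equal(ma_sw$A, ma$A)
  # zero counts handled through the pseudocount floor
  z <- ma_transform(records_from_counts(0, 50), 1e6, 1e6)
  expect_true(is.finite(z$M) && is.finite(z$A))
  expect_error(ma_transform(rec, Inf, 1e6), "finite")
})

test_that("reference window is inclusive and DEG exclusion removes linked genes", {
  rec <- records_from_counts(c(100, 100, 100, 100), c(100, 80, 79, 120))
  links <- tibble::tibble(peak_id = rec$region_id,
                          gene_id = c("g1", "g2", "g3", "g4"),
                          link_class = "gene body")
  sel <- select_reference_peaks(rec, links = links, deg_genes = character(),
                                min_reference = 1)
  expect_equal(sel$is_reference, c(TRUE, TRUE, FALSE, TRUE))
  sel2 <- select_reference_peaks(rec, links = links, deg_genes = "g1",
                                 min_reference = 1)
  expect_equal(sel2$is_reference, c(FALSE, TRUE, FALSE, TRUE))
  expect_error(select_reference_peaks(rec, links = links,
                                      min_reference = 10),
               "reference")
})

test_that("rescaling fit recovers trivial and contaminated linear structure", {
  # all M = 0
  rec0 <- records_from_counts(rep(100, 60), rep(100, 60)) |>
    ma_transform(1e6, 1e6) |>
    dplyr::mutate(is_reference = TRUE)
  expect_warning(m0 <- fit_rescaling(rec0, min_reference = 10), "constant")
  expect_equal(m0$intercept, 0, tolerance = 1e-10)
  expect_equal(m0$slope, 0, tolerance = 1e-10)
  # constant M = 0.5 with varying A
  set.seed(1)
  wt <- round(seq(100, 3000, length.out = 80))
  recc <- records_from_counts(wt, round(wt * 2^0.5)) |>
    ma_transform(1e6, 1e6) |>
    dplyr::mutate(is_reference = TRUE)
  mc <- fit_rescaling(recc, min_reference = 10)
  expect_equal(mc$intercept, 0.5, tolerance = 0.01)
  expect_equal(mc$slope, 0, tolerance = 0.005)
  # M = 1 - 0.2 A + noise with 10% gross outliers, n = 500
  set.seed(99)
  A <- runif(500, 2, 10)
  M <- 1 - 0.2 * A + rnorm(500, 0, 0.1)
  out <- sample(500, 50)
  M[out] <- M[out] + sample(c(-1, 1), 50, TRUE) * runif(50, 1, 3)
  recn <- tibble::tibble(region_id = sprintf("r%03d", 1:500),
                         M = M, A = A, is_reference = TRUE)
  mn <- fit_rescaling(recn, min_reference = 50)
  expect_lt(abs(mn$intercept - 1), 0.05)
  expect_lt(abs(mn$slope + 0.2), 0.05)
  expect_equal(glance(mn)$n_reference, 500)
  expect_equal(tidy(mn)$estimate, c(mn$intercept, mn$slope))
})

test_that("degenerate constant A falls back to an intercept-only fit", {
  rec <- tibble::tibble(region_id = sprintf("r%d", 1:60),
                        M = rnorm(60, 0.3, 0.01), A = 5,
                        is_reference = TRUE)
  expect_warning(m <- fit_rescaling(rec, min_reference = 10), "constant")
  expect_equal(m$slope, 0)
  expect_equal(m$intercept, 0.3, tolerance = 0.02)
})

test_that("rescaling application: on-line records read 100%, M_rescaled -1 reads 50%", {
  model <- structure(list(intercept = 0.4, slope = -0.1, n_reference = 100,
                          estimator = list(), scale = NA),
                     class = "rescaling_model")
  rec <- tibble::tibble(M = c(0.4 - 0.1 * 4, 0.4 - 0.1 * 6 - 1), A = c(4, 6))
  out <- apply_rescaling(rec, model)
  expect_equal(out$percent_of_wt, c(100, 50))
  ident <- structure(list(intercept = 0, slope = 0), class = "rescaling_model")
  rec2 <- tibble::tibble(M = c(-0.3, 0.7), A = c(1, 2))
  expect_equal(apply_rescaling(rec2, ident)$M_rescaled, rec2$M)
})

test_that("binomial differential test matches closed forms and hand-computed BH", {
  model <- structure(list(intercept = 0, slope = 0), class = "rescaling_model")
  rec <- tibble::tibble(region_id = c("r1", "r2", "r3"),
                        wt_count = c(50, 40, 0), mut_count = c(50, 0, 0),
                        A = c(5, 5, 0))
  out <- peak_differential_test(rec, model, 1e6, 1e6)
  expect_equal(out$p_value[1], 1)
  expect_equal(out$p_value[2], 2 * 0.5^40, tolerance = 1e-6)
  expect_equal(out$p_value[3], 1)
  # hand-computed BH: (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
})

test_that("BH equals the textbook step-up on random p-vectors", {
  set.seed(404)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("retention classes follow the percent bands and significance rule", {
  rec <- tibble::tibble(percent_of_wt = c(100, 70, 70, 121, 80),
                        p_adj = c(0.001, 0.01, 0.30, 0.01, 0.001))
  out <- classify_retention(rec)
  expect_equal(out$direction,
               c("unchanged", "reduced", "unchanged", "increased", "unchanged"))
  expect_equal(out$band[1], "80-120 (WT level)")
  expect_equal(out$band[2], "60-80")
  expect_equal(out$band[5], "80-120 (WT level)")
})

test_that("replicate intersection keeps only concordant calls", {
  base <- tibble::tibble(region_id = c("r1", "r2", "r3"), chrom = "chr1",
                         start = c(0, 100, 200), end = c(50, 150, 250))
  r1 <- base |> dplyr::mutate(percent_of_wt = c(40, 60, 100),
                              direction = c("reduced", "reduced", "unchanged"))
  r2 <- base |> dplyr::mutate(percent_of_wt = c(45, 95, 100),
                              direction = c("reduced", "unchanged", "unchanged"))
  fin <- intersect_replicate_calls(r1, r2)
  expect_equal(fin$direction, c("reduced", "unchanged", "unchanged"))
  # intersection property: final reduced set within each replicate's
  expect_true(all(fin$region_id[fin$direction == "reduced"] %in%
                    r1$region_id[r1$direction == "reduced"]))
  expect_error(intersect_replicate_calls(r1, r2[c(2, 1, 3), ]), "universe")
})

test_that("gene-level change picks the biggest decrease with logged ties", {
  rec <- tibble::tibble(
    region_id = c("r1", "r2", "r3", "r4", "r5"),
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    percent_of_wt = c(90, 40, 75, 55, 55),
    band = c("80-120 (WT level)", "40-60", "60-80", "40-60", "40-60"),
    direction = c("unchanged", "reduced", "unchanged", "reduced", "reduced"))
  expect_message(out <- gene_level_change(rec), "tie")
  expect_equal(out$percent_of_wt[out$gene_id == "g1"], 40)
  expect_equal(out$direction[out$gene_id == "g1"], "reduced")
  expect_equal(out$region_id[out$gene_id == "g3"], "r4")
  expect_equal(nrow(out), 3)
})

test_that("monotonicity: raising a mutant count never lowers that region's percent", {
  model <- structure(list(intercept = 0.1, slope = -0.02),
                     class = "rescaling_model")
  for (cnt in c(0, 10, 100, 500)) {
    r1 <- ma_transform(records_from_counts(200, cnt), 1e6, 1e6) |>
      apply_rescaling(model)
    r2 <- ma_transform(records_from_counts(200, cnt + 25), 1e6, 1e6) |>
      apply_rescaling(model)
    expect_gte(r2$percent_of_wt, r1$percent_of_wt)
  }
})

test_that("exact global rescaling yields percent 100 everywhere (regression absorbs the ratio)", {
  wt <- round(seq(50, 5000, length.out = 200))
  # ratio 2 realized in the counts, library sizes equal: all peaks eligible
  rec <- records_from_counts(wt, 2 * wt) |>
    ma_transform(1e6, 1e6)
  rec$is_reference <- rec$is_common
  model <- fit_rescaling(rec, min_reference = 50)
  out <- apply_rescaling(rec, model)
  expect_true(all(abs(out$percent_of_wt - 100) < 1e-6))
  # same ratio realized through library size: M constant at -1
  rec2 <- records_from_counts(wt, wt, lib_wt = 1e6, lib_mut = 2e6) |>
    ma_transform(1e6, 2e6)
  rec2$is_reference <- TRUE
  model2 <- fit_rescaling(rec2, min_reference = 50)
  out2 <- apply_rescaling(rec2, model2)
  expect_true(all(abs(out2$percent_of_wt - 100) < 1e-6))
})
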