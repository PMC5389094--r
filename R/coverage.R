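# Binned normalized coverage tracks, metagene matrices over scaled gene
# bodies, peak-centred matrices, peak-length summaries and gene-level
# coverage comparisons.

#' Binned coverage track from read intervals
#'
#' Counts, per fixed-size bin, the reads overlapping the bin by at least
#' 1 bp (no fractional weighting), then normalizes: RPKM divides by bin
#' length in kb times library size in millions; RPM by library size in
#' millions; `raw` leaves counts. Reads extending beyond a chromosome end
#' are clipped with a warning.
#'
#' @param reads Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 10).
#' @param library_size Total mapped reads for normalization.
#' @param mode `"RPKM"`, `"RPM"` or `"raw"`.
#' @return Object of class `coverage_track`: per-chromosome value vectors
#'   plus bin size, mode and chromosome sizes.
#' @export
binned_coverage <- function(reads, chrom_sizes, bin_size = 10,
                            library_size = NULL, mode = c("RPKM", "RPM", "raw")) {
  mode <- match.arg(mode)
  if (mode != "raw") {
    if (is.null(library_size) || !is.finite(library_size) || library_size <= 0)
      abort("`library_size` must be a positive finite number")
  }
  check_interval_frame(reads, "read table")
  vals <- list()
  for (ch in names(chrom_sizes)) {
    L <- chrom_sizes[[ch]]
    rd <- reads %>% filter(.data$chrom == ch)
    if (any(rd$end > L)) {
      warn(sprintf("%d read(s) extend beyond the end of %s; clipped",
                   sum(rd$end > L), ch))
      rd$end <- pmin(rd$end, L)
      rd <- rd %>% filter(.data$start < .data$end)
    }
    nb <- ceiling(L / bin_size)
    bins <- tibble(chrom = ch,
                   start = (seq_len(nb) - 1) * bin_size,
                   end = pmin(seq_len(nb) * bin_size, L))
    cnt <- count_overlapping(bins, rd)
    v <- switch(mode,
      raw = as.numeric(cnt),
      RPM = cnt / (library_size / 1e6),
      RPKM = cnt / ((bins$end - bins$start) / 1000 * library_size / 1e6))
    vals[[ch]] <- v
  }
  structure(list(values = vals, bin_size = bin_size, mode = mode,
                 chrom_sizes = chrom_sizes,
                 library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), bin %d bp, %s-normalized\n",
              length(x$values), x$bin_size, x$mode))
  invisible(x)
}

# Piecewise-linear integral of a track on one chromosome: C(x) = integral
# of the step function from 0 to x. Mean over [a, b) = (C(b) - C(a)) / (b - a),
# which is exactly the length-weighted mean of the underlying bins.
track_integral_fun <- function(track, chrom) {
  v <- track$values[[chrom]]
  if (is.null(v)) abort(sprintf("track has no chromosome '%s'", chrom))
  bs <- track$bin_size
  L <- track$chrom_sizes[[chrom]]
  edges <- c((seq_along(v) - 1) * bs, L)
  widths <- diff(edges)
  cums <- c(0, cumsum(v * widths))
  function(x) {
    x <- pmin(pmax(x, 0), L)
    i <- pmin(findInterval(x, edges), length(v))
    cums[i] + v[pmax(i, 1)] * (x - edges[pmax(i, 1)])
  }
}

interval_means <- function(intfun, edges) {
  cc <- intfun(edges)
  diff(cc) / diff(edges)
}

#' Metagene coverage matrix over scaled gene bodies
#'
#' Builds a genes-by-bins matrix: `flank_bins` fixed-scale bins over
#' `flank_bp` upstream of the TSS, `body_bins` bins over the gene body
#' linearly rescaled TSS to TES (each bin value is the exact
#' length-weighted mean of the underlying track bins), and `flank_bins`
#' over the downstream flank. Minus-strand genes are orientation-flipped so
#' column 1 is always the 5' end.
#'
#' @param track A [binned_coverage()] track.
#' @param genes Gene tibble with `tss`, `tes`, `strand`.
#' @param body_bins,flank_bp,flank_bins Grid shape.
#' @return Object of class `coverage_matrix` (matrix plus metadata);
#'   columns flagged upstream/body/downstream.
#' @export
metagene_matrix <- function(track, genes, body_bins = 100, flank_bp = 1000,
                            flank_bins = 50) {
  ncol_total <- 2 * flank_bins + body_bins
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = ncol_total,
                dimnames = list(genes$gene_id, NULL))
  for (ch in unique(genes$chrom)) {
    intfun <- track_integral_fun(track, ch)
    idx <- which(genes$chrom == ch)
    for (i in idx) {
      plus <- genes$strand[i] == "+"
      tss <- genes$tss[i]; tes <- genes$tes[i]
      if (plus) {
        edges <- c(seq(tss - flank_bp, tss, length.out = flank_bins + 1),
                   seq(tss, tes, length.out = body_bins + 1)[-1],
                   seq(tes, tes + flank_bp, length.out = flank_bins + 1)[-1])
        mat[i, ] <- interval_means(intfun, edges)
      } else {
        edges <- c(seq(tss + flank_bp, tss, length.out = flank_bins + 1),
                   seq(tss, tes, length.out = body_bins + 1)[-1],
                   seq(tes, tes - flank_bp, length.out = flank_bins + 1)[-1])
        # edges descend; integrate on reversed edges then flip back
        mat[i, ] <- rev(interval_means(intfun, rev(edges)))
      }
    }
  }
  col_type <- c(rep("upstream", flank_bins), rep("body", body_bins),
                rep("downstream", flank_bins))
  structure(list(matrix = mat, col_type = col_type,
                 row_ids = genes$gene_id, kind = "metagene"),
            class = "coverage_matrix")
}

#' Peak-centred coverage matrix
#'
#' Rows are peaks, columns span `[center - flank_bp, center + flank_bp)`
#' in `bins` equal bins, centre = `floor((start + end) / 2)`. With
#' `flank_bp = 0` a single column holds the track value at the centre.
#' Rows are ordered by descending total signal unless `order_by` (a numeric
#' key, one value per peak) is supplied.
#'
#' @param track A [binned_coverage()] track.
#' @param peaks Peak tibble.
#' @param flank_bp Flank on each side of the centre.
#' @param bins Number of columns.
#' @param order_by Optional ordering key (descending).
#' @return A `coverage_matrix` of kind `"peak_center"`.
#' @export
peak_center_matrix <- function(track, peaks, flank_bp = 1000, bins = 100,
                               order_by = NULL) {
  centers <- floor((peaks$start + peaks$end) / 2)
  if (flank_bp == 0) {
    vals <- map_dbl(seq_len(nrow(peaks)), function(i) {
      intfun <- track_integral_fun(track, peaks$chrom[i])
      b <- track$bin_size
      lo <- floor(centers[i] / b) * b
      interval_means(intfun, c(lo, lo + b))
    })
    mat <- matrix(vals, ncol = 1, dimnames = list(peaks$peak_id, NULL))
  } else {
    mat <- matrix(NA_real_, nrow = nrow(peaks), ncol = bins,
                  dimnames = list(peaks$peak_id, NULL))
    for (ch in unique(peaks$chrom)) {
      intfun <- track_integral_fun(track, ch)
      for (i in which(peaks$chrom == ch)) {
        edges <- seq(centers[i] - flank_bp, centers[i] + flank_bp,
                     length.out = bins + 1)
        mat[i, ] <- interval_means(intfun, edges)
      }
    }
  }
  key <- order_by %||% rowSums(mat)
  mat <- mat[order(key, decreasing = TRUE), , drop = FALSE]
  structure(list(matrix = mat, col_type = rep("flank", ncol(mat)),
                 row_ids = rownames(mat), kind = "peak_center"),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("<coverage_matrix:%s> %d rows x %d bins\n", x$kind,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Column-mean profile of a coverage matrix
#' @param x A `coverage_matrix`.
#' @return Tibble: `bin`, `col_type`, `mean_value`.
#' @export
profile_of <- function(x) {
  tibble(bin = seq_len(ncol(x$matrix)), col_type = x$col_type,
         mean_value = colMeans(x$matrix, na.rm = TRUE))
}

#' Write a coverage matrix as TSV
#' @param x A `coverage_matrix`.
#' @param path Output path.
#' @export
write_coverage_matrix <- function(x, path) {
  df <- as_tibble(x$matrix, .name_repair = ~ sprintf("bin_%03d",
                                                     seq_along(.x)))
  df <- bind_cols(tibble(row_id = x$row_ids), df)
  readr::write_tsv(df, path)
}

#' Export a coverage track as bedGraph
#' @param track A [binned_coverage()] track.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- list_rbind(imap(track$values, function(v, ch) {
    bs <- track$bin_size
    L <- track$chrom_sizes[[ch]]
    tibble(chrom = ch, start = (seq_along(v) - 1) * bs,
           end = pmin(seq_along(v) * bs, L), value = v) %>%
      filter(.data$value != 0)
  }))
  readr::write_tsv(rows, path, col_names = FALSE)
}

#' Peak-length summary and rank-sum comparison of two peak sets
#'
#' Lengths are `end - start`. Reports per-set mean and median length and a
#' two-sided Wilcoxon rank-sum comparison ([rank_sum_test()]).
#'
#' @param peaks_a,peaks_b Non-empty peak tibbles.
#' @return List: `summary` tibble (set, n, mean, median), `statistic`,
#'   `p_value`, `method`.
#' @export
peak_length_summary <- function(peaks_a, peaks_b) {
  if (nrow(peaks_a) == 0 || nrow(peaks_b) == 0) {
    abort("both peak sets must be non-empty")
  }
  la <- peaks_a$end - peaks_a$start
  lb <- peaks_b$end - peaks_b$start
  ts <- rank_sum_test(la, lb)
  list(summary = tibble(set = c("A", "B"), n = c(length(la), length(lb)),
                        mean = c(mean(la), mean(lb)),
                        median = c(median(la), median(lb))),
       statistic = ts$statistic, p_value = ts$p_value, method = ts$method)
}

#' Compare gene-level coverage between two matrices
#'
#' Computes per-gene mean coverage over the body columns of two matrices
#' sharing rows and grid, a two-sided rank-sum test of the two gene-level
#' value sets (unpaired, mirroring a plain Wilcoxon comparison), and the
#' median per-gene ratio.
#'
#' @param matrix_wt,matrix_mut `coverage_matrix` objects with identical
#'   `row_ids` and column grids.
#' @return List: `genes` tibble (gene, wt_mean, mut_mean, ratio),
#'   `p_value`, `median_ratio`.
#' @export
compare_coverage <- function(matrix_wt, matrix_mut) {
  if (!identical(matrix_wt$row_ids, matrix_mut$row_ids) ||
      ncol(matrix_wt$matrix) != ncol(matrix_mut$matrix)) {
    off <- symdiff_ids(matrix_wt$row_ids, matrix_mut$row_ids)
    abort(paste0("matrices are not aligned",
                 if (length(off)) paste0("; offending rows: ",
                                         paste(head(off, 5), collapse = ", "))))
  }
  body <- matrix_wt$col_type == "body"
  if (!any(body)) body <- rep(TRUE, ncol(matrix_wt$matrix))
  wt <- rowMeans(matrix_wt$matrix[, body, drop = FALSE])
  mut <- rowMeans(matrix_mut$matrix[, body, drop = FALSE])
  ts <- rank_sum_test(wt, mut)
  ratio <- mut / wt
  list(genes = tibble(gene = matrix_wt$row_ids, wt_mean = wt,
                      mut_mean = mut, ratio = ratio),
       p_value = ts$p_value,
       median_ratio = median(ratio[is.finite(ratio)]))
}

symdiff_ids <- function(a, b) union(setdiff(a, b), setdiff(b, a))
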