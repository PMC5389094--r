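# In-code fixtures shared across test files.

# A hand-laid gene table (0-based half-open) with explicit sub-regions,
# suitable for exact annotation arithmetic.
toy_genes <- function() {
  genes <- tibble::tibble(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 40000, 5000),
    end = c(14000, 43000, 8000),
    strand = c("+", "-", "+")
  )
  marknorm::gene_regions(genes, chrom_length = 1e5)
}

peak_row <- function(id, chrom, start, end) {
  tibble::tibble(peak_id = id, chrom = chrom, start = start, end = end)
}

# A constant-value coverage track built directly (deterministic path).
flat_track <- function(value, chrom_sizes, bin_size = 10) {
  vals <- lapply(chrom_sizes, function(L) rep(value, ceiling(L / bin_size)))
  structure(list(values = vals, bin_size = bin_size, mode = "RPM",
                 chrom_sizes = chrom_sizes, library_size = 1e6),
            class = c("coverage_track"))
}

# Matched-region records with given counts, all common, for the
# normalization-path tests (skips read counting).
records_from_counts <- function(wt, mut, lib_wt = 1e6, lib_mut = 1e6,
                                width = 1000) {
  n <- length(wt)
  kb <- width / 1000
  tibble::tibble(
    region_id = sprintf("region_%05d", seq_len(n)),
    chrom = "chr1",
    start = (seq_len(n) - 1) * 2L * width,
    end = (seq_len(n) - 1) * 2L * width + width,
    is_common = TRUE,
    wt_count = wt, mut_count = mut,
    wt_rpkm = wt / (kb * lib_wt / 1e6),
    mut_rpkm = mut / (kb * lib_mut / 1e6)
  )
}
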