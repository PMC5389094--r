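# File readers and writers. Reading of the standard formats goes through
# rtracklayer; writing is plain formatting with readr. Internally all
# coordinates are 0-based half-open; GFF3 is converted (1-based closed) at
# this boundary.

#' Write gene models as GFF3
#'
#' Emits one `gene` feature per gene plus `five_prime_UTR`, `exon` (the
#' first exon) and `three_prime_UTR` children, 1-based closed coordinates.
#'
#' @param genes Gene tibble with region columns (see [gene_regions()]).
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  feat <- function(type, s, e, id, parent = NULL) {
    attr <- if (is.null(parent)) sprintf("ID=%s", id) else
      sprintf("ID=%s;Parent=%s", id, parent)
    tibble(seqid = genes$chrom, source = "marknorm", type = type,
           start = as.integer(s + 1), end = as.integer(e), score = ".",
           strand = genes$strand, phase = ".", attributes = attr)
  }
  rows <- bind_rows(
    feat("gene", genes$start, genes$end, genes$gene_id),
    feat("five_prime_UTR", genes$utr5_start, genes$utr5_end,
         paste0(genes$gene_id, ".utr5"), genes$gene_id),
    feat("exon", genes$exon1_start, genes$exon1_end,
         paste0(genes$gene_id, ".exon1"), genes$gene_id),
    feat("three_prime_UTR", genes$utr3_start, genes$utr3_end,
         paste0(genes$gene_id, ".utr3"), genes$gene_id)
  ) %>% arrange(.data$seqid, .data$start, .data$type != "gene")
  con <- file(path, "wb")
  writeLines("##gff-version 3", con)
  close(con)
  readr::write_tsv(rows, path, col_names = FALSE, append = TRUE)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file (via rtracklayer), keeps `gene` features, converts to
#' the package's 0-based half-open convention, and attaches sub-regions:
#' from `five_prime_UTR`/`exon`/`three_prime_UTR` children when present,
#' otherwise by the default proportional layout of [gene_regions()].
#'
#' @param path GFF3 file.
#' @param chrom_length Optional chromosome lengths for promoter clipping.
#' @return Gene tibble with region columns.
#' @export
read_genes_gff3 <- function(path, chrom_length = Inf) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = IRanges::start(gr) - 1L,
    end = IRanges::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    id = gr$ID,
    parent = vapply(as.list(gr$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  )
  genes <- df %>%
    filter(.data$type == "gene") %>%
    transmute(gene_id = .data$id, .data$chrom, .data$start, .data$end,
              .data$strand)
  out <- gene_regions(genes, chrom_length = chrom_length)
  child <- function(type, prefix) {
    df %>% filter(.data$type == !!type) %>%
      transmute(gene_id = .data$parent,
                !!paste0(prefix, "_start") := .data$start,
                !!paste0(prefix, "_end") := .data$end)
  }
  for (spec in list(c("five_prime_UTR", "utr5"), c("exon", "exon1"),
                    c("three_prime_UTR", "utr3"))) {
    ch <- child(spec[1], spec[2])
    if (nrow(ch) > 0) {
      out <- rows_update(out, ch, by = "gene_id", unmatched = "ignore")
    }
  }
  # body = gene minus UTRs and first exon, in transcription order
  plus <- out$strand == "+"
  out %>% mutate(
    body_start = ifelse(plus, .data$exon1_end, .data$utr3_end),
    body_end = ifelse(plus, .data$utr3_start, .data$exon1_start)
  )
}

#' Write intervals as BED6
#'
#' @param df Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns (0-based half-open, as BED).
#' @param path Output path.
#' @export
write_bed6 <- function(df, path) {
  check_interval_frame(df, "BED frame")
  col <- function(nm, default) if (nm %in% names(df)) df[[nm]] else default
  out <- tibble(chrom = df$chrom, start = as.integer(df$start),
                end = as.integer(df$end),
                name = col("name", col("peak_id", ".")),
                score = col("score", 0),
                strand = col("strand", "."))
  readr::write_tsv(out, path, col_names = FALSE)
}

#' Read a BED file into a tibble
#'
#' Uses rtracklayer's BED parser; returns 0-based half-open intervals with
#' `name`, `score`, `strand` when present. Lines with start >= end are
#' rejected by the parser.
#'
#' @param path BED file.
#' @return Interval tibble.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = IRanges::start(gr) - 1L,
    end = IRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    strand = as.character(BiocGenerics::strand(gr))
  )
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits genes (GFF3), per-sample called peak lists and read intervals
#' (BED6), counts, expression, truth manifests and library sizes (TSV), and
#' the configuration (YAML). [read_dataset()] restores the bundle.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_genes_gff3(sim$genes, p("genes.gff3"))
  for (m in unique(sim$called_peaks$mark)) {
    for (s in unique(sim$called_peaks$sample)) {
      pk <- sim$called_peaks %>%
        filter(.data$mark == m, .data$sample == s) %>%
        mutate(name = .data$peak_id)
      write_bed6(pk, p(sprintf("peaks_%s_%s.bed", m, s)))
    }
  }
  if (!is.null(sim$reads)) {
    for (m in unique(sim$reads$mark)) {
      for (s in unique(sim$reads$sample)) {
        rd <- sim$reads %>% filter(.data$mark == m, .data$sample == s)
        write_bed6(rd, p(sprintf("reads_%s_%s.bed", m, s)))
      }
    }
  }
  readr::write_tsv(sim$counts, p("counts.tsv"))
  readr::write_tsv(sim$expression, p("expression.tsv"))
  readr::write_tsv(sim$truth_peaks, p("truth_peaks.tsv"))
  readr::write_tsv(sim$truth_genes, p("truth_genes.tsv"))
  readr::write_tsv(enframe_library(sim$library_size), p("library_sizes.tsv"))
  cfg <- sim$config
  cfg$library_size <- as.list(cfg$library_size)
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(dir)
}

enframe_library <- function(x) tibble(sample = names(x), reads = unname(x))

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir Directory containing the bundle.
#' @return A list shaped like a `sim_dataset` (without truth tables if the
#'   bundle lacks them).
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfg <- yaml::read_yaml(p("config.yaml"))
  cfg$library_size <- unlist(cfg$library_size)
  genes <- read_genes_gff3(p("genes.gff3"), chrom_length = cfg$chrom_length)
  counts <- readr::read_tsv(p("counts.tsv"), show_col_types = FALSE)
  peak_files <- list.files(dir, "^peaks_", full.names = FALSE)
  called <- list_rbind(map(peak_files, function(f) {
    parts <- strsplit(sub("\\.bed$", "", f), "_")[[1]]
    read_bed(p(f)) %>%
      transmute(peak_id = .data$name, mark = parts[2],
                sample = paste(parts[3], parts[4], sep = "_"),
                .data$chrom, .data$start, .data$end)
  }))
  read_files <- list.files(dir, "^reads_", full.names = FALSE)
  reads <- if (length(read_files)) list_rbind(map(read_files, function(f) {
    parts <- strsplit(sub("\\.bed$", "", f), "_")[[1]]
    read_bed(p(f)) %>%
      transmute(mark = parts[2], sample = paste(parts[3], parts[4], sep = "_"),
                .data$chrom, .data$start, .data$end)
  })) else NULL
  truth_peaks <- if (file.exists(p("truth_peaks.tsv")))
    readr::read_tsv(p("truth_peaks.tsv"), show_col_types = FALSE) else NULL
  truth_genes <- if (file.exists(p("truth_genes.tsv")))
    readr::read_tsv(p("truth_genes.tsv"), show_col_types = FALSE) else NULL
  libs <- readr::read_tsv(p("library_sizes.tsv"), show_col_types = FALSE)
  list(config = cfg, genes = genes, called_peaks = called, counts = counts,
       reads = reads,
       expression = readr::read_tsv(p("expression.tsv"),
                                    show_col_types = FALSE),
       truth_peaks = truth_peaks, truth_genes = truth_genes,
       library_size = setNames(libs$reads, libs$sample))
}
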