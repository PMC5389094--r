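# Synthetic two-mark, two-genotype ChIP-seq data generator with a ground
# truth manifest. The generator emulates the statistical structure the
# downstream analysis assumes: two repressive marks with distinct peak
# geometries (short first-exon-centred vs long gene-spanning), two
# replicates per genotype sharing a latent per-peak intensity, a mutant
# genotype in which a configurable fraction of peaks has altered retention,
# and an expression table correlated with mark status.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' Defaults describe a compact genome with the features of the Arabidopsis
#' study system: short mark-A peaks (H2AK121ub-like, mean 0.6 kb, anchored
#' on first exons), long mark-B peaks (H3K27me3-like, mean 1.7 kb, spanning
#' gene plus promoter), mark co-occupancy on a subset of genes, and mostly
#' repressed co-marked genes.
#'
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param n_chromosomes,chrom_length Genome shape (bp per chromosome).
#' @param n_genes Total number of genes, placed without overlap.
#' @param mark_a,mark_b Per-mark geometry: `mean_length`, `sd_length` (bp)
#'   and `anchor`, one of `"first_exon"` or `"gene_spanning"`.
#' @param frac_cooccupied,frac_only_a,frac_only_b Fractions of genes carrying
#'   both marks, only mark A, only mark B (the remainder is unmarked).
#' @param retention_mixture List of mixture components, each a list with
#'   `fraction` and a distribution: `type = "point"` with `value`, or
#'   `type = "uniform"` with `min`/`max`. Fractions must sum to 1. The
#'   retention factor multiplies a peak's expected intensity in the mutant.
#' @param couple_retention If `TRUE`, the mark-B peak of a co-marked gene
#'   reuses the gene's mark-A retention draw (coupled loss).
#' @param global_scale Multiplier on all expected intensities.
#' @param dispersion Negative-binomial size parameter for count noise;
#'   `Inf` gives Poisson counts. Must be positive.
#' @param mean_depth Mean expected reads per peak in wild type at the
#'   reference library size.
#' @param library_size Named numeric vector of total mapped reads per sample
#'   (`wt_rep1`, `wt_rep2`, `mut_rep1`, `mut_rep2`).
#' @param read_length Read length in bp for emitted read intervals.
#' @param expressed_fraction Named list: per mark class (`only_a`, `a_and_b`,
#'   `only_b`, `unmarked`), the fraction of genes drawn above the FPKM > 5
#'   expressed threshold.
#' @param deg_fraction Fraction of genes whose mark-A peak has retention
#'   <= 0.6 that are flagged differentially expressed (upregulated,
#'   |log2 fold change| > 1).
#' @param peak_call_min_count Minimum read count for a peak to appear in a
#'   sample's called peak list (peak-caller dropout emulation).
#' @param marks Which marks to emit peaks/counts/reads for.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L,
                       chrom_length = 3e6,
                       n_genes = 400L,
                       mark_a = list(mean_length = 600, sd_length = 150,
                                     anchor = "first_exon"),
                       mark_b = list(mean_length = 1700, sd_length = 300,
                                     anchor = "gene_spanning"),
                       frac_cooccupied = 0.18,
                       frac_only_a = 0.33,
                       frac_only_b = 0.07,
                       retention_mixture = list(
                         list(fraction = 0.7, type = "point", value = 1),
                         list(fraction = 0.3, type = "uniform",
                              min = 0.1, max = 0.6)),
                       couple_retention = TRUE,
                       global_scale = 1,
                       dispersion = 100,
                       mean_depth = 200,
                       library_size = c(wt_rep1 = 1e6, wt_rep2 = 1e6,
                                        mut_rep1 = 1e6, mut_rep2 = 1e6),
                       read_length = 100,
                       expressed_fraction = list(only_a = 0.6, a_and_b = 0.05,
                                                 only_b = 0.05, unmarked = 0.7),
                       deg_fraction = 0.5,
                       peak_call_min_count = 10,
                       marks = c("A", "B")) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              mark_a = mark_a, mark_b = mark_b,
              frac_cooccupied = frac_cooccupied, frac_only_a = frac_only_a,
              frac_only_b = frac_only_b,
              retention_mixture = retention_mixture,
              couple_retention = isTRUE(couple_retention),
              global_scale = global_scale, dispersion = dispersion,
              mean_depth = mean_depth, library_size = library_size,
              read_length = read_length,
              expressed_fraction = expressed_fraction,
              deg_fraction = deg_fraction,
              peak_call_min_count = peak_call_min_count,
              marks = match.arg(marks, c("A", "B"), several.ok = TRUE))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_fraction(cfg$frac_cooccupied, "frac_cooccupied")
  check_fraction(cfg$frac_only_a, "frac_only_a")
  check_fraction(cfg$frac_only_b, "frac_only_b")
  if (cfg$frac_cooccupied + cfg$frac_only_a + cfg$frac_only_b > 1 + 1e-12) {
    abort("mark-class fractions exceed 1")
  }
  fr <- vapply(cfg$retention_mixture, function(k) k$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) abort("retention_mixture fractions must sum to 1")
  if (any(fr < 0)) abort("retention_mixture fractions must be non-negative")
  if (cfg$dispersion <= 0) abort("`dispersion` must be positive (Inf allowed)")
  for (f in c("chrom_length", "n_genes", "global_scale", "mean_depth",
              "read_length")) {
    if (any(cfg[[f]] <= 0)) abort(sprintf("`%s` must be positive", f))
  }
  if (is.null(names(cfg$library_size)) || any(cfg$library_size <= 0)) {
    abort("`library_size` must be a named positive vector")
  }
  lapply(cfg$expressed_fraction, check_fraction, name = "expressed_fraction")
  check_fraction(cfg$deg_fraction, "deg_fraction")
  invisible(cfg)
}

# Minimum clear gap between consecutive gene intervals. 5 kb keeps every
# peak's territory -- gene plus 2 kb on either side -- disjoint from its
# neighbours', so the nearest-downstream-gene annotation of generated
# peaks is unambiguous by construction. Chromosome edges only need
# promoter clearance.
GENE_GAP <- 5000
EDGE_GAP <- 2000

#' Generate non-overlapping gene models
#'
#' Places `n_genes` strand-assigned genes on the configured genome with at
#' least 5 kb between consecutive gene intervals. Each gene carries the five
#' named sub-regions used by the annotation module: promoter (2 kb upstream
#' of the TSS, clipped at the chromosome edge), 5'UTR, first exon, gene
#' body and 3'UTR, all 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return Tibble of gene models, one row per gene.
#' @export
generate_gene_models <- function(config) {
  set.seed(config$seed)
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chromosomes + 1)))
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  out <- vector("list", config$n_chromosomes)
  gidx <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    k <- per_chrom[ci]
    if (k == 0) next
    len <- round(runif(k, 800, 4000))
    needed <- sum(len) + (k - 1) * GENE_GAP + 2 * EDGE_GAP
    if (needed > config$chrom_length) {
      abort(sprintf(
        "cannot place %d genes on %s: need %d bp (gene lengths + %d-bp inter-gene gaps + %d-bp edge gaps) but chromosome is %d bp",
        k, chrom_names[ci], needed, GENE_GAP, EDGE_GAP, config$chrom_length))
    }
    slack <- config$chrom_length - needed
    cuts <- sort(runif(k, 0, slack))
    extras <- floor(diff(c(0, cuts)))
    min_gap <- c(EDGE_GAP, rep(GENE_GAP, max(0, k - 1)))
    pos <- numeric(k)
    cur <- 0
    for (i in seq_len(k)) {
      cur <- cur + min_gap[i] + extras[i]
      pos[i] <- cur
      cur <- cur + len[i]
    }
    strand <- sample(c("+", "-"), k, replace = TRUE)
    out[[ci]] <- tibble(
      gene_id = sprintf("gene_%04d", gidx + seq_len(k)),
      chrom = chrom_names[ci],
      start = pos, end = pos + len, strand = strand
    )
    gidx <- gidx + k
  }
  genes <- list_rbind(out)
  gene_regions(genes, chrom_length = config$chrom_length)
}

#' Derive named sub-regions for gene models
#'
#' Adds strand-aware sub-region columns (promoter, 5'UTR, first exon, gene
#' body, 3'UTR) plus TSS/TES point coordinates to a gene table with
#' `gene_id`, `chrom`, `start`, `end`, `strand`. Region extents follow a
#' fixed proportional layout (5'UTR and 3'UTR: 10% of gene length capped at
#' 200 bp; first exon: 25% capped at 400 bp) unless the table already
#' carries them. The promoter spans 2 kb upstream of the TSS, clipped at
#' the chromosome edge.
#'
#' @param genes Gene tibble (0-based half-open intervals).
#' @param promoter_bp Promoter window size upstream of the TSS.
#' @param chrom_length Chromosome length(s) used to clip promoters; a single
#'   number or a named vector by chromosome. `Inf` disables right clipping.
#' @return The gene tibble with region columns.
#' @export
gene_regions <- function(genes, promoter_bp = 2000, chrom_length = Inf) {
  len <- genes$end - genes$start
  u <- pmin(200, floor(0.1 * len))
  e <- pmin(400, floor(0.25 * len))
  t3 <- pmin(200, floor(0.1 * len))
  plus <- genes$strand == "+"
  clen <- if (length(chrom_length) > 1 || !is.null(names(chrom_length))) {
    unname(chrom_length[genes$chrom])
  } else rep(chrom_length, nrow(genes))
  genes %>%
    mutate(
      tss = ifelse(plus, .data$start, .data$end),
      tes = ifelse(plus, .data$end, .data$start),
      promoter_start = ifelse(plus, pmax(0, .data$start - promoter_bp), .data$end),
      promoter_end = ifelse(plus, .data$start,
                            pmin(clen, .data$end + promoter_bp)),
      utr5_start = ifelse(plus, .data$start, .data$end - u),
      utr5_end = ifelse(plus, .data$start + u, .data$end),
      exon1_start = ifelse(plus, .data$start + u, .data$end - u - e),
      exon1_end = ifelse(plus, .data$start + u + e, .data$end - u),
      body_start = ifelse(plus, .data$start + u + e, .data$start + t3),
      body_end = ifelse(plus, .data$end - t3, .data$end - u - e),
      utr3_start = ifelse(plus, .data$end - t3, .data$start),
      utr3_end = ifelse(plus, .data$end, .data$start + t3)
    )
}

draw_retention <- function(n, mixture) {
  fr <- vapply(mixture, function(k) k$fraction, numeric(1))
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = fr)
  out <- numeric(n)
  for (i in seq_along(mixture)) {
    idx <- comp == i
    m <- mixture[[i]]
    out[idx] <- switch(m$type,
      point = rep(m$value, sum(idx)),
      uniform = runif(sum(idx), m$min, m$max),
      abort(sprintf("unknown retention distribution type '%s'", m$type)))
  }
  out
}

#' Generate peak templates and the truth manifest
#'
#' Assigns each gene a mark class (only-A, A-and-B, only-B, unmarked) and
#' creates one peak template per carried mark: mark-A peaks centred on the
#' first exon with short lengths, mark-B peaks spanning gene plus promoter
#' with long lengths. Each peak draws a latent wild-type intensity and a
#' retention factor (mutant/WT intensity ratio) from the configured
#' mixture; every draw is recorded in the truth manifest.
#'
#' @param genes Output of [generate_gene_models()].
#' @param config A [sim_config()].
#' @return List with `peaks` (templates), `truth_peaks`, `truth_genes`.
#' @export
generate_peak_truth <- function(genes, config) {
  set.seed(config$seed + 1L)
  n <- nrow(genes)
  labels <- sample(c("a_and_b", "only_a", "only_b", "unmarked"), n,
                   replace = TRUE,
                   prob = c(config$frac_cooccupied, config$frac_only_a,
                            config$frac_only_b,
                            1 - config$frac_cooccupied - config$frac_only_a -
                              config$frac_only_b))
  genes$mark_class <- labels
  mk <- list(A = config$mark_a, B = config$mark_b)
  peak_list <- list()
  for (m in config$marks) {
    carriers <- genes %>%
      filter(.data$mark_class %in% if (m == "A") c("only_a", "a_and_b")
             else c("only_b", "a_and_b"))
    if (nrow(carriers) == 0) next
    geo <- mk[[m]]
    len <- pmax(200, round(rnorm(nrow(carriers), geo$mean_length,
                                 geo$sd_length)))
    center <- if (geo$anchor == "first_exon") {
      floor((carriers$exon1_start + carriers$exon1_end) / 2)
    } else {
      floor((pmin(carriers$promoter_start, carriers$start) +
               pmax(carriers$promoter_end, carriers$end)) / 2)
    }
    s <- center - floor(len / 2)
    e <- s + len
    # clip to the gene's exclusive territory and keep >= 1 bp gene overlap
    s <- pmax(s, pmin(carriers$promoter_start, carriers$start) - 100)
    s <- pmax(s, 0)
    e <- pmin(e, pmax(carriers$promoter_end, carriers$end) + 100)
    e <- pmax(e, s + 100)
    s <- pmin(s, carriers$end - 50)
    e <- pmax(e, carriers$start + 50)
    peak_list[[m]] <- tibble(
      peak_id = sprintf("pk%s_%s", m, carriers$gene_id),
      mark = m, chrom = carriers$chrom, start = s, end = e,
      gene_id = carriers$gene_id
    )
  }
  peaks <- list_rbind(peak_list) %>% arrange(.data$chrom, .data$start)
  np <- nrow(peaks)
  sdlog <- 0.5
  intensity <- config$mean_depth * config$global_scale *
    rlnorm(np, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  retention <- draw_retention(np, config$retention_mixture)
  if (config$couple_retention && all(c("A", "B") %in% config$marks)) {
    ia <- peaks$mark == "A"
    ret_a <- setNames(retention[ia], peaks$gene_id[ia])
    ib <- which(peaks$mark == "B" & peaks$gene_id %in% names(ret_a))
    retention[ib] <- ret_a[peaks$gene_id[ib]]
  }
  lib_ref <- unname(config$library_size[1])
  truth_peaks <- tibble(
    peak_id = peaks$peak_id, mark = peaks$mark, gene_id = peaks$gene_id,
    true_intensity = intensity,
    true_rpm = intensity / lib_ref * 1e6,
    retention = retention
  )
  truth_genes <- genes %>%
    select("gene_id", label = "mark_class")
  list(peaks = peaks, truth_peaks = truth_peaks, truth_genes = truth_genes)
}

sim_samples <- function(config) {
  tibble(genotype = rep(c("wt", "mut"), each = 2),
         rep = rep(1:2, 2)) %>%
    mutate(sample = sprintf("%s_rep%d", .data$genotype, .data$rep))
}

#' Sample replicate read counts and read intervals
#'
#' Draws per-sample, per-replicate counts for every peak template from a
#' negative binomial with mean = latent intensity x library-size factor x
#' (retention factor, for mutant samples) and the configured dispersion
#' (size parameter; `Inf` gives Poisson counts). The two replicates of a
#' genotype share the latent intensity, so their counts have equal
#' expectation. Fixed-length reads are placed uniformly within each peak.
#'
#' @param peaks Peak templates from [generate_peak_truth()].
#' @param truth_peaks Truth manifest from [generate_peak_truth()].
#' @param config A [sim_config()].
#' @param reads If `FALSE`, skip read-interval generation (counts only).
#' @return List with `counts` (long tibble: peak_id, mark, sample, count)
#'   and `reads` (tibble: mark, sample, chrom, start, end), plus
#'   `library_size`.
#' @export
sample_replicate_counts <- function(peaks, truth_peaks, config, reads = TRUE) {
  if (config$dispersion <= 0) abort("`dispersion` must be positive")
  set.seed(config$seed + 2L)
  samples <- sim_samples(config)
  lib_ref <- unname(config$library_size[1])
  stopifnot(identical(peaks$peak_id, truth_peaks$peak_id))
  counts_list <- list()
  reads_list <- list()
  for (si in seq_len(nrow(samples))) {
    smp <- samples$sample[si]
    lib <- unname(config$library_size[smp])
    if (is.na(lib)) abort(sprintf("library_size lacks entry for '%s'", smp))
    mu <- truth_peaks$true_intensity * (lib / lib_ref)
    if (samples$genotype[si] == "mut") mu <- mu * truth_peaks$retention
    cnt <- if (is.infinite(config$dispersion)) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = config$dispersion)
    }
    counts_list[[smp]] <- tibble(peak_id = peaks$peak_id, mark = peaks$mark,
                                 sample = smp, count = cnt)
    if (reads) {
      idx <- rep.int(seq_len(nrow(peaks)), cnt)
      w <- peaks$end[idx] - peaks$start[idx]
      rs <- peaks$start[idx] +
        floor(runif(length(idx)) * pmax(1, w - config$read_length))
      reads_list[[smp]] <- tibble(
        mark = peaks$mark[idx], sample = smp, chrom = peaks$chrom[idx],
        start = rs, end = rs + config$read_length
      )
    }
  }
  list(counts = list_rbind(counts_list),
       reads = if (reads) list_rbind(reads_list) else NULL,
       library_size = config$library_size)
}

#' Generate an expression table correlated with mark status
#'
#' Co-marked and only-B genes are drawn mostly below the FPKM > 5 expressed
#' threshold; a configurable fraction of only-A genes is drawn above it.
#' Genes whose mark-A peak has retention <= 0.6 are flagged differentially
#' expressed (upregulated, |log2 fold change| > 1) with probability
#' `deg_fraction`, emulating derepression upon mark loss.
#'
#' @param truth List from [generate_peak_truth()].
#' @param config A [sim_config()].
#' @return Tibble: gene_id, fpkm, deg, lfc.
#' @export
generate_expression <- function(truth, config) {
  set.seed(config$seed + 3L)
  tg <- truth$truth_genes
  n <- nrow(tg)
  efrac <- unlist(config$expressed_fraction)[tg$label]
  efrac[is.na(efrac)] <- 0
  expressed <- runif(n) < efrac
  fpkm <- ifelse(expressed,
                 5 * (1 + rlnorm(n, meanlog = 0.8, sdlog = 1)),
                 runif(n, 0, 5))
  ret_a <- truth$truth_peaks %>%
    filter(.data$mark == "A") %>%
    select("gene_id", "retention")
  tab <- tg %>%
    left_join(ret_a, by = "gene_id") %>%
    mutate(
      strongly_reduced = !is.na(.data$retention) & .data$retention <= 0.6,
      deg = .data$strongly_reduced & runif(n) < config$deg_fraction,
      lfc = ifelse(.data$deg, 1 + abs(rnorm(n)), runif(n, -0.9, 0.9))
    )
  tibble(gene_id = tg$gene_id, fpkm = unname(fpkm), deg = tab$deg,
         lfc = tab$lfc)
}

called_peaks <- function(peaks, counts, config) {
  counts %>%
    filter(.data$count >= config$peak_call_min_count) %>%
    inner_join(peaks, by = c("peak_id", "mark")) %>%
    select("peak_id", "mark", "sample", "chrom", "start", "end", "gene_id")
}

#' Simulate a complete dataset
#'
#' One call producing genes, peak templates, per-sample called peak lists,
#' counts, read intervals, expression table and the truth manifest, all
#' deterministic under the configured seed.
#'
#' @param config A [sim_config()].
#' @param reads Generate read intervals (needed for coverage and for
#'   read-based peak matching).
#' @return List of class `sim_dataset`.
#' @export
simulate_dataset <- function(config = sim_config(), reads = TRUE) {
  genes <- generate_gene_models(config)
  truth <- generate_peak_truth(genes, config)
  cnt <- sample_replicate_counts(truth$peaks, truth$truth_peaks, config,
                                 reads = reads)
  expr <- generate_expression(truth, config)
  truth_genes <- truth$truth_genes %>%
    left_join(expr %>% mutate(expressed = .data$fpkm > 5) %>%
                select("gene_id", "expressed", "deg"),
              by = "gene_id")
  structure(list(
    config = config,
    genes = genes,
    peaks = truth$peaks,
    called_peaks = called_peaks(truth$peaks, cnt$counts, config),
    counts = cnt$counts,
    reads = cnt$reads,
    expression = expr,
    truth_peaks = truth$truth_peaks,
    truth_genes = truth_genes,
    library_size = config$library_size
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d genes, %d peak templates (%s), %d count rows, seed %d\n",
    nrow(x$genes), nrow(x$peaks),
    paste(sprintf("mark %s: %d", unique(x$peaks$mark),
                  table(x$peaks$mark)[unique(x$peaks$mark)]), collapse = ", "),
    nrow(x$counts), x$config$seed))
  invisible(x)
}
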