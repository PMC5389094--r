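# Overlap and enrichment statistics: Fisher's exact test on set overlaps,
# shuffle-permutation region enrichment, hypergeometric term enrichment,
# expression-band categorization, and the retention cross-tabulation
# linking the two marks.

#' Fisher's exact test of the overlap between two gene sets
#'
#' Builds the 2x2 table (in A and B / A only / B only / neither) over the
#' universe and computes the conditional-likelihood two-sided exact p
#' (the sum of all tables with the observed margins whose point probability
#' does not exceed the observed one) and the sample odds ratio
#' `(n11 * n00) / (n10 * n01)` (so a zero off-diagonal cell gives +Inf and
#' a zero diagonal cell gives 0).
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all gene ids.
#' @return One-row tibble: cell counts, `odds_ratio`, `p_value`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  if (length(universe) == 0) abort("empty universe")
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  n11 <- length(intersect(set_a, set_b))
  n10 <- length(setdiff(set_a, set_b))
  n01 <- length(setdiff(set_b, set_a))
  n00 <- length(universe) - n11 - n10 - n01
  fisher_table(n11, n10, n01, n00)
}

#' @rdname fisher_overlap
#' @param n11,n10,n01,n00 Cell counts of a 2x2 table.
#' @export
fisher_table <- function(n11, n10, n01, n00) {
  tab <- matrix(c(n11, n10, n01, n00), nrow = 2)
  p <- fisher.test(tab)$p.value
  or <- (n11 * n00) / (n10 * n01)
  tibble(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
         odds_ratio = or, p_value = p)
}

#' Shuffle-permutation enrichment of peaks in region classes
#'
#' For each region class, counts the peaks overlapping the class (>= 1 bp)
#' and compares with a null distribution obtained by repositioning every
#' peak uniformly at random on its own chromosome, preserving its length
#' (shuffled peaks may overlap each other). The permutation p-value uses
#' the plus-one convention `p = (1 + #(null >= observed)) / (n_shuffles +
#' 1)`, so it is never 0; BH correction is applied across classes.
#'
#' @param peaks Peak tibble.
#' @param region_classes Tibble with `chrom`, `start`, `end`, `class`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_shuffles Number of shuffles (default 500).
#' @param seed Optional seed for the shuffles.
#' @return Tibble: `class`, `observed`, `null_mean`, `p_value`, `p_adj`.
#' @export
shuffle_overlap_enrichment <- function(peaks, region_classes, chrom_sizes,
                                       n_shuffles = 500, seed = NULL) {
  check_interval_frame(peaks, "peak table")
  check_interval_frame(region_classes, "region classes")
  if (!is.null(seed)) set.seed(seed)
  lens <- peaks$end - peaks$start
  csize <- unname(chrom_sizes[peaks$chrom])
  if (any(lens > csize)) {
    abort("peak(s) longer than their chromosome cannot be shuffled")
  }
  np <- nrow(peaks)
  # all shuffled start positions at once: shuffle s, peak i
  shuf_start <- floor(runif(np * n_shuffles) * rep(csize - lens, n_shuffles))
  shuf_end <- shuf_start + rep(lens, n_shuffles)
  shuf_chrom <- rep(peaks$chrom, n_shuffles)
  shuffle_id <- rep(seq_len(n_shuffles), each = np)

  classes <- unique(region_classes$class)
  out <- list_rbind(map(classes, function(cl) {
    cls <- region_classes %>% filter(.data$class == cl)
    obs_hit <- logical(np)
    null_hit <- logical(np * n_shuffles)
    for (ch in unique(cls$chrom)) {
      mi <- merge_intervals(cls$start[cls$chrom == ch],
                            cls$end[cls$chrom == ch])
      pi <- peaks$chrom == ch
      obs_hit[pi] <- obs_hit[pi] |
        overlaps_any_sorted(peaks$start[pi], peaks$end[pi],
                            mi$start, mi$end)
      si <- shuf_chrom == ch
      null_hit[si] <- null_hit[si] |
        overlaps_any_sorted(shuf_start[si], shuf_end[si], mi$start, mi$end)
    }
    observed <- sum(obs_hit)
    null_stat <- as.vector(rowsum(as.numeric(null_hit), shuffle_id))
    tibble(class = cl, observed = observed,
           null_mean = mean(null_stat),
           p_value = (1 + sum(null_stat >= observed)) / (n_shuffles + 1))
  }))
  out %>% mutate(p_adj = p.adjust(.data$p_value, method = "BH"))
}

#' Term over-representation by the hypergeometric tail
#'
#' For each term, the upper-tail hypergeometric p of the number of
#' gene-set members carrying the term, against the universe; BH-adjusted
#' across terms. Works for GO-style terms and transcription-factor family
#' labels alike -- the mapping is caller-supplied and flat. Terms with no
#' universe hits are skipped with a log message.
#'
#' @param gene_set Character vector, subset of `universe`.
#' @param universe Character vector of gene ids.
#' @param term_map Tibble with `gene_id`, `term_id`.
#' @return Tibble: `term_id`, `hits_in_set`, `set_size`,
#'   `hits_in_universe`, `universe_size`, `odds_ratio`, `p_value`, `p_adj`.
#' @export
term_enrichment <- function(gene_set, universe, term_map) {
  gene_set <- intersect(unique(gene_set), universe)
  tm <- term_map %>%
    filter(.data$gene_id %in% universe) %>%
    distinct(.data$gene_id, .data$term_id)
  dropped <- setdiff(unique(term_map$term_id), unique(tm$term_id))
  if (length(dropped) > 0) {
    inform(sprintf("%d term(s) without universe hits skipped", length(dropped)))
  }
  N <- length(universe)
  n <- length(gene_set)
  out <- tm %>%
    group_by(.data$term_id) %>%
    summarise(hits_in_universe = n(),
              hits_in_set = sum(.data$gene_id %in% gene_set),
              .groups = "drop") %>%
    mutate(
      set_size = n, universe_size = N,
      odds_ratio = (.data$hits_in_set * (N - n - .data$hits_in_universe +
                                           .data$hits_in_set)) /
        ((n - .data$hits_in_set) *
           (.data$hits_in_universe - .data$hits_in_set)),
      p_value = phyper(.data$hits_in_set - 1, .data$hits_in_universe,
                       N - .data$hits_in_universe, n, lower.tail = FALSE),
      p_adj = p.adjust(.data$p_value, method = "BH")
    ) %>%
    arrange(.data$p_value)
  out
}

EXPRESSION_EDGES <- c(0, 1, 5, 25, 100, Inf)
EXPRESSION_LABELS <- c("(0,1]", "(1,5]", "(5,25]", "(25,100]", ">100")

#' Expression-band composition of gene sets
#'
#' For each gene set, the fraction of genes per FPKM band (default bands:
#' 0, (0,1], (1,5], (5,25], (25,100], >100) and the expressed fraction
#' under the strict FPKM > 5 rule. Genes missing from the expression table
#' count as FPKM 0 with a warning; negative FPKM is an input error.
#'
#' @param expression Tibble with `gene_id`, `fpkm`.
#' @param gene_sets Named list of character vectors.
#' @return List: `bands` tibble (set, band, n, frac), `expressed` tibble
#'   (set, n_expressed, frac_expressed).
#' @export
expression_categories <- function(expression, gene_sets) {
  if (any(expression$fpkm < 0)) abort("negative FPKM in expression table")
  fpkm_of <- setNames(expression$fpkm, expression$gene_id)
  bands <- list_rbind(imap(gene_sets, function(ids, nm) {
    f <- fpkm_of[ids]
    if (anyNA(f)) {
      warn(sprintf("%d gene(s) of set '%s' missing from expression table; counted as FPKM 0",
                   sum(is.na(f)), nm))
      f[is.na(f)] <- 0
    }
    band <- ifelse(f == 0, "0",
                   as.character(cut(f, EXPRESSION_EDGES,
                                    labels = EXPRESSION_LABELS)))
    tibble(set = nm, gene_id = ids, fpkm = unname(f), band = band)
  }))
  band_levels <- c("0", EXPRESSION_LABELS)
  list(
    bands = bands %>%
      count(.data$set, band = factor(.data$band, band_levels)) %>%
      tidyr::complete(.data$set, .data$band, fill = list(n = 0L)) %>%
      group_by(.data$set) %>%
      mutate(frac = .data$n / sum(.data$n)) %>%
      ungroup() %>%
      mutate(band = as.character(.data$band)),
    expressed = bands %>%
      group_by(.data$set) %>%
      summarise(n_expressed = sum(.data$fpkm > 5),
                frac_expressed = mean(.data$fpkm > 5), .groups = "drop")
  )
}

#' Retention cross-tabulation between two marks
#'
#' Genes carrying both marks are partitioned into bands of mark-A
#' percent-of-WT (rows); each row reports the fraction of its genes per
#' mark-B change class (reduced / unchanged / increased). Row fractions
#' sum to 1.
#'
#' @param records_a,records_b Gene-level tibbles ([gene_level_change()])
#'   with `gene_id`, `percent_of_wt`, `direction`.
#' @param row_edges Band edges for mark-A percents.
#' @param mode `"all"` uses all co-marked genes; `"significant"` keeps only
#'   genes whose mark-A call is reduced or increased.
#' @return Tibble: `row_band`, `n_genes`, one fraction column per mark-B
#'   class; attribute `counts` holds the raw cell counts.
#' @export
retention_crosstab <- function(records_a, records_b,
                               row_edges = RETENTION_EDGES,
                               mode = c("all", "significant")) {
  mode <- match.arg(mode)
  shared <- inner_join(
    records_a %>% select("gene_id", percent_a = "percent_of_wt",
                         dir_a = "direction"),
    records_b %>% select("gene_id", dir_b = "direction"),
    by = "gene_id")
  if (nrow(shared) == 0) abort("no genes shared between the two record sets")
  if (mode == "significant") {
    shared <- shared %>% filter(.data$dir_a != "unchanged")
    if (nrow(shared) == 0) abort("no significant mark-A genes to tabulate")
  }
  labels <- band_labels(row_edges)
  shared <- shared %>%
    mutate(row_band = as.character(cut(.data$percent_a, row_edges,
                                       labels = labels, right = FALSE)))
  cells <- shared %>%
    count(.data$row_band, .data$dir_b) %>%
    tidyr::pivot_wider(names_from = "dir_b", values_from = "n",
                       values_fill = 0L)
  counts <- shared %>% count(.data$row_band, name = "n_genes")
  out <- counts %>% left_join(cells, by = "row_band")
  class_cols <- setdiff(names(out), c("row_band", "n_genes"))
  for (cc in class_cols) out[[cc]] <- out[[cc]] / out$n_genes
  attr(out, "counts") <- cells
  out
}

band_labels <- function(edges) {
  k <- length(edges) - 1
  vapply(seq_len(k), function(i) {
    if (is.infinite(edges[i + 1])) sprintf(">%g", edges[i])
    else sprintf("%g-%g", edges[i], edges[i + 1])
  }, character(1))
}

#' Overlap of reduced-gene sets between two marks
#'
#' Fisher test of the overlap between genes with reduced mark A and genes
#' with reduced mark B over the co-marked universe, with Venn counts.
#'
#' @param genes_reduced_a,genes_reduced_b Character vectors.
#' @param universe Co-marked gene ids.
#' @return One-row tibble: Venn counts (`only_a`, `both`, `only_b`),
#'   `odds_ratio`, `p_value`.
#' @export
reduced_set_overlap <- function(genes_reduced_a, genes_reduced_b, universe) {
  fo <- fisher_overlap(genes_reduced_a, genes_reduced_b, universe)
  tibble(only_a = fo$n10, both = fo$n11, only_b = fo$n01,
         neither = fo$n00, odds_ratio = fo$odds_ratio,
         p_value = fo$p_value)
}
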