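# Peak-to-gene annotation by the Nearest Downstream Gene (NDG) criterion:
# a peak is associated with a gene when it overlaps any of the gene's
# regions (promoter included), or when it lies at most 2 kb upstream of the
# TSS in the gene's orientation. Overlap beats proximity; the 2-kb boundary
# is inclusive.

REGION_TYPES <- c("promoter", "utr5", "exon1", "body", "utr3")
REGION_LABELS <- c(promoter = "promoter", utr5 = "5'UTR",
                   exon1 = "first exon", body = "gene body", utr3 = "3'UTR")
# precedence for the single linkage-class label when a peak overlaps
# several regions of its gene (first exon highest)
REGION_PRECEDENCE <- c("first exon" = 1, "5'UTR" = 2, "3'UTR" = 3,
                       "gene body" = 4, "promoter" = 5,
                       "upstream-within-2kb" = 6)

region_table <- function(genes) {
  list_rbind(map(REGION_TYPES, function(r) {
    s <- genes[[paste0(r, "_start")]]
    e <- genes[[paste0(r, "_end")]]
    keep <- !is.na(s) & !is.na(e) & s < e
    tibble(gene_id = genes$gene_id[keep], chrom = genes$chrom[keep],
           start = s[keep], end = e[keep],
           region = unname(REGION_LABELS[r]))
  }))
}

#' Annotate peaks to genes by the NDG criterion
#'
#' Each peak is assigned to the gene whose regions (promoter, 5'UTR, first
#' exon, gene body, 3'UTR) it overlaps by at least 1 bp, or, failing any
#' overlap, to the nearest gene whose TSS lies at most `promoter_bp`
#' downstream of the peak in the gene's orientation (boundary inclusive).
#' Peaks assigned to no gene are intergenic. When a peak overlaps several
#' regions of its gene, the linkage class follows the precedence
#' first exon > 5'UTR > 3'UTR > gene body > promoter. When a peak overlaps
#' two genes, the gene giving the higher-precedence class (then the larger
#' overlap, then the lexicographically smaller id) wins; equidistant TSS
#' ties in the proximity rule go to the lexicographically smaller gene id
#' and are logged.
#'
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param genes Gene tibble with region columns ([gene_regions()]).
#' @param promoter_bp Upstream window, default 2000.
#' @return Tibble: `peak_id`, `gene_id` (NA if intergenic), `link_class`.
#' @export
assign_peak_to_gene <- function(peaks, genes, promoter_bp = 2000) {
  check_interval_frame(peaks, "peak table")
  unknown <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(unknown) > 0) {
    abort(sprintf("peak chromosome(s) absent from gene models: %s",
                  paste(unknown, collapse = ", ")))
  }
  regions <- region_table(genes)
  hits <- overlap_pairs(peaks, regions)
  ov <- tibble(
    peak_id = peaks$peak_id[hits$query_row],
    gene_id = regions$gene_id[hits$subject_row],
    link_class = regions$region[hits$subject_row],
    overlap = pmin(peaks$end[hits$query_row], regions$end[hits$subject_row]) -
      pmax(peaks$start[hits$query_row], regions$start[hits$subject_row])
  )
  by_overlap <- ov %>%
    mutate(prec = REGION_PRECEDENCE[.data$link_class]) %>%
    group_by(.data$peak_id) %>%
    arrange(.data$prec, desc(.data$overlap), .data$gene_id,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("peak_id", "gene_id", "link_class")

  rest <- peaks %>% filter(!.data$peak_id %in% by_overlap$peak_id)
  by_proximity <- NULL
  if (nrow(rest) > 0) {
    # gene TSS downstream of the peak within the window, strand-aware;
    # gap measured from peak edge to TSS on the half-open scale
    cand <- list_rbind(map(seq_len(nrow(rest)), function(i) {
      g <- genes %>% filter(.data$chrom == rest$chrom[i])
      gap <- ifelse(g$strand == "+", g$tss - rest$end[i],
                    rest$start[i] - g$tss)
      ok <- gap >= 0 & gap <= promoter_bp
      if (!any(ok)) return(NULL)
      tibble(peak_id = rest$peak_id[i], gene_id = g$gene_id[ok],
             gap = gap[ok])
    }))
    if (!is.null(cand) && nrow(cand) > 0) {
      by_proximity <- cand %>%
        group_by(.data$peak_id) %>%
        arrange(.data$gap, .data$gene_id, .by_group = TRUE) %>%
        mutate(tie = n() > 1 & .data$gap[pmin(2, n())] == .data$gap[1]) %>%
        slice(1) %>%
        ungroup()
      nties <- sum(by_proximity$tie)
      if (nties > 0) {
        inform(sprintf(
          "%d peak(s) equidistant from two TSSs; lexicographically smaller gene id chosen",
          nties))
      }
      by_proximity <- by_proximity %>%
        transmute(.data$peak_id, .data$gene_id,
                  link_class = "upstream-within-2kb")
    }
  }
  assigned <- bind_rows(by_overlap, by_proximity)
  peaks %>%
    select("peak_id") %>%
    left_join(assigned, by = "peak_id") %>%
    mutate(link_class = ifelse(is.na(.data$gene_id), "intergenic",
                               .data$link_class))
}

#' @rdname assign_peak_to_gene
#' @export
annotate_peaks <- assign_peak_to_gene

#' Call marked genes from two replicates
#'
#' A gene is marked when at least one peak is associated with it in
#' replicate 1 AND at least one in replicate 2.
#'
#' @param links_rep1,links_rep2 Link tables from [annotate_peaks()].
#' @return Character vector of marked gene ids (sorted).
#' @export
call_marked_genes <- function(links_rep1, links_rep2) {
  g1 <- unique(links_rep1$gene_id[!is.na(links_rep1$gene_id)])
  g2 <- unique(links_rep2$gene_id[!is.na(links_rep2$gene_id)])
  if (length(g1) == 0 || length(g2) == 0) {
    warn("a replicate contributes no gene-associated peaks; marked set is empty")
  }
  sort(intersect(g1, g2))
}

#' Partition two marked-gene sets
#'
#' Splits genes into only-A (A minus B), A-and-B, and only-B (B minus A).
#'
#' @param marked_a,marked_b Character vectors of gene ids.
#' @return Object of class `marked_gene_sets` with the three partition sets
#'   and the input sets; `tidy()` returns the counts.
#' @export
classify_mark_sets <- function(marked_a, marked_b) {
  marked_a <- unique(marked_a)
  marked_b <- unique(marked_b)
  structure(list(
    marked_a = marked_a, marked_b = marked_b,
    only_a = sort(setdiff(marked_a, marked_b)),
    both = sort(intersect(marked_a, marked_b)),
    only_b = sort(setdiff(marked_b, marked_a))
  ), class = "marked_gene_sets")
}

#' @export
print.marked_gene_sets <- function(x, ...) {
  cat(sprintf("<marked_gene_sets> |A| = %d, |B| = %d\n",
              length(x$marked_a), length(x$marked_b)))
  cat(sprintf("  only-A: %d   A-and-B: %d   only-B: %d\n",
              length(x$only_a), length(x$both), length(x$only_b)))
  invisible(x)
}

#' @export
tidy.marked_gene_sets <- function(x, ...) {
  tibble(set = c("marked_a", "marked_b", "only_a", "both", "only_b"),
         n = c(length(x$marked_a), length(x$marked_b), length(x$only_a),
               length(x$both), length(x$only_b)))
}

#' Per-region occupancy of marked genes
#'
#' For each region class, the fraction of marked genes having at least one
#' peak overlapping that class; a single peak may contribute to several
#' classes. The `intergenic` row reports the fraction of peaks assigned to
#' no gene (over peaks, not genes).
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble with region columns.
#' @param marked_genes Gene ids defining the denominator; default all genes
#'   with at least one overlapping peak.
#' @return Tibble: `region`, `n`, `frac`, `denominator`.
#' @export
classify_peak_regions <- function(peaks, genes, marked_genes = NULL) {
  regions <- region_table(genes)
  hits <- overlap_pairs(peaks, regions)
  ov <- tibble(gene_id = regions$gene_id[hits$subject_row],
               region = regions$region[hits$subject_row],
               peak_row = hits$query_row)
  if (is.null(marked_genes)) marked_genes <- unique(ov$gene_id)
  n_marked <- length(marked_genes)
  genic <- ov %>%
    filter(.data$gene_id %in% marked_genes) %>%
    distinct(.data$gene_id, .data$region) %>%
    count(.data$region) %>%
    mutate(frac = .data$n / n_marked, denominator = "marked genes")
  genic <- tibble(region = unname(REGION_LABELS)) %>%
    left_join(genic, by = "region") %>%
    mutate(n = coalesce(.data$n, 0L),
           frac = coalesce(.data$frac, 0),
           denominator = "marked genes")
  n_intergenic <- nrow(peaks) - length(unique(ov$peak_row))
  bind_rows(genic,
            tibble(region = "intergenic", n = n_intergenic,
                   frac = n_intergenic / nrow(peaks), denominator = "peaks"))
}
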