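# Quantitative comparison of ChIP-seq samples between genotypes: peak
# matching into union regions, M-A transform, constrained selection of
# reference peaks (common peaks within +/-20% RPKM whose genes are not
# differentially expressed), robust-regression rescaling, an exact
# binomial read-allocation test with BH correction, percent-of-WT
# retention classes, replicate intersection and gene-level change calls.
#
# The constraint on the reference set is the point of the procedure: when
# a mutation shifts most peaks globally, a rescaling model fitted on ALL
# common peaks absorbs the genuine global change and miscalls it as no
# change. Restricting the reference to peaks that look unchanged (and are
# not linked to differentially expressed genes) anchors the model on a
# plausibly unaffected subpopulation.

#' Match peaks across genotypes into union regions and count reads
#'
#' Wild-type and mutant peaks overlapping by at least 1 bp are merged into
#' a union region flagged common. Wild-type-only peaks are retained as
#' non-common regions; reads of both samples are counted over every region
#' (at least 1 bp overlap), so a mutant count -- and later a retention
#' percent -- is always defined. Mutant-only peaks are not part of the
#' region universe (the reverse comparison covers them).
#'
#' @param peaks_wt,peaks_mut Peak tibbles (`chrom`, `start`, `end`).
#' @param reads_wt,reads_mut Read-interval tibbles for the two samples.
#' @param library_size_wt,library_size_mut Total mapped reads; used for the
#'   RPKM columns.
#' @return Tibble of regions: `region_id`, `chrom`, `start`, `end`,
#'   `is_common`, `wt_count`, `mut_count`, `wt_rpkm`, `mut_rpkm`.
#' @export
match_common_peaks <- function(peaks_wt, peaks_mut, reads_wt, reads_mut,
                               library_size_wt, library_size_mut) {
  check_interval_frame(peaks_wt, "WT peaks")
  check_interval_frame(peaks_mut, "mutant peaks")
  gr_wt <- reduce(as_granges(peaks_wt))
  gr_mut <- reduce(as_granges(peaks_mut))
  merged <- reduce(c(gr_wt, gr_mut))
  keep <- countOverlaps(merged, gr_wt) > 0
  merged <- merged[keep]
  regions <- tibble(
    chrom = as.character(seqnames(merged)),
    start = IRanges::start(merged) - 1L,
    end = IRanges::end(merged),
    is_common = countOverlaps(merged, gr_mut) > 0
  ) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(region_id = sprintf("region_%05d", row_number()), .before = 1)
  regions$wt_count <- count_overlapping(regions, reads_wt)
  regions$mut_count <- count_overlapping(regions, reads_mut)
  if (anyNA(regions$wt_count) || anyNA(regions$mut_count)) {
    bad <- regions$region_id[is.na(regions$wt_count) | is.na(regions$mut_count)]
    abort(sprintf("missing counts for region(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  kb <- (regions$end - regions$start) / 1000
  regions %>%
    mutate(wt_rpkm = .data$wt_count / (kb * library_size_wt / 1e6),
           mut_rpkm = .data$mut_count / (kb * library_size_mut / 1e6))
}

#' M-A transform of matched region counts
#'
#' Scales each count to reads-per-million using its library size, with a
#' pseudocount of 0.5 applied as a floor (`max(count, 0.5)`), then computes
#' `M = log2(mutant intensity / WT intensity)` and `A` = mean log2
#' intensity. The floor form keeps M exact for positive counts, so an
#' exact global rescaling of counts yields an exactly constant M.
#'
#' @param records Region tibble from [match_common_peaks()].
#' @param library_size_wt,library_size_mut Total mapped reads per sample.
#' @param pseudocount Floor applied to zero counts (default 0.5).
#' @return `records` with `wt_intensity`, `mut_intensity`, `M`, `A`.
#' @export
ma_transform <- function(records, library_size_wt, library_size_mut,
                         pseudocount = 0.5) {
  if (!is.finite(library_size_wt) || !is.finite(library_size_mut) ||
      library_size_wt <= 0 || library_size_mut <= 0) {
    abort("library sizes must be positive and finite")
  }
  records %>%
    mutate(
      wt_intensity = pmax(.data$wt_count, pseudocount) / library_size_wt * 1e6,
      mut_intensity = pmax(.data$mut_count, pseudocount) / library_size_mut * 1e6,
      M = log2(.data$mut_intensity / .data$wt_intensity),
      A = 0.5 * (log2(.data$mut_intensity) + log2(.data$wt_intensity))
    )
}

#' Flag reference peaks for the rescaling model
#'
#' A region is a reference when it is common to both peak sets, its
#' mutant/WT RPKM ratio lies within the (inclusive) window, and -- when DEG
#' exclusion is on -- its linked gene is not differentially expressed.
#'
#' @param records Region tibble with RPKM columns.
#' @param links Optional link table (`peak_id` = region id, `gene_id`) from
#'   [annotate_peaks()] run on the regions; required for DEG exclusion.
#' @param deg_genes Character vector of differentially expressed gene ids.
#' @param window Inclusive RPKM-ratio window, default `c(0.8, 1.2)`.
#' @param exclude_deg Apply the DEG exclusion.
#' @param min_reference Minimum admissible number of reference regions.
#' @return `records` with `is_reference` (and `gene_id` if links given).
#' @export
select_reference_peaks <- function(records, links = NULL,
                                   deg_genes = character(),
                                   window = c(0.8, 1.2),
                                   exclude_deg = TRUE,
                                   min_reference = 50) {
  ratio <- records$mut_rpkm / records$wt_rpkm
  ref <- records$is_common & is.finite(ratio) &
    ratio >= window[1] & ratio <= window[2]
  if (!is.null(links)) {
    gmap <- links %>% select(region_id = "peak_id", "gene_id")
    records <- records %>% left_join(gmap, by = "region_id")
    if (exclude_deg && length(deg_genes) > 0) {
      ref <- ref & !(records$gene_id %in% deg_genes)
    }
  }
  if (sum(ref) < min_reference) {
    abort(sprintf(
      "only %d reference region(s) (minimum %d); widen the RPKM window or disable DEG exclusion",
      sum(ref), min_reference))
  }
  records$is_reference <- ref
  records
}

#' Fit the M-on-A rescaling model on reference regions
#'
#' Robust linear regression of M on A (Huber M-estimation, tuning constant
#' 1.345, iterated to a coefficient change below 1e-8 or 50 iterations)
#' over reference-flagged regions only. A degenerate A (zero variance)
#' falls back to an intercept-only robust fit with a warning.
#'
#' @param records Region tibble with `is_reference`, `M`, `A`.
#' @param min_reference Minimum reference count.
#' @return Object of class `rescaling_model` (intercept, slope,
#'   n_reference, estimator descriptor); `tidy()`/`glance()` supported.
#' @export
fit_rescaling <- function(records, min_reference = 50) {
  ref <- records %>% filter(.data$is_reference)
  if (nrow(ref) < min_reference) {
    abort(sprintf("%d reference region(s) < minimum %d", nrow(ref),
                  min_reference))
  }
  est <- list(loss = "Huber", k = 1.345, acc = 1e-8, maxit = 50)
  form <- if (var(ref$A) == 0) {
    warn("reference A values are constant; fitting intercept-only model")
    M ~ 1
  } else M ~ A
  # an exactly linear reference set needs no robust iteration (and rlm's
  # scale estimate degenerates there); take the least-squares solution
  ols <- stats::lm(form, data = ref)
  if (max(abs(stats::resid(ols))) < 1e-8) {
    cf <- coef(ols)
    s <- 0
  } else {
    fit <- MASS::rlm(form, data = ref, psi = MASS::psi.huber, k = est$k,
                     acc = est$acc, maxit = est$maxit)
    cf <- coef(fit)
    s <- unname(fit$s)
  }
  structure(list(intercept = unname(cf[1]),
                 slope = if (length(cf) > 1) unname(cf[2]) else 0,
                 n_reference = nrow(ref), estimator = est, scale = s),
            class = "rescaling_model")
}

#' @export
print.rescaling_model <- function(x, ...) {
  cat(sprintf(
    "<rescaling_model> M = %.4f + %.4f * A  (Huber k = %.3f, n_ref = %d)\n",
    x$intercept, x$slope, x$estimator$k, x$n_reference))
  invisible(x)
}

#' @export
tidy.rescaling_model <- function(x, ...) {
  tibble(term = c("(Intercept)", "A"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.rescaling_model <- function(x, ...) {
  tibble(n_reference = x$n_reference, sigma = x$scale,
         loss = x$estimator$loss, tuning_k = x$estimator$k)
}

#' Apply a rescaling model to all regions
#'
#' `M_rescaled = M - (a + b * A)`; `percent_of_wt = 100 * 2^M_rescaled`.
#' Applied to every region, reference or not, common or not.
#'
#' @param records Region tibble with `M`, `A`.
#' @param model A [fit_rescaling()] model.
#' @return `records` with `M_rescaled` and `percent_of_wt`.
#' @export
apply_rescaling <- function(records, model) {
  records %>%
    mutate(M_rescaled = .data$M - (model$intercept + model$slope * .data$A),
           percent_of_wt = 100 * 2^.data$M_rescaled)
}

#' Exact binomial differential test per region
#'
#' Under the null that a region is unchanged after rescaling, each of its
#' `wt + mut` reads is mutant with probability `p0 = r / (1 + r)` where
#' `r = (lib_mut / lib_wt) * 2^(a + b * A)` is the rescaled library-balance
#' factor at the region's A. The two-sided exact binomial p-value of the
#' observed mutant count is BH-adjusted across all regions of the
#' comparison. Regions with zero total count get p = 1.
#'
#' @param records Region tibble with counts and `A`.
#' @param model A [fit_rescaling()] model.
#' @param library_size_wt,library_size_mut Library sizes.
#' @return `records` with `p_value` and `p_adj`.
#' @export
peak_differential_test <- function(records, model, library_size_wt,
                                   library_size_mut) {
  r <- (library_size_mut / library_size_wt) *
    2^(model$intercept + model$slope * records$A)
  p0 <- r / (1 + r)
  n <- records$wt_count + records$mut_count
  p <- map_dbl(seq_len(nrow(records)), function(i) {
    if (n[i] == 0) return(1)
    binom.test(records$mut_count[i], n[i], p = p0[i])$p.value
  })
  records %>% mutate(p_value = p, p_adj = p.adjust(p, method = "BH"))
}

RETENTION_EDGES <- c(0, 20, 40, 60, 80, 120, 200, Inf)
RETENTION_LABELS <- c("<20", "20-40", "40-60", "60-80", "80-120 (WT level)",
                      "120-200", ">200")

#' Classify retention per region
#'
#' Direction: `reduced` when percent-of-WT < 80 and adjusted p < alpha;
#' `increased` when percent > 120 and adjusted p < alpha; `unchanged`
#' otherwise (80-120% is WT level). Bands follow 20-point steps below 80%.
#'
#' @param records Region tibble with `percent_of_wt` and `p_adj`.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return `records` with `band` and `direction`.
#' @export
classify_retention <- function(records, alpha = 0.05) {
  band <- cut(records$percent_of_wt, RETENTION_EDGES,
              labels = RETENTION_LABELS, right = FALSE)
  sig <- records$p_adj < alpha
  records %>%
    mutate(band = as.character(band),
           direction = case_when(
             .data$percent_of_wt < 80 & sig ~ "reduced",
             .data$percent_of_wt > 120 & sig ~ "increased",
             TRUE ~ "unchanged"))
}

#' One-replicate genotype comparison
#'
#' Chains matching, M-A transform, region annotation, constrained
#' reference selection, robust rescaling, the binomial test and retention
#' classification for one WT/mutant replicate pair.
#'
#' @param peaks_wt,peaks_mut Peak tibbles for the replicate.
#' @param reads_wt,reads_mut Read intervals for the replicate.
#' @param library_size_wt,library_size_mut Library sizes.
#' @param genes Gene models for region annotation (NULL to skip).
#' @param deg_genes DEG ids for reference exclusion.
#' @param window,exclude_deg,min_reference,alpha Tunables (see the
#'   individual steps).
#' @param all_common_reference Ablation switch: use ALL common regions as
#'   reference (the unconstrained normalization the constrained procedure
#'   corrects).
#' @return List: `records` (classified region tibble), `model`.
#' @export
run_replicate_comparison <- function(peaks_wt, peaks_mut, reads_wt, reads_mut,
                                     library_size_wt, library_size_mut,
                                     genes = NULL, deg_genes = character(),
                                     window = c(0.8, 1.2), exclude_deg = TRUE,
                                     min_reference = 50, alpha = 0.05,
                                     all_common_reference = FALSE) {
  rec <- match_common_peaks(peaks_wt, peaks_mut, reads_wt, reads_mut,
                            library_size_wt, library_size_mut) %>%
    ma_transform(library_size_wt, library_size_mut)
  links <- NULL
  if (!is.null(genes)) {
    links <- annotate_peaks(rec %>% rename(peak_id = "region_id"), genes)
  }
  if (all_common_reference) {
    rec <- select_reference_peaks(rec, links = links, deg_genes = character(),
                                  window = c(0, Inf), exclude_deg = FALSE,
                                  min_reference = min_reference)
  } else {
    rec <- select_reference_peaks(rec, links = links, deg_genes = deg_genes,
                                  window = window, exclude_deg = exclude_deg,
                                  min_reference = min_reference)
  }
  model <- fit_rescaling(rec, min_reference = min_reference)
  rec <- rec %>%
    apply_rescaling(model) %>%
    peak_differential_test(model, library_size_wt, library_size_mut) %>%
    classify_retention(alpha = alpha)
  list(records = rec, model = model)
}

#' Intersect differential calls of two replicates
#'
#' A region is finally reduced (resp. increased) only when called so in
#' both replicates. The reported percent-of-WT is the mean of the two
#' replicate percents.
#'
#' @param records_rep1,records_rep2 Classified region tibbles sharing the
#'   same region universe.
#' @return Tibble: region columns, per-replicate percents, `percent_of_wt`
#'   (mean), `direction`, `band`.
#' @export
intersect_replicate_calls <- function(records_rep1, records_rep2) {
  if (!identical(records_rep1$region_id, records_rep2$region_id)) {
    abort("replicate comparisons cover different region universes")
  }
  out <- records_rep1 %>%
    select("region_id", "chrom", "start", "end", any_of("gene_id"),
           percent_rep1 = "percent_of_wt", dir1 = "direction") %>%
    mutate(percent_rep2 = records_rep2$percent_of_wt,
           dir2 = records_rep2$direction,
           percent_of_wt = (.data$percent_rep1 + .data$percent_rep2) / 2,
           direction = case_when(
             .data$dir1 == "reduced" & .data$dir2 == "reduced" ~ "reduced",
             .data$dir1 == "increased" & .data$dir2 == "increased" ~ "increased",
             TRUE ~ "unchanged")) %>%
    select(-"dir1", -"dir2")
  out$band <- as.character(cut(out$percent_of_wt, RETENTION_EDGES,
                               labels = RETENTION_LABELS, right = FALSE))
  out
}

#' Gene-level change assignment
#'
#' Among the regions associated with a gene, the one with the smallest
#' percent-of-WT (biggest decrease) represents the gene; the gene inherits
#' its percent, band and direction. Percent ties go to the
#' lexicographically smaller region id (logged). Genes with no associated
#' region are omitted.
#'
#' @param final_records Output of [intersect_replicate_calls()] (or a
#'   classified single-replicate tibble) carrying `gene_id`.
#' @param links Optional link table mapping `peak_id` (region id) to
#'   `gene_id`, used when `final_records` has no `gene_id` column.
#' @return Tibble: `gene_id`, `region_id`, `percent_of_wt`, `band`,
#'   `direction`.
#' @export
gene_level_change <- function(final_records, links = NULL) {
  rec <- final_records
  if (!"gene_id" %in% names(rec)) {
    if (is.null(links)) abort("no gene_id column and no `links` supplied")
    rec <- rec %>%
      left_join(links %>% select(region_id = "peak_id", "gene_id"),
                by = "region_id")
  }
  rec <- rec %>% filter(!is.na(.data$gene_id))
  ties <- rec %>%
    group_by(.data$gene_id) %>%
    filter(n() > 1, sum(.data$percent_of_wt == min(.data$percent_of_wt)) > 1) %>%
    ungroup()
  if (nrow(ties) > 0) {
    inform(sprintf(
      "%d gene(s) with tied minimal percent-of-WT; smaller region id chosen",
      length(unique(ties$gene_id))))
  }
  rec %>%
    group_by(.data$gene_id) %>%
    arrange(.data$percent_of_wt, .data$region_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("gene_id", "region_id", "percent_of_wt", "band", "direction") %>%
    arrange(.data$gene_id)
}

#' Two-replicate genotype comparison for one mark
#'
#' Builds one region universe from the pooled replicate peak sets of each
#' genotype, runs the constrained comparison separately per replicate with
#' that replicate's reads and library sizes, intersects the calls and
#' assigns gene-level changes.
#'
#' @param peaks_wt,peaks_mut Lists of two peak tibbles (one per replicate).
#' @param reads_wt,reads_mut Lists of two read tibbles.
#' @param library_sizes Named vector with `wt_rep1`, `wt_rep2`, `mut_rep1`,
#'   `mut_rep2`.
#' @param genes,deg_genes,... Passed to [run_replicate_comparison()].
#' @return List of class `genotype_comparison`: `replicates` (two
#'   comparison lists), `final` (intersected regions), `gene_changes`.
#' @export
compare_genotypes <- function(peaks_wt, peaks_mut, reads_wt, reads_mut,
                              library_sizes, genes = NULL,
                              deg_genes = character(), ...) {
  pool <- function(lst) bind_rows(lst) %>% distinct(.data$chrom, .data$start,
                                                    .data$end)
  pw <- pool(peaks_wt)
  pm <- pool(peaks_mut)
  reps <- map(1:2, function(r) {
    run_replicate_comparison(
      pw, pm, reads_wt[[r]], reads_mut[[r]],
      library_sizes[[sprintf("wt_rep%d", r)]],
      library_sizes[[sprintf("mut_rep%d", r)]],
      genes = genes, deg_genes = deg_genes, ...)
  })
  final <- intersect_replicate_calls(reps[[1]]$records, reps[[2]]$records)
  gene_changes <- if ("gene_id" %in% names(final)) {
    gene_level_change(final)
  } else NULL
  structure(list(replicates = reps, final = final,
                 gene_changes = gene_changes),
            class = "genotype_comparison")
}

#' @export
print.genotype_comparison <- function(x, ...) {
  tab <- table(x$final$direction)
  cat(sprintf("<genotype_comparison> %d regions: %s\n", nrow(x$final),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  for (r in 1:2) print(x$replicates[[r]]$model)
  invisible(x)
}

#' @export
glance.genotype_comparison <- function(x, ...) {
  tibble(
    n_regions = nrow(x$final),
    n_reduced = sum(x$final$direction == "reduced"),
    n_increased = sum(x$final$direction == "increased"),
    intercept_rep1 = x$replicates[[1]]$model$intercept,
    slope_rep1 = x$replicates[[1]]$model$slope,
    intercept_rep2 = x$replicates[[2]]$model$intercept,
    slope_rep2 = x$replicates[[2]]$model$slope,
    n_reference_rep1 = x$replicates[[1]]$model$n_reference,
    n_reference_rep2 = x$replicates[[2]]$model$n_reference
  )
}

#' @export
tidy.genotype_comparison <- function(x, ...) {
  x$final
}
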