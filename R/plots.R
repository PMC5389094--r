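# ggplot2 helpers for the main result types.

#' Plot a metagene or peak-centred profile
#'
#' Line plot of the column-mean profile of one or more coverage matrices.
#'
#' @param ... Named `coverage_matrix` objects.
#' @return A ggplot.
#' @export
plot_metagene <- function(...) {
  mats <- list(...)
  if (is.null(names(mats)) || any(names(mats) == "")) {
    names(mats) <- paste0("track", seq_along(mats))
  }
  df <- list_rbind(imap(mats, function(m, nm) {
    profile_of(m) %>% mutate(track = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_value,
                                   colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin (5' to 3')", y = "mean coverage",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coverage_matrix <- function(object, ...) {
  plot_metagene(profile = object)
}

#' M-A plot of a replicate comparison
#'
#' Scatter of M against A with reference peaks highlighted and the fitted
#' rescaling line.
#'
#' @param records Region tibble with `M`, `A`, `is_reference`.
#' @param model Optional [fit_rescaling()] model for the fitted line.
#' @return A ggplot.
#' @export
plot_ma <- function(records, model = NULL) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$A, y = .data$M,
                                    colour = .data$is_reference)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "A (mean log2 intensity)",
                  y = "M (log2 mutant/WT)", colour = "reference") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    p <- p + ggplot2::geom_abline(intercept = model$intercept,
                                  slope = model$slope, colour = "black")
  }
  p
}

#' @export
autoplot.genotype_comparison <- function(object, replicate = 1, ...) {
  plot_ma(object$replicates[[replicate]]$records,
          object$replicates[[replicate]]$model)
}

#' Barplot of gene counts per retention band
#'
#' @param gene_changes Output of [gene_level_change()].
#' @return A ggplot.
#' @export
plot_retention_bands <- function(gene_changes) {
  df <- gene_changes %>%
    count(band = factor(.data$band, RETENTION_LABELS), .data$direction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "percent of WT", y = "genes", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
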