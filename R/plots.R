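# ggplot2 figure helpers for the main result types.

#' Per-amino-acid occupancy bar plot
#'
#' @param aa_table Output of [aggregate_amino_acid()] (optionally several,
#'   bound with a `condition` column).
#' @return A ggplot.
#' @export
plot_occupancy <- function(aa_table) {
  mapping <- if ("condition" %in% names(aa_table)) {
    aes(x = .data$amino_acid, y = .data$rho, fill = .data$condition)
  } else {
    aes(x = .data$amino_acid, y = .data$rho)
  }
  ggplot(aa_table, mapping) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "Amino acid", y = "Relative ribosome occupancy") +
    theme_classic()
}

#' Volcano plot of per-position differential occupancy
#'
#' @param object A `ribodyn_postest` from [position_differential()].
#' @param ... Unused.
#' @return A ggplot, faceted by amino-acid family.
#' @method autoplot ribodyn_postest
#' @export
autoplot.ribodyn_postest <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$log2fc, y = -log10(pmax(.data$q, 1e-300)),
             colour = .data$significant)) +
    geom_point(alpha = 0.6, size = 0.8) +
    facet_wrap(~amino_acid) +
    geom_hline(yintercept = -log10(0.05), linetype = "dashed",
               colour = "grey50") +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red3")) +
    labs(x = "log2 fold change (occupancy)", y = "-log10 adjusted p") +
    theme_classic()
}

#' Metagene plot
#'
#' @param object A `ribodyn_metagene` from [metagene()], or several bound
#'   with a `condition` column.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ribodyn_metagene
#' @export
autoplot.ribodyn_metagene <- function(object, ...) {
  d <- as_tibble(object)
  mapping <- if ("condition" %in% names(d)) {
    aes(x = .data$offset, y = .data$density, colour = .data$condition)
  } else {
    aes(x = .data$offset, y = .data$density)
  }
  ggplot(d, mapping) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    labs(x = "Offset from anchor codon", y = "Normalised footprint density") +
    theme_classic()
}

#' Cumulative-fraction plot
#'
#' @param object A `ribodyn_ecdf_cmp` from [cumulative_fraction_compare()].
#' @param ... Unused.
#' @return A ggplot of both ECDF curves with the MWU p value in the
#'   subtitle.
#' @method autoplot ribodyn_ecdf_cmp
#' @export
autoplot.ribodyn_ecdf_cmp <- function(object, ...) {
  ggplot(ecdf_curves(object),
         aes(x = .data$log2fc, y = .data$cumulative_fraction,
             colour = .data$group)) +
    geom_step() +
    labs(x = "log2 fold change", y = "Cumulative fraction",
         subtitle = paste0("two-tailed MWU p = ",
                           format.pval(object$mwu$p.value, digits = 3))) +
    theme_classic()
}

#' Violin plot of per-transcript CV by condition
#'
#' @param cv_tables Named list of CV tables from [transcript_cv()] (one per
#'   condition).
#' @return A ggplot.
#' @export
plot_cv_violin <- function(cv_tables) {
  d <- purrr::imap_dfr(cv_tables, ~ mutate(.x, condition = .y))
  ggplot(d, aes(x = .data$condition, y = .data$cv, fill = .data$condition)) +
    geom_violin() +
    geom_boxplot(width = 0.1, outlier.shape = NA, fill = "white") +
    labs(x = NULL, y = "CV of A-site occupancy") +
    theme_classic() +
    theme(legend.position = "none")
}

#' Histogram of disome peak intensity fold changes
#'
#' @param peak_fc Output of [peak_fold_change()].
#' @return A ggplot with a dashed line at zero change.
#' @export
plot_peak_fc_hist <- function(peak_fc) {
  ggplot(peak_fc, aes(x = .data$log2fc)) +
    geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "log2 fold change (disome peak intensity)", y = "Peaks") +
    theme_classic()
}
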