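#' Volcano plot of screen phenotypes
#'
#' Phenotype versus -log10 p for genes and NTC pseudo-genes, with hits
#' highlighted at the discriminant threshold used in the call.
#'
#' @param x a `screen_hits` object from [call_hits()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.screen_hits <- function(x, ...) {
  tab <- x$table
  tab$neg_log10_p <- -log10(pmax(tab[[paste0("p_", x$phenotype)]], 1e-300))
  tab$class <- dplyr::case_when(
    tab$hit ~ "hit",
    tab$is_pseudo ~ "NTC pseudo-gene",
    TRUE ~ "gene"
  )
  ggplot2::ggplot(
    tab,
    ggplot2::aes(x = .data[[x$phenotype]], y = .data$neg_log10_p,
                 colour = .data$class)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(hit = "#7B3294", gene = "grey50", `NTC pseudo-gene` = "#008837")
    ) +
    ggplot2::labs(
      x = paste(x$phenotype, "phenotype (log2)"),
      y = expression(-log[10] ~ italic(p)),
      colour = NULL,
      title = sprintf("%d/%d hits at discriminant >= %g (empiric FDR %.2g)",
                      x$n_hits, x$n_genes, x$threshold, x$empiric_fdr)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of module scores
#'
#' Tile heatmap of log2 module scores relative to NTC cells at 0Gy, with
#' rows and columns in the complete-linkage / Pearson clustering order.
#'
#' @param x a `module_scores` object from [score_modules()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.module_scores <- function(x, ...) {
  long <- tidy(x)
  long$key <- paste(long$module, long$condition, sep = "@")
  long$target <- factor(long$target, levels = rownames(x$scores)[x$row_order])
  long$key <- factor(long$key, levels = colnames(x$scores)[x$col_order])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$key, y = .data$target,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = "module @ condition", y = "perturbation target",
                  fill = "log2 score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a flank-normalised coverage profile
#'
#' @param profile tibble from [profile_matrix()].
#' @return a ggplot object.
#' @export
plot_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position,
                                        y = .data$normalized)) +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "position relative to region centre (bp)",
                  y = "flank-normalised coverage") +
    ggplot2::theme_minimal()
}

#' Knockdown overview plot
#'
#' Per-guide knockdown by lane, with the retention threshold marked.
#'
#' @param kd knockdown tibble from [quantify_knockdown()].
#' @param min_kd retention threshold to draw (default 0.75).
#' @return a ggplot object.
#' @export
plot_knockdown <- function(kd, min_kd = 0.75) {
  ggplot2::ggplot(
    dplyr::filter(kd, !is.na(.data$knockdown)),
    ggplot2::aes(x = .data$guide, y = .data$knockdown, colour = .data$lane)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = min_kd, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "knockdown (1 - RNA remaining)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
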