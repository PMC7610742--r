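#' Manhattan plot of one scan
#'
#' Plots -log10 p against genomic position, faceted by chromosome, with
#' the genome-wide and (optionally) Bonferroni thresholds and peaks
#' highlighted.
#'
#' @param sumstats Scan tibble (`chromosome, bp, neglog10p`).
#' @param peaks Optional peak tibble to highlight.
#' @param threshold Genome-wide -log10 p line (default 7.5).
#' @param bonferroni Optional second threshold line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(sumstats, peaks = NULL, threshold = 7.5,
                           bonferroni = NULL) {
  df <- as_tibble(sumstats)
  df$chromosome <- factor(df$chromosome, levels = c(as.character(1:22), "X"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bp / 1e6,
                                        y = .data$neglog10p)) +
    ggplot2::geom_point(size = 0.4, colour = "grey40") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey55") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (!is.null(bonferroni)) {
    p <- p + ggplot2::geom_hline(yintercept = bonferroni,
                                 linetype = "dotted", colour = "grey55")
  }
  if (!is.null(peaks) && nrow(peaks) > 0) {
    pk <- as_tibble(peaks)
    pk$chromosome <- factor(pk$chromosome, levels = levels(df$chromosome))
    p <- p + ggplot2::geom_point(data = pk, colour = "firebrick", size = 1.2)
  }
  p
}

#' @export
autoplot.gwas_clusters <- function(object, ...) {
  members <- object$members
  if (nrow(members) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No clusters"))
  }
  members$chromosome <- factor(members$chromosome,
                               levels = c(as.character(1:22), "X"))
  ggplot2::ggplot(members,
                  ggplot2::aes(x = .data$cM, y = .data$neglog10p,
                               colour = factor(.data$cluster_id))) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$is_lead), size = 1.6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "lead") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "genetic position (cM)",
                  y = expression(-log[10](italic(p))), colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
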