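#' Manhattan-style plot of an association scan
#'
#' @param object An `mwas_result`.
#' @param fdr_line Draw the largest significant p-value as the FDR line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mwas_result
#' @export
autoplot.mwas_result <- function(object, fdr_line = TRUE, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$p))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos,
                                        y = -log10(.data$p),
                                        colour = .data$panel)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p)),
                  colour = "panel") +
    ggplot2::theme_minimal()
  bon <- attr(object, "bonferroni")
  if (!is.null(bon)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(bon),
                                 linetype = "dashed", colour = "blue")
  }
  if (fdr_line && any(df$significant)) {
    thr <- max(df$p[df$significant])
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Per-site posterior inclusion probabilities by LD block
#'
#' @param object A `finemap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot finemap_result
#' @export
autoplot.finemap_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$pip,
                                   colour = .data$in_credible_set)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$block_id), scales = "free_x") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position (bp)", y = "PIP",
                  colour = "in credible set") +
    ggplot2::theme_minimal()
}

#' Paired category proportions for an enrichment result
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- as_tibble(object) |>
    select("category", associated = "proportion_assoc",
           tested = "proportion_all") |>
    pivot_longer(-"category", names_to = "set", values_to = "proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$proportion,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion of CpG sites", fill = NULL) +
    ggplot2::theme_minimal()
}
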