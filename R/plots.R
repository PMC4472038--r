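#' Heatmap of identity scores
#'
#' Classes in rows, query samples in columns, scores mapped from black (0) to
#' green (1).
#'
#' @param object An `identity_scores` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.identity_scores <- function(object, ...) {
  df <- tidy(object)
  df$class <- factor(df$class, levels = rev(rownames(object$scores)))
  df$sample_id <- factor(df$sample_id, levels = colnames(object$scores))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$class,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "green3",
                                 limits = c(0, 1), name = "identity\nscore") +
    ggplot2::labs(x = "query sample", y = "training class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}

#' Cross-validation curve of an identity classifier
#'
#' Mean multinomial deviance with one-SE ribbon along the penalty path; the
#' selected penalty is marked.
#'
#' @param object An `identity_classifier`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.identity_classifier <- function(object, ...) {
  df <- object$cv_deviance
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$penalty), y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(object$selected_penalty),
                        linetype = "dashed") +
    ggplot2::labs(x = "log10 penalty", y = "CV multinomial deviance") +
    ggplot2::theme_minimal()
}

#' Barcode bin heatmap
#'
#' Tile plot of the binned barcode table from [barcode_bins()]: green shades
#' where the gene classifies the tissue, blue shades elsewhere.
#'
#' @param bins Tibble from [barcode_bins()].
#' @return A ggplot.
#' @export
plot_barcode <- function(bins) {
  df <- bins
  df$column <- if ("stage" %in% names(df) && any(!is.na(df$stage))) {
    paste(df$class, ifelse(is.na(df$stage), "", df$stage))
  } else df$class
  df$shade <- paste(ifelse(df$in_classifying_tissue, "clf", "other"), df$bin)
  pal <- c("other <50" = "grey95", "other 50-100" = "lightblue",
           "other 100-1000" = "steelblue", "other >1000" = "darkblue",
           "clf <50" = "grey85", "clf 50-100" = "palegreen",
           "clf 100-1000" = "green3", "clf >1000" = "darkgreen")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$gene_id,
                                   fill = .data$shade)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = pal, name = "mean CPM bin") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}
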