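#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_line geom_abline
#'   scale_x_log10 scale_y_log10 labs theme_minimal coord_flip
NULL

#' Plot enrichment results as a bar chart
#'
#' One bar per enriched item, bar length = number of overlapping targets,
#' fill = adjusted p-value (FDR).
#'
#' @param object a `mirna_enrichment` table.
#' @param top show at most this many items (by p-value).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mirna_enrichment <- function(object, top = 20, ...) {
  df <- head(as_tibble(object), top)
  df$item <- factor(df$item, levels = rev(df$item))
  ggplot(df, aes(x = .data$item, y = .data$X, fill = .data$fdr)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "targets in input list", fill = "FDR") +
    theme_minimal()
}

#' Plot a degree distribution with its power-law fit on log-log axes
#'
#' @param object a `power_law_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.power_law_fit <- function(object, ...) {
  df <- object$data
  line <- tibble(
    degree = df$degree,
    probability = 10^(object$intercept - object$exponent * log10(df$degree))
  )
  ggplot(df, aes(x = .data$degree, y = .data$probability)) +
    geom_point() +
    geom_line(data = line, colour = "steelblue") +
    scale_x_log10() +
    scale_y_log10() +
    labs(
      x = "degree k", y = "P(k)",
      title = sprintf("power-law fit: gamma = %.2f, r-squared = %.2f",
                      object$exponent, object$r_squared)
    ) +
    theme_minimal()
}

#' Plot a ROC curve from a detection evaluation
#'
#' Operating points (one per activity level) with the monotone staircase
#' through them and the no-discrimination diagonal.
#'
#' @param object a `roc_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_eval <- function(object, ...) {
  pts <- object$points[order(object$points$fpr, object$points$tpr), ]
  stair <- tibble(
    fpr = c(0, pts$fpr, 1),
    tpr = cummax(c(0, pts$tpr, 1))
  )
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(data = stair) +
    geom_point(aes(colour = .data$alpha)) +
    labs(
      x = "false positive rate (1 - specificity)",
      y = "true positive rate (sensitivity)",
      colour = "alpha",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    theme_minimal()
}

#' Dot plot of functional-enrichment results
#'
#' Categories on the y-axis; dot size is the gene ratio, colour the FDR.
#'
#' @param object a `functional_enrichment` table.
#' @param top show at most this many categories (by p-value).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.functional_enrichment <- function(object, top = 20, ...) {
  df <- head(as_tibble(object), top)
  df$category <- factor(df$category, levels = rev(df$category))
  ggplot(df, aes(x = .data$gene_ratio, y = .data$category,
                 size = .data$gene_ratio, colour = .data$fdr)) +
    geom_point() +
    labs(x = "gene ratio", y = NULL, colour = "FDR", size = "gene ratio") +
    theme_minimal()
}
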