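#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_col geom_abline labs
#'   coord_equal theme_minimal
#' @export
ggplot2::autoplot

#' Plot similarity scores per database entry
#'
#' @param object A `sigdb_scores` tibble.
#' @param metric Which metric to plot: `"IoU"`, `"IoQ"` or `"IoD"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigdb_scores <- function(object, metric = c("IoU", "IoQ", "IoD"), ...) {
  metric <- match.arg(metric)
  df <- tidy(object)
  df$entry_id <- factor(df$entry_id, levels = df$entry_id[order(-df[[metric]])])
  ggplot(df, aes(x = .data$entry_id, y = .data[[metric]])) +
    geom_col() +
    labs(x = "database entry", y = metric,
         title = "Similarity of database entries to the (secret) query") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a ROC curve
#'
#' @param object A `sigdb_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigdb_roc <- function(object, ...) {
  df <- tidy(object)
  df <- df[order(df$fpr, df$tpr), ]
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step(direction = "vh") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    coord_equal() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    theme_minimal()
}

#' Plot per-length-set AUCs of a correctness evaluation
#'
#' @param object A `sigdb_correctness`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigdb_correctness <- function(object, ...) {
  df <- glance(object)
  ggplot(df, aes(x = factor(.data$entry_len), y = .data$auc,
                 fill = factor(.data$tau))) +
    geom_col(position = "dodge") +
    labs(x = "database entry length (bp)", y = "AUC", fill = "ANI threshold") +
    theme_minimal()
}
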