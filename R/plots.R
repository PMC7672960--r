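#' Plot the row-norm profile of a fitted discriminant matrix
#'
#' @param object A [fit_mtfs_glasso()] result.
#' @param ... Unused.
#' @return A ggplot: per-feature l2 row norm, selected rows highlighted.
#' @export
autoplot.mtfs_glasso <- function(object, ...) {
  df <- tibble::tibble(
    feature = seq_len(nrow(object$W)),
    row_norm = sqrt(rowSums(object$W^2)),
    selected = sqrt(rowSums(object$W^2)) > 1e-8
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$row_norm,
                                   fill = .data$selected)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey80",
                                          `TRUE` = "#2c7fb8")) +
    ggplot2::labs(x = "feature index", y = "row l2 norm",
                  title = paste0("Group-LASSO row norms (lambda = ",
                                 format(object$lambda), ")")) +
    ggplot2::theme_minimal()
}

#' Plot a GCN training-loss trace
#'
#' @param object A [train_gcn()] result.
#' @param ... Unused.
#' @return A ggplot of masked cross-entropy per epoch.
#' @export
autoplot.gcn_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "epoch", y = "masked cross-entropy",
                  title = "GCN training loss") +
    ggplot2::theme_minimal()
}
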