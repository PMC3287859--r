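# ggplot2 displays for fitted objects

#' @describeIn cross_validate CV-error curve against `log(lambda)` with
#'   one-standard-error ribbons and the chosen penalties marked.
#' @param object The fitted object.
#' @export
autoplot.cv_lasso <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = log(.data$lambda), y = .data$cvm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cvm - .data$cvse,
                                      ymax = .data$cvm + .data$cvse),
                         fill = "grey85") +
    ggplot2::geom_point(size = 0.8, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = log(object$lambda_min), linetype = 2) +
    ggplot2::geom_vline(xintercept = log(object$lambda_1se), linetype = 3) +
    ggplot2::labs(x = expression(log(lambda)),
                  y = "mean squared CV error",
                  title = sprintf("%d-fold CV (dashed: lambda_min, dotted: lambda_1se)",
                                  object$K)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_path Coefficient profiles along the penalty path.
#' @param object The fitted object.
#' @export
autoplot.lasso_path <- function(object, ...) {
  df <- tidy.lasso_path(object)
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda), y = .data$estimate,
                                   group = .data$term,
                                   colour = .data$penalized)) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = expression(log(lambda)),
                  y = "standardized coefficient") +
    ggplot2::theme_minimal()
}

#' @describeIn bag_lasso RMIP against SNP rank (zero-RMIP SNPs omitted),
#'   simulating-model SNPs highlighted when `truth` is supplied.
#' @param object The fitted object.
#' @param truth Optional causal SNP ids to highlight.
#' @param ... Unused.
#' @export
autoplot.rmip_table <- function(object, truth = NULL, ...) {
  df <- rmip_report(object, truth = truth)
  df <- df[df$rmip > 0, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$rmip))
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$is_truth,
                                              size = .data$is_truth)) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                              `TRUE` = "firebrick"),
                                   name = "simulating model") +
      ggplot2::scale_size_manual(values = c(`FALSE` = 0.6, `TRUE` = 2),
                                 guide = "none")
  } else {
    p <- p + ggplot2::geom_point(size = 0.6, colour = "grey40")
  }
  p + ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "SNP rank by RMIP", y = "RMIP",
                  title = sprintf("LASSO bagging, B = %d, lambda = %.4g",
                                  object$B, object$lambda)) +
    ggplot2::theme_minimal()
}

#' @describeIn selection_summary Per-truth-SNP selection frequency by
#'   procedure.
#' @param object The fitted object.
#' @param ... Unused.
#' @export
autoplot.selection_summary <- function(object, ...) {
  df <- dplyr::filter(object$per_snp, .data$is_truth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp_id, y = .data$freq,
                                   fill = .data$procedure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "selection frequency over replicates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
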