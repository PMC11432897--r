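#' Plot LOOCV fold probabilities
#'
#' Dot plot of per-document AS probabilities by true group, one panel per
#' annotation source, with the 0.5 decision threshold marked.
#'
#' @param object An `sfl_folds` tibble from [loocv_run()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfl_folds <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("p_manual", "p_auto"),
                              names_to = "annotation", names_prefix = "p_",
                              values_to = "p_AS")
  long <- dplyr::filter(long, !is.na(.data$p_AS))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$y_true, y = .data$p_AS,
                                     colour = .data$y_true)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::facet_wrap(~annotation) +
    ggplot2::labs(x = "true group", y = "P(AS)",
                  title = paste0("LOOCV probabilities (",
                                 attr(object, "variant") %||% "classifier",
                                 ")")) +
    ggplot2::guides(colour = "none")
}

#' Plot a report's metric table
#'
#' Bar chart of accuracy, precision, sensitivity, specificity and AUC per
#' variant, faceted by annotation source.
#'
#' @param object An `sfl_report` from [build_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfl_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              cols = c("accuracy", "precision", "sensitivity",
                                       "specificity", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~annotation) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Differentiation performance") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an annotator's training loss
#'
#' @param object A trained `sfl_annotator`.
#' @param ... Unused.
#' @return A ggplot object of per-epoch mean training loss.
#' @export
autoplot.sfl_annotator <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Tagger training loss", y = "mean per-token loss")
}

#' @importFrom rlang %||%
NULL
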