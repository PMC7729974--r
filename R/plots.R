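# ggplot2 views of the main result types. Plain exports, no styling claims.

#' @method autoplot venn_partition
#' @export
autoplot.venn_partition <- function(object, ...) {
  df <- tibble::tibble(
    set = factor(c("AF only", "common", "FU only"),
                 levels = c("AF only", "common", "FU only")),
    n = c(length(object$af_only_ids), object$n_common,
          length(object$fu_only_ids))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "peptides",
                  title = sprintf("Common = %s%% of AF peptide number",
                                  format(round_half_up(object$pct_of_af_number)))) +
    ggplot2::theme_minimal()
}

#' @method autoplot bin_trend
#' @export
autoplot.bin_trend <- function(object, ...) {
  ggplot2::ggplot(object$by_bin,
                  ggplot2::aes(x = .data$ga_bin, y = .data$mean, group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem
    )) +
    ggplot2::labs(x = "gestational age (WA)", y = object$value,
                  subtitle = sprintf("one-way ANOVA p = %.2g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' ROC curve of a validation report
#'
#' @param object a `validation_report`.
#' @param ... unused.
#' @return a ggplot: empirical ROC curve of the validation scores with the
#'   AUC and its CI in the subtitle.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  sc <- object$scores
  thr <- c(Inf, sort(unique(sc$score), decreasing = TRUE), -Inf)
  roc <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(
      fpr = mean(sc$score[sc$outcome == "noESRD"] >= t),
      tpr = mean(sc$score[sc$outcome == "ESRD"] >= t)
    )
  })
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      subtitle = sprintf("AUC %.2f [%.2f-%.2f]", object$auc,
                         object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a paired origin screen
#'
#' Scatter of per-peptide Spearman rho against -log10 p, FU-origin calls
#' highlighted.
#'
#' @param screen tibble from [paired_origin_screen()].
#' @param alpha significance level drawn as a reference line.
#' @return a ggplot.
#' @export
plot_origin_screen <- function(screen, alpha = 0.05) {
  df <- dplyr::filter(screen, !is.na(.data$rho))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = -log10(.data$p_value),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Spearman rho (paired AF vs FU)", y = "-log10 p",
                  colour = "FU origin") +
    ggplot2::theme_minimal()
}
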