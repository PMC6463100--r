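#' Plot calibrated homopolymer thresholds over the training cloud
#'
#' Scatter of `var` against `frmode` for the training indels, with the
#' threshold lines and the rejection region (`var > maxVar` and
#' `frmode < minFrmode`) shaded. True positives cluster in the
#' low-variance, high-frmode corner; the rejection region should capture
#' only false positives.
#'
#' @param object An [hp_thresholds()] object with a training table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hp_thresholds <- function(object, ...) {
  if (is.null(object$training)) {
    abort("no training table attached; calibrate with calibrate_thresholds()")
  }
  tr <- object$training
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$var, y = .data$frmode,
                                   colour = .data$label)) +
    ggplot2::annotate(
      "rect", xmin = object$max_var, xmax = Inf,
      ymin = -Inf, ymax = object$min_frmode,
      fill = "firebrick", alpha = 0.12
    ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = object$max_var, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$min_frmode, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(TP = "forestgreen",
                                            FP = "firebrick")) +
    ggplot2::labs(
      x = "var (variance of indel event length, bp²)",
      y = "frmode (frequency of modal event length)",
      colour = "Sanger label",
      title = "Homopolymer indel filter calibration",
      subtitle = sprintf("maxVar = %.4g, minFrmode = %.4g; shaded = rejected",
                         object$max_var, object$min_frmode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the confidence-score distribution of merged variants
#'
#' Bar chart of variant counts per confidence score, split by variant
#' type, covering the full 1..max score range.
#'
#' @param object A [merge_callsets()] result.
#' @param max_score Passed to [score_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.merged_variants <- function(object, max_score = NULL, ...) {
  dist <- score_distribution(object, max_score)
  by_type <- dplyr::count(as_tibble(object), score = .data$confidence,
                          .data$type, name = "n")
  ggplot2::ggplot(by_type, ggplot2::aes(x = factor(.data$score,
                                                   levels = dist$score),
                                        y = .data$n, fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "confidence score (supporting combinations)",
                  y = "variants", fill = "type",
                  title = "Confidence-score distribution") +
    ggplot2::theme_minimal()
}

#' Plot the per-gene variant distribution of a report
#'
#' @param object A [build_report()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variant_report <- function(object, ...) {
  pg <- object$per_gene
  if (nrow(pg) == 0) {
    abort("report has no gene annotation; supply an annotation table")
  }
  ggplot2::ggplot(pg, ggplot2::aes(x = stats::reorder(.data$gene, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "gene", y = "variants",
                  title = "Variant distribution per gene") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
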