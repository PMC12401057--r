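#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-gene copy numbers of a genotyping result
#'
#' Stacked per-gene allele copy numbers, shaded by prefix consistency when
#' confidence analysis ran.
#'
#' @param object A `vg_genotype`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vg_genotype <- function(object, ...) {
  calls <- object$calls
  if (nrow(calls) == 0L) {
    return(ggplot2::ggplot() + ggplot2::labs(title = "no allele calls"))
  }
  has_pc <- !all(is.na(calls$prefix_consistency))
  p <- ggplot2::ggplot(calls,
                       ggplot2::aes(x = .data$gene_id, y = .data$copy_number,
                                    fill = if (has_pc) factor(.data$prefix_consistency)
                                           else .data$allele_id)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = "copy number",
                  fill = if (has_pc) "prefix consistency" else "allele") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  p
}

#' Plot a per-gene confidence calibration
#'
#' PPV and passing proportion as a function of the prefix-consistency
#' threshold, one line per gene, with the F-beta-optimal threshold marked.
#'
#' @param object A `vg_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vg_calibration <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("ppv", "passing_proportion"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$gene_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(long, .data$is_optimal), size = 2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "prefix-consistency threshold", y = NULL,
                  colour = "gene") +
    ggplot2::theme_minimal()
}

#' Plot per-gene trio concordance outcomes
#'
#' @param object A `concordance_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concordance_result <- function(object, ...) {
  ggplot2::ggplot(object$per_gene,
                  ggplot2::aes(x = .data$reason, fill = .data$concordant)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "genes",
                  title = sprintf("trio concordance %.3f",
                                  object$trio_concordance)) +
    ggplot2::theme_minimal()
}
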