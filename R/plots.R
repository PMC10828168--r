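#' Plot cross-validated clock predictions
#'
#' Out-of-fold predicted versus true age (years, or lifespan fractions for
#' relative clocks), colored by species, with the identity line and the
#' Pearson R / median absolute error in the title.
#'
#' @param object A `clock_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clock_cv <- function(object, ...) {
  units <- if (object$transform_kind == "relative") "relative age" else "years"
  m <- object$metrics
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               colour = .data$species)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      title = sprintf("%s clock (%s): R = %.2f, MAE = %.3g",
                      object$name, object$cv, m$pearson_r, m$median_abs_error),
      x = paste0("age (", units, ")"),
      y = paste0("DNAm age (", units, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of an EWAS table
#'
#' CpGs by table position against `-log10(p)`, colored by direction of the
#' age correlation, with the genome-wide and suggestive thresholds marked.
#' (Genomic coordinates are not required; join them beforehand and pass a
#' `position` column to order by location.)
#'
#' @param rows EWAS or meta tibble.
#' @param genomewide,suggestive Cutoffs drawn as horizontal lines.
#' @return A ggplot.
#' @export
plot_manhattan <- function(rows, genomewide = 1e-7, suggestive = 1e-5) {
  p <- rows[["p"]] %||% rows[["p_meta"]]
  z <- rows[["z"]] %||% rows[["z_meta"]]
  df <- tibble::tibble(
    pos = rows[["position"]] %||% seq_len(nrow(rows)),
    logp = -log10(p),
    direction = ifelse(z >= 0, "+", "-")
  )
  df <- df[!is.na(df$logp), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$logp,
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(genomewide), colour = "black",
                        linetype = 1) +
    ggplot2::geom_hline(yintercept = -log10(suggestive), colour = "red",
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c("+" = "firebrick", "-" = "steelblue")) +
    ggplot2::labs(x = "CpG", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' Heatmap of an enrichment report
#'
#' Annotation sets by EWAS source and direction, filled with the signed
#' `-log10(p)` (positive red for odds ratio > 1, negative blue for
#' depletion).
#'
#' @param table Output of [enrichment_report()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = interaction(.data$source, .data$direction),
                               y = .data$set_name,
                               fill = .data$signed_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "EWAS source . direction", y = NULL,
                  fill = expression(-log[10](italic(p)) %*% sign(OR > 1))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
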