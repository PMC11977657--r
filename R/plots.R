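# ggplot2 views of landscapes, SSSS curves, CPDV cut points and methylation
# scores.

#' Plot a word-enrichment landscape
#'
#' One line per word: bins (leading-edge size) on the x axis, signed
#' `-log10 p` on the y axis; positive values mean enrichment among the most
#' downregulated genes, negative depletion.
#'
#' @param landscape A `scr_landscape` from [hypergeometric_landscape()].
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  assert_cols(landscape, c("n_leading", "word", "signed_score"), "landscape")
  ggplot2::ggplot(as_tibble(landscape),
                  ggplot2::aes(x = .data$n_leading, y = .data$signed_score,
                               colour = .data$word)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "leading-edge genes (most downregulated first)",
                  y = expression(signed ~ -log[10] ~ italic(P)),
                  colour = "SCR word") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scr_landscape <- function(object, ...) plot_landscape(object)

#' Plot SSSS curves per miRNA
#'
#' @param ssss A `scr_ssss` from [ssss_integration()].
#' @return A ggplot object.
#' @export
plot_ssss <- function(ssss) {
  assert_cols(ssss, c("n_leading", "mirna", "ssss"), "ssss")
  ggplot2::ggplot(as_tibble(ssss),
                  ggplot2::aes(x = .data$n_leading, y = .data$ssss,
                               colour = .data$mirna)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "leading-edge genes", y = "SSSS", colour = "miRNA") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scr_ssss <- function(object, ...) plot_ssss(object)

#' Plot a CPDV curve with its selected cut
#'
#' @param cutpoint A `scr_cutpoint` from [cpdv_select()].
#' @return A ggplot object.
#' @export
plot_cpdv <- function(cutpoint) {
  stopifnot(inherits(cutpoint, "scr_cutpoint"))
  df <- cutpoint$table %>% filter(is.finite(.data$cpdv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$cpdv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = cutpoint$selected_bin,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "bin", y = "CPDV") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scr_cutpoint <- function(object, ...) plot_cpdv(object)

#' Plot cumulative methylation scores by group
#'
#' Bar per sample, coloured by group, with the maximum attainable score
#' (100 x number of sites) marked.
#'
#' @param scores Tibble from [cumulative_methylation()].
#' @return A ggplot object.
#' @export
plot_methylation <- function(scores) {
  assert_cols(scores, c("sample_id", "group", "cumulative", "max_score"), "scores")
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$sample_id, y = .data$cumulative,
                               fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = max(scores$max_score), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "cumulative methylation score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
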