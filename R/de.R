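# Volcano-style classification of a protein quantification table.
#
# The paper-facing rule: a protein is upregulated in the HA medium when
# log2 fold change >= 1 and adjusted p <= 0.05 (both comparisons inclusive),
# downregulated when log2 FC <= -1 at the same p gate, significant-but-small
# when only the p gate passes, and not significant otherwise.  The p-value
# adjustment is Benjamini-Hochberg; the upstream source of the p-values does
# not name its adjustment, so BH (the proteomics field standard) is used and
# stated prominently here.

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] with `method = "BH"`:
#' adjusted values are monotone in p-rank and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) {
    return(numeric())
  }
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
    any(p_values <= 0 | p_values > 1)) {
    abort("p-values must be in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

DE_CLASSES <- c("up", "down", "significant_small_fc", "not_significant")

#' Four-way volcano classification
#'
#' @param log2fc Numeric vector of log2 fold changes (positive = higher in
#'   the HA medium).
#' @param adjusted_p Adjusted p-values, same length.
#' @param fc_threshold Absolute log2 FC threshold (default 1, inclusive).
#' @param p_threshold Adjusted-p threshold (default 0.05, inclusive).
#' @return Factor with levels `up`, `down`, `significant_small_fc`,
#'   `not_significant`.
#' @examples
#' classify_volcano(c(1, -2, 0.5), c(0.05, 0.2, 0.001))
#' @export
classify_volcano <- function(log2fc, adjusted_p, fc_threshold = 1, p_threshold = 0.05) {
  if (length(log2fc) != length(adjusted_p)) abort("inputs must have equal length")
  if (any(!is.finite(log2fc)) || any(!is.finite(adjusted_p))) abort("inputs must be finite")
  cls <- dplyr::case_when(
    adjusted_p <= p_threshold & log2fc >= fc_threshold ~ "up",
    adjusted_p <= p_threshold & log2fc <= -fc_threshold ~ "down",
    adjusted_p <= p_threshold ~ "significant_small_fc",
    TRUE ~ "not_significant"
  )
  factor(cls, levels = DE_CLASSES)
}

#' Adjust and classify a protein quantification table
#'
#' Adds Benjamini-Hochberg adjusted p-values (`padj`) and the four-way
#' volcano class (`de_class`) to a table of per-protein log2 fold changes
#' and raw p-values.
#'
#' @param quant Data frame with at least the fold-change and p-value columns.
#' @param fc_col,p_col Column names (defaults `"log2fc"`, `"pvalue"`).
#' @inheritParams classify_volcano
#' @return The input as a tibble with `padj` and `de_class` columns added.
#' @export
de_classify <- function(quant, fc_col = "log2fc", p_col = "pvalue",
                        fc_threshold = 1, p_threshold = 0.05) {
  if (!is.data.frame(quant)) abort("`quant` must be a data frame")
  if (!all(c(fc_col, p_col) %in% names(quant))) {
    abort(paste0("`quant` must have columns ", fc_col, " and ", p_col))
  }
  out <- as_tibble(quant)
  out$padj <- bh_adjust(out[[p_col]])
  out$de_class <- classify_volcano(out[[fc_col]], out$padj,
    fc_threshold = fc_threshold, p_threshold = p_threshold
  )
  out
}

#' Volcano plot of a classified quantification table
#'
#' @param quant Output of [de_classify()].
#' @param fc_col Fold-change column name.
#' @return A ggplot object; x is log2 FC, y is -log10 adjusted p, colored by
#'   class (up red, down green, significant-small yellow, rest grey).
#' @export
plot_volcano <- function(quant, fc_col = "log2fc") {
  if (!all(c(fc_col, "padj", "de_class") %in% names(quant))) {
    abort("`quant` must be the output of de_classify()")
  }
  ggplot2::ggplot(
    quant,
    ggplot2::aes(.data[[fc_col]], -log10(.data$padj), color = .data$de_class)
  ) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_color_manual(values = c(
      up = "#c0392b", down = "#1e8449",
      significant_small_fc = "#f1c40f", not_significant = "grey60"
    ), drop = FALSE) +
    ggplot2::labs(
      x = expression(log[2] ~ "fold change"),
      y = expression(-log[10] ~ "adjusted" ~ italic(p)),
      color = NULL
    ) +
    ggplot2::theme_minimal()
}
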