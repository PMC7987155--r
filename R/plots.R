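# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_vline geom_tile labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Plot a background score distribution with its calibrated threshold
#'
#' @param object A `score_distribution`.
#' @param threshold Optional `motif_threshold` drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot score_distribution
#' @export
autoplot.score_distribution <- function(object, threshold = NULL, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(x = .data$score, y = .data$prob)) +
    geom_col(width = object$delta * 0.9, fill = "grey35") +
    labs(x = "score (bits)", y = "background probability") +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_vline(xintercept = threshold$t, linetype = "dashed",
                        colour = "firebrick")
  }
  p
}

#' Sequence-logo style view of a PSSM
#'
#' Per-position stacked information contributions (freq x log2(freq/bg)).
#'
#' @param object A `pssm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pssm
#' @export
autoplot.pssm <- function(object, ...) {
  d <- tidy(object)
  d$bits <- d$freq * ifelse(is.finite(d$logodds), d$logodds, 0)
  d$bits <- pmax(d$bits, 0)
  ggplot(d, aes(x = factor(.data$position), y = .data$bits,
                fill = .data$base)) +
    geom_col() +
    labs(x = "motif position", y = "information (bits)") +
    theme_minimal()
}

#' Funnel plot of a regulon comparison cascade
#'
#' @param object A `cascade_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cascade_result
#' @export
autoplot.cascade_result <- function(object, ...) {
  d <- tibble(stage = factor(object$stage, levels = rev(object$stage)),
              count = object$count)
  ggplot(d, aes(x = .data$count, y = .data$stage)) +
    geom_col(fill = "steelblue") +
    labs(x = "genes remaining", y = NULL) +
    theme_minimal()
}

#' Heatmap of per-species posterior probabilities of regulation
#'
#' Rows are ortholog groups in ranked order (as produced by
#' [rank_and_export()]), columns species; missing orthologs are blank.
#'
#' @param ranked Ranked table from [rank_and_export()] with posterior
#'   columns.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_conservation_heatmap <- function(ranked, ...) {
  long <- tidyr::pivot_longer(ranked, dplyr::starts_with("posterior_"),
                              names_to = "species_id", names_prefix = "posterior_",
                              values_to = "posterior")
  long$group_id <- factor(long$group_id, levels = rev(ranked$group_id))
  ggplot(long, aes(x = .data$species_id, y = .data$group_id,
                   fill = .data$posterior)) +
    geom_tile() +
    scale_fill_gradient(low = "yellow", high = "cyan4", na.value = "white") +
    labs(x = NULL, y = NULL, fill = "P(regulated)") +
    theme_minimal()
}
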