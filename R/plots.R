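#' Plot sample PCA scores
#'
#' @param object An `innate_pca` from [pca_samples()].
#' @param sample_map Optional sample map; when given, points are coloured
#'   by population.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.innate_pca <- function(object, sample_map = NULL, ...) {
  d <- object$scores
  if (!is.null(sample_map)) {
    d <- dplyr::left_join(d, sample_map, by = "sample_id")
  }
  p <- ggplot(d, aes(PC1, PC2)) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    theme_minimal()
  if (!is.null(sample_map)) {
    p + geom_point(aes(colour = population), size = 2.5)
  } else {
    p + geom_point(size = 2.5)
  }
}

#' Plot the enrichment running sum
#'
#' Running-sum curve with hit positions marked as a rug; the dashed line
#' marks the enrichment score.
#'
#' @param object An `innate_gsea` from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.innate_gsea <- function(object, ...) {
  ggplot(object$running, aes(position, running)) +
    geom_line(colour = "#2c7fb8") +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_hline(yintercept = object$es, linetype = "dashed", colour = "#d95f02") +
    geom_rug(data = dplyr::filter(object$running, hit), sides = "b",
             colour = "grey30") +
    labs(title = sprintf("%s: ES = %.3f, p = %.3g", object$set_name,
                         object$es, object$p_perm),
         x = "rank in ordered list", y = "running enrichment score") +
    theme_minimal()
}

#' Plot per-mouse J-segment usage
#'
#' @param usage Usage tibble from [j_usage()].
#' @param highlight J segment to highlight (default `TRAJ18`).
#' @return A ggplot (one facet per mouse).
#' @export
plot_j_usage <- function(usage, highlight = "TRAJ18") {
  usage <- dplyr::mutate(usage, highlighted = j_call == highlight)
  ggplot(usage, aes(j_call, frequency, fill = highlighted)) +
    geom_col(show.legend = FALSE) +
    scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "#d95f02")) +
    facet_grid(genotype + subject_id ~ v_call) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6)) +
    labs(x = NULL, y = "frequency")
}
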