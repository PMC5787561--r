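#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.innate_gsea <- function(x, ...) tidy_gsea_row(x)

#' @export
glance.innate_gsea <- function(x, ...) tidy_gsea_row(x)

#' @export
tidy.innate_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -sample_id, names_to = "component",
                      values_to = "score")
}

#' @export
glance.innate_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_components = length(x$explained_variance),
         var_pc1 = x$explained_variance[1],
         var_pc2 = if (length(x$explained_variance) > 1) x$explained_variance[2] else NA_real_)
}

#' @export
tidy.regulator_network <- function(x, ...) x$edges

#' @export
glance.regulator_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_tf_binding = sum(x$edges$type == "tf-binding"),
         n_interaction = sum(x$edges$type != "tf-binding"))
}
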