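#' Read a typed gene-gene interaction table
#'
#' Three-column TSV (`gene_a`, `gene_b`, `type`) standing in for
#' externally retrieved interactions; `type` must be one of
#' `co-expression`, `physical`, `co-regulation`.
#'
#' @param path File path.
#' @return Interaction tibble.
#' @export
read_interactions <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_a", "gene_b", "type") %in% names(x))) {
    abort("interaction table must have columns gene_a, gene_b, type.")
  }
  check_interaction_types(x)
  x
}

interaction_types <- c("co-expression", "physical", "co-regulation")

check_interaction_types <- function(interactions) {
  bad <- which(!interactions$type %in% interaction_types)
  if (length(bad) > 0) {
    abort(sprintf("unknown interaction type '%s' at row %d (allowed: %s).",
                  interactions$type[bad[1]], bad[1],
                  paste(interaction_types, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Assemble the regulator network
#'
#' Nodes are the grouped dysregulated signature genes plus the regulator
#' itself; a `tf-binding` edge runs from the regulator to every node in
#' the target set, and typed interaction edges are kept only when both
#' endpoints are nodes.  Each gene node carries its group and an
#' expression attribute: the dysregulated lineage's log2 fold change for
#' biased genes and the mean of the two lineage log2 fold changes for
#' common (and discordant) genes; the regulator node carries 0 unless it
#' is itself grouped.
#'
#' @param grouped Classified grouped-gene tibble (groups != `none`).
#' @param tf_targets Character vector of regulator target genes (from
#'   [call_tf_targets()]).
#' @param tf_name Gene id of the regulator (e.g. `Tcf3` for E2A).
#' @param interactions Optional interaction tibble from
#'   [read_interactions()].
#' @return Object of class `regulator_network`: list with `nodes` and
#'   `edges` tibbles.  Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
build_network <- function(grouped, tf_targets, tf_name,
                          interactions = NULL) {
  grouped <- grouped[!is.na(grouped$group) & grouped$group != "none", , drop = FALSE]
  nodes <- grouped |>
    dplyr::mutate(expression = dplyr::case_when(
      group == "iNKT-biased" ~ log2fc_inkt,
      group == "gdNKT-biased" ~ log2fc_gdnkt,
      TRUE ~ (log2fc_inkt + log2fc_gdnkt) / 2
    )) |>
    dplyr::select(gene_id, group, log2fc_inkt, log2fc_gdnkt, expression)
  if (!tf_name %in% nodes$gene_id) {
    nodes <- dplyr::bind_rows(
      nodes,
      tibble(gene_id = tf_name, group = "regulator",
             log2fc_inkt = 0, log2fc_gdnkt = 0, expression = 0)
    )
  }
  nodes <- dplyr::arrange(nodes, gene_id)
  tf_edges <- tibble(source = tf_name,
                     target = sort(intersect(tf_targets, setdiff(nodes$gene_id, tf_name))),
                     type = "tf-binding")
  int_edges <- tibble(source = character(), target = character(), type = character())
  if (!is.null(interactions) && nrow(interactions) > 0) {
    check_interaction_types(interactions)
    int_edges <- interactions |>
      dplyr::filter(gene_a %in% nodes$gene_id, gene_b %in% nodes$gene_id,
                    gene_a != gene_b) |>
      dplyr::transmute(source = pmin(gene_a, gene_b),
                       target = pmax(gene_a, gene_b), type = type) |>
      dplyr::distinct() |>
      dplyr::arrange(source, target, type)
  }
  structure(list(nodes = nodes,
                 edges = dplyr::bind_rows(tf_edges, int_edges),
                 tf_name = tf_name),
            class = "regulator_network")
}

#' @export
print.regulator_network <- function(x, ...) {
  cat(sprintf("<regulator_network> regulator '%s': %d nodes, %d edges (%d tf-binding)\n",
              x$tf_name, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$type == "tf-binding")))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = as.data.frame(net$nodes))
}

#' Serialize a regulator network
#'
#' Writes any of: `sif` (`source<TAB>type<TAB>target`), `graphml`
#' (attribute-preserving, via igraph) and `tsv` (node and edge attribute
#' tables).
#'
#' @param net A `regulator_network`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("sif", "graphml", "tsv")`.
#' @param name Basename for the emitted files.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, dir, formats = c("sif", "graphml", "tsv"),
                          name = "network") {
  unknown <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(unknown) > 0) {
    abort(sprintf("unknown format(s): %s", paste(unknown, collapse = ", ")))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if ("sif" %in% formats) {
    p <- file.path(dir, paste0(name, ".sif"))
    writeLines(sprintf("%s\t%s\t%s", net$edges$source, net$edges$type,
                       net$edges$target), p)
    paths <- c(paths, p)
  }
  if ("graphml" %in% formats) {
    p <- file.path(dir, paste0(name, ".graphml"))
    igraph::write_graph(as_igraph(net), p, format = "graphml")
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    pn <- file.path(dir, paste0(name, "_nodes.tsv"))
    pe <- file.path(dir, paste0(name, "_edges.tsv"))
    readr::write_tsv(net$nodes, pn, progress = FALSE)
    readr::write_tsv(net$edges, pe, progress = FALSE)
    paths <- c(paths, pn, pe)
  }
  invisible(paths)
}

#' Read a regulator network back from GraphML
#'
#' @param path GraphML file written by [write_network()].
#' @param tf_name Regulator gene id (defaults to the node with group
#'   `regulator`, if any).
#' @return A `regulator_network`.
#' @export
read_network_graphml <- function(path, tf_name = NULL) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- as_tibble(igraph::as_data_frame(g, what = "vertices")) |>
    dplyr::select(gene_id = name, group, log2fc_inkt, log2fc_gdnkt, expression) |>
    dplyr::arrange(gene_id)
  edges <- as_tibble(igraph::as_data_frame(g, what = "edges")) |>
    dplyr::select(source = from, target = to, type)
  tf_name <- tf_name %||% nodes$gene_id[nodes$group == "regulator"][1]
  if (is.na(tf_name)) tf_name <- NA_character_
  structure(list(nodes = nodes, edges = edges, tf_name = tf_name),
            class = "regulator_network")
}
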