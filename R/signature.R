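#' Derive the innate-like gene signature from two fold-change tables
#'
#' A gene enters the signature only when it is concordantly changed in
#' *both* innate lineages relative to their conventional references:
#' direction `up` requires the iNKT-vs-alpha-beta fold change and the
#' gamma-delta-NKT-vs-gamma-delta fold change to both exceed `up_thresh`
#' (default 1.5), and direction `down` requires both to fall below
#' `down_thresh` (default 0.6).  Genes changed in one lineage only, or in
#' opposite directions, are excluded.
#'
#' @param fc_inkt Fold-change table (from [fold_change()]) for iNKT cells
#'   versus the conventional alpha-beta reference.
#' @param fc_gdnkt Fold-change table for gamma-delta NKT cells versus the
#'   conventional gamma-delta reference.
#' @param up_thresh,down_thresh Linear fold-change gates.
#' @param strict Use strict inequalities at both gates (default; "more
#'   than 1.5-fold").  `FALSE` switches to inclusive comparisons.
#' @return A signature tibble with columns `gene_id`, `direction`
#'   (`up`/`down`), `source` (`derived`), `fc_innate_ab`, `fc_innate_gd`.
#'   Genes present in only one table are dropped with a message.
#' @export
derive_signature <- function(fc_inkt, fc_gdnkt, up_thresh = 1.5,
                             down_thresh = 0.6, strict = TRUE) {
  if (up_thresh <= 1 || down_thresh >= 1 || down_thresh <= 0) {
    abort("need up_thresh > 1 and 0 < down_thresh < 1.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(fc_inkt, gene_id, fc_innate_ab = fc),
    dplyr::select(fc_gdnkt, gene_id, fc_innate_gd = fc),
    by = "gene_id"
  )
  n_dropped <- nrow(fc_inkt) + nrow(fc_gdnkt) - 2 * nrow(joined)
  if (n_dropped > 0) {
    inform(sprintf("derive_signature: %d gene entr%s present in one table only were excluded.",
                   n_dropped, if (n_dropped == 1) "y" else "ies"))
  }
  gt <- if (strict) `>` else `>=`
  lt <- if (strict) `<` else `<=`
  out <- joined |>
    dplyr::mutate(direction = dplyr::case_when(
      gt(fc_innate_ab, up_thresh) & gt(fc_innate_gd, up_thresh) ~ "up",
      lt(fc_innate_ab, down_thresh) & lt(fc_innate_gd, down_thresh) ~ "down",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(direction)) |>
    dplyr::mutate(source = "derived") |>
    dplyr::select(gene_id, direction, source, fc_innate_ab, fc_innate_gd) |>
    dplyr::arrange(gene_id)
  out
}

#' Append literature-curated genes to a derived signature
#'
#' Genes already in the derived set keep their derived direction and
#' source; genes added from the literature list carry
#' `direction = "literature"`, `source = "literature"` and no fold-change
#' values.
#'
#' @param sig Signature tibble from [derive_signature()].
#' @param literature_genes Character vector of gene ids; defaults to the
#'   packaged seven-gene list [innate_literature_genes].
#' @return Signature tibble of size `|derived| + |literature \ derived|`.
#' @export
augment_with_literature <- function(sig, literature_genes = innate_literature_genes) {
  if (length(literature_genes) == 0) abort("`literature_genes` must be non-empty.")
  extra <- setdiff(unique(literature_genes), sig$gene_id)
  dplyr::bind_rows(
    sig,
    tibble(gene_id = extra, direction = "literature", source = "literature",
           fc_innate_ab = NA_real_, fc_innate_gd = NA_real_)
  ) |>
    dplyr::arrange(gene_id)
}

#' Read and write GMT gene-set files
#'
#' GMT is the tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list.")
  }
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a signature as GMT
#'
#' Writes one gene set per direction (`<name>_up`, `<name>_down`, and
#' `<name>_literature` when present).
#'
#' @param sig Signature tibble.
#' @param path Output path.
#' @param name Base name for the sets.
#' @export
signature_to_gmt <- function(sig, path, name = "innate_signature") {
  sets <- split(sig$gene_id, sig$direction)
  names(sets) <- paste(name, names(sets), sep = "_")
  write_gmt(sets, path)
}
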